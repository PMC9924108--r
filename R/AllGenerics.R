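#' @include AllGenerics.R
NULL

#' @export
setGeneric("planId", function(x) standardGeneric("planId"))

#' @export
setGeneric("siteLabel", function(x) standardGeneric("siteLabel"))

#' @export
setGeneric("machine", function(x) standardGeneric("machine"))

#' @export
setGeneric("beams", function(x) standardGeneric("beams"))

#' @export
setGeneric("beamMu", function(x) standardGeneric("beamMu"))

#' @export
setGeneric("totalMu", function(x) standardGeneric("totalMu"))

#' @export
setGeneric("nControlPoints", function(x) standardGeneric("nControlPoints"))

#' @export
setGeneric("nLeafPairs", function(x) standardGeneric("nLeafPairs"))

#' @export
setGeneric("leafWidths", function(x) standardGeneric("leafWidths"))

#' @export
setGeneric("leafBoundaries", function(x) standardGeneric("leafBoundaries"))

#' @export
setGeneric("arcLength", function(x, ...) standardGeneric("arcLength"))

#' @export
setGeneric("validatePlan", function(x, ...) standardGeneric("validatePlan"))
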