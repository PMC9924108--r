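#' @include AllGenerics.R
NULL

## Site labels accepted for a plan.  Archetypes with a synthetic generator
## are the four study sites; OTHER is accepted for imported plans.
.SITE_LEVELS <- c("IMRS", "HN", "MED_LUNG", "PROSTATE", "OTHER")

#' MachineModel: linac geometry and dynamic limits
#'
#' Describes the multileaf collimator (MLC) and the dynamic delivery limits
#' of a linac.  All leaf geometry is expressed in mm projected to
#' isocenter, IEC 61217 coordinates.  Leaf pair index 1 is the pair at the
#' most negative y.
#'
#' @slot name profile name, e.g. \code{"HD120"}.
#' @slot leafWidths per-pair leaf widths (mm at isocenter).
#' @slot leafBoundaries \code{n + 1} strictly increasing y-coordinates (mm)
#'   of the pair boundaries, centered on the midline.
#' @slot maxDoseRate maximum dose rate (MU/min).  \code{NA} means
#'   "resolve from the beam energy label" (see \code{\link{maxDoseRate}}).
#' @slot maxGantrySpeed maximum gantry speed (deg/s).
#' @slot minGap leaf gap (mm) at or below which a pair is treated as
#'   closed (dynamic-leaf-gap convention).
#'
#' @seealso \code{\link{machineModel}}
#' @export
setClass("MachineModel",
    representation(
        name = "character",
        leafWidths = "numeric",
        leafBoundaries = "numeric",
        maxDoseRate = "numeric",
        maxGantrySpeed = "numeric",
        minGap = "numeric"
    )
)

setValidity("MachineModel", function(object) {
    msg <- character()
    w <- object@leafWidths
    b <- object@leafBoundaries
    if (length(w) < 1L || any(!is.finite(w)) || any(w <= 0))
        msg <- c(msg, "leafWidths must all be finite and > 0")
    if (length(b) != length(w) + 1L)
        msg <- c(msg, "leafBoundaries must have length(leafWidths) + 1 entries")
    else {
        if (any(diff(b) <= 0))
            msg <- c(msg, "leafBoundaries must be strictly increasing")
        if (any(abs(diff(b) - w) > 1e-6))
            msg <- c(msg, "boundary spacing must equal leafWidths")
    }
    if (length(object@maxDoseRate) != 1L)
        msg <- c(msg, "maxDoseRate must be a single value (NA for per-energy)")
    else if (!is.na(object@maxDoseRate) && object@maxDoseRate <= 0)
        msg <- c(msg, "maxDoseRate must be > 0")
    if (object@maxGantrySpeed <= 0)
        msg <- c(msg, "maxGantrySpeed must be > 0")
    if (object@minGap < 0)
        msg <- c(msg, "minGap must be >= 0")
    if (length(msg)) msg else TRUE
})

#' ArcBeam: one VMAT arc
#'
#' A dynamic arc with \code{n} control points over \code{p} leaf pairs.
#' Control-point state is stored columnar: \code{gantry} and \code{cmw}
#' are length-\code{n} vectors; \code{bankA}, \code{bankB} are
#' \code{n x p} matrices of leaf-tip x-positions (mm, isocenter plane);
#' \code{jaws} is an \code{n x 4} matrix with columns
#' \code{x1, x2, y1, y2}.  Bank A is the X1-side bank (retracts towards
#' negative x), bank B the X2 side, so the open gap of pair \code{i} is
#' \code{bankB[, i] - bankA[, i] >= 0}.
#'
#' @slot beamId beam identifier.
#' @slot beamMu beam meterset (MU, > 0).
#' @slot energy energy label, e.g. \code{"6FFF"}, \code{"10MV"}.
#' @slot direction gantry rotation direction, \code{"CW"} or \code{"CCW"}.
#' @slot gantry gantry angle per control point, deg in [0, 360).
#' @slot cmw cumulative meterset weight per control point, 0 at the first
#'   control point, 1 at the last, non-decreasing.
#' @slot bankA,bankB leaf-tip position matrices (mm).
#' @slot jaws jaw position matrix (mm), columns x1 < x2, y1 < y2.
#'
#' @seealso \code{\link{arcBeam}}, \code{\link{controlPoint}}
#' @export
setClass("ArcBeam",
    representation(
        beamId = "character",
        beamMu = "numeric",
        energy = "character",
        direction = "character",
        gantry = "numeric",
        cmw = "numeric",
        bankA = "matrix",
        bankB = "matrix",
        jaws = "matrix"
    )
)

## Structural validity only: shape and typing.  Value rules (monotone
## meterset, bank ordering, jaw ordering) are reported as data by
## validatePlan() so that deliberately broken plans can be constructed
## and diagnosed in tests and QA workflows.
setValidity("ArcBeam", function(object) {
    msg <- character()
    n <- length(object@gantry)
    if (n < 2L)
        msg <- c(msg, "an arc needs at least 2 control points")
    if (length(object@cmw) != n)
        msg <- c(msg, "cmw must have one value per control point")
    if (nrow(object@bankA) != n || nrow(object@bankB) != n)
        msg <- c(msg, "bankA/bankB must have one row per control point")
    if (ncol(object@bankA) != ncol(object@bankB))
        msg <- c(msg, "bankA and bankB must have the same number of pairs")
    if (nrow(object@jaws) != n || ncol(object@jaws) != 4L)
        msg <- c(msg, "jaws must be an n x 4 matrix (x1, x2, y1, y2)")
    if (length(object@beamMu) != 1L || !is.finite(object@beamMu))
        msg <- c(msg, "beamMu must be a single finite number")
    if (!object@direction %in% c("CW", "CCW"))
        msg <- c(msg, "direction must be 'CW' or 'CCW'")
    if (length(msg)) msg else TRUE
})

#' VMATPlan: a treatment plan
#'
#' @slot planId plan identifier.
#' @slot site treatment-site label, one of IMRS, HN, MED_LUNG, PROSTATE,
#'   OTHER.
#' @slot machine the \linkS4class{MachineModel} the plan is defined on.
#' @slot beams list of \linkS4class{ArcBeam}.
#'
#' @seealso \code{\link{vmatPlan}}, \code{\link{validatePlan}}
#' @export
setClass("VMATPlan",
    representation(
        planId = "character",
        site = "character",
        machine = "MachineModel",
        beams = "list"
    )
)

setValidity("VMATPlan", function(object) {
    msg <- character()
    if (!object@site %in% .SITE_LEVELS)
        msg <- c(msg, paste0("site must be one of ",
                             paste(.SITE_LEVELS, collapse = ", ")))
    if (length(object@beams) < 1L)
        msg <- c(msg, "a plan needs at least one beam")
    if (!all(vapply(object@beams, is, logical(1), class2 = "ArcBeam")))
        msg <- c(msg, "beams must all be ArcBeam objects")
    else {
        p <- length(object@machine@leafWidths)
        bad <- vapply(object@beams,
                      function(b) ncol(b@bankA) != p, logical(1))
        if (any(bad))
            msg <- c(msg, sprintf(
                "beam(s) %s: leaf count does not match machine ('%s', %d pairs)",
                paste(which(bad), collapse = ", "), object@machine@name, p))
    }
    if (length(msg)) msg else TRUE
})

#' GprModel: a fitted GPR regressor
#'
#' Wraps a fitted random-forest or linear-SVR regression of gamma passing
#' rate on the six plan-complexity features, together with the feature
#' standardization statistics and the target transform used at training
#' time, so that \code{\link{predictGpr}} can reproduce the full
#' prediction pipeline.
#'
#' @slot kind \code{"rfr"} or \code{"svr"}.
#' @slot fit the underlying \pkg{randomForest} or \pkg{e1071} fit.
#' @slot featureNames training feature-column names, in order.
#' @slot center,scale feature standardization statistics (empty when the
#'   model consumes raw features).
#' @slot transformed whether targets were logit-rescaled at training time.
#' @slot transformConfig the \code{\link{transformConfig}} list used.
#'
#' @export
setClass("GprModel",
    representation(
        kind = "character",
        fit = "ANY",
        featureNames = "character",
        center = "numeric",
        scale = "numeric",
        transformed = "logical",
        transformConfig = "list"
    )
)
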