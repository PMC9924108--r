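#' @include AllClasses.R
NULL

## Built-in MLC leaf-width profiles (mm at isocenter), outer to outer.
.MLC_PROFILES <- list(
    HD120 = c(rep(5, 14), rep(2.5, 32), rep(5, 14)),
    Millennium120 = c(rep(10, 10), rep(5, 40), rep(10, 10))
)

## Maximum dose rate (MU/min) by energy label when the machine does not
## pin one: flattening-filter-free beams deliver at much higher rates.
.ENERGY_DOSE_RATE <- c("6FFF" = 1400, "10FFF" = 2400)
.DEFAULT_DOSE_RATE <- 600

#' Construct a machine model
#'
#' Builds a \linkS4class{MachineModel} from a built-in MLC profile or from
#' an explicit leaf-width vector.  Two profiles are built in, both 60-pair
#' Varian geometries: \code{"HD120"} (14 x 5 mm, 32 x 2.5 mm, 14 x 5 mm)
#' and \code{"Millennium120"} (10 x 10 mm, 40 x 5 mm, 10 x 10 mm).  Leaf
#' boundaries are derived from the widths and centered on the midline.
#'
#' The default \code{maxDoseRate = NA} defers the dose-rate ceiling to the
#' beam energy label at the time segment dynamics are derived
#' (600 MU/min for flattened beams, 1400 for 6FFF, 2400 for 10FFF); pass a
#' number to pin it for all beams.
#'
#' @param profile name of a built-in profile (see
#'   \code{\link{machineProfiles}}).
#' @param leafWidths explicit per-pair widths (mm); overrides
#'   \code{profile} geometry when given.
#' @param maxDoseRate maximum dose rate (MU/min) or \code{NA} to resolve
#'   per beam energy.
#' @param maxGantrySpeed maximum gantry speed (deg/s).
#' @param minGap leaf gap (mm) at or below which a pair counts as closed.
#' @param name display name; defaults to \code{profile}.
#' @return a \linkS4class{MachineModel}.
#' @examples
#' m <- machineModel("HD120")
#' nLeafPairs(m)
#' @export
machineModel <- function(profile = "HD120", leafWidths = NULL,
                         maxDoseRate = NA_real_, maxGantrySpeed = 4.8,
                         minGap = 0.5, name = profile) {
    if (is.null(leafWidths)) {
        if (!profile %in% names(.MLC_PROFILES))
            stop("unknown MLC profile '", profile, "'; available: ",
                 paste(names(.MLC_PROFILES), collapse = ", "))
        leafWidths <- .MLC_PROFILES[[profile]]
    }
    span <- sum(leafWidths)
    boundaries <- cumsum(c(0, leafWidths)) - span / 2
    new("MachineModel",
        name = name,
        leafWidths = as.numeric(leafWidths),
        leafBoundaries = boundaries,
        maxDoseRate = as.numeric(maxDoseRate),
        maxGantrySpeed = as.numeric(maxGantrySpeed),
        minGap = as.numeric(minGap))
}

#' Built-in MLC profile names
#' @return character vector of profile names accepted by
#'   \code{\link{machineModel}}.
#' @export
machineProfiles <- function() names(.MLC_PROFILES)

#' Resolve the dose-rate ceiling for a beam energy
#'
#' @param machine a \linkS4class{MachineModel}.
#' @param energy energy label (e.g. \code{"6FFF"}); only consulted when
#'   the machine's own \code{maxDoseRate} is \code{NA}.
#' @return maximum dose rate in MU/min.
#' @export
maxDoseRate <- function(machine, energy = "") {
    if (!is.na(machine@maxDoseRate))
        return(machine@maxDoseRate)
    key <- toupper(gsub("\\s", "", energy))
    if (key %in% names(.ENERGY_DOSE_RATE))
        unname(.ENERGY_DOSE_RATE[[key]])
    else
        .DEFAULT_DOSE_RATE
}

#' @describeIn machineModel number of leaf pairs.
#' @param x a \linkS4class{MachineModel}.
#' @export
setMethod("nLeafPairs", "MachineModel", function(x) length(x@leafWidths))

#' @describeIn machineModel per-pair leaf widths (mm).
#' @export
setMethod("leafWidths", "MachineModel", function(x) x@leafWidths)

#' @describeIn machineModel pair boundary y-coordinates (mm).
#' @export
setMethod("leafBoundaries", "MachineModel", function(x) x@leafBoundaries)

setMethod("show", "MachineModel", function(object) {
    cat("MachineModel '", object@name, "': ",
        length(object@leafWidths), " leaf pairs, span [",
        object@leafBoundaries[1], ", ",
        object@leafBoundaries[length(object@leafBoundaries)], "] mm\n",
        "  max dose rate: ",
        if (is.na(object@maxDoseRate)) "per-energy" else
            paste0(object@maxDoseRate, " MU/min"),
        "; max gantry speed: ", object@maxGantrySpeed,
        " deg/s; min gap: ", object@minGap, " mm\n", sep = "")
})
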