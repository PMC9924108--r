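#' @include machine.R
NULL

#' Construct an arc beam
#'
#' @param beamId beam identifier.
#' @param beamMu beam meterset (MU).
#' @param gantry gantry angle per control point (deg, [0, 360)).
#' @param cmw cumulative meterset weight per control point; any
#'   non-negative non-decreasing sequence is accepted and normalized to
#'   final value 1 when \code{normalize = TRUE} (DICOM convention).
#' @param bankA,bankB leaf-tip position matrices, one row per control
#'   point, one column per pair (mm).  Bank A is the X1 side.
#' @param jaws either a length-4 vector \code{c(x1, x2, y1, y2)} applied
#'   to every control point or an n x 4 matrix.
#' @param energy energy label (e.g. \code{"6FFF"}).
#' @param direction \code{"CW"} or \code{"CCW"}.
#' @param normalize normalize \code{cmw} so the final value is 1.
#' @return an \linkS4class{ArcBeam}.
#' @export
arcBeam <- function(beamId, beamMu, gantry, cmw, bankA, bankB, jaws,
                    energy = "6MV", direction = "CW", normalize = TRUE) {
    n <- length(gantry)
    bankA <- as.matrix(bankA)
    bankB <- as.matrix(bankB)
    if (is.null(dim(jaws)) && length(jaws) == 4L)
        jaws <- matrix(rep(as.numeric(jaws), each = n), nrow = n)
    jaws <- as.matrix(jaws)
    colnames(jaws) <- c("x1", "x2", "y1", "y2")
    cmw <- as.numeric(cmw)
    if (normalize && n > 0L && is.finite(cmw[n]) && cmw[n] > 0)
        cmw <- cmw / cmw[n]
    new("ArcBeam", beamId = as.character(beamId), beamMu = as.numeric(beamMu),
        energy = as.character(energy), direction = match.arg(direction, c("CW", "CCW")),
        gantry = as.numeric(gantry), cmw = cmw,
        bankA = bankA, bankB = bankB, jaws = jaws)
}

#' Construct a VMAT plan
#'
#' @param planId plan identifier.
#' @param site treatment-site label (IMRS, HN, MED_LUNG, PROSTATE, OTHER).
#' @param machine a \linkS4class{MachineModel}.
#' @param beams list of \linkS4class{ArcBeam}.
#' @return a \linkS4class{VMATPlan}.
#' @export
vmatPlan <- function(planId, site, machine, beams) {
    if (is(beams, "ArcBeam")) beams <- list(beams)
    new("VMATPlan", planId = as.character(planId), site = as.character(site),
        machine = machine, beams = beams)
}

#' @describeIn vmatPlan plan identifier.
#' @param x a \linkS4class{VMATPlan}.
#' @export
setMethod("planId", "VMATPlan", function(x) x@planId)

#' @describeIn vmatPlan treatment-site label.
#' @export
setMethod("siteLabel", "VMATPlan", function(x) x@site)

#' @describeIn vmatPlan the plan's machine model.
#' @export
setMethod("machine", "VMATPlan", function(x) x@machine)

#' @describeIn vmatPlan list of beams.
#' @export
setMethod("beams", "VMATPlan", function(x) x@beams)

#' @describeIn vmatPlan total plan MU (sum of beam metersets).
#' @export
setMethod("totalMu", "VMATPlan", function(x)
    sum(vapply(x@beams, function(b) b@beamMu, numeric(1))))

#' @describeIn arcBeam beam meterset (MU).
#' @param x an \linkS4class{ArcBeam}.
#' @export
setMethod("beamMu", "ArcBeam", function(x) x@beamMu)

#' @describeIn arcBeam number of control points.
#' @export
setMethod("nControlPoints", "ArcBeam", function(x) length(x@gantry))

#' @describeIn vmatPlan control points per beam.
#' @export
setMethod("nControlPoints", "VMATPlan", function(x)
    vapply(x@beams, nControlPoints, integer(1)))

#' Extract one control point of a beam
#'
#' Returns the per-control-point view of an \linkS4class{ArcBeam}: gantry
#' angle, cumulative meterset weight, both leaf banks and the four jaws.
#'
#' @param beam an \linkS4class{ArcBeam}.
#' @param i control-point index (1-based).
#' @return a list with elements \code{gantry}, \code{cmw}, \code{bankA},
#'   \code{bankB}, \code{jaws}.
#' @export
controlPoint <- function(beam, i) {
    stopifnot(i >= 1L, i <= nControlPoints(beam))
    list(gantry = beam@gantry[i], cmw = beam@cmw[i],
         bankA = beam@bankA[i, ], bankB = beam@bankB[i, ],
         jaws = beam@jaws[i, ])
}

setMethod("show", "ArcBeam", function(object) {
    cat("ArcBeam '", object@beamId, "': ", object@beamMu, " MU, ",
        nControlPoints(object), " control points, ", object@energy, ", ",
        object@direction, ", gantry ", object@gantry[1], " -> ",
        object@gantry[nControlPoints(object)], " deg (arc ",
        round(arcLength(object), 1), " deg)\n", sep = "")
})

setMethod("show", "VMATPlan", function(object) {
    cat("VMATPlan '", object@planId, "' [", object@site, "] on ",
        object@machine@name, ": ", length(object@beams), " beam(s), ",
        round(totalMu(object), 1), " MU total\n", sep = "")
    for (b in object@beams) show(b)
})

## Signed gantry steps on the shortest-path unwrapped scale: each step is
## mapped into [-180, 180), which is unambiguous for VMAT sampling (~2 deg
## between control points) and handles the 0/360 seam.
.gantrySteps <- function(gantry) {
    d <- diff(gantry)
    ((d + 180) %% 360) - 180
}

#' Unwrap a gantry-angle series
#'
#' Maps a [0, 360) gantry series to a continuous series by taking each
#' step on the shortest path around the circle, removing the 0/360 seam
#' (359.9 followed by 0.1 becomes a +0.2 step).  Used when differencing
#' angles, e.g. for delivery-log comparison.
#'
#' @param gantry numeric vector of angles in degrees.
#' @return numeric vector, same length, starting at \code{gantry[1]}.
#' @export
unwrapAngles <- function(gantry) {
    if (length(gantry) < 2L) return(gantry)
    gantry[1] + c(0, cumsum(.gantrySteps(gantry)))
}

#' @describeIn arcLength total unwrapped gantry angle traversed by a beam
#'   (deg, >= 0); 0 for a static-gantry beam.
#' @export
setMethod("arcLength", "ArcBeam", function(x, ...)
    sum(abs(.gantrySteps(x@gantry))))

#' Arc length of a beam or plan
#'
#' The total gantry angle traversed, unwrapped around the 0/360 seam.  A
#' full arc from 181 deg clockwise through 0 to 179 deg reports 358 deg;
#' partial arcs report their span; a static beam reports 0.
#'
#' @param x an \linkS4class{ArcBeam} or \linkS4class{VMATPlan}.
#' @param ... unused.
#' @return degrees; for a plan, a vector with one entry per beam.
#' @export
setMethod("arcLength", "VMATPlan", function(x, ...)
    vapply(x@beams, arcLength, numeric(1)))

#' Validate a plan against the domain invariants
#'
#' Checks the value rules that define a well-formed VMAT plan: bank B
#' never behind bank A, jaw ordering, meterset weight starting at 0,
#' ending at 1 and non-decreasing, gantry steps consistent with the
#' declared rotation direction, positive MU, and angles in [0, 360).
#' Violations are returned as data (a character vector naming the beam,
#' control point and rule), never raised, so broken plans can be
#' diagnosed.
#'
#' @param x a \linkS4class{VMATPlan}.
#' @param tol numeric tolerance for endpoint and ordering checks.
#' @param ... unused.
#' @return character vector of violations; \code{character(0)} when the
#'   plan is valid.
#' @export
setMethod("validatePlan", "VMATPlan", function(x, tol = 1e-6, ...) {
    out <- character()
    if (!(totalMu(x) > 0))
        out <- c(out, "plan: total MU must be > 0")
    for (bi in seq_along(x@beams)) {
        b <- x@beams[[bi]]
        id <- sprintf("beam %d ('%s')", bi, b@beamId)
        n <- nControlPoints(b)
        if (!(b@beamMu > 0))
            out <- c(out, sprintf("%s: beam MU must be > 0", id))
        if (any(b@gantry < 0 | b@gantry >= 360))
            out <- c(out, sprintf("%s: gantry angles must lie in [0, 360)", id))
        if (abs(b@cmw[1]) > tol)
            out <- c(out, sprintf(
                "%s: first cumulative meterset weight is %.6g, expected 0",
                id, b@cmw[1]))
        if (abs(b@cmw[n] - 1) > tol)
            out <- c(out, sprintf(
                "%s: last cumulative meterset weight is %.6g, expected 1",
                id, b@cmw[n]))
        dec <- which(diff(b@cmw) < -tol)
        for (k in dec)
            out <- c(out, sprintf(
                "%s, control point %d: cumulative meterset weight decreases",
                id, k + 1L))
        crossed <- which(b@bankB < b@bankA - tol, arr.ind = TRUE)
        if (nrow(crossed)) {
            cps <- sort(unique(crossed[, 1]))
            for (k in cps)
                out <- c(out, sprintf(
                    "%s, control point %d: bank B behind bank A (pair %s)",
                    id, k, paste(crossed[crossed[, 1] == k, 2], collapse = ",")))
        }
        badJx <- which(b@jaws[, 1] >= b@jaws[, 2])
        badJy <- which(b@jaws[, 3] >= b@jaws[, 4])
        for (k in badJx)
            out <- c(out, sprintf("%s, control point %d: jaw x1 >= x2", id, k))
        for (k in badJy)
            out <- c(out, sprintf("%s, control point %d: jaw y1 >= y2", id, k))
        steps <- .gantrySteps(b@gantry)
        sgn <- if (b@direction == "CW") 1 else -1
        if (any(sgn * steps < -tol))
            out <- c(out, sprintf(
                "%s: gantry steps inconsistent with %s rotation", id, b@direction))
    }
    out
})

#' Derive per-segment dose rate and gantry speed
#'
#' Dose rate and gantry speed are not stored in RT Plans; they are
#' reconstructed per segment (between consecutive control points) with the
#' standard maximum-constraint delivery model: the segment time is set by
#' whichever axis is limiting,
#' \code{dt = max(dMU / DRmax, dTheta / GSmax)}, and the realized rates
#' follow as \code{DR = dMU / dt} (MU/min) and \code{GS = dTheta / dt}
#' (deg/s).  Segments with neither MU nor gantry motion get zero for both.
#' The dose-rate ceiling comes from \code{\link{maxDoseRate}} (machine
#' override or per-energy default).
#'
#' @param beam an \linkS4class{ArcBeam}.
#' @param machine a \linkS4class{MachineModel}.
#' @return a data.frame with one row per segment: \code{delta_mu} (MU),
#'   \code{delta_theta} (deg), \code{delta_t} (s), \code{dose_rate}
#'   (MU/min), \code{gantry_speed} (deg/s).
#' @examples
#' m <- machineModel("Millennium120", maxDoseRate = 600)
#' b <- arcBeam("a", 10, gantry = c(180, 182), cmw = c(0, 1),
#'              bankA = matrix(-5, 2, 60), bankB = matrix(5, 2, 60),
#'              jaws = c(-10, 10, -10, 10))
#' deriveSegmentDynamics(b, m)  # MU-limited: 1 s, DR 600, GS 2
#' @export
deriveSegmentDynamics <- function(beam, machine) {
    drMax <- maxDoseRate(machine, beam@energy)   # MU/min
    gsMax <- machine@maxGantrySpeed              # deg/s
    dmu <- diff(beam@cmw) * beam@beamMu
    dth <- abs(.gantrySteps(beam@gantry))
    dt <- pmax(dmu / (drMax / 60), dth / gsMax)
    dr <- ifelse(dt > 0, dmu / dt * 60, 0)
    gs <- ifelse(dt > 0, dth / dt, 0)
    data.frame(delta_mu = dmu, delta_theta = dth, delta_t = dt,
               dose_rate = dr, gantry_speed = gs)
}
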