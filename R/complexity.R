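#' @include aperture.R
NULL

## MU delivered in the segment following each control point (the final
## control point carries zero weight -- interval convention).  Used as the
## weight of per-control-point quantities in beam aggregates.
.segmentWeights <- function(beam) {
    c(diff(beam@cmw) * beam@beamMu, 0)
}

#' MU-weighted beam aperture aggregates
#'
#' The beam area (BA) and beam irregularity (BI): the MU-weighted means of
#' the per-control-point aperture area and aperture irregularity over the
#' arc, the weight of a control point being the MU delivered in the
#' segment that follows it (the final control point carries no weight).
#' Control points with a fully closed aperture contribute zero area; their
#' (undefined) irregularity is excluded from the BI average together with
#' its weight.
#'
#' @param beam an \linkS4class{ArcBeam}.
#' @param machine a \linkS4class{MachineModel}.
#' @return a list with \code{ba} (mm^2) and \code{bi} (dimensionless).
#' @export
beamAggregates <- function(beam, machine) {
    g <- .beamGeometry(beam, machine)
    w <- .segmentWeights(beam)
    if (!any(g$aa > 0 & w > 0))
        stop("beam '", beam@beamId,
             "': aperture closed at every weighted control point; ",
             "BA/BI undefined")
    ba <- sum(w * g$aa) / sum(w)
    ok <- !is.na(g$ai)
    bi <- sum(w[ok] * g$ai[ok]) / sum(w[ok])
    list(ba = ba, bi = bi)
}

#' Plan-averaged beam area and irregularity
#'
#' PA and PI: the per-beam BA and BI values averaged over beams with the
#' beam MUs as weighting factors.
#'
#' @param plan a \linkS4class{VMATPlan}.
#' @return a list with \code{pa} (mm^2) and \code{pi} (dimensionless).
#' @export
planAggregates <- function(plan) {
    mu <- vapply(plan@beams, beamMu, numeric(1))
    agg <- lapply(plan@beams, beamAggregates, machine = plan@machine)
    ba <- vapply(agg, `[[`, numeric(1), "ba")
    bi <- vapply(agg, `[[`, numeric(1), "bi")
    list(pa = sum(mu * ba) / sum(mu), pi = sum(mu * bi) / sum(mu))
}

## Per-beam mean leaf travel (mm): total |leaf displacement| summed over
## segments, averaged over participating leaves.
.beamLeafTravel <- function(beam, machine,
                            participation = c("ever-open", "all")) {
    participation <- match.arg(participation)
    travelA <- colSums(abs(diff(beam@bankA)))
    travelB <- colSums(abs(diff(beam@bankB)))
    if (participation == "all") {
        part <- rep(TRUE, ncol(beam@bankA))
    } else {
        g <- .beamGeometry(beam, machine)
        part <- colSums(g$open) > 0
    }
    if (!any(part)) return(0)
    mean(c(travelA[part], travelB[part]))
}

#' Leaf travel per arc length
#'
#' Per beam, LT is the mean over participating leaves of the total
#' distance each leaf tip travels across the arc's segments; a leaf
#' participates when its pair is open (after jaw clipping) at any control
#' point, and both banks' leaves are counted individually.  LT is divided
#' by the beam's arc length (deg), and the per-beam ratios are aggregated
#' to the plan with beam-MU weights, mirroring the PA/PI rule.
#'
#' @param plan a \linkS4class{VMATPlan}.
#' @param participation \code{"ever-open"} (default) restricts the average
#'   to leaves of pairs ever open within the jaws; \code{"all"} averages
#'   over every leaf of both banks.
#' @return plan-level LT/AL in mm/deg.
#' @export
leafTravelPerArcLength <- function(plan, participation = c("ever-open", "all")) {
    participation <- match.arg(participation)
    mu <- vapply(plan@beams, beamMu, numeric(1))
    al <- arcLength(plan)
    if (any(al <= 0))
        stop("leaf travel per arc length undefined: beam(s) ",
             paste(which(al <= 0), collapse = ", "),
             " have zero arc length")
    lt <- vapply(plan@beams, .beamLeafTravel, numeric(1),
                 machine = plan@machine, participation = participation)
    sum(mu * lt / al) / sum(mu)
}

#' Mean dose-rate and gantry-speed variation
#'
#' Per beam, the summed absolute changes of the reconstructed segment dose
#' rate and gantry speed across consecutive segments, each divided by the
#' beam's arc length; aggregated to the plan with beam-MU weights.  A beam
#' delivered at constant dose rate (e.g. every segment MU-limited)
#' contributes zero dose-rate variation.
#'
#' @param plan a \linkS4class{VMATPlan}.
#' @return a list with \code{dr_variation} ((MU/min)/deg) and
#'   \code{gs_variation} ((deg/s)/deg).
#' @seealso \code{\link{deriveSegmentDynamics}}
#' @export
dynamicsVariations <- function(plan) {
    mu <- vapply(plan@beams, beamMu, numeric(1))
    al <- arcLength(plan)
    if (any(al <= 0))
        stop("dynamics variations undefined: beam(s) ",
             paste(which(al <= 0), collapse = ", "),
             " have zero arc length")
    per <- vapply(plan@beams, function(b) {
        dyn <- deriveSegmentDynamics(b, plan@machine)
        c(sum(abs(diff(dyn$dose_rate))), sum(abs(diff(dyn$gantry_speed))))
    }, numeric(2))
    drv <- per[1, ] / al
    gsv <- per[2, ] / al
    list(dr_variation = sum(mu * drv) / sum(mu),
         gs_variation = sum(mu * gsv) / sum(mu))
}

#' Compute the six plan-complexity features
#'
#' Assembles the plan-level modulation indices used as GPR predictors:
#' plan-averaged beam area (PA, mm^2), plan-averaged beam irregularity
#' (PI), total MU, leaf travel per arc length (mm/deg), mean dose-rate
#' variation ((MU/min)/deg) and mean gantry-speed variation ((deg/s)/deg).
#'
#' @param plan a \linkS4class{VMATPlan}.
#' @param intermediates also return the per-control-point (AA, AP, AI) and
#'   per-beam (BA, BI) intermediates as attributes \code{"controlPoints"}
#'   and \code{"beams"}.
#' @return a one-row data.frame with columns \code{plan_id}, \code{site},
#'   \code{PA_mm2}, \code{PI}, \code{total_MU}, \code{LT_per_AL},
#'   \code{DR_var}, \code{GS_var}.
#' @examples
#' plan <- generatePlan(planGeneratorConfig("PROSTATE", seed = 1))
#' computeFeatures(plan)
#' @export
computeFeatures <- function(plan, intermediates = FALSE) {
    agg <- planAggregates(plan)
    dyn <- dynamicsVariations(plan)
    out <- data.frame(
        plan_id = plan@planId, site = plan@site,
        PA_mm2 = agg$pa, PI = agg$pi, total_MU = totalMu(plan),
        LT_per_AL = leafTravelPerArcLength(plan),
        DR_var = dyn$dr_variation, GS_var = dyn$gs_variation,
        stringsAsFactors = FALSE)
    if (intermediates) {
        cpTab <- do.call(rbind, lapply(seq_along(plan@beams), function(bi) {
            b <- plan@beams[[bi]]
            g <- .beamGeometry(b, plan@machine)
            data.frame(plan_id = plan@planId, beam = b@beamId,
                       control_point = seq_along(g$aa),
                       AA_mm2 = g$aa, AP_mm = g$ap, AI = g$ai)
        }))
        beamTab <- do.call(rbind, lapply(plan@beams, function(b) {
            a <- beamAggregates(b, plan@machine)
            data.frame(plan_id = plan@planId, beam = b@beamId,
                       MU = b@beamMu, BA_mm2 = a$ba, BI = a$bi)
        }))
        attr(out, "controlPoints") <- cpTab
        attr(out, "beams") <- beamTab
    }
    out
}

#' Complexity features for a cohort of plans
#'
#' @param plans list of \linkS4class{VMATPlan}.
#' @return a data.frame with one row per plan (columns as
#'   \code{\link{computeFeatures}}).
#' @export
planComplexity <- function(plans) {
    do.call(rbind, lapply(plans, computeFeatures))
}

## Names of the feature columns fed to the regression models.
.FEATURE_COLS <- c("PA_mm2", "PI", "total_MU", "LT_per_AL", "DR_var", "GS_var")

#' Feature column names
#'
#' The six predictor columns of a \code{\link{computeFeatures}} table, in
#' canonical order: PA, PI, total MU, LT/AL, DR variation, GS variation.
#' @return character vector of column names.
#' @export
featureColumns <- function() .FEATURE_COLS
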