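#' @include plan-model.R
NULL

#' Write a plan to the JSON plan dialect
#'
#' Serializes a \linkS4class{VMATPlan} to a plain JSON dialect:
#' \preformatted{
#' {"plan_id": ..., "site": ...,
#'  "machine": {"profile": ..., "overrides": {...}},
#'  "beams": [{"beam_id": ..., "mu": ..., "energy": ..., "direction": ...,
#'             "control_points": [{"gantry": ..., "cmw": ...,
#'                                 "bank_a": [...], "bank_b": [...],
#'                                 "jaws": [x1, x2, y1, y2]}, ...]}]}
#' }
#' The round trip through \code{\link{readPlanJSON}} preserves every
#' field to the serialized precision (17 significant digits).
#'
#' @param plan a \linkS4class{VMATPlan}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePlanJSON <- function(plan, path) {
    m <- plan@machine
    obj <- list(
        plan_id = plan@planId,
        site = plan@site,
        machine = list(
            profile = m@name,
            overrides = list(
                max_dose_rate = m@maxDoseRate,
                max_gantry_speed = m@maxGantrySpeed,
                min_gap = m@minGap)),
        beams = lapply(plan@beams, function(b) list(
            beam_id = b@beamId,
            mu = b@beamMu,
            energy = b@energy,
            direction = b@direction,
            control_points = lapply(seq_len(nControlPoints(b)), function(i)
                list(gantry = b@gantry[i], cmw = b@cmw[i],
                     bank_a = b@bankA[i, ], bank_b = b@bankB[i, ],
                     jaws = unname(b@jaws[i, ]))))))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    invisible(path)
}

.jsonRequire <- function(x, fields, what) {
    miss <- setdiff(fields, names(x))
    if (length(miss))
        stop("invalid plan JSON: ", what, " missing field(s) ",
             paste(miss, collapse = ", "))
}

#' Read a plan from the JSON plan dialect
#'
#' Parses and validates the dialect written by \code{\link{writePlanJSON}}.
#' Structural problems (missing fields, ragged leaf banks, leaf counts
#' that do not match the machine profile) raise descriptive errors naming
#' the beam and control point.
#'
#' @param path path to a plan JSON file.
#' @return a \linkS4class{VMATPlan}.
#' @export
readPlanJSON <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE)
    .jsonRequire(obj, c("plan_id", "site", "machine", "beams"), "plan")
    .jsonRequire(obj$machine, "profile", "machine")
    ov <- obj$machine$overrides
    num <- function(x, default) {
        x <- suppressWarnings(as.numeric(unlist(x)))
        if (length(x) == 1L) x else default
    }
    machine <- machineModel(
        obj$machine$profile,
        maxDoseRate = num(ov$max_dose_rate, NA_real_),
        maxGantrySpeed = num(ov$max_gantry_speed, 4.8),
        minGap = num(ov$min_gap, 0.5))
    p <- nLeafPairs(machine)
    beams <- lapply(seq_along(obj$beams), function(bi) {
        b <- obj$beams[[bi]]
        .jsonRequire(b, c("beam_id", "mu", "control_points"),
                     sprintf("beam %d", bi))
        cps <- b$control_points
        if (length(cps) < 2L)
            stop("invalid plan JSON: beam ", bi, " has fewer than 2 control points")
        for (ci in seq_along(cps)) {
            .jsonRequire(cps[[ci]], c("gantry", "cmw", "bank_a", "bank_b", "jaws"),
                         sprintf("beam %d control point %d", bi, ci))
            if (length(cps[[ci]]$bank_a) != p || length(cps[[ci]]$bank_b) != p)
                stop("invalid plan JSON: beam ", bi, " control point ", ci,
                     " has ", length(cps[[ci]]$bank_a), "/",
                     length(cps[[ci]]$bank_b), " leaf positions against a ",
                     p, "-pair machine")
        }
        arcBeam(b$beam_id, b$mu,
                gantry = vapply(cps, `[[`, numeric(1), "gantry"),
                cmw = vapply(cps, `[[`, numeric(1), "cmw"),
                bankA = do.call(rbind, lapply(cps, function(cp) unlist(cp$bank_a))),
                bankB = do.call(rbind, lapply(cps, function(cp) unlist(cp$bank_b))),
                jaws = do.call(rbind, lapply(cps, function(cp) unlist(cp$jaws))),
                energy = if (!is.null(b$energy)) b$energy else "6MV",
                direction = if (!is.null(b$direction)) b$direction else "CW",
                normalize = FALSE)
    })
    vmatPlan(obj$plan_id, obj$site, machine, beams)
}
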