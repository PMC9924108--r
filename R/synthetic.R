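#' @include complexity.R
NULL

## Site archetype defaults.  The four archetypes emulate the qualitative
## complexity structure of a mixed VMAT cohort: radiosurgery (IMRS) plans
## have small, jagged, heavily modulated apertures and large MU;
## prostate plans have large, smooth, stable apertures with low MU
## variability; head-and-neck and mediastinum/lung sit between.
.SITE_ARCHETYPES <- list(
    IMRS = list(
        n_beams = 6L, n_control_points = 180L, gantry_span = 358,
        aperture_scale = 7, irregularity_level = 2.6, modulation_level = 1.6,
        rotation_per_cp = 1.0, mu_range = c(1800, 3400), mu_shape = 2,
        machine_profile = "HD120", energy = "6FFF"),
    HN = list(
        n_beams = 2L, n_control_points = 180L, gantry_span = 358,
        aperture_scale = 16, irregularity_level = 2.0, modulation_level = 1.8,
        rotation_per_cp = 0.8, mu_range = c(450, 780), mu_shape = 4,
        machine_profile = "Millennium120", energy = "6FFF"),
    MED_LUNG = list(
        n_beams = 2L, n_control_points = 111L, gantry_span = 220,
        aperture_scale = 20, irregularity_level = 1.4, modulation_level = 1.2,
        rotation_per_cp = 0.6, mu_range = c(600, 2200), mu_shape = 5,
        machine_profile = "Millennium120", energy = "6FFF"),
    PROSTATE = list(
        n_beams = 1L, n_control_points = 180L, gantry_span = 358,
        aperture_scale = 27, irregularity_level = 0.5, modulation_level = 1.0,
        rotation_per_cp = 0.4, mu_range = c(560, 720), mu_shape = 12,
        machine_profile = "Millennium120", energy = "10MV")
)

#' Plan-generator configuration
#'
#' Returns the generator settings for one synthetic plan, starting from a
#' treatment-site archetype and applying any overrides.  The archetypes
#' (IMRS, HN, MED_LUNG, PROSTATE) differ in aperture scale, boundary
#' irregularity, control-point-to-control-point leaf modulation, beam
#' count, MU range and MU-per-segment variability, so that the six
#' plan-level complexity metrics separate by site: IMRS has the smallest
#' plan-averaged beam area and highest irregularity, prostate the largest
#' area, lowest irregularity and least MU variability.
#'
#' @param site one of \code{"IMRS"}, \code{"HN"}, \code{"MED_LUNG"},
#'   \code{"PROSTATE"}.
#' @param ... overrides of archetype fields: \code{n_beams},
#'   \code{n_control_points}, \code{gantry_span} (deg),
#'   \code{aperture_scale} (mm, characteristic target radius),
#'   \code{irregularity_level} (mm, per-leaf boundary noise SD),
#'   \code{modulation_level} (mm, per-control-point leaf jitter SD),
#'   \code{rotation_per_cp} (deg of target rotation per control point),
#'   \code{mu_range} (MU), \code{mu_shape} (gamma shape of per-segment
#'   meterset weights; smaller = burstier delivery),
#'   \code{machine_profile}, \code{energy}.
#' @param seed integer seed making \code{\link{generatePlan}}
#'   deterministic, or \code{NULL} to draw from the current RNG stream.
#' @return a list of generator settings (class
#'   \code{"PlanGeneratorConfig"}).
#' @export
planGeneratorConfig <- function(site, ..., seed = NULL) {
    site <- match.arg(site, names(.SITE_ARCHETYPES))
    cfg <- .SITE_ARCHETYPES[[site]]
    dots <- list(...)
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad))
        stop("unknown generator field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
    cfg$site <- site
    cfg$seed <- seed
    stopifnot(cfg$n_beams >= 1L, cfg$n_control_points >= 2L,
              cfg$aperture_scale > 0, cfg$irregularity_level >= 0,
              cfg$modulation_level >= 0)
    structure(cfg, class = "PlanGeneratorConfig")
}

## One synthetic arc: leaf openings trace the chords of a slowly rotating
## ellipse, perturbed per leaf (static boundary irregularity) and per
## control point (AR(1)-smoothed modulation jitter).
.generateBeam <- function(beamId, beamMu, cfg, machine, direction) {
    n <- cfg$n_control_points
    p <- nLeafPairs(machine)
    bnd <- machine@leafBoundaries
    yMid <- (bnd[-1] + bnd[-(p + 1)]) / 2

    ## gantry path
    span <- cfg$gantry_span
    s0 <- runif(1, 0, 360)
    step <- if (n > 1) span / (n - 1) else 0
    ang <- s0 + step * (seq_len(n) - 1) * (if (direction == "CW") 1 else -1)
    gantry <- ang %% 360

    ## meterset weights: gamma increments, burstier for small mu_shape
    dw <- rgamma(n - 1, shape = cfg$mu_shape, rate = 1)
    dw <- pmax(dw, 1e-9)
    cmw <- c(0, cumsum(dw))
    cmw <- cmw / cmw[length(cmw)]

    ## rotating elliptical target
    a <- cfg$aperture_scale * runif(1, 0.85, 1.15)
    b <- cfg$aperture_scale * runif(1, 0.70, 1.05)
    phi0 <- runif(1, 0, pi)
    rot <- cfg$rotation_per_cp * pi / 180
    cx <- rnorm(1, 0, 0.10 * cfg$aperture_scale)
    cy <- rnorm(1, 0, 0.15 * cfg$aperture_scale)
    driftAmp <- 1.5 * cfg$modulation_level
    driftPh <- runif(1, 0, 2 * pi)

    phi <- phi0 + rot * (seq_len(n) - 1)
    cxk <- cx + driftAmp * sin(2 * pi * seq_len(n) / n + driftPh)

    ## chords of the rotated ellipse at each leaf midline (n x p)
    A <- outer(cos(phi)^2 / a^2 + sin(phi)^2 / b^2, rep(1, p))
    B <- outer(2 * sin(phi) * cos(phi) * (1 / a^2 - 1 / b^2), rep(1, p))
    C <- outer(sin(phi)^2 / a^2 + cos(phi)^2 / b^2, rep(1, p))
    Y <- outer(rep(1, n), yMid - cy)
    disc <- (B * Y)^2 - 4 * A * (C * Y^2 - 1)
    openTarget <- disc > 0
    root <- sqrt(pmax(disc, 0))
    xLo <- (-B * Y - root) / (2 * A)
    xHi <- (-B * Y + root) / (2 * A)

    ## static per-leaf irregularity + AR(1) per-control-point jitter
    irrA <- rnorm(p, 0, cfg$irregularity_level)
    irrB <- rnorm(p, 0, cfg$irregularity_level)
    jitA <- .ar1Noise(n, p, cfg$modulation_level)
    jitB <- .ar1Noise(n, p, cfg$modulation_level)

    bankA <- cxk + xLo + rep(irrA, each = n) + jitA
    bankB <- cxk + xHi + rep(irrB, each = n) + jitB
    ## closed pairs park at the target center
    bankA[!openTarget] <- cxk[row(bankA)[!openTarget]]
    bankB[!openTarget] <- bankA[!openTarget]
    ## noise may cross the banks: close those pairs
    crossed <- bankB < bankA
    if (any(crossed)) {
        mid <- (bankA[crossed] + bankB[crossed]) / 2
        bankA[crossed] <- mid
        bankB[crossed] <- mid
    }

    ## static jaws enclosing every opening with a small margin
    anyOpen <- openTarget & (bankB - bankA) > machine@minGap
    if (!any(anyOpen))
        stop("degenerate generator settings: aperture never opens")
    margin <- 2
    jx1 <- min(bankA[anyOpen]) - margin
    jx2 <- max(bankB[anyOpen]) + margin
    openPairs <- which(colSums(anyOpen) > 0)
    jy1 <- bnd[min(openPairs)] - margin
    jy2 <- bnd[max(openPairs) + 1L] + margin

    arcBeam(beamId, beamMu, gantry, cmw, bankA, bankB,
            jaws = c(jx1, jx2, jy1, jy2),
            energy = cfg$energy, direction = direction, normalize = FALSE)
}

## n x p matrix of AR(1) noise with stationary SD `sd` (rho fixed at 0.7:
## leaf jitter is correlated between neighbouring control points).
.ar1Noise <- function(n, p, sd) {
    if (sd <= 0) return(matrix(0, n, p))
    rho <- 0.7
    eps <- matrix(rnorm(n * p, 0, sd), n, p)
    eps[1, ] <- eps[1, ]
    for (k in seq_len(n)[-1])
        eps[k, ] <- rho * eps[k - 1, ] + sqrt(1 - rho^2) * eps[k, ]
    eps
}

#' Generate one synthetic VMAT plan
#'
#' Draws a plan from a site archetype: each arc's leaf openings trace the
#' chords of a smoothly rotating ellipse of characteristic radius
#' \code{aperture_scale}, perturbed per leaf by a static boundary noise
#' (\code{irregularity_level}) and per control point by smoothed leaf
#' jitter (\code{modulation_level}); meterset weights follow gamma
#' increments whose shape controls dose-rate burstiness.  The result
#' always passes \code{\link{validatePlan}}, and is deterministic given
#' \code{(config, seed)}.
#'
#' @param config a \code{\link{planGeneratorConfig}}.
#' @param seed overrides \code{config$seed} when given.
#' @return a \linkS4class{VMATPlan}.
#' @examples
#' p <- generatePlan(planGeneratorConfig("IMRS", seed = 7))
#' validatePlan(p)  # character(0)
#' @export
generatePlan <- function(config, seed = config$seed) {
    if (!is.null(seed)) set.seed(seed)
    machine <- machineModel(config$machine_profile)
    nb <- config$n_beams
    ## plan-to-plan heterogeneity within a site: modulation and boundary
    ## irregularity vary around the archetype level
    config$modulation_level <- config$modulation_level * runif(1, 0.5, 1.5)
    config$irregularity_level <- config$irregularity_level * runif(1, 0.7, 1.3)
    totalMU <- runif(1, config$mu_range[1], config$mu_range[2])
    wb <- rgamma(nb, shape = 8, rate = 1)
    beamMUs <- totalMU * wb / sum(wb)
    beams <- lapply(seq_len(nb), function(k)
        .generateBeam(sprintf("arc%d", k), beamMUs[k], config, machine,
                      direction = if (k %% 2L == 1L) "CW" else "CCW"))
    vmatPlan(sprintf("%s-%06d", config$site,
                     if (is.null(seed)) sample.int(999999L, 1) else
                         seed %% 1000000L),
             config$site, machine, beams)
}

#' Response-model configuration for simulated GPR
#'
#' Settings of the clipped linear-Gaussian model that turns the six
#' z-scored plan-complexity features into a simulated gamma passing rate:
#' \code{gpr = clip(intercept + sum(coef * z) + noise, clip[1], clip[2])}.
#' The default coefficients follow the sign pattern observed for measured
#' GPR (positive for PA and GS variation; negative for PI, total MU,
#' LT/AL and DR variation) and were calibrated once, against a large
#' reference cohort from the default generator, so that the empirical
#' feature-GPR Pearson correlations of a default cohort land on the
#' strong/moderate/weak pattern reported for clinical plans
#' (about +0.72 PA, -0.67 PI, -0.66 MU, +0.62 GS, -0.50 DR, -0.38 LT/AL).
#' They are a calibration device, not a physical model.
#'
#' @param intercept mean GPR (percent) at cohort-average complexity.
#' @param coefficients named numeric vector, one weight (GPR percentage
#'   points per SD) per feature column.
#' @param noise_sd SD of the Gaussian measurement noise (GPR points).
#' @param clip length-2 lower/upper clipping bounds; the upper bound is
#'   100 (a passing rate cannot exceed 100).
#' @return a list of response settings (class \code{"ResponseConfig"}).
#' @export
responseConfig <- function(intercept = 95.5,
                           coefficients = c(
                               PA_mm2 = 0.05, PI = -0.05, total_MU = -0.66,
                               LT_per_AL = -0.17, DR_var = -0.49,
                               GS_var = 1.01),
                           noise_sd = 1.0,
                           clip = c(80, 100)) {
    stopifnot(noise_sd >= 0, length(clip) == 2L, clip[2] == 100,
              all(featureColumns() %in% names(coefficients)))
    structure(list(intercept = intercept,
                   coefficients = coefficients[featureColumns()],
                   noise_sd = noise_sd, clip = clip),
              class = "ResponseConfig")
}

#' Simulate gamma passing rates from complexity features
#'
#' Applies the clipped linear-Gaussian response model of
#' \code{\link{responseConfig}} to a feature table.  Features are z-scored
#' with the supplied cohort statistics (or, by default, with the table's
#' own mean/SD -- cohort-level standardization), so the simulated GPR of a
#' plan is reproducible given the cohort it was generated in.
#'
#' @param features a data.frame containing the six feature columns.
#' @param config a \code{\link{responseConfig}}.
#' @param zstats optional list with \code{mean} and \code{sd} named
#'   vectors over the feature columns; defaults to the cohort's own.
#' @param seed optional integer seed for the noise draw.
#' @return numeric vector of simulated GPR (percent), clipped to
#'   \code{config$clip}.
#' @export
simulateGpr <- function(features, config = responseConfig(), zstats = NULL,
                        seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    x <- as.matrix(features[, featureColumns(), drop = FALSE])
    if (is.null(zstats))
        zstats <- list(mean = colMeans(x), sd = apply(x, 2, stats::sd))
    sds <- ifelse(zstats$sd > 0, zstats$sd, 1)
    z <- sweep(sweep(x, 2, zstats$mean), 2, sds, "/")
    g <- config$intercept +
        drop(z %*% config$coefficients[featureColumns()]) +
        rnorm(nrow(x), 0, config$noise_sd)
    unname(pmin(pmax(g, config$clip[1]), config$clip[2]))
}

#' Default cohort composition
#'
#' Site counts in the proportions of the reference clinical mix (40 IMRS,
#' 25 head and neck, 28 mediastinum/lung, 25 prostate out of 118), scaled
#' to \code{n} by largest remainder.
#'
#' @param n total number of plans.
#' @return named integer vector of per-site counts summing to \code{n}.
#' @export
defaultCohortCounts <- function(n = 118L) {
    base <- c(IMRS = 40, HN = 25, MED_LUNG = 28, PROSTATE = 25)
    raw <- base / sum(base) * n
    cnt <- floor(raw)
    rem <- n - sum(cnt)
    if (rem > 0) {
        up <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
        cnt[up] <- cnt[up] + 1
    }
    out <- as.integer(cnt)
    names(out) <- names(base)
    out
}

#' Generate a synthetic QA cohort
#'
#' Generates a cohort of synthetic VMAT plans across the four site
#' archetypes, computes their six plan-complexity features, and simulates
#' a measured gamma passing rate for each plan with the clipped
#' linear-Gaussian response model.  The returned metadata records the
#' master seed, per-plan seeds, the generative response settings and the
#' cohort z-scoring statistics, so downstream parameter-recovery tests can
#' reconstruct the ground truth.
#'
#' @param counts named per-site plan counts (see
#'   \code{\link{defaultCohortCounts}}).
#' @param seed master seed; the whole cohort is deterministic given
#'   \code{(counts, seed, response, overrides)}.
#' @param response a \code{\link{responseConfig}}.
#' @param overrides optional named list of per-site generator overrides,
#'   e.g. \code{list(IMRS = list(n_beams = 2))}.
#' @return a list with \code{plans} (list of \linkS4class{VMATPlan}),
#'   \code{features} (data.frame), \code{qa} (data.frame with
#'   \code{plan_id}, \code{gpr}), and \code{meta}.
#' @examples
#' coh <- generateQACohort(defaultCohortCounts(24), seed = 11)
#' head(coh$qa)
#' @export
generateQACohort <- function(counts = defaultCohortCounts(), seed = 1L,
                             response = responseConfig(),
                             overrides = list()) {
    stopifnot(all(names(counts) %in% names(.SITE_ARCHETYPES)),
              all(counts >= 0))
    set.seed(seed)
    total <- sum(counts)
    planSeeds <- sample.int(.Machine$integer.max - 1L, total)
    sites <- rep(names(counts), counts)
    plans <- vector("list", total)
    for (i in seq_len(total)) {
        ov <- overrides[[sites[i]]]
        cfg <- do.call(planGeneratorConfig,
                       c(list(site = sites[i], seed = planSeeds[i]), ov))
        plans[[i]] <- generatePlan(cfg)
        plans[[i]]@planId <- sprintf("%s-%03d", sites[i],
                                     sum(sites[seq_len(i)] == sites[i]))
    }
    features <- planComplexity(plans)
    x <- as.matrix(features[, featureColumns()])
    zstats <- list(mean = colMeans(x), sd = apply(x, 2, stats::sd))
    gpr <- simulateGpr(features, response, zstats, seed = seed + 1L)
    list(plans = plans,
         features = features,
         qa = data.frame(plan_id = features$plan_id, gpr = gpr,
                         stringsAsFactors = FALSE),
         meta = list(seed = seed, counts = counts, response = response,
                     zstats = zstats, plan_seeds = planSeeds))
}
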