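mach <- machineModel("Millennium120", maxDoseRate = 600)

## beam whose aperture is a fixed rectangle at every control point
rectBeam <- function(gap, nPairs = 2, n = 3, mu = 100, cmw = NULL,
                     gantrySpan = 60) {
    p <- nLeafPairs(mach)
    bankA <- matrix(0, n, p)
    bankB <- matrix(0, n, p)
    pairs <- 30:(30 + nPairs - 1)
    bankA[, pairs] <- -gap / 2
    bankB[, pairs] <- gap / 2
    if (is.null(cmw)) cmw <- seq(0, 1, length.out = n)
    arcBeam("r", mu, gantry = (180 + gantrySpan * (seq_len(n) - 1) / (n - 1)) %% 360,
            cmw = cmw, bankA = bankA, bankB = bankB,
            jaws = c(-60, 60, -100, 100), energy = "6MV", direction = "CW",
            normalize = FALSE)
}

test_that("beam aggregates are segment-MU-weighted means of AA and AI", {
    ## 3 control points, aperture 10x10 at cp1/2 and 20x10 at cp3;
    ## equal segment MU puts weight 1/2 on each of cp1, cp2 (cp3 has none)
    b <- rectBeam(10, n = 3)
    b@bankA[3, 30:31] <- -10
    b@bankB[3, 30:31] <- 10
    agg <- beamAggregates(b, mach)
    expect_equal(agg$ba, 100)               # final cp carries no weight
    expect_equal(agg$bi, 4 / pi)

    ## weights 1:3 on apertures of area 50 and 100
    b2 <- rectBeam(5, nPairs = 1, n = 3, cmw = c(0, 0.25, 1))
    b2@bankA[2, 30] <- -10; b2@bankB[2, 30] <- 10   # 100 mm2 at cp2
    expect_equal(beamAggregates(b2, mach)$ba, (1 * 25 + 3 * 100) / 4)

    ## constant aperture: BA = AA, BI = AI regardless of weighting
    b3 <- rectBeam(10, n = 5, cmw = c(0, 0.1, 0.6, 0.9, 1))
    agg3 <- beamAggregates(b3, mach)
    expect_equal(agg3$ba, 100)
    expect_equal(agg3$bi, 4 / pi)

    closed <- rectBeam(0)
    expect_error(beamAggregates(closed, mach), "closed")
})

test_that("plan aggregates are beam-MU-weighted and bounded by their inputs", {
    b1 <- rectBeam(10, mu = 100)           # BA 100
    b2 <- rectBeam(20, mu = 300)           # BA 200
    plan <- vmatPlan("p", "OTHER", mach, list(b1, b2))
    agg <- planAggregates(plan)
    expect_equal(agg$pa, (100 * 100 + 300 * 200) / 400)

    single <- vmatPlan("s", "OTHER", mach, list(b1))
    aggS <- planAggregates(single)
    expect_equal(aggS$pa, beamAggregates(b1, mach)$ba)
    expect_equal(aggS$pi, beamAggregates(b1, mach)$bi)

    ## weighted means stay inside [min, max] of the per-beam values
    set.seed(9)
    for (i in 1:10) {
        plans <- generatePlan(planGeneratorConfig("HN"))
        bas <- vapply(beams(plans), function(b)
            beamAggregates(b, machine(plans))$ba, numeric(1))
        pa <- planAggregates(plans)$pa
        expect_gte(pa, min(bas) - 1e-9)
        expect_lte(pa, max(bas) + 1e-9)
    }
})

test_that("leaf travel averages participating leaves and scales linearly", {
    ## one pair translating 0 -> 10 -> 20 mm over a 60 deg arc: both of its
    ## leaves travel 20 mm, all other leaves frozen and closed
    b <- onePairBeam(mach, pair = 30, centers = c(0, 10, 20), gaps = rep(10, 3))
    plan <- vmatPlan("p", "OTHER", mach, b)
    expect_equal(leafTravelPerArcLength(plan), 20 / 60)

    ## no motion at all
    b0 <- onePairBeam(mach, 30, c(0, 0, 0), rep(10, 3))
    expect_equal(leafTravelPerArcLength(vmatPlan("q", "OTHER", mach, b0)), 0)

    ## doubling every excursion doubles LT/AL
    b2 <- onePairBeam(mach, 30, c(0, 20, 40), rep(10, 3))
    expect_equal(leafTravelPerArcLength(vmatPlan("r", "OTHER", mach, b2)),
                 2 * leafTravelPerArcLength(plan))

    ## averaging over all leaves dilutes by the closed ones
    expect_lt(leafTravelPerArcLength(plan, participation = "all"),
              leafTravelPerArcLength(plan))

    static <- onePairBeam(mach, 30, c(0, 10), c(10, 10), gantrySpan = 0)
    expect_error(
        leafTravelPerArcLength(vmatPlan("s", "OTHER", mach, static)),
        "zero arc length")
})

test_that("dynamics variations sum absolute rate changes per degree", {
    ## segment MU chosen so DR = 600, 300, 600 MU/min over a 120 deg arc:
    ## MU-limited segments need dmu = DRmax * dtheta / GSmax / 60
    m <- machineModel("Millennium120", maxDoseRate = 600, maxGantrySpeed = 4.8)
    ## 4 cps, 3 segments of 40 deg each; dt_gantry = 40/4.8 = 8.333 s
    ## DR 600 -> dmu = 83.33; DR 300 -> dmu = 41.67 (gantry-limited)
    dmu <- c(600, 300, 600) / 60 * (40 / 4.8)
    mu <- sum(dmu)
    cmw <- c(0, cumsum(dmu)) / mu
    b <- onePairBeam(m, 30, centers = rep(0, 4), gaps = rep(10, 4),
                     mu = mu, gantrySpan = 120, cmw = cmw)
    plan <- vmatPlan("p", "OTHER", m, b)
    dyn <- deriveSegmentDynamics(b, m)
    expect_equal(dyn$dose_rate, c(600, 300, 600))
    dv <- dynamicsVariations(plan)
    expect_equal(dv$dr_variation, (300 + 300) / 120)

    ## every segment MU-limited: constant DR, zero DR variation
    bConst <- onePairBeam(m, 30, rep(0, 4), rep(10, 4), mu = 1000,
                          gantrySpan = 120)
    dynC <- deriveSegmentDynamics(bConst, m)
    expect_true(all(dynC$dose_rate == 600))
    expect_equal(dynamicsVariations(
        vmatPlan("q", "OTHER", m, bConst))$dr_variation, 0)

    ## constant gantry speed: zero GS variation
    expect_equal(dynamicsVariations(
        vmatPlan("r", "OTHER", m,
                 onePairBeam(m, 30, rep(0, 4), rep(10, 4), mu = 1,
                             gantrySpan = 120)))$gs_variation, 0)
})

test_that("features are translation-invariant and expose intermediates", {
    plan <- generatePlan(planGeneratorConfig("HN", seed = 21))
    f <- computeFeatures(plan, intermediates = TRUE)
    expect_true(all(is.finite(unlist(f[featureColumns()]))))
    expect_gte(f$PI, 1)
    cpTab <- attr(f, "controlPoints")
    beamTab <- attr(f, "beams")
    expect_true(all(c("AA_mm2", "AP_mm", "AI") %in% names(cpTab)))
    expect_true(all(c("BA_mm2", "BI", "MU") %in% names(beamTab)))

    ## shift every leaf and jaw by +5 mm: all six features unchanged
    shifted <- plan
    shifted@beams <- lapply(shifted@beams, function(b) {
        b@bankA <- b@bankA + 5
        b@bankB <- b@bankB + 5
        b@jaws[, 1:2] <- b@jaws[, 1:2] + 5
        b
    })
    fs <- computeFeatures(shifted)
    for (cl in featureColumns())
        expect_equal(fs[[cl]], f[[cl]], tolerance = 1e-9)
})
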