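test_that("plan generation is deterministic and always valid", {
    cfg <- planGeneratorConfig("HN", seed = 99)
    p1 <- generatePlan(cfg)
    p2 <- generatePlan(cfg)
    expect_equal(p1, p2)
    for (site in c("IMRS", "HN", "MED_LUNG", "PROSTATE")) {
        p <- generatePlan(planGeneratorConfig(site, seed = 3))
        expect_identical(validatePlan(p), character(0))
        expect_equal(siteLabel(p), site)
    }
    expect_error(planGeneratorConfig("HN", nonsense = 1), "unknown generator field")
})

test_that("noise-free settings freeze the aperture and leaf travel", {
    cfg <- planGeneratorConfig("PROSTATE", irregularity_level = 0,
                               modulation_level = 0, rotation_per_cp = 0,
                               n_beams = 1L, seed = 8)
    plan <- generatePlan(cfg)
    b <- beams(plan)[[1]]
    ## every control point identical -> no leaf motion at all
    expect_equal(max(abs(diff(b@bankA))), 0)
    expect_equal(leafTravelPerArcLength(plan), 0)
    ## with rotation restored the aperture turns but stays the same size
    cfgR <- planGeneratorConfig("PROSTATE", irregularity_level = 0,
                                modulation_level = 0, n_beams = 1L, seed = 8)
    planR <- generatePlan(cfgR)
    expect_gt(leafTravelPerArcLength(planR), 0)
})

test_that("site archetypes reproduce the cross-site complexity ordering", {
    coh <- cachedCohort(240, seed = 404)
    f <- coh$features
    med <- function(cl, site) median(f[[cl]][f$site == site])
    ## area: prostate largest, radiosurgery smallest
    expect_gt(med("PA_mm2", "PROSTATE"), med("PA_mm2", "HN"))
    expect_gt(med("PA_mm2", "HN"), med("PA_mm2", "IMRS"))
    ## irregularity: radiosurgery highest, prostate lowest
    expect_gt(med("PI", "IMRS"), med("PI", "PROSTATE"))
    ## prostate has the least total-MU variability
    sds <- tapply(f$total_MU, f$site, sd)
    expect_equal(names(which.min(sds)), "PROSTATE")
})

test_that("simulated GPR follows the clipped linear-Gaussian response", {
    coh <- cachedCohort(240, seed = 404)
    f <- coh$features
    ## zero noise, zero z-scores: exactly the intercept
    rc0 <- responseConfig(noise_sd = 0)
    zst <- coh$meta$zstats
    atMean <- f[1, ]
    atMean[featureColumns()] <- as.list(zst$mean)
    expect_equal(simulateGpr(atMean, rc0, zst), rc0$intercept)

    ## clipping: a huge intercept pins everything at exactly 100
    rcHi <- responseConfig(intercept = 150, noise_sd = 0)
    expect_true(all(simulateGpr(f, rcHi) == 100))

    ## all simulated values in [lower clip, 100]
    expect_true(all(coh$qa$gpr >= 80 & coh$qa$gpr <= 100))
    ## concentration just below 100, as for measured passing rates
    expect_gte(mean(coh$qa$gpr > 90), 0.9)
})

test_that("feature-GPR correlations carry the expected sign pattern", {
    coh <- cachedCohort(240, seed = 404)
    cc <- sapply(featureColumns(), function(cl)
        cor(coh$features[[cl]], coh$qa$gpr))
    expect_true(all(sign(cc) == c(1, -1, -1, -1, -1, 1)))
    ## strong predictors clearly dominate the weakest
    expect_gt(abs(cc["PA_mm2"]), abs(cc["LT_per_AL"]))
})

test_that("cohort composition and reproducibility", {
    expect_equal(defaultCohortCounts(118),
                 c(IMRS = 40L, HN = 25L, MED_LUNG = 28L, PROSTATE = 25L))
    expect_equal(sum(defaultCohortCounts(500)), 500L)
    c1 <- generateQACohort(defaultCohortCounts(12), seed = 77)
    c2 <- generateQACohort(defaultCohortCounts(12), seed = 77)
    expect_equal(c1$features, c2$features)
    expect_equal(c1$qa, c2$qa)
    expect_equal(nrow(c1$features), 12L)
    ## metadata lets a single plan be regenerated
    i <- 5L
    cfg <- planGeneratorConfig(c1$features$site[i],
                               seed = c1$meta$plan_seeds[i])
    again <- computeFeatures(generatePlan(cfg))
    expect_equal(again$PA_mm2, c1$features$PA_mm2[i])
})

test_that("site ANOVA separates the archetypes on PA and PI", {
    coh <- cachedCohort(240, seed = 404)
    an <- siteAnova(coh$features)
    expect_lt(an$p[an$feature == "PA_mm2"], 0.05)
    expect_lt(an$p[an$feature == "PI"], 0.05)
})
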