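test_that("repeated hold-out evaluation is reproducible and internally consistent", {
    coh <- cachedCohort(120, seed = 55)
    ev1 <- repeatedHoldoutEval(coh$features, coh$qa$gpr, kinds = "svr",
                               eval = evalConfig(n_repeats = 8, seed = 4))
    ev2 <- repeatedHoldoutEval(coh$features, coh$qa$gpr, kinds = "svr",
                               eval = evalConfig(n_repeats = 8, seed = 4))
    expect_identical(ev1$per_repeat, ev2$per_repeat)
    expect_identical(ev1$summary, ev2$summary)

    ## power-mean inequality on every repeat
    expect_true(all(ev1$per_repeat$rmse >= ev1$per_repeat$mae))
    expect_true(all(ev1$per_repeat$mae >= 0))
    expect_true(all(ev1$per_repeat$frac_within >= 0 &
                    ev1$per_repeat$frac_within <= 1))
    ## 30% of 120 plans held out
    expect_equal(ev1$n_test, 36L)
    expect_error(
        repeatedHoldoutEval(coh$features[1:5, ], coh$qa$gpr[1:5]),
        "at least 10")
})

test_that("a leaked linear response evaluates to near-perfect scores", {
    coh <- cachedCohort(120, seed = 55)
    ## GPR exactly linear in the features, kept off the clipping bound,
    ## fitted with the raw-target SVR: errors at numerical noise level
    g <- 95 + 2 * scale(coh$features$PA_mm2)[, 1]
    ev <- repeatedHoldoutEval(coh$features, g, kinds = "svr",
                              transform = transformConfig(applyTo = "none"),
                              eval = evalConfig(n_repeats = 5, seed = 9))
    ## the epsilon-insensitive tube (0.5 in target units) bounds how close
    ## the fit can get, but the signal is recovered almost perfectly
    expect_gt(ev$summary$r2_mean, 0.95)
    expect_lt(ev$summary$mae_mean, 0.5)
    expect_equal(ev$summary$frac_within, 1)
})

test_that("a mean-only response yields non-positive test R2", {
    coh <- cachedCohort(120, seed = 55)
    set.seed(31)
    gNoise <- rnorm(nrow(coh$features), 95, 1)   # independent of features
    ev <- repeatedHoldoutEval(coh$features, gNoise, kinds = "svr",
                              eval = evalConfig(n_repeats = 10, seed = 2))
    expect_lt(ev$summary$r2_mean, 0.2)
})

test_that("permutation importance isolates informative features", {
    rcPA <- responseConfig(
        coefficients = c(PA_mm2 = 2, PI = -0.5, total_MU = -0.5,
                         LT_per_AL = 0, DR_var = -0.2, GS_var = 0.3),
        noise_sd = 0)
    coh <- cachedCohort(150, seed = 61, response = rcPA)
    n <- nrow(coh$features)
    set.seed(7)
    te <- sample.int(n, 50)
    fit <- fitGprModel(coh$features[-te, ], coh$qa$gpr[-te], "rfr", seed = 3)
    imp <- permutationImportance(fit, coh$features[te, ], coh$qa$gpr[te],
                                 n_shuffles = 30, seed = 12)
    ## the dominant generative weight ranks first
    expect_equal(imp$feature[1], "PA_mm2")
    ## the zero-coefficient feature is statistically indistinguishable
    ## from unimportant
    lt <- imp[imp$feature == "LT_per_AL", ]
    expect_lt(abs(lt$importance), 2 * lt$sd + 1e-8)
})

test_that("correlation report categorizes by the published boundaries", {
    coh <- cachedCohort(120, seed = 55)
    f <- coh$features
    ## perfectly linear response: r = 1, very strong
    rep1 <- correlationReport(f, 2 * f$PA_mm2)
    expect_equal(rep1$r[rep1$feature == "PA_mm2"], 1, tolerance = 1e-12)
    expect_equal(rep1$category[rep1$feature == "PA_mm2"], "very strong")

    ## construct a response with exact sample correlation 0.45 to PA
    x <- scale(f$PA_mm2)[, 1]
    set.seed(5)
    e <- rnorm(length(x))
    e <- resid(lm(e ~ x))
    e <- e / sd(e) * sqrt((length(x) - 1) / length(x))
    xn <- x / sd(x) * sqrt((length(x) - 1) / length(x))
    y <- 0.45 * xn + sqrt(1 - 0.45^2) * e
    repM <- correlationReport(f, y)
    expect_equal(repM$r[repM$feature == "PA_mm2"], 0.45, tolerance = 1e-9)
    expect_equal(repM$category[repM$feature == "PA_mm2"], "moderate")

    ## a constant column is undefined, not an error
    fc <- f
    fc$GS_var <- 1
    repC <- correlationReport(fc, coh$qa$gpr)
    expect_true(is.na(repC$r[repC$feature == "GS_var"]))
    expect_equal(repC$category[repC$feature == "GS_var"], "undefined")
})

test_that("independent noise shows near-zero correlation at large n", {
    coh <- cachedCohort(240, seed = 404)
    set.seed(1234)
    y <- rnorm(nrow(coh$features))
    rep0 <- correlationReport(coh$features, y)
    expect_true(all(abs(rep0$r) < 0.2))
})

test_that("one-way site ANOVA matches the textbook hand computation", {
    ## groups (1,2,3) vs (7,8,9): SSB = 3*(2-5)^2 + 3*(8-5)^2 = 54 on 1 df,
    ## SSW = 2 + 2 = 4 on 4 df -> F = 54 / 1 = 54
    vals <- c(1, 2, 3, 7, 8, 9)
    f <- as.data.frame(setNames(rep(list(vals), 6), featureColumns()))
    f$site <- rep(c("A", "B"), each = 3)
    an <- siteAnova(f)
    expect_equal(an$F, rep(54, 6))
    expect_equal(an$p, rep(pf(54, 1, 4, lower.tail = FALSE), 6))
    expect_equal(an$df_between, rep(1, 6))

    bad <- f[c(1, 4, 5, 6), ]
    expect_error(siteAnova(bad), "at least 2 observations")
})
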