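machWide <- machineModel("Millennium120")

test_that("clipping and closed-pair rules shape the aperture", {
    cp <- list(bankA = rep(0, 60), bankB = rep(0, 60),
               jaws = c(-50, 50, -10, 10))
    cp$bankA[30] <- -5; cp$bankB[30] <- 5      # pair 30 spans y in [-5, 0]
    sh <- clippedOpenings(cp, machWide)
    expect_equal(nrow(sh), 1L)
    expect_equal(apertureArea(sh), 50)          # 10 mm gap x 5 mm leaf
    expect_equal(aperturePerimeter(sh), 30)

    ## jaws cut the 10 mm opening to 4 mm
    cpj <- cp; cpj$jaws <- c(-2, 2, -10, 10)
    shj <- clippedOpenings(cpj, machWide)
    expect_equal(shj$x_hi - shj$x_lo, 4)

    ## clipped gap at or below min_gap counts as closed
    cpg <- cp; cpg$bankA[30] <- -0.2; cpg$bankB[30] <- 0.2
    expect_equal(nrow(clippedOpenings(cpg, machWide)), 0L)
    expect_equal(apertureArea(clippedOpenings(cpg, machWide)), 0)
})

test_that("perimeter merges shared edges and keeps island boundaries", {
    cp <- list(bankA = rep(0, 60), bankB = rep(0, 60),
               jaws = c(-50, 50, -20, 20))
    ## two stacked pairs, identical [0, 10] interval -> one 10 x 10 rect
    cp$bankA[30:31] <- 0; cp$bankB[30:31] <- 10
    sh <- clippedOpenings(cp, machWide)
    expect_equal(apertureArea(sh), 100)
    expect_equal(aperturePerimeter(sh), 40)

    ## a closed pair splits the opening into two polygons
    cp2 <- cp
    cp2$bankA[32] <- 0; cp2$bankB[32] <- 0       # closed
    cp2$bankA[33] <- 0; cp2$bankB[33] <- 10
    sh2 <- clippedOpenings(cp2, machWide)
    expect_equal(apertureArea(sh2), 150)
    expect_equal(aperturePerimeter(sh2), 40 + 30)
})

test_that("aperture irregularity has its closed-form anchors", {
    ## perfect circle, supplied analytically: AI = 1
    r <- 7.3
    expect_equal(apertureIrregularity(list(area = pi * r^2,
                                           perimeter = 2 * pi * r)), 1)
    ## single square opening: AI = 4 / pi
    cp <- list(bankA = rep(0, 60), bankB = rep(0, 60),
               jaws = c(-50, 50, -20, 20))
    cp$bankA[30:31] <- -5; cp$bankB[30:31] <- 5   # 10 x 10 mm square
    sh <- clippedOpenings(cp, machWide)
    expect_equal(apertureIrregularity(sh), 4 / pi)
    ## empty shape: undefined
    empty <- clippedOpenings(list(bankA = rep(0, 60), bankB = rep(0, 60),
                                  jaws = c(-50, 50, -20, 20)), machWide)
    expect_error(apertureIrregularity(empty), "zero-area")
})

test_that("area and perimeter match the rasterization oracle on random apertures", {
    set.seed(421)
    for (profile in machineProfiles()) {
        m <- machineModel(profile)
        for (i in 1:150) {
            sh <- clippedOpenings(randomControlPoint(m), m)
            ora <- rasterOracle(sh)
            expect_equal(apertureArea(sh), ora$area, tolerance = 1e-12)
            expect_equal(aperturePerimeter(sh), ora$perimeter,
                         tolerance = 1e-12)
            if (nrow(sh) > 0)
                expect_gte(apertureIrregularity(sh), 4 / pi - 1e-12)
        }
    }
})

test_that("shrinking the jaw window never increases aperture area", {
    set.seed(77)
    m <- machineModel("HD120")
    for (i in 1:40) {
        cp <- randomControlPoint(m)
        a0 <- apertureArea(clippedOpenings(cp, m))
        cp2 <- cp
        cp2$jaws <- cp$jaws + c(abs(rnorm(1, 0, 5)), -abs(rnorm(1, 0, 5)),
                                abs(rnorm(1, 0, 5)), -abs(rnorm(1, 0, 5)))
        if (cp2$jaws[1] >= cp2$jaws[2] || cp2$jaws[3] >= cp2$jaws[4]) next
        expect_lte(apertureArea(clippedOpenings(cp2, m)), a0 + 1e-12)
    }
})
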