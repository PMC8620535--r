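test_that("band profile is symmetric, positive, peaked at the centre", {
    g <- seq(900, 1100, 0.25)
    p <- lineShapeParams(10, 10, "amplitude")
    y <- bandProfile(1000, 2, p, g)
    expect_true(all(y >= 0))
    expect_equal(g[which.max(y)], 1000)
    expect_equal(max(y), 2)
    # symmetry f(1000 + d) == f(1000 - d)
    expect_equal(y, rev(y))
    # monotone on each side of the maximum
    apex <- which.max(y)
    expect_true(all(diff(y[1:apex]) >= 0))
    expect_true(all(diff(y[apex:length(y)]) <= 0))
    # zero intensity gives a zero profile
    expect_identical(bandProfile(1000, 0, p, g), numeric(length(g)))
})

test_that("product profile FWHM does not exceed either factor width", {
    g <- seq(-200, 200, 0.01)
    for (w in list(c(8, 8), c(8, 30), c(30, 8))) {
        y <- bandProfile(0, 1, lineShapeParams(w[1], w[2], "amplitude"), g)
        half <- range(g[y >= 0.5])
        expect_lte(diff(half), min(w) * 1.001)
    }
})

test_that("area-proportional mode conserves intensity against quadrature", {
    g <- seq(1000 - 50 * 8, 1000 + 50 * 8, 0.2)
    p <- lineShapeParams(8, 8, "area")
    y <- bandProfile(1000, 5, p, g)
    got <- sum((y[-1] + y[-length(y)]) * diff(g)) / 2
    expect_equal(got, 5, tolerance = 1e-6)
    # independent adaptive-quadrature oracle on the same height
    h <- max(y)
    expect_equal(quadArea(h, 1000, 8, 8), 5, tolerance = 1e-6)
})

test_that("width limits recover the pure Lorentzian and Gaussian", {
    g <- seq(-100, 100, 0.5)
    lor <- 1 / (1 + 4 * (g / 12)^2)
    gau <- exp(-4 * log(2) * (g / 12)^2)
    yL <- bandProfile(0, 1, lineShapeParams(1e6, 12, "amplitude"), g)
    yG <- bandProfile(0, 1, lineShapeParams(12, 1e6, "amplitude"), g)
    expect_equal(yL, lor, tolerance = 1e-6)
    expect_equal(yG, gau, tolerance = 1e-6)
})

test_that("synthesis is linear and additive over class filters", {
    set.seed(3)
    m <- ModeBasis(sort(runif(5, 500, 3000)), rep("x", 5))
    led <- buildTransitionLedger(m, randomChi(5))
    led <- generateIntensities(led, seed = 1)
    g <- seq(200, 7000, 1)
    p <- lineShapeParams(8, 8)
    all <- absorbances(synthesizeSpectrum(led, p, g))
    parts <- sapply(c("fundamental", "first_overtone",
                      "binary_combination"),
                    function(cl) absorbances(
                        synthesizeSpectrum(led, p, g, classFilter = cl)))
    expect_equal(all, rowSums(parts), tolerance = 1e-10)
    # empty ledger gives the zero spectrum
    none <- synthesizeSpectrum(filterTransitions(led, region = c(1, 2)),
                               p, g)
    expect_identical(absorbances(none), numeric(length(g)))
    # single transition equals its own band profile
    one <- filterTransitions(led, classes = "fundamental",
                             region = c(positions(led)[1] - 0.5,
                                        positions(led)[1] + 0.5))
    expect_equal(absorbances(synthesizeSpectrum(one, p, g)),
                 bandProfile(positions(one), intensities(one), p, g))
})

test_that("area-proportional synthesis conserves total ledger intensity", {
    set.seed(8)
    m <- ModeBasis(sort(runif(4, 800, 2000)), rep("x", 4))
    led <- generateIntensities(buildTransitionLedger(m, randomChi(4)),
                               seed = 2)
    g <- seq(0, 5000, 0.5)  # covers every band by >> 50 widths
    sp <- synthesizeSpectrum(led, lineShapeParams(8, 8, "area"), g)
    integral <- sum((absorbances(sp)[-1] + absorbances(sp)[-length(g)]) *
                    diff(g)) / 2
    expect_equal(integral, sum(intensities(led)), tolerance = 1e-6)
})

test_that("contribution map double-counts combinations and sums to the spectrum for fundamentals", {
    m <- ModeBasis(c(800, 1200, 2900), c("γCH", "δCH", "νCH"))
    chi <- AnharmonicConstants(matrix(0, 3, 3))
    p <- lineShapeParams(8, 8)
    g <- seq(400, 6500, 1)

    fundOnly <- buildTransitionLedger(m, chi, maxOrder = 1,
                                      intensityRule = 2)
    map <- modeContributionMap(fundOnly, p, g)
    expect_identical(dim(map), c(3L, length(g)))
    expect_equal(colSums(map),
                 absorbances(synthesizeSpectrum(fundOnly, p, g)))
    # each row holds exactly one band
    expect_equal(unname(apply(map, 1, function(r) sum(r > max(r) / 2) > 0)),
                 rep(TRUE, 3))

    # a single combination contributes fully to both rows
    comb <- TransitionLedger(m, data.frame(
        quanta = "1:1+2:1", position = 2000, intensity = 1,
        class = "binary_combination", label = "γCH + δCH"))
    mapC <- modeContributionMap(comb, p, g)
    expect_equal(mapC[1, ], mapC[2, ])
    expect_identical(unname(mapC[3, ]), numeric(length(g)))
    expect_equal(max(mapC[1, ]),
                 max(bandProfile(2000, 1, p, g)))

    # empty ledger gives the zero matrix
    empty <- TransitionLedger(m, transitions(comb)[0, ])
    expect_identical(sum(modeContributionMap(empty, p, g)), 0)
})

test_that("contribution maps export as CSV with mode-label headers", {
    m <- ModeBasis(c(900, 1400), c("γCH", "δring"))
    led <- buildTransitionLedger(m, AnharmonicConstants(matrix(0, 2, 2)))
    g <- seq(800, 3000, 2)
    map <- modeContributionMap(led, lineShapeParams(8, 8), g)
    f <- tempfile(fileext = ".csv")
    writeContributionMap(map, g, f)
    back <- utils::read.csv(f, check.names = FALSE)
    expect_identical(back$mode, rownames(map))
    expect_equal(as.numeric(back[1, -1]), unname(map[1, ]), tolerance = 1e-6)
})
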