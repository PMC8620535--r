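test_that("region fractions sum to one, are width-invariant and equal intensity ratios", {
    set.seed(21)
    m <- ModeBasis(sort(runif(6, 900, 1600)), rep("δCH", 6))
    led <- generateIntensities(buildTransitionLedger(m, randomChi(6)),
                               seed = 4)
    region <- c(range(positions(led))[1] - 400,
                range(positions(led))[2] + 400)
    ref <- regionFractions(integrateClassFractions(
        led, region = region, method = "intensity"))
    for (w in c(4, 8, 16)) {
        rep <- integrateClassFractions(led, lineShapeParams(w, w),
                                       region = region)
        fr <- regionFractions(rep)
        expect_lt(abs(sum(fr) - 1), 1e-9)
        expect_equal(unname(fr), unname(ref), tolerance = 1e-6)
    }
})

test_that("degenerate regions are reported as undefined or trivial", {
    m <- ModeBasis(1000, "δCH")
    led <- buildTransitionLedger(m, AnharmonicConstants(matrix(-5)),
                                 maxOrder = 1, intensityRule = 3)
    one <- integrateClassFractions(led, region = c(400, 1800))
    expect_equal(regionFractions(one)[["fundamental"]], 1, tolerance = 1e-9)
    # two classes of equal intensity split 50/50
    m2 <- twoModeBasis()
    tr <- data.frame(quanta = c("1:1", "1:1+2:1"),
                     position = c(1000, 1200), intensity = c(2, 2),
                     class = c("fundamental", "binary_combination"),
                     label = c("a", "a + b"))
    led2 <- TransitionLedger(m2, tr)
    fr2 <- regionFractions(integrateClassFractions(led2,
                                                   region = c(200, 2200)))
    expect_equal(fr2[["fundamental"]], 0.5, tolerance = 1e-9)
    expect_equal(fr2[["binary_combination"]], 0.5, tolerance = 1e-9)
    # empty region: total zero, fractions flagged NA
    none <- integrateClassFractions(led, region = c(5000, 6000))
    expect_identical(regionTotal(none), 0)
    expect_true(all(is.na(regionFractions(none))))
})

test_that("peak picking finds isolated bands, refines positions, skips flat spectra", {
    g <- seq(1300, 1700, 0.7)
    p <- lineShapeParams(8, 8, "amplitude")
    sp <- Spectrum(g, bandProfile(1500.3, 1, p, g))
    pk <- pickPeaks(sp, minProminence = 0.1)
    expect_identical(nrow(pk), 1L)
    expect_lt(abs(pk$position - 1500.3), 0.5)
    # flat spectrum: no peaks
    expect_identical(nrow(pickPeaks(Spectrum(g, rep(1, length(g))))), 0L)
    # resolved doublet: two equal bands 50 cm-1 apart, width 8
    sp2 <- Spectrum(g, bandProfile(1450, 1, p, g) +
                        bandProfile(1500, 1, p, g))
    pk2 <- pickPeaks(sp2, minProminence = 0.1)
    expect_identical(nrow(pk2), 2L)
    expect_equal(pk2$position, c(1450, 1500), tolerance = 0.5)
})

test_that("prominence filtering suppresses shoulders of larger bands", {
    g <- seq(800, 1200, 0.5)
    p <- lineShapeParams(10, 10, "amplitude")
    y <- bandProfile(1000, 1, p, g) + bandProfile(1012, 0.05, p, g)
    pk <- pickPeaks(Spectrum(g, y), minProminence = 0.1)
    expect_identical(nrow(pk), 1L)
})

test_that("greedy matching reproduces spec'd single-pair examples", {
    rec <- matchPeaks(3310, 3360, tolerance = 60)
    expect_identical(nrow(rec), 1L)
    expect_equal(rec$difference, -50)
    expect_equal(matchPeaks(1500, 1500, tolerance = 10)$difference, 0)
    # outside tolerance both sides are reported unmatched
    none <- matchPeaks(1000, 1100, tolerance = 60)
    expect_identical(nrow(none), 0L)
    expect_equal(attr(none, "unmatchedExp"), 1000)
    expect_equal(attr(none, "unmatchedCalc")$position, 1100)
})

test_that("matching is invariant under permutation of the inputs", {
    set.seed(31)
    exp <- runif(8, 1000, 1400)
    calc <- runif(10, 1000, 1400)
    for (meth in c("greedy", "optimal")) {
        a <- matchPeaks(exp, calc, tolerance = 30, method = meth)
        b <- matchPeaks(sample(exp), sample(calc), tolerance = 30,
                        method = meth)
        expect_equal(a$expPosition, b$expPosition)
        expect_equal(a$calcPosition, b$calcPosition)
    }
})

test_that("optimal matching equals exhaustive enumeration on small instances", {
    set.seed(17)
    for (k in 1:20) {
        nE <- sample(2:5, 1); nC <- sample(2:6, 1)
        exp <- runif(nE, 1000, 1200)
        calc <- runif(nC, 1000, 1200)
        tol <- 40
        opt <- matchPeaks(exp, calc, tolerance = tol, method = "optimal")
        ref <- bruteMatch(exp, calc, tol)
        expect_identical(nrow(opt), ref$card)
        # optimal (squared-cost) matching must achieve the brute-force
        # cardinality; where greedy agrees on cardinality its cost is
        # >= the optimum
        greedy <- matchPeaks(exp, calc, tolerance = tol,
                             method = "greedy")
        expect_lte(nrow(greedy), ref$card)
        if (nrow(greedy) == ref$card)
            expect_gte(sum(abs(greedy$difference)) + 1e-12, ref$cost)
    }
})

test_that("hungarian solver matches brute-force minimum cost", {
    set.seed(13)
    for (k in 1:15) {
        n <- sample(2:6, 1)
        cost <- matrix(runif(n * n), n)
        sol <- anharmonicIR:::solveAssignment(cost)
        expect_equal(sum(cost[cbind(seq_len(n), sol)]),
                     bruteAssignment(cost)$cost, tolerance = 1e-12)
    }
})

test_that("intensity labels threshold as configured", {
    expect_identical(intensityLabel(c(1, 0.75, 0.5, 0.25, 0.05, 0.01)),
                     c("vs", "vs", "s", "m", "w", "vw"))
    expect_error(intensityLabel(1.2), "\\[0, 1\\]")
    expect_error(intensityLabel(-0.1), "\\[0, 1\\]")
    expect_error(intensityLabel(0.5, thresholds = c(vs = 0.3, s = 0.5,
                                                    m = 0.2, w = 0.1)),
                 "decreasing")
})

test_that("assignment tables renormalize to 100 and attach labels", {
    rec <- matchPeaks(c(1664, 1652, 1590), c(1692, 1679, 1609),
                      tolerance = 40, method = "optimal")
    rec$calcIntensity <- c(82.5, 100.0, 49.1)[match(rec$calcPosition,
                                                    c(1692, 1679, 1609))]
    tab <- assignmentTable(rec, expHeights = c(1, 0.97, 0.6))
    expect_equal(max(tab$calc_intensity), 100)
    expect_identical(tab$exp_intensity, c("vs", "vs", "s"))
    expect_error(assignmentTable(rec[0, ]), "non-empty")
    txt <- formatAssignmentTable(tab)
    expect_true(length(txt) == nrow(tab) + 2L)
    f <- tempfile(fileext = ".csv")
    writeAssignmentTable(tab, f, unicodeMinus = TRUE)
    expect_true(any(grepl("−", readLines(f, encoding = "UTF-8"))))
})
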