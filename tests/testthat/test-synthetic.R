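test_that("mode basis generation respects class ranges and determinism", {
    mb <- generateModeBasis(5, 2, 10, seed = 42)
    expect_identical(nModes(mb), 17L)
    wn <- modeWavenumbers(mb)
    ch <- modeCharacters(mb)
    stretch <- wn > 2500
    expect_identical(sum(stretch), 5L)
    expect_true(all(wn[stretch] >= 2950 & wn[stretch] <= 3200))
    ring <- wn > 1600 & wn <= 1750
    expect_identical(sum(ring), 2L)
    expect_true(all(wn[!stretch & !ring] >= 400 &
                    wn[!stretch & !ring] <= 1600))
    expect_true(all(grepl("^γ|^ρ", ch[wn < 1000])))
    # same seed is bit-identical
    expect_identical(mb, generateModeBasis(5, 2, 10, seed = 42))
    expect_false(identical(modeWavenumbers(mb),
                           modeWavenumbers(generateModeBasis(5, 2, 10,
                                                             seed = 43))))
    # single ring mode lands in its range
    one <- generateModeBasis(0, 1, 0, seed = 9)
    expect_true(modeWavenumbers(one) >= 1600 && modeWavenumbers(one) <= 1750)
    expect_error(generateModeBasis(0, 0, 0), "at least one")
})

test_that("generated modes honour the minimum spacing", {
    for (s in 1:5) {
        mb <- generateModeBasis(8, 3, 20, seed = s, minSpacing = 24)
        wn <- sort(modeWavenumbers(mb))
        byClass <- split(wn, cut(wn, c(0, 1600, 1800, Inf)))
        for (cl in byClass)
            if (length(cl) > 1) expect_gte(min(diff(sort(cl))), 24)
    }
})

test_that("anharmonicity generation is symmetric with the stated hierarchy", {
    mb <- generateModeBasis(4, 2, 8, seed = 2)
    chi <- generateAnharmonicity(mb, 30, 3, seed = 5)
    X <- chi@chi
    expect_true(all(X == t(X)))
    wn <- modeWavenumbers(mb)
    expect_true(all(diag(X) < 0))
    # stretches carry the largest diagonal magnitudes
    expect_gt(min(abs(diag(X)[wn > 2500])), max(abs(diag(X)[wn < 1600])))
    # zero scales give the harmonic molecule
    chi0 <- generateAnharmonicity(mb, 0, 0, seed = 5)
    expect_identical(sum(abs(chi0@chi)), 0)
    # determinism
    expect_identical(X, generateAnharmonicity(mb, 30, 3, seed = 5)@chi)
})

test_that("default anharmonicity keeps fundamentals below their harmonics", {
    mb <- generateModeBasis(8, 3, 20, seed = 1)
    chi <- generateAnharmonicity(mb, 30, 3, seed = 2)
    led <- buildTransitionLedger(mb, chi)
    tr <- transitions(led)
    fund <- tr[tr$class == "fundamental", ]
    ids <- vapply(fund$quanta, function(q)
        as.integer(names(parseQuanta(q))), 0L)
    expect_true(all(fund$position < modeWavenumbers(mb)[ids]))
})

test_that("class intensity scaling matches the configured factors", {
    mb <- generateModeBasis(6, 2, 12, seed = 3)   # 20 modes, 230 transitions
    led <- buildTransitionLedger(mb, generateAnharmonicity(mb, seed = 4))
    led <- generateIntensities(led, fundamentalMean = 50,
                               overtoneFactor = 0.02,
                               combinationFactor = 0.05, seed = 6)
    tr <- transitions(led)
    expect_true(all(tr$intensity > 0))
    ratio <- mean(tr$intensity[tr$class == "binary_combination"]) /
        mean(tr$intensity[tr$class == "fundamental"])
    expect_gt(ratio, 0.05 / 3)
    expect_lt(ratio, 0.05 * 3)
    expect_error(generateIntensities(led, overtoneFactor = 0), "\\(0, 1\\]")
    # factors 1 leave the classes statistically indistinguishable
    same <- transitions(generateIntensities(led, 50, 1, 1, seed = 6))
    expect_lt(abs(log(mean(same$intensity[same$class == "fundamental"]) /
                      mean(same$intensity[same$class ==
                                          "binary_combination"]))), 0.5)
})

test_that("observed spectrum reduces to plain synthesis at zero distortion", {
    mb <- generateModeBasis(2, 1, 4, seed = 10)
    led <- generateIntensities(buildTransitionLedger(
        mb, generateAnharmonicity(mb, seed = 11)), seed = 12)
    g <- seq(200, 7000, 1)
    obs <- generateObservedSpectrum(led, wlsB = 0, grid = g,
                                    noiseSigma = 0, baseline = c(0, 0),
                                    seed = 1)
    expect_equal(absorbances(obs),
                 absorbances(synthesizeSpectrum(led,
                                                lineShapeParams(8, 8), g)),
                 tolerance = 1e-12)
    # same seed gives identical noise
    o1 <- generateObservedSpectrum(led, grid = g, noiseSigma = 0.1, seed = 4)
    o2 <- generateObservedSpectrum(led, grid = g, noiseSigma = 0.1, seed = 4)
    expect_identical(absorbances(o1), absorbances(o2))
})

test_that("position displacement follows the inverse WLS algebra", {
    b <- -8e-6
    nu <- c(1000, 3000, 6000)
    shifted <- inverseWLS(nu, wlsParams(b = b))
    # exact inversion: applying the forward map recovers the input
    expect_equal(shifted * (1 + b * shifted), nu, tolerance = 1e-9)
    # first-order shift is -b nu^2 (positive for negative b)
    expect_equal(shifted - nu, -b * nu^2 / (1 + 2 * b * nu),
                 tolerance = 2e-3 * max(abs(shifted - nu)))
    expect_gt(shifted[2] - 3000, 70)
})

test_that("full study bundles are deterministic with exact truth", {
    cfg <- syntheticStudyConfig(nStretch = 3, nRing = 1, nBend = 6)
    st <- generateStudy(cfg, seed = 5)
    st2 <- generateStudy(cfg, seed = 5)
    expect_identical(absorbances(studyObserved(st)),
                     absorbances(studyObserved(st2)))
    expect_identical(studyTruth(st)$wls_b, studyTruth(st2)$wls_b)
    truth <- studyTruth(st)
    expect_identical(truth$seed, 5)
    # truth fractions are exact intensity ratios per region
    tr <- transitions(studyLedger(st))
    rg <- cfg$regions[["ch-stretch"]]
    inside <- tr$position >= rg[1] & tr$position <= rg[2]
    expect_equal(truth$class_fractions[["ch-stretch"]][["fundamental"]],
                 sum(tr$intensity[inside & tr$class == "fundamental"]) /
                     sum(tr$intensity[inside]))
    # harmonic, equal-intensity config: fractions equal count ratios
    cfgH <- syntheticStudyConfig(nStretch = 2, nRing = 1, nBend = 4,
                                 diagScale = 0, offdiagScale = 0,
                                 overtoneFactor = 1, combinationFactor = 1,
                                 sdlog = 0)
    stH <- generateStudy(cfgH, seed = 3)
    trH <- transitions(studyLedger(stH))
    rgAll <- c(100, 10000)
    frH <- regionFractions(integrateClassFractions(studyLedger(stH),
                                                   region = rgAll,
                                                   method = "intensity"))
    expect_equal(frH[["fundamental"]],
                 mean(trH$class == "fundamental"), tolerance = 1e-12)
})

test_that("pipeline recovers the WLS slope from a single default study", {
    st <- generateStudy(seed = 7)
    r <- evaluateStudyRecovery(st)
    expect_lt(r$bRelErr, 0.2)
    expect_gt(r$assignmentAccuracy, 0.7)
    expect_lt(max(r$fractionErrors, na.rm = TRUE), 0.02)
})

test_that("study serialization round-trips through the directory format", {
    st <- generateStudy(syntheticStudyConfig(nStretch = 2, nRing = 1,
                                             nBend = 3), seed = 2)
    d <- file.path(tempdir(), "study-rt")
    writeStudy(st, d)
    led <- readTransitions(file.path(d, "ledger.csv"))
    expect_equal(positions(led), positions(studyLedger(st)),
                 tolerance = 1e-10)
    expect_identical(transitionClasses(led),
                     transitionClasses(studyLedger(st)))
    obs <- readSpectrum(file.path(d, "observed.jdx"))
    expect_equal(absorbances(obs), absorbances(studyObserved(st)),
                 tolerance = 1e-9)
    truth <- jsonlite::fromJSON(file.path(d, "truth.json"))
    expect_equal(truth$wls_b, studyTruth(st)$wls_b, tolerance = 1e-12)
    cfg <- yaml::read_yaml(file.path(d, "config.yaml"))
    expect_equal(cfg$nStretch, 2)
})
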