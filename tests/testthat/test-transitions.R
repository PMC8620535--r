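test_that("quanta classification partitions all inputs into four classes", {
    expect_identical(classifyTransition(c(`3` = 1)), "fundamental")
    expect_identical(classifyTransition(c(`5` = 2)), "first_overtone")
    expect_identical(classifyTransition(c(`2` = 1, `7` = 1)),
                     "binary_combination")
    expect_identical(classifyTransition(c(`1` = 3)), "higher_order")
    expect_identical(classifyTransition(c(`1` = 2, `2` = 1)), "higher_order")
    expect_identical(classifyTransition(c(`1` = 1, `2` = 1, `3` = 1)),
                     "higher_order")
    # string encoding round-trips through the same classifier
    expect_identical(classifyTransition("2:1+7:1"), "binary_combination")

    set.seed(11)
    for (k in 1:50) {
        nmodes <- sample(1:4, 1)
        q <- setNames(sample(1:3, nmodes, replace = TRUE),
                      sample(1:10, nmodes))
        cls <- classifyTransition(q)
        expect_true(cls %in% c("fundamental", "first_overtone",
                               "binary_combination", "higher_order"))
        # exactly one class predicate holds
        preds <- c(length(q) == 1 && sum(q) == 1,
                   length(q) == 1 && sum(q) == 2,
                   length(q) == 2 && sum(q) == 2)
        expect_identical(cls, c("fundamental", "first_overtone",
                                "binary_combination",
                                "higher_order")[c(which(preds), 4)[1]])
    }
})

test_that("invalid quanta are rejected", {
    expect_error(classifyTransition(integer()), "non-empty")
    expect_error(classifyTransition(c(`1` = 0)), "positive")
    expect_error(classifyTransition(c(`1` = -2)), "positive")
    expect_error(classifyTransition(c(`1` = 1, `1` = 1)), "unique")
})

test_that("VPT2 positions reproduce hand-evaluated energies", {
    m <- ModeBasis(3000, "νCH")
    expect_equal(vpt2TransitionPosition(m, AnharmonicConstants(matrix(0)),
                                        c(`1` = 1)), 3000)
    chi <- AnharmonicConstants(matrix(-30))
    expect_equal(vpt2TransitionPosition(m, chi, c(`1` = 1)), 2940)
    expect_equal(vpt2TransitionPosition(m, chi, c(`1` = 2)), 5820)
})

test_that("combination shift equals chi_ij and overtone shift 2 chi_ii", {
    set.seed(42)
    for (k in 1:100) {
        n <- sample(2:5, 1)
        m <- ModeBasis(runif(n, 400, 3200), rep("x", n))
        chi <- randomChi(n)
        i <- sample(n, 1)
        j <- resample(setdiff(seq_len(n), i))
        fi <- vpt2TransitionPosition(m, chi, setNames(1L, i))
        fj <- vpt2TransitionPosition(m, chi, setNames(1L, j))
        ot <- vpt2TransitionPosition(m, chi, setNames(2L, i))
        cb <- vpt2TransitionPosition(m, chi, setNames(c(1L, 1L),
                                                      c(i, j)))
        expect_lt(abs(ot - 2 * fi - 2 * chi@chi[i, i]), 1e-9)
        expect_lt(abs(cb - fi - fj - chi@chi[i, j]), 1e-9)
    }
})

test_that("ledger enumeration has closed-form size, sorted and classified", {
    m3 <- ModeBasis(c(3000, 1600, 800), c("νCH", "νC=O", "γCH"))
    chi3 <- AnharmonicConstants(diag(c(-30, -10, -5)))
    led <- buildTransitionLedger(m3, chi3, maxOrder = 2)
    expect_identical(nTransitions(led), 9L)  # 3 + 3 + 3
    expect_identical(sum(transitionClasses(led) == "fundamental"), 3L)
    expect_identical(sum(transitionClasses(led) == "first_overtone"), 3L)
    expect_identical(sum(transitionClasses(led) == "binary_combination"), 3L)
    expect_false(is.unsorted(positions(led)))

    m1 <- ModeBasis(1000, "δCH")
    led1 <- buildTransitionLedger(m1, AnharmonicConstants(matrix(-5)),
                                  maxOrder = 1)
    expect_identical(nTransitions(led1), 1L)
    expect_identical(transitionClasses(led1), "fundamental")

    set.seed(7)
    m10 <- ModeBasis(sort(runif(10, 400, 3200)), rep("x", 10))
    led10 <- buildTransitionLedger(m10, randomChi(10), maxOrder = 2)
    expect_identical(nTransitions(led10), 65L)  # 10 + 10 + 45
    expect_false(any(transitionClasses(led10) == "higher_order"))
})

test_that("harmonic limit: overtones double and combinations add exactly", {
    set.seed(5)
    n <- 6
    m <- ModeBasis(sort(runif(n, 400, 3200)), rep("x", n))
    led <- buildTransitionLedger(m, AnharmonicConstants(matrix(0, n, n)))
    tr <- transitions(led)
    fund <- setNames(tr$position[tr$class == "fundamental"],
                     tr$quanta[tr$class == "fundamental"])
    for (k in which(tr$class == "first_overtone")) {
        q <- parseQuanta(tr$quanta[k])
        expect_equal(tr$position[k],
                     2 * unname(fund[formatQuanta(setNames(1L, names(q)))]))
    }
    for (k in which(tr$class == "binary_combination")) {
        q <- parseQuanta(tr$quanta[k])
        ids <- names(q)
        expect_equal(tr$position[k],
                     sum(fund[sprintf("%s:1", ids)]), tolerance = 1e-12)
    }
})

test_that("intensity rules are validated and applied per class", {
    m <- twoModeBasis()
    chi <- AnharmonicConstants(matrix(0, 2, 2))
    led <- buildTransitionLedger(m, chi, intensityRule = classIntensityRule(
        fundamental = 10, firstOvertone = 0.1, binaryCombination = 0.5))
    tr <- transitions(led)
    expect_equal(unique(tr$intensity[tr$class == "fundamental"]), 10)
    expect_equal(unique(tr$intensity[tr$class == "first_overtone"]), 1)
    expect_equal(unique(tr$intensity[tr$class == "binary_combination"]), 5)
    expect_error(classIntensityRule(firstOvertone = 0), "\\(0, 1\\]")
    expect_error(buildTransitionLedger(m, AnharmonicConstants(matrix(0)),
                                       maxOrder = 2),
                 "configuration error")
})
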