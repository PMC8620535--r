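#' Parse and format sparse excitation quanta
#'
#' Quanta are stored sparsely: only excited modes appear, as a named
#' integer vector whose names are mode ids.  The string encoding used in
#' ledgers and CSV files joins `"mode:count"` terms with `+`, e.g.
#' `"3:1"` (fundamental of mode 3) or `"2:1+7:1"` (binary combination).
#'
#' @param x for `parseQuanta` a single encoded string; for `formatQuanta`
#'   a named integer vector.
#' @return `parseQuanta` returns a named integer vector sorted by mode id;
#'   `formatQuanta` its string encoding.
#' @examples
#' parseQuanta("2:1+7:1")
#' formatQuanta(c(`5` = 2))
#' @export
parseQuanta <- function(x) {
    stopifnot(is.character(x), length(x) == 1L)
    if (!nzchar(x)) return(integer())
    terms <- strsplit(x, "+", fixed = TRUE)[[1]]
    parts <- strsplit(terms, ":", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 2L
    if (any(bad))
        stop("malformed quanta string: ", x)
    ids <- as.integer(vapply(parts, `[`, "", 1L))
    cnt <- as.integer(vapply(parts, `[`, "", 2L))
    if (any(is.na(ids)) || any(is.na(cnt)))
        stop("malformed quanta string: ", x)
    o <- order(ids)
    stats::setNames(cnt[o], ids[o])
}

#' @rdname parseQuanta
#' @export
formatQuanta <- function(x) {
    x <- checkQuanta(x)
    paste(sprintf("%s:%d", names(x), x), collapse = "+")
}

checkQuanta <- function(quanta) {
    if (is.character(quanta) && length(quanta) == 1L)
        quanta <- parseQuanta(quanta)
    if (length(quanta) == 0L)
        stop("quanta must be non-empty")
    if (is.null(names(quanta)) || any(!nzchar(names(quanta))))
        stop("quanta must be a named vector (names = mode ids)")
    counts <- as.integer(quanta)
    if (any(is.na(counts)) || any(counts < 1L))
        stop("all excitation counts must be positive integers")
    ids <- as.integer(names(quanta))
    if (any(is.na(ids)) || anyDuplicated(ids))
        stop("quanta names must be unique integer mode ids")
    o <- order(ids)
    stats::setNames(counts[o], ids[o])
}

#' Classify a vibrational transition by its excitation quanta
#'
#' The taxonomy partitions all valid quanta into four classes:
#' *fundamental* (one mode raised by one quantum), *first overtone* (one
#' mode raised by two), *binary combination* (two distinct modes raised by
#' one each), and *higher order* (anything else).
#'
#' @param quanta named integer vector (names = mode ids, values = excitation
#'   counts >= 1) or its string encoding (see [parseQuanta()]).
#' @return One of `"fundamental"`, `"first_overtone"`,
#'   `"binary_combination"`, `"higher_order"`.
#' @examples
#' classifyTransition(c(`3` = 1))            # fundamental
#' classifyTransition(c(`5` = 2))            # first_overtone
#' classifyTransition(c(`2` = 1, `7` = 1))   # binary_combination
#' classifyTransition(c(`1` = 2, `2` = 1))   # higher_order
#' @export
classifyTransition <- function(quanta) {
    q <- checkQuanta(quanta)
    n <- length(q)
    tot <- sum(q)
    if (n == 1L && tot == 1L) return("fundamental")
    if (n == 1L && tot == 2L) return("first_overtone")
    if (n == 2L && tot == 2L) return("binary_combination")
    "higher_order"
}

#' Second-order (VPT2-style) transition position
#'
#' Evaluates the textbook deperturbed second-order vibrational energy
#' expression
#' `E(v) = sum_i omega_i (v_i + 1/2) + sum_{i<=j} chi_ij (v_i + 1/2)(v_j + 1/2)`
#' and returns `E(v) - E(0)` for the excited state described by `quanta`.
#' No Fermi-resonance treatment is applied.
#'
#' Useful identities that follow algebraically (and are tested as package
#' invariants): the fundamental of mode *i* lies at
#' `omega_i + 2 chi_ii + (1/2) sum_{j != i} chi_ij`; the first overtone
#' deviates from twice the fundamental by exactly `2 chi_ii`; a binary
#' combination deviates from the sum of its two fundamentals by exactly
#' `chi_ij`.
#'
#' @param modes a [ModeBasis-class].
#' @param chi an [AnharmonicConstants-class] with dimension matching
#'   `modes`.
#' @param quanta sparse excitation (named vector or string encoding).
#' @return Transition wavenumber in cm-1.
#' @examples
#' m <- ModeBasis(3000, "νCH")
#' x <- AnharmonicConstants(matrix(-30))
#' vpt2TransitionPosition(m, x, c(`1` = 1))  # 2940
#' vpt2TransitionPosition(m, x, c(`1` = 2))  # 5820
#' @export
vpt2TransitionPosition <- function(modes, chi, quanta) {
    q <- checkQuanta(quanta)
    n <- nModes(modes)
    if (chiDim(chi) != n)
        stop("configuration error: chi dimension (", chiDim(chi),
             ") does not match number of modes (", n, ")")
    ids <- as.integer(names(q))
    if (any(ids < 1L) || any(ids > n))
        stop("quanta refer to modes outside the mode basis")
    v <- integer(n)
    v[ids] <- q
    omega <- modeWavenumbers(modes)
    X <- chi@chi
    energy <- function(v) {
        p <- v + 0.5
        # sum_{i<=j} chi_ij p_i p_j from the full symmetric matrix
        sum(omega * p) + (sum(X * outer(p, p)) + sum(diag(X) * p^2)) / 2
    }
    energy(v) - energy(integer(n))
}

#' Enumerate fundamentals, first overtones and binary combinations
#'
#' Builds a [TransitionLedger-class] containing every fundamental, and --
#' when `maxOrder = 2` -- every first overtone and binary combination of
#' the mode basis.  Positions come from [vpt2TransitionPosition()];
#' intensities from the supplied rule.  Higher-order transitions are
#' representable in the ledger format but never enumerated here.
#'
#' @param modes a [ModeBasis-class].
#' @param chi an [AnharmonicConstants-class].
#' @param intensityRule either a single non-negative number (constant
#'   intensity), a named numeric vector with per-class values (see
#'   [classIntensityRule()]), or a `function(class, quanta, position)`
#'   returning an intensity.
#' @param maxOrder 1 (fundamentals only) or 2.
#' @param provenance free-text method label stored in the ledger.
#' @return A [TransitionLedger-class], sorted by ascending position; for
#'   `n` modes and `maxOrder = 2` it holds `n + n + n(n-1)/2` transitions.
#' @examples
#' m <- ModeBasis(c(3000, 1600, 800), c("νCH", "νC=O", "γCH"))
#' x <- AnharmonicConstants(diag(c(-30, -10, -5)))
#' nTransitions(buildTransitionLedger(m, x))  # 9
#' @export
buildTransitionLedger <- function(modes, chi,
                                  intensityRule = classIntensityRule(),
                                  maxOrder = 2,
                                  provenance = "VPT2 enumeration") {
    if (!maxOrder %in% c(1, 2))
        stop("maxOrder must be 1 or 2")
    n <- nModes(modes)
    if (n == 0L)
        stop("mode basis is empty")
    if (chiDim(chi) != n)
        stop("configuration error: chi dimension does not match modes")
    ch <- modeCharacters(modes)
    qlist <- list()
    labels <- character()
    for (i in seq_len(n)) {
        qlist[[length(qlist) + 1L]] <- stats::setNames(1L, i)
        labels <- c(labels, ch[i])
    }
    if (maxOrder == 2) {
        for (i in seq_len(n)) {
            qlist[[length(qlist) + 1L]] <- stats::setNames(2L, i)
            labels <- c(labels, paste0("2", ch[i]))
        }
        if (n >= 2L) {
            for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
                qlist[[length(qlist) + 1L]] <-
                    stats::setNames(c(1L, 1L), c(i, j))
                labels <- c(labels, paste(ch[i], "+", ch[j]))
            }
        }
    }
    cls <- vapply(qlist, classifyTransition, "")
    pos <- vapply(qlist, function(q) vpt2TransitionPosition(modes, chi, q), 0)
    ruleFun <- asIntensityRule(intensityRule)
    int <- mapply(function(cl, q, p) ruleFun(cl, q, p), cls, qlist, pos)
    tr <- data.frame(quanta = vapply(qlist, formatQuanta, ""),
                     position = pos, intensity = as.numeric(int),
                     class = cls, label = labels, stringsAsFactors = FALSE)
    TransitionLedger(modes, tr, provenance = provenance)
}

#' Per-class constant intensity rule
#'
#' Convenience intensity rule for [buildTransitionLedger()]: fundamentals
#' get `fundamental`, overtones `fundamental * firstOvertone`, combinations
#' `fundamental * binaryCombination` (the factors mirror the typical
#' orders-of-magnitude weakening of non-fundamental bands).
#'
#' @param fundamental base intensity of a fundamental.
#' @param firstOvertone,binaryCombination multiplicative factors in (0, 1].
#' @return A `function(class, quanta, position)`.
#' @export
classIntensityRule <- function(fundamental = 1, firstOvertone = 0.02,
                               binaryCombination = 0.05) {
    if (firstOvertone <= 0 || firstOvertone > 1 ||
        binaryCombination <= 0 || binaryCombination > 1)
        stop("class factors must lie in (0, 1]")
    function(class, quanta, position) {
        switch(class,
               fundamental = fundamental,
               first_overtone = fundamental * firstOvertone,
               binary_combination = fundamental * binaryCombination,
               0)
    }
}

asIntensityRule <- function(rule) {
    if (is.function(rule)) return(rule)
    if (is.numeric(rule) && length(rule) == 1L && is.null(names(rule))) {
        if (rule < 0) stop("intensity must be non-negative")
        return(function(class, quanta, position) rule)
    }
    if (is.numeric(rule) && !is.null(names(rule))) {
        return(function(class, quanta, position) {
            if (!class %in% names(rule))
                stop("intensity rule has no value for class ", class)
            unname(rule[[class]])
        })
    }
    stop("intensityRule must be a number, a named numeric vector, or a function")
}

#' Filter a ledger by transition class or region
#'
#' @param ledger a [TransitionLedger-class].
#' @param classes character vector of classes to keep (default: all).
#' @param region optional `c(low, high)` window in cm-1.
#' @return The filtered [TransitionLedger-class].
#' @export
filterTransitions <- function(ledger, classes = NULL, region = NULL) {
    tr <- transitions(ledger)
    keep <- rep(TRUE, nrow(tr))
    if (!is.null(classes)) {
        if (!all(classes %in% TRANSITION_CLASSES))
            stop("unknown transition class in filter")
        keep <- keep & tr$class %in% classes
    }
    if (!is.null(region))
        keep <- keep & tr$position >= min(region) & tr$position <= max(region)
    TransitionLedger(modeBasis(ledger), tr[keep, , drop = FALSE],
                     provenance = provenance(ledger))
}
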