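# Independent oracles and small builders shared across tests.

# Adaptive-quadrature area of the Gauss-Lorentz product profile,
# independent of the package's trapezoid normalisation.
quadArea <- function(height, center, fg, fl) {
    f <- function(x) height * exp(-4 * log(2) * ((x - center) / fg)^2) /
        (1 + 4 * ((x - center) / fl)^2)
    stats::integrate(f, center - 200 * max(fg, fl),
                     center + 200 * max(fg, fl),
                     rel.tol = 1e-12, subdivisions = 2000L)$value
}

# Exhaustive minimum-cost assignment for small problems.
bruteAssignment <- function(cost) {
    n <- nrow(cost)
    perms <- function(v) {
        if (length(v) <= 1L) return(list(v))
        do.call(c, lapply(seq_along(v), function(i)
            lapply(perms(v[-i]), function(p) c(v[i], p))))
    }
    best <- Inf; bp <- NULL
    for (p in perms(seq_len(n))) {
        s <- sum(cost[cbind(seq_len(n), p)])
        if (s < best) { best <- s; bp <- p }
    }
    list(cost = best, perm = bp)
}

# Exhaustive best peak-transition matching: maximum cardinality first,
# then minimum total |difference|, over all injective pairings within
# tolerance.  Only viable for a handful of peaks.
bruteMatch <- function(exp, calc, tolerance) {
    nE <- length(exp); nC <- length(calc)
    best <- list(card = -1L, cost = Inf, pairs = NULL)
    expand <- function(i, used, pairs, cost) {
        if (i > nE) {
            card <- nrow(pairs)
            if (card > best$card ||
                (card == best$card && cost < best$cost))
                best <<- list(card = card, cost = cost, pairs = pairs)
            return(invisible())
        }
        expand(i + 1L, used, pairs, cost)  # leave exp i unmatched
        for (j in seq_len(nC)) {
            if (!used[j] && abs(exp[i] - calc[j]) <= tolerance) {
                used[j] <- TRUE
                expand(i + 1L, used, rbind(pairs, c(i, j)),
                       cost + abs(exp[i] - calc[j]))
                used[j] <- FALSE
            }
        }
    }
    expand(1L, rep(FALSE, nC), matrix(integer(), ncol = 2L), 0)
    best
}

twoModeBasis <- function() ModeBasis(c(3000, 1500), c("νCH", "δCH"))

randomChi <- function(n, diag = c(-40, -5), off = c(-10, 10)) {
    chi <- matrix(0, n, n)
    chi[upper.tri(chi)] <- runif(sum(upper.tri(chi)), off[1], off[2])
    chi <- chi + t(chi)
    diag(chi) <- runif(n, diag[1], diag[2])
    AnharmonicConstants(chi)
}

expandedTableColumns <- function(tab) {
    # exp/calc position columns in printed row order, rows with a printed
    # difference only
    ok <- is.finite(tab$exp_position) & is.finite(tab$calc_position)
    list(exp = tab$exp_position[is.finite(tab$exp_position)],
         calc = tab$calc_position[is.finite(tab$calc_position)],
         pairsExp = tab$exp_position[ok], pairsCalc = tab$calc_position[ok],
         diffs = tab$difference[ok])
}

# sample() treats a scalar as 1:n; this does not
resample <- function(v) v[sample.int(length(v), 1L)]
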