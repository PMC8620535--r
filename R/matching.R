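# Hungarian algorithm (shortest augmenting paths with potentials) for the
# square min-cost assignment problem.  Hand-implemented: no assignment
# solver is available among the package's dependencies.  Returns, for each
# row, the assigned column.
solveAssignment <- function(cost) {
    n <- nrow(cost)
    stopifnot(ncol(cost) == n)
    if (n == 0L) return(integer())
    u <- numeric(n + 1)          # row potentials; index i+1, u[1] = dummy row
    v <- numeric(n + 1)          # column potentials; index j+1, v[1] = dummy
    p <- integer(n + 1)          # p[j+1]: row matched to column j (0 = free)
    way <- integer(n + 1)
    for (i in seq_len(n)) {
        p[1] <- i
        j0 <- 0L
        minv <- rep(Inf, n + 1)
        used <- rep(FALSE, n + 1)
        repeat {
            used[j0 + 1L] <- TRUE
            i0 <- p[j0 + 1L]
            free <- which(!used[-1L])           # candidate columns
            cur <- cost[i0, free] - u[i0 + 1L] - v[free + 1L]
            upd <- cur < minv[free + 1L]
            minv[free[upd] + 1L] <- cur[upd]
            way[free[upd] + 1L] <- j0
            k <- which.min(minv[free + 1L])
            j1 <- free[k]
            delta <- minv[j1 + 1L]
            usedIdx <- which(used)
            u[p[usedIdx] + 1L] <- u[p[usedIdx] + 1L] + delta
            v[usedIdx] <- v[usedIdx] - delta
            minv[!used] <- minv[!used] - delta
            j0 <- j1
            if (p[j0 + 1L] == 0L) break
        }
        repeat {
            j1 <- way[j0 + 1L]
            p[j0 + 1L] <- p[j1 + 1L]
            j0 <- j1
            if (j0 == 0L) break
        }
    }
    match <- integer(n)
    for (j in seq_len(n)) if (p[j + 1L] > 0L) match[p[j + 1L]] <- j
    match
}

# Order-preserving alignment of two peak sequences (Needleman-Wunsch style
# dynamic programme).  Sequences are taken in the order supplied; a match
# within tolerance costs the squared difference; the gap penalty exceeds
# any achievable total match cost, so the alignment first maximises the
# number of matched pairs and only then minimises the total squared
# difference.  Returns a 2-column matrix of matched (expIndex, calcIndex).
alignMatch <- function(exp, calc, tolerance) {
    nE <- length(exp); nC <- length(calc)
    G <- (nE + nC) * tolerance^2 + 1
    D <- matrix(Inf, nE + 1L, nC + 1L)
    D[1L, ] <- G * (0:nC)
    D[, 1L] <- G * (0:nE)
    for (i in seq_len(nE)) {
        d <- exp[i] - calc
        c_ij <- ifelse(abs(d) <= tolerance, d^2, Inf)
        for (j in seq_len(nC)) {
            D[i + 1L, j + 1L] <- min(D[i, j] + c_ij[j],
                                     D[i, j + 1L] + G,
                                     D[i + 1L, j] + G)
        }
    }
    pairs <- matrix(integer(), ncol = 2L)
    i <- nE; j <- nC
    while (i > 0L && j > 0L) {
        d <- exp[i] - calc[j]
        cij <- if (abs(d) <= tolerance) d^2 else Inf
        if (is.finite(cij) && D[i + 1L, j + 1L] == D[i, j] + cij) {
            pairs <- rbind(c(i, j), pairs)
            i <- i - 1L; j <- j - 1L
        } else if (D[i + 1L, j + 1L] == D[i, j + 1L] + G) {
            i <- i - 1L
        } else {
            j <- j - 1L
        }
    }
    pairs
}

asCalcTable <- function(calc) {
    if (is(calc, "TransitionLedger")) {
        tr <- transitions(calc)
        data.frame(position = tr$position, intensity = tr$intensity,
                   label = tr$label, stringsAsFactors = FALSE)
    } else if (is.data.frame(calc)) {
        if (!"position" %in% names(calc))
            stop("calc data.frame needs a 'position' column")
        data.frame(position = calc$position,
                   intensity = if ("intensity" %in% names(calc))
                       calc$intensity else NA_real_,
                   label = if ("label" %in% names(calc))
                       as.character(calc$label) else NA_character_,
                   stringsAsFactors = FALSE)
    } else {
        data.frame(position = as.numeric(calc), intensity = NA_real_,
                   label = NA_character_, stringsAsFactors = FALSE)
    }
}

#' Match experimental peaks to calculated transitions
#'
#' Pairs each experimental peak with at most one calculated transition (and
#' vice versa) within a position tolerance, producing assignment records
#' with signed differences `exp - calc`.
#'
#' Three pairing strategies are available:
#' \describe{
#'   \item{`"greedy"`}{nearest-first: candidate pairs are taken in order of
#'     ascending `|exp - calc|` (ties broken on the position values, so the
#'     result is invariant under permutation of the inputs).  Transparent
#'     and order-stable, the default.}
#'   \item{`"optimal"`}{maximum-cardinality, minimum total squared
#'     difference bipartite assignment (Hungarian algorithm).  Unlike
#'     greedy, the optimum never sacrifices a feasible partner for a
#'     marginally closer one.}
#'   \item{`"aligned"`}{order-preserving alignment of the two peak lists
#'     *in the order supplied* (dynamic programme; unmatched entries are
#'     penalised enough that the alignment never sacrifices a feasible
#'     pairing, i.e. matched count is maximised first, total squared
#'     difference second).  This mirrors how assignment tables are read:
#'     consecutive listed features pair with consecutive calculated
#'     transitions even when their spacings locally cross.  Use it to
#'     reproduce published assignment tables from their printed columns.}
#' }
#'
#' @param expPeaks numeric vector of experimental positions (cm-1), or a
#'   data.frame with a `position` column (e.g. from [pickPeaks()]).
#' @param calc a [TransitionLedger-class], a numeric vector of calculated
#'   positions, or a data.frame with `position` (and optionally
#'   `intensity`, `label`) columns.
#' @param tolerance maximum admissible `|exp - calc|` in cm-1 (> 0).
#' @param method `"greedy"`, `"optimal"` or `"aligned"`.
#' @return A data.frame of assignment records with columns `expPosition`,
#'   `calcPosition`, `calcIntensity`, `difference` (= exp - calc, exact)
#'   and `label`, ordered by descending experimental position.  Unmatched
#'   experimental positions and unmatched calculated rows are attached as
#'   attributes `unmatchedExp` and `unmatchedCalc`.
#' @examples
#' matchPeaks(3310, c(3360), tolerance = 60)   # difference -50
#' @export
matchPeaks <- function(expPeaks, calc, tolerance = 40,
                       method = c("greedy", "optimal", "aligned")) {
    method <- match.arg(method)
    if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0)
        stop("tolerance must be a single positive number")
    expPos <- if (is.data.frame(expPeaks)) expPeaks$position
              else as.numeric(expPeaks)
    ct <- asCalcTable(calc)
    nE <- length(expPos); nC <- nrow(ct)
    pairs <- matrix(integer(), ncol = 2L)
    if (nE > 0L && nC > 0L) {
        if (method == "greedy") {
            dmat <- abs(outer(expPos, ct$position, "-"))
            cand <- which(dmat <= tolerance, arr.ind = TRUE)
            if (nrow(cand)) {
                o <- order(dmat[cand], expPos[cand[, 1L]],
                           ct$position[cand[, 2L]])
                cand <- cand[o, , drop = FALSE]
                usedE <- rep(FALSE, nE); usedC <- rep(FALSE, nC)
                keep <- logical(nrow(cand))
                for (k in seq_len(nrow(cand))) {
                    i <- cand[k, 1L]; j <- cand[k, 2L]
                    if (!usedE[i] && !usedC[j]) {
                        keep[k] <- TRUE
                        usedE[i] <- TRUE; usedC[j] <- TRUE
                    }
                }
                pairs <- cand[keep, , drop = FALSE]
            }
        } else if (method == "optimal") {
            N <- max(nE, nC)
            BIG <- N * tolerance^2 + 1
            cost <- matrix(0, N, N)
            d <- outer(expPos, ct$position, "-")
            cost[seq_len(nE), seq_len(nC)] <-
                ifelse(abs(d) <= tolerance, d^2, BIG)
            m <- solveAssignment(cost)
            for (i in seq_len(nE)) {
                j <- m[i]
                if (j <= nC && cost[i, j] < BIG)
                    pairs <- rbind(pairs, c(i, j))
            }
        } else {
            pairs <- alignMatch(expPos, ct$position, tolerance)
        }
    }
    matchedE <- pairs[, 1L]; matchedC <- pairs[, 2L]
    rec <- data.frame(expPosition = expPos[matchedE],
                      calcPosition = ct$position[matchedC],
                      calcIntensity = ct$intensity[matchedC],
                      difference = expPos[matchedE] - ct$position[matchedC],
                      label = ct$label[matchedC],
                      stringsAsFactors = FALSE)
    o <- order(-rec$expPosition, -rec$calcPosition)
    rec <- rec[o, , drop = FALSE]
    rownames(rec) <- NULL
    attr(rec, "unmatchedExp") <- expPos[setdiff(seq_len(nE), matchedE)]
    attr(rec, "unmatchedCalc") <- ct[setdiff(seq_len(nC), matchedC), ,
                                     drop = FALSE]
    rec
}

#' Qualitative intensity label
#'
#' Maps a relative band height (fraction of the spectrum maximum) to the
#' conventional qualitative labels: `vs` (very strong), `s` (strong), `m`
#' (medium), `w` (weak), `vw` (very weak).  The thresholds are
#' configuration values; the defaults are `vs >= 0.75 > s >= 0.50 > m >=
#' 0.25 > w >= 0.05 > vw`.
#'
#' @param relativeHeight numeric in `[0, 1]`.
#' @param thresholds named, strictly decreasing thresholds for
#'   `vs`, `s`, `m`, `w`.
#' @return Character vector of labels.
#' @examples
#' intensityLabel(c(1, 0.5, 0.01))  # "vs" "s" "vw"
#' @export
intensityLabel <- function(relativeHeight,
                           thresholds = c(vs = 0.75, s = 0.50,
                                          m = 0.25, w = 0.05)) {
    if (!identical(names(thresholds), c("vs", "s", "m", "w")) ||
        any(diff(thresholds) >= 0))
        stop("thresholds must be strictly decreasing values for vs, s, m, w")
    if (any(!is.finite(relativeHeight)) || any(relativeHeight < 0) ||
        any(relativeHeight > 1))
        stop("relativeHeight must lie in [0, 1]")
    vapply(relativeHeight, function(h) {
        if (h >= thresholds[["vs"]]) "vs"
        else if (h >= thresholds[["s"]]) "s"
        else if (h >= thresholds[["m"]]) "m"
        else if (h >= thresholds[["w"]]) "w"
        else "vw"
    }, "")
}

#' Format assignment records as a publication-style table
#'
#' Renormalises the calculated intensities so that the most intense
#' calculated band reads 100, optionally attaches qualitative experimental
#' intensity labels, and orders columns the way assignment tables are
#' printed: experimental position, calculated position, calculated relative
#' intensity, signed difference, assignment.
#'
#' @param records data.frame from [matchPeaks()] (non-empty).
#' @param expHeights optional numeric vector of experimental relative
#'   heights (fractions of the spectrum maximum), parallel to `records`,
#'   used to derive `vs`/`s`/`m`/`w`/`vw` labels.
#' @param thresholds passed to [intensityLabel()].
#' @return data.frame with columns `exp_position`, (`exp_intensity`),
#'   `calc_position`, `calc_intensity`, `difference`, `assignment`.
#' @export
assignmentTable <- function(records, expHeights = NULL,
                            thresholds = c(vs = 0.75, s = 0.50,
                                           m = 0.25, w = 0.05)) {
    if (!is.data.frame(records) || nrow(records) == 0L)
        stop("records must be a non-empty data.frame")
    calcInt <- records$calcIntensity
    if (any(is.finite(calcInt)))
        calcInt <- 100 * calcInt / max(calcInt, na.rm = TRUE)
    out <- data.frame(exp_position = records$expPosition,
                      calc_position = records$calcPosition,
                      calc_intensity = calcInt,
                      difference = records$difference,
                      assignment = records$label,
                      stringsAsFactors = FALSE)
    if (!is.null(expHeights)) {
        if (length(expHeights) != nrow(records))
            stop("expHeights must be parallel to records")
        out <- cbind(out[1L],
                     exp_intensity = intensityLabel(expHeights, thresholds),
                     out[-1L])
    }
    rownames(out) <- NULL
    out
}

#' Render an assignment table as aligned text
#'
#' @param table data.frame from [assignmentTable()].
#' @return Character vector of lines.
#' @export
formatAssignmentTable <- function(table) {
    num <- vapply(table, is.numeric, TRUE)
    cols <- names(table)
    body <- table
    for (k in which(num))
        body[[k]] <- ifelse(is.na(table[[k]]), "-",
                            formatC(table[[k]], format = "fg", digits = 6))
    for (k in seq_along(body)) {
        body[[k]] <- as.character(body[[k]])
        body[[k]][is.na(body[[k]])] <- "-"
    }
    widths <- pmax(nchar(cols),
                   vapply(body, function(c) max(nchar(as.character(c)), 0L),
                          0L))
    fmtRow <- function(vals)
        paste(mapply(formatC, as.character(vals), width = widths,
                     MoreArgs = list(flag = "-")), collapse = "  ")
    c(fmtRow(cols), fmtRow(rep("", length(cols))),
      apply(body, 1L, fmtRow))
}

#' Write an assignment table to CSV
#'
#' @param table data.frame from [assignmentTable()].
#' @param path output file.
#' @param unicodeMinus write negative differences with a typographic minus
#'   sign (U+2212) instead of the default ASCII hyphen.
#' @return Invisibly, `path`.
#' @export
writeAssignmentTable <- function(table, path, unicodeMinus = FALSE) {
    if (unicodeMinus && "difference" %in% names(table)) {
        table$difference <- gsub("-", "−",
                                 format(table$difference, trim = TRUE))
    }
    utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
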