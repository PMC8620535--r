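#' Regional integrated-intensity decomposition by transition class
#'
#' Quantifies how much of the absorbance in a wavenumber window originates
#' from fundamentals, first overtones, binary combinations and higher-order
#' transitions.  With `method = "broadened"` (default) each class is
#' broadened into its sub-spectrum with the supplied line shape and
#' integrated over the region by the trapezoid rule; with
#' `method = "intensity"` the calculated intensities of the transitions
#' located inside the region are summed directly.  In area-proportional
#' mode the two routes agree whenever every contributing band lies entirely
#' inside the region, and the fractions are then independent of the width
#' parameters.
#'
#' @param ledger a [TransitionLedger-class].
#' @param params a [LineShapeParams-class] (broadened route only).
#' @param region `c(low, high)` in cm-1.
#' @param method `"broadened"` or `"intensity"`.
#' @param gridStep grid step for the broadened route; default is one
#'   eighth of the smaller width.
#' @return A [RegionReport-class]; when no intensity falls in the region
#'   the report is flagged undefined and the fractions are `NA`.
#' @examples
#' m <- ModeBasis(c(1000, 1500), c("γCH", "δCH"))
#' x <- AnharmonicConstants(matrix(0, 2, 2))
#' led <- buildTransitionLedger(m, x, intensityRule = 1, maxOrder = 1)
#' regionFractions(integrateClassFractions(led, region = c(400, 1800)))
#' @export
integrateClassFractions <- function(ledger, params = lineShapeParams(),
                                    region,
                                    method = c("broadened", "intensity"),
                                    gridStep = NULL) {
    method <- match.arg(method)
    if (length(region) != 2L)
        stop("region must be c(low, high)")
    region <- sort(as.numeric(region))
    tr <- transitions(ledger)
    classes <- TRANSITION_CLASSES
    if (method == "intensity") {
        inside <- tr$position >= region[1] & tr$position <= region[2]
        sums <- vapply(classes, function(cl)
            sum(tr$intensity[inside & tr$class == cl]), 0)
    } else {
        w <- max(params@fwhmGauss, params@fwhmLorentz)
        near <- tr$position >= region[1] - 60 * w &
                tr$position <= region[2] + 60 * w
        trNear <- tr[near, , drop = FALSE]
        if (is.null(gridStep))
            gridStep <- min(params@fwhmGauss, params@fwhmLorentz) / 8
        grid <- seq(region[1], region[2], by = gridStep)
        sums <- vapply(classes, function(cl) {
            sub <- trNear[trNear$class == cl, , drop = FALSE]
            if (nrow(sub) == 0L) return(0)
            trapz(grid, sumProfiles(sub$position, sub$intensity, params, grid))
        }, 0)
    }
    total <- sum(sums)
    defined <- total > 0
    fr <- if (defined) sums / total
          else stats::setNames(rep(NA_real_, 4L), classes)
    new("RegionReport", region = region,
        fractions = stats::setNames(as.numeric(fr), classes),
        totalIntegral = total, defined = defined)
}

#' Pick peaks from a spectrum
#'
#' Detects local maxima, computes their topographic prominence (height
#' above the highest saddle separating the peak from higher terrain),
#' filters by a prominence threshold and a minimum mutual separation, and
#' refines each surviving position by parabolic interpolation of the
#' three-point apex.
#'
#' @param spectrum a [Spectrum-class].
#' @param minProminence minimum prominence, in absorbance units; default is
#'   2\% of the spectrum maximum.
#' @param minSeparation minimum distance between reported peaks (cm-1);
#'   when two candidates are closer, the higher one wins.
#' @return data.frame with columns `position` (refined, cm-1), `height`,
#'   `prominence` and `index` (grid index of the apex), ordered by
#'   ascending position; zero rows for a featureless spectrum.
#' @export
pickPeaks <- function(spectrum, minProminence = NULL, minSeparation = 0) {
    x <- wavenumbers(spectrum)
    y <- absorbances(spectrum)
    n <- length(y)
    if (is.null(minProminence))
        minProminence <- 0.02 * max(y, 0)
    if (n < 3L)
        return(data.frame(position = numeric(), height = numeric(),
                          prominence = numeric(), index = integer()))
    apex <- which(y[2:(n - 1L)] > y[1:(n - 2L)] &
                  y[2:(n - 1L)] >= y[3:n]) + 1L
    if (!length(apex))
        return(data.frame(position = numeric(), height = numeric(),
                          prominence = numeric(), index = integer()))
    prom <- vapply(apex, function(i) {
        h <- y[i]
        left <- if (i > 1L) {
            seg <- y[(i - 1L):1L]
            higher <- which(seg > h)
            if (length(higher)) min(seg[seq_len(higher[1L])])
            else min(seg)
        } else h
        right <- if (i < n) {
            seg <- y[(i + 1L):n]
            higher <- which(seg > h)
            if (length(higher)) min(seg[seq_len(higher[1L])])
            else min(seg)
        } else h
        h - max(left, right)
    }, 0)
    keep <- prom >= minProminence & prom > 0
    apex <- apex[keep]; prom <- prom[keep]
    if (minSeparation > 0 && length(apex) > 1L) {
        o <- order(-y[apex])
        sel <- logical(length(apex))
        for (k in o) {
            if (!any(sel & abs(x[apex] - x[apex[k]]) < minSeparation))
                sel[k] <- TRUE
        }
        apex <- apex[sel]; prom <- prom[sel]
    }
    refine <- function(i) {
        if (i <= 1L || i >= n) return(c(x[i], y[i]))
        denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
        if (denom >= 0) return(c(x[i], y[i]))
        delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
        dx <- (x[i + 1L] - x[i - 1L]) / 2
        c(x[i] + delta * dx, y[i] - 0.25 * (y[i - 1L] - y[i + 1L]) * delta)
    }
    ref <- vapply(apex, refine, numeric(2L))
    out <- data.frame(position = ref[1L, ], height = ref[2L, ],
                      prominence = prom, index = apex)
    out <- out[order(out$position), , drop = FALSE]
    rownames(out) <- NULL
    out
}
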