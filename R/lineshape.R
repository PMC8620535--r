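glShape <- function(x, fg, fl)
    exp(-4 * log(2) * (x / fg)^2) / (1 + 4 * (x / fl)^2)

# Numerical area of the unit-height Gauss-Lorentz product profile.
# The product has no elementary closed-form area, so the normalisation is
# trapezoidal on a dense local grid: span +-50 widths, step = min width / 20.
glUnitArea <- function(fg, fl) {
    w <- max(fg, fl)
    step <- min(fg, fl) / 20
    x <- seq(-50 * w, 50 * w, by = step)
    trapz(x, glShape(x, fg, fl))
}

trapz <- function(x, y) {
    n <- length(x)
    if (n < 2L) return(0)
    sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Gauss-Lorentz product band profile on a grid
#'
#' Evaluates
#' `f(nu) = h exp(-4 ln2 ((nu - nu0)/G)^2) [1 + 4 ((nu - nu0)/L)^2]^-1`
#' on the supplied wavenumber grid.  In area-proportional mode the height
#' `h` is chosen so that the *numerically integrated* band area equals
#' `intensity` (trapezoid on a dense local grid; the product profile has no
#' elementary closed-form area); in amplitude mode `h = intensity`.
#'
#' @param center band centre nu0 in cm-1.
#' @param intensity non-negative band intensity (area or amplitude,
#'   depending on `params@areaMode`).
#' @param params a [LineShapeParams-class].
#' @param grid wavenumber grid in cm-1.
#' @return Numeric vector of profile values on `grid`.
#' @examples
#' g <- seq(900, 1100, 0.5)
#' p <- lineShapeParams(10, 10, "amplitude")
#' max(bandProfile(1000, 2, p, g))  # 2 at 1000 cm-1
#' @export
bandProfile <- function(center, intensity, params, grid) {
    validObject(params)
    if (intensity < 0)
        stop("intensity must be non-negative")
    if (intensity == 0)
        return(numeric(length(grid)))
    h <- if (params@areaMode == "area")
        intensity / glUnitArea(params@fwhmGauss, params@fwhmLorentz)
    else intensity
    h * glShape(grid - center, params@fwhmGauss, params@fwhmLorentz)
}

# Indices of grid points within +-span of center (grid ascending)
gridWindow <- function(grid, center, span) {
    lo <- findInterval(center - span, grid) + 1L
    hi <- findInterval(center + span, grid)
    if (hi < lo) integer() else lo:hi
}

# Sum band profiles of a transition table onto a grid. Each band is only
# evaluated within +-60 max widths of its centre; the Gaussian factor makes
# the truncated tails < 1e-300 of the peak.
sumProfiles <- function(position, intensity, params, grid) {
    y <- numeric(length(grid))
    w <- 60 * max(params@fwhmGauss, params@fwhmLorentz)
    h <- if (params@areaMode == "area")
        intensity / glUnitArea(params@fwhmGauss, params@fwhmLorentz)
    else intensity
    for (k in seq_along(position)) {
        if (h[k] == 0) next
        idx <- gridWindow(grid, position[k], w)
        if (!length(idx)) next
        y[idx] <- y[idx] + h[k] * glShape(grid[idx] - position[k],
                                          params@fwhmGauss, params@fwhmLorentz)
    }
    y
}

#' Broaden a transition ledger into a continuous spectrum
#'
#' Sums the Gauss-Lorentz band profile of every transition (optionally
#' restricted to a set of classes) on the supplied grid.  Synthesis is
#' linear and additive: the spectrum of the full ledger equals the pointwise
#' sum of the per-class spectra.
#'
#' @param ledger a [TransitionLedger-class].
#' @param params a [LineShapeParams-class].
#' @param grid ascending wavenumber grid in cm-1.
#' @param classFilter optional character vector of transition classes to
#'   include.
#' @return A [Spectrum-class] with technique `"synthetic"`.
#' @export
synthesizeSpectrum <- function(ledger, params = lineShapeParams(), grid,
                               classFilter = NULL) {
    if (length(grid) > 1L && any(diff(grid) <= 0))
        stop("grid must be strictly increasing")
    tr <- transitions(ledger)
    if (!is.null(classFilter)) {
        if (!all(classFilter %in% TRANSITION_CLASSES))
            stop("unknown transition class in classFilter")
        tr <- tr[tr$class %in% classFilter, , drop = FALSE]
    }
    y <- if (nrow(tr) == 0L) numeric(length(grid))
    else sumProfiles(tr$position, tr$intensity, params, grid)
    Spectrum(grid, y, technique = "synthetic",
             metadata = list(provenance = provenance(ledger),
                             fwhmGauss = params@fwhmGauss,
                             fwhmLorentz = params@fwhmLorentz,
                             areaMode = params@areaMode))
}

#' Per-mode contribution map
#'
#' Returns a matrix with one row per normal mode and one column per grid
#' point; row *m* is the sum of the band profiles of every transition whose
#' quanta involve mode *m*.  By convention a binary combination contributes
#' its **full** profile to both participating rows, so the column sum of
#' the map generally exceeds the synthesized spectrum wherever combination
#' bands absorb.
#'
#' @param ledger a [TransitionLedger-class] whose mode basis is non-empty.
#' @param params a [LineShapeParams-class].
#' @param grid ascending wavenumber grid in cm-1.
#' @return Numeric matrix `nModes x length(grid)`; row names are the mode
#'   character labels, suffixed with the mode id.
#' @seealso [plotContributionMap()], [writeContributionMap()]
#' @export
modeContributionMap <- function(ledger, params = lineShapeParams(), grid) {
    if (length(grid) > 1L && any(diff(grid) <= 0))
        stop("grid must be strictly increasing")
    n <- nModes(ledger)
    if (n == 0L)
        stop("ledger has an empty mode basis")
    map <- matrix(0, nrow = n, ncol = length(grid))
    rownames(map) <- sprintf("%s [%d]", modeCharacters(ledger), seq_len(n))
    tr <- transitions(ledger)
    for (k in seq_len(nrow(tr))) {
        prof <- bandProfile(tr$position[k], tr$intensity[k], params, grid)
        ids <- as.integer(names(parseQuanta(tr$quanta[k])))
        for (m in ids)
            map[m, ] <- map[m, ] + prof
    }
    map
}

#' Render a contribution map as a colour image
#'
#' @param map matrix from [modeContributionMap()].
#' @param grid the wavenumber grid the map was computed on.
#' @param col colour palette.
#' @param reverseAxis flip the wavenumber axis for conventional descending
#'   display.
#' @return Invisibly, `NULL`; called for its side effect.
#' @export
plotContributionMap <- function(map, grid,
                                col = grDevices::hcl.colors(64, "YlOrRd",
                                                            rev = TRUE),
                                reverseAxis = TRUE) {
    xl <- if (reverseAxis) rev(range(grid)) else range(grid)
    graphics::image(x = grid, y = seq_len(nrow(map)), z = t(map),
                    xlim = xl, col = col,
                    xlab = expression(paste("wavenumber / ", cm^-1)),
                    ylab = "", yaxt = "n")
    graphics::axis(2, at = seq_len(nrow(map)), labels = rownames(map),
                   las = 2, cex.axis = 0.6)
    invisible(NULL)
}

#' Write a contribution map as CSV with mode labels as row headers
#'
#' @param map matrix from [modeContributionMap()].
#' @param grid the wavenumber grid.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeContributionMap <- function(map, grid, path) {
    df <- data.frame(mode = rownames(map), map, check.names = FALSE)
    colnames(df) <- c("mode", format(grid, trim = TRUE))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
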