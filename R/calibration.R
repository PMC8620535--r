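#' Apply wavenumber-linear scaling to calculated positions
#'
#' Maps each calculated wavenumber `nu` to `nu * (a + b * nu)`: the scale
#' factor itself is a linear function of the wavenumber.  For physically
#' sensible parameters (`|b| * nu << 1` over the calibrated range) the
#' mapping is monotone and order-preserving.
#'
#' @param positions numeric wavenumbers in cm-1.
#' @param params a [WLSParams-class].
#' @return Scaled wavenumbers.
#' @examples
#' applyWLS(1000, wlsParams(b = -1e-5))  # 990
#' @export
applyWLS <- function(positions, params) {
    validObject(params)
    s <- params@a + params@b * positions
    if (any(s <= 0))
        stop("range error: WLS scale factor non-positive within position range")
    positions * s
}

#' Invert wavenumber-linear scaling
#'
#' Solves `y * (a + b * y) = nu` for `y` (the larger root, continuous with
#' the identity at `b = 0`).  Used by the synthetic generator to displace
#' "calculated" positions relative to pseudo-experimental ones.
#'
#' @inheritParams applyWLS
#' @return Wavenumbers `y` such that `applyWLS(y, params) == positions`.
#' @export
inverseWLS <- function(positions, params) {
    validObject(params)
    a <- params@a; b <- params@b
    if (b == 0) return(positions / a)
    disc <- a^2 + 4 * b * positions
    if (any(disc <= 0))
        stop("range error: WLS mapping not invertible at these positions")
    (sqrt(disc) - a) / (2 * b)
}

#' Fit WLS parameters to matched calculated/experimental positions
#'
#' Least squares in wavenumber: minimises
#' `sum (exp - calc * (a + b * calc))^2`, which is linear in `(a, b)`
#' through the regressors `calc` and `calc^2`.  Single-parameter mode fixes
#' `a = 1` and fits only the slope.
#'
#' @param calc calculated positions (cm-1), strictly positive.
#' @param exp matched experimental positions (cm-1).
#' @param mode `"single"` (default) or `"two"`.
#' @return A [WLSParams-class] with the fitted coefficients.
#' @examples
#' calc <- c(500, 1000, 1500)
#' fitWLS(calc, applyWLS(calc, wlsParams(b = -8e-6)))
#' @export
fitWLS <- function(calc, exp, mode = c("single", "two")) {
    mode <- match.arg(mode)
    if (length(calc) != length(exp))
        stop("calc and exp must have equal length")
    ok <- is.finite(calc) & is.finite(exp)
    calc <- calc[ok]; exp <- exp[ok]
    if (any(calc <= 0))
        stop("calculated positions must be strictly positive")
    if (mode == "single") {
        if (length(calc) < 1L)
            stop("single-parameter fit needs at least one matched pair")
        b <- sum(calc^2 * (exp - calc)) / sum(calc^4)
        return(wlsParams(a = 1, b = b, mode = "single"))
    }
    if (length(calc) < 2L)
        stop("two-parameter fit needs at least two matched pairs")
    X <- cbind(calc, calc^2)
    coefs <- stats::lm.fit(X, exp)$coefficients
    wlsParams(a = coefs[[1]], b = coefs[[2]], mode = "two")
}

#' ATR evanescent-wave penetration depth
#'
#' `d_p(nu) = lambda / (2 pi n_crystal sqrt(sin^2 theta - (n_sample/n_crystal)^2))`
#' with `lambda = 1/nu` the vacuum wavelength.  The depth falls off as
#' `1/nu`, which is why uncorrected ATR spectra under-weigh the
#' high-wavenumber end.
#'
#' @param wavenumber wavenumbers in cm-1.
#' @param config an [ATRConfig-class].
#' @return Penetration depth in micrometres.
#' @examples
#' penetrationDepth(1000, atrConfig("diamond-45"))  # ~2.01 um
#' @export
penetrationDepth <- function(wavenumber, config) {
    validObject(config)
    if (any(wavenumber <= 0))
        stop("wavenumbers must be positive")
    theta <- config@angle * pi / 180
    root <- sqrt(sin(theta)^2 - (config@nSample / config@nCrystal)^2)
    lambda_cm <- 1 / wavenumber
    1e4 * lambda_cm / (2 * pi * config@nCrystal * root)
}

#' ATR penetration-depth correction of a spectrum
#'
#' Divides the absorbance by the wavenumber-dependent penetration depth
#' `d_p(nu) ~ 1/nu`, i.e. multiplies by `nu`, then rescales globally so
#' that the corrected maximum equals the input maximum.  Peak positions of
#' bands much narrower than their centre wavenumber are essentially
#' unaffected.  The correction is *not* idempotent; a metadata flag guards
#' against accidental double application.
#'
#' @param spectrum a [Spectrum-class] with positive wavenumbers.
#' @param config an [ATRConfig-class].
#' @param force apply even if the spectrum is already flagged as corrected.
#' @return The corrected [Spectrum-class] with `atrCorrected = TRUE` in its
#'   metadata.
#' @export
atrCorrect <- function(spectrum, config, force = FALSE) {
    validObject(config)
    if (any(wavenumbers(spectrum) <= 0))
        stop("spectrum wavenumbers must be positive for ATR correction")
    md <- spectrumMetadata(spectrum)
    if (isTRUE(md$atrCorrected) && !force)
        stop("spectrum is already ATR-corrected (multiplication by the ",
             "wavenumber is not idempotent); pass force = TRUE to override")
    y <- absorbances(spectrum) / penetrationDepth(wavenumbers(spectrum), config)
    if (max(abs(y)) > 0)
        y <- y * max(abs(absorbances(spectrum))) / max(abs(y))
    md$atrCorrected <- TRUE
    new("Spectrum", wavenumber = wavenumbers(spectrum), absorbance = y,
        metadata = md)
}

#' Normalize a spectrum
#'
#' `"max"` scales the highest absorbance to 1 (idempotent); `"vector"`
#' scales the Euclidean norm to 1.
#'
#' @param spectrum a non-zero [Spectrum-class].
#' @param method `"max"` or `"vector"`.
#' @return The normalized [Spectrum-class]; metadata records the method.
#' @export
normalizeSpectrum <- function(spectrum, method = c("max", "vector")) {
    method <- match.arg(method)
    y <- absorbances(spectrum)
    denom <- switch(method, max = max(y), vector = sqrt(sum(y^2)))
    if (!is.finite(denom) || denom == 0)
        stop("cannot normalize an all-zero spectrum")
    md <- spectrumMetadata(spectrum)
    md$normalized <- method
    new("Spectrum", wavenumber = wavenumbers(spectrum), absorbance = y / denom,
        metadata = md)
}
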