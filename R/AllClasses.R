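#' @import methods
NULL

TRANSITION_CLASSES <- c("fundamental", "first_overtone", "binary_combination",
                        "higher_order")

#' Normal-mode basis of a molecule or crystal
#'
#' A `ModeBasis` holds the harmonic description of the vibrational problem:
#' one row per normal mode with its harmonic wavenumber (cm-1) and a
#' mode-character label in the usual spectroscopic convention
#' (`ν` stretching, `δ` in-plane bending, `γ` out-of-plane
#' bending, `ρ` rocking, plus a fragment tag such as `CH`, `CH3`,
#' `ring`, `C=O`).
#'
#' @slot modeId integer mode indices, unique and contiguous from 1.
#' @slot wavenumber harmonic wavenumbers omega_i in cm-1, strictly positive.
#' @slot character non-empty mode-character labels, one per mode.
#'
#' @seealso [ModeBasis()], [AnharmonicConstants-class],
#'   [TransitionLedger-class]
#' @exportClass ModeBasis
setClass("ModeBasis",
         slots = c(modeId = "integer",
                   wavenumber = "numeric",
                   character = "character"))

setValidity("ModeBasis", function(object) {
    n <- length(object@modeId)
    if (length(object@wavenumber) != n || length(object@character) != n)
        return("modeId, wavenumber and character must have equal length")
    if (n == 0L)
        return(TRUE)
    if (!identical(object@modeId, seq_len(n)))
        return("modeId must be unique and contiguous from 1")
    if (any(!is.finite(object@wavenumber)) || any(object@wavenumber <= 0))
        return("harmonic wavenumbers must be finite and strictly positive")
    if (any(is.na(object@character)) || any(!nzchar(object@character)))
        return("mode character labels must be non-empty")
    TRUE
})

#' Construct a ModeBasis
#'
#' @param wavenumber numeric vector of harmonic wavenumbers (cm-1).
#' @param character character vector of mode labels; recycled if length 1.
#'
#' @return A [ModeBasis-class] object.
#' @examples
#' ModeBasis(c(3050, 1650, 1400), c("νCH", "νC=O", "δCH"))
#' @export
ModeBasis <- function(wavenumber = numeric(), character = base::character()) {
    wavenumber <- as.numeric(wavenumber)
    if (length(character) == 1L && length(wavenumber) > 1L)
        character <- rep(character, length(wavenumber))
    new("ModeBasis", modeId = seq_along(wavenumber),
        wavenumber = wavenumber, character = as.character(character))
}

#' Anharmonicity-constant matrix
#'
#' Symmetric matrix of anharmonicity constants chi_ij (cm-1), one
#' row/column per normal mode, as used in the second-order vibrational
#' energy expression
#' `E(v) = sum_i omega_i (v_i + 1/2) + sum_{i<=j} chi_ij (v_i + 1/2)(v_j + 1/2)`.
#'
#' @slot chi square, exactly symmetric numeric matrix (cm-1).
#'
#' @seealso [AnharmonicConstants()], [vpt2TransitionPosition()]
#' @exportClass AnharmonicConstants
setClass("AnharmonicConstants", slots = c(chi = "matrix"))

setValidity("AnharmonicConstants", function(object) {
    chi <- object@chi
    if (!is.numeric(chi))
        return("chi must be numeric")
    if (nrow(chi) != ncol(chi))
        return("chi must be square")
    if (nrow(chi) > 0L && !all(chi == t(chi)))
        return("chi must be exactly symmetric")
    TRUE
})

#' Construct an AnharmonicConstants matrix
#'
#' @param chi square symmetric numeric matrix of chi_ij in cm-1, or a single
#'   number for a one-mode system.
#' @return An [AnharmonicConstants-class] object.
#' @examples
#' AnharmonicConstants(matrix(c(-30, -5, -5, -10), 2))
#' @export
AnharmonicConstants <- function(chi) {
    if (is.numeric(chi) && is.null(dim(chi)))
        chi <- matrix(chi, length(chi) == 1L, length(chi) == 1L)
    new("AnharmonicConstants", chi = chi)
}

#' @describeIn AnharmonicConstants number of modes spanned by the matrix.
#' @param x an `AnharmonicConstants` object.
#' @export
chiDim <- function(x) nrow(x@chi)

#' Ordered collection of vibrational transitions
#'
#' A `TransitionLedger` couples a [ModeBasis-class] with a table of
#' transitions.  Each transition carries its excitation quanta (sparse,
#' encoded as `"mode:count"` terms joined by `+`, e.g. `"2:1+7:1"`), its
#' position (cm-1), intensity (non-negative; unit tag in the column
#' attribute), derived class and a human-readable assignment label.
#' Transitions are kept sorted by ascending position.
#'
#' @slot modes a [ModeBasis-class]; may be empty for ledgers ingested from
#'   tables that do not disclose the underlying normal modes.
#' @slot transitions `data.frame` with columns `quanta`, `position`,
#'   `intensity`, `class`, `label`.
#' @slot provenance free-text method label, e.g. `"periodic harmonic"`,
#'   `"DVPT2"` or `"synthetic"`.
#'
#' @seealso [buildTransitionLedger()], [readTransitions()]
#' @exportClass TransitionLedger
setClass("TransitionLedger",
         slots = c(modes = "ModeBasis",
                   transitions = "data.frame",
                   provenance = "character"))

setValidity("TransitionLedger", function(object) {
    tr <- object@transitions
    need <- c("quanta", "position", "intensity", "class", "label")
    if (!all(need %in% names(tr)))
        return(paste("transitions must have columns:",
                     paste(need, collapse = ", ")))
    if (nrow(tr) == 0L)
        return(TRUE)
    if (any(!is.finite(tr$position)) || any(tr$position <= 0))
        return("transition positions must be finite and positive")
    if (any(!is.finite(tr$intensity)) || any(tr$intensity < 0))
        return("transition intensities must be finite and non-negative")
    if (!all(tr$class %in% TRANSITION_CLASSES))
        return("unknown transition class")
    if (is.unsorted(tr$position))
        return("transitions must be sorted by ascending position")
    n <- nModes(object@modes)
    if (n > 0L) {
        for (q in tr$quanta) {
            if (!nzchar(q)) next
            qq <- parseQuanta(q)
            if (any(as.integer(names(qq)) > n))
                return("quanta refer to modes outside the mode basis")
        }
    }
    TRUE
})

#' Construct a TransitionLedger
#'
#' @param modes a [ModeBasis-class] (possibly empty).
#' @param transitions data.frame with columns `quanta`, `position`,
#'   `intensity`, `class`, `label`; rows are re-sorted by position.
#' @param provenance free-text method label.
#' @return A [TransitionLedger-class].
#' @export
TransitionLedger <- function(modes = ModeBasis(),
                             transitions = emptyTransitions(),
                             provenance = "unspecified") {
    transitions <- transitions[order(transitions$position), , drop = FALSE]
    rownames(transitions) <- NULL
    new("TransitionLedger", modes = modes, transitions = transitions,
        provenance = provenance)
}

emptyTransitions <- function()
    data.frame(quanta = character(), position = numeric(),
               intensity = numeric(), class = character(),
               label = character(), stringsAsFactors = FALSE)

#' A wavenumber-resolved absorbance spectrum
#'
#' Strictly increasing wavenumber grid (cm-1) with absorbance values and
#' technique metadata.  Files stored with a descending grid are reversed on
#' read; renderers may flip the axis for conventional descending display.
#'
#' @slot wavenumber strictly increasing grid (cm-1).
#' @slot absorbance finite values, same length as the grid.
#' @slot metadata list; recognised entries include `technique`
#'   (`"ATR"`, `"DRIFT"`, `"NIR"` or `"synthetic"`), `resolution` (cm-1),
#'   and provenance flags such as `atrCorrected` and `normalized` that guard
#'   against double application of corrections.
#'
#' @seealso [Spectrum()], [readSpectrum()], [atrCorrect()]
#' @exportClass Spectrum
setClass("Spectrum",
         slots = c(wavenumber = "numeric",
                   absorbance = "numeric",
                   metadata = "list"))

setValidity("Spectrum", function(object) {
    x <- object@wavenumber
    y <- object@absorbance
    if (length(x) != length(y))
        return("wavenumber and absorbance must have equal length")
    if (length(x) > 1L && any(diff(x) <= 0))
        return("wavenumber grid must be strictly increasing")
    if (any(!is.finite(y)))
        return("absorbance values must be finite")
    TRUE
})

#' Construct a Spectrum
#'
#' @param wavenumber numeric grid in cm-1 (any order; sorted ascending).
#' @param absorbance numeric values, same length.
#' @param technique one of `"ATR"`, `"DRIFT"`, `"NIR"`, `"synthetic"`.
#' @param resolution nominal instrument resolution in cm-1.
#' @param metadata further metadata entries.
#' @return A [Spectrum-class].
#' @examples
#' Spectrum(seq(400, 1800, 2), rexp(701), technique = "DRIFT", resolution = 2)
#' @export
Spectrum <- function(wavenumber, absorbance, technique = "synthetic",
                     resolution = NA_real_, metadata = list()) {
    o <- order(wavenumber)
    md <- c(list(technique = technique, resolution = resolution),
            metadata[setdiff(names(metadata), c("technique", "resolution"))])
    new("Spectrum", wavenumber = as.numeric(wavenumber)[o],
        absorbance = as.numeric(absorbance)[o], metadata = md)
}

#' Gauss-Lorentz product line-shape parameters
#'
#' The band profile is the product of a Gaussian and a Lorentzian (Cauchy)
#' centred at the same wavenumber,
#' `f(nu) = h exp(-4 ln2 ((nu-nu0)/G)^2) / (1 + 4 ((nu-nu0)/L)^2)`,
#' where `G` and `L` are the full widths at half maximum of the two factors.
#' In `"area"` mode the height `h` is chosen so that the numerically
#' integrated band area equals the transition intensity; in `"amplitude"`
#' mode `h` equals the intensity.
#'
#' @slot fwhmGauss Gaussian FWHM (cm-1), positive.
#' @slot fwhmLorentz Lorentzian FWHM (cm-1), positive.
#' @slot areaMode `"area"` or `"amplitude"`.
#'
#' @seealso [lineShapeParams()], [bandProfile()]
#' @exportClass LineShapeParams
setClass("LineShapeParams",
         slots = c(fwhmGauss = "numeric", fwhmLorentz = "numeric",
                   areaMode = "character"))

setValidity("LineShapeParams", function(object) {
    if (length(object@fwhmGauss) != 1L || !is.finite(object@fwhmGauss) ||
        object@fwhmGauss <= 0)
        return("fwhmGauss must be a single positive number")
    if (length(object@fwhmLorentz) != 1L || !is.finite(object@fwhmLorentz) ||
        object@fwhmLorentz <= 0)
        return("fwhmLorentz must be a single positive number")
    if (!object@areaMode %in% c("area", "amplitude"))
        return("areaMode must be 'area' or 'amplitude'")
    TRUE
})

#' Construct line-shape parameters
#'
#' Defaults follow the package's broadening convention for crystalline
#' spectra: 8 cm-1 for MIR work, 16 cm-1 for NIR (set both widths
#' accordingly), area-proportional normalisation so that integral-intensity
#' decompositions carry the calculated intensities.
#'
#' @param fwhmGauss,fwhmLorentz full widths at half maximum (cm-1).
#' @param areaMode `"area"` (default) or `"amplitude"`.
#' @return A [LineShapeParams-class].
#' @export
lineShapeParams <- function(fwhmGauss = 8, fwhmLorentz = 8,
                            areaMode = c("area", "amplitude")) {
    areaMode <- match.arg(areaMode)
    new("LineShapeParams", fwhmGauss = as.numeric(fwhmGauss),
        fwhmLorentz = as.numeric(fwhmLorentz), areaMode = areaMode)
}

#' Wavenumber-linear-scaling (WLS) parameters
#'
#' The scale factor applied to a calculated wavenumber is modelled as a
#' linear function of the wavenumber itself: `nu_scaled = nu (a + b nu)`.
#' Single-parameter mode fixes the intercept `a = 1`, leaving the slope `b`
#' as the only free parameter.
#'
#' @slot a dimensionless intercept of the scale-factor line.
#' @slot b slope of the scale-factor line, per cm-1.
#' @slot mode `"single"` (a fixed at 1) or `"two"`.
#'
#' @seealso [wlsParams()], [applyWLS()], [fitWLS()]
#' @exportClass WLSParams
setClass("WLSParams",
         slots = c(a = "numeric", b = "numeric", mode = "character"))

setValidity("WLSParams", function(object) {
    if (length(object@a) != 1L || length(object@b) != 1L ||
        !is.finite(object@a) || !is.finite(object@b))
        return("a and b must be single finite numbers")
    if (!object@mode %in% c("single", "two"))
        return("mode must be 'single' or 'two'")
    if (object@mode == "single" && object@a != 1)
        return("single-parameter mode requires a == 1")
    TRUE
})

#' Construct WLS parameters
#'
#' @param a intercept (fixed at 1 in single-parameter mode).
#' @param b slope per cm-1.
#' @param mode `"single"` or `"two"`.
#' @return A [WLSParams-class].
#' @examples
#' wlsParams(b = -8e-6)
#' @export
wlsParams <- function(a = 1, b = 0, mode = c("single", "two")) {
    mode <- match.arg(mode)
    new("WLSParams", a = as.numeric(a), b = as.numeric(b), mode = mode)
}

#' ATR measurement configuration
#'
#' Optical parameters of an attenuated-total-reflection measurement: the
#' refractive indices of the internal reflection element (IRE) and the
#' sample, and the incidence angle.  Validity enforces the evanescent-wave
#' condition `sin^2(theta) > (n_sample/n_crystal)^2`.
#'
#' @slot nCrystal refractive index of the IRE.
#' @slot nSample refractive index of the sample.
#' @slot angle incidence angle in degrees.
#'
#' @seealso [atrConfig()], [penetrationDepth()], [atrCorrect()]
#' @exportClass ATRConfig
setClass("ATRConfig",
         slots = c(nCrystal = "numeric", nSample = "numeric",
                   angle = "numeric"))

setValidity("ATRConfig", function(object) {
    if (!(object@nCrystal > object@nSample && object@nSample > 0))
        return("need nCrystal > nSample > 0")
    if (object@angle <= 0 || object@angle >= 90)
        return("incidence angle must be in (0, 90) degrees")
    s2 <- sin(object@angle * pi / 180)^2
    if (s2 <= (object@nSample / object@nCrystal)^2)
        return("total internal reflection condition violated: sin^2(angle) must exceed (nSample/nCrystal)^2")
    TRUE
})

#' Construct an ATR configuration
#'
#' @param preset optional named preset; `"diamond-45"` gives a diamond IRE
#'   (n = 2.4) at 45 degrees.
#' @param nCrystal,nSample,angle explicit optical parameters; override the
#'   preset where given.
#' @return An [ATRConfig-class].
#' @examples
#' atrConfig("diamond-45")
#' atrConfig(nCrystal = 4.0, nSample = 1.5, angle = 45)  # germanium IRE
#' @export
atrConfig <- function(preset = NULL, nCrystal = NULL, nSample = 1.5,
                      angle = NULL) {
    if (!is.null(preset)) {
        presets <- list("diamond-45" = list(nCrystal = 2.4, angle = 45))
        if (!preset %in% names(presets))
            stop("unknown ATR preset: ", preset)
        p <- presets[[preset]]
        if (is.null(nCrystal)) nCrystal <- p$nCrystal
        if (is.null(angle)) angle <- p$angle
    }
    if (is.null(nCrystal) || is.null(angle))
        stop("nCrystal and angle must be given (directly or via preset)")
    new("ATRConfig", nCrystal = as.numeric(nCrystal),
        nSample = as.numeric(nSample), angle = as.numeric(angle))
}

#' Regional class-wise intensity decomposition
#'
#' Integrated-intensity fractions of a wavenumber window by transition
#' class.  When the total integral is positive the four fractions sum to 1;
#' for an empty region the report is flagged undefined.
#'
#' @slot region `c(low, high)` in cm-1, low < high.
#' @slot fractions named numeric over the four transition classes, in
#'   `[0, 1]`; `NA` when undefined.
#' @slot totalIntegral total integrated intensity over the region
#'   (absorbance * cm-1, or summed intensity for `method = "intensity"`).
#' @slot defined `TRUE` when the region contained any intensity.
#'
#' @seealso [integrateClassFractions()]
#' @exportClass RegionReport
setClass("RegionReport",
         slots = c(region = "numeric", fractions = "numeric",
                   totalIntegral = "numeric", defined = "logical"))

setValidity("RegionReport", function(object) {
    if (length(object@region) != 2L || object@region[1] >= object@region[2])
        return("region must be c(low, high) with low < high")
    if (!identical(names(object@fractions), TRANSITION_CLASSES))
        return("fractions must be named by the four transition classes")
    if (object@defined && abs(sum(object@fractions) - 1) > 1e-9)
        return("fractions must sum to 1 when defined")
    TRUE
})

#' Synthetic study bundle
#'
#' Everything needed to exercise the full pipeline with known ground truth:
#' the generated mode basis and anharmonicity constants, the transition
#' ledger with intensities, the noisy pseudo-experimental spectrum, and a
#' `truth` list recording the WLS slope estimand, per-region class
#' fractions, noise, baseline and the seed.  Regenerating with the same
#' seed is bit-identical.
#'
#' @slot modes [ModeBasis-class]
#' @slot chi [AnharmonicConstants-class]
#' @slot ledger [TransitionLedger-class]
#' @slot observed [Spectrum-class]
#' @slot truth list of ground-truth parameters.
#' @slot config list, the generator configuration.
#'
#' @seealso [generateStudy()]
#' @exportClass SyntheticStudy
setClass("SyntheticStudy",
         slots = c(modes = "ModeBasis", chi = "AnharmonicConstants",
                   ledger = "TransitionLedger", observed = "Spectrum",
                   truth = "list", config = "list"))
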