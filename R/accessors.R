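#' Accessors for the core classes
#'
#' Small generic accessors in place of direct slot access: `nModes()`,
#' `modeWavenumbers()`, `modeCharacters()`, `transitions()`, `positions()`,
#' `intensities()`, `transitionClasses()`, `wavenumbers()`, `absorbances()`,
#' `spectrumMetadata()`, `regionFractions()`, `regionTotal()`.
#'
#' @param object an object of the appropriate class.
#' @return The corresponding slot content in a plain R type.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nModes", function(object) standardGeneric("nModes"))
#' @rdname accessors
#' @export
setMethod("nModes", "ModeBasis", function(object) length(object@modeId))
#' @rdname accessors
#' @export
setMethod("nModes", "TransitionLedger", function(object) nModes(object@modes))

#' @rdname accessors
#' @export
setGeneric("modeWavenumbers", function(object) standardGeneric("modeWavenumbers"))
#' @rdname accessors
#' @export
setMethod("modeWavenumbers", "ModeBasis", function(object) object@wavenumber)
#' @rdname accessors
#' @export
setMethod("modeWavenumbers", "TransitionLedger",
          function(object) object@modes@wavenumber)

#' @rdname accessors
#' @export
setGeneric("modeCharacters", function(object) standardGeneric("modeCharacters"))
#' @rdname accessors
#' @export
setMethod("modeCharacters", "ModeBasis", function(object) object@character)
#' @rdname accessors
#' @export
setMethod("modeCharacters", "TransitionLedger",
          function(object) object@modes@character)

#' @rdname accessors
#' @export
setGeneric("modeBasis", function(object) standardGeneric("modeBasis"))
#' @rdname accessors
#' @export
setMethod("modeBasis", "TransitionLedger", function(object) object@modes)
#' @rdname accessors
#' @export
setMethod("modeBasis", "SyntheticStudy", function(object) object@modes)

#' @rdname accessors
#' @export
setGeneric("transitions", function(object) standardGeneric("transitions"))
#' @rdname accessors
#' @export
setMethod("transitions", "TransitionLedger", function(object) object@transitions)

#' @rdname accessors
#' @export
setGeneric("nTransitions", function(object) standardGeneric("nTransitions"))
#' @rdname accessors
#' @export
setMethod("nTransitions", "TransitionLedger",
          function(object) nrow(object@transitions))

#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
#' @rdname accessors
#' @export
setMethod("positions", "TransitionLedger",
          function(object) object@transitions$position)

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "TransitionLedger",
          function(object) object@transitions$intensity)

#' @rdname accessors
#' @export
setGeneric("transitionClasses", function(object) standardGeneric("transitionClasses"))
#' @rdname accessors
#' @export
setMethod("transitionClasses", "TransitionLedger",
          function(object) object@transitions$class)

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "TransitionLedger", function(object) object@provenance)

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))
#' @rdname accessors
#' @export
setMethod("wavenumbers", "Spectrum", function(object) object@wavenumber)

#' @rdname accessors
#' @export
setGeneric("absorbances", function(object) standardGeneric("absorbances"))
#' @rdname accessors
#' @export
setMethod("absorbances", "Spectrum", function(object) object@absorbance)

#' @rdname accessors
#' @export
setGeneric("spectrumMetadata", function(object) standardGeneric("spectrumMetadata"))
#' @rdname accessors
#' @export
setMethod("spectrumMetadata", "Spectrum", function(object) object@metadata)

#' @rdname accessors
#' @export
setGeneric("technique", function(object) standardGeneric("technique"))
#' @rdname accessors
#' @export
setMethod("technique", "Spectrum",
          function(object) object@metadata$technique %||% "unknown")

#' @rdname accessors
#' @export
setGeneric("regionFractions", function(object) standardGeneric("regionFractions"))
#' @rdname accessors
#' @export
setMethod("regionFractions", "RegionReport", function(object) object@fractions)

#' @rdname accessors
#' @export
setGeneric("regionTotal", function(object) standardGeneric("regionTotal"))
#' @rdname accessors
#' @export
setMethod("regionTotal", "RegionReport", function(object) object@totalIntegral)

#' @rdname accessors
#' @export
setGeneric("regionWindow", function(object) standardGeneric("regionWindow"))
#' @rdname accessors
#' @export
setMethod("regionWindow", "RegionReport", function(object) object@region)

#' @rdname accessors
#' @export
setGeneric("studyLedger", function(object) standardGeneric("studyLedger"))
#' @rdname accessors
#' @export
setMethod("studyLedger", "SyntheticStudy", function(object) object@ledger)

#' @rdname accessors
#' @export
setGeneric("studyObserved", function(object) standardGeneric("studyObserved"))
#' @rdname accessors
#' @export
setMethod("studyObserved", "SyntheticStudy", function(object) object@observed)

#' @rdname accessors
#' @export
setGeneric("studyTruth", function(object) standardGeneric("studyTruth"))
#' @rdname accessors
#' @export
setMethod("studyTruth", "SyntheticStudy", function(object) object@truth)

#' @rdname accessors
#' @export
setGeneric("studyChi", function(object) standardGeneric("studyChi"))
#' @rdname accessors
#' @export
setMethod("studyChi", "SyntheticStudy", function(object) object@chi)

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "ModeBasis", function(object) {
    cat("ModeBasis with", nModes(object), "modes\n")
    if (nModes(object) > 0L) {
        rng <- range(object@wavenumber)
        cat(sprintf("  wavenumbers: %.1f - %.1f cm-1\n", rng[1], rng[2]))
        cat("  characters:", paste(utils::head(unique(object@character), 6),
                                   collapse = ", "),
            if (length(unique(object@character)) > 6) "..." else "", "\n")
    }
})

setMethod("show", "AnharmonicConstants", function(object) {
    cat("AnharmonicConstants over", chiDim(object), "modes")
    if (chiDim(object) > 0L)
        cat(sprintf("; diag range [%.2f, %.2f] cm-1",
                    min(diag(object@chi)), max(diag(object@chi))))
    cat("\n")
})

setMethod("show", "TransitionLedger", function(object) {
    cat("TransitionLedger (", object@provenance, ") with ",
        nTransitions(object), " transitions over ", nModes(object),
        " modes\n", sep = "")
    if (nTransitions(object) > 0L) {
        tab <- table(factor(object@transitions$class,
                            levels = TRANSITION_CLASSES))
        cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
            "\n", sep = "")
        rng <- range(object@transitions$position)
        cat(sprintf("  positions: %.1f - %.1f cm-1\n", rng[1], rng[2]))
    }
})

setMethod("show", "Spectrum", function(object) {
    n <- length(object@wavenumber)
    cat("Spectrum [", technique(object), "], ", n, " points", sep = "")
    if (n > 0L)
        cat(sprintf(", %.1f - %.1f cm-1", object@wavenumber[1],
                    object@wavenumber[n]))
    cat("\n")
})

setMethod("show", "RegionReport", function(object) {
    cat(sprintf("RegionReport %.0f-%.0f cm-1, total integral %.4g\n",
                object@region[1], object@region[2], object@totalIntegral))
    if (object@defined) {
        f <- object@fractions
        for (k in names(f))
            cat(sprintf("  %-20s %6.2f%%\n", k, 100 * f[[k]]))
    } else {
        cat("  (no intensity in region; fractions undefined)\n")
    }
})

setMethod("show", "SyntheticStudy", function(object) {
    cat("SyntheticStudy (seed ", object@truth$seed, ")\n", sep = "")
    show(object@ledger)
    show(object@observed)
})
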