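#' Curated band tables for crystalline menadione (vitamin K3)
#'
#' The package ships, as plain CSV under `extdata`, curated experimental
#' and calculated band positions (cm-1) with relative intensities and
#' mode-character assignments for crystalline menadione
#' (2-methyl-1,4-naphthoquinone):
#' \describe{
#'   \item{`"mir-fundamentals"`}{fundamental bands, 1800-400 cm-1;
#'     experimental DRIFT positions with qualitative intensities and two
#'     sets of periodic-harmonic calculated positions/intensities
#'     (columns `gatti_*` and `tzvp_*`, named after the basis sets), each
#'     with its signed position difference (exp - calc).}
#'   \item{`"ch-region"`}{the C-H stretching window, 3600-2600 cm-1, from
#'     anharmonic calculations; the `fundamental` column flags the six
#'     fundamental features, everything else being first overtones and
#'     binary combinations.  Split experimental features (e.g. 3075/3070)
#'     appear as two rows sharing one calculated partner.}
#'   \item{`"comb-4000-3600"` and `"comb-2800-1800"`}{the two MIR windows
#'     free of fundamentals, populated exclusively by overtones and
#'     binary combinations.}
#' }
#' Rows keep the order of the underlying assignment listing (descending
#' position, with occasional deliberate crossings), which is what the
#' `"aligned"` method of [matchPeaks()] consumes.
#'
#' @param which table identifier, see above.
#' @return A data.frame.
#' @examples
#' head(menadioneBandTable("ch-region"))
#' @export
menadioneBandTable <- function(which = c("mir-fundamentals", "ch-region",
                                         "comb-4000-3600",
                                         "comb-2800-1800")) {
    which <- match.arg(which)
    file <- switch(which,
                   "mir-fundamentals" = "menadione_mir_fundamentals.csv",
                   "ch-region" = "menadione_ch_region.csv",
                   "comb-4000-3600" = "menadione_comb_4000_3600.csv",
                   "comb-2800-1800" = "menadione_comb_2800_1800.csv")
    path <- system.file("extdata", file, package = "anharmonicIR",
                        mustWork = TRUE)
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Transition ledger from a menadione band table
#'
#' Converts the calculated columns of a [menadioneBandTable()] into a
#' [TransitionLedger-class].  Calculated features that serve several split
#' experimental rows are deduplicated so each transition appears once.
#' The underlying normal modes are not disclosed by tabulated data, so the
#' ledger's mode basis is empty and the quanta column is blank; classes
#' come from the tables' explicit class column.
#'
#' @param which table identifier as in [menadioneBandTable()].
#' @param calcSet for `"mir-fundamentals"`: which calculated column set to
#'   use, `"gatti"` or `"tzvp"`.
#' @return A [TransitionLedger-class].
#' @examples
#' menadioneLedger("ch-region")
#' @export
menadioneLedger <- function(which = c("ch-region", "comb-4000-3600",
                                      "comb-2800-1800", "mir-fundamentals"),
                            calcSet = c("gatti", "tzvp")) {
    which <- match.arg(which)
    tab <- menadioneBandTable(which)
    if (which == "mir-fundamentals") {
        calcSet <- match.arg(calcSet)
        pos <- tab[[paste0(calcSet, "_position")]]
        int <- tab[[paste0(calcSet, "_intensity")]]
        keep <- is.finite(pos)
        tr <- data.frame(quanta = "", position = pos[keep],
                         intensity = int[keep], class = "fundamental",
                         label = tab$assignment[keep],
                         stringsAsFactors = FALSE)
        provenance <- paste0("periodic harmonic (", calcSet, ")")
    } else {
        keep <- is.finite(tab$calc_position) &
            !duplicated(tab$calc_position)
        tr <- data.frame(quanta = "", position = tab$calc_position[keep],
                         intensity = tab$calc_intensity[keep],
                         class = tab$class[keep],
                         label = tab$assignment[keep],
                         stringsAsFactors = FALSE)
        provenance <- "anharmonic VPT2"
    }
    TransitionLedger(ModeBasis(), tr, provenance = provenance)
}

#' Standard wavenumber windows of the menadione study configuration
#'
#' Named regions used throughout the shipped configuration: the C-H
#' stretching window, the two fundamental-free MIR windows, the
#' fingerprint region, and the NIR range.
#'
#' @return Named list of `c(low, high)` windows in cm-1.
#' @export
menadioneRegions <- function() {
    list("ch-stretch" = c(2600, 3600),
         "upper-mir" = c(3600, 4000),
         "comb-mir" = c(1800, 2800),
         "fingerprint" = c(400, 1800),
         "nir" = c(4000, 7000))
}

#' Default matching tolerance for a wavenumber region
#'
#' Assignment tolerances reflect how far anharmonic/harmonic calculated
#' positions stray from experiment in each region: 40 cm-1 in and below
#' the fingerprint/combination region, 65 cm-1 above 2600 cm-1 where
#' printed deviations reach about 60 cm-1.
#'
#' @param wavenumber a representative wavenumber of the region (cm-1).
#' @return Tolerance in cm-1.
#' @export
defaultTolerance <- function(wavenumber)
    ifelse(wavenumber > 2600, 65, 40)
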