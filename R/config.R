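#' Default run configuration
#'
#' The run configuration collects every tunable of the pipeline in one
#' serialisable list: named wavenumber windows, per-technique line-shape
#' defaults (8 cm-1 for the 2 cm-1-resolution MIR techniques, 16 cm-1 for
#' 4 cm-1-resolution NIR), WLS mode, matching tolerances (40 cm-1 up to
#' 2600 cm-1, 65 cm-1 above), qualitative intensity-label thresholds, an
#' output directory and a seed.
#'
#' @param ... named overrides.
#' @return Named list.
#' @seealso [readRunConfig()], [writeRunConfig()]
#' @export
defaultRunConfig <- function(...) {
    cfg <- list(
        regions = menadioneRegions(),
        lineshape = list(ATR = list(fwhmGauss = 8, fwhmLorentz = 8),
                         DRIFT = list(fwhmGauss = 8, fwhmLorentz = 8),
                         NIR = list(fwhmGauss = 16, fwhmLorentz = 16),
                         synthetic = list(fwhmGauss = 8, fwhmLorentz = 8)),
        areaMode = "area",
        wlsMode = "single",
        tolerances = list(below2600 = 40, above2600 = 65),
        intensityThresholds = c(vs = 0.75, s = 0.50, m = 0.25, w = 0.05),
        outputDir = ".",
        seed = 1L)
    over <- list(...)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
        stop("unknown config entries: ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    validateRunConfig(cfg)
}

validateRunConfig <- function(cfg) {
    for (nm in names(cfg$regions)) {
        rg <- as.numeric(cfg$regions[[nm]])
        if (length(rg) != 2L || rg[1] >= rg[2])
            stop("invalid region '", nm, "': must be c(low, high)")
        cfg$regions[[nm]] <- rg
    }
    th <- unlist(cfg$intensityThresholds)
    if (any(diff(th) >= 0))
        stop("intensity thresholds must be strictly decreasing")
    cfg$intensityThresholds <- th
    cfg$seed <- as.integer(cfg$seed)
    cfg
}

#' Read / write a run configuration as YAML
#'
#' Round-trip stable: `readRunConfig(writeRunConfig(cfg, path))` returns a
#' configuration equal to `cfg`.
#'
#' @param path YAML file.
#' @param cfg configuration list (see [defaultRunConfig()]).
#' @return `readRunConfig` returns the validated configuration list;
#'   `writeRunConfig` invisibly returns `path`.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    validateRunConfig(yaml::read_yaml(path))
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(cfg, path) {
    yaml::write_yaml(cfg, path)
    invisible(path)
}

#' Line-shape parameters for a technique from a run configuration
#'
#' @param cfg configuration list.
#' @param technique one of the technique tags in `cfg$lineshape`.
#' @return A [LineShapeParams-class].
#' @export
configLineShape <- function(cfg, technique = "synthetic") {
    ls <- cfg$lineshape[[technique]]
    if (is.null(ls))
        stop("no line-shape defaults for technique '", technique, "'")
    lineShapeParams(ls$fwhmGauss, ls$fwhmLorentz, cfg$areaMode)
}

#' Serialize a synthetic study to a directory
#'
#' Writes `ledger.csv`, `observed.jdx` (JCAMP-DX), `truth.json` and
#' `config.yaml`.  With the same study the output is byte-identical,
#' making simulation runs reproducible artefact-for-artefact.
#'
#' @param study a [SyntheticStudy-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @seealso [generateStudy()]
#' @export
writeStudy <- function(study, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeTransitions(studyLedger(study), file.path(dir, "ledger.csv"))
    writeSpectrum(studyObserved(study), file.path(dir, "observed.jdx"),
                  title = "synthetic observed spectrum")
    truth <- studyTruth(study)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    cfgOut <- study@config
    cfgOut$regions <- lapply(cfgOut$regions, as.numeric)
    yaml::write_yaml(cfgOut, file.path(dir, "config.yaml"))
    invisible(dir)
}
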