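# Tokenize a JCAMP-DX / text data line into numbers.  Handles AFFN
# (whitespace-separated), PAC (sign-glued, e.g. "1000+0.5-0.3") and
# typographic Unicode minus signs uniformly.
numTokens <- function(line) {
    line <- gsub("−", "-", line)
    m <- gregexpr("[+-]?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?", line)[[1]]
    if (m[1] == -1L) return(numeric())
    as.numeric(regmatches(line, list(m))[[1]])
}

#' Read a spectrum from JCAMP-DX or two-column text
#'
#' JCAMP-DX support covers the `##XYDATA=(X++(Y..Y))` form in both the
#' AFFN and PAC numeric dialects, plus `##XYPOINTS=(XY..XY)`; `XFACTOR`,
#' `YFACTOR`, `DELTAX` and descending storage are honoured.  Two-column
#' text is wavenumber/absorbance pairs, `#` comments allowed.  Typographic
#' minus signs (U+2212) are accepted everywhere.  The returned grid is
#' always ascending (descending files are reversed consistently).
#'
#' @param path input file.
#' @param format `"auto"` (default; JCAMP is recognised by its `##TITLE`
#'   header), `"jcamp"` or `"text"`.
#' @return A [Spectrum-class]; metadata records the source units and
#'   title where present.
#' @seealso [writeSpectrum()]
#' @export
readSpectrum <- function(path, format = c("auto", "jcamp", "text")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    if (format == "auto")
        format <- if (any(grepl("^##TITLE", lines[seq_len(min(5, length(lines)))])))
            "jcamp" else "text"
    if (format == "jcamp") readJcamp(lines, path) else readXY(lines, path)
}

readXY <- function(lines, path) {
    x <- numeric(); y <- numeric()
    for (k in seq_along(lines)) {
        ln <- sub("#.*$", "", lines[k])
        if (!nzchar(trimws(ln))) next
        tok <- numTokens(ln)
        if (length(tok) != 2L)
            stop("format error in ", path, " at line ", k,
                 ": expected two numeric columns")
        x <- c(x, tok[1]); y <- c(y, tok[2])
    }
    if (!length(x))
        stop("format error in ", path, ": no data points")
    Spectrum(x, y, technique = "unknown",
             metadata = list(source = path, format = "two-column-text"))
}

readJcamp <- function(lines, path) {
    labels <- list()
    dataStart <- NA_integer_; dataKind <- NA_character_
    for (k in seq_along(lines)) {
        ln <- lines[k]
        if (startsWith(ln, "##")) {
            eq <- regexpr("=", ln, fixed = TRUE)
            if (eq == -1L)
                stop("format error in ", path, " at line ", k,
                     ": malformed label line")
            key <- toupper(gsub("[^A-Za-z]", "",
                                substr(ln, 3L, eq - 1L)))
            val <- trimws(substr(ln, eq + 1L, nchar(ln)))
            labels[[key]] <- val
            if (key == "XYDATA") { dataStart <- k + 1L; dataKind <- "xydata" }
            if (key == "XYPOINTS") { dataStart <- k + 1L; dataKind <- "xypoints" }
        }
    }
    if (is.na(dataStart))
        stop("format error in ", path, ": no ##XYDATA or ##XYPOINTS block")
    xf <- as.numeric(labels[["XFACTOR"]] %||% "1")
    yf <- as.numeric(labels[["YFACTOR"]] %||% "1")
    deltax <- suppressWarnings(as.numeric(labels[["DELTAX"]] %||% NA))
    if (is.na(deltax) &&
        !is.null(labels[["FIRSTX"]]) && !is.null(labels[["LASTX"]]) &&
        !is.null(labels[["NPOINTS"]])) {
        np <- as.numeric(labels[["NPOINTS"]])
        if (np > 1)
            deltax <- (as.numeric(labels[["LASTX"]]) -
                       as.numeric(labels[["FIRSTX"]])) / (np - 1)
    }
    x <- numeric(); y <- numeric()
    for (k in dataStart:length(lines)) {
        ln <- lines[k]
        if (startsWith(ln, "##")) break
        tok <- numTokens(ln)
        if (!length(tok)) next
        if (dataKind == "xypoints") {
            if (length(tok) %% 2L != 0L)
                stop("format error in ", path, " at line ", k,
                     ": odd token count in XYPOINTS")
            x <- c(x, tok[seq(1L, length(tok), 2L)] * xf)
            y <- c(y, tok[seq(2L, length(tok), 2L)] * yf)
        } else {
            if (length(tok) < 2L)
                stop("format error in ", path, " at line ", k,
                     ": XYDATA line needs an abscissa and ordinates")
            if (is.na(deltax))
                stop("format error in ", path, " at line ", k,
                     ": XYDATA without DELTAX/FIRSTX/LASTX/NPOINTS")
            ys <- tok[-1L]
            x <- c(x, (tok[1L] + deltax * (seq_along(ys) - 1L)) * xf)
            y <- c(y, ys * yf)
        }
    }
    if (!length(x))
        stop("format error in ", path, ": empty data block")
    tech <- labels[["SPECTROMETERTYPE"]] %||% "unknown"
    res <- suppressWarnings(as.numeric(labels[["RESOLUTION"]] %||% NA))
    Spectrum(x, y, technique = tech, resolution = res,
             metadata = list(source = path, format = "jcamp-dx",
                             title = labels[["TITLE"]] %||% "",
                             xunits = labels[["XUNITS"]] %||% "1/CM",
                             yunits = labels[["YUNITS"]] %||% "ABSORBANCE"))
}

#' Write a spectrum to JCAMP-DX or two-column text
#'
#' JCAMP-DX output is `##XYDATA=(X++(Y..Y))` in AFFN with unit factors and
#' full double precision (round-trips through [readSpectrum()] to within
#' 1e-9).
#'
#' @param spectrum a [Spectrum-class].
#' @param path output file.
#' @param format `"jcamp"` or `"text"`.
#' @param title JCAMP title record.
#' @return Invisibly, `path`.
#' @export
writeSpectrum <- function(spectrum, path, format = c("jcamp", "text"),
                          title = "anharmonicIR spectrum") {
    format <- match.arg(format)
    x <- wavenumbers(spectrum); y <- absorbances(spectrum)
    if (format == "text") {
        writeLines(sprintf("%.10g %.10g", x, y), path)
        return(invisible(path))
    }
    n <- length(x)
    dx <- if (n > 1L) (x[n] - x[1]) / (n - 1) else 0
    hdr <- c(sprintf("##TITLE=%s", title),
             "##JCAMP-DX=4.24",
             "##DATA TYPE=INFRARED SPECTRUM",
             sprintf("##SPECTROMETER TYPE=%s", technique(spectrum)),
             "##XUNITS=1/CM",
             "##YUNITS=ABSORBANCE",
             "##XFACTOR=1",
             "##YFACTOR=1",
             sprintf("##FIRSTX=%.10g", x[1]),
             sprintf("##LASTX=%.10g", x[n]),
             sprintf("##DELTAX=%.10g", dx),
             sprintf("##NPOINTS=%d", n),
             "##XYDATA=(X++(Y..Y))")
    body <- character()
    per <- 4L
    for (s in seq(1L, n, per)) {
        e <- min(s + per - 1L, n)
        body <- c(body, paste(sprintf("%.10g", c(x[s], y[s:e])),
                              collapse = " "))
    }
    writeLines(c(hdr, body, "##END="), path)
    invisible(path)
}

#' Infer the transition class from an assignment label
#'
#' Applies the label grammar of vibrational assignment tables: a leading
#' `2` marks a first overtone (`"2δring"`), a top-level `+` a binary
#' combination (`"δring + νCH"`); parenthesised mixed characters such as
#' `"(δring, νC=O)"` denote a *single* mode and never a combination.
#' Multiple alternative assignments separated by `;` are resolved by the
#' first one.  Anything else is a fundamental.
#'
#' @param label character vector of assignment labels.
#' @return Character vector of transition classes.
#' @examples
#' inferClassFromLabel(c("2δring", "δring + νCH", "(δring, νC=O)"))
#' @export
inferClassFromLabel <- function(label) {
    vapply(label, function(lb) {
        lb <- trimws(strsplit(lb, ";", fixed = TRUE)[[1]][1])
        collapsed <- gsub("\\([^)]*\\)", "M", lb)
        if (grepl("^\\s*2", collapsed)) "first_overtone"
        else if (grepl("\\+", collapsed)) "binary_combination"
        else "fundamental"
    }, "", USE.NAMES = FALSE)
}

#' Read a transition ledger from CSV or JSON
#'
#' Requires `position` and `intensity` columns; the transition class is
#' taken from (in order of precedence) a parsed `quanta` column, an
#' explicit `class` column, or the label grammar applied to a `label` (or
#' `assignment`) column -- see [inferClassFromLabel()].  Typographic minus
#' signs are accepted in numeric columns.
#'
#' @param path CSV or JSON file (JSON as written by [writeTransitions()]).
#' @param provenance provenance string for the ledger.
#' @return A [TransitionLedger-class] (with an empty mode basis unless a
#'   quanta column allows reconstruction of mode ids).
#' @export
readTransitions <- function(path, provenance = NULL) {
    if (!file.exists(path))
        stop("file not found: ", path)
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
        doc <- jsonlite::fromJSON(path)
        tab <- as.data.frame(doc$transitions, stringsAsFactors = FALSE)
        if (is.null(provenance)) provenance <- doc$provenance %||% "file"
        modes <- if (!is.null(doc$modes) && length(doc$modes$wavenumber))
            ModeBasis(doc$modes$wavenumber, doc$modes$character)
        else ModeBasis()
    } else {
        tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                               encoding = "UTF-8")
        modes <- ModeBasis()
        if (is.null(provenance)) provenance <- "file"
    }
    names(tab) <- tolower(names(tab))
    if ("position_cm1" %in% names(tab) && !"position" %in% names(tab))
        tab$position <- tab$position_cm1
    missing <- setdiff(c("position", "intensity"), names(tab))
    if (length(missing))
        stop("schema error in ", path, ": missing columns ",
             paste(missing, collapse = ", "))
    toNum <- function(v) {
        if (is.numeric(v)) return(v)
        as.numeric(gsub("−", "-", v))
    }
    pos <- toNum(tab$position)
    int <- toNum(tab$intensity)
    lab <- if ("label" %in% names(tab)) as.character(tab$label)
           else if ("assignment" %in% names(tab)) as.character(tab$assignment)
           else rep("", nrow(tab))
    quanta <- if ("quanta" %in% names(tab)) as.character(tab$quanta)
              else rep("", nrow(tab))
    cls <- if (any(nzchar(quanta))) {
        vapply(seq_along(quanta), function(i)
            if (nzchar(quanta[i])) classifyTransition(quanta[i])
            else NA_character_, "")
    } else rep(NA_character_, nrow(tab))
    if ("class" %in% names(tab))
        cls[is.na(cls)] <- as.character(tab$class)[is.na(cls)]
    if (anyNA(cls)) {
        if (!any(nzchar(lab)))
            stop("schema error in ", path,
                 ": need a quanta, class, or label/assignment column ",
                 "to determine transition classes")
        cls[is.na(cls)] <- inferClassFromLabel(lab[is.na(cls)])
    }
    tr <- data.frame(quanta = quanta, position = pos, intensity = int,
                     class = cls, label = lab, stringsAsFactors = FALSE)
    TransitionLedger(modes, tr, provenance = provenance)
}

#' Write a transition ledger to CSV or JSON
#'
#' @param ledger a [TransitionLedger-class].
#' @param path output file.
#' @param format `"csv"` or `"json"` (default by file extension).
#' @return Invisibly, `path`.
#' @export
writeTransitions <- function(ledger, path, format = NULL) {
    if (is.null(format))
        format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
                  else "csv"
    tr <- transitions(ledger)
    if (format == "csv") {
        out <- data.frame(quanta = tr$quanta, position_cm1 = tr$position,
                          intensity = tr$intensity, class = tr$class,
                          label = tr$label)
        utils::write.csv(out, path, row.names = FALSE,
                         fileEncoding = "UTF-8")
    } else {
        mb <- modeBasis(ledger)
        doc <- list(provenance = provenance(ledger),
                    modes = list(wavenumber = modeWavenumbers(mb),
                                 character = modeCharacters(mb)),
                    transitions = tr)
        jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                             dataframe = "columns")
    }
    invisible(path)
}
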