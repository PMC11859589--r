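#' Centroided MS/MS spectrum
#'
#' Peaks are stored as a two-column matrix (`mz`, `intensity`), kept sorted
#' ascending by m/z. The precursor m/z is not required to exceed every
#' fragment m/z (isotope peaks above the precursor are legal), but all m/z
#' values must be positive and intensities non-negative.
#'
#' @slot id Spectrum identifier.
#' @slot precursorMz Precursor m/z in Th.
#' @slot polarity `+1L` (positive mode) or `-1L` (negative mode).
#' @slot retentionTime Retention time in minutes.
#' @slot peaks Numeric matrix with columns `mz`, `intensity`.
#' @export
setClass("Spectrum", representation(id = "character",
                                    precursorMz = "numeric",
                                    polarity = "integer",
                                    retentionTime = "numeric",
                                    peaks = "matrix"))

setValidity("Spectrum", function(object) {
  pk <- object@peaks
  if (!is.numeric(pk) || ncol(pk) != 2L)
    return("peaks must be a numeric matrix with columns mz, intensity")
  if (!identical(colnames(pk), c("mz", "intensity")))
    return("peak columns must be named mz, intensity")
  if (nrow(pk)) {
    if (any(pk[, "mz"] <= 0)) return("all peak m/z must be positive")
    if (any(pk[, "intensity"] < 0)) return("intensities must be >= 0")
    if (is.unsorted(pk[, "mz"])) return("peaks must be sorted by m/z")
  }
  if (!object@polarity %in% c(1L, -1L)) return("polarity must be +1 or -1")
  if (length(object@precursorMz) && !is.na(object@precursorMz) &&
      object@precursorMz <= 0)
    return("precursor m/z must be positive")
  TRUE
})

#' Construct a Spectrum
#'
#' @param id Identifier.
#' @param precursorMz Precursor m/z.
#' @param polarity `+1`/`-1` (or `"+"`/`"-"`).
#' @param retentionTime Retention time in minutes (default `NA`).
#' @param mz,intensity Parallel peak vectors; sorted on construction.
#' @return A [Spectrum-class].
#' @export
newSpectrum <- function(id, precursorMz, polarity, mz, intensity,
                     retentionTime = NA_real_) {
  if (is.character(polarity))
    polarity <- if (polarity %in% c("+", "positive")) 1L else -1L
  polarity <- as.integer(polarity)
  stopifnot(length(mz) == length(intensity))
  o <- order(mz)
  pk <- cbind(mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]))
  new("Spectrum", id = as.character(id), precursorMz = as.numeric(precursorMz),
      polarity = polarity, retentionTime = as.numeric(retentionTime),
      peaks = pk)
}

#' @describeIn Spectrum-class peak matrix accessor
#' @param x A `Spectrum`.
#' @export
peaks <- function(x) x@peaks

#' @describeIn Spectrum-class precursor m/z accessor
#' @export
precursorMz <- function(x) x@precursorMz

#' @describeIn Spectrum-class polarity accessor (+1/-1)
#' @export
polarity <- function(x) x@polarity

#' @describeIn Spectrum-class spectrum identifier accessor
#' @export
spectrumId <- function(x) x@id

#' @describeIn Spectrum-class retention time (minutes) accessor
#' @export
retentionTime <- function(x) x@retentionTime

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum ", object@id, ": precursor ",
      sprintf("%.4f", object@precursorMz),
      if (object@polarity > 0) " [+]" else " [-]",
      ", RT ", sprintf("%.2f", object@retentionTime), " min, ",
      nrow(object@peaks), " peaks\n", sep = "")
})

#' Normalize a spectrum to its base peak
#'
#' Rescales intensities so the most intense peak is 100; relative intensities
#' are preserved. Normalization is always explicit — reading spectra never
#' rescales.
#'
#' @param s A [Spectrum-class] with at least one peak.
#' @return A new `Spectrum`.
#' @export
basePeakNormalize <- function(s) {
  stopifnot(is(s, "Spectrum"))
  pk <- s@peaks
  if (!nrow(pk)) stop("cannot normalize a spectrum with no peaks")
  top <- max(pk[, "intensity"])
  if (top <= 0) stop("cannot normalize a spectrum with all-zero intensities")
  pk[, "intensity"] <- 100 * pk[, "intensity"] / top
  initialize(s, peaks = pk)
}

.guessFormat <- function(path, format) {
  format <- match.arg(tolower(format), c("auto", "mgf", "msp"))
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mgf", "msp")) return(ext)
  stop("cannot guess spectral format from extension: ", sQuote(path))
}

#' Read MS/MS spectra from MGF or MSP text files
#'
#' MGF records are `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS`,
#' `CHARGE` (e.g. `1+`/`1-`) and optional `RTINSECONDS`; MSP records start at
#' `Name:` with `PrecursorMZ:`, `Ion_mode:` (`P`/`N`), optional
#' `RetentionTime:` (minutes) and `Num Peaks:`. Peak lists are sorted by m/z
#' on read; intensities are kept on their original scale.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"mgf"` or `"msp"`.
#' @return A list of [Spectrum-class] objects (empty list for an empty file).
#' @export
readSpectra <- function(path, format = "auto") {
  if (!file.exists(path)) stop("no such file: ", sQuote(path))
  format <- .guessFormat(path, format)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (format == "mgf") .readMgf(lines) else .readMsp(lines)
}

.parsePeakLines <- function(lines, where) {
  if (!length(lines)) return(cbind(mz = numeric(0), intensity = numeric(0)))
  parts <- strsplit(lines, "[ \t]+")
  mz <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (any(is.na(mz)) || any(is.na(it)))
    stop("malformed peak line in record ", where)
  cbind(mz = mz, intensity = it)
}

.readMgf <- function(lines) {
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends))
    stop("unbalanced BEGIN IONS/END IONS blocks")
  out <- vector("list", length(begins))
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    block <- block[block != ""]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- toupper(sub("=.*", "", block[kv]))
    vals <- sub("^[^=]*=", "", block[kv])
    getval <- function(k) if (k %in% keys) vals[match(k, keys)] else NA
    title <- getval("TITLE")
    if (is.na(title)) title <- paste0("spectrum_", i)
    pep <- getval("PEPMASS")
    if (is.na(pep)) stop("record ", i, ": missing PEPMASS")
    pep <- as.numeric(strsplit(pep, "[ \t]+")[[1]][1])
    charge <- getval("CHARGE")
    pol <- if (!is.na(charge) && grepl("-", charge)) -1L else 1L
    rt <- getval("RTINSECONDS")
    rt <- if (is.na(rt)) NA_real_ else as.numeric(rt) / 60
    out[[i]] <- tryCatch({
      pk <- .parsePeakLines(block[!kv], i)
      newSpectrum(title, pep, pol, pk[, "mz"], pk[, "intensity"],
               retentionTime = rt)
    }, error = function(e) stop("malformed MGF record ", i, ": ",
                                conditionMessage(e)))
  }
  out
}

.readMsp <- function(lines) {
  starts <- grep("^Name:", lines, ignore.case = TRUE)
  if (!length(starts)) {
    if (all(lines == "")) return(list())
    stop("no 'Name:' records found in MSP file")
  }
  bounds <- c(starts, length(lines) + 1L)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    block <- block[block != ""]
    kv <- grepl("^[A-Za-z_ ]+:", block)
    keys <- tolower(trimws(sub(":.*", "", block[kv])))
    vals <- trimws(sub("^[^:]*:", "", block[kv]))
    getval <- function(k) if (k %in% keys) vals[match(k, keys)] else NA
    nm <- getval("name")
    pep <- suppressWarnings(as.numeric(getval("precursormz")))
    if (is.na(pep)) stop("MSP record ", i, " (", nm, "): missing PrecursorMZ")
    mode <- getval("ion_mode")
    pol <- if (!is.na(mode) && toupper(substr(mode, 1, 1)) == "N") -1L else 1L
    rt <- suppressWarnings(as.numeric(getval("retentiontime")))
    pk <- .parsePeakLines(block[!kv], i)
    npk <- suppressWarnings(as.integer(getval("num peaks")))
    if (!is.na(npk) && npk != nrow(pk))
      stop("MSP record ", i, ": Num Peaks (", npk,
           ") disagrees with peak list (", nrow(pk), ")")
    out[[i]] <- newSpectrum(nm, pep, pol, pk[, "mz"], pk[, "intensity"],
                         retentionTime = rt)
  }
  out
}

#' Write spectra to MGF or MSP
#'
#' @param spectra List of [Spectrum-class] objects.
#' @param path Output file.
#' @param format `"auto"`, `"mgf"` or `"msp"`.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(spectra, path, format = "auto") {
  format <- .guessFormat(path, format)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    pk <- s@peaks
    pklines <- sprintf("%.6f %.4f", pk[, "mz"], pk[, "intensity"])
    if (format == "mgf") {
      hdr <- c("BEGIN IONS",
               paste0("TITLE=", s@id),
               sprintf("PEPMASS=%.6f", s@precursorMz),
               paste0("CHARGE=1", if (s@polarity > 0) "+" else "-"),
               if (!is.na(s@retentionTime))
                 sprintf("RTINSECONDS=%.4f", s@retentionTime * 60))
      writeLines(c(hdr, pklines, "END IONS", ""), con)
    } else {
      hdr <- c(paste0("Name: ", s@id),
               sprintf("PrecursorMZ: %.6f", s@precursorMz),
               paste0("Ion_mode: ", if (s@polarity > 0) "P" else "N"),
               if (!is.na(s@retentionTime))
                 sprintf("RetentionTime: %.4f", s@retentionTime),
               paste0("Num Peaks: ", nrow(pk)))
      writeLines(c(hdr, pklines, ""), con)
    }
  }
  invisible(path)
}

#' Read an aligned LC-MS feature table
#'
#' Comma- or tab-delimited text with header columns `id`, `mz`, `rt_min`,
#' then optional `snr` and `blank_height`, then one column per sample holding
#' peak heights. Missing optional columns are filled with defaults
#' (`blank_height` 0, `snr` `Inf`) and reported via a message. Negative
#' heights are rejected.
#'
#' @param path File path.
#' @return A `data.frame` with one row per feature and an attribute
#'   `"samples"` naming the sample-height columns.
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", sQuote(path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("id", "mz", "rt_min")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("feature table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!"blank_height" %in% names(tab)) {
    message("feature table: no 'blank_height' column; defaulting to 0")
    tab$blank_height <- 0
  }
  if (!"snr" %in% names(tab)) {
    message("feature table: no 'snr' column; defaulting to Inf")
    tab$snr <- Inf
  }
  samples <- setdiff(names(tab), c(required, "snr", "blank_height"))
  if (!length(samples)) stop("feature table has no sample columns")
  hmat <- as.matrix(tab[samples])
  if (any(is.na(hmat))) stop("missing sample heights in feature table")
  if (any(hmat < 0)) stop("negative sample height in feature table")
  if (any(tab$blank_height < 0) || any(tab$snr < 0))
    stop("blank_height and snr must be non-negative")
  tab <- tab[c(required, "snr", "blank_height", samples)]
  attr(tab, "samples") <- samples
  tab
}

#' Write a feature table
#'
#' @param features Feature `data.frame` as returned by [readFeatureTable()].
#' @param path Output path; `.csv` writes comma-separated, anything else tabs.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- features
  # keep Inf representable through write/read
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sample-height column names of a feature table
#' @param features A feature table from [readFeatureTable()].
#' @return Character vector of sample column names.
#' @export
featureSamples <- function(features) {
  s <- attr(features, "samples")
  if (is.null(s))
    s <- setdiff(names(features), c("id", "mz", "rt_min", "snr",
                                    "blank_height"))
  s
}
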