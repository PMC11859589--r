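#' QC and filtering configuration
#'
#' Thresholds for feature-level filtering and MS2 spectral-tag pairing. The
#' defaults are the standard untargeted-metabolomics criteria: features are
#' retained when the best sample-to-blank response ratio exceeds 5, the best
#' peak height exceeds 500 counts and the signal-to-noise ratio exceeds 10;
#' features whose QC-injection coefficient of variation exceeds 30% are
#' discarded. MS2 spectra are paired to MS1 features within 10 ppm and
#' 0.2 min by default (pairing tolerances are method parameters, not
#' literature constants, and are freely overridable).
#'
#' @param blank_ratio_min Minimum (exclusive) max-height/blank ratio.
#' @param height_min Minimum (exclusive) max peak height.
#' @param snr_min Minimum (exclusive) signal-to-noise ratio.
#' @param qc_cv_max Maximum (inclusive) QC coefficient of variation.
#' @param ms2_mz_tol_ppm MS2T pairing m/z tolerance in ppm.
#' @param ms2_rt_tol_min MS2T pairing retention-time tolerance in minutes.
#' @return A list of class `"QCConfig"`.
#' @export
qcConfig <- function(blank_ratio_min = 5, height_min = 500, snr_min = 10,
                     qc_cv_max = 0.30, ms2_mz_tol_ppm = 10,
                     ms2_rt_tol_min = 0.2) {
  cfg <- list(blank_ratio_min = blank_ratio_min, height_min = height_min,
              snr_min = snr_min, qc_cv_max = qc_cv_max,
              ms2_mz_tol_ppm = ms2_mz_tol_ppm,
              ms2_rt_tol_min = ms2_rt_tol_min)
  if (any(vapply(cfg, function(x) !is.numeric(x) || length(x) != 1L ||
                   is.na(x) || x <= 0, logical(1))))
    stop("all QC thresholds must be positive scalars")
  structure(cfg, class = "QCConfig")
}

#' Read a QC configuration from a key=value or YAML file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path Config file. YAML (`.yml`/`.yaml`) or `key = value` lines.
#' @return A `"QCConfig"` list.
#' @export
readQCConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", sQuote(path))
  if (tolower(tools::file_ext(path)) %in% c("yml", "yaml")) {
    vals <- yaml::read_yaml(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    keys <- trimws(sub("=.*", "", lines))
    vals <- as.list(as.numeric(trimws(sub("^[^=]*=", "", lines))))
    names(vals) <- keys
  }
  unknown <- setdiff(names(vals), names(formals(qcConfig)))
  if (length(unknown))
    stop("unknown QC config key(s): ", paste(unknown, collapse = ", "))
  do.call(qcConfig, vals)
}

#' Filter LC-MS features on blank ratio, height and signal-to-noise
#'
#' A feature is retained iff all three strict inequalities hold:
#' `max(sample heights) / blank_height > blank_ratio_min` (a zero blank
#' counts as an infinite ratio, i.e. passes), `max(sample heights) >
#' height_min`, and `snr > snr_min`. Background subtraction is realized as
#' the blank-ratio test; no spectral subtraction is performed. The height
#' criterion uses the maximum across samples so that a metabolite present
#' strongly in a single species survives. Row order is preserved and the
#' operation is idempotent.
#'
#' @param features Feature table from [readFeatureTable()].
#' @param config A [qcConfig()] (or individual thresholds via `...`).
#' @param ... Overrides passed to [qcConfig()].
#' @return The retained subset of `features`, with an attribute
#'   `"removed_counts"` tallying removals per criterion.
#' @export
filterFeatures <- function(features, config = qcConfig(), ...) {
  if (length(list(...))) config <- do.call(qcConfig, utils::modifyList(
    unclass(config), list(...)))
  samples <- featureSamples(features)
  h <- as.matrix(features[samples])
  maxh <- apply(h, 1L, max)
  ratio <- ifelse(features$blank_height == 0, Inf,
                  maxh / features$blank_height)
  pass_ratio <- ratio > config$blank_ratio_min
  pass_height <- maxh > config$height_min
  pass_snr <- features$snr > config$snr_min
  keep <- pass_ratio & pass_height & pass_snr
  removed <- c(blank_ratio = sum(!pass_ratio), height = sum(!pass_height),
               snr = sum(!pass_snr))
  message(sprintf(
    "filterFeatures: retained %d/%d (failed blank ratio %d, height %d, snr %d)",
    sum(keep), nrow(features), removed[1], removed[2], removed[3]))
  out <- features[keep, , drop = FALSE]
  attr(out, "samples") <- samples
  attr(out, "removed_counts") <- removed
  out
}

#' Coefficient-of-variation filter over QC injections
#'
#' Keeps a metabolite iff `sd/mean <= cv_max` over its QC-injection
#' abundances, with the sample (n-1) standard deviation. A metabolite whose
#' QC values are identically zero (sd 0, mean 0) is kept; zero mean with
#' positive sd is dropped (CV undefined/unstable). Decisions are invariant
#' under positive rescaling of a metabolite's QC values.
#'
#' @param qc Numeric matrix, metabolites in rows (rownames = ids), QC
#'   injections in columns; at least 2 columns.
#' @param cv_max Maximum CV (default 0.30).
#' @return Character vector of retained metabolite ids.
#' @export
qcCvFilter <- function(qc, cv_max = 0.30) {
  qc <- as.matrix(qc)
  if (ncol(qc) < 2L)
    stop("need at least 2 QC measurements per metabolite")
  if (is.null(rownames(qc))) rownames(qc) <- seq_len(nrow(qc))
  mu <- rowMeans(qc)
  sdv <- apply(qc, 1L, stats::sd)
  keep <- ifelse(mu == 0, sdv == 0, sdv / mu <= cv_max)
  rownames(qc)[keep]
}

#' Average biological replicates into per-crop means
#'
#' @param x Numeric matrix, metabolites in rows, replicate columns. `NA`
#'   (non-detected) is treated as 0 before averaging.
#' @param groups Factor/character of length `ncol(x)` mapping each replicate
#'   column to its crop. Every crop level must own at least one column.
#' @return Matrix metabolites x crops of arithmetic means, crop columns in
#'   first-appearance order.
#' @export
averageReplicates <- function(x, groups) {
  x <- as.matrix(x)
  if (length(groups) != ncol(x))
    stop("'groups' must have one entry per replicate column")
  groups <- as.character(groups)
  x[is.na(x)] <- 0
  crops <- unique(groups)
  out <- vapply(crops, function(g)
    rowMeans(x[, groups == g, drop = FALSE]), numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x), dimnames = list(rownames(x), crops))
  out
}

#' Pair MS/MS spectra with MS1 features into an MS2 spectral tag library
#'
#' Each spectrum is linked to the single feature minimizing the absolute
#' precursor ppm deviation among features within both the m/z and the
#' retention-time tolerance; spectra with no candidate remain unlinked and
#' are reported. Many spectra may link to one feature. Spectra without a
#' retention time never match when an RT tolerance is in force.
#'
#' @param features Feature table ([readFeatureTable()]).
#' @param spectra List of [Spectrum-class] objects.
#' @param mz_tol_ppm m/z tolerance (ppm) around the feature m/z.
#' @param rt_tol_min Retention-time tolerance in minutes.
#' @return `data.frame` with columns `spectrum_id`, `feature_id`,
#'   `mz_delta_ppm`, `rt_delta_min`; attribute `"unlinked"` holds the ids of
#'   spectra without a candidate feature.
#' @export
buildMS2T <- function(features, spectra, mz_tol_ppm = 10, rt_tol_min = 0.2) {
  if (!nrow(features) || !length(spectra))
    stop("buildMS2T needs non-empty features and spectra")
  rows <- list()
  unlinked <- character(0)
  for (s in spectra) {
    dppm <- ppmError(precursorMz(s), features$mz)
    drt <- retentionTime(s) - features$rt_min
    ok <- abs(dppm) <= mz_tol_ppm & !is.na(drt) & abs(drt) <= rt_tol_min
    if (!any(ok)) {
      unlinked <- c(unlinked, spectrumId(s))
      next
    }
    best <- which(ok)[which.min(abs(dppm[ok]))]
    rows[[length(rows) + 1L]] <- data.frame(
      spectrum_id = spectrumId(s), feature_id = features$id[best],
      mz_delta_ppm = dppm[best], rt_delta_min = drt[best],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spectrum_id = character(0), feature_id = character(0),
               mz_delta_ppm = numeric(0), rt_delta_min = numeric(0))
  if (length(unlinked))
    message("buildMS2T: ", length(unlinked), " spectra left unlinked")
  attr(out, "unlinked") <- unlinked
  out
}
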