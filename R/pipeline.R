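#' Read a pipeline run configuration
#'
#' YAML file with any of the keys accepted by [runPipeline()]; file paths
#' are validated here so a broken configuration fails before any stage
#' runs.
#'
#' @param path YAML config file.
#' @return A named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config error: no such file: ", sQuote(path))
  cfg <- yaml::read_yaml(path)
  for (key in c("spectra", "features", "panel", "rules", "pathway_map")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("config error: ", key, " file does not exist: ",
           sQuote(cfg[[key]]))
  }
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full comparative-metabolomics pipeline
#'
#' Sequences the package end to end: feature filtering and MS2 spectral-tag
#' pairing, rule-based spectrum annotation, presence/absence comparative
#' analytics, abundance clustering with class composition and
#' hypergeometric enrichment, and pathway abundance mapping. Inputs not
#' provided are generated synthetically from `seed`, which makes the
#' pipeline exercisable without any external data; identical configuration
#' and inputs give identical outputs.
#'
#' @param config Named list (or path to a YAML file, read via
#'   [readRunConfig()]) with optional entries: `spectra`, `features`,
#'   `panel`, `rules`, `pathway_map` (file paths), `out_dir` (default
#'   `tempfile()`), `seed` (default 1), `tol_ppm` (10),
#'   `max_substituents` (3), `k` (9), `qc` (list of [qcConfig()]
#'   overrides), `enrichment_correction` (`"none"`/`"BH"`). When no
#'   `pathway_map` is given, enrichment runs over the compound-class
#'   membership map derived from the panel.
#' @return Invisibly, a list with the results of every stage
#'   (`features`, `ms2t`, `annotations`, `comparative`, `clusters`,
#'   `composition`, `enrichment`, `pathway_abundance`, `out_dir`).
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- readRunConfig(config)
  for (key in c("spectra", "features", "panel", "rules", "pathway_map"))
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      stop("config error: ", key, " file does not exist: ",
           sQuote(config[[key]]))
  seed <- config$seed %||% 1
  out_dir <- config$out_dir %||% tempfile("cerealmet_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tol_ppm <- config$tol_ppm %||% 10
  max_sub <- config$max_substituents %||% 3
  k <- config$k %||% 9
  qc <- do.call(qcConfig, config$qc %||% list())
  rules <- .stage("rulebase", {
    if (is.null(config$rules)) defaultRulebase()
    else readRulebase(config$rules)
  })

  panel_bundle <- .stage("panel", {
    if (is.null(config$panel)) generatePanel(panelSpec(), seed = seed)
    else list(panel = readPanel(config$panel), truth = NULL)
  })
  panel <- panel_bundle$panel

  spectra <- .stage("spectra", {
    if (is.null(config$spectra)) benzoxazinoidSpectra(rules, seed = seed)
    else readSpectra(config$spectra)
  })

  features <- .stage("features", {
    if (is.null(config$features)) .syntheticFeatures(spectra)
    else readFeatureTable(config$features)
  })

  kept <- .stage("feature filtering", filterFeatures(features, qc))
  message("pipeline: ", nrow(kept), "/", nrow(features),
          " features retained")
  ms2t <- .stage("MS2T construction",
                 buildMS2T(kept, spectra, qc$ms2_mz_tol_ppm,
                           qc$ms2_rt_tol_min))
  message("pipeline: ", nrow(ms2t), " MS2T links")

  annotations <- .stage("annotation",
                        annotateLibrary(spectra, rules, tol_ppm, max_sub))
  message("pipeline: ", sum(annotations$class != "unannotated"), "/",
          nrow(annotations), " spectra annotated")

  comparative <- .stage("comparative analytics", comparativeReport(panel))
  clusters <- .stage("clustering", clusterPanel(panel, k = k))
  composition <- .stage("composition table",
                        compositionTable(clusters, classLabels(panel)))
  enr_map <- .stage("enrichment map", {
    if (is.null(config$pathway_map)) {
      cls <- classLabels(panel)
      data.frame(id = names(cls), pathway = unname(cls),
                 stringsAsFactors = FALSE)
    } else {
      m <- utils::read.delim(config$pathway_map, stringsAsFactors = FALSE)
      names(m)[1:2] <- c("id", "pathway")
      m
    }
  })
  enrichment <- .stage("enrichment", {
    asg <- clusterAssignment(clusters)
    do.call(rbind, lapply(seq_len(clusters@k), function(cl) {
      res <- hypergeomEnrichment(
        intersect(names(asg)[asg == cl], enr_map$id), enr_map,
        correction = config$enrichment_correction %||% "none")
      cbind(cluster = cl, res)
    }))
  })

  pathway_abundance <- .stage("pathway mapping", {
    graphs <- list(benzoxazinoid = benzoxazinoidPathway(),
                   flavonoid = flavonoidPathway())
    lapply(graphs, function(g) suppressMessages(mapAbundance(g, panel)))
  })

  .stage("report output", {
    writeFeatureTable(kept, file.path(out_dir, "filtered_features.tsv"))
    utils::write.table(ms2t, file.path(out_dir, "ms2t.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(annotations, file.path(out_dir, "annotations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(id = comparative$shared),
      file.path(out_dir, "shared_metabolites.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)
    summ <- data.frame(
      species = speciesNames(panel),
      n_detected = colSums(presence(panel)),
      n_specific = lengths(comparative$specific)[speciesNames(panel)],
      n_missing = lengths(comparative$missing)[speciesNames(panel)])
    utils::write.table(summ, file.path(out_dir, "species_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(class = names(comparative$class_cv),
                 cv_percent = unname(comparative$class_cv)),
      file.path(out_dir, "class_cv.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)
    asg <- clusterAssignment(clusters)
    utils::write.table(
      data.frame(id = names(asg), cluster = unname(asg),
                 crop = cropOfCluster(clusters)[as.character(asg)]),
      file.path(out_dir, "clusters.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(class = rownames(compositionCounts(composition)),
                 compositionCounts(composition),
                 check.names = FALSE),
      file.path(out_dir, "composition.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)
    utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (nm in names(pathway_abundance))
      utils::write.table(
        pathway_abundance[[nm]],
        file.path(out_dir, paste0("pathway_abundance_", nm, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
  })
  invisible(list(features = kept, ms2t = ms2t, annotations = annotations,
                 comparative = comparative, clusters = clusters,
                 composition = composition, enrichment = enrichment,
                 pathway_abundance = pathway_abundance,
                 truth = panel_bundle$truth, panel = panel,
                 out_dir = out_dir))
}

# feature table matching a set of spectra (one feature per spectrum, well
# above the QC thresholds), used when the pipeline runs purely
# synthetically
.syntheticFeatures <- function(spectra) {
  df <- data.frame(
    id = paste0("F", sprintf("%03d", seq_along(spectra))),
    mz = vapply(spectra, precursorMz, numeric(1)),
    rt_min = vapply(spectra, retentionTime, numeric(1)),
    snr = 50, blank_height = 10,
    sample_1 = 5000, sample_2 = 4000, sample_3 = 4500,
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "samples") <- c("sample_1", "sample_2", "sample_3")
  df
}
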