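#' log2 transform with pseudocount
#'
#' @param x Non-negative numeric matrix or vector.
#' @param pseudocount Added before the log (default 1).
#' @return `log2(x + pseudocount)`.
#' @export
log2Transform <- function(x, pseudocount = 1) {
  if (any(x < 0)) stop("abundances must be non-negative")
  log2(x + pseudocount)
}

#' Row-wise Z-scores
#'
#' Centers and scales each row to mean 0 and sample (n-1) standard
#' deviation 1. Constant rows (sd 0) cannot be scaled; they are dropped
#' with a message and reported in the `"dropped"` attribute.
#'
#' @param x Numeric matrix.
#' @return Z-scored matrix, possibly with fewer rows.
#' @export
zscoreRows <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 1L, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (any(const))
    message("zscoreRows: dropping ", sum(const), " constant row(s)")
  x <- x[!const, , drop = FALSE]
  out <- t(scale(t(x)))
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "dropped") <- rownames(as.matrix(sds))[const] %||%
    which(const)
  out
}

#' PCA of a metabolite panel
#'
#' Species are the observations: the metabolite-by-species matrix is
#' transposed and passed to [stats::prcomp()] with centering but no
#' variable scaling (the data are expected to be log2-transformed already).
#'
#' @param x Numeric matrix, metabolites x samples, with >= 2 samples.
#' @return List with `scores` (samples x components) and `explained`
#'   (non-increasing variance fractions summing to <= 1).
#' @export
panelPCA <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("PCA needs at least 2 samples")
  p <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  list(scores = p$x, explained = p$sdev^2 / sum(p$sdev^2))
}

#' Hierarchical clustering of panel metabolites
#'
#' Deterministic clustering of the abundance profiles: log2 transform, row
#' Z-scores, Euclidean distances, agglomeration (Ward by default), and a
#' cut into `k` clusters. Each cluster is then assigned to the species with
#' the highest mean Z-score over its members — the crop in which the
#' cluster's metabolites specifically accumulate.
#'
#' @slot k Number of clusters.
#' @slot assignment Named integer vector, metabolite -> cluster id.
#' @slot cropOfCluster Named character vector, cluster id -> species.
#' @slot linkage,metric Parameters used.
#' @slot dropped Ids of constant rows excluded before clustering.
#' @export
setClass("ClusterResult", representation(k = "integer",
                                         assignment = "integer",
                                         cropOfCluster = "character",
                                         linkage = "character",
                                         metric = "character",
                                         dropped = "character"))

setValidity("ClusterResult", function(object) {
  a <- object@assignment
  if (is.null(names(a))) return("assignment must be named by metabolite id")
  if (length(unique(a)) != object@k) return("empty cluster in assignment")
  if (!all(sort(unique(a)) == seq_len(object@k)))
    return("cluster ids must be 1..k")
  TRUE
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: ", length(object@assignment), " metabolites in ",
      object@k, " clusters (", object@linkage, "/", object@metric, ")\n",
      sep = "")
  print(table(cluster = object@assignment))
})

#' @describeIn ClusterResult-class metabolite -> cluster assignment
#' @param x A `ClusterResult`.
#' @export
clusterAssignment <- function(x) x@assignment

#' @describeIn ClusterResult-class cluster -> accumulating species map
#' @export
cropOfCluster <- function(x) x@cropOfCluster

#' @rdname ClusterResult-class
#' @param panel A [PanelMatrix-class] (or a plain abundance matrix).
#' @param k Number of clusters (default 9, one per species of a nine-crop
#'   panel).
#' @param linkage [stats::hclust()] method, default `"ward.D2"`.
#' @param metric [stats::dist()] method, default `"euclidean"`.
#' @param pseudocount For the log2 transform.
#' @return A `ClusterResult`.
#' @export
clusterPanel <- function(panel, k = 9, linkage = "ward.D2",
                         metric = "euclidean", pseudocount = 1) {
  x <- if (is(panel, "PanelMatrix")) abundances(panel) else as.matrix(panel)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1L ||
      k > nrow(x))
    stop("'k' must be an integer between 1 and the number of metabolites")
  k <- as.integer(k)
  z <- zscoreRows(log2Transform(x, pseudocount))
  dropped <- as.character(attr(z, "dropped"))
  if (k > nrow(z)) stop("'k' exceeds the number of non-constant rows")
  hc <- stats::hclust(stats::dist(z, method = metric), method = linkage)
  raw <- stats::cutree(hc, k = k)
  # relabel clusters by the lexicographically smallest member id so the
  # partition labels are invariant under row permutations of the input
  reps <- vapply(seq_len(k), function(cl) min(names(raw)[raw == cl]),
                 character(1))
  relab <- stats::setNames(match(reps[raw], sort(reps)), names(raw))
  crop <- vapply(seq_len(k), function(cl) {
    mz <- colMeans(z[relab == cl, , drop = FALSE])
    colnames(z)[which.max(mz)]
  }, character(1))
  names(crop) <- as.character(seq_len(k))
  new("ClusterResult", k = k, assignment = relab, cropOfCluster = crop,
      linkage = linkage, metric = metric, dropped = dropped)
}

#' Class-by-cluster composition table
#'
#' Cross-tabulates compound classes against clusters and flags cells that
#' concentrate a class: `"*"` where a cluster holds at least 20% of the
#' class's metabolites, `"**"` at least 40% (class-total denominator). The
#' thresholds are inclusive so that a 20.0% cell is flagged.
#'
#' @slot counts Integer matrix, classes x clusters.
#' @slot flags Character matrix of `""`/`"*"`/`"**"`.
#' @export
setClass("CompositionTable", representation(counts = "matrix",
                                            flags = "matrix"))

setValidity("CompositionTable", function(object) {
  if (!identical(dim(object@counts), dim(object@flags)))
    return("counts and flags must have identical shape")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' @describeIn CompositionTable-class class x cluster count matrix
#' @param x A `CompositionTable`.
#' @export
compositionCounts <- function(x) x@counts

#' @describeIn CompositionTable-class flag matrix (`""`, `"*"`, `"**"`)
#' @export
compositionFlags <- function(x) x@flags

#' @describeIn CompositionTable-class row (class) totals
#' @export
classTotals <- function(x) rowSums(x@counts)

#' @describeIn CompositionTable-class column (cluster) totals
#' @export
clusterTotals <- function(x) colSums(x@counts)

setMethod("show", "CompositionTable", function(object) {
  cnt <- object@counts
  disp <- matrix(paste0(cnt, ifelse(object@flags == "", "",
                                    paste0(" ", object@flags))),
                 nrow = nrow(cnt), dimnames = dimnames(cnt))
  disp <- cbind(disp, total = rowSums(cnt))
  print(disp, quote = FALSE)
  cat("cluster totals:", paste(colSums(cnt), collapse = " "),
      "| grand total:", sum(cnt), "\n")
})

#' @rdname CompositionTable-class
#' @param clusters A [ClusterResult-class] (or a named cluster vector).
#' @param classes Named character vector metabolite id -> class (e.g.
#'   [classLabels()]); must cover every clustered metabolite.
#' @param flag_star,flag_double Inclusive flag thresholds on
#'   count/class-total (defaults 0.20 and 0.40).
#' @return A `CompositionTable`.
#' @export
compositionTable <- function(clusters, classes, flag_star = 0.20,
                             flag_double = 0.40) {
  asg <- if (is(clusters, "ClusterResult")) clusterAssignment(clusters)
         else clusters
  ids <- names(asg)
  if (!all(ids %in% names(classes)))
    stop("class labels missing for some clustered metabolites")
  cls <- classes[ids]
  cnt <- table(class = cls, cluster = asg)
  cnt <- matrix(as.integer(cnt), nrow = nrow(cnt), dimnames = dimnames(cnt))
  share <- cnt / rowSums(cnt)
  flags <- matrix("", nrow = nrow(cnt), ncol = ncol(cnt),
                  dimnames = dimnames(cnt))
  flags[share >= flag_star] <- "*"
  flags[share >= flag_double] <- "**"
  new("CompositionTable", counts = cnt, flags = flags)
}

#' Read a class-by-cluster distribution table
#'
#' Reads a delimited class x cluster count table (first column = class
#' label, remaining columns = clusters) such as the packaged
#' `cluster_class_distribution.tsv`, re-deriving the >=20% / >=40% flags
#' from the counts.
#'
#' @param path File path; default the packaged nine-crop distribution of
#'   1131 metabolites over 18 classes.
#' @return A [CompositionTable-class].
#' @export
readCompositionTable <- function(path = system.file(
    "extdata", "cluster_class_distribution.tsv", package = "cerealmet",
    mustWork = TRUE)) {
  tab <- utils::read.delim(path, check.names = FALSE)
  cnt <- as.matrix(tab[, -1, drop = FALSE])
  rownames(cnt) <- tab[[1]]
  storage.mode(cnt) <- "integer"
  share <- cnt / rowSums(cnt)
  flags <- matrix("", nrow = nrow(cnt), ncol = ncol(cnt),
                  dimnames = dimnames(cnt))
  flags[share >= 0.20] <- "*"
  flags[share >= 0.40] <- "**"
  new("CompositionTable", counts = cnt, flags = flags)
}

#' Hypergeometric over-representation test for pathway membership
#'
#' For each pathway, tests whether the cluster contains more pathway
#' members than expected by chance from the background: the one-sided
#' upper-tail hypergeometric probability `P(X >= k)` with overlap `k`,
#' cluster size `n`, pathway size `K` and background size `N`. No
#' multiple-testing correction is applied by default; Benjamini-Hochberg
#' adjusted values are available with `correction = "BH"`.
#'
#' @param cluster_ids Metabolite ids in the cluster (must lie in the
#'   background).
#' @param pathway_map `data.frame` with columns `id`, `pathway` (a
#'   metabolite may map to several pathways).
#' @param background Background metabolite ids; defaults to all mapped ids.
#' @param correction `"none"` (default) or `"BH"`.
#' @return `data.frame` sorted by p-value with columns `pathway`, `k`, `n`,
#'   `K`, `N`, `p_value` (and `p_adjusted` under BH).
#' @export
hypergeomEnrichment <- function(cluster_ids, pathway_map,
                                background = unique(pathway_map$id),
                                correction = c("none", "BH")) {
  correction <- match.arg(correction)
  if (!length(background)) stop("background set is empty")
  background <- unique(background)
  if (!all(cluster_ids %in% background))
    stop("cluster ids must be a subset of the background")
  if (!all(c("id", "pathway") %in% names(pathway_map)))
    stop("pathway_map needs 'id' and 'pathway' columns")
  pathway_map <- pathway_map[pathway_map$id %in% background, , drop = FALSE]
  cluster_ids <- unique(cluster_ids)
  N <- length(background)
  n <- length(cluster_ids)
  out <- do.call(rbind, lapply(split(pathway_map$id, pathway_map$pathway),
    function(members) {
      members <- unique(members)
      K <- length(members)
      k <- sum(cluster_ids %in% members)
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      data.frame(k = k, n = n, K = K, N = N, p_value = p)
    }))
  out <- cbind(pathway = rownames(out), out)
  rownames(out) <- NULL
  if (correction == "BH")
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$pathway), , drop = FALSE]
}
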