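#' Metabolites detected in every species
#'
#' @param panel A [PanelMatrix-class] with at least one species.
#' @return Character vector of metabolite ids present in all species.
#' @export
sharedMetabolites <- function(panel) {
  stopifnot(ncol(panel) >= 1L)
  pr <- presence(panel)
  rownames(pr)[rowSums(pr) == ncol(pr)]
}

#' Species-specific metabolites
#'
#' A metabolite is specific to a species when it is detected there and
#' nowhere else; the per-species sets are pairwise disjoint.
#'
#' @param panel A [PanelMatrix-class] with at least two species.
#' @return Named list (one element per species) of metabolite id vectors.
#' @export
speciesSpecific <- function(panel) {
  stopifnot(ncol(panel) >= 2L)
  pr <- presence(panel)
  one <- rowSums(pr) == 1L
  lapply(stats::setNames(colnames(pr), colnames(pr)),
         function(sp) rownames(pr)[one & pr[, sp]])
}

#' Species-missing metabolites
#'
#' A metabolite is missing for a species when it is undetected there but
#' detected in every other species — a candidate pathway deficiency of that
#' species.
#'
#' @param panel A [PanelMatrix-class] with at least two species.
#' @return Named list of metabolite id vectors.
#' @export
speciesMissing <- function(panel) {
  stopifnot(ncol(panel) >= 2L)
  pr <- presence(panel)
  allbut <- rowSums(pr) == ncol(pr) - 1L
  lapply(stats::setNames(colnames(pr), colnames(pr)),
         function(sp) rownames(pr)[allbut & !pr[, sp]])
}

#' Detection proportion of a metabolite class in a species
#'
#' The number of class members detected in the species divided by the total
#' number of class members on the panel.
#'
#' @param panel A [PanelMatrix-class].
#' @param class Compound-class label.
#' @param species Species name(s); default all species.
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
detectionProportion <- function(panel, class, species = speciesNames(panel)) {
  cls <- classLabels(panel)
  if (!class %in% cls) stop("unknown metabolite class: ", sQuote(class))
  if (!all(species %in% speciesNames(panel)))
    stop("unknown species in 'species'")
  pr <- presence(panel)[cls == class, species, drop = FALSE]
  colSums(pr) / nrow(pr)
}

#' Coefficient of variation of a class's detection proportions
#'
#' Computes the per-species detection proportions of one metabolite class
#' and returns `100 * sd / mean` over species, with the sample (n-1)
#' standard deviation. Under this convention a class detected at any equal
#' proportion in exactly 3 of 9 species and nowhere else has a CV of
#' exactly 150% regardless of the common proportion (scale invariance);
#' taxonomically restricted classes therefore sit at the top of the CV
#' ranking.
#'
#' @param panel A [PanelMatrix-class] with at least two species.
#' @param class Compound-class label.
#' @return CV as a percentage.
#' @export
classCV <- function(panel, class) {
  stopifnot(ncol(panel) >= 2L)
  p <- detectionProportion(panel, class)
  if (all(p == 0))
    stop("CV undefined: class ", sQuote(class), " detected nowhere")
  100 * stats::sd(p) / mean(p)
}

#' Presence-pattern (upset) counts
#'
#' Groups metabolites by their exact presence pattern across species; every
#' metabolite belongs to exactly one combination, so the counts sum to the
#' panel size. Patterns are labelled by the `+`-joined species names (the
#' empty pattern is `"(none)"`).
#'
#' @param panel A [PanelMatrix-class].
#' @return Named integer vector of counts, sorted decreasing.
#' @export
upsetCounts <- function(panel) {
  pr <- presence(panel)
  pat <- apply(pr, 1L, function(r) {
    s <- colnames(pr)[r]
    if (length(s)) paste(s, collapse = "+") else "(none)"
  })
  sort(table(pat), decreasing = TRUE)
}

#' Full presence/absence comparative report
#'
#' Convenience wrapper producing the shared set, the species-specific and
#' species-missing maps, per-class per-species detection proportions and
#' per-class CVs in one call.
#'
#' @param panel A [PanelMatrix-class].
#' @return List with elements `shared`, `specific`, `missing`,
#'   `detection_proportions` (class x species matrix), `class_cv` (named
#'   vector, `NA` for all-absent classes), `upset`.
#' @export
comparativeReport <- function(panel) {
  classes <- sort(unique(classLabels(panel)))
  dp <- t(vapply(classes, function(cl) detectionProportion(panel, cl),
                 numeric(ncol(panel))))
  cv <- vapply(classes, function(cl)
    tryCatch(classCV(panel, cl), error = function(e) NA_real_), numeric(1))
  list(shared = sharedMetabolites(panel),
       specific = speciesSpecific(panel),
       missing = speciesMissing(panel),
       detection_proportions = dp,
       class_cv = sort(cv, decreasing = TRUE, na.last = TRUE),
       upset = upsetCounts(panel))
}
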