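# All randomness flows from one integer seed: each sub-generator derives its
# own stream seed from (seed, stream-name) and runs under withr::with_seed,
# so sub-generators are mutually independent and reproducible.
.subSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) %% 65521) * 32749 + h) %% 2147483629L + 1L
}

#' The nine cereal species of the default panel
#' @return Character vector of species names.
#' @export
panelSpecies <- function() {
  c("rice", "wheat", "maize", "barley", "sorghum", "common oat",
    "foxtail millet", "broomcorn millet", "adlay")
}

#' Default compound-class sizes of the default panel
#' @return Named integer vector over 18 classes summing to 1131.
#' @export
panelClassSizes <- function() {
  c("AA and derivatives" = 101L, "Alcohols and polyols" = 48L,
    "Alkaloids" = 64L, "BA and derivatives" = 14L, "Benzoxazinoids" = 8L,
    "Coumarins and lignans" = 39L, "Flavonoids" = 311L,
    "HCA derivatives" = 59L, "Lipids" = 172L,
    "Nucleotides and derivates" = 48L, "Organic acids" = 57L,
    "Others" = 30L, "Phenolamides" = 46L, "Phenolic acids" = 33L,
    "Phytohormones" = 27L, "Quinate and derivatives" = 16L,
    "Terpenoids" = 26L, "Vitamins" = 32L)
}

#' Specification of a synthetic metabolite panel
#'
#' Defines the statistical structure the comparative and clustering stages
#' assume: a shared core detected in every species, per-species specific
#' and missing metabolites, taxonomically restricted classes (by default
#' the eight-benzoxazinoid class confined to maize, wheat and adlay), and
#' per-metabolite "home crop" abundance elevation driving the nine
#' abundance clusters. Non-detection is structural (a presence mask), not
#' censoring at a limit. Defaults reproduce the headline composition of a
#' nine-cereal leaf panel: 1131 metabolites in 18 classes, 530 shared,
#' 4-12 species-specific per crop, and home-crop block sizes of
#' 100-154 metabolites.
#'
#' @param species Species names.
#' @param class_sizes Named class sizes; must sum to the panel size.
#' @param n_shared Size of the shared core.
#' @param specific_counts Named per-species species-specific counts.
#' @param missing_counts Named per-species species-missing counts.
#' @param restricted_classes Named list class -> allowed species subset.
#' @param cluster_sizes Named per-species home-crop block sizes; must sum
#'   to the panel size.
#' @param effect_size Mean log2 elevation of a metabolite in its home crop.
#' @param noise_sd Log2-scale abundance noise standard deviation.
#' @param base_log2_mean,base_log2_sd Log2 baseline abundance distribution.
#' @return A list of class `"PanelSpec"`.
#' @export
panelSpec <- function(species = panelSpecies(),
                      class_sizes = panelClassSizes(),
                      n_shared = 530L,
                      specific_counts = c("rice" = 8L, "wheat" = 9L,
                        "maize" = 4L, "barley" = 6L, "sorghum" = 12L,
                        "common oat" = 4L, "foxtail millet" = 5L,
                        "broomcorn millet" = 9L, "adlay" = 9L),
                      missing_counts = c("rice" = 8L, "wheat" = 8L,
                        "maize" = 8L, "barley" = 16L, "sorghum" = 6L,
                        "common oat" = 7L, "foxtail millet" = 12L,
                        "broomcorn millet" = 3L, "adlay" = 43L),
                      restricted_classes = list(
                        "Benzoxazinoids" = c("maize", "wheat", "adlay")),
                      cluster_sizes = c("maize" = 115L, "adlay" = 127L,
                        "rice" = 152L, "foxtail millet" = 130L,
                        "wheat" = 154L, "common oat" = 105L,
                        "barley" = 124L, "broomcorn millet" = 124L,
                        "sorghum" = 100L),
                      effect_size = 5, noise_sd = 0.5,
                      base_log2_mean = 4, base_log2_sd = 1.5) {
  spec <- list(species = species, class_sizes = class_sizes,
               n_shared = as.integer(n_shared),
               specific_counts = specific_counts,
               missing_counts = missing_counts,
               restricted_classes = restricted_classes,
               cluster_sizes = cluster_sizes,
               effect_size = effect_size, noise_sd = noise_sd,
               base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd)
  n <- sum(class_sizes)
  if (!setequal(names(specific_counts), species) ||
      !setequal(names(missing_counts), species) ||
      !setequal(names(cluster_sizes), species))
    stop("specific_counts, missing_counts and cluster_sizes must be named ",
         "by the panel species")
  if (sum(cluster_sizes) != n)
    stop("cluster_sizes must sum to the panel size (", n, ")")
  n_restricted <- sum(class_sizes[names(restricted_classes)])
  for (cl in names(restricted_classes))
    if (!all(restricted_classes[[cl]] %in% species))
      stop("restricted class ", sQuote(cl), " names unknown species")
  free <- n - n_restricted
  need <- spec$n_shared + sum(specific_counts) + sum(missing_counts)
  if (need > free)
    stop("infeasible spec: shared + specific + missing (", need,
         ") exceeds the ", free, " unrestricted metabolites")
  structure(spec, class = "PanelSpec")
}

# the eight benzoxazinoid glycoside structures used as the ids of the
# restricted benzoxazinoid class, so the packaged pathway graph maps onto
# the synthetic panel directly
.benzoxazinoidStructures <- function() {
  list("HBOA" = list(aglycone = "HBOA", substituents = character(0)),
       "HBOA-glucoside" = list(aglycone = "HBOA", substituents = "hexose"),
       "DIBOA-glucoside" = list(aglycone = "DIBOA", substituents = "hexose"),
       "DIBOA-glucoside-hexose" = list(aglycone = "DIBOA",
                                       substituents = c("hexose", "hexose")),
       "DIMBOA-glucoside" = list(aglycone = "DIMBOA",
                                 substituents = "hexose"),
       "DIMBOA-glucoside-hexose" = list(aglycone = "DIMBOA",
                                        substituents = c("hexose", "hexose")),
       "HMBOA-acetyl-glucoside" = list(aglycone = "HMBOA",
                                       substituents = c("hexose", "acetyl")),
       "HMBOA-glucoside-rhamnose" = list(
         aglycone = "HMBOA", substituents = c("hexose", "deoxyhexose")))
}

#' Generate a synthetic metabolite panel with known ground truth
#'
#' Draws presence patterns honoring the spec exactly (shared core,
#' per-species specific and missing sets, restricted classes detected in
#' exactly their allowed species, remaining metabolites in 2 to n-2
#' species), assigns every metabolite a home crop (respecting its presence
#' pattern, filling the per-crop block sizes as far as feasibility allows),
#' and draws log-normal abundances elevated by `effect_size` log2 units in
#' the home crop.
#'
#' @param spec A [panelSpec()].
#' @param seed Integer seed; identical seeds give identical panels.
#' @return List with `panel` (a [PanelMatrix-class]) and `truth` (planted
#'   `shared`, `specific`, `missing`, `restricted` id sets and the `home`
#'   crop assignment).
#' @export
generatePanel <- function(spec = panelSpec(), seed = 1) {
  stopifnot(inherits(spec, "PanelSpec"))
  withr::with_seed(.subSeed(seed, "panel"), .generatePanelImpl(spec))
}

.generatePanelImpl <- function(spec) {
  species <- spec$species
  nsp <- length(species)
  cls <- rep(names(spec$class_sizes), spec$class_sizes)
  ids <- character(length(cls))
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    if (cl == "Benzoxazinoids" &&
        length(idx) == length(.benzoxazinoidStructures()))
      ids[idx] <- names(.benzoxazinoidStructures())
    else
      ids[idx] <- sprintf("%s_%03d", gsub("[^A-Za-z]+", ".", cl),
                          seq_along(idx))
  }
  pres <- matrix(FALSE, length(ids), nsp, dimnames = list(ids, species))
  restricted_ids <- character(0)
  for (cl in names(spec$restricted_classes)) {
    ridx <- ids[cls == cl]
    pres[ridx, spec$restricted_classes[[cl]]] <- TRUE
    restricted_ids <- c(restricted_ids, ridx)
  }
  free <- setdiff(ids, restricted_ids)
  free <- sample(free)
  take <- function(n) {
    if (n == 0L) return(character(0))
    out <- free[seq_len(n)]
    free <<- free[-seq_len(n)]
    out
  }
  shared_ids <- take(spec$n_shared)
  pres[shared_ids, ] <- TRUE
  specific <- lapply(stats::setNames(species, species), function(sp) {
    sel <- take(spec$specific_counts[[sp]])
    pres[sel, sp] <<- TRUE
    sel
  })
  missing <- lapply(stats::setNames(species, species), function(sp) {
    sel <- take(spec$missing_counts[[sp]])
    pres[sel, setdiff(species, sp)] <<- TRUE
    sel
  })
  # background metabolites: present in 2..(nsp-2) species so they never
  # collide with the planted specific/missing/shared definitions
  for (id in free) {
    ksp <- sample(2:(nsp - 2L), 1L)
    pres[id, sample(species, ksp)] <- TRUE
  }
  # home-crop assignment against the per-crop block quotas
  quota <- spec$cluster_sizes[species]
  home <- stats::setNames(character(length(ids)), ids)
  for (id in sample(ids)) {
    avail <- species[pres[id, ]]
    best <- avail[which.max(quota[avail])]
    home[id] <- best
    quota[best] <- quota[best] - 1L
  }
  base <- stats::rnorm(length(ids), spec$base_log2_mean, spec$base_log2_sd)
  eff <- outer(rep(1, length(ids)), rep(0, nsp))
  eff[cbind(seq_along(ids), match(home, species))] <- spec$effect_size
  l2 <- base + eff + matrix(stats::rnorm(length(ids) * nsp, 0,
                                         spec$noise_sd),
                            length(ids), nsp)
  ab <- 2^l2 * pres
  dimnames(ab) <- dimnames(pres)
  list(panel = panelMatrix(ab, cls),
       truth = list(shared = shared_ids, specific = specific,
                    missing = missing, restricted = restricted_ids,
                    home = home))
}

#' Generate a synthetic MS/MS spectrum from an annotation hypothesis
#'
#' The inverse of the annotation grammar: emits the theoretical precursor,
#' Y0, characteristic-loss, cross-ring and absolute diagnostic peaks for
#' the given aglycone/substituent combination, optionally perturbed by
#' Gaussian ppm noise. With `ppm_noise = 0` the peaks sit exactly on the
#' theoretical values, so re-annotation recovers the generating hypothesis
#' at rank 1.
#'
#' @param aglycone Aglycone name in `rulebase`.
#' @param substituentNames Substituent names (repeats allowed; aliases
#'   resolved).
#' @param rulebase A [Rulebase-class].
#' @param ppm_noise Gaussian m/z noise standard deviation in ppm.
#' @param seed Integer seed (only relevant when `ppm_noise > 0`).
#' @param id Spectrum id; defaults to `aglycone+substituents`.
#' @param rt Retention time in minutes.
#' @return A [Spectrum-class].
#' @export
generateSpectrum <- function(aglycone, substituentNames = character(0),
                             rulebase = defaultRulebase(), ppm_noise = 0,
                             seed = 1, id = NULL, rt = 3.0) {
  agl <- aglycones(rulebase)[[aglycone]]
  if (is.null(agl)) stop("unknown aglycone: ", sQuote(aglycone))
  subNames <- if (length(substituentNames))
    resolveSubstituent(rulebase, substituentNames) else character(0)
  pol <- agl$polarities[1]
  exp <- .expectedFragments(agl, subNames, substituents(rulebase),
                            ionSpecies(pol))
  inten <- ifelse(exp$label == "precursor", 55,
           ifelse(exp$label == "Y0", 100,
           ifelse(grepl("^Y0-", exp$label), 45, 35)))
  mz <- exp$mz
  if (ppm_noise > 0) {
    key <- paste(aglycone, paste(subNames, collapse = "+"))
    mz <- withr::with_seed(.subSeed(seed, paste("spectrum", key)),
      mz * (1 + stats::rnorm(length(mz), 0, ppm_noise) * 1e-6))
  }
  if (is.null(id))
    id <- paste(c(aglycone, sort(subNames)), collapse = "+")
  newSpectrum(id, precursorMz = mz[exp$label == "precursor"],
              polarity = pol, mz = mz, intensity = inten,
              retentionTime = rt)
}

#' Synthetic spectra of the eight detected benzoxazinoid glycosides
#'
#' One spectrum per structure of the packaged benzoxazinoid pathway's
#' quantified nodes (HBOA and its glucoside, DIBOA-glucoside and its
#' hexoside, DIMBOA-glucoside and its hexoside, HMBOA-acetyl-glucoside,
#' HMBOA-glucoside-rhamnose).
#'
#' @param rulebase A [Rulebase-class].
#' @param ppm_noise,seed Passed to [generateSpectrum()].
#' @return Named list of [Spectrum-class]; attribute `"truth"` is a
#'   `data.frame` of the generating aglycone/substituents.
#' @export
benzoxazinoidSpectra <- function(rulebase = defaultRulebase(),
                                 ppm_noise = 0, seed = 1) {
  structs <- .benzoxazinoidStructures()
  out <- lapply(names(structs), function(nm)
    generateSpectrum(structs[[nm]]$aglycone, structs[[nm]]$substituents,
                     rulebase, ppm_noise, seed, id = nm))
  names(out) <- names(structs)
  attr(out, "truth") <- data.frame(
    id = names(structs),
    aglycone = vapply(structs, `[[`, "", "aglycone"),
    substituents = vapply(structs, function(s)
      paste(sort(s$substituents), collapse = "+"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Generate QC injection replicates for a panel
#'
#' Log-normal multiplicative noise around each metabolite's mean detected
#' abundance, parameterized so the expected value equals the mean and the
#' coefficient of variation equals `qc_cv` (for a log-normal,
#' `sigma^2 = log(1 + cv^2)`). `qc_cv = 0` gives identical injections.
#'
#' @param panel A [PanelMatrix-class].
#' @param qc_cv Target coefficient of variation (>= 0).
#' @param n_injections Number of QC injections.
#' @param seed Integer seed.
#' @return Matrix metabolites x injections.
#' @export
generateQCInjections <- function(panel, qc_cv = 0.15, n_injections = 10,
                                 seed = 1) {
  stopifnot(qc_cv >= 0, n_injections >= 1)
  ab <- abundances(panel)
  mu <- rowMeans(ab)
  if (qc_cv == 0) {
    out <- matrix(rep(mu, n_injections), nrow = length(mu))
  } else {
    sigma <- sqrt(log(1 + qc_cv^2))
    out <- withr::with_seed(.subSeed(seed, "qc"), {
      fac <- matrix(stats::rlnorm(length(mu) * n_injections,
                                  meanlog = -sigma^2 / 2, sdlog = sigma),
                    nrow = length(mu))
      mu * fac
    })
  }
  dimnames(out) <- list(rownames(ab),
                        sprintf("QC%02d", seq_len(n_injections)))
  out
}

#' Annotation round-trip recovery over the rulebase grid
#'
#' Generates a spectrum for every (aglycone, substituent multiset)
#' combination within the search bounds — multisets of size 0 to 2 over the
#' O-linked residues, plus C-linked sugar combinations for the flavone
#' aglycones — and re-annotates each, scoring whether the rank-1 hypothesis
#' equals the generating one.
#'
#' @param rulebase A [Rulebase-class].
#' @param ppm_noise Gaussian m/z noise in ppm (0 = noise-free).
#' @param seed Integer seed.
#' @param tol_ppm Annotation tolerance.
#' @return `data.frame` with one row per grid case (`aglycone`,
#'   `substituents`, `top_aglycone`, `top_substituents`, `recovered`);
#'   attribute `"recovery"` is the overall top-1 recovery fraction.
#' @export
annotationRecovery <- function(rulebase = defaultRulebase(), ppm_noise = 0,
                               seed = 1, tol_ppm = 10) {
  subs <- substituents(rulebase)
  onames <- names(subs)[vapply(subs, function(s) s$linkage == "O",
                               logical(1))]
  cnames <- names(subs)[vapply(subs, function(s) s$linkage == "C",
                               logical(1))]
  osets <- c(list(character(0)), as.list(onames))
  for (i in seq_along(onames))
    for (j in i:length(onames))
      osets[[length(osets) + 1L]] <- c(onames[i], onames[j])
  rows <- list()
  for (agl in aglycones(rulebase)) {
    sets <- osets
    if (length(agl$fragments)) {  # flavone-type: C-glycosides are in scope
      for (cn in cnames) {
        sets <- c(sets, list(cn))
        for (on in onames) sets <- c(sets, list(c(cn, on)))
      }
    }
    for (ss in sets) {
      s <- generateSpectrum(agl$name, ss, rulebase, ppm_noise, seed)
      h <- annotateSpectrum(s, rulebase, tol_ppm = tol_ppm)
      truth <- paste(sort(ss), collapse = "+")
      rows[[length(rows) + 1L]] <- data.frame(
        aglycone = agl$name, substituents = truth,
        top_aglycone = if (nrow(h)) h$aglycone[1] else NA_character_,
        top_substituents = if (nrow(h)) h$substituents[1] else NA_character_,
        recovered = nrow(h) > 0 && h$aglycone[1] == agl$name &&
          h$substituents[1] == truth,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "recovery") <- mean(out$recovered)
  out
}
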