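#' Decompose a neutral loss into substituent multisets
#'
#' Exhaustively enumerates every multiset of catalog substituents (respecting
#' each item's `max_count`, a total-size bound, and at most one C-linked
#' sugar per multiset) whose summed residue mass matches the observed loss
#' within a ppm tolerance taken relative to the precursor m/z. Results are
#' sorted by multiset size ascending, then absolute mass error ascending.
#'
#' @param loss Observed neutral loss in Da (>= 0 up to tolerance).
#' @param rulebase A [Rulebase-class] (or a substituent definition list).
#' @param precursor_mz Precursor m/z against which the ppm tolerance is
#'   interpreted.
#' @param tol_ppm Tolerance in ppm of `precursor_mz`.
#' @param max_total Maximum multiset size (default 3).
#' @return List of character vectors (substituent names, repeats allowed;
#'   `character(0)` is the empty multiset for a ~0 loss), each with
#'   attribute `"mass_error"`. The empty list means no decomposition.
#' @export
decomposeNeutralLoss <- function(loss, rulebase, precursor_mz,
                                 tol_ppm = 10, max_total = 3) {
  subs <- if (is(rulebase, "Rulebase")) substituents(rulebase) else rulebase
  if (!length(subs)) stop("substituent catalog is empty")
  tol_da <- tol_ppm * 1e-6 * precursor_mz
  if (loss < -tol_da) return(list())
  masses <- vapply(subs, `[[`, numeric(1), "mass")
  maxc <- vapply(subs, `[[`, integer(1), "max_count")
  isC <- vapply(subs, function(s) s$linkage == "C", logical(1))
  nms <- names(subs)
  res <- list()
  recurse <- function(i, counts, total, csum, mass) {
    if (abs(loss - mass) <= tol_da) {
      sel <- rep(nms, counts)
      attr(sel, "mass_error") <- mass - loss
      res[[length(res) + 1L]] <<- sel
    }
    if (i > length(subs) || total >= max_total) return()
    if (mass - loss > tol_da) return()  # masses only grow
    recurse(i + 1L, counts, total, csum, mass)
    top <- min(maxc[i], max_total - total, if (isC[i]) 1L - csum else Inf)
    if (top >= 1L) {
      for (k in seq_len(top)) {
        counts[i] <- k
        recurse(i + 1L, counts, total + k, csum + if (isC[i]) k else 0L,
                mass + k * masses[i])
      }
    }
  }
  recurse(1L, integer(length(subs)), 0L, 0L, 0)
  if (!length(res)) return(list())
  sizes <- lengths(res)
  errs <- abs(vapply(res, attr, numeric(1), "mass_error"))
  keys <- vapply(res, function(x) paste(sort(x), collapse = "+"),
                 character(1))
  # a fully departed residue is by definition cleavable, so at equal mass
  # the O-linked reading of a neutral loss ranks before the C-linked one
  ncl <- vapply(res, function(x) sum(isC[match(x, nms)]), integer(1))
  ord <- order(sizes, errs, ncl, keys)
  res <- res[ord]
  res[!duplicated(keys[ord])]
}

# Expected diagnostic fragments for (aglycone, substituent multiset, ion).
# Y0 retains the aglycone plus all C-linked and mod substituents; O-linked
# substituents cleave.  Aglycone characteristic losses and C-sugar
# cross-ring losses are applied to the Y0 ion (which equals the precursor
# when nothing is cleavable); absolute fragments are ionized directly.
.expectedFragments <- function(agl, subNames, subs, ion) {
  defs <- subs[subNames]
  cleav <- vapply(defs, function(s) s$linkage == "O", logical(1))
  core <- agl$formula
  for (d in defs[!cleav]) core <- core + d$formula
  full <- core
  for (d in defs[cleav]) full <- full + d$formula
  precMz <- ionMz(full, ion)
  y0 <- ionMz(core, ion)
  lab <- character(0); mz <- numeric(0); score <- logical(0)
  addf <- function(l, m, s) {
    lab <<- c(lab, l); mz <<- c(mz, m); score <<- c(score, s)
  }
  addf("precursor", precMz, FALSE)
  if (any(cleav)) addf("Y0", y0, TRUE)
  for (ln in names(agl$losses))
    addf(paste0("Y0-", ln), y0 - formulaMass(agl$losses[[ln]]), TRUE)
  for (d in defs[!cleav & vapply(defs, function(s) s$linkage == "C",
                                 logical(1))])
    for (cn in names(d$cross_ring_losses))
      addf(paste0("Y0-", cn), y0 - formulaMass(d$cross_ring_losses[[cn]]),
           TRUE)
  for (fn in names(agl$fragments))
    addf(fn, ionMz(agl$fragments[[fn]], ion), TRUE)
  keep <- !duplicated(round(mz, 6))
  data.frame(label = lab[keep], mz = mz[keep], scored = score[keep],
             stringsAsFactors = FALSE)
}

#' Match expected characteristic fragments against a spectrum
#'
#' Each expected fragment is matched to the nearest peak within the ppm
#' tolerance; each peak is used at most once. The Y0 ion is part of the
#' evidence only when at least one cleavable (O-linked) substituent is
#' present, i.e. when Y0 differs from the precursor; the precursor itself is
#' never counted as fragment evidence.
#'
#' @param s A [Spectrum-class].
#' @param aglycone Aglycone name (must exist in `rulebase`).
#' @param substituentNames Character vector of substituent catalog names
#'   (repeats = multiplicity); aliases are resolved.
#' @param rulebase A [Rulebase-class].
#' @param tol_ppm Fragment matching tolerance in ppm.
#' @return `data.frame` with columns `label`, `theoretical`, `observed`,
#'   `ppm` — one row per matched, evidence-bearing fragment.
#' @export
matchCharacteristicFragments <- function(s, aglycone, substituentNames,
                                         rulebase, tol_ppm = 10) {
  agl <- aglycones(rulebase)[[aglycone]]
  if (is.null(agl)) stop("unknown aglycone: ", sQuote(aglycone))
  if (!polarity(s) %in% agl$polarities)
    stop("spectrum polarity does not match aglycone ", sQuote(aglycone))
  subNames <- if (length(substituentNames))
    resolveSubstituent(rulebase, substituentNames) else character(0)
  exp <- .expectedFragments(agl, subNames, substituents(rulebase),
                            ionSpecies(polarity(s)))
  .matchFragments(peaks(s), exp[exp$scored, , drop = FALSE], tol_ppm)
}

.matchFragments <- function(pk, exp, tol_ppm) {
  used <- logical(nrow(pk))
  rows <- list()
  if (nrow(pk)) for (i in seq_len(nrow(exp))) {
    dppm <- ppmError(pk[, "mz"], exp$mz[i])
    ok <- abs(dppm) <= tol_ppm & !used
    if (!any(ok)) next
    j <- which(ok)[which.min(abs(dppm[ok]))]
    used[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      label = exp$label[i], theoretical = exp$mz[i],
      observed = pk[j, "mz"], ppm = dppm[j], stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(0), theoretical = numeric(0),
               observed = numeric(0), ppm = numeric(0))
}

#' Annotate one MS/MS spectrum against a rulebase
#'
#' For every aglycone supporting the spectrum polarity, the precursor minus
#' the aglycone ion is decomposed into substituent multisets
#' ([decomposeNeutralLoss()]); each candidate hypothesis is then scored by
#' characteristic-fragment matching. Ranking is lexicographic: more matched
#' fragments first, then fewer substituents (parsimony), then smaller
#' absolute precursor ppm error, with an alphabetical tie-break that makes
#' the order total and deterministic.
#'
#' @param s A [Spectrum-class] with a precursor m/z.
#' @param rulebase A [Rulebase-class] (default [defaultRulebase()]).
#' @param tol_ppm Matching tolerance (precursor and fragments), default 10.
#' @param max_substituents Maximum substituents per hypothesis, default 3.
#' @return `data.frame` of ranked hypotheses with columns `rank`,
#'   `aglycone`, `class`, `substituents` (sorted, `+`-separated),
#'   `n_substituents`, `ion`, `theoretical_mz`, `precursor_ppm`,
#'   `n_matched`; attribute `"fragments"` is the per-hypothesis list of
#'   matched-fragment tables. Zero rows when nothing explains the precursor.
#' @export
annotateSpectrum <- function(s, rulebase = defaultRulebase(), tol_ppm = 10,
                             max_substituents = 3) {
  if (!length(precursorMz(s)) || is.na(precursorMz(s)))
    stop("spectrum ", sQuote(spectrumId(s)), " has no precursor m/z")
  ion <- ionSpecies(polarity(s))
  subs <- substituents(rulebase)
  rows <- list(); frags <- list()
  for (agl in aglycones(rulebase)) {
    if (!polarity(s) %in% agl$polarities) next
    loss <- precursorMz(s) - (agl$mass + ion@massShift)
    decomps <- decomposeNeutralLoss(loss, rulebase, precursorMz(s),
                                    tol_ppm = tol_ppm,
                                    max_total = max_substituents)
    for (d in decomps) {
      exp <- .expectedFragments(agl, d, subs, ion)
      theo <- exp$mz[exp$label == "precursor"]
      pppm <- ppmError(precursorMz(s), theo)
      if (abs(pppm) > tol_ppm) next
      m <- .matchFragments(peaks(s), exp[exp$scored, , drop = FALSE],
                           tol_ppm)
      key <- paste(sort(d), collapse = "+")
      rows[[length(rows) + 1L]] <- data.frame(
        aglycone = agl$name, class = agl$class, substituents = key,
        n_substituents = length(d), ion = ion@label, theoretical_mz = theo,
        precursor_ppm = pppm, n_matched = nrow(m), stringsAsFactors = FALSE)
      frags[[length(frags) + 1L]] <- m
    }
  }
  if (!length(rows)) {
    out <- data.frame(rank = integer(0), aglycone = character(0),
                      class = character(0), substituents = character(0),
                      n_substituents = integer(0), ion = character(0),
                      theoretical_mz = numeric(0), precursor_ppm = numeric(0),
                      n_matched = integer(0))
    attr(out, "fragments") <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$n_matched, out$n_substituents, abs(out$precursor_ppm),
               out$aglycone, out$substituents)
  out <- out[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "fragments") <- frags[ord]
  out
}

#' Verify that a hypothesis satisfies its own mass-closure invariants
#'
#' Independent re-check used by tests: the theoretical precursor must equal
#' the ionized aglycone-plus-residues formula, the precursor ppm must be
#' within tolerance, and every matched fragment must sit on a spectrum peak
#' within tolerance.
#'
#' @param s The annotated [Spectrum-class].
#' @param hyp One row of an [annotateSpectrum()] result.
#' @param fragments The corresponding matched-fragment table.
#' @param rulebase A [Rulebase-class].
#' @param tol_ppm Tolerance in ppm.
#' @return `TRUE`, or an error describing the violated invariant.
#' @export
validateHypothesis <- function(s, hyp, fragments,
                               rulebase = defaultRulebase(), tol_ppm = 10) {
  agl <- aglycones(rulebase)[[hyp$aglycone]]
  subNames <- if (nzchar(hyp$substituents))
    strsplit(hyp$substituents, "+", fixed = TRUE)[[1]] else character(0)
  f <- agl$formula
  for (nm in subNames) f <- f + substituents(rulebase)[[nm]]$formula
  theo <- ionMz(f, hyp$ion)
  if (abs(theo - hyp$theoretical_mz) > 1e-6)
    stop("theoretical precursor does not close over the formula sum")
  if (abs(ppmError(precursorMz(s), theo)) > tol_ppm)
    stop("precursor ppm outside tolerance")
  if (nrow(fragments)) {
    pk <- peaks(s)[, "mz"]
    for (i in seq_len(nrow(fragments))) {
      if (!any(abs(ppmError(pk, fragments$theoretical[i])) <= tol_ppm))
        stop("matched fragment has no supporting peak: ",
             fragments$label[i])
      if (abs(fragments$ppm[i]) > tol_ppm)
        stop("fragment ppm outside tolerance: ", fragments$label[i])
    }
  }
  TRUE
}

#' Annotate a spectral library
#'
#' Applies [annotateSpectrum()] to each spectrum and keeps the rank-1
#' hypothesis; spectra with no admissible hypothesis are reported as
#' `unannotated`.
#'
#' @param spectra Non-empty list of [Spectrum-class] objects (an empty list
#'   yields an empty table).
#' @param rulebase A [Rulebase-class].
#' @param tol_ppm Matching tolerance in ppm.
#' @param max_substituents Per-hypothesis substituent bound.
#' @return `data.frame` with one row per spectrum (`spectrum_id`,
#'   `aglycone`, `substituents`, `class`, `theoretical_mz`,
#'   `precursor_ppm`, `n_matched`; `class` is `"unannotated"` where no
#'   hypothesis exists) and attribute `"class_tally"`.
#' @export
annotateLibrary <- function(spectra, rulebase = defaultRulebase(),
                            tol_ppm = 10, max_substituents = 3) {
  rows <- lapply(spectra, function(s) {
    h <- annotateSpectrum(s, rulebase, tol_ppm, max_substituents)
    if (nrow(h)) {
      data.frame(spectrum_id = spectrumId(s), aglycone = h$aglycone[1],
                 substituents = h$substituents[1], class = h$class[1],
                 theoretical_mz = h$theoretical_mz[1],
                 precursor_ppm = h$precursor_ppm[1],
                 n_matched = h$n_matched[1], stringsAsFactors = FALSE)
    } else {
      data.frame(spectrum_id = spectrumId(s), aglycone = NA_character_,
                 substituents = NA_character_, class = "unannotated",
                 theoretical_mz = NA_real_, precursor_ppm = NA_real_,
                 n_matched = 0L, stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spectrum_id = character(0), aglycone = character(0),
               substituents = character(0), class = character(0),
               theoretical_mz = numeric(0), precursor_ppm = numeric(0),
               n_matched = integer(0))
  attr(out, "class_tally") <- table(out$class)
  out
}
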