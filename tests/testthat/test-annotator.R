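rb <- defaultRulebase()

test_that("rulebase loads with validated aglycones and substituents", {
  expect_s4_class(rb, "Rulebase")
  expect_setequal(names(aglycones(rb)),
                  c("HBOA", "HMBOA", "DIBOA", "DIMBOA", "apigenin",
                    "luteolin", "tricetin", "tricin"))
  expect_identical(resolveSubstituent(rb, c("glucose", "rhamnose")),
                   c("hexose", "deoxyhexose"))
  expect_error(resolveSubstituent(rb, "sulfate"), "unknown substituent")
})

test_that("neutral-loss decomposition finds the acetyl-hexose loss first", {
  d <- decomposeNeutralLoss(204.0639, rb, precursor_mz = 398.1102)
  expect_gt(length(d), 0)
  expect_identical(sort(d[[1]]), c("acetyl", "hexose"))
  # a ~zero loss decomposes to the empty multiset
  d0 <- decomposeNeutralLoss(0, rb, precursor_mz = 300)
  expect_length(d0, 1L)
  expect_length(d0[[1]], 0L)
  # a clearly negative loss has no decomposition
  expect_identical(decomposeNeutralLoss(-5, rb, precursor_mz = 300),
                   list())
})

test_that("decomposition equals exhaustive brute force on random losses", {
  subs <- substituents(rb)[1:6]
  withr::with_seed(41, {
    for (i in 1:40) {
      k <- sample(0:3, 1)
      picked <- sample(names(subs), k, replace = TRUE)
      # respect the same feasibility bounds the enumerator uses
      tab <- table(picked)
      ok <- all(tab <= vapply(subs[names(tab)], `[[`, integer(1),
                              "max_count"))
      if (!ok) next
      loss <- sum(vapply(subs[picked], `[[`, numeric(1), "mass")) +
        rnorm(1, 0, 5e-4)
      prec <- 600
      got <- decomposeNeutralLoss(loss, subs, precursor_mz = prec,
                                  tol_ppm = 10, max_total = 3)
      keys <- sort(vapply(got, function(x) paste(sort(x), collapse = "+"),
                          character(1)))
      expect_identical(keys, bf_decompose(loss, subs, 10e-6 * prec, 3))
    }
  })
})

test_that("the HMBOA-acetyl-hexose example annotates at rank 1", {
  s <- readSpectra(system.file("extdata", "cl1148.mgf",
                               package = "cerealmet"))[[1]]
  h <- annotateSpectrum(s, rb)
  expect_identical(h$aglycone[1], "HMBOA")
  expect_identical(h$substituents[1], "acetyl+hexose")
  expect_identical(h$class[1], "benzoxazinoid")
  expect_identical(h$n_matched[1], 3L)
  fr <- attr(h, "fragments")[[1]]
  expect_setequal(fr$label, c("Y0", "Y0-CO", "Y0-2CO"))
  expect_equal(fr$theoretical[fr$label == "Y0"], 194.0459,
               tolerance = 1e-4)
  expect_true(validateHypothesis(s, h[1, ], fr, rb))
})

test_that("the C-glycosyl luteolin O-pentoside example annotates at rank 1", {
  s <- readSpectra(system.file("extdata", "cl0463.msp",
                               package = "cerealmet"))[[1]]
  h <- annotateSpectrum(s, rb)
  expect_identical(h$aglycone[1], "luteolin")
  expect_identical(h$substituents[1], "C-hexose+pentose")
  expect_identical(h$class[1], "flavone")
  fr <- attr(h, "fragments")[[1]]
  expect_setequal(fr$label, c("Y0", "Y0-120", "Y0-150"))
  # cross-ring Z ions computed from formulas land on the observed peaks
  expect_equal(fr$observed[fr$label == "Y0-120"], 329.0677)
  expect_equal(fr$observed[fr$label == "Y0-150"], 299.0554)
  expect_true(validateHypothesis(s, h[1, ], fr, rb))
})

test_that("fragment matching uses each peak at most once", {
  s <- generateSpectrum("HMBOA", c("hexose", "acetyl"), rb)
  m <- matchCharacteristicFragments(s, "HMBOA", c("glucose", "acetyl"), rb)
  expect_identical(anyDuplicated(m$observed), 0L)
  expect_true(all(abs(m$ppm) <= 10))
  empty <- newSpectrum("e", precursorMz = ionMz("C17H21NO10", "[M-H]-"),
                       polarity = -1L, mz = numeric(0),
                       intensity = numeric(0))
  expect_identical(nrow(matchCharacteristicFragments(
    empty, "HMBOA", c("hexose", "acetyl"), rb)), 0L)
})

test_that("a bare aglycone spectrum yields the zero-substituent hypothesis", {
  s <- generateSpectrum("HBOA", character(0), rb)
  h <- annotateSpectrum(s, rb)
  expect_identical(h$aglycone[1], "HBOA")
  expect_identical(h$substituents[1], "")
  expect_identical(h$n_substituents[1], 0L)
})

test_that("annotation is deterministic and totally ordered", {
  s <- readSpectra(system.file("extdata", "cl1148.mgf",
                               package = "cerealmet"))[[1]]
  h1 <- annotateSpectrum(s, rb)
  h2 <- annotateSpectrum(s, rb)
  expect_identical(h1, h2)
  expect_identical(h1$rank, seq_len(nrow(h1)))
  expect_error(annotateSpectrum(
    newSpectrum("x", NA_real_, -1L, 100, 1), rb), "precursor")
})

test_that("reported hypotheses satisfy their own mass-closure invariants", {
  for (s in list(generateSpectrum("DIMBOA", "hexose", rb),
                 generateSpectrum("tricin", c("hexose", "methyl"), rb))) {
    h <- annotateSpectrum(s, rb)
    frs <- attr(h, "fragments")
    for (i in seq_len(min(nrow(h), 5)))
      expect_true(validateHypothesis(s, h[i, ], frs[[i]], rb))
  }
})

test_that("library annotation tallies classes and handles empty input", {
  sp <- benzoxazinoidSpectra(rb)
  tab <- annotateLibrary(sp, rb)
  expect_identical(nrow(tab), 8L)
  expect_true(all(tab$class == "benzoxazinoid"))
  truth <- attr(sp, "truth")
  expect_identical(tab$aglycone, truth$aglycone)
  expect_identical(tab$substituents, truth$substituents)
  expect_identical(unname(attr(tab, "class_tally")["benzoxazinoid"]), 8L)
  empty <- annotateLibrary(list(), rb)
  expect_identical(nrow(empty), 0L)
})

test_that("noise-free generated spectra are recovered at rank 1", {
  grid <- annotationRecovery(rb, ppm_noise = 0, seed = 5)
  withr::with_seed(42, sub <- grid[sample(nrow(grid), 50), ])
  expect_gte(mean(sub$recovered), 0.95)
})
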