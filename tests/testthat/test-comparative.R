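small_panel <- function(pres, classes = rep("alpha", nrow(pres))) {
  ab <- pres * seq_len(length(pres))  # arbitrary positive abundances
  dimnames(ab) <- dimnames(pres)
  panelMatrix(ab, classes)
}

test_that("panel container enforces its invariants", {
  pres <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2,
                 dimnames = list(c("m1", "m2"), c("sp1", "sp2")))
  p <- small_panel(pres)
  expect_s4_class(p, "PanelMatrix")
  expect_identical(presence(p), abundances(p) > 0)
  expect_error(panelMatrix(matrix(-1, 1, 1,
                                  dimnames = list("m", "s")), "c"),
               "non-negative")
  # round trip through delimited text
  path <- tempfile(fileext = ".tsv")
  writePanel(p, path)
  back <- readPanel(path)
  expect_equal(abundances(back), abundances(p))
  expect_identical(classLabels(back), classLabels(p))
})

test_that("shared/specific/missing match brute force on random matrices", {
  withr::with_seed(51, {
    pres <- matrix(runif(100 * 9) < 0.6, 100, 9,
                   dimnames = list(sprintf("m%03d", 1:100),
                                   paste0("sp", 1:9)))
  })
  p <- small_panel(pres)
  expect_identical(sharedMetabolites(p),
                   rownames(pres)[apply(pres, 1, all)])
  spf <- speciesSpecific(p)
  mis <- speciesMissing(p)
  for (sp in colnames(pres)) {
    expect_identical(spf[[sp]], rownames(pres)[
      pres[, sp] & rowSums(pres[, setdiff(colnames(pres), sp)]) == 0])
    expect_identical(mis[[sp]], rownames(pres)[
      !pres[, sp] & rowSums(pres[, setdiff(colnames(pres), sp)]) == 8])
  }
  # disjointness and complement consistency
  expect_identical(anyDuplicated(unlist(spf)), 0L)
  expect_identical(anyDuplicated(unlist(mis)), 0L)
  expect_length(intersect(sharedMetabolites(p), unlist(mis)), 0L)
  expect_identical(length(sharedMetabolites(p)) +
                     sum(!apply(pres, 1, all)), 100L)
})

test_that("edge patterns land in the right comparative sets", {
  pres <- matrix(TRUE, 3, 4, dimnames = list(c("a", "b", "c"),
                                             paste0("sp", 1:4)))
  pres["b", ] <- c(TRUE, FALSE, FALSE, FALSE)   # specific to sp1
  pres["c", ] <- c(FALSE, TRUE, TRUE, TRUE)     # missing in sp1
  p <- small_panel(pres)
  expect_identical(sharedMetabolites(p), "a")
  expect_identical(speciesSpecific(p)$sp1, "b")
  expect_identical(speciesMissing(p)$sp1, "c")
  expect_length(speciesSpecific(p)$sp2, 0L)
})

test_that("detection proportions count class members per species", {
  pres <- matrix(TRUE, 8, 2, dimnames = list(paste0("b", 1:8),
                                             c("maize", "rice")))
  pres[7:8, "maize"] <- FALSE
  pres[, "rice"] <- FALSE
  p <- small_panel(pres, rep("benzoxazinoid", 8))
  expect_equal(unname(detectionProportion(p, "benzoxazinoid", "maize")),
               0.75)
  expect_equal(unname(detectionProportion(p, "benzoxazinoid", "rice")), 0)
  expect_error(detectionProportion(p, "flavone"), "unknown")
})

test_that("class CV is 150% for any equal 3-of-9 pattern and scale-free", {
  withr::with_seed(52, {
    for (i in 1:20) {
      frac <- runif(1, 0.1, 1)
      nsp <- 9
      n_class <- sample(4:40, 1)
      k_present <- round(frac * n_class)
      if (k_present == 0) k_present <- 1
      pres <- matrix(FALSE, n_class, nsp,
                     dimnames = list(sprintf("m%02d", 1:n_class),
                                     paste0("sp", 1:nsp)))
      in_sp <- sample(nsp, 3)
      pres[seq_len(k_present), in_sp] <- TRUE
      # avoid all-absent rows polluting the panel invariant checks
      p <- small_panel(pres, rep("x", n_class))
      expect_equal(classCV(p, "x"), 150, tolerance = 1e-9)
    }
  })
})

test_that("class CV matches direct sd/mean and rejects absent classes", {
  withr::with_seed(53, {
    pres <- matrix(runif(30 * 9) < 0.5, 30, 9,
                   dimnames = list(sprintf("m%02d", 1:30),
                                   paste0("sp", 1:9)))
  })
  p <- small_panel(pres, rep("y", 30))
  props <- colSums(pres) / 30
  expect_equal(classCV(p, "y"), 100 * sd(props) / mean(props))
  full <- small_panel(matrix(TRUE, 4, 9,
                             dimnames = list(letters[1:4],
                                             paste0("sp", 1:9))),
                      rep("z", 4))
  expect_equal(classCV(full, "z"), 0)
  none <- small_panel(matrix(c(FALSE, TRUE), 2, 9,
                             dimnames = list(c("n", "pp"),
                                             paste0("sp", 1:9))),
                      c("absent", "there"))
  expect_error(classCV(none, "absent"), "undefined")
})

test_that("upset counts partition the panel", {
  withr::with_seed(54, {
    pres <- matrix(runif(60 * 5) < 0.5, 60, 5,
                   dimnames = list(sprintf("m%02d", 1:60),
                                   paste0("sp", 1:5)))
  })
  p <- small_panel(pres)
  cnt <- upsetCounts(p)
  expect_identical(sum(cnt), 60L)
  # brute-force pattern grouping
  pat <- apply(pres, 1, function(r) paste(which(r), collapse = ","))
  expect_identical(length(cnt), length(unique(pat)))
  allp <- small_panel(matrix(TRUE, 3, 2,
                             dimnames = list(letters[1:3], c("A", "B"))))
  expect_identical(as.integer(upsetCounts(allp)["A+B"]), 3L)
})
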