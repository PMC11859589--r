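feat_row <- function(id, heights, blank, snr) {
  d <- data.frame(id = id, mz = 300.1, rt_min = 2, snr = snr,
                  blank_height = blank, stringsAsFactors = FALSE)
  for (i in seq_along(heights)) d[[paste0("s", i)]] <- heights[i]
  d
}

test_that("feature filtering applies the three strict thresholds", {
  f <- rbind(feat_row("keep", c(600, 100, 50), 100, 12),
             feat_row("ratio5", c(600, 10, 10), 120, 12),   # ratio exactly 5
             feat_row("low", c(400, 100, 10), 10, 12),      # height <= 500
             feat_row("noisy", c(600, 100, 10), 10, 10),    # snr exactly 10
             feat_row("noblank", c(501, 0, 0), 0, 11))      # blank 0 => Inf
  attr(f, "samples") <- c("s1", "s2", "s3")
  kept <- suppressMessages(filterFeatures(f))
  expect_identical(kept$id, c("keep", "noblank"))
  # idempotent, order-preserving subset
  again <- suppressMessages(filterFeatures(kept))
  expect_identical(again$id, kept$id)
})

test_that("feature filtering equals the row-wise oracle on random tables", {
  withr::with_seed(31, {
    n <- 50
    f <- do.call(rbind, lapply(seq_len(n), function(i)
      feat_row(sprintf("F%02d", i), runif(3, 0, 2000), runif(1, 0, 300),
               runif(1, 0, 40))))
    attr(f, "samples") <- c("s1", "s2", "s3")
  })
  kept <- suppressMessages(filterFeatures(f))
  oracle <- vapply(seq_len(nrow(f)), function(i) {
    h <- max(f$s1[i], f$s2[i], f$s3[i])
    r <- if (f$blank_height[i] == 0) Inf else h / f$blank_height[i]
    r > 5 && h > 500 && f$snr[i] > 10
  }, logical(1))
  expect_identical(kept$id, f$id[oracle])
})

test_that("QC CV filter keeps <=30% CV with sample sd, scale-invariantly", {
  qc <- rbind(flat = c(100, 100, 100), spread = c(100, 200, NA))
  expect_identical(qcCvFilter(qc[, 1:3][1, , drop = FALSE]), "flat")
  # CV of (100,200) = 70.71/150 ~ 0.471 > 0.30 -> dropped
  expect_identical(qcCvFilter(rbind(a = c(100, 200))), character(0))
  expect_equal(sd(c(100, 200)) / mean(c(100, 200)), 0.4714045,
               tolerance = 1e-6)
  withr::with_seed(32, {
    m <- matrix(rlnorm(40 * 5), 40, 5,
                dimnames = list(sprintf("m%02d", 1:40), NULL))
    scale_fac <- runif(40, 0.1, 1000)
    expect_identical(qcCvFilter(m), qcCvFilter(m * scale_fac))
  })
  # degenerate rows: all-zero kept, zero-mean-positive-sd impossible with
  # non-negative data, but sd>0 with mean 0 drops
  expect_identical(qcCvFilter(rbind(z = c(0, 0, 0))), "z")
  expect_error(qcCvFilter(matrix(1, 2, 1)), "at least 2")
})

test_that("replicate averaging is the per-crop arithmetic mean", {
  x <- matrix(c(10, 20, 30), 1, dimnames = list("m1", NULL))
  expect_equal(unname(averageReplicates(x, rep("crop", 3))[1, 1]), 20)
  expect_equal(unname(averageReplicates(
    matrix(0, 1, 3), rep("c", 3))[1, 1]), 0)
  withr::with_seed(33, {
    big <- matrix(rlnorm(20 * 27), 20, 27,
                  dimnames = list(sprintf("m%02d", 1:20), NULL))
    groups <- rep(paste0("crop", 1:9), each = 3)
    avg <- averageReplicates(big, groups)
    for (m in 1:20) for (g in 1:9)
      expect_equal(avg[m, paste0("crop", g)],
                   mean(big[m, (3 * g - 2):(3 * g)]))
  })
  # missing replicate (NA) counts as non-detected zero
  xna <- matrix(c(10, NA, 20), 1)
  expect_equal(unname(averageReplicates(xna, rep("c", 3))[1, 1]), 10)
  expect_error(averageReplicates(x, c("a", "b")), "one entry per")
})

test_that("MS2T pairing links each spectrum to its best in-tolerance feature", {
  f <- rbind(feat_row("F1", c(1000, 1, 1), 0, 20),
             feat_row("F2", c(1000, 1, 1), 0, 20))
  f$mz <- c(398.1093, 398.1102 * (1 - 6e-6))
  f$rt_min <- c(3.40, 3.39)
  attr(f, "samples") <- c("s1", "s2", "s3")
  s <- newSpectrum("CL1148", 398.1102, -1L, 194.05, 100,
                   retentionTime = 3.39)
  links <- buildMS2T(f, list(s), mz_tol_ppm = 10, rt_tol_min = 0.2)
  expect_identical(nrow(links), 1L)
  expect_identical(links$feature_id, "F1")  # +2.3 ppm beats -6 ppm
  expect_lte(abs(links$mz_delta_ppm), 10)
  expect_lte(abs(links$rt_delta_min), 0.2)
  # a spectrum 30 ppm away stays unlinked
  far <- newSpectrum("far", 398.1102 * (1 + 30e-6), -1L, 100, 1,
                     retentionTime = 3.39)
  l2 <- suppressMessages(buildMS2T(f[1, ], list(far), 10, 0.2))
  expect_identical(nrow(l2), 0L)
  expect_identical(attr(l2, "unlinked"), "far")
})

test_that("MS2T entries always satisfy the tolerance invariants", {
  withr::with_seed(34, {
    f <- do.call(rbind, lapply(1:30, function(i)
      feat_row(sprintf("F%02d", i), c(1000, 1, 1), 0, 20)))
    f$mz <- runif(30, 100, 900)
    f$rt_min <- runif(30, 0.5, 10)
    attr(f, "samples") <- c("s1", "s2", "s3")
    sp <- lapply(1:40, function(i)
      newSpectrum(paste0("s", i), runif(1, 100, 900), -1L, 150, 10,
                  retentionTime = runif(1, 0.5, 10)))
  })
  links <- suppressMessages(buildMS2T(f, sp, 50, 0.5))
  if (nrow(links)) {
    expect_true(all(abs(links$mz_delta_ppm) <= 50))
    expect_true(all(abs(links$rt_delta_min) <= 0.5))
  }
  expect_identical(nrow(links) + length(attr(links, "unlinked")),
                   length(sp))
})

test_that("QC configuration validates and reads from files", {
  expect_error(qcConfig(height_min = -1), "positive")
  cfgfile <- tempfile(fileext = ".yml")
  writeLines(c("blank_ratio_min: 5", "qc_cv_max: 0.25"), cfgfile)
  cfg <- readQCConfig(cfgfile)
  expect_equal(cfg$qc_cv_max, 0.25)
  expect_equal(cfg$height_min, 500)
  kv <- tempfile(fileext = ".cfg")
  writeLines(c("# comment", "snr_min = 12"), kv)
  expect_equal(readQCConfig(kv)$snr_min, 12)
  bad <- tempfile(fileext = ".yml")
  writeLines("unknown_key: 3", bad)
  expect_error(readQCConfig(bad), "unknown_key")
})
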