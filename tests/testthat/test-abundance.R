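test_that("log2 transform shifts by the pseudocount and stays monotone", {
  expect_equal(log2Transform(0, 1), 0)
  expect_equal(log2Transform(7, 1), 3)
  expect_error(log2Transform(-1), "non-negative")
  withr::with_seed(61, {
    x <- sort(runif(50, 0, 1e4))
    expect_false(is.unsorted(log2Transform(x, 1)))
  })
})

test_that("row z-scores have mean 0 and sample sd 1; constants drop", {
  z <- suppressMessages(zscoreRows(rbind(a = c(1, 2, 3))))
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_message(z2 <- zscoreRows(rbind(a = 1:3, b = c(5, 5, 5))),
                 "constant")
  expect_identical(rownames(z2), "a")
  withr::with_seed(62, m <- matrix(rnorm(100), 10, 10))
  z3 <- zscoreRows(m)
  expect_true(all(abs(rowMeans(z3)) < 1e-9))
  expect_equal(unname(apply(z3, 1, sd)), rep(1, 10))
})

test_that("PCA returns ordered variance fractions and orthogonal scores", {
  withr::with_seed(63, {
    rank1 <- outer(rnorm(40), rnorm(6))
    p1 <- panelPCA(rank1)
    expect_gt(p1$explained[1], 0.999)
    iso <- matrix(rnorm(2000 * 8), 2000, 8)
    p2 <- panelPCA(iso)
  })
  expect_true(all(diff(p2$explained) <= 1e-12))
  expect_lte(sum(p2$explained), 1 + 1e-9)
  # isotropic noise spreads variance roughly evenly over 8 components
  expect_lt(max(p2$explained), 2.2 / 8)
  cross <- crossprod(p2$scores)
  expect_lt(max(abs(cross[upper.tri(cross)])), 1e-6)
  expect_error(panelPCA(matrix(1:5, 5, 1)), "2 samples")
})

test_that("clustering is deterministic, permutation-stable, and k-checked", {
  g <- generatePanel(panelSpec(), seed = 3)
  sub <- abundances(g$panel)[1:200, ]
  cl1 <- suppressMessages(clusterPanel(sub, k = 5))
  cl2 <- suppressMessages(clusterPanel(sub, k = 5))
  expect_identical(clusterAssignment(cl1), clusterAssignment(cl2))
  withr::with_seed(64, perm <- sample(nrow(sub)))
  clp <- suppressMessages(clusterPanel(sub[perm, ], k = 5))
  expect_identical(clusterAssignment(clp)[names(clusterAssignment(cl1))],
                   clusterAssignment(cl1))
  one <- suppressMessages(clusterPanel(sub, k = 1))
  expect_identical(unique(unname(clusterAssignment(one))), 1L)
  expect_error(clusterPanel(sub, k = 0), "'k'")
  expect_error(clusterPanel(sub, k = 1e6), "'k'")
})

test_that("9-cluster recovery finds the planted home-crop blocks", {
  g <- generatePanel(panelSpec(), seed = 11)
  cl <- suppressMessages(clusterPanel(g$panel, k = 9))
  asg <- clusterAssignment(cl)
  ari <- mclust::adjustedRandIndex(asg, g$truth$home[names(asg)])
  expect_gte(ari, 0.9)
  # each cluster is attributed to its planted crop
  crops <- cropOfCluster(cl)
  expect_setequal(crops, panelSpecies())
  for (k in names(crops)) {
    members <- names(asg)[asg == as.integer(k)]
    expect_identical(crops[[k]],
                     names(which.max(table(g$truth$home[members]))))
  }
})

test_that("composition tables cross-tabulate with reconciling margins", {
  withr::with_seed(65, {
    ids <- sprintf("m%03d", 1:120)
    asg <- setNames(sample(1:4, 120, replace = TRUE), ids)
    cls <- setNames(sample(c("a", "b", "c"), 120, replace = TRUE), ids)
  })
  ct <- compositionTable(asg, cls)
  for (cc in c("a", "b", "c")) for (k in 1:4)
    expect_identical(compositionCounts(ct)[cc, as.character(k)],
                     sum(cls == cc & asg == k))
  expect_identical(sum(compositionCounts(ct)), 120L)
  expect_equal(unname(classTotals(ct)), unname(table(cls)[c("a", "b", "c")]),
               ignore_attr = TRUE)
  expect_equal(unname(clusterTotals(ct)), unname(table(asg)),
               ignore_attr = TRUE)
})

test_that("composition flags follow the inclusive 20%/40% class-share rule", {
  ids <- paste0("b", 1:8)
  asg <- setNames(c(rep(1L, 6), rep(2L, 2)), ids)
  ct <- compositionTable(asg, setNames(rep("benzoxazinoid", 8), ids))
  expect_identical(compositionFlags(ct)["benzoxazinoid", "1"], "**")
  expect_identical(compositionFlags(ct)["benzoxazinoid", "2"], "*")
  # an even 1/9 spread earns no flags
  ids9 <- paste0("x", 1:9)
  ct9 <- compositionTable(setNames(1:9, ids9),
                          setNames(rep("c", 9), ids9))
  expect_true(all(compositionFlags(ct9) == ""))
  # exactly 20% is flagged (inclusive threshold)
  ids5 <- paste0("y", 1:5)
  ct5 <- compositionTable(setNames(c(1L, 2L, 2L, 2L, 2L), ids5),
                          setNames(rep("c", 5), ids5))
  expect_identical(compositionFlags(ct5)["c", "1"], "*")
})

test_that("the packaged class-by-cluster distribution reconciles", {
  ct <- readCompositionTable()
  cnt <- compositionCounts(ct)
  expect_identical(nrow(cnt), 18L)
  expect_identical(ncol(cnt), 9L)
  expect_identical(as.integer(sum(classTotals(ct))), 1131L)
  expect_identical(as.integer(sum(clusterTotals(ct))), 1131L)
  bx <- cnt["Benzoxazinoids", ]
  expect_identical(unname(sort(bx[bx > 0])), c(2L, 6L))
  fl <- compositionFlags(ct)["Benzoxazinoids", ]
  expect_identical(unname(fl[bx == 6]), "**")
  expect_identical(unname(fl[bx == 2]), "*")
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  map <- data.frame(id = paste0("m", 1:10),
                    pathway = rep(c("P", "Q"), each = 5))
  res <- hypergeomEnrichment(paste0("m", 1:5), map)
  expect_equal(res$p_value[res$pathway == "P"], 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(res$p_value[res$pathway == "Q"], 1)  # k = 0
  expect_error(hypergeomEnrichment("zz", map), "subset")
  expect_error(hypergeomEnrichment(character(0),
                                   map[0, ], background = character(0)),
               "empty")
  withr::with_seed(66, {
    for (i in 1:25) {
      N <- sample(5:12, 1)
      K <- sample(1:N, 1)
      n <- sample(1:N, 1)
      bg <- paste0("g", seq_len(N))
      m <- data.frame(id = bg[seq_len(K)], pathway = "P")
      cluster <- sample(bg, n)
      k <- sum(cluster %in% m$id)
      got <- hypergeomEnrichment(cluster, m, background = bg)
      expect_equal(got$p_value, bf_hyper_tail(N, K, n, k),
                   tolerance = 1e-12)
    }
  })
  # monotone non-increasing in k for fixed margins
  p_of_k <- vapply(0:5, function(k)
    phyper(k - 1, 5, 5, 5, lower.tail = FALSE), numeric(1))
  expect_true(all(diff(p_of_k) <= 0))
  # BH correction is exposed behind a flag
  res_bh <- hypergeomEnrichment(paste0("m", 1:5), map, correction = "BH")
  expect_true("p_adjusted" %in% names(res_bh))
})
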