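# Independent brute-force oracles; intentionally naive implementations that
# never share code with the package internals they check.

# every multiset of catalog items (respecting per-item max_count, total size
# bound, and at most one C-linked sugar) whose residue-mass sum matches the
# loss within tol_da; returned as sorted "a+b+c" keys
bf_decompose <- function(loss, defs, tol_da, max_total = 3) {
  nms <- names(defs)
  ranges <- lapply(defs, function(d) 0:min(d$max_count, max_total))
  grid <- expand.grid(ranges, KEEP.OUT.ATTRS = FALSE)
  keys <- character(0)
  for (r in seq_len(nrow(grid))) {
    cnt <- as.integer(grid[r, ])
    if (sum(cnt) > max_total) next
    csum <- sum(cnt[vapply(defs, function(d) d$linkage == "C", logical(1))])
    if (csum > 1) next
    m <- sum(cnt * vapply(defs, `[[`, numeric(1), "mass"))
    if (abs(m - loss) <= tol_da)
      keys <- c(keys, paste(sort(rep(nms, cnt)), collapse = "+"))
  }
  sort(unique(keys))
}

# literal enumeration of all n-subsets of a background of size N with K
# marked elements: P(overlap >= k)
bf_hyper_tail <- function(N, K, n, k) {
  marked <- seq_len(K)
  hits <- 0L
  subsets <- utils::combn(N, n)
  for (j in seq_len(ncol(subsets)))
    if (sum(subsets[, j] %in% marked) >= k) hits <- hits + 1L
  hits / ncol(subsets)
}

# BFS reachability with minimum step counts over an edge data.frame
bf_reachable <- function(edges, node) {
  dist <- stats::setNames(0L, node)
  queue <- node
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in edges$child[edges$parent == v]) {
      if (!w %in% names(dist)) {
        dist[w] <- dist[[v]] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist[setdiff(names(dist), node)]
}

random_formula <- function() {
  els <- c("C", "H", "N", "O")
  cnt <- sapply(els, function(e) sample(0:12, 1))
  cnt <- cnt[cnt > 0]
  if (!length(cnt)) cnt <- c(C = 1L)
  parseFormula(paste0(names(cnt), cnt, collapse = ""))
}

random_panel <- function(n = 100, nsp = 9, seed = 1) {
  withr::with_seed(seed, {
    pres <- matrix(stats::runif(n * nsp) < 0.7, n, nsp,
                   dimnames = list(sprintf("m%03d", seq_len(n)),
                                   paste0("sp", seq_len(nsp))))
    ab <- matrix(stats::rlnorm(n * nsp), n, nsp,
                 dimnames = dimnames(pres)) * pres
    panelMatrix(ab, sample(c("alpha", "beta", "gamma"), n, replace = TRUE))
  })
}

make_feature_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}
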