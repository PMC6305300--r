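# Independent, deliberately naive reference implementations used as
# oracles.  These must stay structurally different from the package code
# they check.

# biweight midcorrelation written directly from the defining formula
oracle_bicor <- function(x, y) {
  weight_terms <- function(v) {
    med <- median(v)
    u <- (v - med) / (9 * median(abs(v - med)))
    a <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    (v - med) * a
  }
  tx <- weight_terms(x)
  ty <- weight_terms(y)
  sum(tx * ty) / (sqrt(sum(tx^2)) * sqrt(sum(ty^2)))
}

# triple-loop topological overlap
oracle_tom <- function(a) {
  n <- nrow(a)
  out <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- 0
    for (u in seq_len(n)) if (u != i && u != j) shared <- shared + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    out[i, j] <- (shared + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

# one-sided enrichment p by direct enumeration of hypergeometric tables
oracle_fisher_greater <- function(overlap, module_size, marker_size, n_background) {
  kmax <- min(module_size, marker_size)
  total <- 0
  for (k in overlap:kmax) {
    total <- total + choose(marker_size, k) *
      choose(n_background - marker_size, module_size - k) /
      choose(n_background, module_size)
  }
  total
}

# adjusted Rand index from the pair-counting definition
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- sum_i * sum_j / choose(n, 2)
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# proteins x samples matrix holding correlated blocks plus noise rows
make_block_matrix <- function(block_sizes, block_cors, n_samples, n_noise,
                              seed = 1) {
  set.seed(seed)
  rows <- list()
  truth <- integer(0)
  for (b in seq_along(block_sizes)) {
    z <- rnorm(n_samples)
    for (p in seq_len(block_sizes[b])) {
      rows[[length(rows) + 1L]] <-
        sqrt(block_cors[b]) * z + sqrt(1 - block_cors[b]) * rnorm(n_samples)
      truth <- c(truth, b)
    }
  }
  for (p in seq_len(n_noise)) {
    rows[[length(rows) + 1L]] <- rnorm(n_samples)
    truth <- c(truth, 0L)
  }
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("P%04d", seq_len(nrow(m)))
  colnames(m) <- sprintf("S%02d", seq_len(n_samples))
  list(mat = m, truth = truth)
}

# small fully-observed synthetic cohort for integration-style tests
small_cohort <- function(seed = 1, ...) {
  generate_cohort(cohort_design(n_proteins = 400, markers_per_type = 25,
                                module_plan = list(c(40, 0.8), c(30, 0.7)),
                                missing_rate = 0, seed = seed, ...))
}
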