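# Independent oracles used across the suite. These deliberately use naive
# formulations (explicit loops, textbook formulas) so they share no code
# with the implementation they check.

# Textbook Pearson correlation of two vectors.
pearson_oracle <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Partial correlation via the precision matrix (inverse covariance).
partial_cor_precision <- function(x, y, Z) {
  P <- solve(stats::cov(cbind(x, y, Z)))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# Welch-Satterthwaite degrees of freedom, written out directly.
welch_df_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
}

# Graph connectivity by breadth-first search from node 1.
bfs_connected <- function(adj) {
  n <- ncol(adj)
  seen <- rep(FALSE, n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- which(adj[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# Definitional Newman-Girvan modularity by double loop over node pairs.
modularity_oracle <- function(adj, membership) {
  m2 <- sum(adj)                       # 2m
  deg <- rowSums(adj)
  q <- 0
  n <- ncol(adj)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + adj[i, j] - deg[i] * deg[j] / m2
      }
    }
  }
  q / m2
}

# Exact permutation p-values for the edge-wise correlation-difference
# statistic by full enumeration of all C(n_a + n_b, n_a) group splits.
perm_enum_oracle <- function(va, vb) {
  n_a <- nrow(va)
  pooled <- rbind(va, vb)
  n <- nrow(pooled)
  t_obs <- cor(va) - cor(vb)
  splits <- combn(n, n_a)
  hits <- matrix(0, ncol(pooled), ncol(pooled))
  for (s in seq_len(ncol(splits))) {
    idx <- splits[, s]
    tp <- cor(pooled[idx, , drop = FALSE]) -
      cor(pooled[-idx, , drop = FALSE])
    hits <- hits + (abs(tp) >= abs(t_obs) - 1e-12)
  }
  p <- hits / ncol(splits)
  diag(p) <- 1
  list(p = p, t_obs = t_obs, n_splits = ncol(splits))
}

# Small generic atlas + table builders for unit fixtures.
toy_atlas <- function(n, with_ref = TRUE) {
  k <- n + as.integer(with_ref)
  atlas_spec(seq_len(k),
             c(sprintf("R%02d", seq_len(n)), if (with_ref) "cereb"),
             center = cbind(seq_len(k), 0, 0),
             is_reference = c(rep(FALSE, n), if (with_ref) TRUE))
}

toy_table <- function(values, kind = "suvr") {
  suvr_table(values, toy_atlas(ncol(values)), kind = kind)
}

# Two-group cohort fixture with independent-normal regions.
toy_cohort <- function(n_a, n_b, p, seed, mean_a = 1.3, mean_b = 1.3,
                       sd = 0.1) {
  set.seed(seed)
  va <- matrix(rnorm(n_a * p, mean_a, sd), n_a, p)
  vb <- matrix(rnorm(n_b * p, mean_b, sd), n_b, p)
  atl <- toy_atlas(p)
  list(
    a = suvr_table(va, atl, subject_ids = sprintf("A%03d", seq_len(n_a))),
    b = suvr_table(vb, atl, subject_ids = sprintf("B%03d", seq_len(n_b)))
  )
}
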