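#' Edge-wise permutation test of group connectivity differences
#'
#' Observed statistic per edge: the group-A minus group-B difference in
#' across-subject Pearson correlation (optionally on the Fisher-z scale).
#' The null distribution is built by randomly reassigning the pooled
#' subjects to two groups of the original sizes and recomputing the
#' statistic; the two-tailed empirical p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{|T_{perm}| \ge |T_{obs}|\}) / (B + 1)}, so p is never
#' below 1/(B+1).
#'
#' If a permuted split leaves a region with zero variance, that
#' permutation's affected edges contribute a difference of 0 (still
#' counted), with one warning at the end.
#'
#' @param table_a,table_b [suvr_table()]s on the same atlas (group A =
#'   disease, group B = control by convention, so positive differences
#'   read as strengthened connectivity in A).
#' @param n_perm number of permutations B (default 5000).
#' @param seed integer RNG seed.
#' @param statistic_mode `"raw_r"` (default) or `"fisher_z"`.
#' @return An object of class `perm_result`: `delta` (n x n observed
#'   difference, zero diagonal), `pvalues` (n x n, 1 on the diagonal),
#'   `r_a`, `r_b` (the two observed correlation matrices), `n_perm`,
#'   `seed`, `statistic_mode`, `n_a`, `n_b`, `atlas`.
#' @export
permutation_edge_test <- function(table_a, table_b, n_perm = 5000,
                                  seed = 1,
                                  statistic_mode = c("raw_r", "fisher_z")) {
  statistic_mode <- match.arg(statistic_mode)
  stopifnot(inherits(table_a, "suvr_table"), inherits(table_b, "suvr_table"))
  if (!same_atlas(table_a, table_b)) stop("atlas mismatch between tables")
  if (n_perm < 1) stop("n_perm must be >= 1")
  va <- table_a$values
  vb <- table_b$values
  n_a <- nrow(va)
  n_b <- nrow(vb)
  if (n_a < 4 || n_b < 4) stop("each group needs at least 4 subjects")
  if (any(apply(va, 2, stats::sd) == 0) ||
      any(apply(vb, 2, stats::sd) == 0)) {
    stop("zero-variance region in an observed group")
  }
  pooled <- rbind(va, vb)
  n <- n_a + n_b
  p <- ncol(pooled)

  # Canonicalize the permutation space in the unordered pooled subject
  # set: rows sorted by subject id (when ids are unique across groups)
  # and the resampled subset sized to the group holding the smallest id.
  # Only |T| enters the p-value, so this makes p invariant under swapping
  # the two tables while delta cleanly negates.
  ids <- c(table_a$subject_ids, table_b$subject_ids)
  k_sub <- n_a
  if (!anyDuplicated(ids)) {
    ord <- order(ids)
    pooled <- pooled[ord, , drop = FALSE]
    from_a <- c(rep(TRUE, n_a), rep(FALSE, n_b))[ord]
    k_sub <- if (from_a[1]) n_a else n_b
  }

  stat <- function(mat_a, mat_b) {
    ra <- suppressWarnings(stats::cor(mat_a))
    rb <- suppressWarnings(stats::cor(mat_b))
    if (statistic_mode == "fisher_z") {
      ra <- fisher_z(ra)
      rb <- fisher_z(rb)
    }
    ra - rb
  }

  r_a <- stats::cor(va)
  r_b <- stats::cor(vb)
  t_obs <- stat(va, vb)
  diag(t_obs) <- 0
  abs_obs <- abs(t_obs)

  degenerate <- 0L
  count <- matrix(0L, p, p)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n, k_sub)
      t_perm <- stat(pooled[idx, , drop = FALSE],
                     pooled[-idx, , drop = FALSE])
      if (anyNA(t_perm)) {
        degenerate <- degenerate + 1L
        t_perm[is.na(t_perm)] <- 0
      }
      diag(t_perm) <- 0
      count <- count + (abs(t_perm) >= abs_obs)
    }
  })
  if (degenerate > 0) {
    warning(sprintf(
      "%d permutation(s) produced a zero-variance region; affected edges counted as difference 0",
      degenerate))
  }
  pmat <- (1 + count) / (n_perm + 1)
  diag(pmat) <- 1
  dimnames(t_obs) <- dimnames(pmat) <- dimnames(r_a)
  structure(
    list(delta = t_obs, pvalues = pmat, r_a = r_a, r_b = r_b,
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         statistic_mode = statistic_mode, n_a = n_a, n_b = n_b,
         atlas = table_a$atlas, edge_mask = NULL),
    class = "perm_result"
  )
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "perm_result [%s]: %d nodes, n = %d vs %d, B = %d (seed %d)\n",
    x$statistic_mode, ncol(x$delta), x$n_a, x$n_b, x$n_perm, x$seed))
  invisible(x)
}

#' Significant edges of a permutation result
#'
#' @param perm a `perm_result`.
#' @param alpha edge-wise significance level in (0, 1).
#' @return Data frame sorted by |delta| descending: `i`, `j` (node
#'   indices, i < j), `region_i`, `region_j`, `delta`, `p`. A positive
#'   `delta` is a strengthened connection in group A, negative weakened.
#' @export
significant_edges <- function(perm, alpha = 0.05) {
  stopifnot(inherits(perm, "perm_result"))
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  n <- ncol(perm$delta)
  idx <- edge_index(n)
  if (!is.null(perm$edge_mask)) {
    idx <- idx[perm$edge_mask[idx] > 0, , drop = FALSE]
  }
  pv <- perm$pvalues[idx]
  # alpha = 1 returns the full edge universe (p = 1 is attainable)
  keep <- if (alpha >= 1) rep(TRUE, length(pv)) else pv < alpha
  idx <- idx[keep, , drop = FALSE]
  nm <- colnames(perm$delta)
  out <- data.frame(
    i = idx[, 1], j = idx[, 2],
    region_i = nm[idx[, 1]], region_j = nm[idx[, 2]],
    delta = perm$delta[idx], p = perm$pvalues[idx],
    stringsAsFactors = FALSE
  )
  out[order(-abs(out$delta)), , drop = FALSE]
}

#' Compare two groups at a common sparsity threshold
#'
#' Builds both group networks, thresholds each at the common sparsity S,
#' restricts the reported edge universe to the union of the two binarized
#' adjacencies, and runs the permutation test on those edges. A warning is
#' issued if S is below either group's minimal fully-connected sparsity.
#'
#' @param table_a,table_b [suvr_table()]s on the same atlas.
#' @param S common sparsity threshold (e.g. 0.35, or 0.55 for small
#'   matched designs whose percolation threshold is higher).
#' @param n_perm,seed,statistic_mode passed to [permutation_edge_test()].
#' @param rank_by edge ranking passed to [threshold_by_sparsity()].
#' @return List with `network_a`, `network_b` (thresholded
#'   `group_network`s) and `perm` (a `perm_result` whose `edge_mask`
#'   marks the union edge set; [significant_edges()] respects it).
#' @export
compare_at_sparsity <- function(table_a, table_b, S, n_perm = 5000,
                                seed = 1, statistic_mode = "raw_r",
                                rank_by = "signed") {
  net_a <- threshold_by_sparsity(build_group_network(table_a), S, rank_by)
  net_b <- threshold_by_sparsity(build_group_network(table_b), S, rank_by)
  s_min_a <- min_connected_sparsity(net_a, rank_by)$S
  s_min_b <- min_connected_sparsity(net_b, rank_by)$S
  if (S < max(s_min_a, s_min_b)) {
    warning(sprintf(
      "S = %.4g is below a group's minimal fully-connected sparsity (%.4g / %.4g)",
      S, s_min_a, s_min_b))
  }
  perm <- permutation_edge_test(table_a, table_b, n_perm = n_perm,
                                seed = seed,
                                statistic_mode = statistic_mode)
  mask <- (net_a$adjacency + net_b$adjacency) > 0
  perm$edge_mask <- mask * 1L
  list(network_a = net_a, network_b = net_b, perm = perm)
}

#' Export a permutation result for visualization
#'
#' Writes the observed difference matrix as a BrainNet Viewer .edge file
#' (optionally masked to significant edges), a .node file whose color
#' column is each region's net direction of significant connectivity
#' change (+1/-1/0) and whose size column is its count of significant
#' edges, and the significant-edge table as TSV.
#'
#' @param perm a `perm_result`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @param alpha significance level for masking.
#' @return Character vector of the written paths, invisibly.
#' @export
export_perm_result <- function(perm, dir, prefix = "contrast",
                               alpha = 0.05) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- significant_edges(perm, alpha)
  n <- ncol(perm$delta)
  mask <- matrix(0, n, n)
  if (nrow(sig) > 0) {
    mask[cbind(sig$i, sig$j)] <- 1
    mask[cbind(sig$j, sig$i)] <- 1
  }
  delta_masked <- perm$delta * mask
  net_dir <- vapply(seq_len(n), function(i) {
    d <- c(sig$delta[sig$i == i], sig$delta[sig$j == i])
    if (length(d) == 0) 0 else sign(sum(sign(d)))
  }, numeric(1))
  n_sig <- vapply(seq_len(n), function(i) {
    sum(sig$i == i) + sum(sig$j == i)
  }, numeric(1))
  paths <- c(
    edge = file.path(dir, paste0(prefix, "_delta.edge")),
    edge_sig = file.path(dir, paste0(prefix, "_delta_sig.edge")),
    node = file.path(dir, paste0(prefix, ".node")),
    table = file.path(dir, paste0(prefix, "_significant_edges.tsv"))
  )
  write_brainnet_edge(perm$delta, paths["edge"])
  write_brainnet_edge(delta_masked, paths["edge_sig"])
  write_brainnet_node(perm$atlas, net_dir, n_sig, paths["node"])
  utils::write.table(sig, paths["table"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
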