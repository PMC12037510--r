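#' Build a group-level metabolic covariance network
#'
#' Edge weights are the across-subject Pearson correlations between each
#' pair of regions' SUVRs within one group: the standard metabolic
#' covariance construction (nodes = regions, undirected weighted edges).
#'
#' @param suvr a [suvr_table()] holding one group's subjects.
#' @return An object of class `group_network` with elements `weights`
#'   (n x n symmetric, `NA` diagonal), `atlas`, `n_subjects`, and (after
#'   [threshold_by_sparsity()]) `adjacency` and `sparsity`.
#' @export
build_group_network <- function(suvr) {
  stopifnot(inherits(suvr, "suvr_table"))
  vals <- suvr$values
  if (nrow(vals) < 4) stop("need at least 4 subjects")
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance region(s): ",
         paste(colnames(vals)[sds == 0], collapse = ", "))
  }
  w <- stats::cor(vals)
  diag(w) <- NA
  structure(
    list(weights = w, atlas = suvr$atlas, n_subjects = nrow(vals),
         adjacency = NULL, sparsity = NULL),
    class = "group_network"
  )
}

#' @export
print.group_network <- function(x, ...) {
  cat(sprintf("group_network: %d nodes, n = %d subjects",
              ncol(x$weights), x$n_subjects))
  if (!is.null(x$sparsity)) {
    cat(sprintf(", thresholded at S = %.4g (%d edges)",
                x$sparsity, sum(x$adjacency) / 2))
  }
  cat("\n")
  invisible(x)
}

# Descending edge ranking over the upper triangle, ties broken by (i, j)
# lexicographic order. Shared by thresholding and percolation.
rank_edges <- function(weights, rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  n <- ncol(weights)
  idx <- edge_index(n)
  w <- weights[idx]
  if (rank_by == "absolute") w <- abs(w)
  ord <- order(-w, idx[, 1], idx[, 2])
  list(idx = idx[ord, , drop = FALSE], w = w[ord], n = n)
}

#' Threshold a weighted network at a sparsity level
#'
#' Keeps the top `m = round(S * n(n-1)/2)` edges (half-up rounding) of the
#' descending edge ranking and returns the binarized adjacency. Ranking is
#' by signed correlation by default (strongest positive couplings), by
#' absolute value with `rank_by = "absolute"`; ties break lexicographically
#' in (i, j), making the edge set at a lower S always a subset of the edge
#' set at a higher S.
#'
#' @param network a `group_network` or a square symmetric weight matrix.
#' @param S sparsity in (0, 1]: target fraction of all n(n-1)/2 edges.
#' @param rank_by `"signed"` (default) or `"absolute"`.
#' @return For a `group_network` input, the network with `adjacency` and
#'   `sparsity` filled in; for a matrix input, the binary adjacency matrix.
#' @export
threshold_by_sparsity <- function(network, S, rank_by = "signed") {
  w <- if (inherits(network, "group_network")) network$weights else
    as.matrix(network)
  if (S <= 0 || S > 1) stop("S must lie in (0, 1]")
  n <- ncol(w)
  m_all <- n * (n - 1) / 2
  m <- round_half_up(S * m_all)
  if (m < 1) stop("sparsity S yields an empty network (0 edges)")
  rk <- rank_edges(w, rank_by)
  adj <- matrix(0L, n, n, dimnames = dimnames(w))
  sel <- rk$idx[seq_len(m), , drop = FALSE]
  adj[sel] <- 1L
  adj[sel[, c(2, 1), drop = FALSE]] <- 1L
  if (inherits(network, "group_network")) {
    network$adjacency <- adj
    network$sparsity <- S
    network
  } else {
    adj
  }
}

#' Minimal fully-connected sparsity (percolation threshold)
#'
#' Finds the smallest edge count k* such that the top-k* edges of the
#' descending ranking form a single connected component spanning all
#' nodes, by incremental union-find over the ranking, and returns
#' S* = k* / (n(n-1)/2). This is the "sparsest fully connected network"
#' threshold used to pick a common sparsity for group comparison.
#'
#' @inheritParams threshold_by_sparsity
#' @return List with `S` (the minimal sparsity), `k` (edge count) and `n`.
#' @export
min_connected_sparsity <- function(network, rank_by = "signed") {
  w <- if (inherits(network, "group_network")) network$weights else
    as.matrix(network)
  n <- ncol(w)
  if (n < 2) stop("need at least 2 nodes")
  rk <- rank_edges(w, rank_by)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  components <- n
  k_star <- nrow(rk$idx)
  for (e in seq_len(nrow(rk$idx))) {
    ri <- find(rk$idx[e, 1])
    rj <- find(rk$idx[e, 2])
    if (ri != rj) {
      parent[ri] <- rj
      components <- components - 1
      if (components == 1) {
        k_star <- e
        break
      }
    }
  }
  list(S = k_star / (n * (n - 1) / 2), k = k_star, n = n)
}

#' Modularity partition of a thresholded network
#'
#' Louvain community detection on the binarized undirected graph, with
#' Newman-Girvan modularity
#' \eqn{Q = \sum_c (e_c/m - (d_c/2m)^2)}. The RNG seed fixes the (degenerate)
#' optimization so partitions are reproducible.
#'
#' @param adjacency binary symmetric matrix (zero diagonal), or a
#'   thresholded `group_network`.
#' @param seed integer seed (default 0).
#' @return An object of class `modularity_result`: `partition` (integer
#'   module id per node), `Q`, `n_modules`, `seed`.
#' @export
modularity_partition <- function(adjacency, seed = 0) {
  if (inherits(adjacency, "group_network")) {
    if (is.null(adjacency$adjacency)) {
      stop("network has not been thresholded; call threshold_by_sparsity()")
    }
    adjacency <- adjacency$adjacency
  }
  adjacency <- as.matrix(adjacency)
  if (sum(adjacency) == 0) stop("edgeless graph: modularity undefined")
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected",
                                           diag = FALSE)
  comm <- with_seed(seed, igraph::cluster_louvain(g))
  partition <- as.integer(igraph::membership(comm))
  names(partition) <- colnames(adjacency)
  structure(
    list(partition = partition,
         Q = igraph::modularity(g, igraph::membership(comm)),
         n_modules = length(unique(partition)),
         seed = as.integer(seed)),
    class = "modularity_result"
  )
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf("modularity_result: %d modules, Q = %.4f (seed %d)\n",
              x$n_modules, x$Q, x$seed))
  invisible(x)
}
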