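#' @keywords internal
"_PACKAGE"

# Half-up rounding: R's round() is round-half-even, which makes edge counts
# at sparsity thresholds depend on parity. Edge counts must be reproducible,
# so the thresholding operations use half-up throughout.
round_half_up <- function(x) floor(x + 0.5)

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so that library calls do not perturb user simulations.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Fisher z-transform with clipping so that |r| = 1 maps to a large finite
# value rather than +/-Inf (edge statistics must stay comparable).
fisher_z <- function(r, eps = 1e-12) atanh(pmin(pmax(r, -1 + eps), 1 - eps))

# Deterministic per-stage seed derivation: one user-facing seed, independent
# streams per named pipeline stage. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

# Enumerate the upper-triangle edge order used everywhere: (1,2), (1,3), ...
# column-major over the upper triangle, i.e. lexicographic in (i, j).
edge_index <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
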