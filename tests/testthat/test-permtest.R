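test_that("identical pooled groups give zero deltas and p = 1", {
  set.seed(30)
  vals <- matrix(rnorm(8 * 4, 1.3, 0.1), 8, 4)
  atl <- toy_atlas(4)
  a <- suvr_table(vals[1:4, ], atl, subject_ids = paste0("A", 1:4))
  b <- suvr_table(vals[1:4, ], atl, subject_ids = paste0("B", 1:4))
  res <- permutation_edge_test(a, b, n_perm = 50, seed = 1)
  expect_true(all(res$delta == 0))
  expect_true(all(res$pvalues == 1))
  expect_equal(nrow(significant_edges(res, 0.05)), 0)
})

test_that("Monte-Carlo p-values converge to the exact enumeration oracle", {
  co <- toy_cohort(4, 4, 5, seed = 31)
  enum <- perm_enum_oracle(co$a$values, co$b$values)
  expect_equal(enum$n_splits, 70)
  res <- permutation_edge_test(co$a, co$b, n_perm = 4000, seed = 7)
  expect_equal(res$delta, cor(co$a$values) - cor(co$b$values),
               ignore_attr = TRUE)
  off <- upper.tri(res$pvalues)
  expect_lt(max(abs(res$pvalues[off] - enum$p[off])), 0.02)
})

test_that("p-values respect the add-one lower bound", {
  co <- toy_cohort(10, 10, 3, seed = 32)
  # opposite near-perfect couplings: delta ~ 2 on edge (1,2), which no
  # mixed permutation split can reach
  set.seed(132)
  co$a$values[, 2] <- co$a$values[, 1] + rnorm(10, 0, 1e-3)
  co$b$values[, 2] <- 3 - co$b$values[, 1] + rnorm(10, 0, 1e-3)
  res <- permutation_edge_test(co$a, co$b, n_perm = 99, seed = 3)
  expect_gte(min(res$pvalues), 1 / 100)
  expect_equal(res$pvalues[1, 2], 1 / 100)  # the planted edge hits the floor
})

test_that("swapping the groups negates delta and keeps p identical", {
  co <- toy_cohort(8, 11, 5, seed = 33)
  ab <- permutation_edge_test(co$a, co$b, n_perm = 300, seed = 5)
  ba <- permutation_edge_test(co$b, co$a, n_perm = 300, seed = 5)
  expect_equal(ab$delta, -ba$delta)
  expect_identical(ab$pvalues, ba$pvalues)
})

test_that("fisher-z mode transforms the statistic but keeps calibration", {
  co <- toy_cohort(10, 10, 4, seed = 34)
  raw <- permutation_edge_test(co$a, co$b, n_perm = 200, seed = 2)
  fz <- permutation_edge_test(co$a, co$b, n_perm = 200, seed = 2,
                              statistic_mode = "fisher_z")
  expected <- atanh(raw$r_a) - atanh(raw$r_b)
  diag(expected) <- 0
  expect_equal(fz$delta, expected, ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(fz$pvalues > 1 / 201 - 1e-12))
})

test_that("zero-variance permutation splits are counted with a warning", {
  atl <- toy_atlas(3)
  va <- matrix(c(rep(1.5, 5), rnorm(10, 1.3, 0.1)), 5, 3)
  vb <- matrix(rnorm(15, 1.3, 0.1), 5, 3)
  a <- suvr_table(va, atl, subject_ids = paste0("A", 1:5))
  b <- suvr_table(vb, atl, subject_ids = paste0("B", 1:5))
  # region 1 is constant in group A: observed split is degenerate
  expect_error(permutation_edge_test(a, b, 10), "zero-variance")
  # one non-constant subject per group in region 1: any split that pools
  # both leaves the other group constant there
  va2 <- va
  va2[1, 1] <- 2.0
  vb2 <- vb
  vb2[, 1] <- 1.5
  vb2[1, 1] <- 2.1
  a2 <- suvr_table(va2, atl, subject_ids = paste0("A", 1:5))
  b2 <- suvr_table(vb2, atl, subject_ids = paste0("B", 1:5))
  expect_warning(
    res <- permutation_edge_test(a2, b2, n_perm = 400, seed = 9),
    "zero-variance")
  expect_true(all(res$pvalues > 0))
})

test_that("significant_edges sorts by |delta| and honors alpha bounds", {
  co <- toy_cohort(12, 12, 5, seed = 35)
  res <- permutation_edge_test(co$a, co$b, n_perm = 100, seed = 4)
  all_edges <- significant_edges(res, 1)
  expect_equal(nrow(all_edges), 10)     # 5 * 4 / 2
  expect_true(all(diff(abs(all_edges$delta)) <= 1e-15))
  expect_error(significant_edges(res, 0), "alpha")
})

test_that("compare_at_sparsity restricts the edge universe to the union", {
  cfg <- scenario_config(
    group_sizes = c(control = 40, disease = 40), n_regions = 12,
    covariance_model = list(shared_latent = c(control = 0.1,
                                              disease = 0.5)),
    seed = 36)
  co <- generate_cohort(cfg)
  tab_d <- subset_subjects(co$suvr, which(co$subjects$group == "disease"))
  tab_c <- subset_subjects(co$suvr, which(co$subjects$group == "control"))
  m_all <- 12 * 11 / 2
  cmp <- suppressWarnings(
    compare_at_sparsity(tab_d, tab_c, S = 0.35, n_perm = 200, seed = 11))
  union_edges <- sum(cmp$perm$edge_mask[upper.tri(cmp$perm$edge_mask)])
  m <- floor(0.35 * m_all + 0.5)
  expect_lte(union_edges, 2 * m)
  expect_gte(union_edges, m)
  expect_lte(nrow(significant_edges(cmp$perm, 1)), union_edges)
  # S = 1 reproduces the unrestricted test
  cmp1 <- compare_at_sparsity(tab_d, tab_c, S = 1, n_perm = 50, seed = 12)
  expect_equal(nrow(significant_edges(cmp1$perm, 1)), m_all)
  # infeasible S warns
  expect_warning(
    compare_at_sparsity(tab_d, tab_c, S = 12 / m_all, n_perm = 20,
                        seed = 13),
    "minimal fully-connected")
})

test_that("sign patterns agree across sparsity levels on one cohort", {
  co <- generate_cohort(preset_scenario("gout_like", seed = 44))
  tab_d <- subset_subjects(co$suvr, which(co$subjects$group == "gout"))
  tab_c <- subset_subjects(co$suvr, which(co$subjects$group == "control"))
  lo <- compare_at_sparsity(tab_d, tab_c, S = 0.35, n_perm = 300, seed = 1)
  hi <- compare_at_sparsity(tab_d, tab_c, S = 0.55, n_perm = 300, seed = 1)
  sig_lo <- significant_edges(lo$perm, 0.05)
  sig_hi <- significant_edges(hi$perm, 0.05)
  key <- function(d) paste(d$i, d$j)
  shared <- intersect(key(sig_lo), key(sig_hi))
  expect_gt(length(shared), 0)
  expect_true(all(sign(sig_lo$delta[match(shared, key(sig_lo))]) ==
                    sign(sig_hi$delta[match(shared, key(sig_hi))])))
})

test_that("permutation results export to .edge/.node/.tsv", {
  co <- toy_cohort(10, 10, 4, seed = 37)
  res <- permutation_edge_test(co$a, co$b, n_perm = 60, seed = 6)
  dir <- withr::local_tempdir()
  paths <- export_perm_result(res, dir, prefix = "toy")
  expect_true(all(file.exists(paths)))
  back <- read_brainnet_edge(paths[["edge"]])
  d0 <- res$delta
  diag(d0) <- 0
  expect_equal(back, unname(d0), tolerance = 1e-5)
  expect_equal(nrow(read_brainnet_node(paths[["node"]])), 4)
})
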