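test_that("two-group test matches hand-computed Student values", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(3, 4, 5, 6, 7)
  res <- two_group_test(a, b, variance_rule = "always_student")
  expect_equal(res$t, -2)            # pooled sd sqrt(2.5), se = 1
  expect_equal(res$df, 8)
  expect_equal(res$direction, -1)
  expect_equal(res$p, 2 * pt(-2, 8))

  same <- two_group_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("Welch branch matches the Satterthwaite formula oracle", {
  set.seed(8)
  a <- rnorm(12, 0, 1)
  b <- rnorm(30, 0, 4)
  res <- two_group_test(a, b, variance_rule = "always_welch")
  expect_equal(res$test_used, "welch")
  expect_equal(res$df, welch_df_oracle(a, b), tolerance = 1e-10)
  expect_lt(res$df, length(a) + length(b) - 2)
  # the F-test rule also picks Welch for this variance ratio
  expect_equal(two_group_test(a, b)$test_used, "welch")
  # and Student for equal spread at these sizes
  set.seed(9)
  expect_equal(two_group_test(rnorm(30), rnorm(30))$test_used, "student")
})

test_that("two-group test is antisymmetric in its arguments", {
  set.seed(10)
  a <- rnorm(15, 1, 1)
  b <- rnorm(20, 0, 2)
  ab <- two_group_test(a, b)
  ba <- two_group_test(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$df, ba$df)
})

test_that("degenerate two-group inputs follow the stated conventions", {
  expect_equal(two_group_test(c(1, 1, 1), c(1, 1))$p, 1)
  expect_error(two_group_test(c(1, 1), c(2, 2)), "zero variance")
  expect_error(two_group_test(1, c(1, 2)), "at least 2")
})

test_that("region screen flags planted effects and respects alpha", {
  set.seed(12)
  p <- 8
  n <- 50
  va <- matrix(rnorm(n * p, 1.3, 0.1), n, p)
  vb <- matrix(rnorm(n * p, 1.3, 0.1), n, p)
  vb[, 3] <- vb[, 3] + 0.15          # strong planted increase
  atl <- toy_atlas(p)
  sc <- screen_regions(suvr_table(va, atl), suvr_table(vb, atl))
  expect_true(sc$significant[3])
  expect_equal(sc$direction[3], 1)
  # alpha -> 0 flags nothing
  sc0 <- screen_regions(suvr_table(va, atl), suvr_table(vb, atl),
                        alpha = 1e-12)
  expect_lte(sum(sc0$significant), 1)
  # BH mode is at least as conservative as the raw screen
  scbh <- screen_regions(suvr_table(va, atl), suvr_table(vb, atl),
                         adjust = "BH")
  expect_lte(sum(scbh$significant), sum(sc$significant))
  # mismatched atlases refuse to compare
  expect_error(
    screen_regions(suvr_table(va, atl),
                   suvr_table(vb[, 1:7], toy_atlas(7))),
    "atlas")
})

test_that("null-screen false-positive rate is near alpha", {
  rates <- vapply(1:100, function(s) {
    co <- toy_cohort(30, 30, 10, seed = 2000 + s)
    mean(screen_regions(co$a, co$b)$significant)
  }, numeric(1))
  expect_gt(mean(rates), 0.03)
  expect_lt(mean(rates), 0.07)
})

test_that("partial correlation equals Pearson at k = 0 and is exact on y = x", {
  set.seed(14)
  x <- rnorm(40)
  y <- 0.5 * x + rnorm(40)
  expect_equal(partial_correlation(x, y)$r_partial, pearson_oracle(x, y),
               tolerance = 1e-12)
  Z <- cbind(rnorm(40), rnorm(40))
  expect_equal(partial_correlation(x, x, Z)$r_partial, 1, tolerance = 1e-12)
})

test_that("residual and precision-matrix partial correlations agree to 1e-10", {
  set.seed(15)
  for (rep in 1:5) {
    n <- 60
    Z <- cbind(rnorm(n), rbinom(n, 1, 0.5), rnorm(n, 24, 3))
    x <- 0.3 * Z[, 1] + rnorm(n)
    y <- -0.2 * Z[, 1] + 0.4 * x + rnorm(n)
    res <- partial_correlation(x, y, Z)
    expect_equal(res$r_partial, partial_cor_precision(x, y, Z),
                 tolerance = 1e-10)
    expect_equal(res$df, n - 2 - 3)
    # t/p relationship
    expect_equal(res$t, res$r_partial * sqrt(res$df / (1 - res$r_partial^2)))
    expect_equal(res$p, 2 * pt(-abs(res$t), res$df))
  }
})

test_that("partial correlation is invariant to affine covariates and scaling", {
  set.seed(16)
  n <- 50
  Z <- cbind(rnorm(n), rnorm(n))
  x <- rnorm(n)
  y <- rnorm(n)
  base <- partial_correlation(x, y, Z)$r_partial
  expect_equal(partial_correlation(3 * x - 1, -2 * y + 5, Z)$r_partial,
               -base, tolerance = 1e-12)
  Z2 <- cbind(10 * Z[, 1] + 3, Z[, 2] - Z[, 1])
  expect_equal(partial_correlation(x, y, Z2)$r_partial, base,
               tolerance = 1e-10)
})

test_that("partial correlation rejects degenerate inputs", {
  expect_error(partial_correlation(rnorm(4), rnorm(4), cbind(rnorm(4),
                                                             rnorm(4))),
               "n >= k \\+ 3")
  z <- rnorm(20)
  expect_error(partial_correlation(2 * z + 1, rnorm(20), cbind(z)),
               "constant")
})

test_that("biomarker screen is complete-case per pair and recovers a link", {
  cfg <- scenario_config(
    group_sizes = c(control = 300), n_regions = 12,
    biomarker_links = data.frame(
      biomarker = c("uric_acid", "noise1", "noise2"),
      region = c(5, 8, 9), rho = c(0.5, 0, 0),
      missing_rate = c(0.2, 0, 0)),
    seed = 17
  )
  co <- generate_cohort(cfg)
  res <- screen_biomarkers(co$suvr, co$subjects)
  # planted pair flagged with the right sign
  hit <- res[res$region == 5 & res$biomarker == "uric_acid", ]
  expect_true(hit$significant)
  expect_gt(hit$r_partial, 0.3)
  # n varies with per-biomarker missingness
  expect_lt(hit$n, max(res$n))
  expect_true(all(res$n[res$biomarker == "noise1"] == 300))
  # null pairs flagged around the alpha rate
  nulls <- res[res$biomarker %in% c("noise1", "noise2") & res$region != 5, ]
  expect_lt(mean(nulls$significant), 0.2)
})

test_that("fully missing biomarkers are skipped with a warning, not an error", {
  set.seed(18)
  n <- 30
  subjects <- data.frame(subject_id = sprintf("S%02d", 1:n), group = "g",
                         age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5),
                         bmi = rnorm(n, 24, 3), dead = NA_real_,
                         alive = rnorm(n), stringsAsFactors = FALSE)
  tab <- suvr_table(matrix(runif(n * 3, 1, 2), n, 3), toy_atlas(3),
                    subject_ids = subjects$subject_id)
  expect_warning(res <- screen_biomarkers(tab, subjects), "skipped")
  expect_false("dead" %in% res$biomarker)
  expect_equal(sum(res$biomarker == "alive"), 3)
})
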