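test_that("SUVR is target over reference and inverts exactly", {
  raw <- toy_table(matrix(c(2, 1, 1.5, 3), 2, 2), kind = "raw_suv")
  ref <- c(1, 2)
  out <- compute_suvr(raw, ref)
  expect_equal(out$kind, "suvr")
  expect_equal(out$values[1, 1], 2)        # SUV 2 / ref 1
  expect_equal(out$values[2, 2], 1.5)
  # identity: target == reference
  raw2 <- toy_table(matrix(2, 3, 2), kind = "raw_suv")
  expect_true(all(compute_suvr(raw2, rep(2, 3))$values == 1))
  # algebraic inverse on random positive tables
  set.seed(3)
  vals <- matrix(runif(60, 0.5, 4), 10, 6)
  refs <- runif(10, 0.8, 1.6)
  suvr <- compute_suvr(toy_table(vals, kind = "raw_suv"), refs)
  expect_equal(suvr$values * refs, vals, tolerance = 1e-12,
               ignore_attr = TRUE)
  # scale invariance: same c multiplying target and reference
  scl <- compute_suvr(toy_table(vals * 2, kind = "raw_suv"), refs * 2)
  expect_equal(scl$values, suvr$values, tolerance = 1e-12)
})

test_that("non-positive reference errors with the subject named", {
  raw <- toy_table(matrix(1, 2, 2), kind = "raw_suv")
  expect_error(compute_suvr(raw, c(1, 0)), raw$subject_ids[2])
})

make_correction_fixture <- function(seed, n_per = 60, p = 4,
                                    beta_age = 0.01, beta_sex = 0.05,
                                    shift_age = 0) {
  set.seed(seed)
  n <- 2 * n_per
  grp <- rep(c("control", "disease"), each = n_per)
  age <- c(rnorm(n_per, 50, 10), rnorm(n_per, 50 + shift_age, 10))
  sex <- rbinom(n, 1, 0.5)
  vals <- 1.3 + outer(age, rep(beta_age, p)) +
    outer(sex, rep(beta_sex, p)) +
    matrix(rnorm(n * p, 0, 0.05), n, p)
  subjects <- data.frame(subject_id = sprintf("S%03d", 1:n), group = grp,
                         age = age, sex = sex, bmi = 24,
                         stringsAsFactors = FALSE)
  tab <- suvr_table(vals, toy_atlas(p), subject_ids = subjects$subject_id)
  list(tab = tab, subjects = subjects)
}

test_that("fit_correction recovers exact linear structure", {
  fx <- make_correction_fixture(1)
  # constant response: zero slopes, intercept = the constant
  const <- suvr_table(matrix(1.2, 120, 4), toy_atlas(4),
                      subject_ids = fx$subjects$subject_id)
  m <- fit_correction(const, fx$subjects, fit_scope = "pooled")
  expect_equal(unname(m$coefficients$pooled["intercept", ]), rep(1.2, 4))
  expect_equal(max(abs(m$coefficients$pooled[c("b_age", "b_sex"), ])), 0,
               tolerance = 1e-10)
  # exact linear data: slope recovered to 1e-10
  exact <- suvr_table(
    matrix(1 + 0.01 * fx$subjects$age, 120, 4), toy_atlas(4),
    subject_ids = fx$subjects$subject_id)
  m2 <- fit_correction(exact, fx$subjects, fit_scope = "pooled")
  expect_equal(unname(m2$coefficients$pooled["b_age", ]), rep(0.01, 4),
               tolerance = 1e-10)
})

test_that("fitted coefficients match the normal-equations oracle", {
  fx <- make_correction_fixture(7)
  m <- fit_correction(fx$tab, fx$subjects, fit_scope = "pooled")
  X <- cbind(1, fx$subjects$age, fx$subjects$sex)
  beta_oracle <- solve(t(X) %*% X) %*% t(X) %*% fx$tab$values
  expect_equal(unname(m$coefficients$pooled), unname(beta_oracle),
               tolerance = 1e-8)
})

test_that("per-group correction preserves group means exactly", {
  fx <- make_correction_fixture(2)
  m <- fit_correction(fx$tab, fx$subjects, fit_scope = "per_group")
  corr <- apply_correction(m, fx$tab, fx$subjects)
  for (g in c("control", "disease")) {
    idx <- fx$subjects$group == g
    expect_equal(colMeans(corr$values[idx, ]),
                 colMeans(fx$tab$values[idx, ]), tolerance = 1e-10)
    # per-group residuals sum to zero
    pred <- cbind(1, fx$subjects$age[idx], fx$subjects$sex[idx]) %*%
      m$coefficients[[g]]
    expect_equal(max(abs(colSums(fx$tab$values[idx, ] - pred))), 0,
                 tolerance = 1e-8)
  }
})

test_that("pooled residuals are orthogonal to age and sex", {
  fx <- make_correction_fixture(3)
  m <- fit_correction(fx$tab, fx$subjects, fit_scope = "pooled")
  corr <- apply_correction(m, fx$tab, fx$subjects)
  resid <- corr$values - matrix(m$pooled_means, 120, 4, byrow = TRUE)
  age_c <- fx$subjects$age - mean(fx$subjects$age)
  sex_c <- fx$subjects$sex - mean(fx$subjects$sex)
  expect_lt(max(abs(crossprod(age_c, resid))), 1e-8)
  expect_lt(max(abs(crossprod(sex_c, resid))), 1e-8)
})

test_that("pooled correction removes an age confound from the contrast", {
  # groups differ in age, response depends on age only: corrected t-tests
  # should reject at about the nominal rate
  rej <- vapply(1:60, function(s) {
    fx <- make_correction_fixture(300 + s, n_per = 40, p = 2,
                                  shift_age = 10)
    m <- fit_correction(fx$tab, fx$subjects, fit_scope = "pooled")
    corr <- apply_correction(m, fx$tab, fx$subjects)
    idx <- fx$subjects$group == "disease"
    sc <- screen_regions(subset_subjects(corr, which(!idx)),
                         subset_subjects(corr, which(idx)))
    mean(sc$significant)
  }, numeric(1))
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.12)
  # while the raw (uncorrected) contrast is grossly inflated
  fx <- make_correction_fixture(999, n_per = 200, p = 2, shift_age = 10)
  idx <- fx$subjects$group == "disease"
  sc_raw <- screen_regions(subset_subjects(fx$tab, which(!idx)),
                           subset_subjects(fx$tab, which(idx)))
  expect_true(all(sc_raw$significant))
})

test_that("correction errors on unknown groups and degenerate designs", {
  fx <- make_correction_fixture(4)
  m <- fit_correction(fx$tab, fx$subjects, groups = "control")
  only_dis <- subset_subjects(fx$tab, which(fx$subjects$group == "disease"))
  expect_error(apply_correction(m, only_dis, fx$subjects), "disease")

  single_sex <- fx$subjects
  single_sex$sex <- 1
  expect_error(fit_correction(fx$tab, single_sex, fit_scope = "per_group"),
               "rank-deficient|group")
})

test_that("correction model serializes to JSON", {
  fx <- make_correction_fixture(5)
  m <- fit_correction(fx$tab, fx$subjects)
  path <- withr::local_tempfile(fileext = ".json")
  write_correction_model(m, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$fit_scope, "pooled")
  expect_equal(length(back$coefficients$pooled), 4)
})
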