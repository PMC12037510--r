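#' Two-group t-test for one region
#'
#' Two-tailed independent t-test. By default a two-sided F test of
#' variance equality at alpha = 0.05 selects between the pooled-variance
#' Student test and Welch's unequal-variance test (Satterthwaite degrees
#' of freedom); `variance_rule` can force either.
#'
#' @param a,b numeric vectors (disease and control values, in the order
#'   the direction sign should read: `direction = sign(mean(a) - mean(b))`).
#' @param variance_rule `"f_test"` (default), `"always_student"`, or
#'   `"always_welch"`.
#' @return A one-row data frame: `mean_a`, `mean_b`, `sd_a`, `sd_b`, `t`,
#'   `df`, `p`, `test_used`, `direction`.
#' @export
two_group_test <- function(a, b,
                           variance_rule = c("f_test", "always_student",
                                             "always_welch")) {
  variance_rule <- match.arg(variance_rule)
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values")
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(data.frame(mean_a = mean(a), mean_b = mean(b), sd_a = 0,
                        sd_b = 0, t = 0,
                        df = length(a) + length(b) - 2, p = 1,
                        test_used = "student", direction = 0,
                        stringsAsFactors = FALSE))
    }
    stop("zero variance in both groups with unequal means")
  }
  use_welch <- switch(variance_rule,
    always_welch = TRUE,
    always_student = FALSE,
    f_test = {
      ftest <- stats::var.test(a, b)
      is.finite(ftest$p.value) && ftest$p.value < 0.05
    }
  )
  tt <- stats::t.test(a, b, var.equal = !use_welch)
  data.frame(
    mean_a = mean(a), mean_b = mean(b),
    sd_a = stats::sd(a), sd_b = stats::sd(b),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value,
    test_used = if (use_welch) "welch" else "student",
    direction = sign(mean(a) - mean(b)),
    stringsAsFactors = FALSE
  )
}

#' Screen regions for group differences
#'
#' Runs [two_group_test()] per analysis region, disease minus control.
#' Significance is uncorrected `p < alpha` by default (the exploratory
#' screen); Benjamini-Hochberg adjustment is available via `adjust`.
#'
#' @param control,disease [suvr_table()]s on the same atlas (typically
#'   corrected SUVRs).
#' @param alpha significance level (default 0.05).
#' @param variance_rule passed to [two_group_test()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame, one row per region: `region` (index), `id`,
#'   `name`, the [two_group_test()] fields, `p_adj`, and logical
#'   `significant`.
#' @export
screen_regions <- function(control, disease, alpha = 0.05,
                           variance_rule = "f_test",
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!same_atlas(control, disease)) stop("atlas mismatch between tables")
  reg <- analysis_regions(control$atlas)
  rows <- lapply(seq_len(ncol(control$values)), function(r) {
    two_group_test(disease$values[, r], control$values[, r],
                   variance_rule = variance_rule)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(region = seq_len(nrow(reg)), id = reg$id,
                          name = reg$name, stringsAsFactors = FALSE), out)
  out$p_adj <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Partial correlation with covariate adjustment
#'
#' Residualizes `x` and `y` on the covariates (with intercept) by least
#' squares and correlates the residuals. The t statistic is
#' \eqn{t = r \sqrt{df / (1 - r^2)}} with \eqn{df = n - 2 - k} for k
#' covariates; two-tailed p from the t distribution. Equivalent to the
#' precision-matrix (inverse covariance) formulation.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data frame with `k` columns (or
#'   `NULL` for plain Pearson correlation).
#' @return One-row data frame: `n`, `k`, `r_partial`, `t`, `df`, `p`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    Z <- matrix(numeric(0), nrow = length(x), ncol = 0)
  } else {
    Z <- as.matrix(covariates)
  }
  ok <- is.finite(x) & is.finite(y) &
    (if (ncol(Z) > 0) apply(Z, 1, function(r) all(is.finite(r))) else TRUE)
  x <- x[ok]
  y <- y[ok]
  Z <- Z[ok, , drop = FALSE]
  n <- length(x)
  k <- ncol(Z)
  if (n < k + 3) stop(sprintf("need n >= k + 3 complete cases (n=%d, k=%d)",
                              n, k))
  X <- cbind(1, Z)
  rx <- stats::resid(stats::lm.fit(X, x))
  ry <- stats::resid(stats::lm.fit(X, y))
  if (stats::var(rx) <= stats::var(x) * 1e-20 ||
      stats::var(ry) <= stats::var(y) * 1e-20) {
    stop("constant x or y after residualization; correlation undefined")
  }
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  data.frame(n = n, k = k, r_partial = r, t = tstat, df = df, p = p)
}

#' Screen biomarkers against region SUVRs by partial correlation
#'
#' For every (region, biomarker) pair, correlates the region's SUVR with
#' the biomarker after adjusting for the covariates, using the subjects
#' with complete data for that pair (so `n` varies across pairs when
#' biomarkers have different missingness). Pairs with too few complete
#' cases are skipped with a warning.
#'
#' @param suvr a [suvr_table()].
#' @param subjects subject data frame covering the table's rows.
#' @param regions analysis-region indices to screen (default: all).
#' @param biomarkers biomarker column names (default:
#'   [biomarker_columns()] of `subjects`).
#' @param covariates covariate column names (default age, sex, bmi).
#' @param alpha significance level.
#' @param groups optional subset of groups to restrict the screen to.
#' @return Data frame, one row per evaluated pair: `region`, `name`,
#'   `biomarker`, `n`, `k`, `r_partial`, `t`, `df`, `p`, `significant`.
#' @export
screen_biomarkers <- function(suvr, subjects, regions = NULL,
                              biomarkers = NULL,
                              covariates = c("age", "sex", "bmi"),
                              alpha = 0.05, groups = NULL) {
  meta <- align_subjects(suvr, subjects)
  vals <- suvr$values
  if (!is.null(groups)) {
    keep <- meta$group %in% groups
    meta <- meta[keep, , drop = FALSE]
    vals <- vals[keep, , drop = FALSE]
  }
  if (is.null(regions)) regions <- seq_len(ncol(vals))
  if (is.null(biomarkers)) biomarkers <- biomarker_columns(meta)
  miss <- setdiff(covariates, names(meta))
  if (length(miss) > 0) {
    stop("covariate column(s) missing: ", paste(miss, collapse = ", "))
  }
  Z <- as.matrix(meta[, covariates, drop = FALSE])
  reg_names <- colnames(vals)
  out <- list()
  skipped <- character(0)
  for (r in regions) {
    for (bm in biomarkers) {
      res <- tryCatch(
        partial_correlation(vals[, r], meta[[bm]], Z),
        error = function(e) NULL
      )
      if (is.null(res)) {
        skipped <- c(skipped, sprintf("%s/%s", reg_names[r], bm))
        next
      }
      out[[length(out) + 1]] <- cbind(
        data.frame(region = r, name = reg_names[r], biomarker = bm,
                   stringsAsFactors = FALSE),
        res
      )
    }
  }
  if (length(skipped) > 0) {
    warning("skipped pair(s) with too few complete cases: ",
            paste(skipped, collapse = ", "))
  }
  if (length(out) == 0) {
    return(data.frame(region = integer(0), name = character(0),
                      biomarker = character(0), n = integer(0),
                      k = integer(0), r_partial = numeric(0),
                      t = numeric(0), df = numeric(0), p = numeric(0),
                      significant = logical(0)))
  }
  res <- do.call(rbind, out)
  res$significant <- res$p < alpha
  rownames(res) <- NULL
  res
}
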