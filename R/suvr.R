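#' Compute SUVR from raw region SUVs
#'
#' Divides each subject's regional mean SUV by that subject's reference-
#' region mean SUV (SUVR = SUV_target / SUV_reference), the standard
#' intensity normalization with the whole cerebellum as reference.
#'
#' @param raw a [suvr_table()] of kind `"raw_suv"`.
#' @param reference numeric vector of per-subject reference means, in row
#'   order (see [reference_means()]).
#' @return A [suvr_table()] of kind `"suvr"`.
#' @export
compute_suvr <- function(raw, reference) {
  stopifnot(inherits(raw, "suvr_table"))
  if (raw$kind != "raw_suv") stop("input table must have kind 'raw_suv'")
  if (length(reference) != nrow(raw$values)) {
    stop("one reference mean per subject required")
  }
  bad <- which(!is.finite(reference) | reference <= 0)
  if (length(bad) > 0) {
    stop("non-positive reference mean for subject(s): ",
         paste(raw$subject_ids[bad], collapse = ", "))
  }
  suvr_table(raw$values / reference, raw$atlas,
             subject_ids = raw$subject_ids, kind = "suvr")
}

#' Fit the per-region age/sex correction model
#'
#' Ordinary least squares of SUVR on age and sex (with intercept), one
#' model per analysis region. With `fit_scope = "pooled"` a single model
#' is fitted over all included subjects (both groups of a contrast
#' together); with `"per_group"` a separate model is fitted within each
#' group. Per-group mean raw SUVRs are stored for the recentering step of
#' [apply_correction()].
#'
#' @param suvr a [suvr_table()] (kind `"suvr"` or `"raw_suv"`).
#' @param subjects subject data frame (needs `subject_id`, `group`, `age`,
#'   `sex`) covering every row of `suvr`.
#' @param groups groups to include in the fit; default: all groups present.
#' @param fit_scope `"pooled"` (default) or `"per_group"`.
#' @return An object of class `correction_model`: per-region coefficient
#'   triples (intercept, b_age, b_sex) per fitted scope, per-group and
#'   pooled per-region means, the scope tag and the fitted group set.
#' @export
fit_correction <- function(suvr, subjects, groups = NULL,
                           fit_scope = c("pooled", "per_group")) {
  fit_scope <- match.arg(fit_scope)
  meta <- align_subjects(suvr, subjects)
  if (is.null(groups)) groups <- unique(meta$group)
  keep <- meta$group %in% groups
  meta <- meta[keep, , drop = FALSE]
  vals <- suvr$values[keep, , drop = FALSE]
  if (nrow(vals) < 4) stop("need at least 4 subjects to fit the correction")

  ols_coef <- function(v, a, s) {
    X <- cbind(1, a, s)
    if (qr(X)$rank < 3) {
      stop("rank-deficient design (age/sex collinear or constant)")
    }
    qr.coef(qr(X), v)
  }

  region_names <- colnames(vals)
  if (fit_scope == "pooled") {
    cf <- ols_coef(vals, meta$age, meta$sex)
    coefs <- list(pooled = matrix(cf, nrow = 3,
                                  dimnames = list(c("intercept", "b_age",
                                                    "b_sex"), region_names)))
  } else {
    coefs <- lapply(stats::setNames(groups, groups), function(g) {
      idx <- meta$group == g
      if (sum(idx) < 4) {
        stop(sprintf("group '%s' has fewer than 4 subjects", g))
      }
      cf <- tryCatch(ols_coef(vals[idx, , drop = FALSE],
                              meta$age[idx], meta$sex[idx]),
                     error = function(e) {
                       stop(sprintf("group '%s': %s", g, conditionMessage(e)))
                     })
      matrix(cf, nrow = 3, dimnames = list(c("intercept", "b_age", "b_sex"),
                                           region_names))
    })
  }
  group_means <- lapply(stats::setNames(groups, groups), function(g) {
    colMeans(vals[meta$group == g, , drop = FALSE])
  })
  structure(
    list(coefficients = coefs, fit_scope = fit_scope,
         groups = groups, group_means = group_means,
         pooled_means = colMeans(vals)),
    class = "correction_model"
  )
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("correction_model [%s]: groups %s, %d regions\n",
              x$fit_scope, paste(x$groups, collapse = ", "),
              ncol(x$coefficients[[1]])))
  invisible(x)
}

#' Serialize a correction model to JSON
#' @param model a `correction_model`.
#' @param path output path; `NULL` returns the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_correction_model <- function(model, path = NULL) {
  obj <- list(fit_scope = model$fit_scope, groups = model$groups,
              coefficients = lapply(model$coefficients, function(m)
                as.data.frame(t(m))),
              group_means = model$group_means,
              pooled_means = model$pooled_means)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Apply the age/sex correction
#'
#' Forms the corrected SUVR as a recentering constant plus the regression
#' residual. Under `fit_scope = "pooled"` the constant is the per-region
#' mean over the pooled fitted sample, so that group-mean differences
#' driven by age/sex composition are removed (the point of the
#' correction); under `"per_group"` it is the per-group mean, which
#' preserves each group's raw means exactly (per-group OLS residuals sum
#' to zero).
#'
#' @param model a `correction_model` from [fit_correction()].
#' @param suvr the [suvr_table()] to correct.
#' @param subjects subject data frame covering every row of `suvr`.
#' @return A [suvr_table()] of kind `"corrected_suvr"`.
#' @export
apply_correction <- function(model, suvr, subjects) {
  meta <- align_subjects(suvr, subjects)
  missing_groups <- setdiff(unique(meta$group), model$groups)
  if (length(missing_groups) > 0) {
    stop("subject group(s) absent from the correction model: ",
         paste(missing_groups, collapse = ", "))
  }
  vals <- suvr$values
  n <- nrow(vals)
  pred <- matrix(0, n, ncol(vals))
  center <- matrix(0, n, ncol(vals))
  for (g in unique(meta$group)) {
    idx <- meta$group == g
    cf <- if (model$fit_scope == "pooled") model$coefficients$pooled
      else model$coefficients[[g]]
    X <- cbind(1, meta$age[idx], meta$sex[idx])
    pred[idx, ] <- X %*% cf
    ctr <- if (model$fit_scope == "pooled") model$pooled_means
      else model$group_means[[g]]
    center[idx, ] <- matrix(ctr, sum(idx), ncol(vals), byrow = TRUE)
  }
  corrected <- center + (vals - pred)
  suvr_table(corrected, suvr$atlas, subject_ids = suvr$subject_ids,
             kind = "corrected_suvr")
}

# Match subject metadata rows to the rows of a suvr_table, in table order.
align_subjects <- function(suvr, subjects) {
  idx <- match(suvr$subject_ids, subjects$subject_id)
  if (anyNA(idx)) {
    stop("subjects table is missing ids: ",
         paste(suvr$subject_ids[is.na(idx)][1:5], collapse = ", "))
  }
  subjects[idx, , drop = FALSE]
}
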