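#' Scenario configuration for the synthetic cohort generator
#'
#' Describes a multi-group cohort of regional SUVRs with planted ground
#' truth at every level the downstream analysis touches: additive group
#' effects per region, age/sex slopes (confounds), block-structured
#' residual covariance with an optional per-group shared latent factor
#' (so connectivity can differ between groups), biomarker columns tied to
#' specific regions at a target partial correlation, and per-biomarker
#' missingness.
#'
#' The residual correlation of group \eqn{g} is
#' \deqn{R_g = (1 - c_g) R_{block} + c_g J}
#' where \eqn{R_{block}} has within-module correlation `r_w` and
#' between-module correlation `r_b`, \eqn{J} is the all-ones matrix, and
#' \eqn{c_g} is the group's `shared_latent` weight. Raising \eqn{c_g}
#' raises every inter-regional correlation, emulating globally
#' strengthened metabolic connectivity.
#'
#' @param group_sizes named integer vector, group -> subject count.
#' @param n_regions number of analysis regions (default 90).
#' @param atlas optional [atlas_spec()]; defaults to [atlas_aal90()] when
#'   `n_regions` is 90, otherwise a generic atlas is built.
#' @param base_mean baseline SUVR level, scalar or length-`n_regions`.
#' @param effect named list, group -> additive SUVR shift per region
#'   (length `n_regions`); groups absent from the list get zero effect.
#' @param covariate_model list with elements `age` (named list group ->
#'   c(mean, sd)), `sex_p` (named vector group -> male proportion), `bmi`
#'   (named list group -> c(mean, sd)), `beta_age`, `beta_sex` (per-region
#'   slopes, recycled).
#' @param covariance_model list with elements `module` (module id per
#'   region), `r_w`, `r_b`, `sigma` (residual SD), `shared_latent`
#'   (named vector group -> weight in \[0, 1)).
#' @param biomarker_links data frame with columns `biomarker`, `region`
#'   (analysis-region index), `rho` (target partial correlation given age,
#'   sex, BMI), `missing_rate`.
#' @param null_biomarkers character: biomarker columns generated from
#'   covariates plus independent noise only (no region link).
#' @param noise `"gaussian"` (default) or `"t"` for heavier tails
#'   (standardized Student-t residuals, `t_df` degrees of freedom).
#' @param t_df degrees of freedom for `noise = "t"`.
#' @param seed integer RNG seed; generation is fully reproducible from it.
#' @return An object of class `scenario_config`.
#' @seealso [generate_cohort()], [preset_scenario()]
#' @export
scenario_config <- function(group_sizes,
                            n_regions = 90,
                            atlas = NULL,
                            base_mean = 1.3,
                            effect = list(),
                            covariate_model = list(),
                            covariance_model = list(),
                            biomarker_links = NULL,
                            null_biomarkers = character(),
                            noise = c("gaussian", "t"),
                            t_df = 5,
                            seed = 1) {
  noise <- match.arg(noise)
  if (is.null(names(group_sizes)) || any(names(group_sizes) == "")) {
    stop("group_sizes must be a named vector")
  }
  groups <- names(group_sizes)
  if (is.null(atlas)) {
    atlas <- if (n_regions == 90) atlas_aal90() else
      atlas_spec(seq_len(n_regions + 1),
                 c(sprintf("region_%02d", seq_len(n_regions)), "reference"),
                 is_reference = c(rep(FALSE, n_regions), TRUE))
  }
  stopifnot(n_analysis(atlas) == n_regions)

  cm <- covariate_model
  def_age <- c(53, 15)
  cov_model <- list(
    age = fill_by_group(cm$age, groups, def_age),
    sex_p = fill_by_group_num(cm$sex_p, groups, 0.5),
    bmi = fill_by_group(cm$bmi, groups, c(23.5, 3)),
    beta_age = rep_len(cm$beta_age %||% -0.002, n_regions),
    beta_sex = rep_len(cm$beta_sex %||% 0.02, n_regions)
  )

  vm <- covariance_model
  module <- vm$module %||%
    sort(rep_len(seq_len(min(6, n_regions)), n_regions))
  var_model <- list(
    module = rep_len(module, n_regions),
    r_w = vm$r_w %||% 0.45,
    r_b = vm$r_b %||% 0.15,
    sigma = vm$sigma %||% 0.1,
    shared_latent = fill_by_group_num(vm$shared_latent, groups, 0)
  )
  if (any(var_model$shared_latent < 0 | var_model$shared_latent >= 1)) {
    stop("shared_latent weights must lie in [0, 1)")
  }

  if (!is.null(biomarker_links)) {
    biomarker_links <- as.data.frame(biomarker_links)
    stopifnot(all(c("biomarker", "region", "rho", "missing_rate") %in%
                    names(biomarker_links)))
    if (any(abs(biomarker_links$rho) >= 1)) stop("|rho| must be < 1")
    if (any(biomarker_links$missing_rate < 0 |
            biomarker_links$missing_rate >= 1)) {
      stop("missing_rate must lie in [0, 1)")
    }
    if (any(biomarker_links$region < 1 |
            biomarker_links$region > n_regions)) {
      stop("biomarker link region index out of range")
    }
  }

  structure(
    list(group_sizes = group_sizes, groups = groups,
         n_regions = n_regions, atlas = atlas,
         base_mean = rep_len(base_mean, n_regions),
         effect = effect,
         covariate_model = cov_model,
         covariance_model = var_model,
         biomarker_links = biomarker_links,
         null_biomarkers = null_biomarkers,
         noise = noise, t_df = t_df, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

fill_by_group <- function(x, groups, default) {
  out <- stats::setNames(rep(list(default), length(groups)), groups)
  if (!is.null(x)) for (g in intersect(names(x), groups)) out[[g]] <- x[[g]]
  out
}

fill_by_group_num <- function(x, groups, default) {
  out <- stats::setNames(rep(default, length(groups)), groups)
  if (!is.null(x)) out[intersect(names(x), groups)] <-
      x[intersect(names(x), groups)]
  out
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("scenario_config:",
      paste(sprintf("%s=%d", x$groups, x$group_sizes), collapse = ", "),
      sprintf("| %d regions, seed %d\n", x$n_regions, x$seed))
  invisible(x)
}

# Residual correlation matrix for one group; errors if not positive
# definite (checked by Cholesky before any sampling happens).
group_residual_correlation <- function(config, group) {
  m <- config$covariance_model$module
  R <- ifelse(outer(m, m, "=="), config$covariance_model$r_w,
              config$covariance_model$r_b)
  diag(R) <- 1
  c_g <- config$covariance_model$shared_latent[[group]]
  R <- (1 - c_g) * R + c_g
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    stop(sprintf("residual covariance for group '%s' is not positive definite",
                 group))
  }
  list(R = R, chol = ch)
}

#' Generate a synthetic cohort
#'
#' Draws subjects group by group. Per subject: age, sex and BMI from the
#' scenario's covariate model (age clipped to 18-90 years, BMI to >= 12);
#' regional SUVR as
#' \deqn{SUVR_{ir} = \mu_r + \delta_{g(i),r} + \beta^{age}_r age_i +
#'   \beta^{sex}_r sex_i + \epsilon_{ir}}
#' with \eqn{\epsilon_i} multivariate normal (or standardized-t) with the
#' group's block/shared-latent correlation scaled by `sigma`. Each linked
#' biomarker is built from the covariates plus a loading on the linked
#' region's residual,
#' \eqn{\lambda = \rho\,\sigma_\eta / (\sigma_\epsilon \sqrt{1-\rho^2})},
#' so its partial correlation with that region's SUVR given age, sex and
#' BMI equals `rho` in expectation. Missing biomarker entries are masked
#' completely at random at the link's `missing_rate`; masking touches only
#' the missingness flags, never the simulated values.
#'
#' @param config a [scenario_config()].
#' @return A list with elements `subjects` (data frame: `subject_id`,
#'   `group`, `age`, `sex`, `bmi`, one column per biomarker) and `suvr`
#'   (a [suvr_table()] of kind `"suvr"`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  chols <- lapply(stats::setNames(config$groups, config$groups),
                  function(g) group_residual_correlation(config, g))
  with_seed(config$seed, generate_cohort_impl(config, chols))
}

generate_cohort_impl <- function(config, chols) {
  R <- config$n_regions
  cm <- config$covariate_model
  links <- config$biomarker_links
  bm_names <- unique(c(if (!is.null(links)) as.character(links$biomarker),
                       config$null_biomarkers))
  subj_list <- list()
  suvr_list <- list()
  for (g in config$groups) {
    n <- config$group_sizes[[g]]
    age <- pmin(pmax(stats::rnorm(n, cm$age[[g]][1], cm$age[[g]][2]), 18), 90)
    sex <- stats::rbinom(n, 1, cm$sex_p[[g]])
    bmi <- pmax(stats::rnorm(n, cm$bmi[[g]][1], cm$bmi[[g]][2]), 12)
    sigma <- config$covariance_model$sigma
    z <- if (config$noise == "t") {
      df <- config$t_df
      matrix(stats::rt(n * R, df) / sqrt(df / (df - 2)), n, R)
    } else {
      matrix(stats::rnorm(n * R), n, R)
    }
    eps <- (z %*% chols[[g]]$chol) * sigma
    delta <- config$effect[[g]] %||% rep(0, R)
    vals <- matrix(config$base_mean, n, R, byrow = TRUE) +
      matrix(rep_len(delta, R), n, R, byrow = TRUE) +
      outer(age, cm$beta_age) + outer(as.numeric(sex), cm$beta_sex) + eps
    sub <- data.frame(
      subject_id = sprintf("%s_%04d", g, seq_len(n)),
      group = g, age = age, sex = sex, bmi = bmi,
      stringsAsFactors = FALSE
    )
    for (bm in bm_names) {
      lk <- if (!is.null(links)) links[links$biomarker == bm, , drop = FALSE]
        else links
      eta <- stats::rnorm(n)                   # sigma_eta = 1
      val <- 2 + 0.02 * age + 0.5 * sex + 0.1 * bmi + eta
      if (!is.null(lk) && nrow(lk) > 0) {
        for (j in seq_len(nrow(lk))) {
          rho <- lk$rho[j]
          lambda <- rho / (sigma * sqrt(1 - rho^2))  # sigma_eta = 1
          val <- val + lambda * eps[, lk$region[j]]
        }
        # mask draws are always consumed so the RNG stream (and hence every
        # downstream value) is invariant to the missing rate
        rate <- max(lk$missing_rate)
        mask <- stats::runif(n) < rate
        val[mask] <- NA
      }
      sub[[bm]] <- val
    }
    subj_list[[g]] <- sub
    suvr_list[[g]] <- vals
  }
  subjects <- do.call(rbind, subj_list)
  rownames(subjects) <- NULL
  values <- do.call(rbind, suvr_list)
  rownames(values) <- subjects$subject_id
  list(subjects = subjects,
       suvr = suvr_table(values, config$atlas,
                         subject_ids = subjects$subject_id, kind = "suvr"))
}

#' Preset cohort scenarios
#'
#' Named scenario presets mirroring the study conditions of a metabolic-
#' disease FDG-PET cohort: group sizes 497 controls vs 112 hypertension,
#' 56 T2DM, 11 obesity, and a 14 vs 14 age/sex-matched gout contrast;
#' age/sex compositions per group; hypo- or hyper-metabolic planted
#' effects of 0.5 residual-SD magnitude in the direction each condition
#' shows (49 regions down plus right amygdala up for hypertension-like;
#' 38 down for T2DM-like; 4 motor/cingulate regions up for obesity-like;
#' right paracentral lobule up for gout-like); and per-group shared-latent
#' weights so covariance connectivity is attenuated in the hypertension-,
#' T2DM- and obesity-like groups but elevated in the gout-like group.
#' `"null"` has zero effects and identical covariance in both groups.
#'
#' @param name one of `"hypertension_like"`, `"t2dm_like"`,
#'   `"obesity_like"`, `"gout_like"`, `"null"`.
#' @param seed RNG seed stored in the config.
#' @param effect_size planted effect magnitude in units of the residual SD
#'   (default 0.5).
#' @return A [scenario_config()].
#' @export
preset_scenario <- function(name, seed = 1, effect_size = 0.5) {
  valid <- c("hypertension_like", "t2dm_like", "obesity_like",
             "gout_like", "null")
  if (!name %in% valid) {
    stop("unknown preset '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  }
  sigma <- 0.1
  eff <- effect_size * sigma
  ctrl_age <- c(53.37, 15.22)
  ctrl_sex <- 0.5252
  ninety <- 90

  mk_effect <- function(down = integer(), up = integer()) {
    e <- rep(0, ninety)
    e[down] <- -eff
    e[up] <- eff
    e
  }

  switch(name,
    null = scenario_config(
      group_sizes = c(control = 100, disease = 100),
      seed = seed
    ),
    hypertension_like = scenario_config(
      group_sizes = c(control = 497, hypertension = 112),
      # 49 hypometabolic regions (frontal/occipital/temporal slots plus the
      # right superior parietal slot, which carries the uric-acid link) and
      # the right amygdala slot hypermetabolic
      effect = list(hypertension = mk_effect(down = c(setdiff(1:49, 42), 60),
                                             up = 42)),
      covariate_model = list(
        age = list(control = ctrl_age, hypertension = c(63.02, 11.38)),
        sex_p = c(control = ctrl_sex, hypertension = 0.6339)
      ),
      covariance_model = list(
        shared_latent = c(control = 0.45, hypertension = 0.15)
      ),
      biomarker_links = data.frame(
        biomarker = "uric_acid", region = 60, rho = -0.4,
        missing_rate = 0.47
      ),
      null_biomarkers = c("creatinine", "potassium", "apolipoprotein_b"),
      seed = seed
    ),
    t2dm_like = scenario_config(
      group_sizes = c(control = 497, t2dm = 56),
      effect = list(t2dm = mk_effect(down = 1:38)),
      covariate_model = list(
        age = list(control = ctrl_age, t2dm = c(59.68, 10.57)),
        sex_p = c(control = ctrl_sex, t2dm = 0.5714)
      ),
      covariance_model = list(
        shared_latent = c(control = 0.45, t2dm = 0.2)
      ),
      biomarker_links = data.frame(
        biomarker = "triglycerides", region = 7, rho = 0.4,
        missing_rate = 0.43
      ),
      null_biomarkers = "cholinesterase",
      seed = seed
    ),
    obesity_like = scenario_config(
      group_sizes = c(control = 497, obesity = 11),
      effect = list(obesity = mk_effect(up = c(19, 20, 33, 69))),
      covariate_model = list(
        age = list(control = ctrl_age, obesity = c(48.18, 12.38)),
        sex_p = c(control = ctrl_sex, obesity = 0.4545),
        bmi = list(control = c(23.5, 3), obesity = c(33.19, 3.05))
      ),
      covariance_model = list(
        shared_latent = c(control = 0.45, obesity = 0.2)
      ),
      biomarker_links = data.frame(
        biomarker = "ast", region = 19, rho = 0.3, missing_rate = 0.1
      ),
      null_biomarkers = c("urea", "alkaline_phosphatase"),
      seed = seed
    ),
    gout_like = scenario_config(
      group_sizes = c(control = 14, gout = 14),
      effect = list(gout = mk_effect(up = 70)),
      covariate_model = list(
        age = list(control = c(58.57, 14.93), gout = c(58.57, 14.93)),
        sex_p = c(control = 0.8571, gout = 0.8571)
      ),
      covariance_model = list(
        shared_latent = c(control = 0.15, gout = 0.6)
      ),
      biomarker_links = data.frame(
        biomarker = "fasting_glucose", region = 70, rho = -0.4,
        missing_rate = 0.1
      ),
      null_biomarkers = c("total_bilirubin", "alkaline_phosphatase"),
      seed = seed
    )
  )
}

#' Planted differential regions of a preset
#'
#' @param config a [scenario_config()].
#' @param group disease group name; defaults to the second group.
#' @return Data frame with columns `region` (index) and `direction`
#'   (+1/-1) for every region with a nonzero planted effect.
#' @export
planted_regions <- function(config, group = config$groups[2]) {
  e <- config$effect[[group]] %||% rep(0, config$n_regions)
  idx <- which(e != 0)
  data.frame(region = idx, direction = sign(e[idx]))
}
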