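#' Pipeline configuration for one disease-vs-control contrast
#'
#' Bundles every analysis choice in one (YAML-serializable) object.
#' Defaults follow the study conventions: alpha = 0.05, B = 5000
#' permutations, sparsity 0.35 (with `"auto_min_connected"` available to
#' use the sparsest fully-connected threshold of the two groups), pooled
#' age/sex correction.
#'
#' @param disease,control group labels of the contrast.
#' @param subjects_path,suvr_path optional input file paths (used when
#'   the corresponding objects are not passed to [run_contrast()]).
#' @param fit_scope correction scope, `"pooled"` or `"per_group"`.
#' @param alpha significance level for both screens and the edge test.
#' @param variance_rule t-test variance rule (see [two_group_test()]).
#' @param adjust multiple-testing mode for the region screen
#'   (`"none"`/`"BH"`).
#' @param sparsity numeric S in (0, 1] or `"auto_min_connected"`.
#' @param statistic_mode permutation statistic (`"raw_r"`/`"fisher_z"`).
#' @param rank_by edge ranking (`"signed"`/`"absolute"`).
#' @param n_perm number of permutations.
#' @param seed master seed; per-stage streams are derived from it.
#' @param covariates partial-correlation covariate columns.
#' @param out_dir output directory for [run_contrast()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(disease, control = "control",
                            subjects_path = NULL, suvr_path = NULL,
                            fit_scope = "pooled", alpha = 0.05,
                            variance_rule = "f_test", adjust = "none",
                            sparsity = 0.35, statistic_mode = "raw_r",
                            rank_by = "signed", n_perm = 5000, seed = 1,
                            covariates = c("age", "sex", "bmi"),
                            out_dir = "suvrnet_out") {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.numeric(sparsity) && (sparsity <= 0 || sparsity > 1)) {
    stop("sparsity must lie in (0, 1] or be 'auto_min_connected'")
  }
  structure(
    list(disease = disease, control = control,
         subjects_path = subjects_path, suvr_path = suvr_path,
         fit_scope = fit_scope, alpha = alpha,
         variance_rule = variance_rule, adjust = adjust,
         sparsity = sparsity, statistic_mode = statistic_mode,
         rank_by = rank_by, n_perm = as.integer(n_perm),
         seed = as.integer(seed), covariates = covariates,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run one disease-vs-control contrast end to end
#'
#' Executes, in order: age/sex correction (fitted pooled over the two
#' contrast groups by default), per-region group screening, biomarker
#' partial-correlation screening on the flagged regions (within the
#' disease group), group covariance networks with minimal fully-connected
#' sparsity, the edge-wise permutation test at the common sparsity, and
#' BrainNet Viewer exports, writing all result tables plus a JSON run
#' manifest (config echo, seed, versions, per-stage row counts) to
#' `config$out_dir`. Any stage error aborts with the stage name; partial
#' outputs are retained next to a `FAILED` marker file.
#'
#' Reruns with the same inputs and config produce byte-identical output
#' files (the manifest deliberately carries no timestamps).
#'
#' @param config a [pipeline_config()].
#' @param subjects subject data frame; if `NULL`, read from
#'   `config$subjects_path`.
#' @param suvr a [suvr_table()]; if `NULL`, read from `config$suvr_path`
#'   against [atlas_aal90()].
#' @return Invisibly, a list with `screen`, `biomarker_screen`,
#'   `network_disease`, `network_control`, `sparsity_used`, `perm`,
#'   `significant_edges`, `manifest`.
#' @export
run_contrast <- function(config, subjects = NULL, suvr = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  failed <- file.path(out, "FAILED")
  if (file.exists(failed)) file.remove(failed)
  stage <- "load_inputs"
  on_fail <- function(e) {
    writeLines(sprintf("stage: %s\n%s", stage, conditionMessage(e)), failed)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    if (is.null(subjects)) subjects <- read_subject_table(config$subjects_path)
    if (is.null(suvr)) suvr <- read_suvr_table(config$suvr_path, atlas_aal90())
    groups <- c(config$control, config$disease)
    missing_g <- setdiff(groups, unique(subjects$group))
    if (length(missing_g) > 0) {
      stop("group(s) not present in subject table: ",
           paste(missing_g, collapse = ", "))
    }
    meta <- align_subjects(suvr, subjects)
    keep <- meta$group %in% groups
    suvr <- subset_subjects(suvr, which(keep))
    meta <- meta[keep, , drop = FALSE]

    stage <- "correction"
    model <- fit_correction(suvr, meta, groups = groups,
                            fit_scope = config$fit_scope)
    corrected <- apply_correction(model, suvr, meta)
    tab_dis <- subset_subjects(corrected, which(meta$group == config$disease))
    tab_ctl <- subset_subjects(corrected, which(meta$group == config$control))

    stage <- "region_screen"
    screen <- screen_regions(tab_ctl, tab_dis, alpha = config$alpha,
                             variance_rule = config$variance_rule,
                             adjust = config$adjust)
    flagged <- screen$region[screen$significant]

    stage <- "biomarker_screen"
    bm <- biomarker_columns(meta)
    bm_screen <- if (length(flagged) > 0 && length(bm) > 0) {
      screen_biomarkers(corrected, meta, regions = flagged,
                        biomarkers = bm, covariates = config$covariates,
                        alpha = config$alpha, groups = config$disease)
    } else {
      screen_biomarkers(corrected, meta,
                        regions = integer(0), biomarkers = character(0))
    }

    stage <- "networks"
    net_dis <- build_group_network(tab_dis)
    net_ctl <- build_group_network(tab_ctl)
    s_min_dis <- min_connected_sparsity(net_dis, config$rank_by)
    s_min_ctl <- min_connected_sparsity(net_ctl, config$rank_by)
    S <- if (identical(config$sparsity, "auto_min_connected")) {
      max(s_min_dis$S, s_min_ctl$S)
    } else {
      config$sparsity
    }

    stage <- "permutation_test"
    cmp <- compare_at_sparsity(tab_dis, tab_ctl, S = S,
                               n_perm = config$n_perm,
                               seed = derive_seed(config$seed, "permtest"),
                               statistic_mode = config$statistic_mode,
                               rank_by = config$rank_by)
    sig <- significant_edges(cmp$perm, config$alpha)

    stage <- "export"
    utils::write.table(screen, file.path(out, "region_screen.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(bm_screen, file.path(out, "biomarker_screen.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_brainnet_edge(cmp$network_a$weights,
                        file.path(out, "network_disease.edge"))
    write_brainnet_edge(cmp$network_b$weights,
                        file.path(out, "network_control.edge"))
    write_brainnet_node(corrected$atlas,
                        colors = ifelse(screen$significant,
                                        screen$direction, 0),
                        sizes = abs(screen$t),
                        file.path(out, "region_screen.node"))
    export_perm_result(cmp$perm, out, prefix = "contrast",
                       alpha = config$alpha)
    write_correction_model(model, file.path(out, "correction_model.json"))

    stage <- "manifest"
    manifest <- list(
      config = unclass(config),
      versions = list(r = paste(R.version$major, R.version$minor, sep = "."),
                      suvrnet = as.character(utils::packageVersion("suvrnet"))),
      seed = config$seed,
      stage_seeds = list(permtest = derive_seed(config$seed, "permtest")),
      sparsity = list(used = S, min_connected_disease = s_min_dis$S,
                      min_connected_control = s_min_ctl$S),
      counts = list(
        n_disease = nrow(tab_dis$values),
        n_control = nrow(tab_ctl$values),
        n_regions = ncol(corrected$values),
        flagged_regions = length(flagged),
        biomarker_pairs = nrow(bm_screen),
        significant_biomarker_pairs = sum(bm_screen$significant),
        significant_edges = nrow(sig)
      )
    )
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(out, "manifest.json"))
    invisible(list(screen = screen, biomarker_screen = bm_screen,
                   network_disease = cmp$network_a,
                   network_control = cmp$network_b,
                   sparsity_used = S, perm = cmp$perm,
                   significant_edges = sig, manifest = manifest))
  }, error = on_fail)
}

#' Select an age/sex-matched control subset
#'
#' Greedy 1:1 nearest-neighbour matching: for each disease subject (in a
#' seeded random order), picks the unused control of the same sex with
#' the smallest age difference, within the age caliper. Reports the
#' post-match balance (two-sample t-test on age, chi-square test on sex).
#'
#' @param subjects subject data frame.
#' @param disease_group disease group label.
#' @param control_group control pool label (default `"control"`).
#' @param caliper maximal allowed age difference in years (default 5).
#' @param seed RNG seed for the matching order.
#' @return List with `control_ids` (matched subject ids), `balance`
#'   (data frame with age means and the two balance p-values), and
#'   `pairs` (disease id, control id, age difference).
#' @export
run_matched_control_selection <- function(subjects, disease_group,
                                          control_group = "control",
                                          caliper = 5, seed = 1) {
  dis <- subjects[subjects$group == disease_group, , drop = FALSE]
  pool <- subjects[subjects$group == control_group, , drop = FALSE]
  if (nrow(dis) == 0) stop("no subjects in disease group")
  if (nrow(pool) < nrow(dis)) {
    stop(sprintf("control pool (%d) smaller than disease group (%d)",
                 nrow(pool), nrow(dis)))
  }
  ord <- with_seed(seed, sample.int(nrow(dis)))
  used <- rep(FALSE, nrow(pool))
  pairs <- vector("list", nrow(dis))
  for (i in ord) {
    cand <- which(!used & pool$sex == dis$sex[i] &
                    abs(pool$age - dis$age[i]) <= caliper)
    if (length(cand) == 0) {
      done <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
      stop(sprintf(
        "no control within caliper %.1f y for subject %s (age %.1f, sex %d); %d/%d matched so far",
        caliper, dis$subject_id[i], dis$age[i], dis$sex[i],
        if (is.null(done)) 0L else nrow(done), nrow(dis)))
    }
    j <- cand[which.min(abs(pool$age[cand] - dis$age[i]))]
    used[j] <- TRUE
    pairs[[i]] <- data.frame(disease_id = dis$subject_id[i],
                             control_id = pool$subject_id[j],
                             age_diff = pool$age[j] - dis$age[i],
                             stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  matched <- pool[match(pairs$control_id, pool$subject_id), , drop = FALSE]
  age_p <- stats::t.test(matched$age, dis$age)$p.value
  sex_tab <- rbind(table(factor(matched$sex, levels = 0:1)),
                   table(factor(dis$sex, levels = 0:1)))
  sex_p <- if (any(colSums(sex_tab) == 0)) 1 else
    suppressWarnings(stats::chisq.test(sex_tab)$p.value)
  list(
    control_ids = matched$subject_id,
    balance = data.frame(
      mean_age_disease = mean(dis$age), mean_age_control = mean(matched$age),
      p_age = age_p, p_sex = sex_p
    ),
    pairs = pairs
  )
}
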