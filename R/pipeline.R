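# Pipeline orchestration and reporting: one reproducible run of the full
# strategy, with every numeric table written as CSV/JSON under a run
# directory and regenerable figures.
#
# Seeding: one global seed expands into per-stage seeds by fixed offsets
# (+1 subsamples, +2 prediction-error study, +3 relabeling-independent
# stages), so stages can be rerun independently with identical draws.

#' Write a generated cohort to delimited files
#'
#' Wraps [generate_cohort()]: writes the survival CSV, expression TSV,
#' endpoint relabeling CSV and a ground_truth.json under `dir`.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of paths.
#' @export
simulate_cohort_files <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_cohort(spec)
  paths <- list(survival = file.path(dir, "survival.csv"),
                expression = file.path(dir, "expression.tsv"),
                relabeling = file.path(dir, "relabeling.csv"),
                ground_truth = file.path(dir, "ground_truth.json"))
  write_dataset(gen$dataset, paths$survival, paths$expression)
  write.csv(gen$relabeling, paths$relabeling, row.names = FALSE)
  gt <- gen$ground_truth
  gt$label_counts <- lapply(gt$label_counts, function(tb) as.list(tb))
  gt$relabeling <- NULL  # stored separately as CSV
  jsonlite::write_json(gt, paths$ground_truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Run the full stability strategy
#'
#' Executes, in order: the univariate FDR screen; full-data boosting
#' signatures (original and, when a relabeling is given, updated endpoint)
#' with cross-validated step counts; the .632+ prediction-error study; the
#' subsampling selection matrices over the modeling-configuration grid; the
#' joint-selection odds-ratio table and outlier flagging; re-running all
#' configurations with the flagged outliers excluded; and the multi-feature
#' stability report. Results are written under `out_dir` and a summary list is
#' returned.
#'
#' @param dataset a `crs_dataset` (original endpoint).
#' @param out_dir run directory for the outputs.
#' @param relabeling optional endpoint-update table; when `NULL` the grid is
#'   restricted to the original endpoint (8 configurations).
#' @param B_stability subsamples per configuration.
#' @param B_bootstrap bootstrap sets for the prediction-error study (0 skips
#'   the stage).
#' @param n_steps_fixed fixed boosting step count for stability runs.
#' @param penalty boosting penalty (default 9 x cause events).
#' @param mandatory mandatory clinical covariates.
#' @param frequency_threshold inclusion-frequency threshold for the OR table
#'   and the per-feature regressions.
#' @param z_threshold robust z cut for outlier flagging.
#' @param alpha significance level (Bonferroni-corrected across features).
#' @param fdr_q level of the univariate FDR screen.
#' @param seed global seed.
#' @param cause modeled event type.
#' @return invisibly, the summary list (also written as summary.json).
#' @export
run_strategy <- function(dataset, out_dir, relabeling = NULL,
                         B_stability = 200L, B_bootstrap = 50L,
                         n_steps_fixed = 100L, penalty = NULL,
                         mandatory = c("age", "prior_cv"),
                         frequency_threshold = 0.1, z_threshold = 4,
                         alpha = 0.05, fdr_q = 0.05, seed = 1L, cause = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message(sprintf(...))
  summary <- list(seed = seed, n = nrow(dataset$subjects),
                  p = ncol(dataset$expression),
                  events = list(cause1 = n_events(dataset, 1L),
                                cause2 = n_events(dataset, 2L)))
  datasets <- list(original = dataset)
  if (!is.null(relabeling)) {
    datasets$updated <- apply_relabeling(dataset, relabeling)
  }
  endpoints <- names(datasets)

  # 1. univariate screen + FDR
  log_stage("stage 1: univariate Fine-Gray screen with BH-FDR at %.2f", fdr_q)
  screen_cfg <- modeling_config("subdistribution", "univariate_topk",
                                "original", "all_observations")
  pv <- univariate_screen(dataset, screen_cfg, adjust = mandatory, cause = cause)
  fdr_sel <- bh_fdr(pv, fdr_q)
  write.csv(data.frame(feature = names(pv), p = pv,
                       fdr_selected = seq_along(pv) %in% fdr_sel),
            file.path(out_dir, "screen.csv"), row.names = FALSE)
  summary$fdr_selected <- length(fdr_sel)

  # 2. full-data boosting signatures per endpoint
  log_stage("stage 2: full-data boosting signatures (cross-validated steps)")
  set.seed(seed)
  signatures <- lapply(endpoints, function(ep) {
    steps <- cv_select_steps(datasets[[ep]], "subdistribution",
                             penalty = penalty, mandatory = mandatory,
                             cause = cause)
    fit <- boost(datasets[[ep]], "subdistribution",
                 n_steps = as.integer(steps), penalty = penalty,
                 mandatory = mandatory, cause = cause)
    list(steps = as.integer(steps), features = selected_features(fit))
  })
  names(signatures) <- endpoints
  summary$signatures <- signatures

  # 3. prediction-error study
  if (B_bootstrap > 0L) {
    log_stage("stage 3: .632+ prediction-error study (B = %d)", B_bootstrap)
    pec <- tryCatch(
      run_prediction_error_study(dataset, B = B_bootstrap, seed = seed + 2L,
                                 mandatory = mandatory, penalty = penalty,
                                 cause = cause),
      error = function(e) e)
    if (inherits(pec, "error")) {
      summary$prediction_error <- list(failed = conditionMessage(pec))
    } else {
      write.csv(pec_as_table(pec), file.path(out_dir, "curves.csv"),
                row.names = FALSE)
      cmp <- compare_models(pec$models$clinical$oob_matrix,
                            pec$models$full$oob_matrix, pec$times)
      jsonlite::write_json(list(integrated_difference_median = cmp$median,
                                wilcoxon_p = cmp$p, degenerate = cmp$degenerate),
                           file.path(out_dir, "comparison.json"),
                           auto_unbox = TRUE, digits = NA)
      summary$prediction_error <- list(
        signature_steps = pec$signature_steps,
        clinical_vs_full_integrated_diff = cmp$median,
        clinical_vs_full_p = cmp$p)
    }
  }

  # 4. stability matrices, all-observations configurations
  log_stage("stage 4: selection matrices over %d subsamples", B_stability)
  matrices <- list()
  k_by_ep <- list()
  subs_by_ep <- lapply(seq_along(endpoints), function(i) {
    draw_subsamples(nrow(dataset$subjects), B_stability, 0.5, seed = seed + 1L)
  })
  names(subs_by_ep) <- endpoints
  for (ep in endpoints) {
    for (hz in c("subdistribution", "cause_specific")) {
      cfg <- modeling_config(hz, "multivariable_boosting", ep, "all_observations")
      m <- build_selection_matrix(datasets[[ep]], cfg, subs_by_ep[[ep]],
                                  n_steps = n_steps_fixed, penalty = penalty,
                                  mandatory = mandatory, cause = cause)
      matrices[[config_label(cfg)]] <- m
      if (is.null(k_by_ep[[ep]])) {
        k_by_ep[[ep]] <- max(1L, round(mean(rowSums(m$inclusion), na.rm = TRUE)))
      }
      cfg_u <- modeling_config(hz, "univariate_topk", ep, "all_observations")
      matrices[[config_label(cfg_u)]] <-
        build_selection_matrix(datasets[[ep]], cfg_u, subs_by_ep[[ep]],
                               n_steps = n_steps_fixed, penalty = penalty,
                               mandatory = mandatory, k = k_by_ep[[ep]],
                               cause = cause)
    }
  }

  # 5. joint-selection odds ratios and outlier flagging (boosting / original /
  # all-observations matrix)
  log_stage("stage 5: joint-selection odds ratios and outlier flagging")
  ref_label <- config_label(modeling_config("subdistribution",
                                            "multivariable_boosting",
                                            "original", "all_observations"))
  outliers <- list(indices = integer(0), ids = character(0))
  ortab <- tryCatch(
    joint_selection_odds_ratios(matrices[[ref_label]], frequency_threshold),
    error = function(e) e)
  if (!inherits(ortab, "error")) {
    or_df <- as.data.frame(ortab$or)
    or_df <- cbind(feature = rownames(ortab$or), or_df)
    write.csv(or_df, file.path(out_dir, "odds_ratios.csv"), row.names = FALSE)
    # scan every feature with at least moderate inclusion frequency for
    # extreme observations; mutually facilitating pairs are reported as the
    # most suspicious candidates for visual review
    implicated <- rownames(ortab$or)
    fl <- flag_outlier_observations(dataset, implicated, z_threshold)
    outliers <- list(indices = fl$indices, ids = as.character(fl$ids),
                     implicated_features = implicated,
                     facilitating = suggest_implicated_features(ortab))
  } else {
    log_stage("  odds-ratio stage skipped: %s", conditionMessage(ortab))
  }
  jsonlite::write_json(outliers, file.path(out_dir, "outliers.json"),
                       auto_unbox = TRUE, digits = NA)
  summary$outliers <- outliers

  # 6. re-run all configurations with outliers excluded
  if (length(outliers$indices)) {
    log_stage("stage 6: re-running configurations without %d flagged outlier(s)",
              length(outliers$indices))
    for (ep in endpoints) {
      dat_ex <- exclude_observations(datasets[[ep]], outliers$indices)
      subs_ex <- draw_subsamples(nrow(dat_ex$subjects), B_stability, 0.5,
                                 seed = seed + 1L)
      for (hz in c("subdistribution", "cause_specific")) {
        for (selm in c("multivariable_boosting", "univariate_topk")) {
          cfg <- modeling_config(hz, selm, ep, "outliers_excluded")
          matrices[[config_label(cfg)]] <-
            build_selection_matrix(dat_ex, cfg, subs_ex,
                                   n_steps = n_steps_fixed, penalty = penalty,
                                   mandatory = mandatory,
                                   k = if (selm == "univariate_topk") k_by_ep[[ep]] else NULL,
                                   cause = cause)
        }
      }
    }
  }

  # 7. multi-feature stability report
  log_stage("stage 7: modeling-choice regressions over %d configurations",
            length(matrices))
  report <- multi_feature_stability(matrices, frequency_threshold, alpha)
  write.csv(report$frequencies, file.path(out_dir, "frequencies.csv"),
            row.names = FALSE)
  if (!is.null(report$regressions)) {
    write.csv(report$regressions, file.path(out_dir, "stability_regression.csv"),
              row.names = FALSE)
  }
  summary$qualifying_features <- report$qualifying
  summary$frequency_extrema <- list(
    max = max(report$frequencies$max),
    feature_max = report$frequencies$feature[which.max(report$frequencies$max)])
  summary$significant_terms <- report$term_counts

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' Regenerate report tables and figures from a stored run directory
#'
#' Re-reads the CSV/JSON outputs of [run_strategy()] and rebuilds the
#' frequency table (with min/max extrema), the odds-ratio heatmap and the
#' prediction-error figure without recomputation. Idempotent; errors if the
#' run directory lacks the stored results.
#'
#' @param run_dir a directory written by [run_strategy()].
#' @param write_figures write PNG figures next to the tables.
#' @return list with the re-read `frequencies`, `odds_ratios` (or `NULL`),
#'   `curves` (or `NULL`) and `summary`.
#' @export
regenerate_report <- function(run_dir, write_figures = FALSE) {
  freq_path <- file.path(run_dir, "frequencies.csv")
  if (!file.exists(freq_path)) {
    stop("no stored results in ", run_dir, ": run_strategy() must be run first")
  }
  out <- list(frequencies = read.csv(freq_path, check.names = FALSE),
              summary = jsonlite::read_json(file.path(run_dir, "summary.json")))
  orp <- file.path(run_dir, "odds_ratios.csv")
  out$odds_ratios <- if (file.exists(orp)) read.csv(orp, check.names = FALSE) else NULL
  cvp <- file.path(run_dir, "curves.csv")
  out$curves <- if (file.exists(cvp)) read.csv(cvp) else NULL
  if (write_figures) {
    if (!is.null(out$odds_ratios)) {
      m <- as.matrix(out$odds_ratios[, -1])
      rownames(m) <- out$odds_ratios$feature
      ortab <- structure(list(or = m, frequencies = NULL, min_frequency = NA),
                         class = "crs_ortab")
      ggplot2::ggsave(file.path(run_dir, "odds_ratios.png"),
                      plot_joint_selection(ortab), width = 7, height = 6)
    }
    if (!is.null(out$curves)) {
      df <- out$curves
      gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$e632plus,
                                             colour = .data$model)) +
        ggplot2::geom_step() + ggplot2::theme_minimal() +
        ggplot2::labs(x = "time (months)", y = ".632+ Brier score")
      ggplot2::ggsave(file.path(run_dir, "prediction_error.png"), gg,
                      width = 7, height = 5)
    }
  }
  out
}

# long-format table of a prediction-error study
pec_as_table <- function(pec) {
  do.call(rbind, lapply(names(pec$models), function(m) {
    md <- pec$models[[m]]
    data.frame(time = pec$times, model = m, apparent = md$apparent,
               oob = md$oob_mean, noinf = md$noinf, e632plus = md$e632plus)
  }))
}

#' Plot .632+ prediction-error curves
#'
#' @param pec a `crs_pec` from [run_prediction_error_study()].
#' @return a ggplot object (Brier score over time, one line per model).
#' @export
plot_prediction_error <- function(pec) {
  df <- pec_as_table(pec)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$e632plus,
                                   colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (months)", y = ".632+ Brier score",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of joint-selection odds ratios
#'
#' @param ortab a `crs_ortab`.
#' @return a ggplot tile plot; blue = alternative selection (OR < 1), red =
#'   joint selection (OR > 1).
#' @export
plot_joint_selection <- function(ortab) {
  m <- ortab$or
  df <- expand.grid(a = rownames(m), b = colnames(m), stringsAsFactors = FALSE)
  df$log_or <- log(as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$log_or)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log OR") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Scatter plot of two implicated features with outlier flags
#'
#' @param dataset a `crs_dataset`.
#' @param feature_x,feature_y feature names (standardized for display).
#' @param flagged subject positions to mark.
#' @return a ggplot object.
#' @export
plot_outlier_scatter <- function(dataset, feature_x, feature_y,
                                 flagged = integer(0)) {
  df <- data.frame(x = scale(dataset$expression[, feature_x])[, 1L],
                   y = scale(dataset$expression[, feature_y])[, 1L],
                   status = endpoint_label(dataset$subjects),
                   flagged = seq_len(nrow(dataset$subjects)) %in% flagged)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$status,
                                   shape = .data$flagged)) +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::labs(x = feature_x, y = feature_y) +
    ggplot2::theme_minimal()
}
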