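#' Draw subsamples without replacement
#'
#' @param n number of subjects.
#' @param B number of subsamples.
#' @param fraction subsample fraction; each set has `floor(fraction * n)`
#'   distinct subjects (half-size subsampling by default).
#' @param seed RNG seed.
#' @return list of `B` integer index sets.
#' @export
draw_subsamples <- function(n, B, fraction = 0.5, seed = NULL) {
  stopifnot(fraction > 0, fraction < 1, B >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- floor(fraction * n)
  lapply(seq_len(B), function(b) sort(sample.int(n, m)))
}

#' Selection matrix over subsamples for one modeling configuration
#'
#' Repeats signature selection in every subsample. For
#' `multivariable_boosting`, row b records [selected_features()] of a boosting
#' run with a fixed number of steps (fixed model complexity, as in stability
#' selection). For `univariate_topk`, row b marks the `k` features with the
#' smallest univariate Wald p-values on that subsample; when `k` is `NULL` it
#' is set to the rounded mean signature size of a companion boosting run on
#' the same subsamples, mimicking the multivariable approach's sparsity.
#'
#' Subsamples with fewer than 2 events of the modeled cause are recorded as
#' missing rows (with a warning), not dropped silently; inclusion frequencies
#' use valid-row denominators.
#'
#' @param dataset a `crs_dataset` (endpoint version and outlier handling
#'   already applied; must match `config`).
#' @param config a [modeling_config()].
#' @param subsamples list of index sets from [draw_subsamples()].
#' @param n_steps fixed boosting step count (default 100).
#' @param penalty boosting penalty; default 9 x events of the modeled cause
#'   per subsample.
#' @param mandatory mandatory covariate names.
#' @param k top-k size for the univariate method (see above).
#' @param cause modeled event type.
#' @return an object of class `crs_selmat`: the B x p logical `inclusion`
#'   matrix (NA rows for skipped subsamples), the config, the subsamples, and
#'   `k` where applicable.
#' @export
build_selection_matrix <- function(dataset, config, subsamples, n_steps = 100L,
                                   penalty = NULL, mandatory = c("age", "prior_cv"),
                                   k = NULL, cause = 1L) {
  if (config$endpoint != dataset$endpoint_version) {
    stop(sprintf("config endpoint '%s' does not match dataset endpoint '%s'",
                 config$endpoint, dataset$endpoint_version))
  }
  feats <- colnames(dataset$expression)
  p <- length(feats)
  B <- length(subsamples)
  model_type <- config$hazard_type
  inclusion <- matrix(NA, B, p, dimnames = list(NULL, feats))

  if (config$selection_method == "univariate_topk" && is.null(k)) {
    companion <- build_selection_matrix(dataset,
      modeling_config(config$hazard_type, "multivariable_boosting",
                      config$endpoint, config$outlier_handling),
      subsamples, n_steps = n_steps, penalty = penalty,
      mandatory = mandatory, cause = cause)
    sizes <- rowSums(companion$inclusion)
    k <- max(1L, round(mean(sizes, na.rm = TRUE)))
  }

  n_skipped <- 0L
  screen_config <- config
  for (b in seq_len(B)) {
    sub <- subset_dataset(dataset, subsamples[[b]])
    if (n_events(sub, cause) < 2L) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (config$selection_method == "multivariable_boosting") {
      fit <- boost(sub, model_type, n_steps = n_steps, penalty = penalty,
                   mandatory = mandatory, cause = cause)
      inclusion[b, ] <- fit$coefficients != 0
    } else {
      pv <- univariate_screen(sub, screen_config, adjust = mandatory, cause = cause)
      sel <- order(pv)[seq_len(min(k, p))]
      row <- rep(FALSE, p)
      row[sel] <- TRUE
      inclusion[b, ] <- row
    }
  }
  if (n_skipped > 0L) {
    warning(sprintf("%d subsample(s) had < 2 events of cause %d and were recorded as missing",
                    n_skipped, cause))
  }
  structure(list(config = config, subsample_indices = subsamples,
                 inclusion = inclusion, k_univariate = k,
                 n_valid = B - n_skipped, cause = cause, n_steps = n_steps),
            class = "crs_selmat")
}

#' @export
print.crs_selmat <- function(x, ...) {
  cat(sprintf("selection matrix [%s]: %d/%d valid subsamples, %d features, mean signature size %.1f\n",
              config_label(x$config), x$n_valid, nrow(x$inclusion),
              ncol(x$inclusion), mean(rowSums(x$inclusion), na.rm = TRUE)))
  invisible(x)
}

#' Resampling inclusion frequencies
#'
#' Proportion of valid subsamples in which each feature was selected into the
#' signature — the stability measure.
#'
#' @param matrix a `crs_selmat`.
#' @return named per-feature frequency vector in \[0, 1\].
#' @export
inclusion_frequencies <- function(matrix) {
  valid <- !is.na(matrix$inclusion[, 1L])
  if (!any(valid)) stop("no valid subsample rows")
  colMeans(matrix$inclusion[valid, , drop = FALSE])
}

#' Pairwise joint-selection odds ratios
#'
#' For every pair of features passing the inclusion-frequency threshold, the
#' odds ratio of the 2x2 cross-table of their selection indicators over
#' subsamples: OR = (n11 n00) / (n10 n01), with 0.5 added to every cell when
#' any cell is zero. OR >> 1 indicates joint selection, OR << 1 alternative
#' (mutually exclusive) selection; outlier-driven artifacts show up as small
#' clusters of mutually facilitating features that suppress everything else.
#'
#' @param matrix a `crs_selmat`.
#' @param min_frequency inclusion-frequency threshold (default 0.1).
#' @return object of class `crs_ortab`: the symmetric OR matrix (diagonal NA)
#'   and the frequencies of the retained features.
#' @export
joint_selection_odds_ratios <- function(matrix, min_frequency = 0.1) {
  freq <- inclusion_frequencies(matrix)
  keep <- names(freq)[freq >= min_frequency]
  if (length(keep) < 2L) {
    stop(sprintf("fewer than 2 features reach inclusion frequency %.2f", min_frequency))
  }
  valid <- !is.na(matrix$inclusion[, 1L])
  M <- matrix$inclusion[valid, keep, drop = FALSE]
  m <- length(keep)
  or <- base::matrix(NA_real_, m, m, dimnames = list(keep, keep))
  for (j in seq_len(m - 1L)) {
    for (l in (j + 1L):m) {
      n11 <- sum(M[, j] & M[, l]); n10 <- sum(M[, j] & !M[, l])
      n01 <- sum(!M[, j] & M[, l]); n00 <- sum(!M[, j] & !M[, l])
      if (min(n11, n10, n01, n00) == 0L) {
        n11 <- n11 + 0.5; n10 <- n10 + 0.5; n01 <- n01 + 0.5; n00 <- n00 + 0.5
      }
      or[j, l] <- or[l, j] <- (n11 * n00) / (n10 * n01)
    }
  }
  structure(list(or = or, frequencies = freq[keep],
                 min_frequency = min_frequency),
            class = "crs_ortab")
}

#' @export
print.crs_ortab <- function(x, ...) {
  cat(sprintf("joint-selection odds ratios: %d features (frequency >= %.2f)\n",
              nrow(x$or), x$min_frequency))
  print(round(x$or, 2))
  invisible(x)
}

#' Features implicated by the joint-selection structure
#'
#' Algorithmic surrogate for the visual inspection of the OR heatmap: returns
#' the features belonging to at least one mutually facilitating pair
#' (OR >= `or_high`). These are the candidates on which to look for extreme
#' observations with [flag_outlier_observations()].
#'
#' @param ortab a `crs_ortab`.
#' @param or_high facilitation threshold (default 5).
#' @return character vector of feature names (possibly empty).
#' @export
suggest_implicated_features <- function(ortab, or_high = 5) {
  hi <- which(ortab$or >= or_high, arr.ind = TRUE)
  unique(rownames(ortab$or)[unique(as.vector(hi))])
}

#' Flag potential outlier observations
#'
#' Robust z-scores (x - median) / (1.4826 MAD) per implicated feature;
#' subjects exceeding `z_threshold` in absolute value on any implicated
#' feature are flagged. Features with zero MAD are skipped with a warning.
#'
#' @param dataset a `crs_dataset`.
#' @param implicated_features feature names to inspect (typically members of a
#'   mutually facilitating OR cluster).
#' @param z_threshold robust z-score cut (default 4).
#' @return list with `indices` (flagged subject positions), `ids`, and the
#'   per-subject `scores` matrix for scatter-plot review.
#' @export
flag_outlier_observations <- function(dataset, implicated_features, z_threshold = 4) {
  stopifnot(length(implicated_features) > 0)
  X <- dataset$expression[, implicated_features, drop = FALSE]
  scores <- base::matrix(NA_real_, nrow(X), ncol(X),
                         dimnames = list(rownames(X), colnames(X)))
  for (j in seq_len(ncol(X))) {
    s <- mad(X[, j])  # 1.4826 * median absolute deviation
    if (s == 0) {
      warning("zero MAD for feature ", colnames(X)[j], "; skipped")
      next
    }
    scores[, j] <- (X[, j] - median(X[, j])) / s
  }
  flagged <- which(apply(abs(scores) > z_threshold, 1L, any, na.rm = TRUE))
  list(indices = unname(flagged),
       ids = dataset$subjects$id[flagged],
       scores = scores, z_threshold = z_threshold)
}

# Table-3 style display names for the regression terms
.streg_terms <- c("(Intercept)" = "(Intercept)",
                  "sh" = "sh",
                  "outlier_excluded" = "outlier excluded",
                  "original_endpoint" = "original endpoint",
                  "univariate" = "univariate",
                  "sh:outlier_excluded" = "sh x outlier excluded",
                  "sh:original_endpoint" = "sh x original endpoint",
                  "sh:univariate" = "sh x univariate",
                  "outlier_excluded:original_endpoint" = "outlier excluded x original endpoint",
                  "original_endpoint:univariate" = "original endpoint x univariate")

#' Binomial regression of signature inclusion on modeling choices
#'
#' For one feature: logit-link binomial regression of its per-configuration
#' inclusion counts on the four binary modeling choices (Fine-Gray vs
#' cause-specific, outlier exclusion, original vs updated endpoint, univariate
#' vs multivariable selection) with the five two-way interactions involving
#' the hazard model and the endpoint.
#'
#' @param counts data frame with one row per configuration and columns
#'   `hazard_type`, `selection_method`, `endpoint`, `outlier_handling`,
#'   `selected` (number of subsamples selecting the feature) and `total`
#'   (valid subsamples).
#' @return object of class `crs_streg`: data frame of term estimates, standard
#'   errors and Wald p-values, plus a `degenerate` flag when the fit is
#'   separated or non-converged (coefficients then reported as `NA`, not
#'   fabricated).
#' @export
stability_regression <- function(counts) {
  stopifnot(nrow(counts) >= 2, all(c("selected", "total") %in% names(counts)))
  df <- data.frame(
    sh = as.integer(counts$hazard_type == "subdistribution"),
    outlier_excluded = as.integer(counts$outlier_handling == "outliers_excluded"),
    original_endpoint = as.integer(counts$endpoint == "original"),
    univariate = as.integer(counts$selection_method == "univariate_topk"),
    selected = counts$selected, total = counts$total)
  # only factors that vary across the supplied configurations are estimable;
  # restricted grids (e.g. no endpoint update available) drop their terms
  varying <- names(which(vapply(df[c("sh", "outlier_excluded",
                                     "original_endpoint", "univariate")],
                                function(v) length(unique(v)) > 1, logical(1))))
  if (length(varying) == 0L) stop("configurations must differ in at least one modeling choice")
  interactions <- c("sh:outlier_excluded", "sh:original_endpoint",
                    "sh:univariate", "outlier_excluded:original_endpoint",
                    "original_endpoint:univariate")
  keep_int <- interactions[vapply(strsplit(interactions, ":"), function(pr)
    all(pr %in% varying), logical(1))]
  form <- as.formula(paste("cbind(selected, total - selected) ~",
                           paste(c(varying, keep_int), collapse = " + ")))
  fit <- suppressWarnings(glm(form, family = binomial(), data = df))
  sm <- summary(fit)$coefficients
  est <- coef(fit)
  degenerate <- !fit$converged || any(is.na(est)) ||
    any(abs(est) > 10, na.rm = TRUE)
  terms_present <- intersect(names(.streg_terms), names(est))
  tab <- data.frame(
    term = unname(.streg_terms[terms_present]),
    estimate = if (degenerate) NA_real_ else unname(est[terms_present]),
    se = if (degenerate) NA_real_ else unname(sm[terms_present, "Std. Error"]),
    p = if (degenerate) NA_real_ else unname(sm[terms_present, "Pr(>|z|)"]),
    stringsAsFactors = FALSE)
  structure(list(table = tab, degenerate = degenerate, fit = fit),
            class = "crs_streg")
}

#' @export
print.crs_streg <- function(x, ...) {
  if (x$degenerate) cat("degenerate fit (separation or non-convergence)\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' Multi-feature stability report
#'
#' Assembles the full stability analysis over a grid of modeling
#' configurations: the per-configuration inclusion-frequency table with
#' per-feature min/max columns, and, for every feature reaching
#' `frequency_threshold` in at least one configuration, the modeling-choice
#' binomial regression, with Bonferroni correction across features per term
#' and counts of significantly positive/negative effects per term.
#'
#' @param matrices list of `crs_selmat` objects covering the config grid.
#' @param frequency_threshold per-feature qualification threshold (default 0.1).
#' @param alpha significance level before Bonferroni correction (default 0.05).
#' @return object of class `crs_stabreport` with elements `frequencies`
#'   (features x configs data frame with `min`/`max`), `regressions` (long
#'   data frame: feature x term with estimate, p, Bonferroni flag, sign),
#'   `term_counts` (per-term counts of significant positive/negative effects),
#'   `qualifying` and `degenerate` feature names.
#' @export
multi_feature_stability <- function(matrices, frequency_threshold = 0.1,
                                    alpha = 0.05) {
  stopifnot(length(matrices) >= 2)
  labels <- vapply(matrices, function(m) config_label(m$config), character(1))
  freq <- do.call(cbind, lapply(matrices, inclusion_frequencies))
  colnames(freq) <- labels
  freq_df <- data.frame(feature = rownames(freq), freq,
                        min = apply(freq, 1L, min), max = apply(freq, 1L, max),
                        check.names = FALSE, row.names = NULL)

  qualifying <- rownames(freq)[apply(freq, 1L, max) >= frequency_threshold]
  reg_rows <- list()
  degenerate <- character(0)
  for (f in qualifying) {
    counts <- do.call(rbind, lapply(matrices, function(m) {
      valid <- !is.na(m$inclusion[, 1L])
      data.frame(hazard_type = m$config$hazard_type,
                 selection_method = m$config$selection_method,
                 endpoint = m$config$endpoint,
                 outlier_handling = m$config$outlier_handling,
                 selected = sum(m$inclusion[valid, f]),
                 total = sum(valid), stringsAsFactors = FALSE)
    }))
    sr <- stability_regression(counts)
    if (sr$degenerate) degenerate <- c(degenerate, f)
    tab <- sr$table
    tab$feature <- f
    reg_rows[[f]] <- tab
  }
  regs <- do.call(rbind, reg_rows)
  rownames(regs) <- NULL
  if (!is.null(regs)) {
    n_feat <- length(qualifying)
    regs$p_bonferroni <- pmin(1, regs$p * n_feat)
    regs$significant <- !is.na(regs$p_bonferroni) & regs$p_bonferroni <= alpha
    regs$sign <- sign(regs$estimate)
    terms <- setdiff(unique(regs$term), "(Intercept)")
    term_counts <- do.call(rbind, lapply(terms, function(tm) {
      sub <- regs[regs$term == tm & regs$significant, , drop = FALSE]
      data.frame(term = tm, n_positive = sum(sub$sign > 0, na.rm = TRUE),
                 n_negative = sum(sub$sign < 0, na.rm = TRUE))
    }))
  } else {
    term_counts <- data.frame(term = character(0), n_positive = integer(0),
                              n_negative = integer(0))
  }
  structure(list(frequencies = freq_df, regressions = regs,
                 term_counts = term_counts, qualifying = qualifying,
                 degenerate = degenerate, alpha = alpha,
                 frequency_threshold = frequency_threshold),
            class = "crs_stabreport")
}

#' @export
print.crs_stabreport <- function(x, ...) {
  cat(sprintf("stability report: %d qualifying features (frequency >= %.2f), %d degenerate fits\n",
              length(x$qualifying), x$frequency_threshold, length(x$degenerate)))
  if (nrow(x$term_counts)) {
    cat("Bonferroni-significant effects per term:\n")
    print(x$term_counts)
  }
  invisible(x)
}
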