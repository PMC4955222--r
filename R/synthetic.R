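#' Specification for a synthetic competing-risks cohort
#'
#' Defines a cohort with the statistical structure the stability strategy
#' assumes: two competing causes of death driven by latent cause-specific
#' exponential hazards, a high-dimensional block-correlated expression matrix
#' with a few truly prognostic features, clinical covariates (age, prior
#' cardiovascular event) entering both hazards, random plus administrative
#' censoring, a handful of extreme-valued outlier subjects that induce
#' spurious joint-selection structure, and an endpoint update reclassifying a
#' small fraction of subjects between event categories.
#'
#' Defaults are the desk-scale profile: n = 250, p = 500, 5 informative
#' features per cause (each placed at the head of its own correlation block),
#' log hazard ratio 0.5 per standardized feature, blocks of 10 at within-block
#' correlation 0.5. [study_spec()] sizes the cohort to the hemodialysis study
#' conditions instead.
#'
#' @param n subjects.
#' @param p expression features.
#' @param n_informative_cause1,n_informative_cause2 truly prognostic features
#'   per cause.
#' @param effect_size log hazard ratio per informative feature (per SD).
#' @param block_size,within_block_correlation expression correlation structure.
#' @param baseline_rate_cause1,baseline_rate_cause2 exponential cause-specific
#'   baseline hazards per month.
#' @param admin_censor_time administrative censoring (months).
#' @param random_censor_rate exponential dropout rate per month.
#' @param n_outliers subjects given extreme expression values.
#' @param outlier_magnitude shift in feature standard deviations.
#' @param relabel_fractions named vector of endpoint-update probabilities
#'   (`none_to_cause1`, `none_to_cause2`, `cause1_to_cause2`,
#'   `cause2_to_cause1`).
#' @param age_effect log hazard ratio per SD of age (both causes).
#' @param prior_cv_effect_cause1,prior_cv_effect_cause2 log hazard ratios of a
#'   prior cardiovascular event.
#' @param prior_cv_prevalence Bernoulli rate of the prior-event indicator.
#' @param seed integer; fully determines the generated cohort.
#' @return an object of class `crs_cohort_spec`.
#' @export
cohort_spec <- function(n = 250L, p = 500L,
                        n_informative_cause1 = 5L, n_informative_cause2 = 5L,
                        effect_size = 0.5,
                        block_size = 10L, within_block_correlation = 0.5,
                        baseline_rate_cause1 = 0.007,
                        baseline_rate_cause2 = 0.016,
                        admin_censor_time = 24,
                        random_censor_rate = 0.01,
                        n_outliers = 3L, outlier_magnitude = 6,
                        relabel_fractions = c(none_to_cause1 = 0.015,
                                              none_to_cause2 = 0.05,
                                              cause1_to_cause2 = 0.2,
                                              cause2_to_cause1 = 0.03),
                        age_effect = 0.3,
                        prior_cv_effect_cause1 = 0.5,
                        prior_cv_effect_cause2 = 0.2,
                        prior_cv_prevalence = 0.3,
                        seed = 1L) {
  spec <- list(n = as.integer(n), p = as.integer(p),
               n_informative_cause1 = as.integer(n_informative_cause1),
               n_informative_cause2 = as.integer(n_informative_cause2),
               effect_size = effect_size, block_size = as.integer(block_size),
               within_block_correlation = within_block_correlation,
               baseline_rate_cause1 = baseline_rate_cause1,
               baseline_rate_cause2 = baseline_rate_cause2,
               admin_censor_time = admin_censor_time,
               random_censor_rate = random_censor_rate,
               n_outliers = as.integer(n_outliers),
               outlier_magnitude = outlier_magnitude,
               relabel_fractions = relabel_fractions,
               age_effect = age_effect,
               prior_cv_effect_cause1 = prior_cv_effect_cause1,
               prior_cv_effect_cause2 = prior_cv_effect_cause2,
               prior_cv_prevalence = prior_cv_prevalence,
               seed = as.integer(seed))
  with(spec, {
    if (n_informative_cause1 + n_informative_cause2 > p)
      stop("more informative features than features")
    if (within_block_correlation < 0 || within_block_correlation >= 1)
      stop("within_block_correlation must be in [0, 1)")
    if (baseline_rate_cause1 <= 0 || baseline_rate_cause2 <= 0 ||
        random_censor_rate < 0)
      stop("hazard rates must be positive")
    if ((n_informative_cause1 + n_informative_cause2) * block_size > p)
      stop("not enough blocks to host the informative features (need p >= (n1+n2)*block_size)")
    if (n_outliers > 0 && block_size < 3)
      stop("outlier injection needs block_size >= 3 (two null features per informative block)")
  })
  structure(spec, class = "crs_cohort_spec")
}

#' Study-scale cohort specification
#'
#' Sizes the generator to the hemodialysis cohort conditions: 321 subjects
#' followed over 24 months with heavy censoring and cause-specific baseline
#' rates calibrated (by Monte-Carlo, at the default effect structure) so that
#' the expected event counts are about 30 deaths with and 71 deaths without a
#' prior cardiovascular event. The feature dimension defaults to the study's
#' ~26k but is usually reduced for desk work (the event-time distribution does
#' not depend on the number of null features).
#'
#' @param p number of features.
#' @param seed RNG seed.
#' @param ... overrides passed on to [cohort_spec()].
#' @return a `crs_cohort_spec`.
#' @export
study_spec <- function(p = 26323L, seed = 1L,
                       baseline_rate_cause1 = 0.0026,
                       baseline_rate_cause2 = 0.0079,
                       ...) {
  cohort_spec(n = 321L, p = p,
              baseline_rate_cause1 = baseline_rate_cause1,
              baseline_rate_cause2 = baseline_rate_cause2,
              admin_censor_time = 24,
              random_censor_rate = 0.01,
              seed = seed, ...)
}

# block indices and informative feature placement for a spec
informative_layout <- function(spec) {
  n_blocks <- ceiling(spec$p / spec$block_size)
  block_of <- rep(seq_len(n_blocks), each = spec$block_size)[seq_len(spec$p)]
  lead <- function(b) (b - 1L) * spec$block_size + 1L  # first feature of block b
  inf1 <- vapply(seq_len(spec$n_informative_cause1), lead, integer(1))
  inf2 <- vapply(spec$n_informative_cause1 +
                   seq_len(spec$n_informative_cause2), lead, integer(1))
  list(block_of = block_of, informative_cause1 = inf1, informative_cause2 = inf2)
}

#' Generate a synthetic cohort with ground truth
#'
#' Expression is drawn as correlated Gaussian blocks
#' (\eqn{x = \sqrt{\rho}\, z_{block} + \sqrt{1-\rho}\, \epsilon}); latent event
#' times per cause come from exponential proportional-hazards models with
#' linear predictors over the informative features and the clinical
#' covariates; the observed time is the minimum of the two cause times, random
#' censoring, and administrative censoring, with the event type given by the
#' winning cause. Outlier subjects (chosen among cause-1 events where
#' possible) receive extreme values on two null features within the first
#' cause-1-informative feature's correlation block, so that their spurious
#' signal competes with a true feature. An endpoint relabeling is drawn from
#' `relabel_fractions` and returned (not applied).
#'
#' @param spec a [cohort_spec()].
#' @return list with `dataset` (original endpoint, outliers injected),
#'   `ground_truth` (informative indices, true coefficients, outlier subjects
#'   and features, relabeling table, label bookkeeping), and `relabeling` (the
#'   endpoint-update table for [apply_relabeling()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "crs_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n; p <- spec$p
  lay <- informative_layout(spec)
  rho <- spec$within_block_correlation
  n_blocks <- max(lay$block_of)
  Zb <- base::matrix(rnorm(n * n_blocks), n, n_blocks)
  X <- sqrt(rho) * Zb[, lay$block_of, drop = FALSE] +
    sqrt(1 - rho) * base::matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("feat%05d", seq_len(p))

  age <- rnorm(n, 66.3, 17.3)
  prior_cv <- rbinom(n, 1L, spec$prior_cv_prevalence)
  age_std <- (age - 66.3) / 17.3

  beta1 <- numeric(p); beta1[lay$informative_cause1] <- spec$effect_size
  beta2 <- numeric(p); beta2[lay$informative_cause2] <- spec$effect_size
  lp1 <- as.numeric(X %*% beta1) + spec$age_effect * age_std +
    spec$prior_cv_effect_cause1 * prior_cv
  lp2 <- as.numeric(X %*% beta2) + spec$age_effect * age_std +
    spec$prior_cv_effect_cause2 * prior_cv

  t1 <- rexp(n, spec$baseline_rate_cause1 * exp(lp1))
  t2 <- rexp(n, spec$baseline_rate_cause2 * exp(lp2))
  cens <- if (spec$random_censor_rate > 0) rexp(n, spec$random_censor_rate)
          else rep(Inf, n)
  obs <- pmin(t1, t2, cens, spec$admin_censor_time)
  cause <- ifelse(obs == t1, 1L, ifelse(obs == t2, 2L, NA))
  status <- as.integer(!is.na(cause))

  # quick feasibility diagnostic (expected events under unit multipliers)
  lam <- spec$baseline_rate_cause1 + spec$baseline_rate_cause2 +
    spec$random_censor_rate
  e1 <- n * spec$baseline_rate_cause1 / lam * (1 - exp(-lam * spec$admin_censor_time))
  if (e1 < 1) {
    stop(sprintf("infeasible spec: expected cause-1 events %.2f < 1 (raise rates or follow-up)", e1))
  }

  subjects <- data.frame(id = sprintf("S%04d", seq_len(n)), time = obs,
                         status = status, cause = cause,
                         age = age, prior_cv = prior_cv,
                         stringsAsFactors = FALSE)
  dataset <- competing_risks_dataset(subjects, X, "original")

  # outliers: extreme values on two null features sharing the first
  # cause-1-informative feature's correlation block (a shared aberrant
  # measurement). Subjects are taken among the cause-1 events whose
  # idiosyncratic part of that informative feature is smallest: their events
  # are not in line with the true feature's trend, so the aberrant values
  # manufacture a spurious competitor whose removal lets the true feature
  # recover. Selecting on the idiosyncratic component (rather than the
  # observed value) leaves their values on the target features unbiased.
  outlier_features <- colnames(X)[lay$informative_cause1[1L] + 1:2]
  outlier_subjects <- integer(0)
  if (spec$n_outliers > 0L) {
    pool <- which(status == 1L & cause == 1L)
    if (length(pool) < spec$n_outliers) pool <- seq_len(n)
    f1 <- lay$informative_cause1[1L]
    resid <- X[pool, f1] - sqrt(rho) * Zb[pool, lay$block_of[f1]]
    picked <- pool[order(resid)][seq_len(spec$n_outliers)]
    inj <- inject_outliers(dataset, spec$n_outliers, spec$outlier_magnitude,
                           outlier_features, from = picked)
    dataset <- inj$dataset
    outlier_subjects <- sort(picked)
  }

  relabeling <- draw_relabeling(dataset, spec$relabel_fractions)

  ground_truth <- list(
    informative_cause1 = lay$informative_cause1,
    informative_cause2 = lay$informative_cause2,
    beta_cause1 = beta1, beta_cause2 = beta2,
    outlier_subjects = outlier_subjects,
    outlier_features = if (spec$n_outliers > 0L) outlier_features else character(0),
    relabeling = relabeling,
    label_counts = list(
      original = table(endpoint_label(dataset$subjects)),
      updated = table(relabeling$updated_label)))
  list(dataset = dataset, ground_truth = ground_truth, relabeling = relabeling)
}

# endpoint update: move random fractions of subjects between label categories
draw_relabeling <- function(dataset, fractions) {
  lab <- endpoint_label(dataset$subjects)
  upd <- lab
  move <- function(from, to, frac) {
    idx <- which(lab == from & upd == lab)  # not already moved
    k <- rbinom(1L, length(idx), frac)
    if (k > 0L) upd[sample(idx, k)] <<- to
    invisible(NULL)
  }
  move("none", "cause1", fractions[["none_to_cause1"]])
  move("none", "cause2", fractions[["none_to_cause2"]])
  move("cause1", "cause2", fractions[["cause1_to_cause2"]])
  move("cause2", "cause1", fractions[["cause2_to_cause1"]])
  data.frame(id = dataset$subjects$id, original_label = lab,
             updated_label = upd, stringsAsFactors = FALSE)
}

#' Inject extreme-valued outlier subjects
#'
#' Shifts the chosen subjects' values on the target features by
#' `magnitude` x the feature's standard deviation.
#'
#' @param dataset a `crs_dataset`.
#' @param n_outliers number of subjects to perturb (0 returns the dataset
#'   unchanged).
#' @param magnitude shift in feature SDs; must be positive.
#' @param target_features feature names to perturb.
#' @param seed optional RNG seed for the subject draw.
#' @param from optional pool of candidate subject positions.
#' @return list with the perturbed `dataset` and the outlier `indices`.
#' @export
inject_outliers <- function(dataset, n_outliers, magnitude, target_features,
                            seed = NULL, from = NULL) {
  n <- nrow(dataset$subjects)
  stopifnot(n_outliers < n)
  if (n_outliers == 0L) return(list(dataset = dataset, indices = integer(0)))
  if (magnitude <= 0) stop("outlier magnitude must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(from)) from <- seq_len(n)
  idx <- if (length(from) == n_outliers) from else sort(sample(from, n_outliers))
  expr <- dataset$expression
  for (f in target_features) {
    expr[idx, f] <- expr[idx, f] + magnitude * sd(expr[, f])
  }
  out <- dataset
  out$expression <- expr
  list(dataset = out, indices = idx)
}
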