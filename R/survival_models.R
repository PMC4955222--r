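#' Censoring survivor function G(t)
#'
#' Kaplan-Meier estimator of the censoring distribution: censoring is treated
#' as the "event" and all true events are censored. Required by the Fine-Gray
#' weighted risk sets and by inverse-probability-of-censoring (IPCW) Brier
#' scores.
#'
#' @param dataset a `crs_dataset`.
#' @return a [crs_stepfun()] starting at 1.
#' @export
censoring_survival <- function(dataset) {
  s <- dataset$subjects
  fit <- survival::survfit(survival::Surv(s$time, s$status == 0) ~ 1)
  survfit_to_stepfun(fit, start_value = 1)
}

#' Aalen-Johansen cumulative incidence
#'
#' Nonparametric estimator of \eqn{F_k(t) = P(T \le t, \epsilon = k)}, the
#' probability of a cause-k event by time t in the presence of the competing
#' cause. Computed from the multi-state Kaplan-Meier machinery in
#' \pkg{survival}.
#'
#' @param dataset a `crs_dataset`.
#' @param cause event type, 1 or 2.
#' @return a [crs_stepfun()] starting at 0, nondecreasing.
#' @export
aalen_johansen <- function(dataset, cause) {
  stopifnot(cause %in% c(1, 2))
  s <- dataset$subjects
  state <- factor(ifelse(s$status == 0, 0L, s$cause), levels = c(0L, 1L, 2L))
  fit <- survival::survfit(survival::Surv(s$time, state) ~ 1)
  col <- match(as.character(cause), fit$states)
  if (is.na(col)) {  # no event of this cause observed
    return(crs_stepfun(numeric(0), numeric(0), 0))
  }
  survfit_to_stepfun(fit, col = col, start_value = 0)
}

#' Cause-specific Cox proportional hazards fit
#'
#' Newton-Raphson maximizer of the Breslow partial likelihood in which
#' other-cause events are censored at their event time. Intended for
#' low-dimensional fits; high-dimensional fitting is done by [boost()].
#'
#' @param dataset a `crs_dataset`.
#' @param covariates covariate names (clinical columns or feature names).
#' @param cause modeled event type.
#' @return a `crs_fit` with coefficients, standard errors, Wald p-values and
#'   the maximized partial log-likelihood.
#' @export
fit_cox_cause_specific <- function(dataset, covariates, cause = 1L) {
  Z <- build_design(dataset, covariates)
  fit_pl_matrix(dataset, Z, "cause_specific", cause)
}

#' Fine-Gray subdistribution hazard fit
#'
#' Maximizes the censoring-weighted partial likelihood of the Fine-Gray model
#' for the given cause: subjects with a competing event remain in the risk set
#' after their event time with weight \eqn{G(t-)/G(\min(T_i,t)-)} from
#' [censoring_survival()]; censored subjects leave as usual. With no competing
#' events the fit coincides with [fit_cox_cause_specific()].
#'
#' @inheritParams fit_cox_cause_specific
#' @return a `crs_fit`.
#' @export
fit_fine_gray <- function(dataset, covariates, cause = 1L) {
  Z <- build_design(dataset, covariates)
  fit_pl_matrix(dataset, Z, "subdistribution", cause)
}

#' Univariate per-feature screen
#'
#' Fits, for every expression feature, the configured hazard model with
#' covariates {feature} + `adjust` and returns the feature's Wald p-value.
#' Non-converged per-feature fits report p = 1 (with a message) rather than
#' failing the screen.
#'
#' @param dataset a `crs_dataset`.
#' @param config a [modeling_config()]; only `hazard_type` is used here.
#' @param adjust mandatory adjustment covariates (clinical column names).
#' @param cause modeled event type.
#' @return named p-value vector in `feature_names` order.
#' @export
univariate_screen <- function(dataset, config, adjust = c("age", "prior_cv"),
                              cause = 1L) {
  model_type <- config$hazard_type
  pd <- build_pl_data(dataset, model_type, cause)
  Z <- build_design(dataset, adjust)[pd$ord, , drop = FALSE]
  X <- dataset$expression[pd$ord, , drop = FALSE]
  res <- cpp_univariate_pvalues(pd$time, pd$d, pd$ext, pd$gdenom, pd$gminus,
                                rep(0, length(pd$time)), Z, X, 50L, 1e-9)
  n_bad <- sum(res$converged == 0)
  if (n_bad > 0) {
    message(sprintf("univariate screen: %d feature fit(s) did not converge; p recorded as 1", n_bad))
  }
  setNames(as.numeric(res$pvalue), colnames(dataset$expression))
}

#' Benjamini-Hochberg selection
#'
#' Step-up false discovery rate control: selects the features whose BH-adjusted
#' p-value is at most `q` (equivalently, the largest k with
#' \eqn{p_{(k)} \le k q / m}).
#'
#' @param pvalues p-value vector.
#' @param q FDR level.
#' @return integer indices of selected entries.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  which(p.adjust(pvalues, method = "BH") <= q)
}

#' Interaction check between clinical and expression linear predictors
#'
#' Refits a Fine-Gray model on the two extracted per-subject scores and their
#' product, to check whether the combined clinical + expression model could be
#' improved by an interaction term.
#'
#' @param dataset a `crs_dataset`.
#' @param lp_clinical,lp_expression per-subject scores aligned to subjects.
#' @param cause modeled event type.
#' @return list with the full `crs_fit`, the interaction coefficient and its
#'   Wald p-value.
#' @export
interaction_check <- function(dataset, lp_clinical, lp_expression, cause = 1L) {
  stopifnot(length(lp_clinical) == nrow(dataset$subjects),
            length(lp_expression) == nrow(dataset$subjects))
  if (sd(lp_expression) == 0 || sd(lp_clinical) == 0) {
    # a constant score carries no information: the interaction is degenerate
    return(list(fit = NULL, interaction_coef = 0, interaction_p = 1))
  }
  Z <- cbind(lp_clinical = lp_clinical, lp_expression = lp_expression,
             interaction = lp_clinical * lp_expression)
  fit <- fit_pl_matrix(dataset, Z, "subdistribution", cause)
  list(fit = fit,
       interaction_coef = unname(fit$coefficients["interaction"]),
       interaction_p = unname(fit$pvalues["interaction"]))
}
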