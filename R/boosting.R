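#' Componentwise likelihood-based boosting for competing-risks regression
#'
#' Regularized multivariable estimation for a cause-specific Cox or Fine-Gray
#' subdistribution hazard model with a high-dimensional candidate set (the
#' expression features) and a small set of mandatory, unpenalized clinical
#' covariates.
#'
#' Starting from all candidate coefficients at zero (and the mandatory
#' covariates at their unpenalized partial-likelihood fit), each boosting step
#' (a) evaluates, for every candidate j, the penalized one-parameter update
#' \eqn{\Delta\beta_j = U_j / (I_j + \lambda)} where \eqn{U_j, I_j} are the
#' partial-likelihood score and Fisher information at the current linear
#' predictor, (b) applies the update of the candidate maximizing the penalized
#' score statistic \eqn{U_j^2/(I_j + \lambda)} (ties broken towards the lowest
#' index), and (c) refreshes the mandatory covariates by one Newton step with
#' the candidate contribution as offset (`mand_full_refit = TRUE`
#' re-converges them instead). Candidates are standardized internally (mean 0,
#' sd 1); reported candidate coefficients are on the standardized scale.
#'
#' @param dataset a `crs_dataset`.
#' @param model_type `"subdistribution"` (Fine-Gray) or `"cause_specific"`.
#' @param n_steps number of boosting steps (0 returns the mandatory-only fit).
#' @param penalty nonnegative penalty \eqn{\lambda}; default 9 x (number of
#'   events of the modeled cause).
#' @param mandatory names of mandatory clinical covariates; may be
#'   `character(0)`.
#' @param cause modeled event type.
#' @param mand_full_refit fully re-converge the mandatory covariates after
#'   every step instead of the single Newton refresh.
#' @return an object of class `crs_boost` with elements `coefficients`
#'   (candidate scale: standardized), `mandatory_coef`, `step_trace`
#'   (data frame: step, feature, increment), `loglik_path`, `center`/`scale`
#'   used for standardization, and the fitting metadata.
#' @export
boost <- function(dataset, model_type = c("subdistribution", "cause_specific"),
                  n_steps = 100L, penalty = NULL,
                  mandatory = c("age", "prior_cv"), cause = 1L,
                  mand_full_refit = FALSE) {
  model_type <- match.arg(model_type)
  stopifnot(n_steps >= 0)
  d_events <- n_events(dataset, cause)
  if (is.null(penalty)) penalty <- 9 * d_events
  if (penalty < 0) stop("penalty must be nonnegative")

  pd <- build_pl_data(dataset, model_type, cause)
  n <- length(pd$time)
  ctr <- colMeans(dataset$expression)
  scl <- apply(dataset$expression, 2L, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1  # constant features: dead candidates
  X <- scale(dataset$expression, center = ctr, scale = scl)[pd$ord, , drop = FALSE]
  Z <- if (length(mandatory)) build_design(dataset, mandatory)[pd$ord, , drop = FALSE]
       else matrix(0, n, 0L)

  res <- cpp_boost(pd$time, pd$d, pd$ext, pd$gdenom, pd$gminus, rep(0, n),
                   Z, X, as.integer(n_steps), penalty, mand_full_refit)
  feats <- colnames(dataset$expression)
  trace <- data.frame(step = seq_len(n_steps),
                      feature = feats[res$trace_feature],
                      increment = as.numeric(res$trace_delta))
  eta_train <- as.numeric(X %*% res$beta_candidate) +
    if (ncol(Z)) as.numeric(Z %*% res$beta_mandatory) else 0
  structure(list(coefficients = setNames(as.numeric(res$beta_candidate), feats),
                 mandatory_coef = setNames(as.numeric(res$beta_mandatory), mandatory),
                 step_trace = trace,
                 eta = eta_train,
                 n_steps = as.integer(n_steps), penalty = penalty,
                 mandatory = mandatory, model_type = model_type, cause = cause,
                 center = ctr, scale = scl,
                 loglik_path = as.numeric(res$loglik_path),
                 mandatory_path = res$mandatory_path,
                 pl_data = pd),
            class = "crs_boost")
}

#' @export
print.crs_boost <- function(x, ...) {
  cat(sprintf("componentwise boosting fit (%s, cause %d): %d steps, penalty %.1f\n",
              x$model_type, x$cause, x$n_steps, x$penalty))
  sel <- selected_features(x)
  cat(sprintf("  %d selected feature(s); mandatory: %s\n", length(sel),
              paste(sprintf("%s=%.3f", names(x$mandatory_coef), x$mandatory_coef),
                    collapse = ", ")))
  invisible(x)
}

#' Features selected by a boosting fit
#'
#' Candidate features with a nonzero coefficient; mandatory covariates are
#' never part of the signature.
#'
#' @param fit a `crs_boost`.
#' @return character vector of feature names.
#' @export
selected_features <- function(fit) {
  names(fit$coefficients)[fit$coefficients != 0]
}

#' @export
predict_lp.crs_boost <- function(fit, dataset) {
  X <- scale(dataset$expression[, names(fit$coefficients), drop = FALSE],
             center = fit$center, scale = fit$scale)
  lp <- as.numeric(X %*% fit$coefficients)
  if (length(fit$mandatory)) {
    Z <- build_design(dataset, fit$mandatory)
    lp <- lp + as.numeric(Z %*% fit$mandatory_coef)
  }
  lp
}

# candidate-only part of the linear predictor (expression score)
predict_lp_candidates <- function(fit, dataset) {
  X <- scale(dataset$expression[, names(fit$coefficients), drop = FALSE],
             center = fit$center, scale = fit$scale)
  as.numeric(X %*% fit$coefficients)
}

# mandatory-only part (clinical score)
predict_lp_mandatory <- function(fit, dataset) {
  if (!length(fit$mandatory)) return(rep(0, nrow(dataset$subjects)))
  Z <- build_design(dataset, fit$mandatory)
  as.numeric(Z %*% fit$mandatory_coef)
}

# Linear predictors on `newdata` after every boosting step of `fit`
# (n x (n_steps+1) matrix, column s+1 = after step s). Used by the
# cross-validated step selection.
boost_eta_path <- function(fit, newdata) {
  n <- nrow(newdata$subjects)
  S <- fit$n_steps
  X <- scale(newdata$expression[, names(fit$coefficients), drop = FALSE],
             center = fit$center, scale = fit$scale)
  Z <- if (length(fit$mandatory)) build_design(newdata, fit$mandatory)
       else matrix(0, n, 0L)
  out <- matrix(0, n, S + 1L)
  mp <- fit$mandatory_path  # q x (S+1)
  eta_cand <- rep(0, n)
  out[, 1L] <- if (ncol(Z)) as.numeric(Z %*% mp[, 1L]) else 0
  if (S > 0L) {
    jidx <- match(fit$step_trace$feature, colnames(newdata$expression))
    for (s in seq_len(S)) {
      eta_cand <- eta_cand + X[, jidx[s]] * fit$step_trace$increment[s]
      out[, s + 1L] <- eta_cand + if (ncol(Z)) as.numeric(Z %*% mp[, s + 1L]) else 0
    }
  }
  out
}

# event-stratified fold assignment (by status x cause), returns integer vector
stratified_folds <- function(subjects, cause, n_folds) {
  strata <- ifelse(subjects$status == 0, 0L,
                   ifelse(subjects$cause == cause, 1L, 2L))
  fold <- integer(nrow(subjects))
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validated choice of the number of boosting steps
#'
#' Event-stratified K-fold cross-validation: for each fold, boosting is run on
#' the complement and the held-out contribution to the (weighted) partial
#' log-likelihood is evaluated at every step count as
#' \eqn{\ell_{full}(\beta) - \ell_{train}(\beta)} (Verweij-van Houwelingen).
#' Returns the step count maximizing the sum over folds.
#'
#' @inheritParams boost
#' @param max_steps largest step count considered.
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return the chosen step count (integer in 0..max_steps); the per-step CV
#'   criterion is attached as attribute `"cv_loglik"`.
#' @export
cv_select_steps <- function(dataset, model_type = c("subdistribution", "cause_specific"),
                            penalty = NULL, mandatory = c("age", "prior_cv"),
                            max_steps = 100L, n_folds = 10L, cause = 1L,
                            seed = NULL) {
  model_type <- match.arg(model_type)
  stopifnot(n_folds >= 2, max_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  d_events <- n_events(dataset, cause)
  if (is.null(penalty)) penalty <- 9 * d_events

  fold <- NULL
  for (attempt in seq_len(10L)) {
    cand <- stratified_folds(dataset$subjects, cause, n_folds)
    ok <- all(vapply(seq_len(n_folds), function(k) {
      sum(dataset$subjects$status[cand != k] == 1 &
            dataset$subjects$cause[cand != k] == cause, na.rm = TRUE) > 0
    }, logical(1)))
    if (ok) { fold <- cand; break }
    warning("cross-validation fold without events of the modeled cause; re-drawing")
  }
  if (is.null(fold)) stop("could not draw folds with events in every training set")

  pd_full <- build_pl_data(dataset, model_type, cause)
  cv <- rep(0, max_steps + 1L)
  for (k in seq_len(n_folds)) {
    train <- subset_dataset(dataset, which(fold != k))
    fit_k <- boost(train, model_type, n_steps = max_steps, penalty = penalty,
                   mandatory = mandatory, cause = cause)
    eta_full <- boost_eta_path(fit_k, dataset)[pd_full$ord, , drop = FALSE]
    ll_full <- vapply(seq_len(ncol(eta_full)), function(s) {
      cpp_pl_loglik(pd_full$time, pd_full$d, pd_full$ext, pd_full$gdenom,
                    pd_full$gminus, eta_full[, s])
    }, numeric(1))
    cv <- cv + (ll_full - fit_k$loglik_path)
  }
  chosen <- which.max(cv) - 1L
  attr(chosen, "cv_loglik") <- cv
  chosen
}
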