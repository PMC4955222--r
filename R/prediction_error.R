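#' Bootstrap sets of size 0.632 n without replacement
#'
#' @param n number of subjects.
#' @param B number of bootstrap sets.
#' @param seed RNG seed.
#' @return list of `B` lists with `in_bag` (size `round(0.632 n)`) and the
#'   disjoint `out_of_bag` complement.
#' @export
draw_632_bootstrap <- function(n, B, seed = NULL) {
  stopifnot(B >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- round(0.632 * n)
  lapply(seq_len(B), function(b) {
    inb <- sort(sample.int(n, m))
    list(in_bag = inb, out_of_bag = setdiff(seq_len(n), inb))
  })
}

#' Predicted cumulative incidence
#'
#' Per-subject predicted probability of a cause-1 event by each time.
#' For Fine-Gray fits, \eqn{\hat F_1(t|x) = 1 - \exp(-\hat\Lambda_{0}(t)
#' e^{x'\beta})} with the Breslow-type baseline from the weighted risk sets.
#' For cause-specific fits, the product-integral combination of both causes'
#' baselines is used, which requires the competing cause's fit as
#' `fit_cause2`. Times beyond the last baseline jump are clamped to the last
#' value with a warning.
#'
#' @param fit a `crs_fit` or `crs_boost` for the cause of interest.
#' @param dataset dataset to predict for.
#' @param times evaluation time grid.
#' @param fit_cause2 cause-2 fit (cause-specific models only).
#' @return n x length(times) matrix of predicted incidences, monotone in t.
#' @export
predict_cif <- function(fit, dataset, times, fit_cause2 = NULL) {
  lp <- predict_lp(fit, dataset)
  bl <- breslow_baseline(fit)
  if (length(bl$time) && max(times) > max(bl$time)) {
    warning("prediction times beyond the last event time; baseline clamped")
  }
  if (fit$model_type == "subdistribution") {
    Lambda0 <- cumsum_step(bl, times)
    out <- 1 - exp(-outer(exp(lp), Lambda0))
  } else {
    if (is.null(fit_cause2)) {
      stop("cause-specific prediction needs the competing cause's fit (fit_cause2)")
    }
    lp2 <- predict_lp(fit_cause2, dataset)
    bl2 <- breslow_baseline(fit_cause2)
    # product-integral over the merged event-time grid:
    # F1(t|x) = sum_{te <= t} S(te- | x) dLambda1(te|x)
    grid <- sort(unique(c(bl$time, bl2$time)))
    d1 <- step_increments(bl, grid)
    d2 <- step_increments(bl2, grid)
    n <- length(lp)
    out_grid <- base::matrix(0, n, length(grid))
    H1 <- outer(exp(lp), d1)       # n x grid: cause-1 hazard increments
    H2 <- outer(exp(lp2), d2)
    cumH <- t(apply(H1 + H2, 1L, cumsum))
    Sminus <- cbind(1, exp(-cumH[, -ncol(cumH), drop = FALSE]))
    out_grid <- t(apply(Sminus * H1, 1L, cumsum))
    idx <- findInterval(times, grid)
    out <- cbind(0, out_grid)[, idx + 1L, drop = FALSE]
  }
  if (any(times <= 0)) out[, times <= 0] <- 0
  pmin(pmax(out, 0), 1)
}

# Breslow baseline hazard increments of a fitted model; fit$eta is the
# training linear predictor in pl (ascending time) order.
breslow_baseline <- function(fit) {
  pd <- fit$pl_data
  res <- cpp_breslow_baseline(pd$time, pd$d, pd$ext, pd$gdenom, pd$gminus, fit$eta)
  list(time = as.numeric(res$time), dhaz = as.numeric(res$dhaz))
}

# cumulative baseline at arbitrary times
cumsum_step <- function(bl, times) {
  if (!length(bl$time)) return(rep(0, length(times)))
  cum <- cumsum(bl$dhaz)
  idx <- findInterval(times, bl$time)
  c(0, cum)[idx + 1L]
}

# baseline increments re-expressed on a merged grid (0 where no jump)
step_increments <- function(bl, grid) {
  d <- rep(0, length(grid))
  if (length(bl$time)) d[match(bl$time, grid)] <- bl$dhaz
  d
}

# IPCW weights for the competing-risks Brier score at time t:
# events of any cause by t get 1/G(T_i-); subjects still event-free at t get
# 1/G(t); subjects censored by t contribute 0. Cause-2 events by t count as
# status 0 (no cause-1 event), consistent with cumulative-incidence
# prediction.
ipcw_status_weights <- function(dataset, t, G, cause = 1L) {
  s <- dataset$subjects
  event_by_t <- s$status == 1 & s$time <= t
  at_risk <- s$time > t
  status1 <- as.numeric(event_by_t & s$cause == cause)
  w <- numeric(nrow(s))
  if (any(event_by_t)) {
    g <- step_eval(G, s$time[event_by_t], left = TRUE)
    if (any(g <= 0)) stop("censoring survival is 0 at a required event time; use a shorter time grid")
    w[event_by_t] <- 1 / g
  }
  if (any(at_risk)) {
    gt <- step_eval(G, t)
    if (gt <= 0) stop("censoring survival is 0 at t; use a shorter time grid")
    w[at_risk] <- 1 / gt
  }
  list(status = status1, weight = w)
}

#' IPCW Brier score curve
#'
#' Inverse-probability-of-censoring weighted Brier score for the cause-1
#' status at each time: the mean squared difference between the predicted
#' cumulative incidence and the observed status, reweighted for censoring.
#'
#' @param predictions n x length(times) matrix from [predict_cif()].
#' @param dataset the subjects being scored.
#' @param times evaluation grid (matching `predictions` columns).
#' @param cause event type scored (default 1).
#' @param G censoring survivor function; defaults to
#'   [censoring_survival()] of `dataset` (pass the full-data estimate when
#'   scoring out-of-bag subsets).
#' @return per-time Brier score vector.
#' @export
brier_curve <- function(predictions, dataset, times, cause = 1L, G = NULL) {
  stopifnot(ncol(predictions) == length(times),
            nrow(predictions) == nrow(dataset$subjects))
  if (is.null(G)) G <- censoring_survival(dataset)
  vapply(seq_along(times), function(j) {
    sw <- ipcw_status_weights(dataset, times[j], G, cause)
    mean(sw$weight * (sw$status - predictions[, j])^2)
  }, numeric(1))
}

#' No-information Brier error
#'
#' Brier score when every subject's outcome is paired with every subject's
#' prediction (the permutation no-information rate used by the .632+
#' estimator).
#'
#' @inheritParams brier_curve
#' @return per-time error vector.
#' @export
no_information_error <- function(predictions, dataset, times, cause = 1L, G = NULL) {
  stopifnot(ncol(predictions) == length(times))
  if (is.null(G)) G <- censoring_survival(dataset)
  vapply(seq_along(times), function(j) {
    sw <- ipcw_status_weights(dataset, times[j], G, cause)
    f <- predictions[, j]
    mean(sw$weight * (sw$status^2 - 2 * sw$status * mean(f) + mean(f^2)))
  }, numeric(1))
}

#' .632+ combination of apparent and out-of-bag error
#'
#' Relative overfitting R = (oob - apparent) / (noinf - apparent), clipped to
#' \[0, 1\] (0 when the denominator is nonpositive or oob does not exceed the
#' apparent error; oob capped at noinf); weight w = 0.632 / (1 - 0.368 R);
#' returns (1 - w) apparent + w min(oob, noinf). Vectorized over time.
#'
#' @param apparent,oob,noinf aligned per-time error vectors.
#' @return the .632+ error estimate.
#' @export
dot632plus <- function(apparent, oob, noinf) {
  stopifnot(length(oob) == length(apparent), length(noinf) == length(apparent))
  oob_c <- pmin(oob, noinf)
  R <- ifelse(noinf > apparent & oob_c > apparent,
              (oob_c - apparent) / (noinf - apparent), 0)
  R <- pmin(pmax(R, 0), 1)
  w <- 0.632 / (1 - 0.368 * R)
  (1 - w) * apparent + w * oob_c
}

#' Compare two models' resampling error curves
#'
#' Per-bootstrap trapezoidal integral of (error_a - error_b) over the time
#' grid, and a two-sided Wilcoxon signed-rank test of these integrated
#' differences across bootstrap sets. Positive integrals mean model b has the
#' lower (better) error.
#'
#' @param oob_a,oob_b B x length(times) matrices of per-bootstrap out-of-bag
#'   error curves, evaluated on the same bootstrap sets and grid.
#' @param times the time grid.
#' @return list with the per-bootstrap `integrated_differences`, their median,
#'   the Wilcoxon `p` (1 with `degenerate = TRUE` when all differences are 0),
#'   and `degenerate`.
#' @export
compare_models <- function(oob_a, oob_b, times) {
  stopifnot(dim(oob_a) == dim(oob_b), ncol(oob_a) == length(times))
  dt <- diff(times)
  trap <- function(y) sum(dt * (y[-1L] + y[-length(y)]) / 2)
  ints <- apply(oob_a - oob_b, 1L, trap)
  ints <- ints[is.finite(ints)]
  if (all(ints == 0)) {
    return(list(integrated_differences = ints, median = 0, p = 1,
                degenerate = TRUE))
  }
  p <- suppressWarnings(wilcox.test(ints, mu = 0)$p.value)
  list(integrated_differences = ints, median = median(ints), p = p,
       degenerate = FALSE)
}

# evaluate an Aalen-Johansen null "model" fitted on `dataset` as a prediction
# matrix with n_rows identical rows
aj_prediction <- function(dataset, times, cause = 1L,
                          n_rows = nrow(dataset$subjects)) {
  aj <- aalen_johansen(dataset, cause)
  vals <- step_eval(aj, times)
  base::matrix(rep(vals, each = n_rows), nrow = n_rows)
}

#' .632+ bootstrap prediction-error study
#'
#' The full resampling comparison of three models for the cause-1 cumulative
#' incidence: (i) the Aalen-Johansen null model using no covariates, (ii) a
#' regression model with the clinical covariates only, and (iii) clinical +
#' expression via componentwise boosting with the step count chosen by
#' cross-validation. Each bootstrap set (0.632 n, without replacement) refits
#' all three models on the in-bag subjects, including the cross-validation,
#' and scores the out-of-bag subjects; apparent and no-information errors come
#' from the full-data fits and all are combined into .632+ curves.
#'
#' @param dataset a `crs_dataset`.
#' @param B number of bootstrap sets (the study design used 500; scale down
#'   for exploration).
#' @param seed RNG seed.
#' @param times evaluation grid; default 40 equally spaced points from 0 to
#'   the 95th percentile of observed times.
#' @param model_type hazard model for (ii) and (iii).
#' @param mandatory clinical covariates.
#' @param max_steps,n_folds cross-validation settings for the boosting model.
#' @param penalty boosting penalty (default 9 x cause events).
#' @param cause modeled event type.
#' @return object of class `crs_pec`: the grid, per-model apparent /
#'   out-of-bag mean / no-information / .632+ curves, the per-bootstrap
#'   out-of-bag curves for [compare_models()], and the failed-iteration count.
#' @export
run_prediction_error_study <- function(dataset, B = 500L, seed = NULL,
                                       times = NULL,
                                       model_type = "subdistribution",
                                       mandatory = c("age", "prior_cv"),
                                       max_steps = 100L, n_folds = 10L,
                                       penalty = NULL, cause = 1L) {
  if (!is.null(seed)) set.seed(seed)
  s <- dataset$subjects
  if (is.null(times)) {
    times <- seq(0, quantile(s$time, 0.95), length.out = 40L)
  }
  n <- nrow(s)
  G_full <- censoring_survival(dataset)

  fit_models <- function(data, cv_seed) {
    steps <- cv_select_steps(data, model_type, penalty = penalty,
                             mandatory = mandatory, max_steps = max_steps,
                             n_folds = n_folds, cause = cause, seed = cv_seed)
    list(
      null = NULL,
      clinical = fit_pl_matrix(data, build_design(data, mandatory),
                               if (model_type == "subdistribution") "subdistribution" else "cause_specific",
                               cause),
      full = boost(data, model_type, n_steps = as.integer(steps),
                   penalty = penalty, mandatory = mandatory, cause = cause))
  }
  predict_all <- function(models, train, newdata) {
    list(null = aj_prediction(train, times, cause, n_rows = nrow(newdata$subjects)),
         clinical = predict_cif(models$clinical, newdata, times),
         full = predict_cif(models$full, newdata, times))
  }

  full_models <- fit_models(dataset, cv_seed = NULL)
  apparent_pred <- predict_all(full_models, dataset, dataset)
  apparent <- lapply(apparent_pred, brier_curve, dataset = dataset,
                     times = times, cause = cause, G = G_full)
  noinf <- lapply(apparent_pred, no_information_error, dataset = dataset,
                  times = times, cause = cause, G = G_full)
  # null-model predictions are identical across subjects: noinf == apparent
  sets <- draw_632_bootstrap(n, B)
  oob <- lapply(c("null", "clinical", "full"), function(m) {
    base::matrix(NA_real_, B, length(times))
  })
  names(oob) <- c("null", "clinical", "full")
  n_failed <- 0L
  for (b in seq_len(B)) {
    res <- tryCatch({
      train <- subset_dataset(dataset, sets[[b]]$in_bag)
      test <- subset_dataset(dataset, sets[[b]]$out_of_bag)
      models <- fit_models(train, cv_seed = NULL)
      preds <- predict_all(models, train, test)
      lapply(preds, brier_curve, dataset = test, times = times,
             cause = cause, G = G_full)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    for (m in names(oob)) oob[[m]][b, ] <- res[[m]]
  }
  if (n_failed > 0L) {
    warning(sprintf("%d of %d bootstrap iteration(s) failed and were excluded",
                    n_failed, B))
  }
  if (B - n_failed < 2L) warning("fewer than 2 valid bootstrap iterations: estimates unstable")

  models_out <- lapply(names(oob), function(m) {
    oob_mean <- colMeans(oob[[m]], na.rm = TRUE)
    list(apparent = apparent[[m]], oob_mean = oob_mean, noinf = noinf[[m]],
         e632plus = dot632plus(apparent[[m]], oob_mean, noinf[[m]]),
         oob_matrix = oob[[m]])
  })
  names(models_out) <- names(oob)
  structure(list(times = times, models = models_out, B = B,
                 n_failed = n_failed, cause = cause,
                 signature_steps = full_models$full$n_steps,
                 full_fit = full_models$full,
                 clinical_fit = full_models$clinical),
            class = "crs_pec")
}

#' @export
print.crs_pec <- function(x, ...) {
  cat(sprintf(".632+ prediction-error study: %d bootstrap sets (%d failed), %d times up to %.1f\n",
              x$B, x$n_failed, length(x$times), max(x$times)))
  last <- length(x$times)
  for (m in names(x$models)) {
    cat(sprintf("  %-8s .632+ at t=%.1f: %.4f\n", m, x$times[last],
                x$models[[m]]$e632plus[last]))
  }
  invisible(x)
}
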