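# Internal glue between crs_dataset objects and the C++ partial-likelihood
# engine. All engine calls take subjects sorted by ascending time; `ord` maps
# back to canonical subject order.
#
# Fine-Gray weighted risk sets: a subject with a competing (other-cause) event
# stays at risk after its event time with weight G(t-)/G(T_k-), where G is the
# censoring survivor function (Kaplan-Meier with the censoring indicator as
# the "event"). G evaluated left-continuously; a zero value cannot occur
# before the last observed time, but is floored anyway.

build_pl_data <- function(dataset, model_type, cause = 1L) {
  s <- dataset$subjects
  ord <- order(s$time)
  time <- s$time[ord]
  status <- s$status[ord]
  cs <- s$cause[ord]
  d <- as.integer(status == 1 & !is.na(cs) & cs == cause)
  n <- length(time)
  if (model_type == "subdistribution") {
    G <- censoring_survival(dataset)
    gmin <- step_eval(G, time, left = TRUE)
    gmin <- pmax(gmin, 1e-10)
    ext <- as.integer(status == 1 & !is.na(cs) & cs != cause)
    list(ord = ord, time = time, d = d, ext = ext, gdenom = gmin, gminus = gmin)
  } else {
    list(ord = ord, time = time, d = d, ext = integer(n),
         gdenom = rep(1, n), gminus = rep(1, n))
  }
}

# Design matrix for a set of covariate names, looked up in the clinical table
# first, then in the expression matrix.
build_design <- function(dataset, covariates) {
  clin_names <- setdiff(names(dataset$subjects), c("id", "time", "status", "cause"))
  cols <- lapply(covariates, function(v) {
    if (v %in% clin_names) {
      as.numeric(dataset$subjects[[v]])
    } else if (v %in% colnames(dataset$expression)) {
      dataset$expression[, v]
    } else {
      stop("unknown covariate: ", v)
    }
  })
  Z <- do.call(cbind, cols)
  colnames(Z) <- covariates
  Z
}

# Newton fit of the (weighted) partial likelihood on an explicit design
# matrix; shared by the exported regression fits and interaction_check.
fit_pl_matrix <- function(dataset, Z, model_type, cause = 1L,
                          maxit = 50L, tol = 1e-9) {
  pd <- build_pl_data(dataset, model_type, cause)
  Zs <- Z[pd$ord, , drop = FALSE]
  fit <- cpp_newton(pd$time, pd$d, pd$ext, pd$gdenom, pd$gminus,
                    rep(0, length(pd$time)), Zs, maxit, tol)
  if (!fit$converged) {
    stop(sprintf("partial-likelihood Newton fit did not converge in %d iterations (loglik %.6f%s)",
                 fit$iter, fit$loglik,
                 if (fit$singular) ", singular information" else ""))
  }
  beta <- as.numeric(fit$beta)
  V <- tryCatch(solve(fit$imat), error = function(e) NULL)
  se <- if (is.null(V)) rep(NA_real_, length(beta)) else sqrt(pmax(diag(V), 0))
  if (any(abs(beta) > 10)) {
    warning("very large coefficient(s): possible complete separation")
  }
  z <- beta / se
  structure(list(coefficients = setNames(beta, colnames(Z)),
                 se = setNames(se, colnames(Z)),
                 pvalues = setNames(2 * pnorm(-abs(z)), colnames(Z)),
                 loglik = fit$loglik,
                 model_type = model_type, cause = cause,
                 covariates = colnames(Z),
                 converged = fit$converged, iter = fit$iter,
                 pl_data = pd, eta = as.numeric(Zs %*% beta)),
            class = "crs_fit")
}

#' @export
print.crs_fit <- function(x, ...) {
  cat(sprintf("%s hazard fit (cause %d), partial log-likelihood %.4f\n",
              x$model_type, x$cause, x$loglik))
  print(data.frame(coef = x$coefficients, se = x$se, p = x$pvalues))
  invisible(x)
}

# linear predictor of a fitted model on (possibly new) data
predict_lp <- function(fit, dataset) {
  UseMethod("predict_lp")
}

#' @export
predict_lp.crs_fit <- function(fit, dataset) {
  Z <- build_design(dataset, fit$covariates)
  as.numeric(Z %*% fit$coefficients)
}
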