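test_that("censoring survival is the product-limit estimator of the censoring distribution", {
  # no censored subjects: G == 1 everywhere
  subj <- data.frame(id = letters[1:4], time = 1:4, status = 1L,
                     cause = c(1L, 2L, 1L, 2L), age = 60, prior_cv = 0L)
  d <- competing_risks_dataset(subj, matrix(0, 4, 1, dimnames = list(NULL, "g")))
  G <- censoring_survival(d)
  expect_equal(step_eval(G, c(0, 2, 10)), c(1, 1, 1))

  # all censored at distinct times: steps 2/3, 1/3, 0
  subj$status <- 0L; subj$cause <- NA
  d <- competing_risks_dataset(subj[1:3, ], matrix(0, 3, 1, dimnames = list(NULL, "g")))
  G <- censoring_survival(d)
  expect_equal(step_eval(G, c(1, 2, 3)), c(2/3, 1/3, 0))
  expect_equal(step_eval(G, c(1, 2, 3), left = TRUE), c(1, 2/3, 1/3))

  # mixed 6-subject example, hand-computed product limit
  subj <- data.frame(id = letters[1:6], time = 1:6,
                     status = c(1L, 0L, 1L, 0L, 0L, 1L),
                     cause = c(1L, NA, 2L, NA, NA, 1L),
                     age = 60, prior_cv = 0L)
  d <- competing_risks_dataset(subj, matrix(0, 6, 1, dimnames = list(NULL, "g")))
  G <- censoring_survival(d)
  # censorings at t=2 (5 at risk), t=4 (3 at risk), t=5 (2 at risk)
  expect_equal(step_eval(G, c(1.5, 2, 4, 5)),
               c(1, 4/5, 4/5 * 2/3, 4/5 * 2/3 * 1/2))
})

test_that("Aalen-Johansen incidence matches hand computation and reduces to the ECDF", {
  # single event type, no censoring: empirical distribution function
  subj <- data.frame(id = letters[1:5], time = c(2, 4, 5, 7, 9), status = 1L,
                     cause = 1L, age = 60, prior_cv = 0L)
  d <- competing_risks_dataset(subj, matrix(0, 5, 1, dimnames = list(NULL, "g")))
  aj <- aalen_johansen(d, 1)
  expect_equal(step_eval(aj, c(2, 4, 5, 7, 9)), (1:5) / 5)
  expect_equal(step_eval(aj, 1), 0)

  # all events cause 2: cause-1 incidence is identically zero
  subj$cause <- 2L
  d <- competing_risks_dataset(subj, matrix(0, 5, 1, dimnames = list(NULL, "g")))
  expect_equal(step_eval(aalen_johansen(d, 1), c(1, 5, 10)), c(0, 0, 0))

  # 8-subject two-cause example vs manual AJ increments KM(t-) d_1(t)/n(t)
  subj <- data.frame(id = letters[1:8], time = 1:8,
                     status = c(1L, 1L, 0L, 1L, 1L, 0L, 1L, 1L),
                     cause = c(1L, 2L, NA, 1L, 2L, NA, 1L, 2L),
                     age = 60, prior_cv = 0L)
  d <- competing_risks_dataset(subj, matrix(0, 8, 1, dimnames = list(NULL, "g")))
  manual_aj <- function(cause) {
    km <- 1; F <- 0; out <- numeric(8)
    for (t in 1:8) {
      at_risk <- sum(subj$time >= t)
      d1 <- sum(subj$time == t & subj$status == 1 & subj$cause == cause)
      dall <- sum(subj$time == t & subj$status == 1)
      F <- F + km * d1 / at_risk
      km <- km * (1 - dall / at_risk)
      out[t] <- F
    }
    out
  }
  expect_equal(step_eval(aalen_johansen(d, 1), 1:8), manual_aj(1), tolerance = 1e-12)
  expect_equal(step_eval(aalen_johansen(d, 2), 1:8), manual_aj(2), tolerance = 1e-12)
  # incidences sum to 1 - KM(all-cause) and are nondecreasing
  s_all <- step_eval(aalen_johansen(d, 1), 1:8) + step_eval(aalen_johansen(d, 2), 1:8)
  expect_true(all(diff(step_eval(aalen_johansen(d, 1), 1:8)) >= 0))
  expect_true(all(s_all <= 1 + 1e-12))
})

test_that("cause-specific Cox optimum matches coxph and a derivative-free maximizer", {
  d <- random_dataset(n = 20, p = 2, seed = 11)
  fit <- fit_cox_cause_specific(d, c("age", "g01"), cause = 1)

  # independent oracle 1: survival::coxph with Breslow ties
  df <- cbind(d$subjects, g01 = d$expression[, "g01"])
  df$ev <- df$status == 1 & !is.na(df$cause) & df$cause == 1
  cx <- survival::coxph(survival::Surv(time, ev) ~ age + g01, data = df,
                        ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(cx)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(cx)))), tolerance = 1e-6)

  # independent oracle 2: derivative-free maximization of the brute-force
  # partial likelihood
  dd <- as.integer(df$ev)
  Z <- cbind(df$age, d$expression[, "g01"])
  opt <- optim(c(0, 0), function(b) -bf_coxph_loglik(b, df$time, dd, Z),
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-6)
})

test_that("Cox recovers a known log hazard ratio in a two-group simulation", {
  set.seed(21)
  n <- 2000
  grp <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.1 * exp(0.7 * grp))
  cens <- rexp(n, 0.05)
  subj <- data.frame(id = sprintf("s%04d", 1:n), time = pmin(t_ev, cens),
                     status = as.integer(t_ev <= cens),
                     cause = ifelse(t_ev <= cens, 1L, NA),
                     age = 60, prior_cv = grp)
  d <- competing_risks_dataset(subj, matrix(rnorm(n), n, 1, dimnames = list(NULL, "g")))
  fit <- fit_cox_cause_specific(d, "prior_cv", cause = 1)
  expect_equal(unname(fit$coefficients), 0.7, tolerance = 0.1)

  # null covariate: coefficient near zero, |z| modest
  fit0 <- fit_cox_cause_specific(d, "g", cause = 1)
  expect_lt(abs(fit0$coefficients / fit0$se), 4)
})

test_that("Fine-Gray matches cmprsk::crr, the no-competing-event reduction, and a brute-force oracle", {
  skip_if_not_installed("cmprsk")
  d <- random_dataset(n = 50, p = 3, seed = 12)
  fit <- fit_fine_gray(d, c("age", "prior_cv", "g01"))
  s <- d$subjects
  cr <- cmprsk::crr(s$time, ifelse(s$status == 0, 0, s$cause),
                    cbind(s$age, s$prior_cv, d$expression[, "g01"]),
                    failcode = 1, cencode = 0, gtol = 1e-12)
  expect_equal(unname(fit$coefficients), unname(cr$coef), tolerance = 1e-6)

  # no competing events: Fine-Gray coincides with cause-specific Cox
  d1 <- random_dataset(n = 30, p = 2, seed = 13, cause2_prob = 0)
  expect_equal(fit_fine_gray(d1, c("age", "g01"))$coefficients,
               fit_cox_cause_specific(d1, c("age", "g01"))$coefficients,
               tolerance = 1e-6)

  # derivative-free maximization of the weighted partial likelihood
  d <- random_dataset(n = 22, p = 1, seed = 14)
  fit <- fit_fine_gray(d, c("age", "g01"))
  s <- d$subjects
  G <- censoring_survival(d)
  Z <- cbind(s$age, d$expression[, "g01"])
  opt <- optim(c(0, 0),
               function(b) -bf_fg_loglik(b, s$time, s$status, s$cause, Z, G),
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-6)
})

test_that("Fine-Gray recovers the sign of a cause-1 effect", {
  hits <- vapply(1:20, function(r) {
    g <- generate_cohort(cohort_spec(n = 150, p = 20, block_size = 4,
                                     n_informative_cause1 = 1,
                                     n_informative_cause2 = 1,
                                     effect_size = 0.8, n_outliers = 0,
                                     seed = 100 + r))
    f <- fit_fine_gray(g$dataset, colnames(g$dataset$expression)[
      g$ground_truth$informative_cause1])
    unname(f$coefficients[1]) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("univariate screen is deterministic, calibrated under the null, and ranks signal", {
  cfg_sh <- modeling_config("subdistribution", "univariate_topk",
                            "original", "all_observations")
  # duplicated features get identical p-values
  d <- random_dataset(n = 60, p = 3, seed = 15)
  X <- cbind(d$expression, dup = d$expression[, 1])
  colnames(X)[4] <- "g01dup"
  d2 <- competing_risks_dataset(d$subjects, X)
  pv <- univariate_screen(d2, cfg_sh)
  expect_equal(unname(pv["g01"]), unname(pv["g01dup"]), tolerance = 1e-10)

  # all-null simulation: approximately uniform p-values
  g <- generate_cohort(cohort_spec(n = 200, p = 300, effect_size = 0,
                                   n_outliers = 0, block_size = 3,
                                   within_block_correlation = 0, seed = 16))
  pv <- univariate_screen(g$dataset, cfg_sh)
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 1e-3)

  # informative features of a generated cohort rank in the lower tail
  g <- generate_cohort(cohort_spec(n = 250, p = 100, effect_size = 0.8,
                                   n_outliers = 0, seed = 17))
  pv <- univariate_screen(g$dataset, cfg_sh)
  ranks <- rank(pv)[g$ground_truth$informative_cause1]
  expect_lt(median(ranks), 10)

  # cause-specific variant runs and agrees with coxph on one feature
  cfg_csh <- modeling_config("cause_specific", "univariate_topk",
                             "original", "all_observations")
  pv2 <- univariate_screen(d, cfg_csh)
  expect_true(all(pv2 >= 0 & pv2 <= 1))
})

test_that("BH selection equals its brute-force step-up definition", {
  expect_length(bh_fdr(c(0.001, 0.01, 0.02, 0.9), 0.05), 3)
  expect_length(bh_fdr(rep(1, 10), 0.05), 0)
  bf_bh <- function(p, q) {
    m <- length(p); o <- order(p)
    k <- max(c(0, which(p[o] <= seq_len(m) * q / m)))
    if (k == 0) integer(0) else sort(o[seq_len(k)])
  }
  set.seed(18)
  for (i in 1:200) {
    p <- runif(sample(5:50, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(sort(bh_fdr(p, q)), bf_bh(p, q))
  }
})

test_that("interaction check detects a product effect and not its absence", {
  # degenerate: constant expression score
  d <- random_dataset(n = 40, p = 2, seed = 19)
  res <- interaction_check(d, rnorm(40), rep(0, 40))
  expect_equal(res$interaction_coef, 0)
  expect_equal(res$interaction_p, 1)

  # power: outcome driven by a product of two scores
  gen_inter <- function(seed, beta_int) {
    set.seed(seed)
    n <- 400
    lp_c <- rnorm(n); lp_e <- rnorm(n)
    rate <- 0.05 * exp(0.3 * lp_c + 0.3 * lp_e + beta_int * lp_c * lp_e)
    t_ev <- rexp(n, rate)
    cens <- rexp(n, 0.04)
    subj <- data.frame(id = sprintf("s%04d", 1:n), time = pmin(t_ev, cens, 24),
                       status = as.integer(t_ev <= pmin(cens, 24)),
                       cause = ifelse(t_ev <= pmin(cens, 24), 1L, NA),
                       age = 60, prior_cv = 0L)
    d <- competing_risks_dataset(subj, matrix(rnorm(n), n, 1,
                                              dimnames = list(NULL, "g")))
    list(d = d, lp_c = lp_c, lp_e = lp_e)
  }
  detected <- vapply(1:10, function(r) {
    gi <- gen_inter(300 + r, 0.5)
    interaction_check(gi$d, gi$lp_c, gi$lp_e)$interaction_p < 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.6)

  # permuting the expression score destroys the interaction on average
  set.seed(31)
  perm_p <- vapply(1:10, function(r) {
    gi <- gen_inter(300 + r, 0.5)
    interaction_check(gi$d, gi$lp_c, sample(gi$lp_e))$interaction_p
  }, numeric(1))
  expect_gt(median(perm_p), 0.1)
})
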