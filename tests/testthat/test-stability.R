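# hand-built selection matrix for arithmetic tests
make_selmat <- function(inclusion, config = modeling_config()) {
  structure(list(config = config, subsample_indices = NULL,
                 inclusion = inclusion, k_univariate = NULL,
                 n_valid = sum(!is.na(inclusion[, 1])), cause = 1L,
                 n_steps = 100L),
            class = "crs_selmat")
}

test_that("subsample draws have the right size, are seeded, and balance inclusion", {
  subs <- draw_subsamples(10, 20, 0.5, seed = 1)
  expect_true(all(vapply(subs, length, integer(1)) == 5))
  expect_true(all(vapply(subs, anyDuplicated, integer(1)) == 0L))
  expect_identical(subs, draw_subsamples(10, 20, 0.5, seed = 1))

  # law of large numbers: per-subject inclusion rate ~ 0.5
  big <- draw_subsamples(100, 10000, 0.5, seed = 2)
  rate <- tabulate(unlist(big), 100) / 10000
  expect_true(all(abs(rate - 0.5) < 0.02))
})

test_that("inclusion frequencies are column means over valid rows", {
  M <- rbind(c(TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE),
             c(FALSE, TRUE, FALSE), c(TRUE, FALSE, FALSE),
             c(NA, NA, NA))
  colnames(M) <- c("a", "b", "c")
  sm <- make_selmat(M)
  f <- inclusion_frequencies(sm)
  expect_equal(unname(f), c(3/4, 2/4, 0))
  # invariant under row permutation
  sm2 <- make_selmat(M[c(5, 3, 1, 4, 2), ])
  expect_equal(inclusion_frequencies(sm2), f)
})

test_that("joint-selection odds ratios match the cross-table arithmetic", {
  # counts (n11, n10, n01, n00) = (30, 20, 20, 30) -> OR = 2.25
  M <- cbind(a = rep(c(TRUE, TRUE, FALSE, FALSE), c(30, 20, 20, 30)),
             b = rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 20, 20, 30)))
  or <- joint_selection_odds_ratios(make_selmat(M), min_frequency = 0.1)
  expect_equal(or$or["a", "b"], 2.25)
  expect_equal(or$or["b", "a"], 2.25)
  expect_true(is.na(or$or["a", "a"]))

  # zero cell: continuity correction 0.5 everywhere
  M <- cbind(a = rep(c(TRUE, TRUE, FALSE, FALSE), c(10, 0, 5, 85)),
             b = rep(c(TRUE, FALSE, TRUE, FALSE), c(10, 0, 5, 85)))
  or <- joint_selection_odds_ratios(make_selmat(M), min_frequency = 0.05)
  expect_equal(or$or["a", "b"], (10.5 * 85.5) / (0.5 * 5.5), tolerance = 1e-12)

  # independent selection: OR near 1 over large B
  set.seed(3)
  M <- cbind(a = runif(20000) < 0.3, b = runif(20000) < 0.4)
  or <- joint_selection_odds_ratios(make_selmat(M), min_frequency = 0.1)
  expect_lt(abs(log(or$or["a", "b"])), 0.15)

  # below-threshold features are rejected
  M <- cbind(a = rep(FALSE, 100), b = rep(FALSE, 100))
  expect_error(joint_selection_odds_ratios(make_selmat(M)), "fewer than 2")
})

test_that("univariate top-k selects exactly k features per subsample row", {
  g <- generate_cohort(cohort_spec(n = 100, p = 20, block_size = 4,
                                   n_informative_cause1 = 2,
                                   n_informative_cause2 = 2,
                                   n_outliers = 0, seed = 50))
  subs <- draw_subsamples(100, 10, 0.5, seed = 51)
  cfg <- modeling_config("subdistribution", "univariate_topk",
                         "original", "all_observations")
  m <- build_selection_matrix(g$dataset, cfg, subs, k = 4)
  expect_true(all(rowSums(m$inclusion) == 4))
  expect_equal(m$k_univariate, 4)
})

test_that("duplicated features share univariate inclusion but compete under boosting", {
  g <- generate_cohort(cohort_spec(n = 150, p = 20, block_size = 4,
                                   n_informative_cause1 = 1,
                                   n_informative_cause2 = 1,
                                   effect_size = 1, n_outliers = 0, seed = 52))
  d <- g$dataset
  X <- cbind(d$expression, dup = d$expression[, 1])
  colnames(X)[21] <- "dup01"
  d2 <- competing_risks_dataset(d$subjects, X)
  subs <- draw_subsamples(150, 30, 0.5, seed = 53)

  cfg_u <- modeling_config("subdistribution", "univariate_topk",
                           "original", "all_observations")
  mu <- build_selection_matrix(d2, cfg_u, subs, k = 3)
  fu <- inclusion_frequencies(mu)
  # identical p-values: the duplicate pair is selected together
  expect_equal(unname(fu["feat00001"]), unname(fu["dup01"]), tolerance = 0.05)

  cfg_b <- modeling_config("subdistribution", "multivariable_boosting",
                           "original", "all_observations")
  mb <- build_selection_matrix(d2, cfg_b, subs, n_steps = 50)
  fb <- inclusion_frequencies(mb)
  both <- mean(mb$inclusion[, "feat00001"] & mb$inclusion[, "dup01"], na.rm = TRUE)
  either <- mean(mb$inclusion[, "feat00001"] | mb$inclusion[, "dup01"], na.rm = TRUE)
  # boosting needs only one of two identical copies
  expect_lt(both, either)
})

test_that("outlier flagging recovers injected extremes and respects the MAD guard", {
  # constant feature: zero MAD, no flags, warning
  d <- random_dataset(n = 30, p = 2, seed = 54)
  X <- cbind(d$expression, flat = rep(1, 30))
  colnames(X)[3] <- "flat"
  d2 <- competing_risks_dataset(d$subjects, X)
  expect_warning(res <- flag_outlier_observations(d2, "flat"), "zero MAD")
  expect_length(res$indices, 0)

  # injected magnitude-6 outliers are flagged at threshold 4
  d <- random_dataset(n = 100, p = 3, seed = 55)
  inj <- inject_outliers(d, 3L, 6, "g02", seed = 56)
  res <- flag_outlier_observations(inj$dataset, "g02", 4)
  expect_setequal(res$indices, inj$indices)

  # clean Gaussian data: false flags are rare
  set.seed(57)
  n_flags <- vapply(1:20, function(r) {
    d <- random_dataset(n = 250, p = 1, seed = 5700 + r)
    length(flag_outlier_observations(d, "g01", 4)$indices)
  }, integer(1))
  expect_lt(mean(n_flags), 1)
})

test_that("modeling-choice regression recovers a known logistic model", {
  grid <- config_grid()
  counts <- do.call(rbind, lapply(grid, function(cfg) {
    data.frame(hazard_type = cfg$hazard_type,
               selection_method = cfg$selection_method,
               endpoint = cfg$endpoint,
               outlier_handling = cfg$outlier_handling,
               stringsAsFactors = FALSE)
  }))
  sh <- as.integer(counts$hazard_type == "subdistribution")
  oe <- as.integer(counts$outlier_handling == "outliers_excluded")
  oep <- as.integer(counts$endpoint == "original")
  uni <- as.integer(counts$selection_method == "univariate_topk")
  eta <- -1 + 0.8 * sh - 0.5 * oe + 1.2 * oep - 0.7 * uni + 0.6 * sh * oep
  set.seed(58)
  counts$total <- 5000L
  counts$selected <- rbinom(16, 5000L, plogis(eta))
  sr <- stability_regression(counts)
  expect_false(sr$degenerate)
  est <- setNames(sr$table$estimate, sr$table$term)
  expect_equal(unname(est["(Intercept)"]), -1, tolerance = 0.1)
  expect_equal(unname(est["sh"]), 0.8, tolerance = 0.15)
  expect_equal(unname(est["original endpoint"]), 1.2, tolerance = 0.15)
  expect_equal(unname(est["sh x original endpoint"]), 0.6, tolerance = 0.2)
  expect_equal(unname(est["univariate"]), -0.7, tolerance = 0.15)

  # identical frequency in all configs: non-intercept estimates ~ 0
  counts$selected <- 300L
  sr0 <- stability_regression(counts)
  nonint <- sr0$table$estimate[sr0$table$term != "(Intercept)"]
  expect_true(all(abs(nonint) < 1e-6))
})

test_that("modeling-choice regression optimum matches derivative-free maximization", {
  grid <- config_grid()
  counts <- do.call(rbind, lapply(grid, function(cfg) {
    data.frame(hazard_type = cfg$hazard_type,
               selection_method = cfg$selection_method,
               endpoint = cfg$endpoint,
               outlier_handling = cfg$outlier_handling,
               stringsAsFactors = FALSE)
  }))
  set.seed(59)
  counts$total <- 200L
  counts$selected <- rbinom(16, 200L, runif(16, 0.05, 0.6))
  sr <- stability_regression(counts)
  expect_false(sr$degenerate)

  sh <- as.integer(counts$hazard_type == "subdistribution")
  oe <- as.integer(counts$outlier_handling == "outliers_excluded")
  oep <- as.integer(counts$endpoint == "original")
  uni <- as.integer(counts$selection_method == "univariate_topk")
  Xm <- cbind(1, sh, oe, oep, uni, sh * oe, sh * oep, sh * uni,
              oe * oep, oep * uni)
  negll <- function(b) {
    eta <- as.numeric(Xm %*% b)
    -sum(counts$selected * eta - counts$total * log1p(exp(eta)))
  }
  # derivative-free maximization with restarts
  opt <- list(par = rep(0, 10), value = negll(rep(0, 10)))
  for (i in 1:8) {
    opt <- optim(opt$par, negll, method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 20000))
  }
  glm_ll <- -negll(sr$table$estimate)
  expect_equal(glm_ll, -opt$value, tolerance = 1e-6)
})

test_that("separated inclusion patterns are reported as degenerate, not fabricated", {
  grid <- config_grid()
  counts <- do.call(rbind, lapply(grid, function(cfg) {
    data.frame(hazard_type = cfg$hazard_type,
               selection_method = cfg$selection_method,
               endpoint = cfg$endpoint,
               outlier_handling = cfg$outlier_handling,
               total = 100L, stringsAsFactors = FALSE)
  }))
  counts$selected <- ifelse(counts$hazard_type == "subdistribution", 100L, 0L)
  sr <- stability_regression(counts)
  expect_true(sr$degenerate)
  expect_true(all(is.na(sr$table$estimate)))
})

test_that("the multi-feature report assembles frequencies, extrema and term counts", {
  set.seed(60)
  grid <- config_grid(endpoints = "original")
  feats <- c("f1", "f2", "f3")
  matrices <- lapply(grid, function(cfg) {
    # f1 depends on the hazard model; f2 constant; f3 below threshold
    p1 <- if (cfg$hazard_type == "subdistribution") 0.6 else 0.25
    M <- cbind(f1 = runif(400) < p1, f2 = runif(400) < 0.3,
               f3 = runif(400) < 0.01)
    make_selmat(M, cfg)
  })
  rep <- multi_feature_stability(matrices, frequency_threshold = 0.1)
  expect_setequal(rep$qualifying, c("f1", "f2"))
  # min/max columns are the row-wise extrema of the frequency table
  fr <- rep$frequencies
  cfg_cols <- setdiff(names(fr), c("feature", "min", "max"))
  expect_equal(fr$min, apply(fr[, cfg_cols], 1, min))
  expect_equal(fr$max, apply(fr[, cfg_cols], 1, max))
  # the hazard-model effect on f1 is detected
  f1_sh <- rep$regressions[rep$regressions$feature == "f1" &
                             rep$regressions$term == "sh", ]
  expect_true(f1_sh$significant)
  expect_gt(f1_sh$estimate, 0)
  # single-feature input reduces to that feature's regression
  matrices1 <- lapply(matrices, function(m) {
    m$inclusion <- m$inclusion[, "f1", drop = FALSE]; m
  })
  rep1 <- multi_feature_stability(matrices1, frequency_threshold = 0.1)
  expect_equal(rep1$qualifying, "f1")
  expect_equal(rep1$regressions$estimate,
               rep$regressions$estimate[rep$regressions$feature == "f1"],
               tolerance = 1e-9)
})
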