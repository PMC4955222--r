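# Small in-code fixtures shared across test files.

# minimal valid dataset with explicit values
toy_dataset <- function() {
  subj <- data.frame(id = c("a", "b", "c"),
                     time = c(5, 10, 15),
                     status = c(1L, 0L, 1L),
                     cause = c(1L, NA, 2L),
                     age = c(60, 70, 55),
                     prior_cv = c(1L, 0L, 0L))
  X <- matrix(c(0.5, -1, 2, 1, 0, -0.5), 3, 2,
              dimnames = list(NULL, c("gA", "gB")))
  competing_risks_dataset(subj, X)
}

# random competing-risks dataset with continuous times (no ties)
random_dataset <- function(n = 40, p = 5, seed = 1, censor_prob = 0.3,
                           cause2_prob = 0.5) {
  set.seed(seed)
  subj <- data.frame(id = sprintf("s%03d", seq_len(n)),
                     time = round(rexp(n, 0.08), 4),
                     status = rbinom(n, 1L, 1 - censor_prob))
  subj$cause <- ifelse(subj$status == 1L,
                       1L + rbinom(n, 1L, cause2_prob), NA)
  subj$age <- rnorm(n, 65, 12)
  subj$prior_cv <- rbinom(n, 1L, 0.3)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("g%02d", seq_len(p))))
  competing_risks_dataset(subj, X)
}

# brute-force partial log-likelihood for the cause-specific Cox model
# (Breslow ties), independent of the C++ engine
bf_coxph_loglik <- function(beta, time, d, Z) {
  eta <- as.numeric(Z %*% beta)
  ll <- 0
  for (i in which(d == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# brute-force Fine-Gray weighted partial log-likelihood: competing-event
# subjects stay at risk after their time with weight G(t-)/G(T_k-)
bf_fg_loglik <- function(beta, time, status, cause, Z, G) {
  eta <- as.numeric(Z %*% beta)
  gm <- step_eval(G, time, left = TRUE)
  ll <- 0
  for (i in which(status == 1 & cause == 1)) {
    t <- time[i]
    w <- ifelse(time >= t, 1,
                ifelse(status == 1 & cause == 2,
                       step_eval(G, t, left = TRUE) / gm, 0))
    ll <- ll + eta[i] - log(sum(w * exp(eta)))
  }
  ll
}
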