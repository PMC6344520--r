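# Independent brute-force oracles used across tests. These deliberately use
# explicit loops and textbook formulas, not the package's vectorized code.

oracle_enorm <- function(values) {
  out <- numeric(nrow(values) - 1)
  for (i in seq_len(nrow(values) - 1)) {
    s <- 0
    for (j in 1:6) s <- s + (values[i + 1, j] - values[i, j])^2
    out[i] <- sqrt(s)
  }
  out
}

oracle_fd <- function(values) {
  out <- numeric(nrow(values) - 1)
  for (i in seq_len(nrow(values) - 1)) {
    s <- 0
    for (j in 1:6) s <- s + abs(values[i + 1, j] - values[i, j])
    out[i] <- s
  }
  out
}

oracle_r2 <- function(obs, pred) {
  ss_res <- 0
  ss_tot <- 0
  m <- sum(obs) / length(obs)
  for (i in seq_along(obs)) {
    ss_res <- ss_res + (obs[i] - pred[i])^2
    ss_tot <- ss_tot + (obs[i] - m)^2
  }
  1 - ss_res / ss_tot
}

oracle_r2_cor <- function(obs, pred) {
  n <- length(obs)
  mo <- sum(obs) / n
  mp <- sum(pred) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (obs[i] - mo) * (pred[i] - mp)
    sxx <- sxx + (obs[i] - mo)^2
    syy <- syy + (pred[i] - mp)^2
  }
  if (syy == 0 || sxx == 0) return(0)
  sxy^2 / (sxx * syy)
}

# Benjamini-Hochberg step-up, straight from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- running
  }
  adj
}

random_motion_params <- function(t_rows, seed, scale = 1) {
  set.seed(seed)
  motion_params(matrix(rnorm(t_rows * 6, sd = scale), t_rows, 6),
                subject_id = paste0("rand", seed))
}

# Small complete cohort for fast pipeline tests.
small_cohort <- function(n = 120, seed = 5, n_physical = 6, n_psych = 6,
                         r2_physical = 0.11) {
  generate_cohort(cohort_spec(
    n_subjects = n, n_physical = n_physical, n_psych = n_psych,
    n_drug_like = min(3, n_psych), r2_physical = r2_physical,
    missing_rate_max = 0, seed = seed))
}

fast_control <- function() learner_control(num_trees = 60, max_components = 8)

fast_plan <- function(..., seed = 1) {
  cv_plan(k_inner = 4, k_outer = 3, n_repeats = 2,
          n_search = c(ENET = 4, PCR = 4, PLS = 3, SVR = 3, RF = 2, CF = 2),
          seed = seed, control = fast_control(), ...)
}
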