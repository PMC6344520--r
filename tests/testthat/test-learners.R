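sim_xy <- function(n = 80, p = 6, seed = 1, signal = function(X) X[, 1]) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  list(X = X, y = signal(X))
}

test_that("all six learners satisfy the fit/predict contract", {
  d <- sim_xy(n = 70, seed = 2, signal = function(X) X[, 1] + 0.5 * X[, 2] +
                                                     rnorm(nrow(X), sd = 0.5))
  new <- matrix(rnorm(15 * 6), 15, 6, dimnames = list(NULL, colnames(d$X)))
  for (nm in learner_names()) {
    h <- sample_hypers(nm, 1, p = 6, n = 70, seed = 3)[[1]]
    f <- fit_base(nm, d$X, d$y, h, seed = 4, control = fast_control())
    pr <- predict(f, new)
    expect_length(pr, 15)
    expect_true(all(is.finite(pr)), info = nm)
    vi <- variable_importance(f, d$X, d$y)
    expect_length(vi, 6)
    expect_true(all(is.finite(vi)) && all(vi >= 0), info = nm)
  }
})

test_that("degenerate outcomes are refused", {
  d <- sim_xy(n = 30)
  expect_error(fit_base("ENET", d$X, rep(1, 30),
                        list(lambda = 0.1, alpha = 0.5)), "degenerate")
})

test_that("ENET recovers an exact linear signal and kills VI under heavy penalty", {
  d <- sim_xy(n = 100, seed = 5, signal = function(X) 3 * X[, 1])
  f <- fit_base("ENET", d$X, d$y, list(lambda = 1e-5, alpha = 0.5))
  expect_gt(oracle_r2(d$y, predict(f, d$X)), 0.999)
  vi <- variable_importance(f, d$X, d$y)
  expect_equal(which.max(vi), 1L, ignore_attr = TRUE)
  expect_gt(vi[1], 10 * max(vi[-1]))

  f0 <- fit_base("ENET", d$X, d$y, list(lambda = 1e6, alpha = 1))
  expect_equal(unname(variable_importance(f0, d$X, d$y)), rep(0, 6))
})

test_that("PCR with all components reproduces OLS", {
  d <- sim_xy(n = 60, seed = 7,
              signal = function(X) X %*% seq(-1, 1, length.out = 6) +
                                   rnorm(nrow(X), sd = 0.3))
  f <- fit_base("PCR", d$X, d$y, list(ncomp = 6))
  ols <- stats::lm.fit(cbind(1, d$X), d$y)
  pred_ols <- cbind(1, d$X) %*% ols$coefficients
  expect_equal(predict(f, d$X), as.numeric(pred_ols), tolerance = 1e-8)
})

test_that("PLS predictions agree with PCR/OLS on a well-conditioned problem", {
  d <- sim_xy(n = 80, seed = 8,
              signal = function(X) 2 * X[, 1] - X[, 3] +
                                   rnorm(nrow(X), sd = 0.2))
  f <- fit_base("PLS", d$X, d$y, list(ncomp = 6))
  ols <- stats::lm.fit(cbind(1, d$X), d$y)
  pred_ols <- as.numeric(cbind(1, d$X) %*% ols$coefficients)
  expect_equal(predict(f, d$X), pred_ols, tolerance = 1e-6)
})

test_that("scale-standardizing learners are invariant to predictor rescaling", {
  d <- sim_xy(n = 70, seed = 9,
              signal = function(X) X[, 1] - X[, 2] + rnorm(nrow(X), sd = 0.3))
  resc <- d$X
  resc[, 1] <- resc[, 1] * 1000
  resc[, 2] <- resc[, 2] / 50
  for (nm in c("ENET", "PCR", "PLS", "SVR")) {
    h <- sample_hypers(nm, 1, p = 6, n = 70, seed = 10)[[1]]
    f1 <- fit_base(nm, d$X, d$y, h, seed = 11)
    f2 <- fit_base(nm, resc, d$y, h, seed = 11)
    p1 <- predict(f1, d$X)
    p2 <- predict(f2, resc)
    expect_equal(p1, p2, tolerance = 1e-6, info = nm)
  }
})

test_that("loess filter importance separates a perfect univariate signal", {
  d <- sim_xy(n = 120, seed = 12, signal = function(X) X[, 1])
  vi <- loess_filter_vi(d$X, d$y)
  expect_gt(vi[1], 0.99)
  expect_lt(max(vi[-1]), 0.15)
  # nonlinear signal is also captured (loess, not a linear filter)
  y_nl <- sin(2 * d$X[, 2])
  vi_nl <- loess_filter_vi(d$X, y_nl)
  expect_equal(which.max(vi_nl), 2L)
  # near-binary features fall back gracefully
  Xb <- cbind(d$X, bin = rep(c(0, 1), 60))
  expect_true(all(is.finite(loess_filter_vi(Xb, d$y))))
})

test_that("loess filter importance agrees with the caret reference", {
  skip_if_not_installed("caret")
  d <- sim_xy(n = 90, seed = 13,
              signal = function(X) X[, 1]^2 + rnorm(nrow(X), sd = 0.3))
  vi <- loess_filter_vi(d$X, d$y)
  ref <- caret::filterVarImp(as.data.frame(d$X), d$y, nonpara = TRUE)
  expect_equal(unname(vi), ref$Overall, tolerance = 1e-6)
})

test_that("permutation importance is symmetric for exchangeable predictors", {
  vi_rf <- 0
  vi_cf <- 0
  n_seeds <- 10
  for (seed in seq_len(n_seeds)) {
    d <- sim_xy(n = 250, seed = 20 + seed,
                signal = function(X) X[, 1] + X[, 2] +
                                     rnorm(nrow(X), sd = 0.5))
    f <- fit_base("RF", d$X, d$y, list(mtry = 3), seed = seed,
                  control = fast_control())
    vi_rf <- vi_rf + variable_importance(f, d$X, d$y)[1:2]
    g <- fit_base("CF", d$X, d$y, list(mtry = 3), seed = seed,
                  control = fast_control())
    vi_cf <- vi_cf + variable_importance(g, d$X, d$y)[1:2]
  }
  expect_lt(abs(vi_rf[1] / vi_rf[2] - 1), 0.2)
  expect_lt(abs(vi_cf[1] / vi_cf[2] - 1), 0.2)
})

test_that("forests on pure noise show no spurious inner-CV skill", {
  # with the correlation-based R2, a no-signal learner scores at the null
  # floor (about 1/n), far below any real effect size
  r2s <- vapply(1:8, function(seed) {
    d <- sim_xy(n = 60, seed = 40 + seed,
                signal = function(X) rnorm(nrow(X)))
    fit <- tune_learner("RF", d$X, d$y, k_inner = 4, n_search = 2,
                        seed = seed, control = fast_control(),
                        compute_vi = FALSE)
    fit$train_r2_cv
  }, 0)
  expect_gte(min(r2s), 0)
  expect_lt(mean(r2s), 0.06)
})

test_that("conditional-inference forest is deterministic and finds signal", {
  d <- sim_xy(n = 200, seed = 50,
              signal = function(X) 2 * X[, 1] + rnorm(nrow(X), sd = 0.3))
  f1 <- fit_base("CF", d$X, d$y, list(mtry = 3), seed = 77,
                 control = fast_control())
  f2 <- fit_base("CF", d$X, d$y, list(mtry = 3), seed = 77,
                 control = fast_control())
  expect_identical(predict(f1, d$X), predict(f2, d$X))
  expect_gt(oracle_r2(d$y, predict(f1, d$X)), 0.5)
  vi <- variable_importance(f1, d$X, d$y)
  expect_equal(which.max(vi), 1L, ignore_attr = TRUE)
})

test_that("hyperparameter spaces and complexity orderings are coherent", {
  for (nm in learner_names()) {
    hs <- sample_hypers(nm, 8, p = 20, n = 100, seed = 60)
    keys <- vapply(hs, function(h) complexity_key(nm, h), 0)
    expect_true(all(is.finite(keys)), info = nm)
    # total order: no two sampled settings share a key unless identical
    expect_equal(anyDuplicated(keys[!duplicated(hs)]), 0, info = nm)
  }
  # orientation spot-checks: simpler settings get smaller keys
  expect_lt(complexity_key("ENET", list(lambda = 1, alpha = 0.5)),
            complexity_key("ENET", list(lambda = 1e-3, alpha = 0.5)))
  expect_lt(complexity_key("PCR", list(ncomp = 2)),
            complexity_key("PCR", list(ncomp = 10)))
  expect_lt(complexity_key("SVR", list(cost = 0.1, epsilon = 0.1)),
            complexity_key("SVR", list(cost = 100, epsilon = 0.1)))
  expect_lt(complexity_key("RF", list(mtry = 2)),
            complexity_key("RF", list(mtry = 8)))
})
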