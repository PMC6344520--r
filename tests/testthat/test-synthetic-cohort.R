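test_that("cohort generation is bit-reproducible under a fixed seed", {
  s <- cohort_spec(n_subjects = 80, n_physical = 6, n_psych = 8,
                   n_drug_like = 3, seed = 11)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(a$features$values, b$features$values)
  expect_identical(a$outcome, b$outcome)
  expect_identical(a$truth$loadings, b$truth$loadings)
})

test_that("spec validation rejects infeasible configurations", {
  expect_error(cohort_spec(r2_physical = 1), "r2_physical")
  expect_error(cohort_spec(missing_rate_max = 0.1), "missing_rate_max")
  expect_error(cohort_spec(psych_loading = 1.2), "psych_loading")
  # loadings too weak for the requested block R2
  s <- cohort_spec(n_subjects = 50, r2_physical = 0.9,
                   loading_range = c(0.01, 0.02), anchor_loading = 0.02)
  expect_error(generate_cohort(s), "infeasible calibration")
})

test_that("physical-block calibration matches a large-n OLS oracle", {
  # closed-form calibration claims population R2 = 0.11 for the best linear
  # function of the physical block; check by OLS at n = 1e5
  s <- cohort_spec(n_subjects = 1e5, n_psych = 5, n_drug_like = 2,
                   missing_rate_max = 0, seed = 21)
  ch <- generate_cohort(s)
  X <- select_block(ch$features, "physical")
  r2 <- summary(stats::lm(ch$outcome ~ X))$r.squared
  expect_lt(abs(r2 - 0.11), 0.01)

  # psychological block ditto, against the stored closed-form truth
  Xp <- select_block(ch$features, "psychological")
  r2p <- summary(stats::lm(ch$outcome ~ Xp))$r.squared
  expect_lt(abs(r2p - ch$truth$r2_psych), 0.01)
})

test_that("a zero-R2 spec yields an outcome independent of the predictors", {
  s <- cohort_spec(n_subjects = 4000, n_psych = 10, n_drug_like = 2,
                   r2_physical = 0, missing_rate_max = 0, seed = 31)
  ch <- generate_cohort(s)
  X <- ch$features$values
  cors <- abs(stats::cor(X, ch$outcome))
  # null correlations: none should exceed ~4/sqrt(n)
  expect_true(max(cors) < 4 / sqrt(s$n_subjects))
  expect_equal(ch$truth$outcome_loading, 0)
})

test_that("missingness respects the 6.25% cap and is MCAR", {
  ch <- generate_cohort(cohort_spec(n_subjects = 464, seed = 3))
  miss_frac <- colMeans(is.na(ch$features$values))
  expect_true(max(miss_frac) <= 0.0625)
  expect_true(any(miss_frac > 0))

  # MCAR: per-subject missing count uncorrelated with the outcome; across
  # seeds the 1%-level test should reject at roughly its nominal rate
  rejections <- 0
  n_seeds <- 60
  for (seed in seq_len(n_seeds)) {
    ch_i <- generate_cohort(cohort_spec(n_subjects = 150, n_physical = 5,
                                        n_psych = 10, n_drug_like = 3,
                                        seed = 1000 + seed))
    nm <- rowSums(is.na(ch_i$features$values))
    if (stats::sd(nm) > 0 &&
        stats::cor.test(nm, ch_i$outcome)$p.value < 0.01)
      rejections <- rejections + 1
  }
  expect_lt(rejections, 6)  # ~0.6 expected under MCAR
})

test_that("motion generator: degenerate settings and drift-only calibration", {
  still <- generate_motion_series(n_trs = 50, drift_sd = 0, spike_rate = 0,
                                  seed = 1)
  expect_warning(s <- summarize_motion(still), "undefined")
  expect_equal(s$mean_enorm, 0)

  # drift only: mean per-TR ENORM ~= drift_sd * E[chi_6]
  e_chi6 <- sqrt(2) * gamma(3.5) / gamma(3)
  sigma <- 0.05
  means <- vapply(1:40, function(seed) {
    summarize_motion(generate_motion_series(n_trs = 240, drift_sd = sigma,
                                            spike_rate = 0,
                                            seed = seed))$mean_enorm
  }, 0)
  expect_equal(mean(means), sigma * e_chi6, tolerance = 0.01)
})

test_that("synthetic motion cohort is right-skewed and log reduces the skew", {
  mts <- generate_motion_cohort(n_subjects = 200, seed = 17)
  me <- vapply(mts, function(m) summarize_motion(m)$mean_enorm, 0)
  skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  expect_gt(skew(me), 0.5)            # clearly right-skewed
  expect_lt(abs(skew(log(me))), abs(skew(me)))
})

test_that("feature table CSV + sidecar round-trips", {
  ch <- generate_cohort(cohort_spec(n_subjects = 30, n_physical = 4,
                                    n_psych = 5, n_drug_like = 2, seed = 2))
  f <- tempfile(fileext = ".csv")
  write_feature_table(ch$features, f)
  back <- read_feature_table(f)
  expect_equal(back$values, ch$features$values)
  expect_identical(back$block, ch$features$block)
  expect_identical(back$subblock, ch$features$subblock)
  unlink(c(f, sub("\\.csv$", ".labels.tsv", f)))
})

test_that("motion .1D files round-trip through writer and reader", {
  mp <- generate_motion_series(n_trs = 20, seed = 9)
  f <- tempfile(fileext = ".1D")
  write_motion_params(mp, f)
  back <- read_motion_params(f)
  expect_equal(back$values, mp$values, tolerance = 1e-8)
  unlink(f)
})
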