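make_table <- function(values, n_phys = ncol(values)) {
  vars <- colnames(values)
  block <- stats::setNames(
    c(rep("physical", n_phys), rep("psychological", ncol(values) - n_phys)),
    vars)
  sub <- stats::setNames(
    c(rep(NA_character_, n_phys), rep("nondrug", ncol(values) - n_phys)),
    vars)
  feature_table(values, block = block, subblock = sub, max_missing = 1)
}

test_that("imputation leaves complete tables untouched (idempotence)", {
  ch <- small_cohort(n = 40)
  out <- knn_impute(ch$features, k = 3)
  expect_identical(out$values, ch$features$values)
  # and is idempotent after one pass on an incomplete table
  ch2 <- generate_cohort(cohort_spec(n_subjects = 60, n_physical = 5,
                                     n_psych = 5, n_drug_like = 2, seed = 8))
  once <- knn_impute(ch2$features, k = 3)
  twice <- knn_impute(once, k = 3)
  expect_identical(once$values, twice$values)
})

test_that("k = 1 imputation copies the nearest subject's value", {
  vals <- cbind(a = c(0, 0.1, 10), b = c(1, NA, 50))
  tab <- make_table(vals)
  out <- knn_impute(tab, k = 1)
  # subject 2 is far closer to subject 1 than to subject 3 on variable a
  expect_equal(unname(out$values[2, "b"]), 1)
  # observed cells unchanged
  expect_equal(unname(out$values[-2, ]), unname(vals[-2, ]))
})

test_that("imputed values beat mean-zero noise in a mask-and-recover test", {
  # recovery is only possible where variables are correlated, so the
  # fixture uses a strongly latent-loaded block; independent variables
  # cannot do better than about SD * sqrt(1 + 1/k), which bounds the rest
  for (seed in 1:5) {
    ch <- generate_cohort(cohort_spec(n_subjects = 150, n_physical = 8,
                                      n_psych = 4, n_drug_like = 2,
                                      missing_rate_max = 0,
                                      loading_range = c(0.8, 1.2),
                                      seed = 100 + seed))
    vals <- ch$features$values
    set.seed(seed)
    mask <- matrix(stats::runif(length(vals)) < 0.15, nrow(vals))
    hidden <- vals
    hidden[mask] <- NA
    tab <- ch$features
    tab$values <- hidden
    out <- knn_impute(tab, k = 5)
    loads <- ch$truth$loadings
    strong <- names(loads)[loads >= 0.8]
    err2 <- c(strong = 0, weak = 0)
    ref2 <- c(strong = 0, weak = 0)
    for (jn in colnames(vals)) {
      j <- match(jn, colnames(vals))
      if (!any(mask[, j])) next
      grp <- if (jn %in% strong) "strong" else "weak"
      err2[grp] <- err2[grp] +
        sum((out$values[mask[, j], j] - vals[mask[, j], j])^2)
      ref2[grp] <- ref2[grp] + sum(mask[, j]) * stats::var(vals[, j])
    }
    # pooled over the correlated block, imputation beats mean-zero noise;
    # independent variables floor at about SD * sqrt(1 + 1/k) ~ 1.1 SD
    expect_lt(err2[["strong"]], ref2[["strong"]])
    expect_lt(err2[["weak"]], 1.5^2 * ref2[["weak"]])
  }
})

test_that("imputation errors name fully-missing variables and bad k", {
  vals <- cbind(a = c(1, 2, 3), b = c(NA, NA, NA))
  tab <- make_table(vals)
  expect_error(knn_impute(tab, k = 1), "unimputable.*b")
  expect_error(knn_impute(make_table(cbind(a = c(1, NA, 3),
                                           b = c(0, 1, 2))), k = 3),
               "k must be smaller")
})

test_that("residualized psychological block is orthogonal to the physical block", {
  ch <- small_cohort(n = 80, seed = 12)
  imp <- knn_impute(ch$features, k = 5)
  res <- residualize_psychological(imp)
  phys <- imp$values[, imp$block == "physical"]
  expect_lt(max(abs(stats::cor(res$values, phys))), 1e-10)
  expect_lt(max(abs(colMeans(res$values))), 1e-10)  # intercept removed
  expect_true(all(res$block == "psychological"))
  expect_equal(ncol(res$values), sum(imp$block == "psychological"))
})

test_that("residualization degenerate cases: collinearity and independence", {
  set.seed(4)
  n <- 50
  phys <- matrix(rnorm(n * 3), n, 3,
                 dimnames = list(NULL, c("p1", "p2", "p3")))
  psy_dup <- 2 * phys[, 1]              # exactly collinear with physical
  psy_ind <- rnorm(n)                   # independent of physical block
  vals <- cbind(phys, q_dup = psy_dup, q_ind = psy_ind)
  tab <- make_table(vals, n_phys = 3)
  res <- residualize_psychological(tab)
  expect_lt(max(abs(res$values[, "q_dup"])), 1e-10)
  # independent variable survives nearly unchanged (variance shrinks by at
  # most the chance R2 of 3 covariates)
  expect_gt(stats::var(res$values[, "q_ind"]) / stats::var(psy_ind), 0.8)

  # rank-deficient physical block is refused with the culprit named
  vals_bad <- cbind(phys, p_dup = phys[, 1], q = rnorm(n))
  tab_bad <- make_table(vals_bad, n_phys = 4)
  expect_error(residualize_psychological(tab_bad), "rank deficient.*p_dup")

  # incomplete tables are refused
  vals_na <- vals
  vals_na[1, 1] <- NA
  expect_error(residualize_psychological(make_table(vals_na, n_phys = 3)),
               "imputed")
})
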