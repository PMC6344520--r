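# Repeated nested cross-validation around the stacked ensemble. The inner
# loop tunes each base learner by k_inner-fold CV with random search and the
# one-SE rule; the outer loop evaluates the stacked model on held-out folds;
# pooled outer predictions give one R2 per repeat; fold-level stacked
# variable importance is averaged across folds.

#' Plan for a repeated nested cross-validation run
#'
#' @param k_inner inner folds for hyperparameter tuning (default 10).
#' @param k_outer outer folds for performance evaluation (default 10).
#' @param n_repeats number of repeats of the whole nested CV (default 20).
#' @param n_search random-search candidates per learner: a single number,
#'   or a named vector/list with one entry per learner name to give cheap
#'   learners a wider search than expensive ones (default 20).
#' @param seed master seed; all repeat-, fold- and learner-level seeds are
#'   derived from it, so runs are bit-reproducible.
#' @param learners learner names to include (default all six).
#' @param control a [learner_control()].
#' @return list of class `cv_plan`.
#' @export
cv_plan <- function(k_inner = 10, k_outer = 10, n_repeats = 20,
                    n_search = 20, seed = 1, learners = learner_names(),
                    control = learner_control()) {
  stopifnot(k_inner >= 2, k_outer >= 2, n_repeats >= 1,
            all(learners %in% learner_names()))
  structure(list(k_inner = as.integer(k_inner),
                 k_outer = as.integer(k_outer),
                 n_repeats = as.integer(n_repeats), n_search = n_search,
                 seed = as.integer(seed), learners = learners,
                 control = control),
            class = "cv_plan")
}

search_size <- function(plan, name) {
  ns <- plan$n_search
  if (length(ns) == 1 && is.null(names(ns))) return(as.integer(ns))
  if (!is.null(names(ns)) && name %in% names(ns))
    return(as.integer(ns[[name]]))
  as.integer(if (!is.null(ns[["default"]])) ns[["default"]] else 20L)
}

fold_assignment <- function(n, k) {
  sample(rep(seq_len(k), length.out = n))
}

#' Tune, select and refit one base learner
#'
#' Random-search candidates are scored by `k_inner`-fold CV R-squared
#' (per-fold squared correlation of observed and predicted, averaged over
#' folds; SE = fold SD / sqrt(k)); the one-SE rule picks the simplest
#' near-best setting; the learner is refit on all rows with the chosen
#' setting and its raw variable importance is computed on that refit. The
#' returned object carries `train_r2_cv`, the R-squared of the chosen
#' setting's pooled inner-CV validation predictions (the learner's single
#' set of cross-validated predicted values) — the "expected out-of-sample
#' R-squared" used as its stacking weight.
#'
#' @param name learner name.
#' @param X complete training matrix.
#' @param y outcome.
#' @param k_inner number of inner folds.
#' @param n_search number of random-search candidates.
#' @param seed integer seed (candidates, folds, and stochastic fits).
#' @param control a [learner_control()].
#' @param compute_vi also compute raw variable importance on the refit
#'   (default TRUE).
#' @return A `fitted_base` with `train_r2_cv` and (optionally) `vi_raw`.
#' @export
tune_learner <- function(name, X, y, k_inner = 10, n_search = 20, seed = 1,
                         control = learner_control(), compute_vi = TRUE) {
  n <- nrow(X)
  cands <- sample_hypers(name, n_search, p = ncol(X), n = n, seed = seed,
                         control = control)
  set.seed(seed + 1L)
  folds <- fold_assignment(n, k_inner)
  fit_seeds <- matrix(sample.int(2147483646L, length(cands) * k_inner),
                      length(cands), k_inner)

  scores <- matrix(NA_real_, length(cands), k_inner)
  cv_preds <- matrix(NA_real_, length(cands), n)
  for (ci in seq_along(cands)) {
    for (f in seq_len(k_inner)) {
      tr <- folds != f
      fit <- fit_base(name, X[tr, , drop = FALSE], y[tr], cands[[ci]],
                      seed = fit_seeds[ci, f], control = control,
                      compute_vi = FALSE)
      pred <- predict(fit, X[!tr, , drop = FALSE])
      scores[ci, f] <- r2_cor(y[!tr], pred)
      cv_preds[ci, !tr] <- pred
    }
  }
  mean_r2 <- rowMeans(scores)
  se_r2 <- apply(scores, 1, stats::sd) / sqrt(k_inner)
  cmplx <- vapply(cands, function(h) complexity_key(name, h), 0)
  chosen <- one_se_select(mean_r2, se_r2, cmplx, cands)

  fit <- fit_base(name, X, y, cands[[chosen]], seed = seed,
                  control = control)
  fit$train_r2_cv <- r2_cor(y, cv_preds[chosen, ])
  fit$cv_scores <- data.frame(
    candidate = seq_along(cands), mean_r2 = mean_r2, se_r2 = se_r2,
    complexity = cmplx, chosen = seq_along(cands) == chosen)
  if (compute_vi) fit$vi_raw <- variable_importance(fit, X, y)
  fit
}

#' Repeated nested cross-validation of the stacked ensemble
#'
#' For every repeat, subjects are partitioned into `k_outer` folds. On each
#' outer-training set all requested learners are tuned ([tune_learner()]),
#' stacked ([stack_ensemble()]), and used to predict the held-out fold;
#' the pooled outer predictions give the repeat's R-squared (squared
#' correlation `r2`, the caret convention, plus the variance-decomposition
#' `r2_ss`). Stacked
#' variable importance (0-100) is computed per fold from the outer-training
#' refits and averaged across folds. Nothing from an outer validation fold
#' influences tuning, fitting, or the stacking weights.
#'
#' @param X complete numeric predictor matrix (use [knn_impute()] first),
#'   or a complete [feature_table()] combined with `subset`.
#' @param y numeric outcome (log mean ENORM).
#' @param plan a [cv_plan()].
#' @param subset when `X` is a [feature_table()]: `"all"`, `"physical"`,
#'   `"psychological"`, or `"residualized"` (psychological residuals on the
#'   physical block).
#' @return Object of class `ncv_result`: a list of per-repeat results, each
#'   with `pooled_predictions`, `r2`, `stacked_vi`, `fold_ids`,
#'   `mean_weights`, and a `train_fingerprint` audit vector (one checksum
#'   of the sorted outer-training indices per fold).
#' @export
nested_cv <- function(X, y, plan = cv_plan(), subset = "all") {
  if (inherits(X, "feature_table")) {
    if (anyNA(X$values))
      stop("feature table contains missing values; run knn_impute() first")
    X <- if (subset == "residualized")
      residualize_psychological(X)$values
    else select_block(X, subset)
  }
  stopifnot(is.matrix(X), !anyNA(X), length(y) == nrow(X))
  if (ncol(X) == 0) stop("no predictors selected")
  n <- nrow(X)

  set.seed(plan$seed)
  repeat_seeds <- sample.int(2147483646L, plan$n_repeats)

  repeats <- vector("list", plan$n_repeats)
  for (r in seq_len(plan$n_repeats)) {
    set.seed(repeat_seeds[r])
    folds <- fold_assignment(n, plan$k_outer)
    tune_seeds <- matrix(sample.int(2147483646L,
                                    plan$k_outer * length(plan$learners)),
                         plan$k_outer, length(plan$learners))

    preds <- numeric(n)
    vi_folds <- matrix(NA_real_, plan$k_outer, ncol(X),
                       dimnames = list(NULL, colnames(X)))
    w_folds <- matrix(NA_real_, plan$k_outer, length(plan$learners),
                      dimnames = list(NULL, plan$learners))
    fingerprints <- numeric(plan$k_outer)

    for (f in seq_len(plan$k_outer)) {
      tr <- folds != f
      fingerprints[f] <- sum(which(tr) * 1.0)
      Xtr <- X[tr, , drop = FALSE]
      ytr <- y[tr]
      bases <- lapply(seq_along(plan$learners), function(li) {
        tune_learner(plan$learners[li], Xtr, ytr,
                     k_inner = plan$k_inner,
                     n_search = search_size(plan, plan$learners[li]),
                     seed = tune_seeds[f, li], control = plan$control,
                     compute_vi = TRUE)
      })
      ens <- stack_ensemble(bases)
      preds[!tr] <- predict(ens, X[!tr, , drop = FALSE])
      vi_folds[f, ] <- stacked_vi(lapply(bases, function(b) b$vi_raw),
                                  ens$weights)
      w_folds[f, ] <- ens$weights
    }

    repeats[[r]] <- list(
      pooled_predictions = preds,
      r2 = r2_cor(y, preds),
      r2_ss = pooled_r2(y, preds),
      stacked_vi = colMeans(vi_folds),
      fold_ids = folds,
      mean_weights = colMeans(w_folds),
      train_fingerprint = fingerprints)
  }
  structure(repeats, class = "ncv_result",
            learners = plan$learners, n = n, p = ncol(X),
            variables = colnames(X))
}

#' Summarize repeated nested-CV results
#'
#' Mean and 95% confidence interval (mean +/- 1.96 times the SD of the
#' repeat-level values) of the pooled R-squared and of each variable's
#' stacked importance.
#'
#' @param repeats an `ncv_result` from [nested_cv()].
#' @return Object of class `study_summary` with `r2` (per-repeat values,
#'   mean, sd, ci) and `vi` (matrix of per-repeat importances, mean, ci).
#' @export
summarize_repeats <- function(repeats) {
  stopifnot(inherits(repeats, "ncv_result"))
  r2s <- vapply(repeats, function(r) r$r2, 0)
  vis <- do.call(rbind, lapply(repeats, function(r) r$stacked_vi))
  degenerate <- length(r2s) < 2
  if (degenerate)
    warning("single repeat: confidence intervals are degenerate")
  sd_r2 <- if (degenerate) 0 else stats::sd(r2s)
  sd_vi <- if (degenerate) rep(0, ncol(vis)) else apply(vis, 2, stats::sd)
  r2ss <- vapply(repeats, function(r)
    if (is.null(r$r2_ss)) NA_real_ else r$r2_ss, 0)
  structure(list(
    r2 = list(values = r2s, mean = mean(r2s), sd = sd_r2,
              ci = mean(r2s) + c(-1, 1) * 1.96 * sd_r2),
    r2_ss = list(values = r2ss, mean = mean(r2ss)),
    vi = list(values = vis, mean = colMeans(vis),
              ci = cbind(lo = colMeans(vis) - 1.96 * sd_vi,
                         hi = colMeans(vis) + 1.96 * sd_vi)),
    n_repeats = length(r2s), degenerate = degenerate),
    class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("<study_summary> %d repeats: R2 = %.3f (95%% CI %.3f to %.3f)\n",
              x$n_repeats, x$r2$mean, x$r2$ci[1], x$r2$ci[2]))
  top <- sort(x$vi$mean, decreasing = TRUE)
  cat("top variables:", paste(names(utils::head(top, 5)), collapse = ", "),
      "\n")
  invisible(x)
}
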