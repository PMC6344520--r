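# Stacking algebra: one-SE hyperparameter selection, R2-weighted model
# averaging, and 0-100 scaled stacked variable importance.

#' One-standard-error hyperparameter selection
#'
#' Returns the index of the simplest candidate whose mean inner-CV
#' R-squared is at least `max(mean) - se[best]`, where `se` is the standard
#' error of the fold scores of the best candidate. Ties on complexity are
#' broken by a deterministic serialization of the setting.
#'
#' @param mean_r2 mean inner-CV R-squared per candidate.
#' @param se_r2 standard error (fold SD / sqrt(k)) per candidate.
#' @param complexity complexity key per candidate (larger = more complex).
#' @param settings optional list of hyperparameter lists used only for
#'   deterministic tie-breaking.
#' @return integer index of the selected candidate.
#' @export
one_se_select <- function(mean_r2, se_r2, complexity, settings = NULL) {
  n <- length(mean_r2)
  if (n == 0) stop("no candidate settings to select from")
  stopifnot(length(se_r2) == n, length(complexity) == n)
  best <- which.max(mean_r2)
  threshold <- mean_r2[best] - se_r2[best]
  eligible <- which(mean_r2 >= threshold)
  keys <- if (is.null(settings)) as.character(seq_len(n))
          else vapply(settings, function(s)
            paste(names(s), vapply(s, format, "", digits = 15),
                  collapse = ";"), "")
  eligible[order(complexity[eligible], keys[eligible])][1]
}

#' Combine fitted base learners into a stacked ensemble
#'
#' Weights are proportional to each base's expected out-of-sample
#' R-squared from the inner CV, clamped at zero (a weighted mean with
#' negative weights is uninterpretable); if every base has non-positive
#' R-squared the weights fall back to uniform.
#'
#' @param bases list of `fitted_base` objects with `train_r2_cv` populated.
#' @return An object of class `stacked_ensemble` with fields `bases` and
#'   `weights` (non-negative, summing to 1).
#' @export
stack_ensemble <- function(bases) {
  stopifnot(length(bases) >= 1,
            all(vapply(bases, inherits, TRUE, "fitted_base")))
  r2 <- vapply(bases, function(b) b$train_r2_cv, 0)
  if (anyNA(r2)) stop("all bases need train_r2_cv before stacking")
  w <- pmax(r2, 0)
  if (sum(w) <= 0) w <- rep(1, length(w))
  w <- w / sum(w)
  structure(list(bases = bases, weights = w,
                 learner = vapply(bases, function(b) b$name, "")),
            class = "stacked_ensemble")
}

#' @export
print.stacked_ensemble <- function(x, ...) {
  cat("<stacked_ensemble>\n")
  print(round(stats::setNames(x$weights, x$learner), 3))
  invisible(x)
}

#' Predict from a stacked ensemble
#'
#' The weighted arithmetic mean of the base-learner predictions.
#'
#' @param object a `stacked_ensemble`.
#' @param newdata numeric matrix.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.stacked_ensemble <- function(object, newdata, ...) {
  preds <- vapply(object$bases, predict, numeric(nrow(newdata)),
                  newdata = newdata)
  as.numeric(preds %*% object$weights)
}

scale_0_100 <- function(v) {
  rng <- range(v)
  if (rng[2] - rng[1] <= 0) return(rep(0, length(v)))
  100 * (v - rng[1]) / (rng[2] - rng[1])
}

#' Stacked variable importance on the 0-100 scale
#'
#' Each base's raw importance vector is min-max scaled to `[0, 100]`
#' (a constant vector contributes uniform zeros), then the scaled vectors
#' are averaged with the stacking weights.
#'
#' @param vi_list list of raw importance vectors (equal length).
#' @param weights stacking weights (non-negative, summing to 1).
#' @return numeric vector in `[0, 100]`.
#' @export
stacked_vi <- function(vi_list, weights) {
  stopifnot(length(vi_list) == length(weights))
  scaled <- lapply(vi_list, scale_0_100)
  out <- Reduce(`+`, Map(`*`, scaled, weights))
  stats::setNames(as.numeric(out), names(vi_list[[1]]))
}

#' Pooled R-squared of predictions against observations
#'
#' The primary performance metric of the pipeline: the squared Pearson
#' correlation between observed and predicted values, the regression
#' R-squared convention of the caret modeling framework. It is
#' non-negative, so a no-signal model scores near `1/n` rather than
#' slightly negative. Predictions with zero variance (e.g. a fully
#' shrunken elastic net) score 0.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return numeric scalar in `[0, 1]`.
#' @export
r2_cor <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) return(0)
  stats::cor(observed, predicted)^2
}

#' Variance-decomposition R-squared
#'
#' `1 - SS_res / SS_tot`; can be negative for models worse than predicting
#' the mean. Reported alongside [r2_cor()] for diagnostic purposes.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return numeric scalar <= 1.
#' @export
pooled_r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}
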