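# The six base learners behind one contract: sample_hypers() draws
# random-search candidates, complexity_key() orders settings for the one-SE
# rule (larger = more complex), fit_base() fits, predict() predicts, and
# variable_importance() returns the learner's own importance measure:
#   ENET       |standardized coefficients|
#   PCR / PLS  |implied standardized coefficients| (loading-weighted sums)
#   RF / CF    increase in out-of-bag MSE under per-feature permutation
#   SVR        loess "filter" R2 of y on each feature alone

#' Names of the six base learners
#' @return character vector `c("ENET","PCR","PLS","SVR","RF","CF")`.
#' @export
learner_names <- function() c("ENET", "PCR", "PLS", "SVR", "RF", "CF")

#' Shared tuning knobs of the base learners
#'
#' @param num_trees trees per forest for RF and CF (default 500).
#' @param min_node minimum node size for the forests (default 5).
#' @param cif_alpha stopping level for the conditional-inference forest's
#'   per-node association test (default 0.05, Bonferroni-corrected over the
#'   `mtry` candidates).
#' @param cif_subsample subsampling fraction (without replacement) for CF
#'   trees (default 0.632).
#' @param cif_max_depth depth cap for CF trees (default 30, effectively
#'   unbounded; the association test is the usual stopping rule).
#' @param loess_span,loess_degree loess parameters of the SVR filter
#'   importance (defaults 0.75 and 2).
#' @param max_components upper bound on PCR/PLS components (default 30).
#' @return list of class `learner_control`.
#' @export
learner_control <- function(num_trees = 500, min_node = 5, cif_alpha = 0.05,
                            cif_subsample = 0.632, cif_max_depth = 30,
                            loess_span = 0.75, loess_degree = 2,
                            max_components = 30) {
  structure(list(num_trees = num_trees, min_node = min_node,
                 cif_alpha = cif_alpha, cif_subsample = cif_subsample,
                 cif_max_depth = cif_max_depth, loess_span = loess_span,
                 loess_degree = loess_degree,
                 max_components = max_components),
            class = "learner_control")
}

#' Draw random-search hyperparameter candidates for one learner
#'
#' Search spaces: ENET penalty `lambda` log-uniform on `[1e-4, 1]` with mix
#' `alpha` uniform on `[0, 1]`; PCR/PLS `ncomp` uniform over
#' `1..min(max_components, p, n-2)`; SVR `cost` log-uniform on `[1e-2, 1e3]`
#' and `epsilon` log-uniform on `[1e-3, 1]`; RF/CF `mtry` uniform over
#' `floor(sqrt(p))..floor(p/3)`. Discrete spaces are sampled without
#' replacement, so fewer than `n_search` candidates may be returned.
#'
#' @param name learner name (see [learner_names()]).
#' @param n_search number of candidates to draw.
#' @param p number of predictors.
#' @param n number of training rows.
#' @param seed integer seed.
#' @param control a [learner_control()].
#' @return list of hyperparameter lists.
#' @export
sample_hypers <- function(name, n_search, p, n, seed = 1,
                          control = learner_control()) {
  set.seed(seed)
  switch(name,
    ENET = lapply(seq_len(n_search), function(i)
      list(lambda = 10^stats::runif(1, -4, 0), alpha = stats::runif(1))),
    PCR = ,
    PLS = {
      kmax <- max(1L, min(control$max_components, p, n - 2L))
      ks <- sample(seq_len(kmax), min(n_search, kmax))
      lapply(ks, function(k) list(ncomp = k))
    },
    SVR = lapply(seq_len(n_search), function(i)
      list(cost = 10^stats::runif(1, -2, 3),
           epsilon = 10^stats::runif(1, -3, 0))),
    RF = ,
    CF = {
      lo <- max(1L, floor(sqrt(p)))
      hi <- max(lo, floor(p / 3))
      ms <- sample(seq(lo, hi), min(n_search, hi - lo + 1L))
      lapply(ms, function(m) list(mtry = m))
    },
    stop("unknown learner: ", name)
  )
}

#' Complexity key of a hyperparameter setting (larger = more complex)
#'
#' Orders settings for the one-SE rule: larger penalty, fewer components,
#' smaller cost, and smaller mtry are simpler. Secondary terms make the
#' ordering total.
#'
#' @inheritParams sample_hypers
#' @param hypers one hyperparameter list.
#' @return numeric scalar.
#' @export
complexity_key <- function(name, hypers) {
  switch(name,
    ENET = -log10(hypers$lambda) + 1e-9 * hypers$alpha,
    PCR = ,
    PLS = as.numeric(hypers$ncomp),
    SVR = log10(hypers$cost) - 1e-9 * log10(hypers$epsilon),
    RF = ,
    CF = as.numeric(hypers$mtry),
    stop("unknown learner: ", name)
  )
}

drop_constant_columns <- function(X) {
  sds <- apply(X, 2, stats::sd)
  keep <- is.finite(sds) & sds > 0
  if (!any(keep)) stop("all predictors are constant")
  list(X = X[, keep, drop = FALSE], keep = keep)
}

#' Fit one base learner
#'
#' @param name learner name.
#' @param X complete numeric training matrix with column names.
#' @param y numeric outcome.
#' @param hypers hyperparameter list from [sample_hypers()].
#' @param seed seed for the stochastic learners (RF, CF).
#' @param control a [learner_control()].
#' @param compute_vi prepare the forest importance measures during the fit
#'   (default TRUE; tuning fits pass FALSE since only predictions are
#'   scored there).
#' @return An object of class `fitted_base`.
#' @export
fit_base <- function(name, X, y, hypers, seed = 1,
                     control = learner_control(), compute_vi = TRUE) {
  stopifnot(is.matrix(X), !anyNA(X), length(y) == nrow(X))
  if (stats::sd(y) == 0) stop("degenerate outcome: zero variance")
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%03d", seq_len(ncol(X)))
  full_names <- colnames(X)
  dc <- drop_constant_columns(X)
  X <- dc$X
  p <- ncol(X)

  model <- switch(name,
    ENET = glmnet::glmnet(X, y, alpha = hypers$alpha,
                          lambda = hypers$lambda, standardize = TRUE),
    PCR = {
      ctr <- colMeans(X)
      scl <- apply(X, 2, stats::sd)
      Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
      sv <- svd(Z)
      rank <- sum(sv$d > sv$d[1] * 1e-10)
      k <- min(hypers$ncomp, rank)
      dk <- sv$d[seq_len(k)]
      # orthogonal scores: component coefficients by simple projections
      gam <- crossprod(sv$u[, seq_len(k), drop = FALSE], y - mean(y)) / dk
      coef_std <- sv$v[, seq_len(k), drop = FALSE] %*% gam
      list(center = ctr, scale = scl, coef_std = drop(coef_std),
           intercept = mean(y), ncomp_used = k)
    },
    PLS = {
      kmax <- max(1L, min(hypers$ncomp, p, nrow(X) - 2L))
      m <- mixOmics::pls(X, y, ncomp = kmax, mode = "regression",
                         scale = TRUE)
      list(fit = m, ncomp_used = kmax, scale = apply(X, 2, stats::sd))
    },
    SVR = e1071::svm(x = X, y = y, type = "eps-regression",
                     kernel = "radial", cost = hypers$cost,
                     epsilon = hypers$epsilon, scale = TRUE),
    RF = ranger::ranger(x = X, y = y, num.trees = control$num_trees,
                        mtry = min(hypers$mtry, p),
                        min.node.size = control$min_node,
                        importance = if (compute_vi) "permutation" else "none",
                        scale.permutation.importance = FALSE,
                        seed = seed, num.threads = 1),
    CF = {
      fit <- cif_fit_cpp(X, y, num_trees = control$num_trees,
                         mtry = min(hypers$mtry, p),
                         min_node = control$min_node,
                         alpha = control$cif_alpha,
                         subsample = control$cif_subsample,
                         max_depth = control$cif_max_depth,
                         seed = seed, importance = compute_vi)
      fit$colnames <- colnames(X)
      fit
    },
    stop("unknown learner: ", name)
  )

  structure(list(name = name, hypers = hypers, model = model,
                 feature_names = full_names, keep = dc$keep,
                 train_r2_cv = NA_real_, vi_raw = NULL, seed = seed,
                 control = control),
            class = "fitted_base")
}

#' @export
print.fitted_base <- function(x, ...) {
  cat("<fitted_base>", x$name, "- inner-CV R2:",
      format(x$train_r2_cv, digits = 3), "\n")
  invisible(x)
}

#' Predict from a fitted base learner
#'
#' @param object a `fitted_base`.
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @return numeric vector of predictions on the outcome scale.
#' @export
predict.fitted_base <- function(object, newdata, ...) {
  X <- newdata[, object$feature_names[object$keep], drop = FALSE]
  m <- object$model
  out <- switch(object$name,
    ENET = as.numeric(stats::predict(m, X, s = object$hypers$lambda)),
    PCR = {
      Z <- sweep(sweep(X, 2, m$center), 2, m$scale, "/")
      as.numeric(Z %*% m$coef_std) + m$intercept
    },
    PLS = {
      if (is.null(rownames(X)))
        rownames(X) <- sprintf("r%05d", seq_len(nrow(X)))
      pr <- stats::predict(m$fit, X)
      as.numeric(pr$predict[, 1, m$ncomp_used])
    },
    SVR = as.numeric(stats::predict(m, X)),
    RF = ranger::predictions(stats::predict(m, data = X,
                                            num.threads = 1)),
    CF = as.numeric(cif_predict_cpp(m$trees, X)),
    stop("unknown learner: ", object$name)
  )
  unname(out)
}

#' Loess filter variable importance
#'
#' The SVR importance measure: the outcome is regressed on each feature
#' alone with a loess smoother and the R-squared of that fit is the
#' feature's importance. Features where loess cannot fit (e.g. near-binary)
#' fall back to a linear fit; zero-variance features score 0.
#'
#' @param X numeric matrix.
#' @param y numeric outcome.
#' @param span,degree loess parameters (defaults 0.75 and 2).
#' @return non-negative numeric vector, one entry per column of `X`.
#' @export
loess_filter_vi <- function(X, y, span = 0.75, degree = 2) {
  sst <- sum((y - mean(y))^2)
  vi <- apply(X, 2, function(x) {
    if (stats::sd(x) == 0 || sst == 0) return(0)
    r2 <- tryCatch({
      fit <- stats::loess(y ~ x, span = span, degree = degree,
                          data = data.frame(x = x, y = y))
      1 - sum(stats::residuals(fit)^2) / sst
    }, error = function(e) NA_real_, warning = function(w) NA_real_)
    if (!is.finite(r2))
      r2 <- stats::cor(x, y)^2
    min(max(r2, 0), 1)
  })
  unname(vi)
}

#' Learner-specific variable importance
#'
#' Returns the raw (unscaled) importance vector of a fitted base learner,
#' one non-negative value per training predictor (in training column
#' order): absolute standardized coefficients for ENET, absolute implied
#' standardized coefficients for PCR and PLS, unscaled permutation increase
#' in out-of-bag MSE for RF and CF (negatives floored at 0), and the loess
#' filter R-squared for SVR.
#'
#' @param object a `fitted_base`.
#' @param X training matrix (needed for the SVR filter and coefficient
#'   standardization).
#' @param y training outcome (needed for the SVR filter).
#' @return named non-negative numeric vector of length `ncol(X)`.
#' @export
variable_importance <- function(object, X, y) {
  stopifnot(inherits(object, "fitted_base"))
  Xk <- X[, object$feature_names[object$keep], drop = FALSE]
  m <- object$model
  vi_kept <- switch(object$name,
    ENET = {
      b <- as.numeric(stats::coef(m, s = object$hypers$lambda))[-1]
      abs(b) * apply(Xk, 2, stats::sd)
    },
    PCR = abs(m$coef_std),
    PLS = {
      # implied coefficients via exact finite differences (the PLS
      # prediction is linear in X); step = 1 SD gives standardized scale
      x0 <- colMeans(Xk)
      probe <- rbind(x0, sweep(diag(m$scale, ncol(Xk)), 2, x0, "+"))
      dimnames(probe) <- list(sprintf("probe%03d", seq_len(nrow(probe))),
                              colnames(Xk))
      pr <- stats::predict(m$fit, probe)$predict[, 1, m$ncomp_used]
      abs(pr[-1] - pr[1])
    },
    SVR = loess_filter_vi(Xk, y, span = object$control$loess_span,
                          degree = object$control$loess_degree),
    RF = pmax(m$variable.importance, 0),
    CF = pmax(as.numeric(m$importance), 0),
    stop("unknown learner: ", object$name)
  )
  vi <- stats::setNames(numeric(length(object$feature_names)),
                        object$feature_names)
  vi[object$feature_names[object$keep]] <- as.numeric(vi_kept)
  vi
}
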