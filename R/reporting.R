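# Reporting: massive-univariate comparison statistics, partial-dependence
# curves, and the four-model study report (physical / psychological /
# combined / residualized psychological).

#' Univariate Pearson correlations of every predictor with the outcome
#'
#' For each variable: Pearson r, Fisher-z 95% confidence interval,
#' Benjamini-Hochberg FDR-corrected p-value across all variables in the
#' table, and the sign of the association. Zero-variance variables are
#' reported as undefined (`NA`) and excluded from the FDR family;
#' correlations of exactly +/-1 get a degenerate CI and are flagged.
#'
#' @param X complete numeric matrix or complete [feature_table()].
#' @param y numeric outcome.
#' @return data.frame of class `correlation_report` with columns
#'   `variable, r, ci_lo, ci_hi, p, p_fdr, sign, flag`.
#' @export
univariate_correlations <- function(X, y) {
  if (inherits(X, "feature_table")) X <- X$values
  stopifnot(is.matrix(X), !anyNA(X), length(y) == nrow(X))
  n <- nrow(X)
  rows <- lapply(colnames(X), function(v) {
    x <- X[, v]
    if (stats::sd(x) == 0)
      return(data.frame(variable = v, r = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, p = NA_real_,
                        sign = NA_character_, flag = "zero_variance",
                        stringsAsFactors = FALSE))
    r <- stats::cor(x, y)
    if (abs(r) >= 1 - 1e-12) {
      data.frame(variable = v, r = r, ci_lo = r, ci_hi = r, p = 0,
                 sign = if (r >= 0) "+" else "-", flag = "degenerate",
                 stringsAsFactors = FALSE)
    } else {
      z <- atanh(r)
      hw <- 1.96 / sqrt(n - 3)
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      data.frame(variable = v, r = r, ci_lo = tanh(z - hw),
                 ci_hi = tanh(z + hw),
                 p = 2 * stats::pt(-abs(tstat), n - 2),
                 sign = if (r >= 0) "+" else "-", flag = "",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p)
  out$p_fdr[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  class(out) <- c("correlation_report", "data.frame")
  out
}

#' Partial-dependence curve of one variable under a stacked ensemble
#'
#' The variable is swept over a quantile grid (quantiles rather than a
#' uniform grid, to handle skewed predictors); at each grid value the curve
#' is the mean stacked prediction over all subjects with that variable
#' forced to the grid value and everything else at its observed values.
#'
#' @param ensemble a `stacked_ensemble` (or single `fitted_base`).
#' @param X the predictor matrix the ensemble was trained on.
#' @param variable variable (column) name.
#' @param n_grid number of quantile grid points (default 20).
#' @return data.frame of class `pdp_curve` with columns `grid` (strictly
#'   increasing) and `mean_prediction`.
#' @export
partial_dependence <- function(ensemble, X, variable, n_grid = 20) {
  stopifnot(is.matrix(X))
  if (!variable %in% colnames(X))
    stop("variable '", variable, "' is not in the model")
  grid <- unique(stats::quantile(X[, variable],
                                 probs = seq(0, 1, length.out = n_grid),
                                 names = FALSE, type = 7))
  mp <- vapply(grid, function(g) {
    Xg <- X
    Xg[, variable] <- g
    mean(predict(ensemble, Xg))
  }, 0)
  structure(data.frame(grid = grid, mean_prediction = mp),
            class = c("pdp_curve", "data.frame"), variable = variable)
}

#' Full study report: four predictor-subset models plus univariate table
#'
#' Imputes the cohort's feature table once ([knn_impute()]), then runs
#' repeated nested CV for the physical-only, psychological-only, combined,
#' and residualized-psychological predictor sets, and computes the
#' univariate correlation table. Returns per-model R-squared summaries and
#' top-importance tables.
#'
#' @param cohort a `synthetic_cohort`, or a list with elements `features`
#'   (a [feature_table()]) and `outcome`.
#' @param plan a [cv_plan()]; per-model plans get distinct derived seeds.
#' @param k_impute neighbors for imputation (default 5).
#' @param subsets predictor subsets to run (default all four).
#' @param n_top size of the highlighted top-importance table (default 10).
#' @return list of class `study_report` with `models` (named list of
#'   `study_summary`), `top_vi` (named list of data.frames),
#'   `correlations`, and `table` (the imputed feature table).
#' @export
study_report <- function(cohort, plan = cv_plan(), k_impute = 5,
                         subsets = c("physical", "psychological", "all",
                                     "residualized"),
                         n_top = 10) {
  stopifnot(all(c("features", "outcome") %in% names(cohort)))
  table <- knn_impute(cohort$features, k = k_impute, seed = plan$seed)
  y <- cohort$outcome

  models <- list()
  top_vi <- list()
  for (i in seq_along(subsets)) {
    sub <- subsets[i]
    plan_i <- plan
    plan_i$seed <- plan$seed + i
    res <- nested_cv(table, y, plan_i, subset = sub)
    sm <- summarize_repeats(res)
    models[[sub]] <- sm
    ord <- order(sm$vi$mean, decreasing = TRUE)[seq_len(min(n_top,
                                                            length(sm$vi$mean)))]
    top_vi[[sub]] <- data.frame(
      variable = names(sm$vi$mean)[ord],
      mean_vi = unname(sm$vi$mean[ord]),
      ci_lo = unname(sm$vi$ci[ord, "lo"]),
      ci_hi = unname(sm$vi$ci[ord, "hi"]),
      stringsAsFactors = FALSE)
  }

  structure(list(models = models, top_vi = top_vi,
                 correlations = univariate_correlations(table, y),
                 table = table),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (nm in names(x$models)) {
    s <- x$models[[nm]]
    cat(sprintf("  %-14s R2 = %6.3f (95%% CI %6.3f to %6.3f)\n", nm,
                s$r2$mean, s$r2$ci[1], s$r2$ci[2]))
  }
  invisible(x)
}

#' Write the tables of a study report as TSV files
#'
#' Writes `model_r2.tsv`, `variable_importance.tsv` and
#' `univariate_correlations.tsv` into a directory.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r2 <- do.call(rbind, lapply(names(report$models), function(nm) {
    s <- report$models[[nm]]
    data.frame(model = nm, mean_r2 = s$r2$mean, ci_lo = s$r2$ci[1],
               ci_hi = s$r2$ci[2], n_repeats = s$n_repeats)
  }))
  utils::write.table(r2, file.path(dir, "model_r2.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  vi <- do.call(rbind, lapply(names(report$models), function(nm) {
    s <- report$models[[nm]]
    data.frame(model = nm, variable = names(s$vi$mean),
               mean_vi = unname(s$vi$mean),
               ci_lo = unname(s$vi$ci[, "lo"]),
               ci_hi = unname(s$vi$ci[, "hi"]))
  }))
  utils::write.table(vi, file.path(dir, "variable_importance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(report$correlations),
                     file.path(dir, "univariate_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
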