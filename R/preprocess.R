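# Preprocessing: kNN imputation of the predictor table (done once, globally,
# before the repeated nested CV, and without ever using the outcome) and the
# residualization that strips the physical-block signal out of every
# psychological predictor.

#' k-nearest-neighbor imputation of a feature table
#'
#' Each missing cell is replaced by the mean of that variable over the `k`
#' nearest subjects (among those observed for the variable). Distances are
#' Euclidean on z-scored variables, restricted per pair to the variables
#' observed in both subjects and rescaled by the fraction of shared
#' variables (Gower-style normalization), so subjects with different
#' missingness patterns remain comparable. Observed cells are never
#' modified, and the outcome plays no role. Neighbor ties are broken by a
#' seeded shuffle of subject order, for determinism.
#'
#' @param table a [feature_table()].
#' @param k number of neighbors (default 5); must be smaller than the
#'   number of subjects.
#' @param seed seed for the tie-breaking shuffle.
#' @return The imputed [feature_table()] (no missing cells).
#' @export
knn_impute <- function(table, k = 5, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$values
  n <- nrow(X); p <- ncol(X)
  if (k >= n) stop("k must be smaller than the number of subjects")
  if (!anyNA(X)) return(table)

  all_missing <- colSums(!is.na(X)) == 0
  if (any(all_missing))
    stop("unimputable: variable(s) missing for all subjects: ",
         paste(colnames(X)[all_missing], collapse = ", "))
  none_observed <- rowSums(!is.na(X)) == 0
  if (any(none_observed))
    stop("subject(s) with no observed values: ",
         paste(table$subjects[none_observed], collapse = ", "))

  mu <- colMeans(X, na.rm = TRUE)
  sd_ <- apply(X, 2, stats::sd, na.rm = TRUE)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd_, "/")

  M <- !is.na(Z)                     # observed mask
  Z0 <- Z; Z0[!M] <- 0
  Mn <- M * 1
  # pairwise sums of squared differences over shared observed variables:
  # sum_k m_ik m_jk (z_ik - z_jk)^2 = A + t(A) - 2C
  A <- (Z0 * Z0) %*% t(Mn)
  C <- Z0 %*% t(Z0)
  n_shared <- Mn %*% t(Mn)
  D2 <- (A + t(A) - 2 * C) * p / pmax(n_shared, 1)
  D2[n_shared == 0] <- Inf
  diag(D2) <- Inf

  set.seed(seed)
  tie_rank <- sample.int(n)

  out <- X
  for (i in which(rowSums(!M) > 0)) {
    ord <- order(D2[i, ], tie_rank)
    for (j in which(!M[i, ])) {
      donors <- ord[M[ord, j]]
      use <- donors[seq_len(min(k, length(donors)))]
      out[i, j] <- mean(X[use, j])
    }
  }
  table$values <- out
  table
}

#' Residualize psychological predictors on the physical block
#'
#' Each psychological variable is replaced by its ordinary-least-squares
#' residual on an intercept plus all physical variables, fitted once on the
#' full sample; the physical variables are dropped from the output. The
#' residuals are exactly orthogonal (to numerical tolerance) to the
#' physical block, so any predictive signal they retain is variance not
#' shared with physical characteristics. Note the fit uses the full sample,
#' outside cross-validation — this mirrors the analysis it implements and is
#' a known (mild) leakage caveat.
#'
#' @param table a complete (imputed) [feature_table()].
#' @return A [feature_table()] containing only the residualized
#'   psychological variables.
#' @export
residualize_psychological <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (anyNA(table$values))
    stop("table must be imputed (complete) before residualization")
  phys <- table$variables[table$block == "physical"]
  psy <- table$variables[table$block == "psychological"]
  if (!length(phys)) stop("no physical variables to residualize on")
  if (!length(psy)) stop("no psychological variables to residualize")

  Xp <- cbind(`(Intercept)` = 1, table$values[, phys, drop = FALSE])
  qrp <- qr(Xp)
  if (qrp$rank < ncol(Xp)) {
    dropped <- colnames(Xp)[qrp$pivot[(qrp$rank + 1):ncol(Xp)]]
    stop("physical block is rank deficient; collinear variable(s): ",
         paste(dropped, collapse = ", "))
  }
  resid <- qr.resid(qrp, table$values[, psy, drop = FALSE])
  colnames(resid) <- psy

  feature_table(resid,
                block = stats::setNames(rep("psychological", length(psy)), psy),
                subblock = table$subblock[psy],
                subjects = table$subjects,
                max_missing = 1)
}
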