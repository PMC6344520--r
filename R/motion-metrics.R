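#' Six-parameter rigid-body realignment time series
#'
#' Container for the per-volume head-motion estimates of one resting-state
#' scan: three rotations (roll, pitch, yaw, in degrees) followed by three
#' translations (dS, dL, dP, in mm), one row per TR, as produced by AFNI's
#' `3dVolreg`.
#'
#' @param values numeric matrix with T rows (T >= 2) and 6 columns in the
#'   order roll, pitch, yaw, dS, dL, dP. All entries must be finite.
#' @param tr_seconds repetition time in seconds (metadata only; the motion
#'   metrics are per-TR quantities and do not use it).
#' @param subject_id subject identifier.
#' @return An object of class `motion_params`.
#' @export
motion_params <- function(values, tr_seconds = 2, subject_id = "subject") {
  values <- as.matrix(values)
  if (ncol(values) != 6L)
    stop("motion parameters must have exactly 6 columns, got ", ncol(values))
  if (nrow(values) < 2L)
    stop("motion parameters must have at least 2 time points, got ", nrow(values))
  if (!all(is.finite(values)))
    stop("motion parameters must be finite")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a positive scalar")
  storage.mode(values) <- "double"
  colnames(values) <- c("roll", "pitch", "yaw", "dS", "dL", "dP")
  structure(
    list(values = values, tr_seconds = as.numeric(tr_seconds),
         subject_id = as.character(subject_id)),
    class = "motion_params"
  )
}

#' @export
print.motion_params <- function(x, ...) {
  cat("<motion_params> subject", x$subject_id, "-", nrow(x$values),
      "TRs, TR =", x$tr_seconds, "s\n")
  invisible(x)
}

#' Per-TR Euclidean-norm motion (ENORM)
#'
#' The Euclidean (L2) norm of the backward first difference of the six
#' realignment parameters, one value per TR transition (length T-1).
#' Rotations in degrees and translations in mm are combined without
#' rescaling, following the AFNI convention.
#'
#' @param params a [motion_params()] object.
#' @return Numeric vector of length T-1, non-negative.
#' @export
enorm_series <- function(params) {
  stopifnot(inherits(params, "motion_params"))
  d <- diff(params$values)
  sqrt(rowSums(d * d))
}

#' Per-TR framewise displacement (FD)
#'
#' The L1 norm of the same backward-difference vectors used by
#' [enorm_series()]: the sum of absolute parameter changes per TR.
#' Elementwise FD >= ENORM always holds (L1 >= L2).
#'
#' @inheritParams enorm_series
#' @return Numeric vector of length T-1, non-negative.
#' @export
fd_series <- function(params) {
  stopifnot(inherits(params, "motion_params"))
  d <- diff(params$values)
  rowSums(abs(d))
}

#' Scan-level motion summary
#'
#' Averages the per-TR ENORM and FD series over the T-1 difference values and
#' takes natural logs of both means. The log of mean ENORM is the dependent
#' variable of the prediction analyses (the log tames the right skew of
#' motion distributions). For a zero-motion scan the log is undefined: the
#' log fields are returned as `NA` with `log_defined = FALSE` and a warning,
#' so such subjects can be excluded from modeling rather than silently
#' propagating `-Inf`.
#'
#' @inheritParams enorm_series
#' @return A `motion_summary` list with fields `subject_id`, `mean_enorm`,
#'   `mean_fd`, `log_mean_enorm`, `log_mean_fd`, `n_trs`, `log_defined`.
#' @export
summarize_motion <- function(params) {
  en <- enorm_series(params)
  fd <- fd_series(params)
  mean_enorm <- mean(en)
  mean_fd <- mean(fd)
  defined <- mean_enorm > 0
  if (!defined)
    warning("zero-motion scan for subject '", params$subject_id,
            "': log motion is undefined; exclude from modeling")
  structure(
    list(subject_id = params$subject_id,
         mean_enorm = mean_enorm,
         mean_fd = mean_fd,
         log_mean_enorm = if (defined) log(mean_enorm) else NA_real_,
         log_mean_fd = if (defined) log(mean_fd) else NA_real_,
         n_trs = nrow(params$values),
         log_defined = defined),
    class = "motion_summary"
  )
}

#' @export
print.motion_summary <- function(x, ...) {
  cat(sprintf("<motion_summary> %s: mean ENORM %.4g, mean FD %.4g (%d TRs)\n",
              x$subject_id, x$mean_enorm, x$mean_fd, x$n_trs))
  invisible(x)
}

#' Collect motion summaries into a data frame
#'
#' @param summaries a list of `motion_summary` objects (or a single one).
#' @return data.frame with one row per scan.
#' @export
motion_summary_table <- function(summaries) {
  if (inherits(summaries, "motion_summary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(subject_id = s$subject_id, mean_enorm = s$mean_enorm,
               mean_fd = s$mean_fd, log_mean_enorm = s$log_mean_enorm,
               log_mean_fd = s$log_mean_fd, n_trs = s$n_trs,
               stringsAsFactors = FALSE)
  }))
}
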