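#' Read a six-column realignment-parameter text file
#'
#' Reads whitespace-delimited motion-parameter files (AFNI `.1D` style);
#' lines starting with `#` are ignored. Column-order dialects are mapped onto
#' the canonical AFNI ordering (3 rotations then 3 translations):
#' `"afni"` and `"fsl"` files already list rotations first, `"spm"` files
#' list translations first and are reordered. Units are taken as stored in
#' the file; no radian/degree conversion is attempted.
#'
#' @param path file path.
#' @param convention column ordering of the file: `"afni"` (default),
#'   `"fsl"`, or `"spm"`.
#' @param tr_seconds repetition time in seconds (metadata).
#' @param subject_id subject identifier; defaults to the file name without
#'   extension.
#' @return A [motion_params()] object.
#' @export
read_motion_params <- function(path, convention = c("afni", "fsl", "spm"),
                               tr_seconds = 2, subject_id = NULL) {
  convention <- match.arg(convention)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  m <- as.matrix(utils::read.table(path, comment.char = "#",
                                   colClasses = "numeric"))
  if (ncol(m) != 6L)
    stop("expected 6 columns in '", path, "', got ", ncol(m))
  perm <- switch(convention, afni = 1:6, fsl = 1:6, spm = c(4:6, 1:3))
  motion_params(m[, perm, drop = FALSE], tr_seconds = tr_seconds,
                subject_id = subject_id)
}

#' Write one motion-parameter series as a `.1D` text file
#'
#' @param params a [motion_params()] object.
#' @param path output path.
#' @export
write_motion_params <- function(params, path) {
  stopifnot(inherits(params, "motion_params"))
  utils::write.table(format(params$values, trim = TRUE, digits = 10),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write per-subject motion summaries as TSV
#'
#' Columns: `subject_id mean_enorm mean_fd log_mean_enorm log_mean_fd n_trs`.
#'
#' @param summaries list of `motion_summary` objects.
#' @param path output path.
#' @export
write_motion_summaries <- function(summaries, path) {
  df <- motion_summary_table(summaries)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motion-summary TSV written by [write_motion_summaries()]
#'
#' @param path file path.
#' @return data.frame with one row per scan.
#' @export
read_motion_summaries <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
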