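#' Subjects-by-predictors feature table with block labels
#'
#' The predictor container used throughout the pipeline: an n x p numeric
#' matrix (missing values as `NA`), a block label per variable
#' (`"physical"` or `"psychological"`), and for psychological variables a
#' sub-block label (`"drug"` or `"nondrug"`).
#'
#' @param values numeric matrix, subjects in rows, predictors in columns;
#'   `NA` marks missing entries. Column names are the variable names.
#' @param block named character vector mapping each variable to
#'   `"physical"` or `"psychological"`.
#' @param subblock optional named character vector mapping psychological
#'   variables to `"drug"` or `"nondrug"` (`NA` for physical variables).
#' @param subjects subject identifiers; defaults to row names or
#'   `sprintf("S%04d", 1:n)`.
#' @param max_missing maximum tolerated per-variable missing fraction
#'   (default 0.0625); exceeding it is an error.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, block, subblock = NULL, subjects = NULL,
                          max_missing = 0.0625) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    stop("values must have column (variable) names")
  vars <- colnames(values)
  if (is.null(subjects)) {
    subjects <- rownames(values)
    if (is.null(subjects)) subjects <- sprintf("S%04d", seq_len(nrow(values)))
  }
  rownames(values) <- subjects
  block <- block[vars]
  if (anyNA(block) || !all(block %in% c("physical", "psychological")))
    stop("every variable needs a block label in {physical, psychological}")
  if (is.null(subblock)) {
    subblock <- stats::setNames(rep(NA_character_, length(vars)), vars)
  } else {
    subblock <- subblock[vars]
    names(subblock) <- vars
  }
  psy <- vars[block == "psychological"]
  bad <- psy[!(subblock[psy] %in% c("drug", "nondrug"))]
  if (length(bad))
    stop("psychological variables without a {drug, nondrug} sub-block: ",
         paste(utils::head(bad, 5), collapse = ", "))
  miss <- colMeans(is.na(values))
  if (any(miss > max_missing + 1e-12))
    stop("variables exceed the maximum missing fraction (",
         max_missing, "): ",
         paste(vars[miss > max_missing + 1e-12], collapse = ", "))
  structure(
    list(subjects = subjects, variables = vars, values = values,
         block = block, subblock = subblock),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  nb <- table(x$block)
  cat(sprintf(
    "<feature_table> %d subjects x %d variables (%d physical, %d psychological); %.2f%% missing\n",
    length(x$subjects), length(x$variables),
    sum(x$block == "physical"), sum(x$block == "psychological"),
    100 * mean(is.na(x$values))))
  invisible(x)
}

#' Select a predictor block as a plain matrix
#'
#' @param table a [feature_table()].
#' @param subset one of `"all"`, `"physical"`, `"psychological"`.
#' @return numeric matrix with the selected columns.
#' @export
select_block <- function(table, subset = c("all", "physical", "psychological")) {
  stopifnot(inherits(table, "feature_table"))
  subset <- match.arg(subset)
  keep <- if (subset == "all") table$variables
          else table$variables[table$block == subset]
  if (!length(keep)) stop("subset '", subset, "' selects zero variables")
  table$values[, keep, drop = FALSE]
}

#' Write a feature table as CSV plus a block-label sidecar TSV
#'
#' The CSV holds `subject_id` plus one column per variable; the sidecar TSV
#' has columns `variable block subblock`.
#'
#' @param table a [feature_table()].
#' @param path_csv path for the values CSV.
#' @param path_sidecar path for the label sidecar TSV; defaults to the CSV
#'   path with extension replaced by `.labels.tsv`.
#' @export
write_feature_table <- function(table, path_csv, path_sidecar = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(path_sidecar))
    path_sidecar <- sub("\\.csv$", ".labels.tsv", path_csv)
  df <- data.frame(subject_id = table$subjects, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path_csv, row.names = FALSE)
  side <- data.frame(variable = table$variables,
                     block = unname(table$block),
                     subblock = unname(table$subblock),
                     stringsAsFactors = FALSE)
  utils::write.table(side, path_sidecar, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path_csv, path_sidecar))
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path_csv path of the values CSV.
#' @param path_sidecar path of the label sidecar TSV.
#' @param max_missing passed to [feature_table()].
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path_csv, path_sidecar = NULL,
                               max_missing = 0.0625) {
  if (is.null(path_sidecar))
    path_sidecar <- sub("\\.csv$", ".labels.tsv", path_csv)
  df <- utils::read.csv(path_csv, check.names = FALSE,
                        stringsAsFactors = FALSE)
  side <- utils::read.table(path_sidecar, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  values <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  feature_table(values,
                block = stats::setNames(side$block, side$variable),
                subblock = stats::setNames(side$subblock, side$variable),
                subjects = df$subject_id, max_missing = max_missing)
}
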