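#' Write an expression matrix and phenotype table to tab-separated files
#'
#' The matrix is written with a `feature_id` first column and a header row of
#' sample IDs; missing cells become empty fields. The phenotype table keeps
#' its header row. Both round-trip losslessly through [read_expression()] and
#' [read_phenotype()].
#'
#' @param expr features x samples numeric matrix.
#' @param pheno phenotype data.frame (sample_id, diagnosis, age, sex, apoe4).
#' @param dir output directory (created if absent).
#' @return named character vector of the two file paths
#'   (`expression`, `phenotype`).
#' @export
write_dataset <- function(expr, pheno, dir) {
  check_expr(expr)
  check_pheno(pheno, expr)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create directory: ", dir)
  }
  expr_path <- file.path(dir, "expression.tsv")
  pheno_path <- file.path(dir, "phenotype.tsv")
  df <- data.frame(feature_id = rownames(expr), expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  tryCatch({
    utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    utils::write.table(pheno, pheno_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }, error = function(e) {
    stop("failed writing dataset under ", dir, ": ", conditionMessage(e))
  })
  c(expression = expr_path, phenotype = pheno_path)
}

#' Read a tab-separated expression matrix
#'
#' @param path file written in the [write_dataset()] layout (first column
#'   feature IDs, header of sample IDs, empty fields = missing).
#' @return features x samples numeric matrix.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  expr <- as.matrix(df[, -1, drop = FALSE])
  mode(expr) <- "numeric"
  rownames(expr) <- df[[1]]
  check_expr(expr)
}

#' Read a tab-separated phenotype table
#'
#' @param path file with header `sample_id diagnosis age sex apoe4`.
#' @return data.frame.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pheno <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  pheno$sample_id <- as.character(pheno$sample_id)
  check_pheno(pheno)
}

#' Read candidate direction sets from a two-column file
#'
#' @param path tab-separated file with columns `feature_id` and `direction`
#'   (values `positive`/`negative`); an optional `expanded` logical column is
#'   preserved.
#' @return data.frame with columns feature_id, direction, expanded.
#' @export
read_candidate_sets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("feature_id", "direction") %in% names(df))) {
    stop("candidate set file needs columns feature_id and direction")
  }
  if (!all(df$direction %in% c("positive", "negative"))) {
    stop("direction must be 'positive' or 'negative'")
  }
  if (is.null(df$expanded)) df$expanded <- FALSE
  df[c("feature_id", "direction", "expanded")]
}
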