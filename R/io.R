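#' Read and write the pipeline's tabular files
#'
#' Counts and expression matrices travel as TSV with features in rows and
#' samples in columns (first column = feature id); metadata and phenotypes
#' as plain TSV/CSV.  Ground truth is serialized as JSON.
#'
#' @param x Matrix or data frame to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the object.
#' @name hetcirc-io
NULL

#' @rdname hetcirc-io
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname hetcirc-io
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname hetcirc-io
#' @export
write_meta_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname hetcirc-io
#' @export
read_meta_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' @rdname hetcirc-io
#' @export
write_phenotypes_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname hetcirc-io
#' @export
read_phenotypes_csv <- function(path)
  utils::read.csv(path, stringsAsFactors = FALSE)

#' @rdname hetcirc-io
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname hetcirc-io
#' @export
read_truth_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
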