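#' Read and write expression tables
#'
#' Dense expression files are TSV (or CSV) with a header row of sample ids
#' and a first column of gene ids. Sparse matrices use MatrixMarket `.mtx`
#' files with plain-text row (gene) and column (sample) id sidecars, one id
#' per line.
#'
#' @param path File to read or write.
#' @param unit Measurement unit of the stored values (see [expression_tbl()]).
#' @param delim Field delimiter; `"\t"` (default) or `","`.
#' @return `read_expression()` and `read_expression_mtx()` return an
#'   expression table; the writers return the input invisibly.
#' @export
read_expression <- function(path, unit = c("counts", "TPM", "RPKM", "quantile"),
                            delim = "\t") {
  unit <- match.arg(unit)
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  names(x)[1] <- "gene_id"
  expression_tbl(x, unit = unit)
}

#' @rdname read_expression
#' @param x An expression table.
#' @export
write_expression <- function(x, path, delim = "\t") {
  readr::write_delim(x, path, delim = delim, progress = FALSE)
  invisible(x)
}

#' @rdname read_expression
#' @param genes_path,samples_path Sidecar files holding the gene ids (matrix
#'   rows) and sample ids (matrix columns), one per line.
#' @export
read_expression_mtx <- function(path, genes_path, samples_path,
                                unit = c("counts", "TPM", "RPKM", "quantile")) {
  unit <- match.arg(unit)
  m <- as.matrix(Matrix::readMM(path))
  rownames(m) <- readLines(genes_path)
  colnames(m) <- readLines(samples_path)
  expression_tbl(m, unit = unit)
}

#' @rdname read_expression
#' @export
write_expression_mtx <- function(x, path, genes_path, samples_path) {
  m <- as_expr_matrix(x)
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
  writeLines(rownames(m), genes_path)
  writeLines(colnames(m), samples_path)
  invisible(x)
}

#' Read annotation-style side tables
#'
#' `read_gene_lengths()` expects columns `gene_id` and `length` (bp);
#' `read_id_map()` expects `transcript_id` and `gene_id`;
#' `read_annotation()` expects `sample_id`, `tissue_group`, `source_type`
#' and `study_id`; `read_gene_list()` reads one gene id per line, ignoring
#' blank lines and `#` comments.
#'
#' @param path File to read.
#' @return A tibble (or, for `read_gene_list()`, a character vector).
#' @export
read_gene_lengths <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1:2] <- c("gene_id", "length")
  x <- mutate(x, length = as.integer(.data$length))
  if (any(is.na(x$length)) || any(x$length <= 0)) {
    abort("gene lengths must be positive integers")
  }
  if (anyDuplicated(x$gene_id)) abort("duplicate gene ids in length table")
  x
}

#' @rdname read_gene_lengths
#' @export
read_id_map <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1:2] <- c("transcript_id", "gene_id")
  x
}

#' @rdname read_gene_lengths
#' @export
read_annotation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "tissue_group", "source_type", "study_id")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(paste("annotation table missing columns:",
                paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(x$source_type), c("in_vivo", "in_vitro", "unknown"))
  if (length(bad)) {
    abort(paste("source_type must be in_vivo/in_vitro/unknown; found:",
                paste(bad, collapse = ", ")))
  }
  x
}

#' @rdname read_gene_lengths
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}
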