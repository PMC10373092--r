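#' Expression tables
#'
#' An expression table is an ordinary tibble whose first column, `gene_id`,
#' holds unique gene (or transcript) identifiers and whose remaining columns
#' hold non-negative expression values for uniquely named samples. The
#' measurement unit travels with the table as the `"unit"` attribute and is
#' checked by downstream operations, so that e.g. quantile transformation
#' refuses raw counts.
#'
#' @param x A data frame with a `gene_id` column and one numeric column per
#'   sample, or a numeric matrix with gene ids as row names and sample ids as
#'   column names.
#' @param unit Measurement unit: `"counts"`, `"TPM"`, `"RPKM"`, or
#'   `"quantile"`.
#' @return A tibble of class `ueg_expr` (genes x samples) carrying the unit.
#' @examples
#' m <- matrix(c(0, 5, 2, 8), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' expression_tbl(m, unit = "counts")
#' @export
expression_tbl <- function(x, unit = c("counts", "TPM", "RPKM", "quantile")) {
  unit <- match.arg(unit)
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("matrix input needs gene ids as rownames and sample ids as colnames")
    }
    x <- tibble(gene_id = rownames(x), as_tibble(x, .name_repair = "minimal"))
  }
  x <- as_tibble(x)
  if (!"gene_id" %in% names(x)) {
    abort("expression table must have a 'gene_id' column")
  }
  x <- select(x, "gene_id", dplyr::everything())
  validate_expr(x, unit)
  structure(x, unit = unit, class = c("ueg_expr", class(tibble())))
}

validate_expr <- function(x, unit) {
  if (anyDuplicated(x$gene_id)) abort("duplicate gene ids in expression table")
  samp <- setdiff(names(x), "gene_id")
  if (length(samp) == 0L) abort("expression table has no sample columns")
  if (anyDuplicated(samp)) abort("duplicate sample ids in expression table")
  vals <- as.matrix(x[samp])
  if (!is.numeric(vals)) abort("sample columns must be numeric")
  if (anyNA(vals)) abort("expression values must not be missing")
  if (any(vals < 0)) abort("expression values must be non-negative")
  if (unit == "quantile" && any(vals > 1)) {
    abort("quantile-unit values must lie in [0, 1]")
  }
  invisible(x)
}

#' @rdname expression_tbl
#' @export
expr_unit <- function(x) {
  u <- attr(x, "unit", exact = TRUE)
  if (is.null(u)) abort("not an expression table: missing 'unit' attribute")
  u
}

#' @rdname expression_tbl
#' @export
expr_samples <- function(x) setdiff(names(x), "gene_id")

#' @rdname expression_tbl
#' @export
expr_genes <- function(x) x$gene_id

#' Convert an expression table to a plain matrix
#'
#' @param x An expression table (see [expression_tbl()]).
#' @return A numeric genes x samples matrix with dimnames.
#' @export
as_expr_matrix <- function(x) {
  samp <- expr_samples(x)
  m <- as.matrix(x[samp])
  rownames(m) <- x$gene_id
  m
}

## rebuild a ueg_expr from a matrix, keeping validation in one place
expr_from_matrix <- function(m, unit) {
  expression_tbl(m, unit = unit)
}

check_unit <- function(x, allowed, op) {
  u <- expr_unit(x)
  if (!u %in% allowed) {
    abort(sprintf("%s expects unit %s, got '%s'", op,
                  paste(sQuote(allowed), collapse = " or "), u))
  }
  u
}

#' @export
print.ueg_expr <- function(x, ...) {
  cat(sprintf("# Expression table: %d genes x %d samples [unit: %s]\n",
              nrow(x), length(expr_samples(x)), expr_unit(x)))
  NextMethod()
}
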