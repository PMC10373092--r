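#' Sample-wise quantile transformation
#'
#' Replaces each expression value by its percentile rank among the nonzero
#' values of the same sample: for a nonzero value `x_j`,
#' `Q_j = |{i : 0 < x_i <= x_j}| / |{i : 0 < x_i}|`; zeros stay exactly
#' zero. Ties therefore share the maximum rank, the largest nonzero value
#' of every sample maps to exactly 1, and the denominator is the sample's
#' own transcriptome size, so undetected genes do not dilute the ranks of
#' detected ones. The transform is invariant to positive rescaling of a
#' sample, which is what makes profiles from different batches and
#' sequencing depths comparable on a common [0, 1] scale.
#'
#' This is a within-sample rank transform, not cross-sample quantile
#' normalization to a shared reference distribution.
#'
#' @param x An expression table in TPM or RPKM unit.
#' @return An expression table with unit `"quantile"`, values in [0, 1].
#' @examples
#' m <- matrix(c(0, 2, 4, 8), 4, 1, dimnames = list(paste0("g", 1:4), "s1"))
#' quantile_transform(expression_tbl(m, "TPM"))
#' @export
quantile_transform <- function(x) {
  check_unit(x, c("TPM", "RPKM"), "quantile_transform")
  m <- as_expr_matrix(x)
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  empty <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    nz <- v > 0
    n_nz <- sum(nz)
    if (n_nz == 0L) {
      empty[j] <- TRUE
      next
    }
    out[nz, j] <- rank(v[nz], ties.method = "max") / n_nz
  }
  if (any(empty)) {
    warn(sprintf(
      "quantile_transform: %d sample(s) with no nonzero values returned as all-zero (%s)",
      sum(empty), paste(head(colnames(m)[empty], 5), collapse = ", ")))
  }
  expression_tbl(out, unit = "quantile")
}
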