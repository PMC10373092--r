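#' Collapse transcript-level rows to gene level
#'
#' When several transcripts map to the same gene, the gene's expression in
#' each sample is taken as the maximum over its transcripts. Rows whose ids
#' are absent from the map are dropped with a message reporting the count.
#'
#' @param x An expression table whose `gene_id` column holds transcript ids.
#' @param id_map A data frame with columns `transcript_id` and `gene_id`.
#' @return An expression table with one row per target gene, same unit.
#' @export
collapse_to_genes <- function(x, id_map) {
  stopifnot(all(c("transcript_id", "gene_id") %in% names(id_map)))
  unit <- expr_unit(x)
  hit <- x$gene_id %in% id_map$transcript_id
  if (!any(hit)) abort("no transcript ids of the matrix are present in id_map")
  n_drop <- sum(!hit)
  if (n_drop > 0) {
    inform(sprintf("collapse_to_genes: dropped %d unmapped transcript row(s)",
                   n_drop))
  }
  m <- as_expr_matrix(x)[hit, , drop = FALSE]
  gene <- id_map$gene_id[match(rownames(m), id_map$transcript_id)]
  idx <- split(seq_len(nrow(m)), gene)
  res <- vapply(idx, function(i) {
    apply(m[i, , drop = FALSE], 2, max)
  }, numeric(ncol(m)))
  if (ncol(m) == 1L) {
    out <- matrix(res, ncol = 1, dimnames = list(names(idx), colnames(m)))
  } else {
    out <- t(res)
    colnames(out) <- colnames(m)
  }
  expression_tbl(out, unit = unit)
}

length_vector <- function(x, lengths) {
  stopifnot(all(c("gene_id", "length") %in% names(lengths)))
  i <- match(x$gene_id, lengths$gene_id)
  if (anyNA(i)) {
    miss <- x$gene_id[is.na(i)]
    abort(paste("missing gene length(s) for:",
                paste(head(miss, 5), collapse = ", "),
                if (length(miss) > 5) sprintf("... (%d total)", length(miss))))
  }
  len <- as.numeric(lengths$length[i])
  if (any(len <= 0)) abort("gene lengths must be positive")
  len
}

warn_zero_columns <- function(m, op) {
  zero <- colSums(m) == 0
  if (any(zero)) {
    warn(sprintf("%s: %d all-zero sample column(s) kept as zeros (%s)",
                 op, sum(zero), paste(head(colnames(m)[zero], 5),
                                      collapse = ", ")))
  }
  zero
}

#' Length- and depth-normalize read counts
#'
#' `tpm_normalize()` computes transcripts per million,
#' `TPM_g = 1e6 * (c_g / l_g) / sum_i(c_i / l_i)` per sample, so every
#' non-degenerate sample column sums to one million. `rpkm_normalize()`
#' computes reads per kilobase per million mapped reads,
#' `RPKM_g = 1e9 * c_g / (l_g * N)` with `N` the sample's total count.
#' All-zero sample columns stay all-zero and trigger a warning.
#'
#' @param x An expression table of raw counts.
#' @param lengths Data frame with columns `gene_id` and `length` (bp),
#'   covering every gene in `x`.
#' @return An expression table in the requested unit.
#' @examples
#' m <- matrix(c(10, 30), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' counts <- expression_tbl(m, "counts")
#' lens <- data.frame(gene_id = c("a", "b"), length = c(1000, 1000))
#' tpm_normalize(counts, lens)
#' @export
tpm_normalize <- function(x, lengths) {
  check_unit(x, "counts", "tpm_normalize")
  m <- as_expr_matrix(x)
  len <- length_vector(x, lengths)
  warn_zero_columns(m, "tpm_normalize")
  rate <- m / len
  denom <- colSums(rate)
  denom[denom == 0] <- 1  # degenerate columns stay zero
  out <- sweep(rate, 2, denom, "/") * 1e6
  expression_tbl(out, unit = "TPM")
}

#' @rdname tpm_normalize
#' @export
rpkm_normalize <- function(x, lengths) {
  check_unit(x, "counts", "rpkm_normalize")
  m <- as_expr_matrix(x)
  len <- length_vector(x, lengths)
  warn_zero_columns(m, "rpkm_normalize")
  N <- colSums(m)
  N[N == 0] <- 1
  out <- 1e9 * sweep(m / len, 2, N, "/")
  expression_tbl(out, unit = "RPKM")
}

#' Remove low-quality samples by internal reference genes
#'
#' A sample is considered low quality and removed when the expression of
#' any of the supplied internal reference genes is exactly zero; the
#' conventional defaults for human data are the lowly expressed reference
#' genes GUSB, HPRT1 and HMBS.
#'
#' @param x An expression table.
#' @param ref_genes Character vector of reference gene ids; all must be
#'   present in `x`.
#' @return A list with `matrix` (the filtered expression table) and
#'   `report`, a `ueg_qc` object listing kept and removed samples and the
#'   per-sample zero-reference flags.
#' @export
qc_filter <- function(x, ref_genes = c("GUSB", "HPRT1", "HMBS")) {
  miss <- setdiff(ref_genes, x$gene_id)
  if (length(miss)) {
    abort(paste("reference gene(s) absent from matrix:",
                paste(miss, collapse = ", ")))
  }
  m <- as_expr_matrix(x)
  ref <- m[ref_genes, , drop = FALSE]
  zero_ref <- ref == 0
  removed <- colnames(m)[colSums(zero_ref) > 0]
  kept <- setdiff(colnames(m), removed)
  if (length(kept) == 0L) abort("qc_filter removed every sample")
  flags <- tibble(
    sample_id = colnames(m),
    kept = !colnames(m) %in% removed,
    zero_ref_genes = vapply(seq_len(ncol(ref)), function(j) {
      paste(ref_genes[zero_ref[, j]], collapse = ",")
    }, character(1))
  )
  report <- structure(
    list(kept = kept, removed = removed, reference_genes = ref_genes,
         flags = flags),
    class = "ueg_qc"
  )
  out <- expression_tbl(m[, kept, drop = FALSE], unit = expr_unit(x))
  list(matrix = out, report = report)
}

#' @export
print.ueg_qc <- function(x, ...) {
  cat(sprintf(
    "Reference-gene QC: kept %d, removed %d of %d samples (refs: %s)\n",
    length(x$kept), length(x$removed),
    length(x$kept) + length(x$removed),
    paste(x$reference_genes, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.ueg_qc <- function(x, ...) x$flags
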