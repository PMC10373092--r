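#' Expression detection thresholds
#'
#' A detection threshold is a (unit, value) pair; a gene is called expressed
#' in a sample when its normalized value is greater than or equal to the
#' threshold (inclusive). `default_thresholds()` returns the four presets in
#' common use: TPM >= 0.1 (the GTEx choice, the most sensitive for lowly
#' expressed genes), TPM >= 1.0, RPKM >= 0.3, and RPKM >= 1.0; when `unit`
#' is given only the presets of that unit are returned.
#'
#' @param unit `"TPM"` or `"RPKM"`.
#' @param value Positive threshold value.
#' @return A `ueg_threshold` object, or for `default_thresholds()` a named
#'   list of them.
#' @export
detection_threshold <- function(unit = c("TPM", "RPKM"), value) {
  unit <- match.arg(unit)
  if (!is.numeric(value) || length(value) != 1L || value <= 0) {
    abort("threshold value must be a single positive number")
  }
  structure(list(unit = unit, value = value), class = "ueg_threshold")
}

#' @rdname detection_threshold
#' @export
default_thresholds <- function(unit = NULL) {
  th <- list(
    detection_threshold("TPM", 0.1),
    detection_threshold("TPM", 1.0),
    detection_threshold("RPKM", 0.3),
    detection_threshold("RPKM", 1.0)
  )
  names(th) <- vapply(th, threshold_label, character(1))
  if (!is.null(unit)) th <- th[vapply(th, function(t) t$unit == unit, logical(1))]
  th
}

threshold_label <- function(threshold) {
  paste0(tolower(threshold$unit), "_", format(threshold$value))
}

#' @export
print.ueg_threshold <- function(x, ...) {
  cat(sprintf("Detection threshold: %s >= %s\n", x$unit, format(x$value)))
  invisible(x)
}

#' Call genes expressed per sample
#'
#' @param x An expression table whose unit matches the threshold's unit.
#' @param threshold A [detection_threshold()].
#' @return A `ueg_detection` tibble (`gene_id` plus one logical column per
#'   sample) carrying the threshold as an attribute.
#' @export
detect_expression <- function(x, threshold = detection_threshold("TPM", 0.1)) {
  stopifnot(inherits(threshold, "ueg_threshold"))
  u <- expr_unit(x)
  if (u != threshold$unit) {
    abort(sprintf("matrix unit '%s' does not match threshold unit '%s'",
                  u, threshold$unit))
  }
  m <- as_expr_matrix(x) >= threshold$value
  out <- tibble(gene_id = rownames(m), as_tibble(m, .name_repair = "minimal"))
  structure(out, threshold = threshold,
            class = c("ueg_detection", class(tibble())))
}

detection_matrix <- function(detection) {
  stopifnot(inherits(detection, "ueg_detection"))
  m <- as.matrix(detection[setdiff(names(detection), "gene_id")])
  rownames(m) <- detection$gene_id
  m
}

#' Global expression specificity
#'
#' The global expression specificity of a gene, phi, is the fraction of
#' transcriptomes in the compendium that express it at the stated detection
#' threshold: phi = 1 marks a ubiquitously expressed gene, phi near 0 a
#' highly specific one. No tissue stratification is involved.
#'
#' @param detection A `ueg_detection` table from [detect_expression()].
#' @return A tibble with `gene_id`, `phi`, `n_detected`, `n_samples`.
#' @export
global_specificity <- function(detection) {
  m <- detection_matrix(detection)
  if (ncol(m) < 1L) abort("global_specificity needs at least one sample")
  tibble(
    gene_id = rownames(m),
    phi = unname(rowMeans(m)),
    n_detected = as.integer(rowSums(m)),
    n_samples = ncol(m)
  )
}

#' Tissue-based expression specificity
#'
#' The traditional stratified counterpart of phi: a tissue group is said to
#' express a gene when at least `tissue_expressed_frac` (default 80%) of its
#' samples detect it, and the specificity is the fraction of tissue groups
#' expressing the gene. Only annotated samples present in the detection
#' table enter the computation; annotated samples absent from it (e.g.
#' removed by QC) and tissue groups left without samples are dropped with
#' a message.
#'
#' @param detection A `ueg_detection` table.
#' @param annotation Data frame with `sample_id` and `tissue_group`.
#' @param tissue_expressed_frac Fraction of a tissue's samples that must
#'   detect a gene for the tissue to count as expressing it (inclusive).
#' @return A tibble with `gene_id`, `tissue_specificity`, `n_tissues`.
#' @export
tissue_specificity <- function(detection, annotation,
                               tissue_expressed_frac = 0.8) {
  m <- detection_matrix(detection)
  ann <- filter(annotation, .data$sample_id %in% colnames(m))
  n_absent <- nrow(annotation) - nrow(ann)
  if (n_absent > 0) {
    inform(sprintf(
      "tissue_specificity: ignoring %d annotated sample(s) absent from the detection matrix (e.g. removed by QC)",
      n_absent))
  }
  groups <- split(ann$sample_id, ann$tissue_group)
  sizes <- lengths(groups)
  if (any(sizes == 0L)) {
    inform(sprintf("tissue_specificity: dropped %d empty tissue group(s)",
                   sum(sizes == 0L)))
    groups <- groups[sizes > 0L]
  }
  if (length(groups) == 0L) abort("no tissue group with samples")
  per_tissue <- vapply(groups, function(s) {
    rowMeans(m[, s, drop = FALSE]) >= tissue_expressed_frac
  }, logical(nrow(m)))
  tibble(
    gene_id = rownames(m),
    tissue_specificity = unname(rowMeans(per_tissue)),
    n_tissues = length(groups)
  )
}

#' Transcriptome sizes
#'
#' The transcriptome size of a sample is the number of genes it expresses
#' at the detection threshold. The summary attribute reports the median and
#' the central 80% interval (10th to 90th percentile) across samples.
#'
#' @param detection A `ueg_detection` table.
#' @return A tibble with `sample_id` and `n_expressed`; the attribute
#'   `"summary"` holds a one-row tibble with `median`, `q10`, `q90`,
#'   `n_genes`.
#' @export
transcriptome_sizes <- function(detection) {
  m <- detection_matrix(detection)
  sizes <- colSums(m)
  out <- tibble(sample_id = colnames(m), n_expressed = as.integer(sizes))
  qs <- quantile(sizes, c(0.1, 0.5, 0.9), type = 7, names = FALSE)
  attr(out, "summary") <- tibble(
    median = qs[2], q10 = qs[1], q90 = qs[3], n_genes = nrow(m)
  )
  out
}

#' Specificity table across thresholds
#'
#' Computes phi for each gene at each supplied detection threshold (one
#' column per threshold, named `phi_<unit>_<value>`), and optionally the
#' tissue-based specificity at the first threshold when a sample annotation
#' is supplied.
#'
#' @param x A normalized expression table (TPM or RPKM).
#' @param thresholds A list of [detection_threshold()] objects in the same
#'   unit as `x`; defaults to the presets of that unit.
#' @param annotation Optional annotation with `sample_id`, `tissue_group`.
#' @param tissue_expressed_frac See [tissue_specificity()].
#' @return A tibble with `gene_id`, one `phi_*` column per threshold and,
#'   if annotated, `tissue_specificity`.
#' @export
specificity_table <- function(x, thresholds = default_thresholds(expr_unit(x)),
                              annotation = NULL, tissue_expressed_frac = 0.8) {
  if (inherits(thresholds, "ueg_threshold")) thresholds <- list(thresholds)
  if (length(thresholds) == 0L) abort("no thresholds supplied")
  out <- tibble(gene_id = x$gene_id)
  for (th in thresholds) {
    det <- detect_expression(x, th)
    out[[paste0("phi_", threshold_label(th))]] <- global_specificity(det)$phi
  }
  if (!is.null(annotation)) {
    det1 <- detect_expression(x, thresholds[[1]])
    ts <- tissue_specificity(det1, annotation, tissue_expressed_frac)
    out <- left_join(out, select(ts, "gene_id", "tissue_specificity"),
                     by = "gene_id")
  }
  out
}

#' Tabulate genes by specificity interval
#'
#' Counts genes per specificity interval, optionally within named gene
#' sets. The intervals are `[0.8, 1.0]` (closed at 0.8, so a gene with
#' phi exactly 0.8 counts as ubiquitous), `(0.6, 0.8)`, `(0.4, 0.6]`,
#' `(0.2, 0.4]` and `[0, 0.2]`. Set members absent from the table are
#' tallied in the `n_missing` attribute rather than dropped silently.
#'
#' @param spec A tibble with `gene_id` and a phi column.
#' @param phi_col Name of the phi column to tabulate.
#' @param gene_sets Optional named list of gene-id vectors; a row group
#'   `"all"` covering every gene is always included.
#' @param breaks Interior breakpoints of the intervals.
#' @return A tibble with `set`, `interval`, `n`, `pct`, `set_size`; the
#'   attribute `"n_missing"` is a named count of absent set members.
#' @export
interval_table <- function(spec, phi_col = "phi_tpm_0.1", gene_sets = NULL,
                           breaks = c(0.2, 0.4, 0.6, 0.8)) {
  if (!phi_col %in% names(spec)) {
    abort(sprintf("column '%s' not found in specificity table", phi_col))
  }
  phi <- spec[[phi_col]]
  if (any(phi < 0 | phi > 1)) abort("phi values must lie in [0, 1]")
  breaks <- sort(breaks)
  edges <- c(0, breaks, 1)
  labels <- paste0(format(edges[-length(edges)]), "-", format(edges[-1]))
  top <- breaks[length(breaks)]
  assign_interval <- function(p) {
    # top bin closed at its lower edge; others (lo, hi]; bottom [0, lo]
    k <- ifelse(p >= top, length(labels),
                pmax(findInterval(p, edges, left.open = TRUE), 1L))
    factor(labels[k], levels = rev(labels))
  }
  sets <- c(list(all = spec$gene_id), gene_sets)
  n_missing <- integer(length(sets))
  names(n_missing) <- names(sets)
  rows <- purrr::imap(sets, function(ids, nm) {
    present <- intersect(ids, spec$gene_id)
    n_missing[[nm]] <<- length(ids) - length(present)
    iv <- assign_interval(phi[match(present, spec$gene_id)])
    tab <- table(iv)
    tibble(set = nm, interval = factor(names(tab), levels = levels(iv)),
           n = as.integer(tab),
           pct = if (length(present)) 100 * as.integer(tab) / length(present)
                 else 0,
           set_size = length(present))
  })
  out <- bind_rows(rows)
  attr(out, "n_missing") <- n_missing
  out
}
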