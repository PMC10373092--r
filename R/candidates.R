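#' Per-tissue-group detection rates
#'
#' For each requested gene and each annotated tissue group, the fraction
#' of the group's samples in which the gene is detected. Genes absent from
#' the detection matrix are not an error; they are reported via the
#' `"not_found"` attribute and by [evaluate_candidates()].
#'
#' @param detection A `ueg_detection` table.
#' @param annotation Data frame with `sample_id` and `tissue_group`.
#' @param genes Character vector of candidate gene ids.
#' @return A tibble with `gene_id`, `tissue_group`, `n_samples`,
#'   `n_detected`, `rate`; attribute `"not_found"` lists unknown genes.
#' @export
per_group_detection <- function(detection, annotation, genes) {
  m <- detection_matrix(detection)
  ann <- filter(annotation, .data$sample_id %in% colnames(m))
  groups <- split(ann$sample_id, ann$tissue_group)
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) == 0L) abort("annotation covers no detection sample")
  found <- intersect(genes, rownames(m))
  missing <- setdiff(genes, rownames(m))
  rows <- purrr::imap(groups, function(s, nm) {
    sub <- m[found, s, drop = FALSE]
    tibble(gene_id = found, tissue_group = nm, n_samples = length(s),
           n_detected = as.integer(rowSums(sub)),
           rate = unname(rowMeans(sub)))
  })
  out <- bind_rows(rows) |> arrange(.data$gene_id, .data$tissue_group)
  attr(out, "not_found") <- missing
  out
}

#' Evaluate candidate genes for ubiquity and restricted repression
#'
#' Screens a candidate list (e.g. putative disallowed genes: ubiquitous
#' genes thought to be selectively repressed in one cell type) against the
#' compendium-wide statistics. Each gene receives one verdict:
#'
#' * `constitutive` - ubiquitous (phi >= `ueg_cut` at the loose threshold)
#'   and stable (IQR <= `iqr_cut`): the expression pattern a genuinely
#'   disallowed gene should show outside its repressing tissue;
#' * `variable_ubiquitous` - ubiquitous but with high rank variability
#'   (IQR > `iqr_cut`): widely detected yet condition-sensitive, so
#'   repression is unlikely to be unique to one cell type;
#' * `restricted` - not ubiquitous (phi < `ueg_cut`);
#' * `not_found` - absent from the supplied tables.
#'
#' For ubiquitous candidates, tissue groups whose detection rate falls
#' below `repressed_rate` are flagged as putative repression sites.
#'
#' @param genes Character vector of candidate gene ids.
#' @param spec Specificity table with the phi column `phi_col`.
#' @param drm `ueg_dynrange` table (IQR, skewness, percentile vector).
#' @param group_rates Output of [per_group_detection()] for these genes.
#' @param ueg_cut Ubiquity cutoff on phi (default 0.8).
#' @param iqr_cut Variability band edge (default 0.2).
#' @param repressed_rate Per-group detection rate below which a group is
#'   flagged as repressed for an otherwise ubiquitous gene (default 0.5).
#' @param phi_col Name of the phi column used by the verdict rule.
#' @return A `candidate_report` tibble: one row per candidate with phi,
#'   IQR, skewness, Q50, verdict and flagged (low-rate) groups.
#' @export
evaluate_candidates <- function(genes, spec, drm, group_rates,
                                ueg_cut = 0.8, iqr_cut = 0.2,
                                repressed_rate = 0.5,
                                phi_col = "phi_tpm_0.1") {
  if (!phi_col %in% names(spec)) {
    abort(sprintf("specificity table lacks column '%s'", phi_col))
  }
  base <- tibble(gene_id = genes) |>
    left_join(spec, by = "gene_id") |>
    left_join(select(drm, "gene_id", "iqr", "skewness", "q50"),
              by = "gene_id")
  flagged <- group_rates |>
    filter(.data$rate < repressed_rate) |>
    group_by(.data$gene_id) |>
    summarise(flagged_groups = paste(.data$tissue_group, collapse = ","),
              min_group_rate = min(.data$rate), .groups = "drop")
  out <- base |>
    left_join(flagged, by = "gene_id") |>
    mutate(
      phi = .data[[phi_col]],
      verdict = dplyr::case_when(
        is.na(.data$phi) | is.na(.data$iqr) ~ "not_found",
        .data$phi >= ueg_cut & .data$iqr <= iqr_cut ~ "constitutive",
        .data$phi >= ueg_cut ~ "variable_ubiquitous",
        TRUE ~ "restricted"
      ),
      flagged_groups = ifelse(.data$verdict %in%
                                c("constitutive", "variable_ubiquitous"),
                              .data$flagged_groups, NA_character_)
    )
  structure(out, class = c("candidate_report", class(tibble())))
}
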