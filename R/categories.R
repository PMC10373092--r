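ueg_category_levels <- c("UEGs@1.0", "UEGs@0.1", "MSG", "SEGs@1.0", "SEGs@0.1")

#' Assign the five specificity categories to gene clusters
#'
#' Each cluster is categorized from its median global specificity at a
#' strict (TPM >= 1.0) and a loose (TPM >= 0.1) detection threshold. Rules
#' are evaluated in order and the first match wins:
#'
#' 1. median phi at the strict threshold >= `ueg_cut` -> `UEGs@1.0`
#'    (ubiquitous even under stringent detection);
#' 2. median phi at the loose threshold >= `ueg_cut` -> `UEGs@0.1`
#'    (ubiquitous only under sensitive detection, typically lowly
#'    expressed or variable genes);
#' 3. median phi at the loose threshold <= `seg_cut` -> `SEGs@0.1`
#'    (restricted even under sensitive detection);
#' 4. median phi at the strict threshold <= `seg_cut` -> `SEGs@1.0`;
#' 5. otherwise -> `MSG` (moderately specific).
#'
#' The five categories partition all clustered genes.
#'
#' @param clusters A `ueg_clusters` object.
#' @param spec A specificity table carrying both phi columns.
#' @param drm Optional `ueg_dynrange` table; when given, per-cluster median
#'   IQR, skewness and Q50 are added (needed later by [select_lovar()]).
#' @param ueg_cut,seg_cut Median-phi cutoffs (defaults 0.8 and 0.3).
#' @param phi_strict,phi_loose Names of the phi columns at the strict and
#'   loose thresholds.
#' @return A `ueg_categories` object; `tidy()` gives per-gene rows,
#'   `$clusters` the per-cluster summary.
#' @export
assign_categories <- function(clusters, spec, drm = NULL,
                              ueg_cut = 0.8, seg_cut = 0.3,
                              phi_strict = "phi_tpm_1",
                              phi_loose = "phi_tpm_0.1") {
  stopifnot(inherits(clusters, "ueg_clusters"))
  for (col in c(phi_strict, phi_loose)) {
    if (!col %in% names(spec)) {
      abort(sprintf("specificity table lacks required column '%s'", col))
    }
  }
  genes <- clusters$assignments
  sp <- left_join(genes, spec, by = "gene_id")
  if (anyNA(sp[[phi_strict]]) || anyNA(sp[[phi_loose]])) {
    abort("specificity table does not cover every clustered gene")
  }
  summ <- sp |>
    group_by(.data$cluster) |>
    summarise(size = n(),
              median_phi_strict = median(.data[[phi_strict]]),
              median_phi_loose = median(.data[[phi_loose]]),
              .groups = "drop")
  if (!is.null(drm)) {
    dr <- left_join(genes, drm, by = "gene_id") |>
      group_by(.data$cluster) |>
      summarise(median_iqr = median(.data$iqr),
                median_skewness = median(.data$skewness),
                median_q50 = median(.data$q50), .groups = "drop")
    summ <- left_join(summ, dr, by = "cluster")
  }
  summ <- left_join(summ, clusters$exemplars, by = "cluster")
  summ$category <- factor(with(summ, ifelse(
    median_phi_strict >= ueg_cut, "UEGs@1.0", ifelse(
      median_phi_loose >= ueg_cut, "UEGs@0.1", ifelse(
        median_phi_loose <= seg_cut, "SEGs@0.1", ifelse(
          median_phi_strict <= seg_cut, "SEGs@1.0", "MSG"))))),
    levels = ueg_category_levels)
  gene_cat <- genes |>
    left_join(select(summ, "cluster", "category"), by = "cluster")
  structure(list(clusters = summ, genes = gene_cat,
                 ueg_cut = ueg_cut, seg_cut = seg_cut),
            class = "ueg_categories")
}

#' @export
print.ueg_categories <- function(x, ...) {
  tab <- table(x$genes$category)
  cat("Specificity categories (genes per category):\n")
  print(tab)
  invisible(x)
}

#' @rdname assign_categories
#' @param x A `ueg_categories` object.
#' @param ... Unused.
#' @export
tidy.ueg_categories <- function(x, ...) x$genes

#' @rdname assign_categories
#' @export
glance.ueg_categories <- function(x, ...) {
  tab <- table(x$genes$category)
  out <- tibble(n_clusters = nrow(x$clusters), n_genes = nrow(x$genes))
  for (nm in names(tab)) out[[nm]] <- as.integer(tab[[nm]])
  out
}

#' Select low-variability UEGs (LoVarUEGs)
#'
#' From the clusters in a UEG category, keeps those whose median expression
#' variability (IQR of quantile ranks) is at most `iqr_cut`, takes all
#' their member genes, and then removes per-gene outliers whose raw-scale
#' dynamic range contradicts their rank-scale stability: within each
#' cluster, the robust z-score of `log10(Q95/Q5)` of the raw normalized
#' values (a small floor avoids division by zero) must not exceed
#' `outlier_z`. The surviving genes have stable relative expression across
#' the compendium and are usable as internal reference genes.
#'
#' @param categories A `ueg_categories` object built with a `drm` (so that
#'   per-cluster median IQR is available).
#' @param drm The `ueg_dynrange` table of quantile ranks (per-gene IQR).
#' @param raw The raw normalized expression table (e.g. TPM) used for the
#'   raw-scale outlier screen.
#' @param iqr_cut Maximum cluster-median IQR (default 0.2, the low
#'   variability band).
#' @param outlier_z Robust z-score cutoff (default 3).
#' @param floor Floor added to raw percentiles before the log fold range.
#' @return A `lovar_set` object; `tidy()` gives one row per considered
#'   gene with `selected` and outlier diagnostics, `$selected` the gene
#'   ids, `$outliers` the removed genes with reasons.
#' @export
select_lovar <- function(categories, drm, raw, iqr_cut = 0.2, outlier_z = 3,
                         floor = 1e-3) {
  stopifnot(inherits(categories, "ueg_categories"))
  if (!"median_iqr" %in% names(categories$clusters)) {
    abort("assign_categories() must be run with 'drm' so median IQR is known")
  }
  cl <- filter(categories$clusters,
               .data$category %in% c("UEGs@1.0", "UEGs@0.1"),
               .data$median_iqr <= iqr_cut)
  if (nrow(cl) == 0L) {
    warn("no UEG cluster passed the variability gate; empty LoVar set")
    empty <- tibble(gene_id = character(), cluster = integer(),
                    iqr = numeric(), fold_range = numeric(), z = numeric(),
                    selected = logical())
    return(structure(list(genes = empty, selected = character(),
                          outliers = empty, clusters = cl,
                          removed_fraction = NA_real_),
                     class = "lovar_set"))
  }
  members <- filter(categories$genes, .data$cluster %in% cl$cluster)
  m <- as_expr_matrix(raw)
  miss <- setdiff(members$gene_id, rownames(m))
  if (length(miss)) {
    abort(paste("raw matrix lacks gene(s):", paste(head(miss, 5),
                                                   collapse = ", ")))
  }
  sub <- m[members$gene_id, , drop = FALSE]
  q <- t(apply(sub, 1, quantile, probs = c(0.05, 0.95), type = 7,
               names = FALSE))
  fold <- log10((q[, 2] + floor) / (q[, 1] + floor))
  gen <- members |>
    left_join(select(drm, "gene_id", "iqr"), by = "gene_id") |>
    mutate(fold_range = fold) |>
    group_by(.data$cluster) |>
    mutate(z = robust_z(.data$fold_range)) |>
    ungroup() |>
    mutate(selected = .data$z <= outlier_z)
  outliers <- gen |>
    filter(!.data$selected) |>
    mutate(reason = sprintf("raw fold-range robust z = %.2f > %.1f",
                            .data$z, outlier_z))
  structure(list(
    genes = gen,
    selected = gen$gene_id[gen$selected],
    outliers = outliers,
    clusters = cl,
    removed_fraction = nrow(outliers) / nrow(gen)
  ), class = "lovar_set")
}

## robust z-score; zero spread -> all zeros (no outliers detectable)
robust_z <- function(x) {
  s <- mad(x)
  if (s == 0) return(rep(0, length(x)))
  (x - median(x)) / s
}

#' @export
print.lovar_set <- function(x, ...) {
  cat(sprintf(
    "LoVarUEG set: %d genes from %d clusters (%d outliers removed, %.2f%%)\n",
    length(x$selected), nrow(x$clusters), nrow(x$outliers),
    100 * (x$removed_fraction %||% 0)))
  invisible(x)
}

#' @rdname select_lovar
#' @param x A `lovar_set` object.
#' @param ... Unused.
#' @export
tidy.lovar_set <- function(x, ...) x$genes

#' @rdname select_lovar
#' @export
glance.lovar_set <- function(x, ...) {
  tibble(n_selected = length(x$selected), n_clusters = nrow(x$clusters),
         n_outliers = nrow(x$outliers),
         removed_pct = 100 * (x$removed_fraction %||% NA_real_))
}
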