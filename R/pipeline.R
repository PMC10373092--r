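pipeline_sections <- list(
  input = c("counts", "lengths", "annotation", "id_map", "unit"),
  qc = c("ref_genes", "enabled"),
  thresholds = c("strict", "loose"),
  grid = c("from", "to", "by"),
  clustering = c("method", "seed", "k", "damping", "preference", "maxit",
                 "convits"),
  categories = c("ueg_cut", "seg_cut"),
  lovar = c("iqr_cut", "outlier_z"),
  output = c("dir"),
  seed = NULL
)

#' Pipeline configuration
#'
#' Validates a nested configuration list (or YAML file) against the known
#' sections and keys; unknown keys are an error before any computation.
#' Sections: `input` (file paths: `counts`, `lengths`, `annotation`,
#' optional `id_map`; `unit` of the counts file), `qc` (`ref_genes`,
#' `enabled`), `thresholds` (`strict`, `loose` TPM values), `grid`
#' (`from`/`to`/`by` percentiles), `clustering` (`method`, `seed`, `k`,
#' `damping`, `preference`, `maxit`, `convits`), `categories`
#' (`ueg_cut`, `seg_cut`), `lovar` (`iqr_cut`, `outlier_z`), `output`
#' (`dir`), and a top-level `seed`.
#'
#' @param config A nested list, or a path to a YAML file with the same
#'   structure.
#' @return The validated configuration with defaults filled in.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  bad_sections <- setdiff(names(config), names(pipeline_sections))
  if (length(bad_sections)) {
    abort(paste("unknown config section(s):",
                paste(bad_sections, collapse = ", ")))
  }
  for (sec in setdiff(names(config), "seed")) {
    bad <- setdiff(names(config[[sec]]), pipeline_sections[[sec]])
    if (length(bad)) {
      abort(sprintf("unknown key(s) in config section '%s': %s", sec,
                    paste(bad, collapse = ", ")))
    }
  }
  defaults <- list(
    input = list(unit = "counts"),
    qc = list(ref_genes = NULL, enabled = TRUE),
    thresholds = list(strict = 1.0, loose = 0.1),
    grid = list(from = 5, to = 95, by = 5),
    clustering = list(method = "affinity", seed = NULL, k = NULL,
                      damping = 0.9, preference = NULL, maxit = 500,
                      convits = 50),
    categories = list(ueg_cut = 0.8, seg_cut = 0.3),
    lovar = list(iqr_cut = 0.2, outlier_z = 3),
    output = list(dir = NULL),
    seed = 1L
  )
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$clustering$seed)) cfg$clustering$seed <- cfg$seed
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full UEG characterization pipeline
#'
#' Orchestrates all stages on a counts matrix: reference-gene QC, TPM
#' normalization, sample-wise quantile transformation, specificity at the
#' loose and strict detection thresholds (plus tissue specificity if
#' annotated), transcriptome sizes, dynamic ranges, percentile clustering,
#' five-way categorization, and LoVarUEG selection. When `output$dir` is
#' set, every stage table is written as TSV along with a JSON run manifest
#' (seed, thresholds, output list); reruns with the same inputs and seed
#' produce byte-identical outputs.
#'
#' @param config A [pipeline_config()] list or YAML path.
#' @param data Optional list with `counts` (expression table), `lengths`,
#'   and optionally `annotation` and `id_map`, bypassing the `input` file
#'   paths.
#' @return A list of stage artifacts: `qc`, `tpm`, `quantile`, `spec`,
#'   `sizes`, `drm`, `clusters`, `categories`, `lovar`, `manifest`.
#' @export
run_pipeline <- function(config = list(), data = NULL) {
  cfg <- pipeline_config(config)
  if (is.null(data)) {
    if (is.null(cfg$input$counts) || is.null(cfg$input$lengths)) {
      abort("config$input must name 'counts' and 'lengths' files (or pass data=)")
    }
    data <- run_stage("input", list(
      counts = read_expression(cfg$input$counts, unit = cfg$input$unit),
      lengths = read_gene_lengths(cfg$input$lengths),
      annotation = if (!is.null(cfg$input$annotation))
        read_annotation(cfg$input$annotation),
      id_map = if (!is.null(cfg$input$id_map))
        read_id_map(cfg$input$id_map)
    ))
  }
  counts <- data$counts
  if (!is.null(data$id_map)) {
    counts <- run_stage("collapse", collapse_to_genes(counts, data$id_map))
  }
  qc <- NULL
  if (isTRUE(cfg$qc$enabled) && !is.null(cfg$qc$ref_genes)) {
    qcres <- run_stage("qc", qc_filter(counts, cfg$qc$ref_genes))
    counts <- qcres$matrix
    qc <- qcres$report
  }
  tpm <- run_stage("normalize", tpm_normalize(counts, data$lengths))
  qmat <- run_stage("quantile", quantile_transform(tpm))
  th_loose <- detection_threshold("TPM", cfg$thresholds$loose)
  th_strict <- detection_threshold("TPM", cfg$thresholds$strict)
  spec <- run_stage("specificity",
    specificity_table(tpm, thresholds = list(th_loose, th_strict),
                      annotation = data$annotation))
  sizes <- run_stage("sizes",
    transcriptome_sizes(detect_expression(tpm, th_loose)))
  grid <- seq(cfg$grid$from, cfg$grid$to, by = cfg$grid$by)
  drm <- run_stage("dynamic_range", dynamic_range(qmat, grid = grid))
  clusters <- run_stage("clustering", percentile_cluster(
    drm, method = cfg$clustering$method, seed = cfg$clustering$seed,
    k = cfg$clustering$k, damping = cfg$clustering$damping,
    maxit = cfg$clustering$maxit, convits = cfg$clustering$convits,
    preference = cfg$clustering$preference))
  phi_loose_col <- paste0("phi_", threshold_label(th_loose))
  phi_strict_col <- paste0("phi_", threshold_label(th_strict))
  categories <- run_stage("categories", assign_categories(
    clusters, spec, drm = drm, ueg_cut = cfg$categories$ueg_cut,
    seg_cut = cfg$categories$seg_cut, phi_strict = phi_strict_col,
    phi_loose = phi_loose_col))
  lovar <- run_stage("lovar", select_lovar(
    categories, drm, tpm, iqr_cut = cfg$lovar$iqr_cut,
    outlier_z = cfg$lovar$outlier_z))
  manifest <- list(
    package = "uegkit",
    version = as.character(utils::packageVersion("uegkit")),
    seed = cfg$seed,
    thresholds = list(loose = cfg$thresholds$loose,
                      strict = cfg$thresholds$strict),
    grid = grid,
    clustering = cfg$clustering[c("method", "seed", "damping")],
    outputs = character()
  )
  res <- list(qc = qc, tpm = tpm, quantile = qmat, spec = spec,
              sizes = sizes, drm = drm, clusters = clusters,
              categories = categories, lovar = lovar, manifest = manifest)
  if (!is.null(cfg$output$dir)) {
    res$manifest <- run_stage("output", write_pipeline_outputs(
      res, cfg$output$dir, manifest))
  }
  res
}

write_pipeline_outputs <- function(res, dir, manifest) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    path <- file.path(dir, name)
    readr::write_tsv(x, path, progress = FALSE)
    name
  }
  out <- c(
    w(res$tpm, "tpm.tsv"),
    w(res$quantile, "quantile.tsv"),
    w(res$spec, "specificity.tsv"),
    w(res$sizes, "transcriptome_sizes.tsv"),
    w(res$drm, "dynamic_range.tsv"),
    w(tidy(res$clusters), "clusters.tsv"),
    w(res$categories$clusters, "cluster_categories.tsv"),
    w(tidy(res$categories), "gene_categories.tsv"),
    w(tidy(res$lovar), "lovar.tsv")
  )
  if (!is.null(res$qc)) {
    out <- c(out, w(tidy(res$qc), "qc_flags.tsv"))
  }
  manifest$outputs <- out
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}
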