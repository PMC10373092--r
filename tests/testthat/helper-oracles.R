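# Independent brute-force oracles and small fixture builders.

# expression table from a matrix with autogenerated dimnames
tiny_expr <- function(m, unit = "TPM") {
  if (is.null(dim(m))) m <- matrix(m, ncol = 1)
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  expression_tbl(m, unit = unit)
}

# random non-negative matrix with zeros and ties
rand_expr_matrix <- function(nr, nc, zero_frac = 0.3) {
  vals <- sample(c(0, 1, 2, 5, 5, 10, round(runif(6, 0, 50), 2)),
                 nr * nc, replace = TRUE)
  vals[runif(nr * nc) < zero_frac] <- 0
  m <- matrix(vals, nr, nc)
  rownames(m) <- sprintf("g%03d", seq_len(nr))
  colnames(m) <- sprintf("s%03d", seq_len(nc))
  m
}

# Quantile transform by direct double-loop counting (the definition itself)
brute_quantile <- function(m) {
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    denom <- sum(m[, j] > 0)
    for (i in seq_len(nrow(m))) {
      if (m[i, j] > 0) {
        out[i, j] <- sum(m[, j] > 0 & m[, j] <= m[i, j]) / denom
      }
    }
  }
  out
}

# Global specificity by explicit loop counting
brute_phi <- function(m, thr) {
  vapply(seq_len(nrow(m)), function(i) {
    n_expr <- 0
    for (j in seq_len(ncol(m))) if (m[i, j] >= thr) n_expr <- n_expr + 1
    n_expr / ncol(m)
  }, numeric(1))
}

# Adjusted Fisher-Pearson skewness by direct summation
skew_oracle <- function(x) {
  n <- length(x)
  xb <- mean(x)
  s <- sqrt(sum((x - xb)^2) / (n - 1))
  total <- 0
  for (v in x) total <- total + ((v - xb) / s)^3
  n / ((n - 1) * (n - 2)) * total
}

# small quick simulator config (fast unit-test scale)
small_sim_config <- function(seed = 11, samples_per_tissue = 10, ...) {
  sim_config(
    samples_per_tissue = samples_per_tissue,
    classes = list(
      ueg_high = gene_class(60, log(1000), 1.0, 0.2),
      ueg_low = gene_class(40, log(5), 2.2, 1.5),
      msg = gene_class(30, log(100), 1.0, 0.5),
      seg = gene_class(60, log(100), 1.0, 0.5),
      disallowed = gene_class(9, log(8), 0.3, 0.2),
      qc_ref = gene_class(3, log(20), 0.1, 0.2)
    ),
    seed = seed,
    ...
  )
}

qc_gene_ids <- function(sim) sim$truth$gene_id[sim$truth$class == "qc_ref"]

# dynamic-range-like fixture with two planted shape groups
two_shape_drm <- function(n_per = 25, noise = 0.01, seed = 42) {
  withr::with_seed(seed, {
    grid <- seq(5, 95, 5)
    high <- t(vapply(seq_len(n_per), function(i) {
      pmin(pmax(0.8 + rnorm(length(grid), 0, noise), 0), 1)
    }, numeric(length(grid))))
    low <- t(vapply(seq_len(n_per), function(i) {
      pmin(pmax(0.15 + rnorm(length(grid), 0, noise), 0), 1)
    }, numeric(length(grid))))
    m <- rbind(high, low)
    m <- t(apply(m, 1, sort))  # keep rows monotone like real percentiles
    colnames(m) <- sprintf("s%02d", seq_along(grid))
    rownames(m) <- c(sprintf("hi%02d", seq_len(n_per)),
                     sprintf("lo%02d", seq_len(n_per)))
    drm <- dynamic_range(expression_tbl(m, "quantile"), grid = grid)
    # replace percentile columns with the planted vectors themselves
    for (i in seq_along(grid)) drm[[sprintf("q%02d", grid[i])]] <- m[, i]
    drm
  })
}

# demo-scale artifacts, generated once and shared across test files
.demo_cache <- new.env(parent = emptyenv())

demo_artifacts <- function() {
  if (!is.null(.demo_cache$art)) return(.demo_cache$art)
  cfg <- sim_config(seed = 20211)
  sim <- simulate_compendium(cfg)
  qc <- qc_filter(sim$counts, ref_genes = qc_gene_ids(sim))
  tpm <- tpm_normalize(qc$matrix, sim$lengths)
  qmat <- quantile_transform(tpm)
  spec <- specificity_table(tpm)
  drm <- suppressWarnings(dynamic_range(qmat))
  .demo_cache$art <- list(cfg = cfg, sim = sim, qc = qc, tpm = tpm,
                          qmat = qmat, spec = spec, drm = drm)
  .demo_cache$art
}

demo_pipeline <- function() {
  if (!is.null(.demo_cache$pipe)) return(.demo_cache$pipe)
  art <- demo_artifacts()
  .demo_cache$pipe <- suppressMessages(suppressWarnings(run_pipeline(
    list(seed = 7, qc = list(ref_genes = qc_gene_ids(art$sim))),
    data = list(counts = art$sim$counts, lengths = art$sim$lengths,
                annotation = art$sim$annotation)
  )))
  .demo_cache$pipe
}
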