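#' Gene-class settings for the compendium simulator
#'
#' @param n Number of genes in the class.
#' @param meanlog,sdlog Log-normal location and scale of the per-gene
#'   baseline mean expression (nominal TPM units after the generator's
#'   global rescale).
#' @param sdlog_within Log-scale SD of the per-sample multiplicative
#'   biological noise around a gene's baseline (0 = none).
#' @return A `gene_class` list.
#' @export
gene_class <- function(n, meanlog, sdlog, sdlog_within = 0) {
  stopifnot(n >= 0, sdlog >= 0, sdlog_within >= 0)
  structure(list(n = as.integer(n), meanlog = meanlog, sdlog = sdlog,
                 sdlog_within = sdlog_within), class = "gene_class")
}

#' Configuration for the synthetic transcriptome compendium
#'
#' The generator emulates the statistical structure a UEG analysis
#' assumes: a bimodal specificity landscape made of ubiquitously
#' high-expressed genes (`ueg_high`, stable housekeeping-like), ubiquitous
#' but lowly expressed and more variable genes (`ueg_low`), moderately
#' specific genes active in a subset of tissues (`msg`), tissue-restricted
#' genes (`seg`), disallowed-type genes (ubiquitous, stable, repressed in
#' one tissue), and three guaranteed-positive QC reference genes; plus
#' library-size and batch variation, and detection dropout concentrated at
#' low expression.
#'
#' Defaults describe the bundled demo compendium: 2000 genes (after the
#' class counts below) across 8 tissue groups x 50 samples = 400
#' transcriptomes.
#'
#' @param n_tissues Number of tissue groups (>= 2).
#' @param samples_per_tissue Scalar or length-`n_tissues` vector (uneven
#'   designs emulate tissue overrepresentation).
#' @param classes Named list of [gene_class()] settings; the names
#'   `ueg_high`, `ueg_low`, `msg`, `seg`, `disallowed`, `qc_ref` are
#'   recognized.
#' @param seg_tissue_breadth,msg_tissue_breadth Number of tissues a
#'   restricted / moderately specific gene occupies.
#' @param repression_factor Multiplier applied to a disallowed gene's mean
#'   in its repressed tissue.
#' @param dropout_midpoint Mean expression (nominal TPM) at which the
#'   dropout probability is 0.5; `0` disables dropout.
#' @param dropout_steepness Slope of the logistic dropout curve in log
#'   mean expression.
#' @param lib_sdlog Log-scale SD of per-sample library-size factors.
#' @param n_batches,batch_sdlog Number of batches and log-scale SD of the
#'   multiplicative batch factors.
#' @param depth Expected total read count per (unit-factor) sample.
#' @param bad_sample_frac Fraction of samples planted as low quality (one
#'   QC reference gene zeroed).
#' @param length_range Gene lengths are drawn log-uniformly in this bp
#'   range, so TPM and RPKM orderings differ.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `ueg_sim_config` list.
#' @export
sim_config <- function(n_tissues = 8,
                       samples_per_tissue = 50,
                       classes = list(
                         ueg_high = gene_class(600, log(1000), 1.0, 0.2),
                         ueg_low = gene_class(380, log(5), 2.2, 1.5),
                         msg = gene_class(300, log(100), 1.0, 0.5),
                         seg = gene_class(600, log(100), 1.0, 0.5),
                         disallowed = gene_class(9, log(8), 0.3, 0.2),
                         qc_ref = gene_class(3, log(20), 0.1, 0.2)
                       ),
                       seg_tissue_breadth = 1,
                       msg_tissue_breadth = 4,
                       repression_factor = 0.002,
                       dropout_midpoint = 0.001,
                       dropout_steepness = 0.35,
                       lib_sdlog = 0.3,
                       n_batches = 4,
                       batch_sdlog = 0.2,
                       depth = 1e7,
                       bad_sample_frac = 0.05,
                       length_range = c(500, 1e4),
                       seed = 20211) {
  cfg <- structure(as.list(environment()), class = "ueg_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "ueg_sim_config"))
  if (cfg$n_tissues < 2) abort("need at least 2 tissues")
  spt <- cfg$samples_per_tissue
  if (!length(spt) %in% c(1L, cfg$n_tissues) || any(spt < 1)) {
    abort("samples_per_tissue must be a positive scalar or one value per tissue")
  }
  known <- c("ueg_high", "ueg_low", "msg", "seg", "disallowed", "qc_ref")
  bad <- setdiff(names(cfg$classes), known)
  if (length(bad)) {
    abort(paste("unknown gene class(es):", paste(bad, collapse = ", ")))
  }
  ok <- vapply(cfg$classes, inherits, logical(1), "gene_class")
  if (!all(ok)) abort("every class entry must be built with gene_class()")
  if (sum(vapply(cfg$classes, `[[`, integer(1), "n")) < 2) {
    abort("need at least 2 genes in total")
  }
  if (cfg$seg_tissue_breadth < 1 || cfg$seg_tissue_breadth > cfg$n_tissues ||
      cfg$msg_tissue_breadth < 1 || cfg$msg_tissue_breadth > cfg$n_tissues) {
    abort("tissue breadths must lie in [1, n_tissues]")
  }
  if (cfg$repression_factor < 0 || cfg$repression_factor > 1) {
    abort("repression_factor must lie in [0, 1]")
  }
  if (cfg$bad_sample_frac < 0 || cfg$bad_sample_frac > 1) {
    abort("bad_sample_frac must lie in [0, 1]")
  }
  if (cfg$dropout_midpoint < 0 || cfg$dropout_steepness <= 0) {
    abort("dropout_midpoint must be >= 0 and dropout_steepness > 0")
  }
  if (cfg$lib_sdlog < 0 || cfg$batch_sdlog < 0 || cfg$n_batches < 1 ||
      cfg$depth <= 0) {
    abort("library/batch/depth settings must be non-negative (depth > 0)")
  }
  if (length(cfg$length_range) != 2 || any(cfg$length_range <= 0) ||
      diff(cfg$length_range) < 0) {
    abort("length_range must be an increasing positive pair")
  }
  invisible(cfg)
}

class_prefix <- c(ueg_high = "UEGH", ueg_low = "UEGL", msg = "MSG",
                  seg = "SEG", disallowed = "DAG", qc_ref = "QCREF")

## Deterministic design phase shared by the generator and expected_phi():
## consumes the leading part of the seeded RNG stream in a fixed order.
sim_design <- function(cfg) {
  cls <- cfg$classes
  n_per <- vapply(cls, `[[`, integer(1), "n")
  classes <- rep(names(cls), n_per)
  n <- length(classes)
  gene_id <- unlist(lapply(names(cls), function(nm) {
    if (n_per[[nm]] == 0L) return(character())
    sprintf("%s_%04d", class_prefix[[nm]], seq_len(n_per[[nm]]))
  }), use.names = FALSE)
  lengths_bp <- round(exp(runif(n, log(cfg$length_range[1]),
                                log(cfg$length_range[2]))))
  base_mean <- unlist(lapply(names(cls), function(nm) {
    c <- cls[[nm]]
    if (c$n == 0L) return(numeric())
    rlnorm(c$n, c$meanlog, c$sdlog)
  }), use.names = FALSE)
  sdw <- unlist(lapply(names(cls), function(nm) {
    rep(cls[[nm]]$sdlog_within, cls[[nm]]$n)
  }), use.names = FALSE)
  tt <- cfg$n_tissues
  active <- matrix(TRUE, n, tt)
  repressed <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (classes[i] == "seg") {
      active[i, ] <- FALSE
      active[i, sample.int(tt, cfg$seg_tissue_breadth)] <- TRUE
    } else if (classes[i] == "msg") {
      active[i, ] <- FALSE
      active[i, sample.int(tt, cfg$msg_tissue_breadth)] <- TRUE
    } else if (classes[i] == "disallowed") {
      repressed[i] <- sample.int(tt, 1)
    }
  }
  mu <- base_mean * active
  dis <- which(classes == "disallowed")
  if (length(dis)) {
    mu[cbind(dis, repressed[dis])] <-
      base_mean[dis] * cfg$repression_factor
  }
  # global rescale so an average tissue's nominal TPM total is 1e6,
  # putting class means on an interpretable TPM scale
  scale <- 1e6 / mean(colSums(mu))
  mu <- mu * scale
  base_mean <- base_mean * scale
  # dropout probability per gene x tissue, logistic-decreasing in log mean
  p_drop <- matrix(0, n, tt)
  if (cfg$dropout_midpoint > 0) {
    pos <- mu > 0
    p_drop[pos] <- plogis(cfg$dropout_steepness *
                            (log(cfg$dropout_midpoint) - log(mu[pos])))
    p_drop[classes == "qc_ref", ] <- 0
  }
  spt <- rep(cfg$samples_per_tissue, length.out = cfg$n_tissues)
  rho <- cfg$depth / mean(colSums(mu * (lengths_bp / 1000)))
  list(gene_id = gene_id, class = classes, lengths_bp = lengths_bp,
       base_mean = base_mean, sdw = sdw, active = active,
       repressed = repressed, mu = mu, p_drop = p_drop, spt = spt,
       rho = rho)
}

#' Generate a synthetic transcriptome compendium with truth tables
#'
#' Mechanism: each gene draws a baseline mean from its class log-normal;
#' restricted genes are active only in their assigned tissues; disallowed
#' genes keep their baseline everywhere except the repressed tissue, where
#' the mean is multiplied by `repression_factor`. Per sample, a
#' library-size factor and a batch factor multiply all genes, per-gene
#' log-normal within noise perturbs the mean, counts are Poisson of the
#' scaled means (rate proportional to gene length, so TPM/RPKM
#' normalization is exercised), and dropout independently zeroes values
#' with a probability that decreases logistically in log mean expression.
#' QC reference genes are kept positive in good samples; a planted
#' fraction of bad samples has one QC reference gene zeroed.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (expression table), `lengths`,
#'   `annotation`, `truth` (per-gene class, planted means, active and
#'   repressed tissues, dropout, stability flag), `bad_samples`, and the
#'   resolved `config`.
#' @export
simulate_compendium <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    d <- sim_design(config)
    n <- length(d$gene_id)
    spt <- d$spt
    ns <- sum(spt)
    tissue_of <- rep(seq_len(config$n_tissues), times = spt)
    sample_id <- sprintf("S%04d", seq_len(ns))
    batch <- sample.int(config$n_batches, ns, replace = TRUE)
    batch_fac <- rlnorm(config$n_batches, 0, config$batch_sdlog)
    lib_fac <- rlnorm(ns, 0, config$lib_sdlog)
    f <- lib_fac * batch_fac[batch]
    W <- matrix(rlnorm(n * ns, 0, d$sdw), n, ns)
    lambda <- d$mu[, tissue_of, drop = FALSE] * W *
      (d$lengths_bp / 1000) * d$rho
    lambda <- sweep(lambda, 2, f, "*")
    counts <- matrix(rpois(n * ns, lambda), n, ns)
    # dropout thinning
    pd <- d$p_drop[, tissue_of, drop = FALSE]
    counts[matrix(runif(n * ns), n, ns) < pd] <- 0L
    # QC reference genes: guaranteed positive in good samples
    qc_rows <- which(d$class == "qc_ref")
    if (length(qc_rows)) {
      counts[qc_rows, ] <- pmax(counts[qc_rows, , drop = FALSE], 1L)
    }
    n_bad <- round(config$bad_sample_frac * ns)
    bad <- sort(sample.int(ns, n_bad))
    if (length(qc_rows) && n_bad > 0) {
      zero_gene <- sample(qc_rows, n_bad, replace = TRUE)
      counts[cbind(zero_gene, bad)] <- 0L
    }
    dimnames(counts) <- list(d$gene_id, sample_id)
    annotation <- tibble(
      sample_id = sample_id,
      tissue_group = sprintf("tissue%02d", tissue_of),
      source_type = ifelse(batch %% 2 == 0, "in_vitro", "in_vivo"),
      study_id = sprintf("study%02d", batch)
    )
    truth <- tibble(
      gene_id = d$gene_id,
      class = d$class,
      base_mean = d$base_mean,
      sdlog_within = d$sdw,
      length_bp = d$lengths_bp,
      active_tissues = vapply(seq_len(n), function(i) {
        paste(sprintf("tissue%02d", which(d$active[i, ])), collapse = ",")
      }, character(1)),
      repressed_tissue = ifelse(is.na(d$repressed), NA_character_,
                                sprintf("tissue%02d", d$repressed)),
      dropout_prob = rowSums(d$p_drop * d$active) /
        pmax(rowSums(d$active), 1),
      stable = d$class == "ueg_high"
    )
    list(
      counts = expression_tbl(counts, unit = "counts"),
      lengths = tibble(gene_id = d$gene_id,
                       length = as.integer(d$lengths_bp)),
      annotation = annotation,
      truth = truth,
      bad_samples = sample_id[bad],
      config = config
    )
  })
}

#' Expected global specificity under a simulator configuration
#'
#' The analytic/Monte-Carlo oracle for phi recovery: for each gene it
#' composes the tissue design, the dropout curve and the count model into
#' the expected fraction of samples detecting the gene at the threshold.
#' The per-tissue detection probability is computed in closed form from
#' the Poisson tail given a sample factor, averaged by Monte Carlo over
#' the library/batch factor and the within-gene noise with a dedicated
#' seed (independent of the generator's sampling phase; the denominator of
#' the TPM transform is taken at its conditional expectation, which is
#' accurate because thousands of genes contribute to it). The expectation
#' refers to good-quality samples, i.e. the compendium after the reference
#' gene QC filter has removed the planted bad samples.
#'
#' @param config A [sim_config()].
#' @param threshold A TPM [detection_threshold()].
#' @param mc_reps Monte-Carlo replicates for the factor/noise average.
#' @param mc_seed Seed of the Monte-Carlo average (defaults to a fixed
#'   offset of the config seed).
#' @return A tibble with `gene_id`, `class`, `expected_phi`.
#' @export
expected_phi <- function(config, threshold = detection_threshold("TPM", 0.1),
                         mc_reps = 1000, mc_seed = NULL) {
  validate_sim_config(config)
  if (threshold$unit != "TPM") abort("expected_phi is defined for TPM thresholds")
  d <- withr::with_seed(config$seed, sim_design(config))
  mc_seed <- mc_seed %||% ((config$seed + 1000003L) %% .Machine$integer.max)
  n <- length(d$gene_id)
  tt <- config$n_tissues
  w <- d$spt / sum(d$spt)
  ew <- exp(d$sdw^2 / 2)
  lkb <- d$lengths_bp / 1000
  # E[sum(c/l) | f] per unit f, per tissue (dropout-thinned)
  dconst <- colSums((1 - d$p_drop) * d$mu * ew) * d$rho / 1000
  base_rate <- d$mu * (lkb * d$rho)  # n x tt, per unit f and W
  withr::with_seed(mc_seed, {
    fdraws <- rlnorm(mc_reps, 0, config$lib_sdlog) *
      rlnorm(mc_reps, 0, config$batch_sdlog)
    acc <- matrix(0, n, tt)
    for (r in seq_len(mc_reps)) {
      fr <- fdraws[r]
      Wr <- rlnorm(n, 0, d$sdw)
      for (t in seq_len(tt)) {
        cmin <- pmax(1, ceiling(threshold$value * fr * dconst[t] *
                                  lkb * 1000 / 1e6))
        lam <- base_rate[, t] * Wr * fr
        acc[, t] <- acc[, t] + ppois(cmin - 1, lam, lower.tail = FALSE)
      }
    }
    acc <- acc / mc_reps
  })
  det <- (1 - d$p_drop) * acc
  phi <- as.vector(det %*% w)
  tibble(gene_id = d$gene_id, class = d$class, expected_phi = phi)
}

#' Bundled candidate-gene scenario
#'
#' Builds the 16-gene candidate list used to demonstrate the disallowed
#' gene evaluation: the planted disallowed genes (ubiquitous, stable,
#' repressed in one tissue; expected verdict `constitutive` with their
#' repressed tissue flagged) plus tissue-restricted genes (expected
#' verdict `restricted`).
#'
#' @param sim Output of [simulate_compendium()].
#' @param n_stable,n_variable Number of stable-ubiquitous and
#'   variable/restricted candidates.
#' @return A tibble with `gene_id` and `planted`
#'   (`"stable_ubiquitous"` / `"variable_restricted"`).
#' @export
candidate_scenario <- function(sim, n_stable = 9, n_variable = 7) {
  truth <- sim$truth
  stable <- head(truth$gene_id[truth$class == "disallowed"], n_stable)
  varres <- head(truth$gene_id[truth$class == "seg"], n_variable)
  if (length(stable) < n_stable || length(varres) < n_variable) {
    abort("configuration does not contain enough disallowed/seg genes")
  }
  tibble(
    gene_id = c(stable, varres),
    planted = rep(c("stable_ubiquitous", "variable_restricted"),
                  c(n_stable, n_variable))
  )
}
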