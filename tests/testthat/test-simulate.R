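test_that("simulation is deterministic and validates its configuration", {
  cfg <- small_sim_config(seed = 21)
  s1 <- simulate_compendium(cfg)
  s2 <- simulate_compendium(cfg)
  expect_identical(as_expr_matrix(s1$counts), as_expr_matrix(s2$counts))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_compendium(small_sim_config(seed = 22))
  expect_false(identical(as_expr_matrix(s1$counts),
                         as_expr_matrix(s3$counts)))
  expect_error(sim_config(n_tissues = 1), "at least 2 tissues")
  expect_error(sim_config(repression_factor = 2), "repression_factor")
  expect_error(sim_config(bad_sample_frac = -0.1), "bad_sample_frac")
  expect_error(sim_config(length_range = c(100, 50)), "length_range")
  expect_error(sim_config(not_a_knob = 1), "unused argument")
  expect_error(sim_config(classes = list(oops = gene_class(5, 0, 1))),
               "unknown gene class")
})

test_that("without restricted classes or dropout, phi is 1 by construction", {
  cfg <- sim_config(
    n_tissues = 4, samples_per_tissue = 6,
    classes = list(ueg_high = gene_class(30, log(1000), 0.5, 0),
                   qc_ref = gene_class(3, log(50), 0.1, 0)),
    dropout_midpoint = 0, bad_sample_frac = 0, seed = 30)
  sim <- simulate_compendium(cfg)
  tpm <- tpm_normalize(sim$counts, sim$lengths)
  phi <- global_specificity(detect_expression(tpm,
                                              detection_threshold("TPM", 0.1)))
  expect_true(all(phi$phi == 1))
})

test_that("expected_phi composes tissue design, dropout and sampling", {
  # restricted gene in 1 of 4 equal tissues, no dropout -> 0.25
  cfg <- sim_config(
    n_tissues = 4, samples_per_tissue = 10,
    classes = list(seg = gene_class(10, log(1000), 0.3, 0),
                   ueg_high = gene_class(10, log(1000), 0.3, 0)),
    seg_tissue_breadth = 1, dropout_midpoint = 0, bad_sample_frac = 0,
    seed = 31)
  ep <- expected_phi(cfg, mc_reps = 50)
  expect_equal(ep$expected_phi[ep$class == "seg"], rep(0.25, 10),
               tolerance = 1e-6)
  expect_equal(ep$expected_phi[ep$class == "ueg_high"], rep(1, 10),
               tolerance = 1e-6)
  # uneven design: restricted gene's phi equals its tissues' sample share
  cfg2 <- sim_config(
    n_tissues = 4, samples_per_tissue = c(70, 10, 10, 10),
    classes = list(seg = gene_class(20, log(1000), 0.3, 0)),
    seg_tissue_breadth = 1, dropout_midpoint = 0, bad_sample_frac = 0,
    seed = 32)
  ep2 <- expected_phi(cfg2, mc_reps = 50)
  sim2 <- simulate_compendium(cfg2)
  share <- c(tissue01 = 0.7, tissue02 = 0.1, tissue03 = 0.1, tissue04 = 0.1)
  expect_equal(ep2$expected_phi,
               unname(share[sim2$truth$active_tissues]), tolerance = 1e-6)
  # uniform planted dropout of 0.1 -> expected phi 0.9
  cfg3 <- sim_config(
    n_tissues = 2, samples_per_tissue = 10,
    seg_tissue_breadth = 1, msg_tissue_breadth = 1,
    classes = list(ueg_high = gene_class(20, log(1e5), 0, 0)),
    dropout_midpoint = (1e6 / 20) * exp(qlogis(0.1)), dropout_steepness = 1,
    bad_sample_frac = 0, seed = 33)
  # with a single class of identical means, the rescale fixes mu = 1e6/20
  ep3 <- expected_phi(cfg3, mc_reps = 50,
                      threshold = detection_threshold("TPM", 0.1))
  expect_equal(ep3$expected_phi, rep(0.9 * 1, 20), tolerance = 1e-3)
})

test_that("estimated phi converges to expected_phi as samples grow", {
  phi_err <- function(spt, seed) {
    cfg <- small_sim_config(seed = seed, samples_per_tissue = spt)
    sim <- simulate_compendium(cfg)
    qc <- qc_filter(sim$counts, ref_genes = qc_gene_ids(sim))
    tpm <- tpm_normalize(qc$matrix, sim$lengths)
    phi <- global_specificity(detect_expression(
      tpm, detection_threshold("TPM", 0.1)))
    ep <- expected_phi(cfg, mc_reps = 400)
    mean(abs(phi$phi - ep$expected_phi[match(phi$gene_id, ep$gene_id)]))
  }
  expect_lt(phi_err(125, seed = 41), phi_err(13, seed = 41))
})

test_that("planted variance structure: ubiquitous-high below restricted IQR", {
  sim <- simulate_compendium(small_sim_config(seed = 51))
  qc <- qc_filter(sim$counts, ref_genes = qc_gene_ids(sim))
  tpm <- tpm_normalize(qc$matrix, sim$lengths)
  drm <- suppressWarnings(dynamic_range(quantile_transform(tpm)))
  j <- dplyr::inner_join(drm, sim$truth, by = "gene_id")
  # ueg_high genes keep stable ranks; variable ubiquitous genes vary more
  expect_lt(median(j$iqr[j$class == "ueg_high"]),
            median(j$iqr[j$class == "ueg_low"]))
})

test_that("planted bad samples are exactly the ones the QC filter removes", {
  cfg <- small_sim_config(seed = 61, bad_sample_frac = 0.1)
  sim <- simulate_compendium(cfg)
  expect_length(sim$bad_samples, round(0.1 * sum(rep(10, 8))))
  res <- qc_filter(sim$counts, ref_genes = qc_gene_ids(sim))
  expect_setequal(res$report$removed, sim$bad_samples)
})

test_that("gene lengths vary so the two normalization units diverge", {
  sim <- simulate_compendium(small_sim_config(seed = 71))
  expect_true(all(sim$lengths$length >= 500 & sim$lengths$length <= 1e4))
  tpm <- as_expr_matrix(tpm_normalize(sim$counts, sim$lengths))
  rpkm <- as_expr_matrix(rpkm_normalize(sim$counts, sim$lengths))
  # within a sample the units differ by a scalar, but that scalar differs
  # across samples, so unit-specific thresholds call different gene sets
  ratio <- colSums(tpm) / colSums(rpkm)
  expect_gt(diff(range(ratio)) / mean(ratio), 0.01)
  det_tpm <- colSums(tpm >= 0.1)
  det_rpkm <- colSums(rpkm >= 0.3)
  expect_false(all(det_tpm == det_rpkm))
})
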