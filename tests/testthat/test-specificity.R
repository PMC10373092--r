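test_that("detection is inclusive at the threshold and checks units", {
  m <- matrix(c(0, 0.1, 0.0999, 5), 4, 1)
  x <- tiny_expr(m, "TPM")
  det <- detect_expression(x, detection_threshold("TPM", 0.1))
  expect_equal(unname(uegkit:::detection_matrix(det)[, 1]),
               c(FALSE, TRUE, FALSE, TRUE))
  expect_error(detect_expression(x, detection_threshold("RPKM", 0.3)),
               "does not match")
  expect_error(detection_threshold("TPM", -1), "positive")
  # raising the threshold never turns a call on
  d1 <- uegkit:::detection_matrix(detect_expression(x, detection_threshold("TPM", 0.1)))
  d2 <- uegkit:::detection_matrix(detect_expression(x, detection_threshold("TPM", 1)))
  expect_true(all(d2 <= d1))
})

test_that("global specificity equals the brute-force proportion", {
  m <- matrix(c(1, 1, 1, 1, 0), 1, 5)
  rownames(m) <- "g"; colnames(m) <- paste0("s", 1:5)
  det <- detect_expression(expression_tbl(m, "TPM"),
                           detection_threshold("TPM", 0.5))
  expect_equal(global_specificity(det)$phi, 0.8)
  set.seed(403)
  for (rep in 1:10) {
    m <- rand_expr_matrix(sample(2:20, 1), sample(2:20, 1))
    thr <- sample(c(0.1, 1, 5), 1)
    det <- detect_expression(tiny_expr(m), detection_threshold("TPM", thr))
    expect_equal(global_specificity(det)$phi, brute_phi(m, thr))
  }
})

test_that("phi is monotone in the threshold, genewise", {
  set.seed(404)
  m <- rand_expr_matrix(40, 12)
  x <- tiny_expr(m)
  p1 <- global_specificity(detect_expression(x, detection_threshold("TPM", 0.1)))$phi
  p2 <- global_specificity(detect_expression(x, detection_threshold("TPM", 1)))$phi
  expect_true(all(p2 <= p1))
})

test_that("tissue specificity applies the 80% rule inclusively", {
  # 4 tissues x 5 samples; gene passes the rule in exactly 2 tissues
  m <- matrix(0, 2, 20)
  rownames(m) <- c("gA", "gB")
  colnames(m) <- sprintf("s%02d", 1:20)
  ann <- data.frame(sample_id = colnames(m),
                    tissue_group = rep(paste0("t", 1:4), each = 5))
  m["gA", 1:5] <- 1            # t1: 5/5
  m["gA", 6:9] <- 1            # t2: 4/5 = 80%, inclusive -> expressing
  m["gA", 11:13] <- 1          # t3: 3/5 -> not expressing
  det <- detect_expression(expression_tbl(m, "TPM"),
                           detection_threshold("TPM", 0.5))
  ts <- tissue_specificity(det, ann)
  expect_equal(ts$tissue_specificity[ts$gene_id == "gA"], 0.5)
  expect_equal(ts$tissue_specificity[ts$gene_id == "gB"], 0)
  # gene detected everywhere -> 1 regardless of grouping
  m2 <- m; m2["gB", ] <- 2
  det2 <- detect_expression(expression_tbl(m2, "TPM"),
                            detection_threshold("TPM", 0.5))
  ts2 <- tissue_specificity(det2, ann)
  expect_equal(ts2$tissue_specificity[ts2$gene_id == "gB"], 1)
  # brute-force check of the boundary on random small designs
  set.seed(405)
  for (rep in 1:5) {
    mm <- rand_expr_matrix(8, 12)
    aa <- data.frame(sample_id = colnames(mm),
                     tissue_group = sample(c("x", "y", "z"), 12,
                                           replace = TRUE))
    dd <- detect_expression(tiny_expr(mm), detection_threshold("TPM", 1))
    got <- tissue_specificity(dd, aa)
    dm <- uegkit:::detection_matrix(dd)
    want <- vapply(rownames(mm), function(g) {
      per <- vapply(split(aa$sample_id, aa$tissue_group),
                    function(s) mean(dm[g, s]) >= 0.8, logical(1))
      mean(per)
    }, numeric(1))
    expect_equal(got$tissue_specificity, unname(want[got$gene_id]))
  }
})

test_that("transcriptome sizes are detection column sums with a summary", {
  m <- matrix(c(0, 0, 0,
                1, 2, 3), 3, 2)
  rownames(m) <- paste0("g", 1:3); colnames(m) <- c("empty", "full")
  det <- detect_expression(expression_tbl(m, "TPM"),
                           detection_threshold("TPM", 1))
  sizes <- transcriptome_sizes(det)
  expect_equal(sizes$n_expressed[sizes$sample_id == "empty"], 0L)
  expect_equal(sizes$n_expressed[sizes$sample_id == "full"], 3L)
  s <- attr(sizes, "summary")
  expect_equal(s$n_genes, 3)
  expect_true(s$q10 <= s$median & s$median <= s$q90)
})

test_that("interval table bins phi with a closed top bin", {
  spec <- tibble::tibble(gene_id = paste0("g", 1:10), phi_tpm_0.1 = 1)
  tab <- interval_table(spec)
  top <- tab[tab$interval == "0.8-1.0", ]
  expect_equal(top$n, 10L)
  expect_equal(top$pct, 100)
  # phi exactly 0.8 -> top bin; 0.2 -> bottom bin; 0.6 -> (0.4,0.6]
  spec2 <- tibble::tibble(gene_id = paste0("g", 1:3),
                          phi_tpm_0.1 = c(0.8, 0.2, 0.6))
  t2 <- interval_table(spec2)
  expect_equal(t2$n[t2$interval == "0.8-1.0"], 1L)
  expect_equal(t2$n[t2$interval == "0.0-0.2"], 1L)
  expect_equal(t2$n[t2$interval == "0.4-0.6"], 1L)
  # empty set -> zero row; absent members tallied as missing
  t3 <- interval_table(spec2, gene_sets = list(none = character(),
                                               partial = c("g1", "zz")))
  expect_true(all(t3$n[t3$set == "none"] == 0))
  expect_equal(attr(t3, "n_missing")[["partial"]], 1L)
  expect_equal(sum(t3$n[t3$set == "partial"]), 1L)
  # per-set counts always sum to the set's present-gene count
  set.seed(406)
  spec4 <- tibble::tibble(gene_id = paste0("g", 1:50),
                          phi_tpm_0.1 = runif(50))
  sets <- list(a = sample(spec4$gene_id, 20), b = spec4$gene_id)
  t4 <- interval_table(spec4, gene_sets = sets)
  sums <- tapply(t4$n, t4$set, sum)
  expect_equal(as.vector(sums[c("a", "all", "b")]), c(20L, 50L, 50L))
})

test_that("specificity_table combines thresholds and tissue specificity", {
  set.seed(407)
  m <- rand_expr_matrix(15, 8)
  ann <- data.frame(sample_id = colnames(m),
                    tissue_group = rep(c("t1", "t2"), each = 4))
  st <- specificity_table(tiny_expr(m), annotation = ann)
  expect_named(st, c("gene_id", "phi_tpm_0.1", "phi_tpm_1",
                     "tissue_specificity"))
  expect_true(all(st$phi_tpm_1 <= st$phi_tpm_0.1))
  expect_true(all(st$tissue_specificity >= 0 & st$tissue_specificity <= 1))
})
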