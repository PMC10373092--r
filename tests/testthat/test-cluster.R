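test_that("affinity propagation recovers two planted shape groups exactly", {
  drm <- two_shape_drm()
  cl <- percentile_cluster(drm, method = "affinity", seed = 1)
  expect_equal(cl$k, 2)
  truth <- rep(1:2, each = 25)
  expect_equal(mclust::adjustedRandIndex(cl$assignments$cluster, truth), 1)
  # exemplar belongs to its own cluster
  td <- tidy(cl)
  ex <- unique(td[, c("cluster", "exemplar")])
  for (i in seq_len(nrow(ex))) {
    expect_equal(td$cluster[td$gene_id == ex$exemplar[i]], ex$cluster[i])
  }
})

test_that("clustering is deterministic and handles identical rows", {
  drm <- two_shape_drm(noise = 0.05, seed = 9)
  c1 <- percentile_cluster(drm, seed = 3)
  c2 <- percentile_cluster(drm, seed = 3)
  expect_identical(c1$assignments, c2$assignments)
  k1 <- percentile_cluster(drm, method = "kmeans", seed = 5, k = 2)
  k2 <- percentile_cluster(drm, method = "kmeans", seed = 5, k = 2)
  expect_identical(k1$assignments, k2$assignments)
  # identical rows -> a single cluster
  m <- matrix(0.4, 6, 8, dimnames = list(paste0("g", 1:6), paste0("s", 1:8)))
  drm_id <- suppressWarnings(dynamic_range(expression_tbl(m, "quantile"),
                                           grid = seq(10, 90, 10)))
  cl_id <- percentile_cluster(drm_id)
  expect_equal(cl_id$k, 1)
  expect_true(all(cl_id$assignments$cluster == 1))
  expect_error(percentile_cluster(drm, method = "kmeans"), "needs 'k'")
})

test_that("homogeneity: zero for singletons/identical members, ordered for truth", {
  m <- matrix(0.4, 6, 8, dimnames = list(paste0("g", 1:6), paste0("s", 1:8)))
  drm_id <- suppressWarnings(dynamic_range(expression_tbl(m, "quantile")))
  cl_id <- percentile_cluster(drm_id)
  expect_equal(cluster_homogeneity(cl_id), 0)
  # every gene its own cluster -> 0 (medoid = itself)
  drm <- two_shape_drm()
  cl <- percentile_cluster(drm)
  expect_equal(cluster_homogeneity(cl, labels = seq_len(50)), 0)
  # true labels are tighter than a permuted labelling
  withr::with_seed(7, {
    perm <- sample(rep(1:2, each = 25))
  })
  h_true <- cluster_homogeneity(cl, labels = rep(1:2, each = 25))
  h_perm <- cluster_homogeneity(cl, labels = perm)
  expect_lt(h_true, h_perm)
})

cluster_fixture <- function() {
  cl <- structure(list(
    assignments = tibble::tibble(gene_id = sprintf("g%02d", 1:8),
                                 cluster = rep(1:4, each = 2)),
    exemplars = tibble::tibble(cluster = 1:4,
                               exemplar = sprintf("g%02d", c(1, 3, 5, 7))),
    method = "affinity", k = 4, converged = TRUE, iterations = 10,
    features = matrix(0, 8, 2, dimnames = list(sprintf("g%02d", 1:8), NULL)),
    seed = 1), class = "ueg_clusters")
  spec <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:8),
    phi_tpm_1 = rep(c(0.95, 0.4, 0.2, 0.5), each = 2),
    phi_tpm_0.1 = rep(c(1.0, 0.9, 0.25, 0.6), each = 2))
  list(cl = cl, spec = spec)
}

test_that("category rules fire in the documented order", {
  f <- cluster_fixture()
  cats <- assign_categories(f$cl, f$spec)
  got <- as.character(cats$clusters$category)
  # medians per cluster: (0.95,1.0) (0.4,0.9) (0.2,0.25) (0.5,0.6)
  expect_equal(got, c("UEGs@1.0", "UEGs@0.1", "SEGs@0.1", "MSG"))
  # SEGs@1.0: strict phi low but loose phi in the middle band
  f$spec$phi_tpm_1 <- rep(c(0.95, 0.4, 0.2, 0.25), each = 2)
  f$spec$phi_tpm_0.1 <- rep(c(1.0, 0.9, 0.25, 0.5), each = 2)
  cats2 <- assign_categories(f$cl, f$spec)
  expect_equal(as.character(cats2$clusters$category)[4], "SEGs@1.0")
  # every gene categorized exactly once (partition)
  td <- tidy(cats)
  expect_equal(nrow(td), 8)
  expect_false(any(is.na(td$category)))
  expect_error(assign_categories(f$cl, f$spec[, 1:2]), "lacks required")
})

test_that("UEGs@1.0 clusters always have median strict phi above the cut", {
  pipe <- demo_pipeline()
  cl <- pipe$categories$clusters
  expect_true(all(cl$median_phi_strict[cl$category == "UEGs@1.0"] >= 0.8))
  expect_true(all(cl$median_phi_loose[cl$category == "UEGs@0.1"] >= 0.8))
  expect_true(all(cl$median_phi_loose[cl$category == "SEGs@0.1"] <= 0.3))
  # partition invariant at gene level
  td <- tidy(pipe$categories)
  expect_equal(sum(table(td$category)), nrow(td))
})

test_that("select_lovar gates on UEG category and cluster-median IQR", {
  f <- cluster_fixture()
  drm <- tibble::tibble(gene_id = sprintf("g%02d", 1:8),
                        iqr = rep(c(0.05, 0.3, 0.01, 0.01), each = 2),
                        skewness = 0, q50 = 0.5, n = 10)
  raw <- tiny_expr(matrix(rep(c(100, 50, 1, 20), each = 2), 8, 6,
                          dimnames = list(sprintf("g%02d", 1:8),
                                          sprintf("s%02d", 1:6))))
  cats <- assign_categories(f$cl, f$spec, drm = drm)
  lv <- select_lovar(cats, drm, raw)
  # cluster 1 (UEGs@1.0, iqr .05) selected; cluster 2 (UEG, iqr .3) gated
  # out; clusters 3/4 excluded by category despite tiny iqr
  expect_setequal(lv$selected, c("g01", "g02"))
  expect_equal(lv$genes$cluster, c(1L, 1L))
  # no qualifying cluster -> empty set with warning
  cats2 <- cats
  cats2$clusters$median_iqr <- 0.5
  expect_warning(lv2 <- select_lovar(cats2, drm, raw), "empty LoVar")
  expect_length(lv2$selected, 0)
  expect_error(select_lovar(assign_categories(f$cl, f$spec), drm, raw),
               "median IQR")
})

test_that("lovar outlier removal drops raw-scale fold-range outliers", {
  set.seed(411)
  n <- 40
  ids <- sprintf("g%02d", 1:n)
  cl <- structure(list(
    assignments = tibble::tibble(gene_id = ids, cluster = 1L),
    exemplars = tibble::tibble(cluster = 1L, exemplar = ids[1]),
    method = "affinity", k = 1, converged = TRUE, iterations = 5,
    features = matrix(0, n, 2, dimnames = list(ids, NULL)), seed = 1),
    class = "ueg_clusters")
  spec <- tibble::tibble(gene_id = ids, phi_tpm_1 = 0.95, phi_tpm_0.1 = 1)
  drm <- tibble::tibble(gene_id = ids, iqr = 0.05, skewness = 0, q50 = 0.6,
                        n = 30)
  raw_m <- matrix(rlnorm(n * 30, log(100), 0.05), n, 30,
                  dimnames = list(ids, sprintf("s%02d", 1:30)))
  raw_m[n, ] <- 100 * c(rep(0.001, 3), rep(1, 24), rep(1000, 3))  # wild range
  cats <- assign_categories(cl, spec, drm = drm)
  lv <- select_lovar(cats, drm, tiny_expr(raw_m))
  expect_true(ids[n] %in% lv$outliers$gene_id)
  expect_false(ids[n] %in% lv$selected)
  expect_gte(mean(ids[-n] %in% lv$selected), 0.95)
})

test_that("tidy and glance methods return well-formed summaries", {
  drm <- two_shape_drm()
  cl <- percentile_cluster(drm)
  g <- glance(cl)
  expect_equal(g$k, 2)
  expect_true(g$converged)
  expect_gte(g$homogeneity, 0)
  td <- tidy(cl)
  expect_named(td, c("gene_id", "cluster", "cluster_size", "exemplar"))
  expect_equal(sum(unique(td[, c("cluster", "cluster_size")])$cluster_size),
               50)
})
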