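#' Percentile clustering of genes by distribution shape
#'
#' Clusters genes on their dynamic-range percentile vectors, i.e. by the
#' shape of their global expression distribution. The default engine is
#' affinity propagation on negative squared Euclidean distances with the
#' preference set to the median off-diagonal similarity, so the number of
#' clusters is inferred from the data and every cluster is represented by
#' an exemplar gene. If message passing fails to converge the damping is
#' escalated (up to three retries) before erroring with diagnostics. The
#' alternative engine is seeded k-means (10 restarts) with a supplied `k`.
#'
#' @param drm A `ueg_dynrange` table from [dynamic_range()].
#' @param method `"affinity"` or `"kmeans"`.
#' @param seed Integer seed; clustering is deterministic given the seed.
#' @param k Number of clusters for k-means (ignored by affinity).
#' @param damping,maxit,convits Affinity-propagation controls.
#' @param preference Self-similarity; defaults to the median off-diagonal
#'   similarity. Lower values give fewer clusters.
#' @return A `ueg_clusters` object: use [tidy()] for per-gene assignments
#'   and [glance()] for the one-row run summary.
#' @export
percentile_cluster <- function(drm, method = c("affinity", "kmeans"),
                               seed = 1L, k = NULL, damping = 0.9,
                               maxit = 500, convits = 50, preference = NULL) {
  method <- match.arg(method)
  X <- dynrange_matrix(drm)
  if (nrow(X) < 2L) abort("percentile_cluster needs at least 2 genes")
  if (any(!is.finite(X))) abort("percentile vectors must be finite")
  if (method == "affinity") {
    if (nrow(unique(X)) == 1L) {
      # all rows identical: one cluster, first gene as exemplar
      res <- list(labels = rep(1L, nrow(X)), exemplars = 1L,
                  iterations = 0L, converged = TRUE)
    } else {
      S <- -as.matrix(stats::dist(X))^2
      pref <- preference %||% median(S[upper.tri(S)])
      diag(S) <- pref
      res <- NULL
      dampings <- unique(pmin(c(damping, 0.95, 0.975, 0.99), 0.995))
      for (d in dampings) {
        res <- affinity_propagation(S, damping = d, maxit = maxit,
                                    convits = convits)
        if (res$converged) break
      }
      if (!res$converged) {
        abort(sprintf(
          "affinity propagation did not converge (tried damping %s; maxit=%d, %d exemplars at stop)",
          paste(format(dampings), collapse = ", "), maxit,
          length(res$exemplars)))
      }
    }
    out <- list(
      assignments = tibble(gene_id = rownames(X), cluster = res$labels),
      exemplars = tibble(cluster = seq_along(res$exemplars),
                         exemplar = rownames(X)[res$exemplars]),
      method = "affinity", k = length(res$exemplars),
      converged = res$converged, iterations = res$iterations,
      features = X, seed = seed
    )
  } else {
    if (is.null(k)) {
      abort("k-means mode needs 'k' (e.g. borrow affinity's discovered count)")
    }
    km <- withr::with_seed(seed,
      kmeans(X, centers = k, nstart = 10, iter.max = 100))
    out <- list(
      assignments = tibble(gene_id = rownames(X), cluster = km$cluster),
      exemplars = tibble(cluster = seq_len(k), exemplar = NA_character_),
      method = "kmeans", k = k, converged = TRUE,
      iterations = km$iter, features = X, seed = seed, centers = km$centers
    )
  }
  structure(out, class = "ueg_clusters")
}

#' @export
print.ueg_clusters <- function(x, ...) {
  cat(sprintf("Percentile clustering (%s): %d genes in %d clusters\n",
              x$method, nrow(x$assignments), x$k))
  invisible(x)
}

#' @rdname percentile_cluster
#' @param x,object A `ueg_clusters` object.
#' @param ... Unused.
#' @export
tidy.ueg_clusters <- function(x, ...) {
  sizes <- count(x$assignments, .data$cluster, name = "cluster_size")
  x$assignments |>
    left_join(sizes, by = "cluster") |>
    left_join(x$exemplars, by = "cluster")
}

#' @rdname percentile_cluster
#' @export
glance.ueg_clusters <- function(x, ...) {
  tibble(method = x$method, k = x$k, n_genes = nrow(x$assignments),
         converged = x$converged, iterations = x$iterations,
         homogeneity = cluster_homogeneity(x))
}

#' Within-cluster homogeneity
#'
#' Mean Euclidean distance from each gene's percentile vector to its
#' cluster representative: the exemplar gene for affinity propagation, the
#' centroid for k-means. Zero when every member equals its representative;
#' lower is tighter.
#'
#' @param clusters A `ueg_clusters` object.
#' @param labels Optional replacement labels (integer vector aligned with
#'   the clustered genes), e.g. a permutation for a null comparison; the
#'   representatives are then recomputed from these labels as medoids.
#' @return Non-negative scalar.
#' @export
cluster_homogeneity <- function(clusters, labels = NULL) {
  X <- clusters$features
  if (is.null(labels)) {
    labels <- clusters$assignments$cluster
    if (clusters$method == "kmeans") {
      reps <- clusters$centers[labels, , drop = FALSE]
      return(mean(sqrt(rowSums((X - reps)^2))))
    }
    ex <- clusters$exemplars$exemplar[labels]
    reps <- X[ex, , drop = FALSE]
    return(mean(sqrt(rowSums((X - reps)^2))))
  }
  # labels supplied: representative = medoid of each labelled group
  stopifnot(length(labels) == nrow(X))
  total <- 0
  for (k in unique(labels)) {
    members <- which(labels == k)
    sub <- X[members, , drop = FALSE]
    D <- as.matrix(stats::dist(sub))
    med <- which.min(colSums(D))
    total <- total + sum(D[, med])
  }
  total / nrow(X)
}
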