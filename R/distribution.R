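#' Adjusted Fisher-Pearson sample skewness
#'
#' `skew = n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)` with `s`
#' the sample standard deviation. Requires at least three values; constant
#' input has undefined skewness and is returned as `NaN` with a warning.
#'
#' @param x Numeric vector.
#' @return A single numeric value.
#' @examples
#' sample_skewness(c(1, 2, 3))   # symmetric -> 0
#' @export
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) abort("skewness needs at least 3 values")
  s <- sd(x)
  if (s == 0) {
    warn("skewness undefined for constant input; returning NaN")
    return(NaN)
  }
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}

## row-wise skewness without warnings; constant rows -> NaN, n < 3 -> NA
row_skewness <- function(m) {
  n <- ncol(m)
  if (n < 3L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  cm <- m - mu
  s <- sqrt(rowSums(cm^2) / (n - 1))
  out <- rep(NaN, nrow(m))
  ok <- s > 0
  out[ok] <- n / ((n - 1) * (n - 2)) * rowSums((cm[ok, , drop = FALSE] /
                                                 s[ok])^3)
  out
}

#' Per-gene dynamic-range summary
#'
#' Summarizes each gene's distribution of (by default quantile-rank)
#' expression values across the compendium into its empirical percentile
#' vector on a grid (default Q5 to Q95 in steps of 5), together with the
#' median (Q50), the interquartile range (IQR = Q75 - Q25, the expression
#' variability) and the distribution skewness. Percentiles use linear
#' interpolation between order statistics (R's default type 7); this choice
#' matters downstream because cluster boundaries depend on it.
#'
#' @param x An expression table; normally the quantile-transformed matrix,
#'   but raw normalized values are accepted (e.g. for raw-scale screening),
#'   in which case entries are no longer confined to [0, 1].
#' @param grid Percentile grid, strictly increasing within (0, 100).
#' @return A `ueg_dynrange` tibble with `gene_id`, one `q<pp>` column per
#'   grid point, `q50`, `iqr`, `skewness` and `n` (sample count).
#' @export
dynamic_range <- function(x, grid = seq(5, 95, by = 5)) {
  if (length(grid) < 1L || any(diff(grid) <= 0) ||
      any(grid <= 0) || any(grid >= 100)) {
    abort("grid must be strictly increasing within (0, 100)")
  }
  m <- as_expr_matrix(x)
  n <- ncol(m)
  if (n < 2L) abort("dynamic_range needs at least 2 samples")
  probs <- c(grid / 100, 0.25, 0.5, 0.75)
  qs <- t(apply(m, 1, quantile, probs = probs, type = 7, names = FALSE))
  ng <- length(grid)
  skew <- row_skewness(m)
  n_const <- sum(is.nan(skew))
  if (n_const > 0) {
    warn(sprintf("dynamic_range: skewness undefined (NaN) for %d constant gene(s)",
                 n_const))
  }
  out <- tibble(gene_id = rownames(m))
  pct_cols <- sprintf("q%02d", grid)
  for (i in seq_len(ng)) out[[pct_cols[i]]] <- unname(qs[, i])
  out$q50 <- unname(qs[, ng + 2])
  out$iqr <- unname(qs[, ng + 3] - qs[, ng + 1])
  out$skewness <- unname(skew)
  out$n <- n
  structure(out, grid = grid, unit = expr_unit(x),
            class = c("ueg_dynrange", class(tibble())))
}

#' Extract the percentile-vector matrix of a dynamic-range table
#'
#' @param drm A `ueg_dynrange` table.
#' @return Numeric matrix (genes x grid points) of the percentile columns.
#' @export
dynrange_matrix <- function(drm) {
  grid <- attr(drm, "grid", exact = TRUE)
  if (is.null(grid)) abort("not a dynamic-range table")
  m <- as.matrix(drm[sprintf("q%02d", grid)])
  rownames(m) <- drm$gene_id
  m
}
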