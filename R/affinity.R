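#' Affinity propagation clustering
#'
#' A vectorized implementation of affinity propagation (message passing
#' between responsibility and availability matrices on a similarity
#' matrix). The number of clusters is determined by the data and the
#' self-similarity ("preference"); each cluster is represented by an
#' exemplar, an actual data point. Tie-breaking is deterministic (first
#' index), so identical inputs always give identical labels.
#'
#' @param S Square similarity matrix; the diagonal holds the preference.
#' @param damping Update damping factor in [0.5, 1).
#' @param maxit Maximum number of message-passing iterations.
#' @param convits Stop once the exemplar set is unchanged for this many
#'   consecutive iterations.
#' @return A list with `labels` (integer cluster per point, numbered by
#'   exemplar order), `exemplars` (indices), `iterations`, `converged`.
#' @keywords internal
affinity_propagation <- function(S, damping = 0.9, maxit = 500, convits = 50) {
  n <- nrow(S)
  if (n != ncol(S)) abort("similarity matrix must be square")
  if (damping < 0.5 || damping >= 1) abort("damping must be in [0.5, 1)")
  # tiny deterministic jitter removes degenerate ties (standard practice)
  jit <- outer(seq_len(n), seq_len(n), function(i, j) ((i * 31 + j) %% 97))
  S <- S + (jit - 48) * 1e-12 * (max(abs(S)) + 1)
  R <- A <- matrix(0, n, n)
  idx <- cbind(seq_len(n), seq_len(n))
  e_hist <- matrix(FALSE, n, convits)
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    M <- A + S
    j1 <- max.col(M, ties.method = "first")
    i1 <- cbind(seq_len(n), j1)
    m1 <- M[i1]
    M[i1] <- -Inf
    j2 <- max.col(M, ties.method = "first")
    m2 <- M[cbind(seq_len(n), j2)]
    Rnew <- S - m1
    Rnew[i1] <- S[i1] - m2
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0)
    Rp[idx] <- R[idx]
    cs <- colSums(Rp)
    Anew <- rep(cs, each = n) - Rp
    dA <- Anew[idx]
    Anew <- pmin(Anew, 0)
    Anew[idx] <- dA
    A <- damping * A + (1 - damping) * Anew
    E <- (R[idx] + A[idx]) > 0
    e_hist[, (it - 1L) %% convits + 1L] <- E
    if (it >= convits && any(E)) {
      stable <- rowSums(e_hist)
      if (all(stable == 0L | stable == convits)) {
        converged <- TRUE
        break
      }
    }
  }
  exemplars <- which((R[idx] + A[idx]) > 0)
  if (length(exemplars) == 0L) {
    # fall back to the point with the highest net self-evidence
    exemplars <- which.max(R[idx] + A[idx])
  }
  labels <- assign_to_exemplars(S, exemplars)
  # final refinement: re-pick each cluster's exemplar as the member with
  # maximal within-cluster similarity, then reassign once (Frey & Dueck)
  for (k in seq_along(exemplars)) {
    members <- which(labels == k)
    if (length(members) > 1L) {
      within <- colSums(S[members, members, drop = FALSE])
      exemplars[k] <- members[which.max(within)]
    }
  }
  exemplars <- sort(exemplars)
  labels <- assign_to_exemplars(S, exemplars)
  list(labels = labels, exemplars = exemplars, iterations = it,
       converged = converged)
}

assign_to_exemplars <- function(S, exemplars) {
  labels <- max.col(S[, exemplars, drop = FALSE], ties.method = "first")
  labels[exemplars] <- seq_along(exemplars)
  labels
}
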