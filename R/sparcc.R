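# SparCC: correlation inference for compositional count data.
#
# The algorithm estimates linear ("basis") correlations between taxa from
# log-ratio variances t_ij = var(log(x_i/x_j)). Under an approximate
# sparsity assumption (most taxa uncorrelated), the basis variances w_i^2
# solve a linear system built from row sums of t, and the correlation is
# rho_ij = (w_i^2 + w_j^2 - t_ij) / (2 w_i w_j). Strongly correlated pairs
# violate the sparsity assumption, so the pair with the largest |rho| is
# iteratively excluded from the system and the solution refreshed. The
# whole procedure is repeated over Dirichlet resamples of the counts
# (prior counts + 1) and the median correlation reported.

#' Prevalence filter for network input
#'
#' Keeps OTUs whose maximum per-sample relative abundance is strictly
#' greater than `min_relab` (default 0.1%), the inclusion rule for
#' co-occurrence analysis.
#'
#' @param table an [otu_table()].
#' @param min_relab strict relative-abundance threshold.
#' @return a filtered [otu_table()].
#' @export
prevalence_filter <- function(table, min_relab = 0.001) {
  relab <- relative_abundance(table)
  keep <- apply(relab, 2, max) > min_relab
  m <- unclass_counts(table)[, keep, drop = FALSE]
  otu_table(m)
}

#' Basis variances from a log-ratio variance matrix
#'
#' Solves the SparCC sparsity-approximation linear system. With S_i the
#' set of partners of taxon i not excluded, the equations are
#' sum_{j in S_i} t_ij = |S_i| w_i^2 + sum_{j in S_i} w_j^2; in matrix
#' form (diag(|S_i|) + S) w^2 = rowSums(t * S). Exposed so the linear
#' system can be checked directly against hand-worked solutions.
#'
#' @param t_mat symmetric matrix of log-ratio variances.
#' @param exclusions 2-column matrix of excluded pairs (may have 0 rows).
#' @return vector of basis variances (floored at a small positive value).
#' @export
sparcc_basis_variances <- function(t_mat,
                                   exclusions = matrix(integer(0), 0, 2)) {
  D <- nrow(t_mat)
  S <- matrix(1, D, D)
  diag(S) <- 0
  if (nrow(exclusions)) {
    for (k in seq_len(nrow(exclusions))) {
      i <- exclusions[k, 1]; j <- exclusions[k, 2]
      S[i, j] <- S[j, i] <- 0
    }
  }
  A <- S + diag(rowSums(S))
  b <- rowSums(t_mat * S)
  w2 <- tryCatch(solve(A, b), error = function(e) {
    # rank-deficient after exclusions: minimum-norm least-squares solution
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
  })
  w2 <- drop(w2)
  # a non-positive solution violates the variance interpretation; floor it
  # at the smallest observed log-ratio variance (the data's own scale) so
  # correlations with low-variance taxa cannot blow up to +/-1
  off <- t_mat[upper.tri(t_mat)]
  v_min <- if (any(off > 0)) min(off[off > 0]) else 1e-12
  w2[w2 <= 0] <- v_min
  pmax(w2, 1e-12)
}

rho_from_basis <- function(t_mat, w2) {
  w <- sqrt(w2)
  r <- (outer(w2, w2, "+") - t_mat) / (2 * outer(w, w))
  diag(r) <- 1
  pmin(pmax(r, -1), 1)
}

# one SparCC pass on a fraction matrix (samples x taxa)
sparcc_single <- function(frac, n_exclusion_iters, exclusion_threshold) {
  lf <- log(frac)
  V <- stats::cov(lf)
  v <- diag(V)
  t_mat <- outer(v, v, "+") - 2 * V # var(log x_i - log x_j)
  D <- nrow(t_mat)
  excl <- matrix(integer(0), 0, 2)
  n_excl <- integer(D)
  w2 <- sparcc_basis_variances(t_mat, excl)
  r <- rho_from_basis(t_mat, w2)
  for (it in seq_len(n_exclusion_iters)) {
    rr <- abs(r)
    diag(rr) <- 0
    if (nrow(excl)) {
      for (k in seq_len(nrow(excl))) {
        rr[excl[k, 1], excl[k, 2]] <- 0
        rr[excl[k, 2], excl[k, 1]] <- 0
      }
    }
    m <- which.max(rr)
    i <- (m - 1) %% D + 1
    j <- (m - 1) %/% D + 1
    if (rr[i, j] <= exclusion_threshold) break
    # never let a taxon lose so many partners the system degenerates
    if (n_excl[i] >= D - 3 || n_excl[j] >= D - 3) break
    excl <- rbind(excl, c(i, j))
    n_excl[i] <- n_excl[i] + 1L
    n_excl[j] <- n_excl[j] + 1L
    w2 <- sparcc_basis_variances(t_mat, excl)
    r <- rho_from_basis(t_mat, w2)
  }
  r
}

#' SparCC correlations for an OTU table
#'
#' @param counts an [otu_table()] (or matrix, samples x OTUs) with at
#'   least 4 OTUs, none all-zero (apply [prevalence_filter()] first).
#' @param n_dirichlet number of Dirichlet resamples (median taken).
#' @param n_exclusion_iters maximum strongly-correlated-pair exclusions
#'   per resample.
#' @param exclusion_threshold |rho| above which a pair is excluded from
#'   the basis system.
#' @param seed integer seed.
#' @return symmetric correlation matrix in `[-1, 1]` with unit diagonal.
#' @export
sparcc_correlations <- function(counts, n_dirichlet = 20,
                                n_exclusion_iters = 10,
                                exclusion_threshold = 0.1, seed = 1) {
  m <- unclass_counts(counts)
  if (ncol(m) < 4) stop("SparCC needs at least 4 OTUs")
  if (any(colSums(m) == 0)) {
    stop("all-zero OTU(s) present; filter before SparCC")
  }
  D <- ncol(m)
  set.seed(seed)
  acc <- array(NA_real_, c(D, D, n_dirichlet))
  for (b in seq_len(n_dirichlet)) {
    # per-sample Dirichlet(counts + 1) draw of the underlying fractions
    g <- matrix(stats::rgamma(length(m), shape = t(m) + 1), ncol = D,
                byrow = TRUE)
    frac <- g / rowSums(g)
    acc[, , b] <- sparcc_single(frac, n_exclusion_iters,
                                exclusion_threshold)
  }
  r <- apply(acc, c(1, 2), stats::median)
  dimnames(r) <- list(colnames(m), colnames(m))
  r
}

#' Permutation p-values for SparCC correlations
#'
#' Permutes each OTU's counts across samples independently (destroying
#' all between-taxon association while keeping each taxon's abundance
#' distribution), recomputes the SparCC correlation per permutation, and
#' reports the two-sided pseudo-p
#' (#\{|r_perm| >= |r_obs|\} + 1) / (n_perm + 1).
#'
#' @param counts as in [sparcc_correlations()].
#' @param r_obs observed correlation matrix.
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed.
#' @param n_dirichlet Dirichlet resamples per permutation (fewer than for
#'   the observed statistic is usual; default 5).
#' @return symmetric matrix of p-values in (0, 1].
#' @export
sparcc_pvalues <- function(counts, r_obs, n_perm = 100, seed = 1,
                           n_dirichlet = 5) {
  m <- unclass_counts(counts)
  D <- ncol(m)
  set.seed(seed)
  exceed <- matrix(0L, D, D)
  for (k in seq_len(n_perm)) {
    perm <- apply(m, 2, sample)
    r_perm <- sparcc_correlations(otu_table(perm), n_dirichlet = n_dirichlet,
                                  seed = sample.int(.Machine$integer.max, 1))
    exceed <- exceed + (abs(r_perm) >= abs(r_obs))
  }
  p <- (exceed + 1) / (n_perm + 1)
  diag(p) <- 1
  dimnames(p) <- dimnames(r_obs)
  p
}
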