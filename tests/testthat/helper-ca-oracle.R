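# Direct generalized-eigenproblem oracle for (partial-free) CCA on small
# tables: chi-square standardisation, weighted least-squares projection on
# the constraints, then eigendecomposition of the fitted matrix.

cca_eigen_oracle <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  P <- Y / sum(Y)
  r <- rowSums(P)
  c_ <- colSums(P)
  Qbar <- diag(1 / sqrt(r)) %*% (P - outer(r, c_)) %*% diag(1 / sqrt(c_))
  # weighted centring of the constraints (row-mass weights)
  Xc <- sweep(X, 2, colSums(X * r))
  Xw <- diag(sqrt(r)) %*% Xc
  H <- Xw %*% solve(crossprod(Xw)) %*% t(Xw)
  fitted <- H %*% Qbar
  ev_c <- svd(fitted)$d^2
  ev_u <- svd(Qbar - fitted)$d^2
  list(constrained = ev_c[ev_c > 1e-12],
       unconstrained = ev_u[ev_u > 1e-12],
       total_inertia = sum(Qbar^2))
}
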