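# Independent oracle implementations used to certify the compiled solvers
# and the simulator. These deliberately use a different algorithm (full
# proximal gradient, direct estimators) than the package code paths.

# full proximal-gradient group lasso, run to tight tolerance
oracle_prox_group_lasso <- function(X, y, idx, w, lam,
                                    iters = 100000L, tol = 1e-12) {
  H <- crossprod(X)
  L <- max(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  c0 <- crossprod(X, y)
  b <- numeric(ncol(X))
  for (t in seq_len(iters)) {
    z <- b - (H %*% b - c0) / L
    bn <- as.numeric(z)
    for (k in seq_along(idx)) {
      zi <- bn[idx[[k]]]
      nz <- sqrt(sum(zi^2))
      thr <- lam * w[k] / L
      bn[idx[[k]]] <- if (nz > thr) (1 - thr / nz) * zi else 0
    }
    if (max(abs(bn - b)) < tol) { b <- bn; break }
    b <- bn
  }
  b
}

# proximal gradient for the GGGL-1 objective (network term is a quadratic
# Laplacian form, folded into the smooth part)
oracle_prox_gggl1 <- function(X, y, idx, w, lam, A, mu,
                              iters = 100000L, tol = 1e-12) {
  p <- ncol(X)
  G <- length(idx)
  M <- matrix(0, G, p)
  for (g in seq_len(G)) M[g, idx[[g]]] <- 1 / length(idx[[g]])
  Lap <- diag(rowSums(A)) - A
  H <- crossprod(X) + 2 * mu * t(M) %*% Lap %*% M
  L <- max(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  c0 <- crossprod(X, y)
  b <- numeric(p)
  for (t in seq_len(iters)) {
    z <- b - (H %*% b - c0) / L
    bn <- as.numeric(z)
    for (k in seq_len(G)) {
      zi <- bn[idx[[k]]]
      nz <- sqrt(sum(zi^2))
      thr <- lam * w[k] / L
      bn[idx[[k]]] <- if (nz > thr) (1 - thr / nz) * zi else 0
    }
    if (max(abs(bn - b)) < tol) { b <- bn; break }
    b <- bn
  }
  b
}

# Hudson's two-population FST estimator, averaged over SNPs
oracle_hudson_fst <- function(dosage, labels) {
  d1 <- dosage[labels == 1, , drop = FALSE]
  d2 <- dosage[labels == 2, , drop = FALSE]
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  n1 <- 2 * colSums(!is.na(d1))
  n2 <- 2 * colSums(!is.na(d2))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num, na.rm = TRUE) / mean(den, na.rm = TRUE)
}

# direct tail enumeration of the hypergeometric distribution (plain choose())
oracle_hyper_tail <- function(k, N, K, n) {
  if (k <= 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  sum(choose(K, k:hi) * choose(N - K, n - (k:hi))) / choose(N, n)
}

# group-lasso objective value
gl_objective <- function(X, y, idx, w, lam, b) {
  0.5 * sum((y - X %*% b)^2) +
    lam * sum(vapply(seq_along(idx),
                     function(g) w[g] * sqrt(sum(b[idx[[g]]]^2)), 0))
}
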