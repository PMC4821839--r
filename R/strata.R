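#' Pairwise identity-by-state distance matrix
#'
#' `distance(i, j)` is the mean over mutually non-missing SNPs of
#' `|g_i - g_j| / 2`, i.e. one minus the PLINK-style IBS similarity. Computed
#' via genotype-class indicator cross-products, so it scales to thousands of
#' SNPs.
#'
#' @param G a `genotype_matrix` (missing entries allowed; every subject pair
#'   must share at least one non-missing SNP).
#' @return object of class `distance_matrix` (`subject_ids`, `values`:
#'   symmetric, zero diagonal, entries in `[0, 1]`).
#' @export
ibs_matrix <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$dosage
  if (any(!is.na(X) & X != 0 & X != 1 & X != 2)) {
    stop("IBS requires hard genotype calls in {0, 1, 2}")
  }
  M <- !G$missing_mask
  I0 <- (!is.na(X) & X == 0) * 1
  I1 <- (!is.na(X) & X == 1) * 1
  I2 <- (!is.na(X) & X == 2) * 1
  shared <- M %*% t(M)
  if (any(shared[upper.tri(shared)] == 0)) {
    stop("some subject pair shares no non-missing SNP")
  }
  diff2 <- I0 %*% t(I2); diff2 <- diff2 + t(diff2)
  diff1 <- I0 %*% t(I1) + I1 %*% t(I2)
  diff1 <- diff1 + t(diff1)
  D <- (diff1 + 2 * diff2) / (2 * shared)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(G$subject_ids, G$subject_ids)
  structure(list(subject_ids = G$subject_ids, values = D),
            class = "distance_matrix")
}

#' Complete-linkage agglomerative clustering
#'
#' Hand-rolled Lance-Williams agglomeration with the maximum (complete)
#' update, merging the closest pair at each step. Merge heights are
#' non-decreasing for complete linkage.
#'
#' @param D a `distance_matrix` (or plain symmetric matrix).
#' @param n_clusters number of clusters at which to cut, in `[1, n]`.
#' @return list with `labels` (integer cluster assignment at the cut),
#'   `merge_heights` (the n-1 merge distances) and `merges` (two-column
#'   matrix of merged cluster indices, `hclust`-style negative singletons).
#' @export
complete_linkage <- function(D, n_clusters) {
  d <- if (inherits(D, "distance_matrix")) D$values else as.matrix(D)
  n <- nrow(d)
  if (n_clusters < 1 || n_clusters > n) stop("n_clusters must be in [1, n]")
  active <- seq_len(n)
  members <- as.list(seq_len(n))
  id <- -seq_len(n)            # hclust convention: negatives are singletons
  work <- d
  diag(work) <- Inf
  heights <- numeric(0)
  merges <- matrix(0L, 0, 2)
  labels_at_cut <- NULL
  if (n_clusters == n) labels_at_cut <- seq_len(n)
  step <- 0L
  while (length(active) > 1) {
    sub <- work[active, active, drop = FALSE]
    ij <- arrayInd(which.min(sub), dim(sub))
    i <- active[min(ij)]; j <- active[max(ij)]
    step <- step + 1L
    heights <- c(heights, work[i, j])
    merges <- rbind(merges, c(id[i], id[j]))
    id[i] <- step
    members[[i]] <- c(members[[i]], members[[j]])
    # complete linkage: distance to the merged cluster is the max
    upd <- pmax(work[i, active], work[j, active])
    work[i, active] <- upd
    work[active, i] <- upd
    work[i, i] <- Inf
    active <- setdiff(active, j)
    if (length(active) == n_clusters) {
      lab <- integer(n)
      for (ci in seq_along(active)) lab[members[[active[ci]]]] <- ci
      labels_at_cut <- lab
    }
  }
  list(labels = labels_at_cut, merge_heights = heights, merges = merges)
}

#' Ancestry principal components
#'
#' Two bases: `"ibs-distance"` performs classical scaling (double-centering
#' of squared IBS distances) and eigendecomposes; `"standardized-relationship"`
#' eigendecomposes `Z Z' / p` with `Z` the per-SNP variance-standardized
#' dosage matrix. Components are oriented so the first subject's score is
#' non-negative. The first component is the conventional stratification
#' covariate (recorded, never auto-applied: with near-maximal sparsity the
#' rank-1 pathway fit can fail to converge after ancestry adjustment, so
#' adjustment stays an explicit user choice).
#'
#' @param G a `genotype_matrix`; `"standardized-relationship"` requires no
#'   missing entries (impute first).
#' @param k number of components (`k <= n`).
#' @param basis `"ibs-distance"` or `"standardized-relationship"`.
#' @return object of class `ancestry_components` with `component_scores`
#'   (n x k), `eigenvalues`, and a `degenerate` flag (all eigenvalues ~ 0).
#' @export
ancestry_pcs <- function(G, k = 2L,
                         basis = c("ibs-distance", "standardized-relationship")) {
  basis <- match.arg(basis)
  n <- nrow(G$dosage)
  if (k > n) stop("k exceeds the number of subjects")
  if (basis == "ibs-distance") {
    D <- ibs_matrix(G)$values
    B <- -0.5 * scale(t(scale(t(D^2), center = TRUE, scale = FALSE)),
                      center = TRUE, scale = FALSE)
    B <- (B + t(B)) / 2
  } else {
    if (any(G$missing_mask)) {
      stop("standardized-relationship basis requires complete genotypes; impute first")
    }
    Z <- scale(G$dosage)
    Z[, attr(Z, "scaled:scale") == 0] <- 0
    B <- tcrossprod(Z) / ncol(Z)
  }
  eg <- eigen(B, symmetric = TRUE)
  vals <- eg$values[seq_len(k)]
  vecs <- eg$vectors[, seq_len(k), drop = FALSE]
  scores <- sweep(vecs, 2, sqrt(pmax(eg$values[seq_len(k)], 0)), `*`)
  for (j in seq_len(k)) {  # orient: first subject's score non-negative
    if (scores[1, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- G$subject_ids
  colnames(scores) <- sprintf("PC%d", seq_len(k))
  structure(list(subject_ids = G$subject_ids,
                 component_scores = scores,
                 eigenvalues = vals,
                 degenerate = all(abs(eg$values) < 1e-10)),
            class = "ancestry_components")
}

#' Mean silhouette width
#'
#' Silhouette of a labelling under a distance matrix (or of a score vector,
#' using absolute differences); used to quantify how well a component or a
#' clustering separates groups.
#'
#' @param labels integer/character group labels.
#' @param D a `distance_matrix`, symmetric matrix, or numeric vector of
#'   scores (distance = absolute difference).
#' @return mean silhouette width in `[-1, 1]`.
#' @export
silhouette_width <- function(labels, D) {
  if (is.numeric(D) && is.null(dim(D))) D <- abs(outer(D, D, `-`))
  d <- if (inherits(D, "distance_matrix")) D$values else as.matrix(D)
  labels <- as.integer(factor(labels))
  n <- length(labels)
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("silhouette needs at least 2 clusters")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(ks, labels[i]),
                    function(kk) mean(d[i, labels == kk]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
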