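#' Multivariate phenotype container
#' @param values n x q numeric matrix (no missing values); rows are subjects.
#' @param subject_ids,feature_ids optional ids overriding dimnames.
#' @return object of class `phenotype_matrix`.
#' @export
phenotype_matrix <- function(values, subject_ids = rownames(values),
                             feature_ids = colnames(values)) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("phenotype matrix must have no missing values")
  if (is.null(subject_ids)) subject_ids <- sprintf("subj%03d", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- sprintf("trait%02d", seq_len(ncol(values)))
  dimnames(values) <- list(subject_ids, feature_ids)
  structure(list(subject_ids = subject_ids, feature_ids = feature_ids,
                 values = values), class = "phenotype_matrix")
}

as_phenotype_values <- function(Y) {
  if (inherits(Y, "phenotype_matrix")) Y$values else as.matrix(Y)
}

#' Residualize a phenotype on clinical covariates
#'
#' Each phenotype column is replaced by its least-squares residual on an
#' intercept plus the selected covariates (the general-linear-model
#' adjustment applied before dimension reduction; e.g. adjust for `pma`
#' only, or for `ga` and `pma`). Residuals are orthogonal to every selected
#' covariate.
#'
#' @param Y a `phenotype_matrix` or numeric matrix.
#' @param C a `covariate_table` aligned with `Y`'s subjects.
#' @param which character vector of covariate names to adjust for.
#' @return a `phenotype_matrix` of residuals.
#' @export
residualize <- function(Y, C, which) {
  vals <- as_phenotype_values(Y)
  miss <- setdiff(which, names(C))
  if (length(miss)) {
    stop(sprintf("covariate(s) not present: %s", paste(miss, collapse = ", ")))
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(as.data.frame(C)[, which, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient covariate design; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  res <- qr.resid(qrX, vals)
  out <- phenotype_matrix(res,
                          subject_ids = if (inherits(Y, "phenotype_matrix")) Y$subject_ids else rownames(vals),
                          feature_ids = if (inherits(Y, "phenotype_matrix")) Y$feature_ids else colnames(vals))
  out
}

#' Scree-elbow component count
#'
#' Selects the eigenvalue index with maximum perpendicular distance to the
#' chord joining the first and last points of the scree plot; ties break to
#' the smallest index, so a linearly decreasing spectrum yields `k = 1`.
#'
#' @param eigenvalues non-increasing, non-negative values (length >= 2).
#' @return integer `k >= 1`.
#' @export
select_components_elbow <- function(eigenvalues) {
  m <- length(eigenvalues)
  if (m < 2) stop("need at least 2 eigenvalues for the elbow rule")
  if (any(eigenvalues < 0)) stop("eigenvalues must be non-negative")
  x1 <- c(1, eigenvalues[1]); x2 <- c(m, eigenvalues[m])
  v <- x2 - x1
  # perpendicular distance of (i, lambda_i) to the chord: |cross product|/|v|
  i <- seq_len(m)
  cross <- v[1] * (eigenvalues - x1[2]) - v[2] * (i - x1[1])
  d <- abs(cross) / sqrt(sum(v^2))
  which.max(d)  # ties -> smallest index
}

#' PCA reduction of the phenotype
#'
#' Column-centered SVD. With `k = "auto"` the component count is the scree
#' elbow of the full eigenvalue spectrum. Component signs are fixed so the
#' largest-magnitude loading of each component is positive.
#'
#' @param Y a `phenotype_matrix` or numeric matrix (n >= 2 rows).
#' @param k number of components, or `"auto"`.
#' @return object of class `reduced_phenotype` with `component_scores`
#'   (n x k), `component_loadings` (q x k), `explained_variance` (top-k
#'   eigenvalues of the sample covariance), `k`, and the full spectrum in
#'   `attr(, "spectrum")`.
#' @export
pca_reduce <- function(Y, k = "auto") {
  vals <- as_phenotype_values(Y)
  n <- nrow(vals); q <- ncol(vals)
  if (n < 2) stop("need n >= 2 subjects for PCA")
  ctr <- scale(vals, center = TRUE, scale = FALSE)
  sv <- svd(ctr)
  ev <- sv$d^2 / (n - 1)
  if (identical(k, "auto")) {
    k <- select_components_elbow(ev)
  }
  k <- as.integer(k)
  if (k > min(n, q)) stop(sprintf("k = %d exceeds min(n, q) = %d", k, min(n, q)))
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  for (j in seq_len(k)) {  # deterministic sign
    pivot <- which.max(abs(V[, j]))
    if (V[pivot, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- sweep(U, 2, d, `*`)
  subject_ids <- if (inherits(Y, "phenotype_matrix")) Y$subject_ids else rownames(vals)
  if (is.null(subject_ids)) subject_ids <- sprintf("subj%03d", seq_len(n))
  rownames(scores) <- subject_ids
  colnames(scores) <- colnames(V) <- sprintf("PC%d", seq_len(k))
  out <- structure(list(subject_ids = subject_ids,
                        component_scores = scores,
                        component_loadings = V,
                        explained_variance = ev[seq_len(k)],
                        k = k), class = "reduced_phenotype")
  attr(out, "spectrum") <- ev
  out
}

#' @export
print.reduced_phenotype <- function(x, ...) {
  tot <- sum(attr(x, "spectrum"))
  cat(sprintf("reduced_phenotype: %d subjects, k = %d (%.1f%% variance)\n",
              length(x$subject_ids), x$k,
              100 * sum(x$explained_variance) / tot))
  invisible(x)
}
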