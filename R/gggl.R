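#' GGGL configuration
#'
#' The graph-guided group lasso adds a network-smoothing penalty with weight
#' `mu` to the gene-group lasso over one pathway's SNPs. `GGGL-1` fuses the
#' mean signed coefficients of adjacent genes (functionally related genes get
#' similar effects); `GGGL-2` fuses their size-normalized coefficient norms
#' (similar selection magnitude, sign-free). `mu = 0` reduces both to the
#' plain gene-group lasso.
#'
#' @param mu network-prior weight (>= 0); the reference grid is
#'   `c(0.1, 1, 10)`.
#' @param lambda_fraction sparsity as a fraction of the plain group-lasso
#'   zero threshold, in (0, 1].
#' @param variant `"GGGL-1"` or `"GGGL-2"`.
#' @param n_subsamples,subsample_fraction resampling controls for gene
#'   selection probabilities.
#' @param selection_threshold gene selection-probability cutoff (0.4, the
#'   step change in the probability distribution).
#' @param top_k_snps SNP ranking length (30).
#' @param max_sweeps,tol solver controls (KKT residual target).
#' @param seed resampling seed.
#' @return object of class `gggl_config`.
#' @export
gggl_config <- function(mu = 1, lambda_fraction = 0.5,
                        variant = c("GGGL-1", "GGGL-2"),
                        n_subsamples = 100L, subsample_fraction = 0.5,
                        selection_threshold = 0.4, top_k_snps = 30L,
                        max_sweeps = 2000L, tol = 1e-6, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(mu >= 0, lambda_fraction > 0, lambda_fraction <= 1,
            selection_threshold > 0, selection_threshold < 1,
            n_subsamples >= 1, subsample_fraction > 0,
            subsample_fraction <= 1, top_k_snps >= 1)
  structure(list(mu = mu, lambda_fraction = lambda_fraction,
                 variant = variant,
                 n_subsamples = as.integer(n_subsamples),
                 subsample_fraction = subsample_fraction,
                 selection_threshold = selection_threshold,
                 top_k_snps = as.integer(top_k_snps),
                 max_sweeps = as.integer(max_sweeps), tol = tol,
                 seed = as.integer(seed)),
            class = "gggl_config")
}

#' Gene network from GO annotation set overlap
#'
#' Pairwise semantic similarity of the genes' GO (Biological Process) term
#' sets: Dice `2|A n B| / (|A| + |B|)` or Jaccard `|A n B| / |A u B|`.
#' Computed by an incidence-matrix cross-product; the adjacency is symmetric
#' with zero diagonal and weights in `[0, 1]`.
#'
#' @param gene_go_table data.frame/data.table with columns `gene_id`, `term`.
#'   Every gene must have at least one term.
#' @param measure `"dice"` (default) or `"jaccard"`.
#' @return object of class `gene_network` (`gene_ids`, `adjacency`).
#' @export
go_adjacency <- function(gene_go_table, measure = c("dice", "jaccard")) {
  measure <- match.arg(measure)
  dt <- data.table::as.data.table(gene_go_table)
  bad <- unique(dt$gene_id[is.na(dt$term) | !nzchar(dt$term)])
  if (length(bad)) {
    stop(sprintf("gene(s) with empty GO term set: %s",
                 paste(head(bad, 3), collapse = ", ")))
  }
  dt <- unique(dt[, c("gene_id", "term")])
  genes <- sort(unique(dt$gene_id))
  terms <- sort(unique(dt$term))
  B <- matrix(0, length(genes), length(terms),
              dimnames = list(genes, terms))
  B[cbind(match(dt$gene_id, genes), match(dt$term, terms))] <- 1
  inter <- tcrossprod(B)
  sizes <- diag(inter)
  A <- if (measure == "dice") {
    2 * inter / outer(sizes, sizes, `+`)
  } else {
    uni <- outer(sizes, sizes, `+`) - inter
    inter / uni
  }
  A[!is.finite(A)] <- 0
  diag(A) <- 0
  A <- (A + t(A)) / 2
  structure(list(gene_ids = genes, adjacency = A), class = "gene_network")
}

as_gene_groups <- function(gene_groups, p) {
  if (is.null(names(gene_groups))) {
    names(gene_groups) <- sprintf("gene%03d", seq_along(gene_groups))
  }
  cols <- sort(unlist(gene_groups, use.names = FALSE))
  if (length(cols) != p || !identical(as.integer(cols), seq_len(p))) {
    stop("gene_groups must partition the design columns")
  }
  gene_groups
}

align_adjacency <- function(net, gene_ids) {
  A <- if (inherits(net, "gene_network")) net$adjacency else as.matrix(net)
  if (!is.null(rownames(A))) {
    miss <- setdiff(gene_ids, rownames(A))
    if (length(miss)) {
      stop(sprintf("network lacks gene(s): %s", paste(head(miss, 3), collapse = ", ")))
    }
    A <- A[gene_ids, gene_ids, drop = FALSE]
  } else if (nrow(A) != length(gene_ids)) {
    stop("unnamed adjacency has wrong dimension")
  }
  if (max(abs(A - t(A))) > 1e-12 || any(A < 0) || any(diag(A) != 0)) {
    stop("adjacency must be symmetric, non-negative, zero-diagonal")
  }
  A
}

#' Graph-guided group lasso solve
#'
#' Minimizes
#' `0.5 ||y - X beta||^2 + lam * sum_g w_g ||beta_g|| + mu * sum_{i<j} A_ij Phi(beta_i, beta_j)`
#' with `Phi = (s_i - s_j)^2` on mean signed coefficients (GGGL-1) or
#' `Phi = (||beta_i||/sqrt(|i|) - ||beta_j||/sqrt(|j|))^2` (GGGL-2), by block
#' coordinate descent with the network term absorbed into each block's smooth
#' part. Gene weights are `sqrt(|g|)`; `lam` defaults to `lambda_fraction`
#' of the plain group-lasso zero threshold.
#'
#' @param X SNP design restricted to one pathway's genes (n x p).
#' @param y response vector (the leading reduced-phenotype component, or a
#'   fitted trait score).
#' @param gene_groups named list: gene id -> column indices (a partition of
#'   the columns of `X`).
#' @param net a `gene_network` (or adjacency matrix) covering the genes.
#' @param config a `gggl_config`.
#' @param lam optional explicit penalty level overriding `lambda_fraction`.
#' @param standardize center/scale columns and center y (default TRUE).
#' @return object of class `gggl_fit`: `snp_coefficients`,
#'   `selected_genes`, `objective` (per-sweep trace), `kkt`, `lam`.
#' @export
gggl_solve <- function(X, y, gene_groups, net, config = gggl_config(),
                       lam = NULL, standardize = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in the design or response")
  }
  gene_groups <- as_gene_groups(gene_groups, ncol(X))
  A <- align_adjacency(net, names(gene_groups))
  if (standardize) {
    X <- standardize_columns(X)
    y <- y - mean(y)
  }
  w <- sqrt(lengths(gene_groups))
  if (is.null(lam)) {
    lam <- config$lambda_fraction * lambda_max(X, y, gene_groups, w)
  }
  idx0 <- lapply(gene_groups, function(i) as.integer(i) - 1L)
  vnum <- if (config$variant == "GGGL-1") 1L else 2L
  fit <- cpp_gggl(X, y, idx0, as.numeric(w), lam, A, config$mu, vnum,
                  numeric(ncol(X)), config$max_sweeps, config$tol,
                  100L, 1e-10)
  beta <- as.numeric(fit$beta)
  gnorm <- vapply(gene_groups, function(i) sqrt(sum(beta[i]^2)), 0)
  structure(list(snp_coefficients = stats::setNames(beta, colnames(X)),
                 selected_genes = names(gene_groups)[gnorm > 1e-10],
                 objective = as.numeric(fit$objective),
                 kkt = fit$kkt, converged = fit$converged, lam = lam),
            class = "gggl_fit")
}

#' Gene selection probabilities by subsampling
#'
#' Repeats [gggl_solve()] on `n_subsamples` subject subsamples (drawn without
#' replacement, `subsample_fraction` of subjects each) and reports the
#' fraction of fits in which each gene was selected. Genes above
#' `selection_threshold` (default 0.4) form the reported selection set.
#'
#' @inheritParams gggl_solve
#' @param keep_fits also return the per-subsample fits (needed for SNP
#'   ranking).
#' @return object of class `gene_selection_probabilities`: `probability`
#'   (named), `genes_above_threshold`, `n_subsamples`, and optionally `fits`.
#' @export
gene_selection_probabilities <- function(X, y, gene_groups, net,
                                         config = gggl_config(),
                                         keep_fits = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  gene_groups <- as_gene_groups(gene_groups, ncol(X))
  n <- nrow(X)
  m <- floor(config$subsample_fraction * n)
  if (m < 10) stop("subsample size < 10 subjects")
  hits <- stats::setNames(numeric(length(gene_groups)), names(gene_groups))
  fits <- if (keep_fits) vector("list", config$n_subsamples) else NULL
  with_seed(derive_seed(config$seed, 307L), {
    for (s in seq_len(config$n_subsamples)) {
      rows <- sample.int(n, m)
      fit <- gggl_solve(X[rows, , drop = FALSE], y[rows], gene_groups, net,
                        config)
      hits[fit$selected_genes] <- hits[fit$selected_genes] + 1
      if (keep_fits) fits[[s]] <- fit
    }
  })
  prob <- hits / config$n_subsamples
  structure(list(probability = prob,
                 genes_above_threshold = names(prob)[prob > config$selection_threshold],
                 n_subsamples = config$n_subsamples,
                 threshold = config$selection_threshold,
                 fits = fits),
            class = "gene_selection_probabilities")
}

#' Rank SNPs across subsample fits
#'
#' SNPs ordered by selection frequency (nonzero coefficient across fits),
#' ties broken by mean absolute coefficient, then by SNP id; truncated to
#' `top_k`.
#'
#' @param fits list of `gggl_fit` objects (or a
#'   `gene_selection_probabilities` with `fits` kept).
#' @param top_k ranking length (default 30).
#' @return data.table `snp_id`, `frequency`, `mean_abs_coefficient`.
#' @export
rank_snps <- function(fits, top_k = 30L) {
  if (inherits(fits, "gene_selection_probabilities")) fits <- fits$fits
  if (!length(fits)) stop("need at least one fit")
  ids <- names(fits[[1]]$snp_coefficients)
  if (is.null(ids)) ids <- sprintf("col%04d", seq_along(fits[[1]]$snp_coefficients))
  nf <- length(fits)
  sel <- numeric(length(ids)); absum <- numeric(length(ids))
  for (f in fits) {
    nz <- abs(f$snp_coefficients) > 1e-10
    sel <- sel + nz
    absum <- absum + abs(f$snp_coefficients)
  }
  dt <- data.table::data.table(snp_id = ids, frequency = sel / nf,
                               mean_abs_coefficient = absum / nf)
  data.table::setorder(dt, -frequency, -mean_abs_coefficient, snp_id)
  head(dt, top_k)
}

#' Stability of GGGL selections across the network-prior grid
#'
#' Runs [gene_selection_probabilities()] for each value of `mu_grid`
#' (reference grid 0.1, 1, 10) and reports the per-mu gene selection sets,
#' the per-mu top-k SNP lists and their pairwise and overall intersection
#' sizes — the qualitative stability check of the network prior.
#'
#' @inheritParams gggl_solve
#' @param mu_grid network-prior weights to compare.
#' @return list with `gene_sets` (per mu), `snp_lists` (per mu),
#'   `gene_sets_identical` (logical), `snp_overlap` (pairwise matrix) and
#'   `snp_overlap_all` (size of the intersection of all lists).
#' @export
mu_stability_report <- function(X, y, gene_groups, net,
                                config = gggl_config(),
                                mu_grid = c(0.1, 1, 10)) {
  if (!length(mu_grid)) stop("mu_grid must be nonempty")
  res <- lapply(mu_grid, function(m) {
    cfg <- config; cfg$mu <- m
    gp <- gene_selection_probabilities(X, y, gene_groups, net, cfg,
                                       keep_fits = TRUE)
    list(genes = gp$genes_above_threshold,
         snps = rank_snps(gp$fits, config$top_k_snps)$snp_id,
         probabilities = gp$probability)
  })
  names(res) <- paste0("mu=", mu_grid)
  gene_sets <- lapply(res, `[[`, "genes")
  snp_lists <- lapply(res, `[[`, "snps")
  L <- length(mu_grid)
  ov <- matrix(NA_integer_, L, L, dimnames = list(names(res), names(res)))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    ov[i, j] <- length(intersect(snp_lists[[i]], snp_lists[[j]]))
  }
  list(mu_grid = mu_grid,
       gene_sets = gene_sets,
       snp_lists = snp_lists,
       probabilities = lapply(res, `[[`, "probabilities"),
       gene_sets_identical = all(vapply(gene_sets, setequal, TRUE,
                                        y = gene_sets[[1]])),
       snp_overlap = ov,
       snp_overlap_all = length(Reduce(intersect, snp_lists)))
}
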