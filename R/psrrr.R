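#' PsRRR configuration
#'
#' Parameters of the pathway sparse reduced-rank regression: `lambda_fraction`
#' scales the data-dependent penalty ceiling (0.99 gives near-maximal
#' sparsity, so each fit admits only the strongest pathway signal);
#' resampling uses `n_subsamples` half-subsamples; the adaptive weight-tuning
#' loop runs `tuning_iterations` rounds of `tuning_fits_per_iteration`
#' null-response fits each.
#'
#' @param lambda_fraction penalty as a fraction of `lambda_max`, in (0, 1].
#' @param n_subsamples stability-selection subsamples.
#' @param subsample_fraction fraction of subjects per subsample.
#' @param tuning_iterations weight-tuning rounds.
#' @param tuning_fits_per_iteration null fits per tuning round (desk-scale
#'   default 200; raise towards the published 2000x10 + 4000x10 budget for
#'   full-scale runs).
#' @param tuning_damping exponent of the multiplicative weight update, (0, 1].
#'   Selection is a near-deterministic argmax in the weights (the measured
#'   sensitivity of log selection frequency to log weight is ~10), so steps
#'   must be small: the default 0.05 keeps the fixed-point iteration stable;
#'   larger values oscillate.
#' @param max_alt_iterations alternating (b, a) iterations per rank-1 fit.
#' @param tol relative objective tolerance for the alternation.
#' @param solver_tol KKT tolerance of the inner group-lasso solves.
#' @param seed integer seed governing all resampling.
#' @return object of class `psrrr_config`.
#' @export
psrrr_config <- function(lambda_fraction = 0.99, n_subsamples = 100L,
                         subsample_fraction = 0.5, tuning_iterations = 20L,
                         tuning_fits_per_iteration = 200L,
                         tuning_damping = 0.05, max_alt_iterations = 25L,
                         tol = 1e-4, solver_tol = 1e-6, seed = 1L) {
  stopifnot(lambda_fraction > 0, lambda_fraction <= 1,
            n_subsamples >= 1, subsample_fraction > 0, subsample_fraction <= 1,
            tuning_iterations >= 0, tuning_fits_per_iteration >= 1,
            tuning_damping > 0, tuning_damping <= 1,
            max_alt_iterations >= 1, tol > 0)
  structure(list(lambda_fraction = lambda_fraction,
                 n_subsamples = as.integer(n_subsamples),
                 subsample_fraction = subsample_fraction,
                 tuning_iterations = as.integer(tuning_iterations),
                 tuning_fits_per_iteration = as.integer(tuning_fits_per_iteration),
                 tuning_damping = tuning_damping,
                 max_alt_iterations = as.integer(max_alt_iterations),
                 tol = tol, solver_tol = solver_tol,
                 seed = as.integer(seed)),
            class = "psrrr_config")
}

#' Initial pathway weights
#'
#' The standard group-lasso size correction `w_g = sqrt(|g|)` on the expanded
#' group sizes; the starting point of the adaptive tuning.
#' @param groups a `pathway_groups`.
#' @return object of class `pathway_weights`.
#' @export
initial_weights <- function(groups) {
  w <- sqrt(as.numeric(groups$group_sizes))
  structure(list(weights = stats::setNames(w, groups$group_ids),
                 provenance = "initial",
                 tuning_history = NULL),
            class = "pathway_weights")
}

as_weight_vector <- function(weights, groups) {
  w <- if (inherits(weights, "pathway_weights")) weights$weights else weights
  if (!is.null(names(w))) w <- w[groups$group_ids]
  if (length(w) != length(groups$group_ids) || any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be positive and match the pathway universe")
  }
  as.numeric(w)
}

# center/scale columns; constant columns get unit scale
standardize_columns <- function(X) {
  ctr <- colMeans(X)
  X <- sweep(X, 2, ctr)
  sc <- sqrt(colSums(X^2) / max(nrow(X) - 1, 1))
  sc[sc < 1e-12] <- 1
  sweep(X, 2, sc, `/`)
}

#' Penalized group-lasso solve
#'
#' Minimizes `0.5 ||y - X b||^2 + lam * sum_g w_g ||b_g||_2` by block
#' coordinate descent (compiled), certifying the KKT conditions: for active
#' groups `X_g'(y - X b) = lam w_g b_g / ||b_g||`, for zero groups
#' `||X_g'(y - X b)|| <= lam w_g`, within `tol` relative.
#'
#' @param X complete, column-standardized expanded design.
#' @param y response vector.
#' @param groups a `pathway_groups` or list of column index vectors.
#' @param weights a `pathway_weights` or positive numeric vector.
#' @param lam penalty level (>= 0).
#' @param beta0 optional warm start.
#' @param max_sweeps,tol solver controls.
#' @return coefficient vector with attributes `kkt`, `converged`,
#'   `objective` (per-sweep trace).
#' @export
group_lasso_solve <- function(X, y, groups, weights, lam, beta0 = NULL,
                              max_sweeps = 1000L, tol = 1e-7) {
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in the design or response")
  }
  if (lam < 0) stop("lam must be >= 0")
  idx <- if (inherits(groups, "pathway_groups")) groups$group_index_lists else groups
  w <- if (inherits(groups, "pathway_groups")) as_weight_vector(weights, groups)
       else as.numeric(if (inherits(weights, "pathway_weights")) weights$weights else weights)
  idx0 <- lapply(idx, function(i) as.integer(i) - 1L)
  if (is.null(beta0)) beta0 <- numeric(ncol(X))
  fit <- cpp_group_lasso(X, y, idx0, w, lam, beta0,
                         as.integer(max_sweeps), tol, 100L, 1e-10)
  structure(as.numeric(fit$beta), kkt = fit$kkt, converged = fit$converged,
            objective = as.numeric(fit$objective))
}

#' Data-dependent penalty ceiling
#'
#' Smallest `lam` at which the all-zero solution satisfies the group-lasso
#' KKT conditions: `max_g ||X_g' y|| / w_g`.
#' @param X expanded design.
#' @param y response.
#' @param groups group index structure.
#' @param weights positive weights.
#' @return scalar `lambda_max`.
#' @export
lambda_max <- function(X, y, groups, weights) {
  idx <- if (inherits(groups, "pathway_groups")) groups$group_index_lists else groups
  w <- if (inherits(groups, "pathway_groups")) as_weight_vector(weights, groups)
       else as.numeric(if (inherits(weights, "pathway_weights")) weights$weights else weights)
  xty <- crossprod(X, y)
  max(vapply(seq_along(idx),
             function(g) sqrt(sum(xty[idx[[g]]]^2)) / w[g], 0))
}

# Core alternating rank-1 fit on a pre-expanded, pre-standardized design.
# Yc must be column-centered. Returns expanded b, unit a, trace, lam.
fit_rank1_core <- function(Xs, Yc, idx, w, config) {
  q <- ncol(Yc)
  a <- if (q == 1) 1 else {
    v <- svd(Yc, nu = 0, nv = 1)$v[, 1]
    if (v[1] < 0) v <- -v
    v
  }
  idx0 <- lapply(idx, function(i) as.integer(i) - 1L)
  b <- numeric(ncol(Xs))
  trace <- numeric(0)
  lam_trace <- numeric(0)
  lam <- NA_real_
  converged <- FALSE
  obj_prev <- Inf
  for (it in seq_len(config$max_alt_iterations)) {
    ytil <- as.numeric(Yc %*% a)
    xty <- crossprod(Xs, ytil)
    lam_max <- max(vapply(seq_along(idx),
                          function(g) sqrt(sum(xty[idx[[g]]]^2)) / w[g], 0))
    lam <- config$lambda_fraction * lam_max
    lam_trace <- c(lam_trace, lam)
    sol <- cpp_group_lasso(Xs, ytil, idx0, w, lam, b,
                           500L, config$solver_tol, 100L, 1e-10)
    b <- as.numeric(sol$beta)
    if (all(b == 0)) { trace <- c(trace, 0.5 * sum(Yc^2)); break }
    xb <- as.numeric(Xs %*% b)
    anew <- as.numeric(crossprod(Yc, xb))
    na <- sqrt(sum(anew^2))
    if (na == 0) break
    a <- anew / na
    pen <- sum(vapply(seq_along(idx),
                      function(g) w[g] * sqrt(sum(b[idx[[g]]]^2)), 0))
    obj <- 0.5 * (sum(Yc^2) - 2 * sum((crossprod(Yc, xb)) * a) + sum(xb^2)) +
      lam * pen
    trace <- c(trace, obj)
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) <= config$tol * max(1, abs(obj_prev))) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  if (a[1] < 0) { a <- -a; b <- -b }
  sel <- which(vapply(idx, function(i) sqrt(sum(b[i]^2)), 0) > 1e-10)
  list(b = b, a = a, selected = sel, lam = lam, lam_trace = lam_trace,
       objective_trace = trace, converged = converged)
}

#' Rank-1 pathway sparse reduced-rank regression fit
#'
#' Alternates (i) `b`-updates by weighted group lasso on the working response
#' `Y a`, with the penalty set to `lambda_fraction` of the current
#' `lambda_max(a)`, and (ii) `a`-updates along the cross-covariance
#' direction `Y' X b`, normalized to unit length. Stops on relative objective
#' change `< tol` or after `max_alt_iterations` (non-convergence is flagged,
#' not raised). If `b` collapses to zero the fit reports empty selection.
#'
#' @param X original design (n x p, complete); expansion and per-column
#'   standardization happen internally.
#' @param Y a `reduced_phenotype`, `phenotype_matrix` or numeric matrix
#'   (columns are centered internally).
#' @param groups a `pathway_groups`.
#' @param weights a `pathway_weights` or numeric vector.
#' @param config a `psrrr_config`.
#' @return object of class `rank_one_fit`: `snp_coefficients` (expanded),
#'   `snp_effects` (collapsed per original SNP), `trait_loadings` (unit
#'   norm), `selected_pathways`, `lam`, `objective_trace`, `converged`.
#' @export
fit_rank1 <- function(X, Y, groups, weights, config = psrrr_config()) {
  Yc <- response_matrix(Y)
  Yc <- scale(Yc, center = TRUE, scale = FALSE)
  Xs <- standardize_columns(expand_design(as_design(X), groups))
  w <- as_weight_vector(weights, groups)
  core <- fit_rank1_core(Xs, Yc, groups$group_index_lists, w, config)
  structure(list(snp_coefficients = core$b,
                 snp_effects = collapse_coefficients(core$b, groups),
                 trait_loadings = core$a,
                 selected_pathways = groups$group_ids[core$selected],
                 lam = core$lam, lam_trace = core$lam_trace,
                 objective_trace = core$objective_trace,
                 converged = core$converged),
            class = "rank_one_fit")
}

as_design <- function(X) {
  if (inherits(X, "genotype_matrix")) {
    if (any(X$missing_mask)) stop("design has missing genotypes; impute first")
    X$dosage
  } else as.matrix(X)
}

response_matrix <- function(Y) {
  if (inherits(Y, "reduced_phenotype")) Y$component_scores
  else if (inherits(Y, "phenotype_matrix")) Y$values
  else as.matrix(Y)
}

#' Adaptive pathway-weight tuning against null selection bias
#'
#' Large or internally correlated pathways are preferentially selected even
#' when the response carries no genetic signal. Starting from
#' `w_g = sqrt(|g|)`, each round fits the rank-1 model to row-permuted (null)
#' responses, measures per-pathway null selection frequencies `f_g`, and
#' applies the damped multiplicative correction
#' `w_g <- w_g * ((f_g + eps) / (mean(f) + eps))^damping` with
#' `eps = 1 / (2 * fits)`, pushing null selection towards uniformity.
#'
#' @inheritParams fit_rank1
#' @return a `pathway_weights` with `provenance = "tuned"` (or `"initial"`
#'   when `tuning_iterations = 0`) and the per-round null frequencies in
#'   `tuning_history`.
#' @export
tune_weights <- function(X, Y, groups, config = psrrr_config()) {
  Yc <- scale(response_matrix(Y), center = TRUE, scale = FALSE)
  Xs <- standardize_columns(expand_design(as_design(X), groups))
  idx <- groups$group_index_lists
  G <- length(idx)
  w <- sqrt(as.numeric(groups$group_sizes))
  history <- list()
  if (config$tuning_iterations > 0) {
    nfit <- config$tuning_fits_per_iteration
    eps <- 1 / (2 * nfit)
    n <- nrow(Yc)
    with_seed(derive_seed(config$seed, 101L), {
      for (iter in seq_len(config$tuning_iterations)) {
        hits <- numeric(G)
        for (f in seq_len(nfit)) {
          Yp <- Yc[sample.int(n), , drop = FALSE]
          core <- fit_rank1_core(Xs, Yp, idx, w, config)
          hits[core$selected] <- hits[core$selected] + 1
        }
        fg <- hits / nfit
        history[[iter]] <- stats::setNames(fg, groups$group_ids)
        w <- w * ((fg + eps) / (mean(fg) + eps))^config$tuning_damping
      }
    })
  }
  structure(list(weights = stats::setNames(w, groups$group_ids),
                 provenance = if (config$tuning_iterations > 0) "tuned" else "initial",
                 tuning_history = history),
            class = "pathway_weights")
}

#' Stability selection over pathways
#'
#' Draws `n_subsamples` subject subsamples of size
#' `floor(subsample_fraction * n)` without replacement, fits the rank-1 model
#' on each, and reports per-pathway selection frequencies together with the
#' mean absolute correlation between the fitted genetic score `X_g b_g` and
#' the fitted trait score `Y a` over the subsamples where the pathway was
#' selected. In `null_mode` the response rows are independently permuted per
#' subsample before fitting, yielding the null benchmark frequencies.
#'
#' @inheritParams fit_rank1
#' @param null_mode permute the response per subsample.
#' @return object of class `selection_frequencies` with `frequency`,
#'   `mean_correlation` (both named by pathway), `n_subsamples`, `null_mode`.
#' @export
stability_select <- function(X, Y, groups, weights, config = psrrr_config(),
                             null_mode = FALSE) {
  Yc <- scale(response_matrix(Y), center = TRUE, scale = FALSE)
  Xd <- as_design(X)
  n <- nrow(Yc)
  m <- floor(config$subsample_fraction * n)
  if (m < 10) stop(sprintf("subsample size %d is too small (< 10 subjects)", m))
  idx <- groups$group_index_lists
  w <- as_weight_vector(weights, groups)
  G <- length(idx)
  hits <- numeric(G)
  corsum <- numeric(G)
  nonconv <- 0L
  Xexp <- expand_design(Xd, groups)
  with_seed(derive_seed(config$seed, if (null_mode) 211L else 199L), {
    for (s in seq_len(config$n_subsamples)) {
      rows <- sample.int(n, m)
      Xs <- standardize_columns(Xexp[rows, , drop = FALSE])
      Ys <- scale(Yc[rows, , drop = FALSE], center = TRUE, scale = FALSE)
      if (null_mode) Ys <- Ys[sample.int(m), , drop = FALSE]
      core <- fit_rank1_core(Xs, Ys, idx, w, config)
      if (!core$converged) nonconv <- nonconv + 1L
      if (length(core$selected)) {
        ya <- as.numeric(Ys %*% core$a)
        for (g in core$selected) {
          hits[g] <- hits[g] + 1
          sg <- as.numeric(Xs[, idx[[g]], drop = FALSE] %*% core$b[idx[[g]]])
          cv <- suppressWarnings(cor(sg, ya))
          corsum[g] <- corsum[g] + abs(if (is.na(cv)) 0 else cv)
        }
      }
    }
  })
  freq <- hits / config$n_subsamples
  meancor <- ifelse(hits > 0, corsum / pmax(hits, 1), 0)
  out <- structure(list(frequency = stats::setNames(freq, groups$group_ids),
                        mean_correlation = stats::setNames(meancor, groups$group_ids),
                        n_subsamples = config$n_subsamples,
                        null_mode = null_mode),
                   class = "selection_frequencies")
  attr(out, "n_nonconverged") <- nonconv
  out
}

#' Rank pathways by stability-selection evidence
#'
#' Sort by empirical selection frequency (descending), ties broken by mean
#' absolute correlation with the fitted trait score (descending), then by
#' pathway id (lexicographic). Null frequencies are attached for reporting.
#'
#' @param emp,null `selection_frequencies` over the same pathway universe.
#' @return object of class `pathway_ranking`: a data.table with columns
#'   `pathway_id`, `frequency`, `null_frequency`, `mean_correlation`.
#' @export
rank_pathways <- function(emp, null = NULL) {
  ids <- names(emp$frequency)
  if (!is.null(null)) {
    if (!setequal(ids, names(null$frequency))) {
      stop("empirical and null frequencies cover different pathway universes")
    }
    nullf <- null$frequency[ids]
  } else {
    nullf <- rep(NA_real_, length(ids))
  }
  dt <- data.table::data.table(pathway_id = ids,
                               frequency = as.numeric(emp$frequency),
                               null_frequency = as.numeric(nullf),
                               mean_correlation = as.numeric(emp$mean_correlation[ids]))
  data.table::setorder(dt, -frequency, -mean_correlation, pathway_id)
  data.table::setattr(dt, "class", c("pathway_ranking", class(dt)))
  dt
}
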