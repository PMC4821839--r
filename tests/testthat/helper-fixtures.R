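# Small in-code fixtures shared across test files.

# random standardized design + group index lists
make_gl_instance <- function(seed, n = 30, sizes = c(4, 4, 4)) {
  set.seed(seed)
  p <- sum(sizes)
  X <- scale(matrix(rnorm(n * p), n, p))
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  idx <- split(seq_len(p), rep(seq_along(sizes), sizes))
  y <- as.numeric(scale(rnorm(n), scale = FALSE))
  list(X = X, y = y, idx = unname(idx), w = sqrt(sizes))
}

# hand-built pathway_groups over p SNPs with given expanded group sizes
# (disjoint groups, identity expansion)
make_groups <- function(sizes) {
  p <- sum(sizes)
  idx <- split(seq_len(p), rep(seq_along(sizes), sizes))
  structure(list(group_ids = sprintf("pw%02d", seq_along(sizes)),
                 group_index_lists = stats::setNames(unname(idx),
                                                     sprintf("pw%02d", seq_along(sizes))),
                 expansion_map = seq_len(p),
                 group_sizes = stats::setNames(as.integer(sizes),
                                               sprintf("pw%02d", seq_along(sizes))),
                 snp_ids = sprintf("s%04d", seq_len(p))),
            class = "pathway_groups")
}

# a small study with a strong single-pathway signal
quick_study <- function(seed = 1, n = 100, h = 0.6, n_snps = 300,
                        n_genes = 45, n_pathways = 6,
                        pathway_size_range = c(4, 7), ...) {
  cfg <- sim_config(n_subjects = n, n_snps = n_snps, n_genes = n_genes,
                    n_pathways = n_pathways,
                    pathway_size_range = pathway_size_range,
                    heritability = h, seed = seed, ...)
  simulate_study(cfg)
}
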