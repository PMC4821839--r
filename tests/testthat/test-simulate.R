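test_that("genotype simulation is seed-deterministic and well coded", {
  cfg <- sim_config(n_subjects = 40, n_snps = 200, missing_rate = 0.02, seed = 9)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$genotypes$dosage, g2$genotypes$dosage)
  expect_identical(g1$variants, g2$variants)
  vals <- g1$genotypes$dosage
  expect_true(all(vals[!is.na(vals)] %in% c(0, 1, 2)))
  expect_gt(mean(is.na(vals)), 0.005)
  expect_lt(mean(is.na(vals)), 0.05)
})

test_that("invalid configurations are rejected with messages", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.05, 0.6)), "maf_range")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(trait_rank = 5, trait_dim = 3), "trait_rank")
  expect_error(sim_config(pathway_size_range = c(0, 5)), "pathway_size_range")
})

test_that("subpopulation differentiation matches the Hudson FST estimator", {
  base <- list(n_subjects = 200, n_snps = 5000, n_subpops = 2,
               missing_rate = 0, ld_rho = 0, ld_block_size = 1)
  g0 <- simulate_genotypes(do.call(sim_config, c(base, fst = 0, seed = 21)))
  f0 <- oracle_hudson_fst(g0$genotypes$dosage, g0$subpop_labels)
  expect_lt(abs(f0), 0.01)

  g1 <- simulate_genotypes(do.call(sim_config, c(base, fst = 0.1, seed = 22)))
  f1 <- oracle_hudson_fst(g1$genotypes$dosage, g1$subpop_labels)
  expect_gte(f1, 0.07)
  expect_lte(f1, 0.13)
})

test_that("LD blocks induce adjacent-SNP correlation; pooled MAF in range", {
  cfg <- sim_config(n_subjects = 300, n_snps = 500, ld_block_size = 10,
                    ld_rho = 0.8, missing_rate = 0, seed = 4)
  g <- simulate_genotypes(cfg)$genotypes$dosage
  within <- sapply(seq(1, 491, by = 10), function(j) cor(g[, j], g[, j + 1]))
  across <- sapply(seq(10, 490, by = 10), function(j) cor(g[, j], g[, j + 1]))
  expect_gt(mean(within), 0.4)       # thresholded copula attenuates 0.8
  expect_lt(abs(mean(across)), 0.1)  # block boundaries are independent
  f <- colMeans(g) / 2
  maf <- pmin(f, 1 - f)
  expect_gte(mean(maf), cfg$maf_range[1] - 0.02)
  expect_lte(mean(maf), cfg$maf_range[2] + 0.02)
})

test_that("annotation respects overlap and size constraints", {
  cfg0 <- sim_config(n_snps = 400, n_genes = 80, n_pathways = 8,
                     pathway_size_range = c(5, 8), overlap_fraction = 0, seed = 2)
  ann0 <- simulate_annotation(cfg0)
  counts <- table(ann0$annotation$gene_to_pathways$gene_id)
  expect_true(all(counts == 1))
  expect_true(all(lengths(ann0$gene_sets) >= 5 & lengths(ann0$gene_sets) <= 8))

  cfg1 <- sim_config(n_snps = 400, n_genes = 80, n_pathways = 8,
                     pathway_size_range = c(5, 8), overlap_fraction = 0.08,
                     seed = 2)
  ann1 <- simulate_annotation(cfg1)
  counts1 <- table(ann1$annotation$gene_to_pathways$gene_id)
  expect_true(any(counts1 == 2))
  expect_true(all(counts1 <= 2))
  # every SNP maps to at most 2 genes (here: exactly one)
  expect_true(all(table(ann1$annotation$snp_to_genes$snp_id) <= 2))
  expect_error(simulate_annotation(
    sim_config(n_snps = 400, n_genes = 10, n_pathways = 8,
               pathway_size_range = c(5, 8), overlap_fraction = 0)),
    "infeasible")
})

test_that("same-pathway gene pairs are closer in the GO network", {
  cfg <- sim_config(n_snps = 400, n_genes = 60, n_pathways = 6,
                    pathway_size_range = c(6, 9), seed = 8)
  ann <- simulate_annotation(cfg)
  # recompute similarity directly from the emitted table
  sets <- split(ann$gene_go_table$term, ann$gene_go_table$gene_id)
  dice <- function(a, b) 2 * length(intersect(a, b)) / (length(a) + length(b))
  g2p <- ann$annotation$gene_to_pathways
  related <- merge(g2p, g2p, by = "pathway_id", allow.cartesian = TRUE)
  related <- related[related$gene_id.x < related$gene_id.y, ]
  rel_sim <- mapply(function(a, b) dice(sets[[a]], sets[[b]]),
                    related$gene_id.x, related$gene_id.y)
  genes <- names(sets)
  set.seed(1)
  pairs <- cbind(sample(genes, 300, TRUE), sample(genes, 300, TRUE))
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  keyrel <- paste(related$gene_id.x, related$gene_id.y)
  off <- pairs[!(paste(pairs[, 1], pairs[, 2]) %in% keyrel), , drop = FALSE]
  off_sim <- mapply(function(a, b) dice(sets[[a]], sets[[b]]),
                    off[, 1], off[, 2])
  expect_gt(mean(rel_sim), stats::median(off_sim))
  # and the packaged adjacency agrees with the direct recomputation
  A <- ann$network$adjacency
  i <- match(related$gene_id.x, rownames(A))
  j <- match(related$gene_id.y, colnames(A))
  expect_equal(A[cbind(i, j)], unname(rel_sim), tolerance = 1e-12)
})

test_that("phenotype heritability is calibrated and null is null", {
  # null construction: no genotype-phenotype correlation beyond chance
  cfg0 <- sim_config(n_subjects = 150, n_snps = 200, n_genes = 30,
                     n_pathways = 4, pathway_size_range = c(4, 6),
                     heritability = 0, missing_rate = 0, seed = 31)
  geno <- simulate_genotypes(cfg0)
  ann <- simulate_annotation(cfg0)
  ph0 <- suppressWarnings(simulate_phenotype(geno$genotypes, ann, cfg0))
  b <- ph0$truth$snp_effect_vector
  expect_true(all(b == 0))
  set.seed(1)
  bprobe <- rnorm(ncol(geno$genotypes$dosage))
  bprobe[-ph0$truth$causal_snp_indices] <- 0
  xb <- geno$genotypes$dosage %*% ifelse(is.na(bprobe), 0, bprobe)
  rs <- abs(cor(xb, ph0$phenotype$values))
  expect_lt(mean(rs), 2 / sqrt(cfg0$n_subjects))

  # calibration: mean realized heritability over 20 replicates within +-0.05
  hs <- vapply(1:20, function(s) {
    cfg <- sim_config(n_subjects = 150, n_snps = 200, n_genes = 30,
                      n_pathways = 4, pathway_size_range = c(4, 6),
                      heritability = 0.3, missing_rate = 0, seed = 100 + s)
    st <- simulate_study(cfg)
    # direct recomputation: var(Xb a') / var(Y - C Gamma)
    X <- st$genotypes$dosage
    g <- X %*% st$truth$snp_effect_vector
    g <- scale(g, scale = FALSE)
    signal <- g %*% t(st$truth$trait_loading_vector)
    Cstd <- scale(cbind(st$covariates$ga, st$covariates$pma))
    Ygen <- st$phenotype$values - Cstd %*% st$truth$covariate_coefficient_matrix
    sum(apply(signal, 2, var)) / sum(apply(Ygen, 2, var))
  }, 0)
  expect_gte(mean(hs), 0.25)
  expect_lte(mean(hs), 0.35)
})

test_that("causal SNPs lie inside causal pathways", {
  st <- quick_study(seed = 5)
  stg <- st$annotation$snp_to_genes
  causal_path_genes <- unique(unlist(st$gene_sets[st$truth$causal_pathway_ids]))
  allowed <- stg$snp_id[stg$gene_id %in% causal_path_genes]
  expect_true(all(st$truth$causal_snp_ids %in% allowed))
  expect_equal(which(st$truth$snp_effect_vector != 0),
               st$truth$causal_snp_indices)
})

test_that("heritability 0 with causal pathways warns, does not error", {
  cfg <- sim_config(n_subjects = 50, n_snps = 100, n_genes = 10,
                    n_pathways = 2, pathway_size_range = c(3, 4),
                    heritability = 0, seed = 3)
  geno <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg)
  expect_warning(simulate_phenotype(geno$genotypes, ann, cfg), "heritability")
})

test_that("study artifacts round-trip as plain text", {
  st <- quick_study(seed = 12, n = 30, n_snps = 120, n_genes = 18,
                    n_pathways = 3, pathway_size_range = c(4, 5))
  dir <- withr::local_tempdir()
  files <- write_study(st, dir, prefix = "toy")
  expect_true(all(file.exists(files)))
  rt <- read_genotypes(file.path(dir, "toy.raw"), dialect = "plink-raw")
  expect_identical(rt$genotypes$dosage, st$genotypes$dosage)
  sets <- read_gmt(file.path(dir, "toy.pathways.gmt"))
  expect_identical(lapply(sets, identity), st$gene_sets)
})
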