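# pathrider

Pathway- and network-guided sparse regression for imaging genetics.

## What problem this solves

Studies that relate genome-wide genotypes to a **multivariate quantitative
trait** — the motivating case is voxel-wise white-matter fractional
anisotropy in a preterm-infant cohort of ~72 subjects, adjusted for
gestational age at birth (GA) and postmenstrual age at scan (PMA) — face
p ≫ n and weak per-SNP signal. `pathrider` implements a biology-guided
two-stage analysis for that regime, plus everything around it: genotype QC,
phenotype adjustment and reduction, population-stratification diagnostics,
enrichment tests, and a synthetic-data generator with planted ground truth
so the whole chain is verifiable.

**Stage 1 — pathway ranking (PsRRR).** A rank-1 sparse reduced-rank
regression `Y ≈ X b aᵀ`, `‖a‖₂ = 1`, with an overlapping group-lasso penalty
`λ Σ_g w_g ‖b_g‖₂` over pathways (overlaps handled by column duplication).
λ is a fraction (default 0.99, near-maximal sparsity) of the data-dependent
ceiling `λ_max`. Pathway weights start at `√|g|` and are tuned adaptively so
that *null* (permuted-response) selection frequencies become uniform,
removing pathway-size/LD selection bias. Pathways are then ranked by
stability selection: selection frequency over 100 half-subsamples, ties
broken by the mean |correlation| between the fitted genetic score and trait
score, with permuted-response null frequencies reported alongside.

**Stage 2 — gene/SNP localisation (GGGL).** Within the top pathway, a
graph-guided group lasso couples genes through a GO-similarity network `A`
(Dice/Jaccard overlap of GO term sets):
`½‖y − Xβ‖² + λ Σ_g w_g‖β_g‖ + μ Σ_{i<j} A_ij Φ(β_i, β_j)`,
where GGGL-1 fuses mean signed gene effects and GGGL-2 fuses
size-normalized gene norms. Genes are reported by subsample selection
probability (threshold 0.4), SNPs by selection frequency across fits, with a
stability report over the prior-strength grid μ ∈ {0.1, 1, 10}.

Solvers are compiled (RcppArmadillo) block coordinate descent with KKT
certificates, verified against independent proximal-gradient oracles in the
test suite.

## Worked example

```r
library(pathrider)

cfg <- sim_config(n_subjects = 200, n_snps = 400, n_genes = 45, n_pathways = 8,
                  pathway_size_range = c(4, 6), heritability = 0.5, seed = 42)
study <- simulate_study(cfg)

G <- impute_missing(filter_variants(study$genotypes), "column-mean")  # MAF>=5%, call rate>=99%
red <- pca_reduce(residualize(study$phenotype, study$covariates, c("ga", "pma")), k = "auto")
groups <- build_groups(study$annotation, study$gene_sets, snp_ids = G$snp_ids)

pcfg <- psrrr_config(n_subsamples = 50, tuning_iterations = 5,
                     tuning_fits_per_iteration = 100, seed = 42)
weights <- tune_weights(G, red, groups, pcfg)
emp <- stability_select(G, red, groups, weights, pcfg)
nul <- stability_select(G, red, groups, weights, pcfg, null_mode = TRUE)
ranking <- rank_pathways(emp, nul)
head(ranking, 4)
```

This prints (output produced by the code above):

```
SNPs retained: 252 of 400
reduced_phenotype: 200 subjects, k = 2 (62.1% variance)
   pathway_id frequency null_frequency mean_correlation
1:    path005         1           0.08        0.7550884
2:    path001         0           0.16        0.0000000
3:    path002         0           0.06        0.0000000
4:    path003         0           0.04        0.0000000
planted causal pathway: path005
```

The planted causal pathway is selected in 100% of subsamples while its
permuted-response null frequency is 8% — the empirical-vs-null gap is the
evidence of association. Continuing into the top pathway:

```r
top <- ranking$pathway_id[1]
pg  <- pathway_gene_design(G, study$annotation, study$gene_sets[[top]])
net <- go_adjacency(study$gene_go_table[study$gene_go_table$gene_id %in% names(pg$gene_groups), ])
gp  <- gene_selection_probabilities(pg$X, red$component_scores[, 1],
                                    pg$gene_groups, net,
                                    gggl_config(mu = 1, n_subsamples = 50, seed = 42))
sort(gp$probability, decreasing = TRUE)
```

```
gene0035 gene0018 gene0038 gene0005
    1.00     0.24     0.16     0.06
genes above 0.4: gene0035
planted causal genes: gene0005 gene0018 gene0035 gene0038
```

All four genes of this small pathway carry planted effects, but the random
per-SNP effect sizes concentrate most of the realized signal on `gene0035`,
and at this sample size only it clears the 0.4 step-change threshold — a
faithful picture of what gene-level selection probabilities do and do not
establish. (The test suite's recovery scenarios, with five comparable
network-clustered causal genes in a larger pathway, recover the full set
identically across μ ∈ {0.1, 1, 10}.)

One call runs everything end to end, deterministically, writing TSV/GMT/JSON
artifacts and a digest-bearing run report:

```r
report <- run_pipeline(list(seed = 42), out_dir = "out")
```

A small CLI mirrors the stages: `inst/exec/pathrider qc|strata|enrich|run`.

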