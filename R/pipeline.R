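#' Restrict a design to one pathway's genes
#'
#' Builds the SNP design and gene grouping used by the graph-guided group
#' lasso: columns are the (QC-retained) SNPs mapped to the pathway's genes,
#' partitioned by gene. A SNP mapped to two genes of the pathway is assigned
#' to the first gene (lexicographic) so the groups remain a partition.
#'
#' @param G a complete `genotype_matrix` (imputed).
#' @param ann annotation with `snp_to_genes`.
#' @param genes character vector: the pathway's gene ids.
#' @return list with `X` (n x p design), `gene_groups` (named list of column
#'   indices) and `snp_ids`.
#' @export
pathway_gene_design <- function(G, ann, genes) {
  stg <- if (is.data.frame(ann)) ann else ann$snp_to_genes
  stg <- stg[stg$gene_id %in% genes & stg$snp_id %in% G$snp_ids, ]
  if (!nrow(stg)) stop("no SNPs map to the requested genes")
  stg <- stg[order(stg$snp_id, stg$gene_id), ]
  stg <- stg[!duplicated(stg$snp_id), ]  # partition: first gene wins
  snp_ids <- sort(unique(stg$snp_id))
  X <- G$dosage[, snp_ids, drop = FALSE]
  gene_groups <- split(match(stg$snp_id, snp_ids), stg$gene_id)
  gene_groups <- gene_groups[order(names(gene_groups))]
  list(X = X, gene_groups = gene_groups, snp_ids = snp_ids)
}

pipeline_defaults <- function() {
  list(
    seed = 1L,
    simulation = list(),
    qc = list(maf_min = 0.05, call_rate_min = 0.99),
    impute = list(strategy = "column-mean"),
    adjust = list(covariates = c("ga", "pma"), use_ancestry_pc = FALSE),
    pca = list(k = "auto"),
    psrrr = list(),
    gggl = list(),
    enrich = list(top_k = NULL)
  )
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- utils::modifyList(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full synthetic-study pipeline
#'
#' Executes, under one master seed: simulation, variant QC, imputation,
#' ancestry diagnostics, covariate residualization, PCA reduction, pathway
#' group construction, adaptive weight tuning, empirical and null stability
#' selection, pathway ranking, graph-guided group lasso on the top pathway,
#' and over-representation of the planted causal pathways among the top
#' ranks. All stage artifacts are written as TSV/GMT/JSON and the run report
#' lists each with a content digest; re-running with an identical config
#' reproduces byte-identical artifacts.
#'
#' @param config a list, or path to a JSON file with (any of) the entries
#'   `seed`, `simulation`, `qc`, `impute`, `adjust`, `pca`, `psrrr`, `gggl`,
#'   `enrich`.
#' @param out_dir artifact directory (created).
#' @return invisibly, the run report (also written as `report.json`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- merge_config(pipeline_defaults(), config)
  seed <- as.integer(cfg$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(name) file.path(out_dir, name)
  written <- character(0)
  emit <- function(dt, name) {
    data.table::fwrite(dt, art(name), sep = "\t")
    written <<- c(written, name)
  }

  sim_args <- cfg$simulation
  sim_args$seed <- seed
  scfg <- stage("simulate", do.call(sim_config, sim_args))
  study <- stage("simulate", simulate_study(scfg))
  emit(data.table::as.data.table(study$variants), "variants.tsv")
  write_gmt(study$gene_sets, art("pathways.gmt")); written <- c(written, "pathways.gmt")
  emit(study$gene_go_table, "gene_go.tsv")
  emit(data.table::as.data.table(study$covariates), "covariates.tsv")
  jsonlite::write_json(
    list(causal_pathway_ids = study$truth$causal_pathway_ids,
         causal_gene_ids = study$truth$causal_gene_ids,
         causal_snp_ids = study$truth$causal_snp_ids,
         realized_heritability = study$truth$realized_heritability),
    art("truth.json"), auto_unbox = TRUE, digits = NA)
  written <- c(written, "truth.json")

  Gq <- stage("qc", filter_variants(study$genotypes,
                                    maf_min = cfg$qc$maf_min,
                                    call_rate_min = cfg$qc$call_rate_min))
  Gc <- stage("impute", impute_missing(Gq, strategy = cfg$impute$strategy))

  # IBS works on hard calls with pairwise-complete SNPs, so ancestry is
  # diagnosed on the QC'd matrix before imputation
  anc <- stage("strata", ancestry_pcs(Gq, k = min(2L, nrow(Gq$dosage)),
                                      basis = "ibs-distance"))
  emit(data.table::data.table(subject_id = anc$subject_ids,
                              anc$component_scores), "ancestry_pcs.tsv")

  covs <- study$covariates
  adj <- cfg$adjust$covariates
  if (isTRUE(cfg$adjust$use_ancestry_pc)) {
    covs$ancestry_pc1 <- anc$component_scores[, 1]
    adj <- union(adj, "ancestry_pc1")
  }
  Yadj <- stage("adjust", residualize(study$phenotype, covs, adj))
  red <- stage("reduce", pca_reduce(Yadj, k = cfg$pca$k))
  emit(data.table::data.table(subject_id = red$subject_ids,
                              red$component_scores), "phenotype_scores.tsv")

  groups <- stage("groups", build_groups(study$annotation, study$gene_sets,
                                         snp_ids = Gc$snp_ids))
  pargs <- cfg$psrrr
  pargs$seed <- derive_seed(seed, 2L)
  pcfg <- stage("psrrr", do.call(psrrr_config, pargs))
  wts <- stage("psrrr", tune_weights(Gc, red, groups, pcfg))
  emp <- stage("psrrr", stability_select(Gc, red, groups, wts, pcfg))
  nullf <- stage("psrrr", {
    ncfg <- pcfg; ncfg$seed <- derive_seed(seed, 3L)
    stability_select(Gc, red, groups, wts, ncfg, null_mode = TRUE)
  })
  ranking <- stage("psrrr", rank_pathways(emp, nullf))
  emit(ranking, "ranking.tsv")

  top_pathway <- ranking$pathway_id[1]
  gargs <- cfg$gggl
  gargs$seed <- derive_seed(seed, 5L)
  gcfg <- stage("gggl", do.call(gggl_config, gargs))
  pg <- stage("gggl", pathway_gene_design(Gc, study$annotation,
                                          study$gene_sets[[top_pathway]]))
  net <- stage("gggl", {
    tab <- study$gene_go_table
    go_adjacency(tab[tab$gene_id %in% names(pg$gene_groups), ])
  })
  yscalar <- red$component_scores[, 1]
  gp <- stage("gggl", gene_selection_probabilities(pg$X, yscalar,
                                                   pg$gene_groups, net, gcfg,
                                                   keep_fits = TRUE))
  emit(data.table::data.table(gene_id = names(gp$probability),
                              probability = as.numeric(gp$probability),
                              above_threshold = names(gp$probability) %in%
                                gp$genes_above_threshold),
       "gene_probabilities.tsv")
  snps <- stage("gggl", rank_snps(gp$fits, gcfg$top_k_snps))
  emit(snps, "top_snps.tsv")

  top_k <- cfg$enrich$top_k %||% min(30L, nrow(ranking))
  enr <- stage("enrich", category_overrepresentation(
    ranking, study$truth$causal_pathway_ids, top_k))
  emit(data.table::data.table(category = "causal_pathways", k = enr$k,
                              n = enr$n, K = enr$K, N = enr$N,
                              p_value = enr$p_value), "enrichment.tsv")

  report <- list(
    package_version = as.character(utils::packageVersion("pathrider")),
    seed = seed,
    config = cfg,
    n_subjects = nrow(Gc$dosage),
    n_snps_input = scfg$n_snps,
    n_snps_retained = ncol(Gc$dosage),
    phenotype_components = red$k,
    weight_provenance = wts$provenance,
    psrrr_nonconverged_fits = attr(emp, "n_nonconverged") %||% 0L,
    top_pathway = top_pathway,
    causal_pathways = study$truth$causal_pathway_ids,
    recovered = top_pathway %in% study$truth$causal_pathway_ids,
    genes_above_threshold = gp$genes_above_threshold,
    enrichment_p = enr$p_value,
    artifacts = {
      dig <- vapply(written, function(f) unname(tools::md5sum(art(f))), "")
      as.list(dig)
    }
  )
  jsonlite::write_json(report, art("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
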