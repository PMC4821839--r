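#' Simulation configuration
#'
#' Bundles the generative knobs for the synthetic imaging-genetics cohort:
#' genotypes in LD blocks with optional two-subpopulation structure
#' (Balding-Nichols allele-frequency model), SNPs grouped into (possibly
#' overlapping) pathways, and a multivariate quantitative phenotype carrying a
#' rank-1 pathway-structured genetic signal plus clinical covariate effects
#' (gestational age at birth, postmenstrual age at scan) and Gaussian noise.
#'
#' Defaults emulate the statistical structure of a small preterm-infant
#' imaging-genetics cohort: 72 subjects, SNPs with MAF >= 5%, two continuous
#' covariates, a PCA-reduced trait of dimension 10 and a single causal
#' pathway at heritability 0.3.
#'
#' @param n_subjects number of subjects (cohort default 72).
#' @param n_snps number of SNPs.
#' @param maf_range ancestral minor-allele-frequency range, in (0, 0.5].
#' @param ld_block_size SNPs per LD block.
#' @param ld_rho latent adjacent-SNP correlation within a block, in [0, 1).
#' @param n_subpops number of subpopulations.
#' @param fst Balding-Nichols differentiation parameter, in [0, 1).
#' @param n_genes,n_pathways annotation dimensions.
#' @param pathway_size_range min/max genes per pathway.
#' @param overlap_fraction target fraction of genes belonging to >1 pathway.
#' @param n_causal_pathways pathways carrying genetic signal.
#' @param causal_genes_per_pathway optionally restrict the signal to this many
#'   network-clustered genes per causal pathway (default: all genes).
#' @param trait_dim phenotype dimensionality (post-PCA scale).
#' @param trait_rank 1 gives the pure rank-1 signal; larger values add
#'   orthogonal nuisance components carrying no genetic signal.
#' @param heritability target genetic variance fraction of the
#'   covariate-adjusted phenotype, in [0, 1).
#' @param covariate_effects length-2 numeric, effect scale of ga and pma.
#' @param missing_rate completely-at-random genotype missingness.
#' @param seed integer seed; all outputs are reproducible given the config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 72L, n_snps = 1000L,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10L, ld_rho = 0.7,
                       n_subpops = 1L, fst = 0,
                       n_genes = 100L, n_pathways = 20L,
                       pathway_size_range = c(5L, 15L),
                       overlap_fraction = 0.1,
                       n_causal_pathways = 1L,
                       causal_genes_per_pathway = NULL,
                       trait_dim = 10L, trait_rank = 1L,
                       heritability = 0.3,
                       covariate_effects = c(0.5, 0.5),
                       missing_rate = 0.01, seed = 1L) {
  stopifnot(n_subjects >= 2, n_snps >= 1, ld_block_size >= 1,
            n_subpops >= 1, n_genes >= 1, n_pathways >= 1,
            trait_dim >= 1, n_causal_pathways >= 0)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an increasing pair within (0, 0.5]")
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must be a proportion")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be a proportion in [0, 1)")
  }
  if (heritability < 0 || heritability >= 1) {
    stop("heritability must be in [0, 1)")
  }
  if (pathway_size_range[1] < 1 || pathway_size_range[1] > pathway_size_range[2]) {
    stop("pathway_size_range must be an increasing pair with min >= 1")
  }
  if (trait_rank < 1 || trait_rank > trait_dim) {
    stop("trait_rank must be in [1, trait_dim]")
  }
  if (length(covariate_effects) != 2) {
    stop("covariate_effects must have length 2 (ga, pma)")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
    n_subpops = as.integer(n_subpops), fst = fst,
    n_genes = as.integer(n_genes), n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    overlap_fraction = overlap_fraction,
    n_causal_pathways = as.integer(n_causal_pathways),
    causal_genes_per_pathway = causal_genes_per_pathway,
    trait_dim = as.integer(trait_dim), trait_rank = as.integer(trait_rank),
    heritability = heritability,
    covariate_effects = as.numeric(covariate_effects),
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate genotypes with LD blocks and subpopulation structure
#'
#' Minor-allele counts in \{0, 1, 2\} are generated by thresholding two
#' independent AR(1) Gaussian latents per subject (one per haplotype) at the
#' subject's subpopulation allele frequency, giving a controllable
#' adjacent-SNP correlation within each LD block. Subpopulation frequencies
#' follow the Balding-Nichols construction: Beta draws around a shared
#' ancestral frequency with variance governed by `fst`. Missing genotypes are
#' masked completely at random.
#'
#' @param config a [sim_config()].
#' @return A list with `genotypes` (a `genotype_matrix`), `variants`
#'   (a `variant_table`) and `subpop_labels` (integer vector).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects; p <- config$n_snps
  with_seed(derive_seed(config$seed, 11L), {
    p_anc <- runif(p, config$maf_range[1], config$maf_range[2])
    K <- config$n_subpops
    if (K > 1 && config$fst > 0) {
      a <- p_anc * (1 - config$fst) / config$fst
      b <- (1 - p_anc) * (1 - config$fst) / config$fst
      freq <- matrix(rbeta(K * p, rep(a, each = K), rep(b, each = K)),
                     nrow = K)
      freq <- pmin(pmax(freq, 1e-3), 1 - 1e-3)
    } else {
      freq <- matrix(rep(p_anc, each = K), nrow = K)
    }
    labels <- rep(seq_len(K), length.out = n)
    labels <- sort(labels)

    thr <- qnorm(freq[labels, , drop = FALSE])  # n x p thresholds
    rho <- config$ld_rho
    blk <- config$ld_block_size
    latent <- function() {
      Z <- matrix(rnorm(n * p), n, p)
      if (rho > 0 && blk > 1) {
        for (j in seq_len(p)) {
          if ((j - 1) %% blk != 0) {
            Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * Z[, j]
          }
        }
      }
      Z
    }
    dosage <- (latent() < thr) + (latent() < thr)
    storage.mode(dosage) <- "double"
    if (config$missing_rate > 0) {
      dosage[runif(n * p) < config$missing_rate] <- NA_real_
    }
    snp_ids <- sprintf("snp%05d", seq_len(p))
    subject_ids <- sprintf("subj%03d", seq_len(n))
    dimnames(dosage) <- list(subject_ids, snp_ids)
    variants <- variant_table(
      snp_id = snp_ids, chromosome = rep("1", p),
      position = 1L + (seq_len(p) - 1L) * 5000L,
      allele1 = rep("A", p), allele2 = rep("B", p))
    list(genotypes = genotype_matrix(dosage),
         variants = variants,
         subpop_labels = labels)
  })
}

#' Simulate SNP/gene/pathway annotation, GO table and gene network
#'
#' SNPs are assigned to genes in contiguous blocks; pathways are windows over
#' a shuffled gene ordering so that consecutive pathways share genes (each
#' shared gene belongs to exactly two pathways), realising the requested
#' overlap fraction. Each pathway owns a pool of GO terms; member genes draw
#' most of their annotation from their pathways' pools, so functionally
#' related (same-pathway) genes share terms and acquire high semantic
#' similarity in the derived gene network.
#'
#' @param config a [sim_config()].
#' @return list with `annotation` (snp/gene and gene/pathway multimaps),
#'   `gene_sets` (named list, GMT-style), `gene_go_table` (data.table with
#'   columns gene_id, term), `network` (a `gene_network`), `gene_ids`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nG <- config$n_genes; K <- config$n_pathways
  snps_per_gene <- config$n_snps %/% nG
  if (snps_per_gene < 1) {
    stop("n_genes exceeds n_snps: no SNPs available per gene")
  }
  with_seed(derive_seed(config$seed, 23L), {
    gene_ids <- sprintf("gene%04d", seq_len(nG))
    snp_ids <- sprintf("snp%05d", seq_len(config$n_snps))
    gene_of_snp <- rep(NA_character_, config$n_snps)
    gene_of_snp[seq_len(nG * snps_per_gene)] <-
      rep(gene_ids, each = snps_per_gene)
    snp_to_genes <- data.table::data.table(
      snp_id = snp_ids[!is.na(gene_of_snp)],
      gene_id = gene_of_snp[!is.na(gene_of_snp)])

    # pathway windows over a shuffled gene order, overlapping consecutively
    sizes <- sample(seq(config$pathway_size_range[1],
                        config$pathway_size_range[2]), K, replace = TRUE)
    n_overlap <- round(config$overlap_fraction * nG)
    ov <- integer(max(K - 1, 0))
    if (K > 1 && n_overlap > 0) {
      ov <- rep(n_overlap %/% (K - 1), K - 1)
      extra <- n_overlap - sum(ov)
      if (extra > 0) ov[seq_len(extra)] <- ov[seq_len(extra)] + 1L
      # cap: a shared gene must sit in exactly two pathways
      for (k in seq_len(K - 1)) {
        ov[k] <- min(ov[k], sizes[k] - 1L, sizes[k + 1] - 1L)
      }
      for (k in seq_len(K)[-1]) {
        if (k < K && ov[k - 1] + ov[k] >= sizes[k]) {
          ov[k] <- max(0L, sizes[k] - ov[k - 1] - 1L)
        }
      }
    }
    needed <- sum(sizes) - sum(ov)
    if (needed > nG) {
      stop(sprintf(paste0("infeasible overlap/size demands: pathways need %d",
                          " distinct genes but only %d exist"), needed, nG))
    }
    ord <- sample(gene_ids)
    starts <- cumsum(c(1L, sizes[-K] - ov))
    path_ids <- sprintf("path%03d", seq_len(K))
    gene_sets <- lapply(seq_len(K), function(k) {
      ord[starts[k]:(starts[k] + sizes[k] - 1L)]
    })
    names(gene_sets) <- path_ids
    gene_to_pathways <- data.table::rbindlist(lapply(path_ids, function(pid) {
      data.table::data.table(gene_id = gene_sets[[pid]], pathway_id = pid)
    }))

    # GO annotation: pathway-specific pools plus a global background
    n_bg <- 20L
    bg_terms <- sprintf("GO:bg%03d", seq_len(n_bg))
    pool <- lapply(path_ids, function(pid) sprintf("GO:%s:t%d", pid, 1:6))
    names(pool) <- path_ids
    rows <- lapply(gene_ids, function(g) {
      paths <- gene_to_pathways[gene_to_pathways$gene_id == g, ]$pathway_id
      terms <- character(0)
      for (pid in paths) terms <- c(terms, sample(pool[[pid]], 4L))
      terms <- c(terms, sample(bg_terms, 2L))
      if (!length(paths)) terms <- c(terms, paste0("GO:solo:", g))
      data.table::data.table(gene_id = g, term = unique(terms))
    })
    gene_go_table <- data.table::rbindlist(rows)
    network <- go_adjacency(gene_go_table, measure = "dice")
    list(annotation = list(snp_to_genes = snp_to_genes,
                           gene_to_pathways = gene_to_pathways),
         gene_sets = gene_sets,
         gene_go_table = gene_go_table,
         network = network,
         gene_ids = gene_ids)
  })
}

#' Simulate a multivariate phenotype with a planted rank-1 genetic signal
#'
#' Builds `Y = C Gamma + (X b) a' + nuisance + E`: `b` is supported only on
#' SNPs of the causal pathways (optionally restricted to a network-clustered
#' subset of their genes), `a` is a unit trait-loading vector, `C` holds two
#' standardized clinical covariates (ga, pma) and `E` is i.i.d. Gaussian with
#' variance calibrated so the genetic variance fraction of the
#' covariate-adjusted phenotype matches `config$heritability`.
#'
#' @param G output of [simulate_genotypes()] (the `genotypes` element or the
#'   whole list).
#' @param ann output of [simulate_annotation()].
#' @param config a [sim_config()].
#' @return list with `phenotype` (a `phenotype_matrix`), `covariates`
#'   (a `covariate_table`) and `truth` (planted ground truth).
#' @export
simulate_phenotype <- function(G, ann, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(G, "genotype_matrix")) G <- G$genotypes
  n <- nrow(G$dosage); p <- ncol(G$dosage); q <- config$trait_dim
  h <- config$heritability
  with_seed(derive_seed(config$seed, 37L), {
    path_ids <- names(ann$gene_sets)
    nc <- min(config$n_causal_pathways, length(path_ids))
    causal_paths <- if (nc > 0) sort(sample(path_ids, nc)) else character(0)
    if (config$n_causal_pathways > 0 && h == 0) {
      warning("heritability is 0: causal pathways carry no signal")
    }

    causal_genes <- character(0)
    for (pid in causal_paths) {
      gset <- intersect(ann$gene_sets[[pid]],
                        unique(ann$annotation$snp_to_genes$gene_id))
      m <- config$causal_genes_per_pathway
      if (!is.null(m) && m < length(gset)) {
        # pick a network-clustered subset: a seed gene plus its most
        # similar neighbours in the GO-derived adjacency
        A <- ann$network$adjacency[gset, gset, drop = FALSE]
        seed_gene <- gset[which.max(rowSums(A))]
        nb <- names(sort(A[seed_gene, ], decreasing = TRUE))
        gset <- c(seed_gene, setdiff(nb, seed_gene)[seq_len(m - 1L)])
      }
      causal_genes <- union(causal_genes, gset)
    }
    stg <- ann$annotation$snp_to_genes
    causal_snp_ids <- unique(stg[stg$gene_id %in% causal_genes, ]$snp_id)
    causal_idx <- sort(match(causal_snp_ids, G$snp_ids))

    b <- numeric(p)
    if (length(causal_idx) && h > 0) b[causal_idx] <- rnorm(length(causal_idx))

    X <- G$dosage
    if (anyNA(X)) {  # internal mean imputation just for signal construction
      mu <- colMeans(X, na.rm = TRUE)
      idx <- which(is.na(X), arr.ind = TRUE)
      X[idx] <- mu[idx[, 2]]
    }
    g <- as.numeric(X %*% b)
    g <- g - mean(g)

    a <- rnorm(q)
    a <- a / sqrt(sum(a^2))
    if (a[1] < 0) a <- -a

    ga <- runif(n, 24, 32)     # gestational age at birth, weeks
    pma <- runif(n, 38, 44)    # postmenstrual age at scan, weeks
    Cstd <- cbind(ga = as.numeric(scale(ga)), pma = as.numeric(scale(pma)))
    Gamma <- rbind(config$covariate_effects[1] * rnorm(q) / sqrt(q),
                   config$covariate_effects[2] * rnorm(q) / sqrt(q))

    var_g <- var(g)
    R <- config$trait_rank
    signal <- outer(g, a)
    nuis <- matrix(0, n, q)
    if (R > 1 && var_g > 0) {
      V <- matrix(rnorm(q * (R - 1)), q)
      V <- qr.Q(qr(cbind(a, V)))[, -1, drop = FALSE]  # orthogonal to a
      U <- matrix(rnorm(n * (R - 1), sd = sqrt(var_g)), n)
      nuis <- U %*% t(V)
    }
    if (var_g > 0 && h > 0) {
      sig2q <- var_g * (1 / h - 1) - (R - 1) * var_g
      if (sig2q <= 0) {
        stop("heritability too high for the requested trait_rank")
      }
      sig2 <- sig2q / q
    } else {
      sig2 <- 1
      signal <- matrix(0, n, q)
    }
    E <- matrix(rnorm(n * q, sd = sqrt(sig2)), n, q)
    Ygen <- signal + nuis + E
    Y <- Cstd %*% Gamma + Ygen

    realized <- if (var_g > 0 && h > 0) {
      sum(apply(signal, 2, var)) / sum(apply(Ygen, 2, var))
    } else 0

    feature_ids <- sprintf("trait%02d", seq_len(q))
    dimnames(Y) <- list(G$subject_ids, feature_ids)
    truth <- list(causal_pathway_ids = causal_paths,
                  causal_gene_ids = sort(causal_genes),
                  causal_snp_indices = causal_idx,
                  causal_snp_ids = G$snp_ids[causal_idx],
                  snp_effect_vector = b,
                  trait_loading_vector = a,
                  covariate_coefficient_matrix = Gamma,
                  realized_heritability = realized)
    list(phenotype = phenotype_matrix(Y),
         covariates = covariate_table(G$subject_ids, ga = ga, pma = pma),
         truth = truth)
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_genotypes()], [simulate_annotation()]
#' and [simulate_phenotype()] under one config.
#' @param config a [sim_config()].
#' @return list with elements `genotypes`, `variants`, `subpop_labels`,
#'   `annotation`, `gene_sets`, `gene_go_table`, `network`, `phenotype`,
#'   `covariates`, `truth`.
#' @export
simulate_study <- function(config) {
  geno <- simulate_genotypes(config)
  ann <- simulate_annotation(config)
  phen <- simulate_phenotype(geno$genotypes, ann, config)
  c(geno, ann, phen)
}

#' Write simulated study artifacts as plain-text files
#'
#' Genotypes as PLINK-style `.raw` (plus `.bim`/`.fam`-like TSVs), pathways
#' as GMT, gene/GO table and phenotype/covariates as TSV, ground truth as
#' JSON.
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @param prefix file name stem.
#' @return invisibly, the vector of files written.
#' @export
write_study <- function(study, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(ext) file.path(dir, paste0(prefix, ext))
  write_genotypes(study$genotypes, f(".raw"), dialect = "plink-raw")
  data.table::fwrite(as.data.table(study$variants), f(".bim.tsv"), sep = "\t")
  fam <- data.table::data.table(subject_id = study$genotypes$subject_ids,
                                subpop = study$subpop_labels)
  data.table::fwrite(fam, f(".fam.tsv"), sep = "\t")
  write_gmt(study$gene_sets, f(".pathways.gmt"))
  data.table::fwrite(study$gene_go_table, f(".gene_go.tsv"), sep = "\t")
  ph <- data.table::data.table(subject_id = study$phenotype$subject_ids)
  ph <- cbind(ph, data.table::as.data.table(study$phenotype$values))
  data.table::fwrite(ph, f(".phenotype.tsv"), sep = "\t")
  data.table::fwrite(data.table::as.data.table(study$covariates),
                     f(".covariates.tsv"), sep = "\t")
  tr <- study$truth
  tr$snp_effect_vector <- NULL  # long; recoverable from indices + json below
  jsonlite::write_json(c(tr, list(
    snp_effects = study$truth$snp_effect_vector[study$truth$causal_snp_indices])),
    f(".truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(f(".raw"), f(".bim.tsv"), f(".fam.tsv"), f(".pathways.gmt"),
              f(".gene_go.tsv"), f(".phenotype.tsv"), f(".covariates.tsv"),
              f(".truth.json")))
}
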