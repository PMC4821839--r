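#' Genotype matrix container
#'
#' Subjects-by-SNPs minor-allele counts with an implicit missingness mask
#' (`NA` entries). After imputation dosages may be fractional in `[0, 2]`.
#'
#' @param dosage numeric matrix with subject and SNP dimnames (or supply ids).
#' @param subject_ids,snp_ids optional ids overriding dimnames.
#' @return object of class `genotype_matrix` with fields `subject_ids`,
#'   `snp_ids`, `dosage`, `missing_mask`.
#' @export
genotype_matrix <- function(dosage, subject_ids = rownames(dosage),
                            snp_ids = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(subject_ids)) subject_ids <- sprintf("subj%03d", seq_len(nrow(dosage)))
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%05d", seq_len(ncol(dosage)))
  if (anyDuplicated(snp_ids)) stop("duplicated snp_ids")
  if (any(!is.na(dosage))) {
    rng <- range(dosage, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("dosage values must lie in [0, 2]")
  }
  dimnames(dosage) <- list(subject_ids, snp_ids)
  structure(list(subject_ids = subject_ids, snp_ids = snp_ids,
                 dosage = dosage, missing_mask = is.na(dosage)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs, %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage), 100 * mean(x$missing_mask)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' SNP coordinate table
#' @param snp_id,chromosome,position,allele1,allele2 per-variant columns;
#'   positions are 1-based base pairs.
#' @return a `variant_table` (data.table).
#' @export
variant_table <- function(snp_id, chromosome, position, allele1 = "A",
                          allele2 = "B") {
  if (anyDuplicated(snp_id)) stop("duplicated snp_ids in variant table")
  if (any(position < 1)) stop("positions must be positive (1-based)")
  dt <- data.table::data.table(snp_id = as.character(snp_id),
                               chromosome = as.character(chromosome),
                               position = as.integer(position),
                               allele1 = allele1, allele2 = allele2)
  data.table::setattr(dt, "class", c("variant_table", class(dt)))
  dt
}

#' Gene coordinate table (1-based inclusive spans)
#' @param gene_id,chromosome,start,end per-gene columns.
#' @return a `gene_model_table` (data.table).
#' @export
gene_model_table <- function(gene_id, chromosome, start, end) {
  if (any(end < start)) stop("gene end < start")
  dt <- data.table::data.table(gene_id = as.character(gene_id),
                               chromosome = as.character(chromosome),
                               start = as.integer(start),
                               end = as.integer(end))
  data.table::setattr(dt, "class", c("gene_model_table", class(dt)))
  dt
}

#' Subject covariate table
#' @param subject_ids subject identifiers.
#' @param ... named numeric covariates (e.g. `ga`, `pma`, `ancestry_pc1`),
#'   complete (no NA) and of matching length.
#' @return a `covariate_table` (data.table).
#' @export
covariate_table <- function(subject_ids, ...) {
  cov <- list(...)
  for (nm in names(cov)) {
    if (length(cov[[nm]]) != length(subject_ids)) {
      stop(sprintf("covariate '%s' length mismatch", nm))
    }
    if (anyNA(cov[[nm]])) stop(sprintf("covariate '%s' has missing values", nm))
  }
  dt <- data.table::data.table(subject_id = as.character(subject_ids))
  for (nm in names(cov)) dt[[nm]] <- as.numeric(cov[[nm]])
  data.table::setattr(dt, "class", c("covariate_table", class(dt)))
  dt
}

#' Write genotypes to disk
#'
#' `plink-raw` writes the usual additive-coded `.raw` layout (header
#' `FID IID PAT MAT SEX PHENOTYPE` then one column per SNP named
#' `<snp>_<counted allele>`, values 0/1/2/NA, space separated).
#' `additive-tsv` writes a plain TSV with subject ids in the first column.
#'
#' @param G a `genotype_matrix`.
#' @param path output file.
#' @param dialect `"plink-raw"` or `"additive-tsv"`.
#' @param counted_allele allele suffix used for `.raw` column names.
#' @export
write_genotypes <- function(G, path, dialect = c("plink-raw", "additive-tsv"),
                            counted_allele = "B") {
  dialect <- match.arg(dialect)
  if (dialect == "plink-raw") {
    dt <- data.table::data.table(FID = G$subject_ids, IID = G$subject_ids,
                                 PAT = 0L, MAT = 0L, SEX = 0L,
                                 PHENOTYPE = -9L)
    dos <- data.table::as.data.table(G$dosage)
    data.table::setnames(dos, paste0(G$snp_ids, "_", counted_allele))
    data.table::fwrite(cbind(dt, dos), path, sep = " ", na = "NA",
                       quote = FALSE)
  } else {
    dt <- data.table::data.table(subject_id = G$subject_ids)
    dt <- cbind(dt, data.table::as.data.table(G$dosage))
    data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  }
  invisible(path)
}

#' Read genotypes from disk
#'
#' Round-trips [write_genotypes()] exactly. Dosage codes other than
#' 0/1/2/NA raise a parse error naming the offending row and column
#' (fractional dosages are not accepted on input files).
#'
#' @param path input file.
#' @param dialect `"plink-raw"` or `"additive-tsv"`.
#' @return list with `genotypes` (a `genotype_matrix`) and `variants` (a
#'   minimal `variant_table` reconstructed from column names).
#' @export
read_genotypes <- function(path, dialect = c("plink-raw", "additive-tsv")) {
  dialect <- match.arg(dialect)
  hdr <- strsplit(readLines(path, n = 1),
                  if (dialect == "plink-raw") " " else "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(hdr)) {
    stop(sprintf("duplicated snp_ids in '%s': %s", path,
                 paste(unique(hdr[duplicated(hdr)])[1:3], collapse = ", ")))
  }
  dt <- tryCatch(
    data.table::fread(path, na.strings = "NA", header = TRUE,
                      colClasses = NULL, showProgress = FALSE),
    error = function(e) stop(sprintf("failed to parse '%s': %s", path,
                                     conditionMessage(e))))
  if (dialect == "plink-raw") {
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(dt))) {
      stop("not a .raw file: missing FID/IID/.../PHENOTYPE header columns")
    }
    subject_ids <- as.character(dt$IID)
    snp_cols <- setdiff(names(dt), meta)
    snp_ids <- sub("_[^_]*$", "", snp_cols)
  } else {
    if (names(dt)[1] != "subject_id") {
      stop("additive-tsv must have 'subject_id' as its first column")
    }
    subject_ids <- as.character(dt$subject_id)
    snp_cols <- setdiff(names(dt), "subject_id")
    snp_ids <- snp_cols
  }
  if (anyDuplicated(snp_ids)) {
    stop(sprintf("duplicated snp_ids in '%s': %s", path,
                 paste(unique(snp_ids[duplicated(snp_ids)])[1:3],
                       collapse = ", ")))
  }
  M <- as.matrix(dt[, snp_cols, with = FALSE])
  if (!is.numeric(M)) {
    bad <- which(is.na(suppressWarnings(as.numeric(M))) &
                   !is.na(M))[1]
    rc <- arrayInd(bad, dim(M))
    stop(sprintf("non-numeric dosage at row %d, SNP '%s' in '%s'",
                 rc[1], snp_ids[rc[2]], path))
  }
  storage.mode(M) <- "double"
  ok <- is.na(M) | M == 0 | M == 1 | M == 2
  if (!all(ok)) {
    rc <- arrayInd(which(!ok)[1], dim(M))
    stop(sprintf("invalid dosage code %s at row %d, SNP '%s' in '%s'",
                 format(M[rc]), rc[1], snp_ids[rc[2]], path))
  }
  dimnames(M) <- list(subject_ids, snp_ids)
  list(genotypes = genotype_matrix(M),
       variants = variant_table(snp_id = snp_ids,
                                chromosome = rep("1", length(snp_ids)),
                                position = seq_along(snp_ids)))
}

#' Variant quality control
#'
#' Retains SNPs with minor allele frequency `>= maf_min` and call rate
#' `>= call_rate_min`, both computed on non-missing dosages. MAF is
#' `min(f, 1 - f)` with `f = mean(dosage)/2`. Defaults are the conventional
#' GWAS thresholds (MAF 5%, genotyping rate 99%). The subject set is
#' unchanged; the operation is idempotent.
#'
#' @param G a `genotype_matrix`.
#' @param maf_min minimum minor-allele frequency (default 0.05).
#' @param call_rate_min minimum per-SNP call rate (default 0.99).
#' @return filtered `genotype_matrix`; retained ids in `attr(, "retained")`.
#' @export
filter_variants <- function(G, maf_min = 0.05, call_rate_min = 0.99) {
  stopifnot(inherits(G, "genotype_matrix"))
  call_rate <- colMeans(!G$missing_mask)
  f <- colMeans(G$dosage, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0  # all-missing column
  keep <- maf >= maf_min & call_rate >= call_rate_min
  if (!any(keep)) warning("no SNPs pass the variant filters")
  out <- genotype_matrix(G$dosage[, keep, drop = FALSE])
  attr(out, "retained") <- G$snp_ids[keep]
  out
}

#' Impute residual missing genotypes
#'
#' @param G a `genotype_matrix`.
#' @param strategy `"column-mean"` (fractional dosages allowed) or
#'   `"column-mode"` (most frequent code, ties to the smaller code).
#' @return a complete `genotype_matrix` (no missing entries).
#' @export
impute_missing <- function(G, strategy = c("column-mean", "column-mode")) {
  strategy <- match.arg(strategy)
  X <- G$dosage
  if (!anyNA(X)) return(G)
  nmiss <- colSums(is.na(X))
  if (any(nmiss == nrow(X))) {
    stop(sprintf("all-missing SNP column(s): %s",
                 paste(head(G$snp_ids[nmiss == nrow(X)], 3), collapse = ", ")))
  }
  fill <- if (strategy == "column-mean") {
    colMeans(X, na.rm = TRUE)
  } else {
    apply(X, 2, function(col) {
      tab <- table(factor(col[!is.na(col)], levels = c(0, 1, 2)))
      as.numeric(names(tab)[which.max(tab)])
    })
  }
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- fill[idx[, 2]]
  genotype_matrix(X)
}

#' Map SNPs to genes by genomic proximity
#'
#' A SNP maps to a gene iff its position lies in
#' `[start - window, end + window]`, inclusive at both ends; multi-gene hits
#' are all retained. Default window 10 kb, the conventional "near a RefSeq
#' gene" margin.
#'
#' @param variants a `variant_table`.
#' @param genes a `gene_model_table` (shared chromosome naming).
#' @param window flanking margin in base pairs.
#' @return data.table `snp_to_genes` with columns `snp_id`, `gene_id`,
#'   sorted for order-independence.
#' @export
map_snps_to_genes <- function(variants, genes, window = 10000L) {
  v <- data.table::as.data.table(variants)[, c("snp_id", "chromosome", "position")]
  g <- data.table::as.data.table(genes)[, c("gene_id", "chromosome", "start", "end")]
  g$lo <- g$start - as.integer(window)
  g$hi <- g$end + as.integer(window)
  v$pos2 <- v$position
  hits <- g[v, on = .(chromosome, lo <= pos2, hi >= position),
            nomatch = NULL,
            .(snp_id = i.snp_id, gene_id = x.gene_id)]
  data.table::setorder(hits, snp_id, gene_id)
  unique(hits)
}

#' Build pathway SNP groups on an expanded design
#'
#' Excluded pathways are dropped, but their genes remain available to other
#' pathways. A SNP whose gene(s) belong to several retained pathways is
#' duplicated into each pathway's block of expanded columns, so the grouped
#' penalty downstream is a plain non-overlapping group lasso on the expanded
#' design. Pathways with zero mapped SNPs are dropped with a message.
#'
#' @param ann annotation with `snp_to_genes` (data.table snp_id, gene_id).
#'   The `annotation` element of [simulate_annotation()] works directly.
#' @param gene_sets named list: pathway id -> character vector of gene ids.
#' @param exclusions pathway ids to drop (e.g. redundant cancer pathways).
#' @param snp_ids column order of the original design; defaults to sorted
#'   unique mapped SNP ids.
#' @return object of class `pathway_groups` with `group_ids`,
#'   `group_index_lists` (expanded column indices per pathway),
#'   `expansion_map` (expanded column -> original column), `group_sizes`,
#'   `snp_ids`.
#' @export
build_groups <- function(ann, gene_sets, exclusions = character(),
                         snp_ids = NULL) {
  stg <- if (is.data.frame(ann)) ann else ann$snp_to_genes
  gene_sets <- gene_sets[setdiff(names(gene_sets), exclusions)]
  if (!length(gene_sets)) stop("no pathways remain after exclusions")
  if (is.null(snp_ids)) snp_ids <- sort(unique(stg$snp_id))

  group_ids <- character(0)
  group_index_lists <- list()
  expansion_map <- integer(0)
  offset <- 0L
  for (pid in names(gene_sets)) {
    snps <- unique(stg[stg$gene_id %in% gene_sets[[pid]], ]$snp_id)
    cols <- sort(match(snps, snp_ids))
    cols <- cols[!is.na(cols)]
    if (!length(cols)) {
      message(sprintf("pathway '%s' has no mapped SNPs; dropped", pid))
      next
    }
    group_ids <- c(group_ids, pid)
    group_index_lists[[pid]] <- offset + seq_along(cols)
    expansion_map <- c(expansion_map, cols)
    offset <- offset + length(cols)
  }
  if (!length(group_ids)) stop("all pathways are empty after SNP mapping")
  structure(list(group_ids = group_ids,
                 group_index_lists = group_index_lists,
                 expansion_map = expansion_map,
                 group_sizes = lengths(group_index_lists),
                 snp_ids = snp_ids),
            class = "pathway_groups")
}

#' @export
print.pathway_groups <- function(x, ...) {
  cat(sprintf("pathway_groups: %d pathways, %d expanded columns over %d SNPs\n",
              length(x$group_ids), length(x$expansion_map),
              length(unique(x$expansion_map))))
  invisible(x)
}

#' Expand a design matrix by the pathway duplication map
#' @param X n x p matrix in the original SNP column order.
#' @param groups a `pathway_groups`.
#' @return n x p_expanded matrix.
#' @export
expand_design <- function(X, groups) {
  X[, groups$expansion_map, drop = FALSE]
}

#' Collapse expanded coefficients back to per-SNP effects
#'
#' Sums expanded coefficients over the preimages of the expansion map,
#' reproducing an effect vector of the original width (reporting only; the
#' penalty always acts on the expanded design).
#' @param beta coefficient vector on the expanded design.
#' @param groups a `pathway_groups`.
#' @return numeric vector, one entry per original SNP column.
#' @export
collapse_coefficients <- function(beta, groups) {
  p <- length(groups$snp_ids)
  out <- numeric(p)
  agg <- rowsum(beta, group = groups$expansion_map)
  out[as.integer(rownames(agg))] <- agg[, 1]
  names(out) <- groups$snp_ids
  out
}

#' Read a GMT gene-set file
#' @param path tab-separated file: set id, description, then gene ids.
#' @return named list of character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1)
  desc <- vapply(parts, `[`, "", 2)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(desc, ids)
  sets
}

#' Write a GMT gene-set file
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
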