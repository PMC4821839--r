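test_that("genotype IO round-trips both dialects and rejects bad codes", {
  st <- quick_study(seed = 7, n = 25, n_snps = 60, n_genes = 8, n_pathways = 2,
                    pathway_size_range = c(3, 4))
  dir <- withr::local_tempdir()
  for (dialect in c("plink-raw", "additive-tsv")) {
    f <- file.path(dir, paste0("g.", dialect))
    write_genotypes(st$genotypes, f, dialect = dialect)
    rt <- read_genotypes(f, dialect = dialect)
    expect_identical(rt$genotypes$dosage, st$genotypes$dosage)
    expect_identical(rt$genotypes$missing_mask, st$genotypes$missing_mask)
    expect_identical(rt$genotypes$subject_ids, st$genotypes$subject_ids)
  }

  # dosage code 3 -> parse error naming the cell
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("subject_id\tsnpA\tsnpB", "s1\t0\t3", "s2\t1\t2"), bad)
  expect_error(read_genotypes(bad, "additive-tsv"), "snpB")

  # NA tokens become mask entries
  nam <- file.path(dir, "na.tsv")
  writeLines(c("subject_id\tsnpA\tsnpB", "s1\tNA\t2", "s2\t1\tNA"), nam)
  g <- read_genotypes(nam, "additive-tsv")$genotypes
  expect_identical(g$missing_mask,
                   matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2,
                          dimnames = list(c("s1", "s2"), c("snpA", "snpB"))))

  dup <- file.path(dir, "dup.tsv")
  writeLines(c("subject_id\tsnpA\tsnpA", "s1\t0\t1"), dup)
  expect_error(read_genotypes(dup, "additive-tsv"), "duplicated")
})

test_that("variant QC applies the MAF and call-rate thresholds", {
  # hand-computed: col1 MAF 0.1 complete -> kept; col2 all zero -> MAF 0,
  # dropped; col3 one missing of five -> call rate 0.8, dropped
  M <- cbind(snp1 = c(0, 0, 0, 0, 1),
             snp2 = c(0, 0, 0, 0, 0),
             snp3 = c(0, 1, 1, 0, NA))
  G <- genotype_matrix(M, subject_ids = paste0("s", 1:5))
  out <- filter_variants(G, maf_min = 0.05, call_rate_min = 0.99)
  expect_identical(out$snp_ids, "snp1")

  # vacuous filter keeps everything; default thresholds are 0.05 / 0.99
  expect_identical(filter_variants(G, 0, 0)$snp_ids, c("snp1", "snp2", "snp3"))
  expect_identical(formals(filter_variants)$maf_min, 0.05)
  expect_identical(formals(filter_variants)$call_rate_min, 0.99)

  # idempotence
  once <- filter_variants(G)
  expect_identical(filter_variants(once)$dosage, once$dosage)

  allhalf <- genotype_matrix(matrix(rep(c(0, 1, 2, 1), 3), 4, 3))
  expect_identical(filter_variants(allhalf)$dosage, allhalf$dosage)
})

test_that("imputation fills by mean or mode and only touches missing cells", {
  M <- cbind(a = c(0, 2, NA), b = c(1, 1, 1), c = c(0, NA, 2))
  G <- genotype_matrix(M)
  mean_imp <- impute_missing(G, "column-mean")
  expect_equal(unname(mean_imp$dosage[3, "a"]), 1.0)
  expect_equal(unname(mean_imp$dosage[2, "c"]), 1.0)
  expect_false(any(mean_imp$missing_mask))
  expect_identical(mean_imp$dosage[1, ], G$dosage[1, ])

  M2 <- cbind(a = c(0, 0, 2, NA))
  mode_imp <- impute_missing(genotype_matrix(M2), "column-mode")
  expect_equal(unname(mode_imp$dosage[4, 1]), 0)

  expect_identical(impute_missing(genotype_matrix(M[, 2, drop = FALSE]),
                                  "column-mean")$dosage[, 1],
                   G$dosage[, 2])
  expect_error(impute_missing(genotype_matrix(cbind(x = c(NA, NA))), "column-mean"),
               "all-missing")
})

test_that("SNP-gene mapping uses the inclusive +-window convention", {
  genes <- gene_model_table(gene_id = c("gA", "gB"), chromosome = c("1", "1"),
                            start = c(50000, 58000), end = c(60000, 70000))
  v <- variant_table(snp_id = c("in_gA", "edge", "out", "shared", "otherchr"),
                     chromosome = c("1", "1", "1", "1", "2"),
                     position = c(55000, 40000, 39999, 59000, 55000))
  m <- map_snps_to_genes(v, genes, window = 10000)
  expect_setequal(m$gene_id[m$snp_id == "in_gA"], c("gA", "gB"))
  expect_true("gA" %in% m$gene_id[m$snp_id == "edge"])       # exactly start-10000
  expect_false("out" %in% m$snp_id)                          # start-10001
  expect_setequal(m$gene_id[m$snp_id == "shared"], c("gA", "gB"))
  expect_false("otherchr" %in% m$snp_id)

  # order independence
  perm <- sample(nrow(v))
  m2 <- map_snps_to_genes(v[perm, ], genes[2:1, ], window = 10000)
  expect_identical(as.data.frame(m), as.data.frame(m2))
})

test_that("group building duplicates shared SNPs and honors exclusions", {
  ann <- list(snp_to_genes = data.table::data.table(
    snp_id = c("s1", "s2", "s3", "s4", "s5"),
    gene_id = c("g1", "g1", "g1", "g2", "g3")))
  sets <- list(pwA = c("g1", "g2"), pwB = c("g1", "g3"), pwC = "g2")
  snp_ids <- paste0("s", 1:5)

  gr <- build_groups(ann, sets, snp_ids = snp_ids)
  # g1's three SNPs appear once per pathway containing g1
  expect_equal(sum(gr$expansion_map %in% 1:3), 6)
  expect_equal(length(gr$expansion_map),
               sum(unlist(lapply(gr$group_index_lists, length))))
  expect_setequal(sort(unique(gr$expansion_map)), 1:5)
  # each expanded column belongs to exactly one group
  expect_identical(sort(unlist(gr$group_index_lists, use.names = FALSE)),
                   seq_along(gr$expansion_map))

  # disjoint pathways partition with no duplication
  gr2 <- build_groups(ann, list(p1 = "g2", p2 = "g3"), snp_ids = snp_ids)
  expect_equal(length(gr2$expansion_map), 2)

  # exclusion drops the pathway but keeps genes available to others
  gr3 <- build_groups(ann, sets, exclusions = "pwA", snp_ids = snp_ids)
  expect_false("pwA" %in% gr3$group_ids)
  expect_true(all(1:3 %in% gr3$expansion_map[gr3$group_index_lists$pwB]))
  expect_error(build_groups(ann, sets, exclusions = names(sets)), "no pathways")

  # empty pathways are dropped with a message
  expect_message(
    gr4 <- build_groups(ann, c(sets, list(pwD = "nonexistent")), snp_ids = snp_ids),
    "pwD")
  expect_false("pwD" %in% gr4$group_ids)
})

test_that("coefficient collapse inverts the expansion", {
  ann <- list(snp_to_genes = data.table::data.table(
    snp_id = c("s1", "s2", "s3"), gene_id = c("g1", "g1", "g2")))
  sets <- list(pwA = c("g1", "g2"), pwB = "g1")
  gr <- build_groups(ann, sets, snp_ids = paste0("s", 1:3))
  beta <- seq_along(gr$expansion_map) / 10
  collapsed <- collapse_coefficients(beta, gr)
  direct <- tapply(beta, gr$expansion_map, sum)
  expect_equal(unname(collapsed[as.integer(names(direct))]),
               as.numeric(direct))
  X <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, paste0("s", 1:3)))
  expect_equal(expand_design(X, gr), X[, gr$expansion_map])
})
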