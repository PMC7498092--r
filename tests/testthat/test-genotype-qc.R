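test_that("computeMaf matches hand-counted allele frequencies", {
    expect_equal(computeMaf(c(0, 1, 2)), 0.5)
    expect_equal(computeMaf(c(0, 0, 0)), 0)
    expect_equal(computeMaf(c(2, 2, 2)), 0)       # folded to the minor side
    expect_equal(computeMaf(c(0, 0, 1, 2)), 0.375) # 3 of 8 alleles
    expect_error(computeMaf(numeric(0)), "empty")
    expect_error(computeMaf(c(0, 3)), "0, 1 or 2")
})

test_that("MAF filter is boundary-inclusive and matches a recount oracle", {
    ## 50 samples: MAFs 0.29, 0.30, 0.50 by construction
    d <- rbind(c(rep(1, 29), rep(0, 21)),
               c(rep(1, 30), rep(0, 20)),
               c(rep(1, 50)))
    gt <- GenotypeMatrix(d, chrom = rep("1", 3), pos = c(10L, 20L, 30L))
    kept <- filterMaf(gt, qcThresholds(maf_min = 0.3))
    expect_equal(nrow(kept), 2L)
    expect_equal(attr(kept, "maf_filter"), c(retained = 2L, removed = 1L))
    ## threshold 0 keeps everything
    expect_equal(nrow(filterMaf(gt, qcThresholds(maf_min = 0))), 3L)
    ## random table vs brute-force recount
    set.seed(1)
    d2 <- matrix(sample(0:2, 40 * 30, TRUE,
                        prob = c(0.5, 0.3, 0.2)), 40, 30)
    gt2 <- GenotypeMatrix(d2, chrom = rep("1", 40), pos = seq_len(40) * 100L)
    kept2 <- filterMaf(gt2, qcThresholds())
    d2o <- dosages(gt2)
    maf_oracle <- sapply(seq_len(40), function(i) {
        f <- sum(d2o[i, ]) / 60
        min(f, 1 - f)
    })
    expect_identical(rownames(kept2), rownames(gt2)[maf_oracle >= 0.3])
})

test_that("ldR2 is squared Pearson correlation, invariant to allele flips", {
    d1 <- c(0, 0, 1, 1, 2, 2)
    expect_equal(ldR2(d1, d1), 1)
    expect_equal(ldR2(d1, 2 - d1), 1)
    d2 <- c(0, 1, 0, 1, 2, 2)
    ## explicit sum formula, independent of cor()
    n <- 6
    num <- (n * sum(d1 * d2) - sum(d1) * sum(d2))^2
    den <- (n * sum(d1^2) - sum(d1)^2) * (n * sum(d2^2) - sum(d2)^2)
    expect_equal(ldR2(d1, d2), num / den)
    expect_error(ldR2(rep(1, 6), d1), "monomorphic")
})

test_that("block grouping requires R^2 with every member", {
    ## A and B near-identical; C close to B but not to A: with the
    ## threshold between R2(A,C) and min(R2(A,B), R2(B,C)), C must be
    ## rejected from {A, B} under the all-pairwise rule
    set.seed(4)
    A <- sample(0:2, 60, TRUE, prob = c(0.3, 0.4, 0.3))
    B <- A; B[1] <- (B[1] + 1) %% 3
    C <- B; C[2:4] <- (C[2:4] + 1) %% 3
    r2ab <- ldR2(A, B); r2bc <- ldR2(B, C); r2ac <- ldR2(A, C)
    thr <- (r2ac + min(r2ab, r2bc)) / 2
    expect_true(r2ac < thr && thr < min(r2ab, r2bc))
    gt <- GenotypeMatrix(rbind(A, B, C), chrom = rep("1", 3),
                         pos = c(100L, 200L, 300L))
    res <- groupLdBlocks(gt, qcThresholds(ld_r2_min = thr))
    expect_equal(res$blocks$block_id, c(1L, 1L, 2L))
    expect_equal(nrow(res$genotypes), 2L)
    expect_equal(res$blocks$tag_snp_id[1:2], rep(rownames(gt)[1], 2))
})

test_that("perfect LD collapses to one tag; no LD keeps all SNPs", {
    v <- c(0, 1, 2, 1, 0, 2, 1, 1)
    gt <- GenotypeMatrix(matrix(rep(v, 3), nrow = 3, byrow = TRUE),
                         chrom = rep("2", 3), pos = c(1L, 2L, 3L))
    res <- groupLdBlocks(gt, qcThresholds())
    expect_equal(nrow(res$genotypes), 1L)
    expect_equal(unique(res$blocks$block_id), 1L)
    set.seed(2)
    d <- matrix(sample(0:2, 10 * 60, TRUE, prob = c(0.3, 0.4, 0.3)), 10, 60)
    gt2 <- GenotypeMatrix(d, chrom = rep("1", 10), pos = seq_len(10) * 1000L)
    res2 <- groupLdBlocks(gt2, qcThresholds())
    expect_equal(nrow(res2$genotypes), 10L)  # independent draws: no LD
})

test_that("blocks partition the input, never span chromosomes, and satisfy the R^2 guarantee", {
    cfg <- simulationConfig(n_snps = 80, n_genes = 5, seed = 21, n_cis_effects = 0, n_trans_effects = 0,
                            ld_block_size_mean = 3, n_chromosomes = 4)
    st <- simulateStudy(cfg)
    gt <- filterMaf(recodeToMinor(st$genotypes), qcThresholds())
    res <- groupLdBlocks(gt, qcThresholds())
    expect_setequal(res$blocks$snp_id, rownames(gt))
    expect_equal(nrow(res$blocks), nrow(gt))
    d <- dosages(gt)
    m <- snpMap(gt)
    for (bl in split(res$blocks, res$blocks$block_id)) {
        expect_length(unique(bl$chrom), 1L)
        ids <- bl$snp_id
        if (length(ids) > 1)
            for (i in 2:length(ids))
                for (j in 1:(i - 1))
                    expect_gte(ldR2(d[ids[i], ], d[ids[j], ]), 0.9)
        expect_true(bl$tag_snp_id[1] %in% ids)
    }
    ## monotonicity: a stricter threshold never merges blocks
    n_strict <- max(groupLdBlocks(gt, qcThresholds(ld_r2_min = 0.99))$blocks$block_id)
    expect_gte(n_strict, max(res$blocks$block_id))
    ## regrouping the tags at the same threshold is a near no-op by
    ## construction (tags of distinct blocks failed the pairwise rule
    ## against at least one member, adjacent tags rarely merge)
    res_tags <- groupLdBlocks(res$genotypes, qcThresholds())
    expect_gte(max(res_tags$blocks$block_id), max(res$blocks$block_id) * 0.8)
})

test_that("minor-allele recoding folds frequencies to <= 0.5", {
    d <- rbind(c(2, 2, 2, 1), c(0, 1, 0, 0))
    gt <- GenotypeMatrix(d, chrom = c("1", "1"), pos = c(1L, 2L))
    rec <- dosages(recodeToMinor(gt))
    expect_equal(rec[1, ], c(0, 0, 0, 1), ignore_attr = TRUE)
    expect_equal(rec[2, ], c(0, 1, 0, 0), ignore_attr = TRUE)
})

test_that("a minimal VCF converts to the dosage coding", {
    skip_if_not_installed("vcfR")
    vcf <- c("##fileformat=VCFv4.2",
             "##contig=<ID=1>",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S01", "S02", "S03", sep = "\t"),
             paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
                   "0/0", "0/1", "1/1", sep = "\t"),
             paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
                   "0|1", "0|0", "1|1", sep = "\t"))
    f <- tempfile(fileext = ".vcf")
    writeLines(vcf, f)
    gt <- readVcfDosages(f)
    expect_equal(unname(dosages(gt)["rs1", ]), c(0, 1, 2))
    expect_equal(unname(dosages(gt)["rs2", ]), c(1, 0, 2))
    expect_equal(snpMap(gt)$pos, c(100L, 200L))
})
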