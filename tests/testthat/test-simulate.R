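test_that("identical configs give identical studies", {
    cfg <- simulationConfig(n_snps = 60, n_genes = 25, seed = 7)
    a <- simulateStudy(cfg)
    b <- simulateStudy(cfg)
    expect_identical(dosages(a$genotypes), dosages(b$genotypes))
    expect_identical(SummarizedExperiment::assay(a$counts, "counts"),
                     SummarizedExperiment::assay(b$counts, "counts"))
    expect_identical(a$pedigree, b$pedigree)
    expect_identical(a$covariates, b$covariates)
    expect_identical(a$truth$planted_pairs, b$truth$planted_pairs)
    ## and a different seed gives different data
    c <- simulateStudy(simulationConfig(n_snps = 60, n_genes = 25, seed = 8))
    expect_false(identical(dosages(a$genotypes), dosages(c$genotypes)))
})

test_that("covariates match the two-group design", {
    cfg <- simulationConfig(n_snps = 20, n_genes = 10, seed = 2)
    cov <- simulateCovariates(cfg, sprintf("S%02d", 1:38))
    expect_equal(as.vector(table(cov$breed)), c(11, 27))
    expect_equal(nlevels(cov$batch), 5)
    expect_equal(sort(unique(as.character(cov$batch))), paste0("batch", 1:5))
    expect_true(all(cov$rin >= 5 & cov$rin <= 10))
})

test_that("founders-only pedigree yields an identity A-matrix", {
    cfg <- simulationConfig(n_snps = 20, n_genes = 10, seed = 3,
                            founders_only = TRUE)
    ped <- simulatePedigree(cfg)
    expect_true(all(ped$sire == "0" & ped$dam == "0"))
    A <- kinshipMatrix(ped, attr(ped, "samples"))
    expect_equal(unname(A), diag(38))
})

test_that("simulated pedigree spans the configured generations with shared parents", {
    cfg <- simulationConfig(n_snps = 20, n_genes = 10, seed = 4)
    ped <- simulatePedigree(cfg)
    samples <- attr(ped, "samples")
    expect_length(samples, 38)
    expect_true(all(samples %in% ped$animal))
    ## every study animal has known parents and a 4-deep ancestor chain
    rows <- ped[match(samples, ped$animal), ]
    expect_true(all(rows$sire != "0"))
    depth <- function(id) {
        d <- 0
        while (id != "0") {
            id <- ped$sire[match(id, ped$animal)]
            if (is.na(id)) break
            d <- d + 1
        }
        d
    }
    expect_true(all(vapply(samples, depth, numeric(1)) >= 4))
    ## full sibs exist among the study animals
    key <- paste(rows$sire, rows$dam)
    expect_true(any(duplicated(key)))
})

test_that("offspring dosages are always Mendelian-consistent with parents", {
    ## craft a pedigree whose observed samples include parents and children
    ped <- data.frame(
        animal = c("F1", "F2", "F3", "F4", paste0("C", 1:6)),
        sire = c("0", "0", "0", "0", rep(c("F1", "F3"), each = 3)),
        dam = c("0", "0", "0", "0", rep(c("F2", "F4"), each = 3)),
        stringsAsFactors = FALSE)
    attr(ped, "samples") <- ped$animal
    attr(ped, "animal_breed") <- stats::setNames(rep("Duroc", 10), ped$animal)
    cfg <- simulationConfig(n_snps = 120, n_genes = 5, seed = 11, n_cis_effects = 0, n_trans_effects = 0,
                            ld_block_size_mean = 4)
    gt <- simulateGenotypes(cfg, ped)
    d <- dosages(gt)
    alleleRange <- function(x) cbind(lo = as.numeric(x == 2),
                                     hi = as.numeric(x > 0))
    for (ch in paste0("C", 1:6)) {
        i <- match(ch, colnames(d))
        sire <- ped$sire[match(ch, ped$animal)]
        dam <- ped$dam[match(ch, ped$animal)]
        lo <- alleleRange(d[, sire])[, "lo"] + alleleRange(d[, dam])[, "lo"]
        hi <- alleleRange(d[, sire])[, "hi"] + alleleRange(d[, dam])[, "hi"]
        expect_true(all(d[, i] >= lo & d[, i] <= hi))
    }
})

test_that("LD blocks are near-copies and MAF targets are achievable", {
    cfg <- simulationConfig(n_samples_group1 = 150, n_samples_group2 = 350,
                            n_snps = 100, n_genes = 5, seed = 5, n_cis_effects = 0, n_trans_effects = 0,
                            ld_block_size_mean = 3, founders_only = TRUE)
    ped <- simulatePedigree(cfg)
    gt <- simulateGenotypes(cfg, ped)
    d <- dosages(gt)
    ba <- attr(gt, "block_assignments")
    ## within-block pairwise R^2 >= 0.9 by construction (founder-level
    ## flips only)
    for (bl in unique(ba$block)) {
        ii <- which(ba$block == bl)
        if (length(ii) < 2) next
        for (a in ii[-1])
            expect_gte(ldR2(d[ii[1], ], d[a, ]), 0.9)
    }
    ## founder frequencies are drawn so most SNPs clear the MAF threshold
    maf <- apply(d, 1, computeMaf)
    expect_gt(mean(maf >= 0.3), 0.8)
    expect_true(all(maf <= 0.5))
})

test_that("planted pair labels respect the 1 Mb cis rule", {
    cfg <- simulationConfig(n_snps = 150, n_genes = 60, seed = 6,
                            n_cis_effects = 6, n_trans_effects = 6)
    st <- simulateStudy(cfg)
    tp <- st$truth$planted_pairs
    expect_equal(nrow(tp), 12)
    smap <- snpMap(st$genotypes)
    gmap <- geneMapOf(st$counts)
    i <- match(tp$snp_id, smap$snp_id)
    j <- match(tp$gene_id, gmap$gene_id)
    lab <- classifyCisTrans(smap$chrom[i], smap$pos[i], gmap$chrom[j],
                            gmap$start[j], gmap$end[j], 1e6)
    expect_identical(tp$class, lab)
    expect_equal(sum(lab == "cis"), 6)
    expect_equal(sum(lab == "trans"), 6)
})

test_that("zero covariate effect sds produce zero coefficients", {
    cfg <- simulationConfig(n_snps = 20, n_genes = 15, seed = 9,
                            covariate_effect_sds = c(breed = 0, batch = 0,
                                                     rin = 0, age = 0),
                            n_cis_effects = 0, n_trans_effects = 0)
    st <- simulateStudy(cfg)
    ce <- st$truth$covariate_effects
    expect_true(all(ce$breed == 0) && all(ce$batch == 0) &&
                    all(ce$rin == 0) && all(ce$age == 0))
})

test_that("trans targets are drawn preferentially from the designated category", {
    hits <- vapply(1:10, function(s) {
        cfg <- simulationConfig(n_snps = 40, n_genes = 100, seed = 100 + s,
                                n_cis_effects = 0, n_trans_effects = 20,
                                target_category_fraction = 0.3,
                                target_category_bias = 3)
        st <- simulateStudy(cfg)
        mean(st$truth$planted_pairs$gene_id %in% st$truth$category_genes)
    }, numeric(1))
    ## expected fraction 3q/(1+2q) = 0.5625 at q = 0.3, allocated exactly
    expect_true(all(abs(hits - 0.5625) < 0.06))
})

test_that("sample mismatches are rejected naming the axis", {
    cfg <- simulationConfig(n_snps = 20, n_genes = 10, seed = 2)
    ped <- simulatePedigree(cfg)
    gt <- simulateGenotypes(cfg, ped)
    cov <- simulateCovariates(cfg, attr(ped, "samples"))
    cov2 <- cov[c(2:38, 1), ]
    expect_error(simulateExpression(cfg, gt, cov2, ped), "samples")
})

test_that("a written study round-trips through the plain-text formats", {
    cfg <- simulationConfig(n_snps = 30, n_genes = 12, seed = 13)
    st <- simulateStudy(cfg)
    dir <- withr::local_tempdir()
    paths <- writeSimulatedStudy(st, dir)
    gt2 <- readGenotypesTsv(paths["genotypes"])
    expect_equal(dosages(gt2), dosages(st$genotypes))
    expect_equal(snpMap(gt2), snpMap(st$genotypes))
    se2 <- readCountsTsv(paths["counts"])
    expect_equal(SummarizedExperiment::assay(se2, "counts"),
                 SummarizedExperiment::assay(st$counts, "counts"))
    ped2 <- readPedigreeCsv(paths["pedigree"])
    expect_equal(ped2$animal, st$pedigree$animal)
    cov2 <- readCovariatesTsv(paths["covariates"])
    expect_equal(cov2$sample_id, st$covariates$sample_id)
})
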