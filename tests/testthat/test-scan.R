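test_that("whitening inverts the covariance factor", {
    n <- 12
    x <- rnorm(n)
    ## the default 1e-8 relative ridge bounds the attainable exactness
    expect_equal(whiten(x, diag(n)), x, tolerance = 1e-7)
    expect_equal(whiten(x, 4 * diag(n)), x / 2, tolerance = 1e-7)
    expect_equal(whiten(x, diag(n), ridge_fraction = 0), x, tolerance = 1e-14)
    set.seed(2)
    M <- matrix(rnorm(n * n), n)
    K <- crossprod(M) + diag(n)
    L <- whiteningFactor(K)
    Linv <- forwardsolve(L, diag(n))
    expect_equal(Linv %*% K %*% t(Linv), diag(n), tolerance = 1e-6)
    ## whitened i.i.d.-K draws have near-identity covariance
    set.seed(3)
    Z <- matrix(rnorm(5000 * n), 5000, n) %*% chol(K)
    W <- t(Linv %*% t(Z))
    emp <- crossprod(W) / nrow(W)
    expect_lt(max(abs(emp - diag(n))), 0.1)
    expect_error(whiteningFactor(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("residualization projects out the design exactly", {
    set.seed(4)
    n <- 20
    C <- cbind(1, rnorm(n), rep(c(0, 1), each = n / 2))
    x <- rnorm(n)
    r <- residualize(x, C)
    expect_lt(max(abs(crossprod(C, r))), 1e-10)
    ## already-orthogonal input is unchanged
    expect_equal(residualize(r, C), r, tolerance = 1e-10)
    ## a design column is annihilated
    expect_equal(residualize(C[, 2], C), rep(0, n), tolerance = 1e-10)
    ## rank deficiency is an error
    expect_error(residualize(x, cbind(C, C[, 2])), "rank deficient")
})

test_that("linearTest reduces to the Pearson correlation t-test", {
    set.seed(5)
    n <- 30
    y <- rnorm(n)
    g <- sample(0:2, n, TRUE)
    res <- linearTest(y, g)
    ct <- stats::cor.test(y, g)
    expect_equal(res$statistic, unname(ct$statistic), tolerance = 1e-10)
    expect_equal(res$p, ct$p.value, tolerance = 1e-10)
    expect_equal(res$df, n - 2)
    ## perfect fit
    res2 <- linearTest(g + 0, g + 0)
    expect_lt(res2$p, 1e-20)
})

test_that("anovaTest handles class structure and reduces to t^2 for two classes", {
    ## equal class means -> F = 0, p = 1
    g <- rep(c(0, 1, 2), each = 4)
    y <- rep(c(1, -1), 6)   # each class mean 0
    res <- anovaTest(y, g)
    expect_equal(res$statistic, 0, tolerance = 1e-12)
    expect_equal(res$p, 1, tolerance = 1e-12)
    expect_equal(res$df_num, 2)
    ## two observed classes: F equals squared t of the dosage model
    set.seed(6)
    g2 <- rep(c(0, 2), each = 10)
    y2 <- rnorm(20) + 0.5 * g2
    a <- anovaTest(y2, g2)
    l <- linearTest(y2, g2)
    expect_equal(a$statistic, l$statistic^2, tolerance = 1e-8)
    expect_equal(a$p, l$p, tolerance = 1e-8)
    expect_equal(a$df_num, 1)
    ## single class is untestable with a reason
    u <- anovaTest(rnorm(10), rep(1, 10))
    expect_true(is.na(u$p))
    expect_match(u$reason, "class")
})

test_that("batched scan equals per-pair GLS fits", {
    for (seed in 1:3) {
        fx <- randomScanFixture(seed)
        sc <- runScan(fx$Y, fx$gmap, fx$gt, fx$C, fx$K)
        rec <- scanRecords(sc)
        for (i in c(1, 3)) for (j in c(2, 11, 20)) {
            y <- fx$Y[i, ]; g <- fx$G[j, ]
            rl <- rec[rec$model == "linear" &
                          rec$gene_id == rownames(fx$Y)[i] &
                          rec$snp_id == rownames(fx$G)[j], ]
            o <- glsLinearOracle(y, g, fx$C, fx$K)
            expect_equal(rl$statistic, o$t, tolerance = 1e-8)
            expect_equal(rl$p, o$p, tolerance = 1e-8)
            expect_equal(rl$effect, o$slope, tolerance = 1e-8)
            ra <- rec[rec$model == "anova" &
                          rec$gene_id == rownames(fx$Y)[i] &
                          rec$snp_id == rownames(fx$G)[j], ]
            oa <- glsAnovaOracle(y, g, fx$C, fx$K)
            expect_equal(ra$statistic, oa$F, tolerance = 1e-8)
            expect_equal(ra$p, oa$p, tolerance = 1e-8)
        }
    }
})

test_that("cis/trans classification is boundary-inclusive on the gene interval", {
    expect_equal(classifyCisTrans("1", 1e6 + 1 - 1e6, "1", 1e6 + 1, 2e6), "cis")
    g_start <- 5e6
    expect_equal(classifyCisTrans("1", g_start - 1e6, "1", g_start, g_start + 1e4), "cis")
    expect_equal(classifyCisTrans("1", g_start - 1e6 - 1, "1", g_start, g_start + 1e4), "trans")
    expect_equal(classifyCisTrans("1", g_start + 1e4 + 1e6, "1", g_start, g_start + 1e4), "cis")
    expect_equal(classifyCisTrans("2", g_start, "1", g_start, g_start + 1e4), "trans")
})

test_that("BH adjustment matches the hand step-up", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
    expect_equal(bhFdr(0.007), 0.007)
    set.seed(7)
    p <- runif(200)^2
    expect_equal(bhFdr(p), refBh(p), tolerance = 1e-12)
})

test_that("scan records are complete, partitioned, and FDR-consistent", {
    fx <- randomScanFixture(9, ngenes = 4, nsnps = 10)
    sc <- runScan(fx$Y, fx$gmap, fx$gt, fx$C, fx$K)
    rec <- scanRecords(sc)
    expect_equal(nrow(rec), 4 * 10 * 2)
    expect_equal(scanSummary(sc)$n_pairs_per_model, 40)
    for (m in c("linear", "anova")) for (cl in c("cis", "trans")) {
        r <- rec[rec$model == m & rec$class == cl, ]
        if (!nrow(r)) next
        expect_equal(r$fdr, bhFdr(r$p))
        expect_true(all(r$fdr >= r$p, na.rm = TRUE))
    }
})

test_that("results are identical across chunkings and common permutations", {
    fx <- randomScanFixture(10, ngenes = 7, nsnps = 9)
    sc1 <- runScan(fx$Y, fx$gmap, fx$gt, fx$C, fx$K,
                   scanConfig(chunk_size = 2))
    sc2 <- runScan(fx$Y, fx$gmap, fx$gt, fx$C, fx$K,
                   scanConfig(chunk_size = 1000))
    ## equal to floating-point rounding: chunk shape changes the BLAS
    ## call sequence, so the last bits may differ
    expect_equal(scanRecords(sc1), scanRecords(sc2), tolerance = 1e-10)
    expect_identical(scanRecords(sc1)[c("snp_id", "gene_id", "model",
                                        "class", "df1", "df2", "reason")],
                     scanRecords(sc2)[c("snp_id", "gene_id", "model",
                                        "class", "df1", "df2", "reason")])
    ## permute samples everywhere simultaneously
    set.seed(11)
    pi <- sample(ncol(fx$Y))
    gt_p <- GenotypeMatrix(fx$G[, pi], chrom = snpMap(fx$gt)$chrom,
                           pos = snpMap(fx$gt)$pos)
    sc3 <- runScan(fx$Y[, pi], fx$gmap, gt_p, fx$C[pi, ],
                   fx$K[pi, pi], scanConfig(chunk_size = 2))
    expect_equal(scanRecords(sc3)$statistic, scanRecords(sc1)$statistic,
                 tolerance = 1e-9)
})

test_that("degenerate pairs are reported untestable, never dropped", {
    fx <- randomScanFixture(12, ngenes = 3, nsnps = 4)
    ## make one SNP collinear with the breed column and one gene constant
    G <- fx$G
    G[2, ] <- 2 * as.numeric(fx$cov$breed == "L")
    gt <- GenotypeMatrix(G, chrom = snpMap(fx$gt)$chrom,
                         pos = snpMap(fx$gt)$pos)
    Y <- fx$Y
    Y[3, ] <- 5
    sc <- runScan(Y, fx$gmap, gt, fx$C, fx$K)
    rec <- scanRecords(sc)
    expect_equal(nrow(rec), 3 * 4 * 2)
    bad <- rec[rec$snp_id == rownames(G)[2] & rec$model == "linear", ]
    expect_true(all(is.na(bad$p)))
    expect_true(all(bad$reason == "degenerate pair"))
    badg <- rec[rec$gene_id == rownames(Y)[3], ]
    expect_true(all(is.na(badg$p)))
})

test_that("null scan p-values are uniform", {
    set.seed(13)
    n <- 38
    fx <- randomScanFixture(14, n = n, ngenes = 40, nsnps = 60)
    sc <- runScan(fx$Y, fx$gmap, fx$gt, fx$C, K = NULL)
    rec <- scanRecords(sc)
    for (m in c("linear", "anova")) {
        p <- rec$p[rec$model == m & !is.na(rec$p)]
        expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
    }
})

test_that("sample misalignment is rejected naming the first mismatch", {
    fx <- randomScanFixture(15, ngenes = 2, nsnps = 3)
    Y <- fx$Y
    colnames(Y)[5] <- "WRONG"
    expect_error(runScan(Y, fx$gmap, fx$gt, fx$C, fx$K), "WRONG")
})

test_that("orthonormalized coordinates reproduce the scan's partial correlation", {
    fx <- randomScanFixture(16, ngenes = 2, nsnps = 3)
    y <- fx$Y[1, ]; g <- fx$G[2, ]
    vz <- orthonormalizeForViz(y, g, fx$C, fx$K)
    expect_equal(sum(vz$y^2), 1, tolerance = 1e-12)
    expect_equal(sum(vz$g^2), 1, tolerance = 1e-12)
    lt <- linearTest(y, g, fx$C, fx$K)
    r_back <- sign(lt$statistic) *
        sqrt(lt$statistic^2 / (lt$statistic^2 + lt$df))
    expect_equal(vz$r, r_back, tolerance = 1e-10)
    ## with intercept-only design and identity kinship it is Pearson r
    vz0 <- orthonormalizeForViz(y, g)
    expect_equal(vz0$r, stats::cor(y, g), tolerance = 1e-10)
})
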