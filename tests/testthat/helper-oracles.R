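## Independent reference implementations used as oracles. These share no
## code with the package paths they check.

options(feqtl.verbose = FALSE)

## Step-by-step TMM recipe: upper-quartile reference selection, M/A
## values on library-scaled counts, double trimming (30% on M, 5% on A),
## precision-weighted mean of surviving M-values, geometric-mean centring.
refTmm <- function(m, trimM = 0.3, trimA = 0.05) {
    lib <- colSums(m)
    f75 <- apply(m, 2, stats::quantile, probs = 0.75) / lib
    ref <- which.min(abs(f75 - mean(f75)))
    one <- function(j) {
        obs <- m[, j]; nO <- lib[j]
        rv <- m[, ref]; nR <- lib[ref]
        M <- log2((obs / nO) / (rv / nR))
        A <- (log2(obs / nO) + log2(rv / nR)) / 2
        v <- (nO - obs) / (nO * obs) + (nR - rv) / (nR * rv)
        fin <- is.finite(M) & is.finite(A)
        M <- M[fin]; A <- A[fin]; v <- v[fin]
        if (max(abs(M)) < 1e-6) return(1)
        n <- length(M)
        loL <- floor(n * trimM) + 1; hiL <- n + 1 - loL
        loS <- floor(n * trimA) + 1; hiS <- n + 1 - loS
        keep <- rank(M) >= loL & rank(M) <= hiL &
            rank(A) >= loS & rank(A) <= hiS
        2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
    }
    f <- vapply(seq_len(ncol(m)), one, numeric(1))
    f / exp(mean(log(f)))
}

## Hand-rolled BH step-up.
refBh <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(n)
    out[o] <- q
    out
}

## Two-sided Fisher p by exhaustive enumeration over the hypergeometric
## support of a 2x2 table with fixed margins.
refFisher2x2 <- function(tab) {
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
    m1 <- a + b; m2 <- cc + d; k <- a + cc; N <- m1 + m2
    support <- max(0, k - m2):min(m1, k)
    pr <- stats::dhyper(support, m1, m2, k)
    sum(pr[pr <= stats::dhyper(a, m1, m2, k) * (1 + 1e-7)])
}

## Monte-Carlo gene dropping: estimate the additive relationship between
## two animals as twice the kinship coefficient (probability a random
## allele from each is identical by descent).
refGeneDrop <- function(ped, id1, id2, ndrop = 2e4, seed = 1) {
    set.seed(seed)
    idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
    s <- ifelse(ped$sire == "0", 0L, idx[ped$sire])
    d <- ifelse(ped$dam == "0", 0L, idx[ped$dam])
    n <- nrow(ped)
    acc <- numeric(ndrop)
    for (r in seq_len(ndrop)) {
        a1 <- integer(n); a2 <- integer(n)
        cnt <- 0L
        for (i in seq_len(n)) {
            if (s[i] == 0L) {
                a1[i] <- cnt + 1L; a2[i] <- cnt + 2L; cnt <- cnt + 2L
            } else {
                a1[i] <- if (stats::runif(1) < 0.5) a1[s[i]] else a2[s[i]]
                a2[i] <- if (stats::runif(1) < 0.5) a1[d[i]] else a2[d[i]]
            }
        }
        i <- idx[[id1]]; j <- idx[[id2]]
        acc[r] <- mean(c(a1[i] == a1[j], a1[i] == a2[j],
                         a2[i] == a1[j], a2[i] == a2[j]))
    }
    list(a = 2 * mean(acc), mc_sd = 2 * stats::sd(acc) / sqrt(ndrop))
}

## Per-pair generalized least squares fits via lm() on whitened data.
glsLinearOracle <- function(y, g, C, K = NULL) {
    n <- length(y)
    L <- if (is.null(K)) diag(n) else t(chol(K + diag(1e-8 * mean(diag(K)), n)))
    yw <- forwardsolve(L, y); gw <- forwardsolve(L, g)
    Cw <- forwardsolve(L, C)
    fit <- stats::lm(yw ~ 0 + Cw + gw)
    cf <- summary(fit)$coefficients
    list(t = cf["gw", "t value"], p = cf["gw", "Pr(>|t|)"],
         slope = cf["gw", "Estimate"])
}

glsAnovaOracle <- function(y, g, C, K = NULL) {
    n <- length(y)
    L <- if (is.null(K)) diag(n) else t(chol(K + diag(1e-8 * mean(diag(K)), n)))
    yw <- forwardsolve(L, y)
    Cw <- forwardsolve(L, C)
    Gi <- stats::model.matrix(~ 0 + factor(g))
    Giw <- forwardsolve(L, Gi)
    f0 <- stats::lm(yw ~ 0 + Cw)
    f1 <- stats::lm(yw ~ 0 + Cw + Giw)
    av <- stats::anova(f0, f1)
    list(F = av$F[2], p = av$`Pr(>F)`[2])
}

## A random small scan instance: full covariate design, random SPD
## kinship, gaussian expression, random dosages.
randomScanFixture <- function(seed, n = 38, ngenes = 5, nsnps = 20) {
    set.seed(seed)
    ids <- sprintf("S%02d", seq_len(n))
    M <- matrix(stats::rnorm(n * n), n)
    K <- crossprod(M) / n + diag(n) * 0.5
    dimnames(K) <- list(ids, ids)
    cov <- data.frame(sample_id = ids,
                      breed = factor(rep(c("D", "L"), c(11, n - 11))),
                      batch = factor(sample(rep_len(paste0("b", 1:5), n))),
                      rin = stats::rnorm(n, 8, 0.5),
                      age_days = round(stats::rnorm(n, 170, 10)))
    C <- studyDesign(cov)
    Y <- matrix(stats::rnorm(ngenes * n), ngenes, n,
                dimnames = list(sprintf("g%03d", seq_len(ngenes)), ids))
    G <- matrix(sample(0:2, nsnps * n, TRUE), nsnps, n,
                dimnames = list(sprintf("s%03d", seq_len(nsnps)), ids))
    gt <- GenotypeMatrix(G, chrom = rep("1", nsnps),
                         pos = seq(1000L, by = 1000000L, length.out = nsnps))
    ## genes alternate between the SNP chromosome (cis pairs arise) and
    ## another one (trans)
    gmap <- data.frame(gene_id = rownames(Y),
                       chrom = rep_len(c("1", "2"), ngenes),
                       start = seq(1L, by = 2000000L, length.out = ngenes),
                       end = seq(1L, by = 2000000L, length.out = ngenes) + 1000L,
                       stringsAsFactors = FALSE)
    list(Y = Y, G = dosages(gt), gt = gt, C = C, K = K, cov = cov,
         gmap = gmap)
}

## Gene coordinate table of a SummarizedExperiment, in row order.
geneMapOf <- function(se) {
    rr <- SummarizedExperiment::rowRanges(se)
    data.frame(gene_id = rownames(se),
               chrom = as.character(GenomicRanges::seqnames(rr)),
               start = GenomicRanges::start(rr),
               end = GenomicRanges::end(rr), stringsAsFactors = FALSE)
}

## Simulate, prepare and scan in one go (shared by several suites).
scanSimulatedStudy <- function(cfg, models = c("linear", "anova"),
                               use_kinship = TRUE) {
    st <- simulateStudy(cfg)
    K <- if (use_kinship)
        kinshipMatrix(st$pedigree, attr(st$pedigree, "samples"))
    else NULL
    pe <- prepareExpression(st$counts)
    sc <- runScan(pe$expr, geneMapOf(pe$se), recodeToMinor(st$genotypes),
                  studyDesign(st$covariates), K, scanConfig(models = models))
    list(study = st, prep = pe, scan = sc, K = K)
}
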