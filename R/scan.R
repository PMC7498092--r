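#' Scan configuration
#'
#' @param cis_distance cis window in bp around the gene interval, default
#'   1e6
#' @param models character subset of \code{c("linear", "anova")}
#' @param ridge_fraction relative ridge added to the kinship matrix before
#'   Cholesky factorization (times the mean diagonal)
#' @param alpha_report p-value cutoff used in scan summaries, default 0.01
#' @param chunk_size genes per processing chunk (performance knob; results
#'   are identical across chunkings)
#' @return list of class \code{"ScanConfig"}
#' @export
scanConfig <- function(cis_distance = 1e6, models = c("linear", "anova"),
                       ridge_fraction = 1e-8, alpha_report = 0.01,
                       chunk_size = 2000L) {
    stopifnot(cis_distance > 0, length(models) >= 1,
              all(models %in% c("linear", "anova")), chunk_size >= 1)
    structure(list(cis_distance = cis_distance, models = models,
                   ridge_fraction = ridge_fraction,
                   alpha_report = alpha_report,
                   chunk_size = as.integer(chunk_size)),
              class = "ScanConfig")
}

#' Expand covariates to a full-rank design matrix
#'
#' Intercept, breed and batch as treatment-coded factors, RIN and age as
#' numeric covariates. Any column subset may be absent from the input; the
#' intercept is always included.
#'
#' @param covariates data.frame with any of breed, batch, rin, age_days
#' @return numeric design matrix (samples x k), full column rank
#' @export
studyDesign <- function(covariates) {
    terms <- intersect(c("breed", "batch", "rin", "age_days"),
                       names(covariates))
    fml <- if (length(terms))
        stats::as.formula(paste("~", paste(terms, collapse = " + ")))
    else ~ 1
    C <- stats::model.matrix(fml, data = covariates)
    qrC <- qr(C)
    if (qrC$rank < ncol(C))
        stop("design matrix is rank deficient; collinear column(s): ",
             paste(colnames(C)[qrC$pivot[seq(qrC$rank + 1, ncol(C))]],
                   collapse = ", "))
    rownames(C) <- if (!is.null(covariates$sample_id)) covariates$sample_id
                   else rownames(covariates)
    C
}

#' Whitening by the inverse Cholesky factor of a covariance matrix
#'
#' Returns L^{-1} x where L L' = K (lower-triangular). A small ridge
#' (\code{ridge_fraction} times the mean diagonal) keeps the factorization
#' defined for a positive semidefinite K.
#'
#' @param x numeric vector (length n) or matrix (n x p), sample dimension
#'   first
#' @param K n x n symmetric positive (semi)definite matrix
#' @param ridge_fraction relative ridge, default 1e-8
#' @return transformed vector/matrix
#' @export
whiten <- function(x, K, ridge_fraction = 1e-8) {
    L <- whiteningFactor(K, ridge_fraction)
    v <- is.null(dim(x))
    out <- forwardsolve(L, if (v) cbind(x) else x)
    if (v) drop(out) else out
}

#' Lower Cholesky factor of K plus ridge
#'
#' @inheritParams whiten
#' @return lower-triangular L with L L' = K + ridge I
#' @export
whiteningFactor <- function(K, ridge_fraction = 1e-8) {
    stopifnot(is.matrix(K), nrow(K) == ncol(K))
    if (max(abs(K - t(K))) > 1e-8 * mean(diag(K)))
        stop("kinship matrix is not symmetric")
    Kr <- K + diag(ridge_fraction * mean(diag(K)), nrow(K))
    L <- tryCatch(t(chol(Kr)), error = function(e) {
        ev <- min(eigen(Kr, symmetric = TRUE, only.values = TRUE)$values)
        stop(sprintf(
            "kinship matrix not positive definite after ridge (smallest eigenvalue %.3g)",
            ev))
    })
    L
}

#' Residualize a vector against a design matrix
#'
#' x - C (C'C)^{-1} C' x, computed through the QR decomposition of C.
#'
#' @param x numeric vector (or n x p matrix, sample dimension first)
#' @param C full-column-rank design matrix
#' @return residual, orthogonal to every column of C
#' @export
residualize <- function(x, C) {
    qrC <- qr(C)
    if (qrC$rank < ncol(C))
        stop("design matrix is rank deficient; collinear column(s): ",
             paste(colnames(C)[qrC$pivot[seq(qrC$rank + 1, ncol(C))]],
                   collapse = ", "))
    qr.resid(qrC, x)
}

#' Classify SNP-gene pairs as cis or trans
#'
#' cis iff the SNP is on the gene's chromosome and its position falls in
#' [start - cis_distance, end + cis_distance] (1-based, inclusive).
#'
#' @param snp_chrom,snp_pos SNP coordinates (vectors recycle)
#' @param gene_chrom,gene_start,gene_end gene interval
#' @param cis_distance window in bp, default 1e6
#' @return character vector, "cis" or "trans"
#' @export
classifyCisTrans <- function(snp_chrom, snp_pos, gene_chrom, gene_start,
                             gene_end, cis_distance = 1e6) {
    ifelse(snp_chrom == gene_chrom &
               snp_pos >= gene_start - cis_distance &
               snp_pos <= gene_end + cis_distance, "cis", "trans")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (\code{stats::p.adjust}, method "BH").
#'
#' @param pvals numeric vector of p-values (NA allowed)
#' @return adjusted values in input order
#' @export
bhFdr <- function(pvals) stats::p.adjust(pvals, method = "BH")

## Whitened, covariate-residualized, row-unit-normalised version of a
## variables-by-samples matrix. Returns list(R = unit rows, norm = residual
## row norms, ok = rows with usable residual variation).
.preparePredictors <- function(X, Q, Linv, tol = 1e-10) {
    Xw <- X %*% t(Linv)
    E <- Xw - (Xw %*% Q) %*% t(Q)
    nrm <- sqrt(rowSums(E^2))
    scale <- sqrt(rowSums(Xw^2))
    ok <- nrm > tol * pmax(scale, 1)
    R <- E / ifelse(ok, nrm, 1)
    list(R = R, norm = nrm, ok = ok)
}

## Internal batched scan on prepared matrices.
## Y: genes x n (expression), G: snps x n (dosage), C: n x k, Linv: n x n.
## Returns list(linear = list(stat, p, effect, ok), anova = ...) as requested.
.scanCore <- function(Y, G, C, Linv, models) {
    n <- ncol(Y); k <- ncol(C)
    Cw <- Linv %*% C
    qrC <- qr(Cw)
    if (qrC$rank < k)
        stop("design matrix is rank deficient after whitening; collinear ",
             "column(s): ",
             paste(colnames(C)[qrC$pivot[seq(qrC$rank + 1, k)]], collapse = ", "))
    Q <- qr.Q(qrC)
    py <- .preparePredictors(Y, Q, Linv)
    out <- list()
    if ("linear" %in% models) {
        pg <- .preparePredictors(G, Q, Linv)
        df <- n - k - 1
        r <- py$R %*% t(pg$R)
        r <- pmin(pmax(r, -1), 1)
        tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
        p <- 2 * stats::pt(-abs(tt), df)
        effect <- r * outer(py$norm, ifelse(pg$ok, pg$norm, 1), "/")
        ok <- outer(py$ok, pg$ok, "&")
        p[!ok] <- NA_real_; tt[!ok] <- NA_real_; effect[!ok] <- NA_real_
        out$linear <- list(stat = tt, p = p, effect = effect, ok = ok,
                           df1 = matrix(1, nrow(Y), nrow(G)), df2 = df)
    }
    if ("anova" %in% models) {
        nsnp <- nrow(G); ngene <- nrow(Y)
        Fm <- matrix(NA_real_, ngene, nsnp)
        pm <- matrix(NA_real_, ngene, nsnp)
        d1 <- matrix(NA_real_, ngene, nsnp)
        for (s in seq_len(nsnp)) {
            g <- G[s, ]
            classes <- sort(unique(g))
            if (length(classes) < 2L) next
            Gi <- t(vapply(classes[-1L], function(cl) as.numeric(g == cl),
                           numeric(n)))
            pgi <- .preparePredictors(Gi, Q, Linv)
            Ri <- pgi$R[pgi$ok, , drop = FALSE]
            if (!nrow(Ri)) next
            qrG <- qr(t(Ri))
            q <- qrG$rank
            if (q < 1L) next
            Qg <- qr.Q(qrG)[, seq_len(q), drop = FALSE]
            S <- py$R %*% Qg
            expl <- pmin(rowSums(S^2), 1)
            dfden <- n - k - q
            if (dfden <= 0) next
            Fv <- (expl / q) / pmax((1 - expl) / dfden, .Machine$double.eps)
            Fv[!py$ok] <- NA_real_
            Fm[, s] <- Fv
            pm[, s] <- stats::pf(Fv, q, dfden, lower.tail = FALSE)
            d1[, s] <- q
        }
        out$anova <- list(stat = Fm, p = pm, effect = matrix(NA_real_, ngene, nsnp),
                          ok = !is.na(pm), df1 = d1, df2 = n - k)
    }
    out
}

#' Linear-dosage association test for one gene-SNP pair
#'
#' Generalized least squares slope t-test: expression and dosage are
#' whitened by the inverse Cholesky factor of K, residualized against the
#' covariate design, and the partial correlation converted to a
#' t-statistic on n - k - 1 degrees of freedom.
#'
#' @param y expression vector
#' @param g dosage vector
#' @param C design matrix (samples x k) including the intercept
#' @param K error covariance (kinship) matrix; NULL for identity
#' @return list(statistic, df, effect, p); untestable pairs (dosage
#'   explained by the covariates) return NA with a \code{reason}
#' @export
linearTest <- function(y, g, C = matrix(1, length(y), 1), K = NULL) {
    Linv <- .linvOf(K, length(y))
    r <- .scanCore(rbind(y), rbind(g), C, Linv, "linear")$linear
    if (!r$ok[1, 1])
        return(list(statistic = NA_real_, df = r$df2, effect = NA_real_,
                    p = NA_real_, reason = "degenerate predictor"))
    list(statistic = r$stat[1, 1], df = r$df2, effect = r$effect[1, 1],
         p = r$p[1, 1], reason = NA_character_)
}

#' Genotype-factor ANOVA test for one gene-SNP pair
#'
#' Nested-model F-test of per-genotype-class means (indicator columns for
#' the observed classes minus one) against the covariate-only model, on
#' whitened data.
#'
#' @inheritParams linearTest
#' @return list(statistic, df_num, df_den, p, reason)
#' @export
anovaTest <- function(y, g, C = matrix(1, length(y), 1), K = NULL) {
    Linv <- .linvOf(K, length(y))
    r <- .scanCore(rbind(y), rbind(g), C, Linv, "anova")$anova
    if (!isTRUE(r$ok[1, 1]))
        return(list(statistic = NA_real_, df_num = NA_real_,
                    df_den = NA_real_, p = NA_real_,
                    reason = "fewer than two usable genotype classes"))
    q <- r$df1[1, 1]
    list(statistic = r$stat[1, 1], df_num = q, df_den = r$df2 - q,
         p = r$p[1, 1], reason = NA_character_)
}

.linvOf <- function(K, n, ridge_fraction = 1e-8) {
    if (is.null(K)) diag(n)
    else forwardsolve(whiteningFactor(K, ridge_fraction), diag(n))
}

#' All-pairs cis/trans eQTL scan
#'
#' Tests every gene-SNP pair under the requested models with covariate
#' adjustment and kinship error covariance, classifies pairs cis/trans at
#' the configured distance, and applies Benjamini-Hochberg FDR separately
#' within each (model x cis/trans) partition. Whitening and covariate
#' residualization are computed once and reused across pairs; genes are
#' processed in chunks, with results independent of the chunking up to
#' floating-point rounding (the chunk shape changes the BLAS call
#' sequence, so the last bits of a statistic may differ).
#'
#' @param expr genes-by-samples normalized expression matrix
#' @param gene_map data.frame (gene_id, chrom, start, end) or NULL if
#'   \code{expr} rownames match \code{gene_ranges}
#' @param gt a \linkS4class{GenotypeMatrix}
#' @param design design matrix from \code{\link{studyDesign}} (rownames =
#'   sample ids)
#' @param K kinship error covariance over the same samples; NULL for
#'   identity
#' @param config a \code{\link{scanConfig}}
#' @return an \linkS4class{EqtlScan}
#' @export
runScan <- function(expr, gene_map, gt, design, K = NULL,
                    config = scanConfig()) {
    G <- dosages(gt)
    samples <- colnames(expr)
    mism <- which(samples != colnames(G))
    if (length(mism))
        stop("sample misalignment between expression and genotypes, first ",
             "mismatched id: '", samples[mism[1]], "'")
    if (!is.null(rownames(design))) {
        mism <- which(samples != rownames(design))
        if (length(mism))
            stop("sample misalignment between expression and design, first ",
                 "mismatched id: '", samples[mism[1]], "'")
    }
    if (!is.null(K)) {
        stopifnot(nrow(K) == length(samples))
        if (!is.null(rownames(K)) && any(rownames(K) != samples))
            stop("sample misalignment between expression and kinship, first ",
                 "mismatched id: '",
                 samples[which(rownames(K) != samples)[1]], "'")
    }
    stopifnot(identical(rownames(expr), gene_map$gene_id))
    smap <- snpMap(gt)
    n <- length(samples)
    Linv <- .linvOf(K, n, config$ridge_fraction)

    cls <- outer(seq_len(nrow(expr)), seq_len(nrow(smap)),
                 function(i, j) classifyCisTrans(
                     smap$chrom[j], smap$pos[j], gene_map$chrom[i],
                     gene_map$start[i], gene_map$end[i], config$cis_distance))

    chunks <- split(seq_len(nrow(expr)),
                    ceiling(seq_len(nrow(expr)) / config$chunk_size))
    recs <- list()
    for (model in config$models) {
        parts <- lapply(chunks, function(ii) {
            res <- .scanCore(expr[ii, , drop = FALSE], G, design, Linv,
                             model)[[model]]
            data.frame(
                snp_id = rep(smap$snp_id, each = length(ii)),
                gene_id = rep(gene_map$gene_id[ii], times = nrow(smap)),
                model = model,
                class = as.vector(cls[ii, , drop = FALSE]),
                statistic = as.vector(res$stat),
                df1 = as.vector(res$df1),
                df2 = res$df2 - if (model == "anova")
                    ifelse(is.na(as.vector(res$df1)), 0, as.vector(res$df1))
                    else 0,
                effect = as.vector(res$effect),
                p = as.vector(res$p),
                reason = ifelse(as.vector(res$ok), NA_character_,
                                "degenerate pair"),
                stringsAsFactors = FALSE)
        })
        rm <- do.call(rbind, parts)
        ## canonical row order (gene-major, then SNP) so results are
        ## bitwise identical across chunkings
        rm <- rm[order(match(rm$gene_id, gene_map$gene_id),
                       match(rm$snp_id, smap$snp_id)), ]
        rownames(rm) <- NULL
        recs[[model]] <- rm
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    ## BH within each model x class partition
    records$fdr <- NA_real_
    for (m in config$models) for (cl in c("cis", "trans")) {
        sel <- records$model == m & records$class == cl
        if (any(sel)) records$fdr[sel] <- bhFdr(records$p[sel])
    }
    part <- interaction(records$model, records$class, sep = " ")
    partitions <- do.call(rbind, lapply(levels(part), function(lv) {
        r <- records[part == lv, ]
        data.frame(partition = lv, n_tests = nrow(r),
                   n_untestable = sum(!is.na(r$reason)),
                   n_low_p = sum(r$p < config$alpha_report, na.rm = TRUE))
    }))
    new("EqtlScan", records = records,
        summary = list(n_genes = nrow(expr), n_snps = nrow(smap),
                       n_pairs_per_model = as.numeric(nrow(expr)) * nrow(smap),
                       models = config$models, partitions = partitions),
        config = unclass(config))
}

#' Orthonormalized visualization coordinates for one pair
#'
#' Expression and genotype are centered and scaled, whitened, residualized
#' against the covariate design and normalized to unit length — the scale
#' on which the scan's partial correlation lives, so a scatter plot of the
#' two returned vectors displays exactly the tested association;
#' \code{dot(y, g)} equals the scan's partial correlation.
#'
#' @inheritParams linearTest
#' @return list(y, g, r): unit-norm numeric vectors and their inner
#'   product
#' @export
orthonormalizeForViz <- function(y, g, C = matrix(1, length(y), 1), K = NULL) {
    Linv <- .linvOf(K, length(y))
    prep <- function(x) {
        x <- (x - mean(x)) / stats::sd(x)
        e <- residualize(drop(Linv %*% x), Linv %*% C)
        e / sqrt(sum(e^2))
    }
    ys <- prep(y); gs <- prep(g)
    list(y = ys, g = gs, r = sum(ys * gs))
}

#' Scan size contract
#'
#' Number of gene-SNP pairs tested per model for declared dimensions.
#'
#' @param n_genes,n_snps declared dimensions
#' @return numeric pair count (n_genes x n_snps)
#' @export
scanPairCount <- function(n_genes, n_snps) as.numeric(n_genes) * as.numeric(n_snps)
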