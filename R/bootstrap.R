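#' Permutation ("bootstrapping") configuration
#'
#' @param n_iterations number of genotype-shuffling iterations, default
#'   1000
#' @param alpha_low p-value cutoff counted per iteration, default 0.01
#' @param order_ranks ranks of the smallest p-values saved per iteration,
#'   default c(1, 10, 100)
#' @param seed integer seed; iteration i uses seed + i
#' @return list of class \code{"BootstrapConfig"}
#' @export
bootstrapConfig <- function(n_iterations = 1000, alpha_low = 0.01,
                            order_ranks = c(1, 10, 100), seed = 1L) {
    stopifnot(n_iterations >= 1, alpha_low > 0, alpha_low < 1,
              all(order_ranks >= 1), !is.unsorted(order_ranks))
    structure(list(n_iterations = as.integer(n_iterations),
                   alpha_low = alpha_low,
                   order_ranks = as.integer(order_ranks),
                   seed = as.integer(seed)),
              class = "BootstrapConfig")
}

#' Shuffle each SNP's genotypes across samples
#'
#' Every SNP's dosage vector is permuted independently; the per-SNP dosage
#' multiset (and hence MAF) is preserved while any association with
#' expression, covariates or kinship is destroyed.
#'
#' @param gt a \linkS4class{GenotypeMatrix}
#' @param seed integer seed
#' @return a \linkS4class{GenotypeMatrix} of the same shape
#' @export
permuteGenotypes <- function(gt, seed) {
    d <- dosages(gt)
    withSeed(seed, {
        for (i in seq_len(nrow(d)))
            d[i, ] <- d[i, sample.int(ncol(d))]
    })
    m <- snpMap(gt)
    out <- GenotypeMatrix(d, chrom = m$chrom, pos = m$pos)
    stopifnot(identical(rownames(out), rownames(gt)))
    out
}

## Low-p counts and order statistics per (model x class) partition from a
## scan record table.
.partitionStats <- function(records, alpha, ranks) {
    parts <- c("linear cis", "linear trans", "anova cis", "anova trans")
    key <- paste(records$model, records$class)
    counts <- numeric(length(parts)); names(counts) <- parts
    os <- matrix(NA_real_, length(parts), length(ranks),
                 dimnames = list(parts, paste0("rank", ranks)))
    for (pt in parts) {
        p <- records$p[key == pt]
        p <- p[!is.na(p)]
        counts[pt] <- sum(p < alpha)
        sp <- sort(p)
        os[pt, ] <- ifelse(ranks <= length(sp), sp[pmin(ranks, length(sp))],
                           NA_real_)
    }
    list(counts = counts, order_stats = os)
}

#' Upper-tail normal probability of an observed count
#'
#' z = (observed - mean(null)) / sd(null); returns P(Z > z) under the
#' standard normal. Values below 2.2e-16 are reported as such by
#' \code{format()}-level printing but returned exactly.
#'
#' @param observed observed count
#' @param null_counts vector of permutation-null counts (length >= 2)
#' @return upper-tail probability
#' @export
normalTailProb <- function(observed, null_counts) {
    stopifnot(length(null_counts) >= 2)
    s <- stats::sd(null_counts)
    if (s == 0) stop("degenerate null: permutation counts have zero sd")
    stats::pnorm((observed - mean(null_counts)) / s, lower.tail = FALSE)
}

#' Empirical exceedance probability of a k-th smallest p-value
#'
#' Fraction of permutation iterations whose k-th smallest p-value is
#' strictly lower than the observed one.
#'
#' @param observed_kth observed k-th smallest p-value
#' @param null_kths per-iteration k-th smallest p-values
#' @return probability in [0, 1]
#' @export
orderStatExceedance <- function(observed_kth, null_kths) {
    stopifnot(length(null_kths) >= 1)
    mean(null_kths < observed_kth, na.rm = TRUE)
}

#' Genotype-permutation null for the all-pairs scan
#'
#' Repeats the full scan on per-SNP-shuffled genotypes, recording per
#' iteration the number of p-values below \code{alpha_low} and the
#' requested order statistics, per (model x cis/trans) partition, and
#' summarises the observed data against that null: a normal-approximation
#' upper-tail probability for the low-p count and empirical exceedance
#' probabilities for each saved rank.
#'
#' @inheritParams runScan
#' @param scan_cfg a \code{\link{scanConfig}}
#' @param boot_cfg a \code{\link{bootstrapConfig}}
#' @param observed optionally, a precomputed \linkS4class{EqtlScan} of the
#'   unpermuted data (saves one scan)
#' @return list of class \code{"BootstrapSummary"}: \code{null_counts}
#'   (iterations x partitions), \code{null_order_stats} (iterations x
#'   partitions x ranks), \code{observed_counts},
#'   \code{observed_order_stats}, \code{z}, \code{normal_tail_p},
#'   \code{exceedance} (partitions x ranks), \code{config}
#' @export
bootstrapNull <- function(expr, gene_map, gt, design, K = NULL,
                          scan_cfg = scanConfig(),
                          boot_cfg = bootstrapConfig(), observed = NULL) {
    alpha <- boot_cfg$alpha_low; ranks <- boot_cfg$order_ranks
    if (is.null(observed))
        observed <- runScan(expr, gene_map, gt, design, K, scan_cfg)
    obs <- .partitionStats(scanRecords(observed), alpha, ranks)
    parts <- names(obs$counts)
    B <- boot_cfg$n_iterations
    null_counts <- matrix(NA_real_, B, length(parts),
                          dimnames = list(NULL, parts))
    null_os <- array(NA_real_, c(B, length(parts), length(ranks)),
                     dimnames = list(NULL, parts, paste0("rank", ranks)))
    for (b in seq_len(B)) {
        gtp <- permuteGenotypes(gt, boot_cfg$seed + b)
        sc <- tryCatch(runScan(expr, gene_map, gtp, design, K, scan_cfg),
                       error = function(e)
                           stop("scan failed in permutation iteration ", b,
                                ": ", conditionMessage(e)))
        st <- .partitionStats(scanRecords(sc), alpha, ranks)
        null_counts[b, ] <- st$counts
        null_os[b, , ] <- st$order_stats
    }
    z <- normal_p <- stats::setNames(rep(NA_real_, length(parts)), parts)
    for (pt in parts) {
        s <- stats::sd(null_counts[, pt])
        if (!is.na(s) && s > 0) {
            z[pt] <- (obs$counts[pt] - mean(null_counts[, pt])) / s
            normal_p[pt] <- stats::pnorm(z[pt], lower.tail = FALSE)
        }
    }
    exceed <- matrix(NA_real_, length(parts), length(ranks),
                     dimnames = dimnames(obs$order_stats))
    for (pt in parts) for (j in seq_along(ranks))
        if (!is.na(obs$order_stats[pt, j]))
            exceed[pt, j] <- orderStatExceedance(obs$order_stats[pt, j],
                                                 null_os[, pt, j])
    structure(list(null_counts = null_counts, null_order_stats = null_os,
                   observed_counts = obs$counts,
                   observed_order_stats = obs$order_stats,
                   z = z, normal_tail_p = normal_p, exceedance = exceed,
                   config = unclass(boot_cfg)),
              class = "BootstrapSummary")
}
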