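#' QC thresholds for genotype filtering
#'
#' @param maf_min minor-allele-frequency threshold (inclusive), default 0.3
#' @param ld_r2_min minimum pairwise dosage R^2 for SNPs to share an LD
#'   block, default 0.9
#' @return list of class \code{"QcThresholds"}
#' @export
qcThresholds <- function(maf_min = 0.3, ld_r2_min = 0.9) {
    .checkFraction(maf_min, "maf_min", 0, 0.5)
    .checkFraction(ld_r2_min, "ld_r2_min", 1e-12, 1)
    structure(list(maf_min = maf_min, ld_r2_min = ld_r2_min),
              class = "QcThresholds")
}

#' Minor allele frequency of a dosage vector
#'
#' @param dosages vector of minor-allele dosages in \{0,1,2\}
#' @return min(f, 1 - f) where f = sum(dosages) / (2 n); in [0, 0.5]
#' @examples
#' computeMaf(c(0, 1, 2))   # 0.5
#' computeMaf(c(0, 0, 1, 2)) # 0.375
#' @export
computeMaf <- function(dosages) {
    if (length(dosages) == 0L) stop("empty dosage vector")
    if (!all(dosages %in% c(0, 1, 2))) stop("dosages must be 0, 1 or 2")
    f <- sum(dosages) / (2 * length(dosages))
    min(f, 1 - f)
}

#' Recode dosages so they count the minor allele
#'
#' SNPs whose allele frequency exceeds 0.5 are flipped (dosage -> 2 -
#' dosage), matching the 0 = homozygote major / 2 = homozygote minor
#' convention.
#'
#' @param gt a \linkS4class{GenotypeMatrix}
#' @return a \linkS4class{GenotypeMatrix}
#' @export
recodeToMinor <- function(gt) {
    d <- dosages(gt)
    f <- rowSums(d) / (2 * ncol(d))
    flip <- f > 0.5
    if (any(flip)) d[flip, ] <- 2 - d[flip, ]
    m <- snpMap(gt)
    GenotypeMatrix(d, chrom = m$chrom, pos = m$pos)
}

#' Filter SNPs by minor allele frequency
#'
#' Keeps SNPs with MAF >= \code{thr$maf_min} (boundary inclusive: the
#' threshold removes underpowered SNPs, so a SNP exactly at it stays).
#'
#' @param gt a \linkS4class{GenotypeMatrix}
#' @param thr a \code{\link{qcThresholds}}
#' @return the filtered \linkS4class{GenotypeMatrix}; attribute
#'   \code{maf_filter} records retained/removed counts
#' @export
filterMaf <- function(gt, thr = qcThresholds()) {
    d <- dosages(gt)
    maf <- apply(d, 1L, computeMaf)
    keep <- maf >= thr$maf_min
    .msg("MAF filter at %.3g: %d retained, %d removed",
         thr$maf_min, sum(keep), sum(!keep))
    out <- gt[keep, ]
    attr(out, "maf_filter") <- c(retained = sum(keep), removed = sum(!keep))
    out
}

#' Squared Pearson correlation between two dosage vectors
#'
#' @param d1,d2 equal-length dosage vectors, both non-constant
#' @return R^2 in [0, 1]
#' @export
ldR2 <- function(d1, d2) {
    stopifnot(length(d1) == length(d2), length(d1) >= 2)
    if (stats::sd(d1) == 0 || stats::sd(d2) == 0)
        stop("monomorphic SNP: LD R^2 undefined for a constant dosage vector")
    stats::cor(d1, d2)^2
}

#' Group SNPs into LD blocks and keep one tag per block
#'
#' A single left-to-right pass per chromosome: the current block absorbs
#' the next SNP iff its dosage R^2 with every SNP already in the block is
#' at least \code{thr$ld_r2_min}; otherwise a new block starts. Blocks
#' never span chromosomes. The tag is the first member by position.
#'
#' @param gt a MAF-filtered \linkS4class{GenotypeMatrix}
#' @param thr a \code{\link{qcThresholds}}
#' @return list with \code{blocks} (data.frame block_id, chrom, tag_snp_id,
#'   snp_id — one row per member) and \code{genotypes} (the reduced
#'   \linkS4class{GenotypeMatrix} of tag SNPs)
#' @export
groupLdBlocks <- function(gt, thr = qcThresholds()) {
    d <- dosages(gt)
    m <- snpMap(gt)
    n_snp <- nrow(d)
    block_id <- integer(n_snp)
    bid <- 0L
    members <- integer(0)
    for (i in seq_len(n_snp)) {
        absorb <- length(members) > 0L &&
            m$chrom[i] == m$chrom[members[1L]] &&
            all(vapply(members, function(j) ldR2(d[i, ], d[j, ]),
                       numeric(1)) >= thr$ld_r2_min)
        if (!absorb) {
            bid <- bid + 1L
            members <- i
        } else members <- c(members, i)
        block_id[i] <- bid
    }
    tag_idx <- vapply(split(seq_len(n_snp), block_id), `[`, integer(1), 1L)
    blocks <- data.frame(block_id = block_id,
                         chrom = m$chrom,
                         tag_snp_id = m$snp_id[tag_idx[block_id]],
                         snp_id = m$snp_id,
                         stringsAsFactors = FALSE)
    reduced <- gt[tag_idx, ]
    .msg("LD grouping at R^2 >= %.3g: %d SNPs -> %d blocks",
         thr$ld_r2_min, n_snp, length(tag_idx))
    list(blocks = blocks, genotypes = reduced)
}

#' Full genotype QC: minor-allele recoding, MAF filter, LD tag selection
#'
#' @param gt a \linkS4class{GenotypeMatrix}
#' @param thr a \code{\link{qcThresholds}}
#' @return as \code{\link{groupLdBlocks}}, computed on the recoded,
#'   MAF-filtered table
#' @export
genotypeQc <- function(gt, thr = qcThresholds()) {
    groupLdBlocks(filterMaf(recodeToMinor(gt), thr), thr)
}
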