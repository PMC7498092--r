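#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowRanges colData
#' @importFrom GenomicRanges GRanges start end seqnames findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame queryHits subjectHits
NULL

#' GenotypeMatrix: SNP dosages with genomic positions
#'
#' A thin subclass of \linkS4class{RangedSummarizedExperiment} holding a
#' SNPs-by-samples dosage assay. Dosages count copies of the minor allele:
#' 0 (homozygote major), 1 (heterozygote), 2 (homozygote minor). Each SNP
#' carries a 1-based genomic position in \code{rowRanges}. Within each
#' chromosome, SNPs are kept sorted by position; the constructor reorders
#' rows as needed.
#'
#' @slot .. see \linkS4class{RangedSummarizedExperiment}; the single assay
#'   must be named \code{"dosage"}.
#' @name GenotypeMatrix-class
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

.validGenotypeMatrix <- function(object) {
    msg <- character()
    if (!("dosage" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'dosage' is missing")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        bad <- !(d %in% c(0, 1, 2))
        if (any(bad))
            msg <- c(msg, sprintf(
                "dosages must be 0, 1 or 2; %d offending value(s), first at row '%s'",
                sum(bad), rownames(d)[which(bad, arr.ind = TRUE)[1L, 1L]]))
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "SNP ids (rownames) must be present and unique")
    rr <- SummarizedExperiment::rowRanges(object)
    if (length(rr) > 1L) {
        chr <- as.character(GenomicRanges::seqnames(rr))
        pos <- GenomicRanges::start(rr)
        if (any(unlist(tapply(pos, factor(chr, levels = unique(chr)), is.unsorted))))
            msg <- c(msg, "SNPs must be sorted by position within each chromosome")
    }
    if (length(msg)) msg else TRUE
}
setValidity("GenotypeMatrix", .validGenotypeMatrix)

#' Construct a GenotypeMatrix
#'
#' @param dosage integer/numeric matrix, SNPs x samples, values in \{0,1,2\};
#'   rownames are SNP ids, colnames sample ids.
#' @param chrom character vector of chromosome names, one per SNP.
#' @param pos integer vector of 1-based positions, one per SNP.
#' @return A \linkS4class{GenotypeMatrix} with rows ordered by
#'   (chromosome, position).
#' @examples
#' d <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 2, dimnames = list(c("s1", "s2"), NULL))
#' gm <- GenotypeMatrix(d, chrom = c("1", "1"), pos = c(100L, 50L))
#' snpMap(gm)
#' @export
GenotypeMatrix <- function(dosage, chrom, pos) {
    dosage <- as.matrix(dosage)
    if (is.null(rownames(dosage)))
        rownames(dosage) <- sprintf("snp%04d", seq_len(nrow(dosage)))
    if (is.null(colnames(dosage)))
        colnames(dosage) <- sprintf("S%02d", seq_len(ncol(dosage)))
    stopifnot(length(chrom) == nrow(dosage), length(pos) == nrow(dosage))
    o <- order(factor(chrom, levels = unique(chrom)), pos)
    dosage <- dosage[o, , drop = FALSE]
    chrom <- chrom[o]; pos <- pos[o]
    rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, width = 1L))
    names(rr) <- rownames(dosage)
    new("GenotypeMatrix", SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage), rowRanges = rr))
}

#' EqtlScan: results of an all-pairs eQTL scan
#'
#' Holds the per-pair association records of a linear/ANOVA generalized least
#' squares scan, a summary of test counts, and the scan configuration.
#'
#' @slot records data.frame with one row per (gene, SNP, model): snp_id,
#'   gene_id, model, class (cis/trans), statistic, df1, df2, effect, p, fdr,
#'   reason (NA when testable).
#' @slot summary list of test counts and low-p counts per partition.
#' @slot config list echoing the \code{\link{scanConfig}} used.
#' @name EqtlScan-class
#' @aliases EqtlScan-class
#' @exportClass EqtlScan
setClass("EqtlScan", representation(
    records = "data.frame", summary = "list", config = "list"))

setValidity("EqtlScan", function(object) {
    req <- c("snp_id", "gene_id", "model", "class", "statistic", "df1", "df2",
             "effect", "p", "fdr", "reason")
    if (!all(req %in% names(object@records)))
        return(paste("records missing columns:",
                     paste(setdiff(req, names(object@records)), collapse = ", ")))
    p <- object@records$p
    if (any(!is.na(p) & (p < 0 | p > 1))) return("p-values outside [0, 1]")
    TRUE
})

#' @describeIn EqtlScan-class compact display
#' @param object an \code{EqtlScan}
#' @export
setMethod("show", "EqtlScan", function(object) {
    s <- object@summary
    cat("EqtlScan:", nrow(object@records), "records (",
        s$n_genes, "genes x", s$n_snps, "SNPs;",
        paste(s$models, collapse = "+"), ")\n")
    tab <- s$partitions
    if (!is.null(tab)) {
        cat("  tests / untestable / p<", object@config$alpha_report, "per partition:\n")
        print(tab)
    }
    invisible(NULL)
})
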