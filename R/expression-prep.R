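#' Gene filter configuration
#'
#' @param min_reads minimum read count, default 5
#' @param min_samples number of samples that must reach \code{min_reads}
#'   (default 11, the size of the smaller breed group)
#' @param z_max outlier threshold in sd units on normalized expression,
#'   default 3
#' @return list of class \code{"GeneFilterConfig"}
#' @export
geneFilterConfig <- function(min_reads = 5, min_samples = 11, z_max = 3) {
    stopifnot(min_reads > 0, min_samples > 0, z_max > 0)
    structure(list(min_reads = min_reads, min_samples = min_samples,
                   z_max = z_max), class = "GeneFilterConfig")
}

.countsOf <- function(counts) {
    if (is(counts, "SummarizedExperiment"))
        SummarizedExperiment::assay(counts, "counts")
    else as.matrix(counts)
}

#' TMM normalization factors
#'
#' Weighted trimmed mean of M-values scaling factors (edgeR's
#' \code{calcNormFactors}), rescaled so their geometric mean is 1. The
#' factor multiplies the library size to give each sample's effective size.
#'
#' @param counts genes-by-samples count matrix or SummarizedExperiment
#'   with a \code{"counts"} assay
#' @return named numeric vector of per-sample factors
#' @export
tmmFactors <- function(counts) {
    m <- .countsOf(counts)
    if (any(colSums(m) == 0)) stop("sample with zero library size")
    f <- edgeR::calcNormFactors(m, method = "TMM")
    f <- f / exp(mean(log(f)))
    stats::setNames(f, colnames(m))
}

#' Log2 counts-per-million on TMM-effective library sizes
#'
#' value = log2((count + 0.5) / (library size x TMM factor) x 1e6)
#'
#' @param counts count matrix or SummarizedExperiment
#' @param factors per-sample factors from \code{\link{tmmFactors}}
#' @return genes-by-samples matrix of log2-CPM values
#' @export
logNormalize <- function(counts, factors = tmmFactors(counts)) {
    m <- .countsOf(counts)
    eff <- colSums(m) * factors[colnames(m)]
    log2(sweep(m + 0.5, 2L, eff, "/") * 1e6)
}

#' Filter genes on minimum counts
#'
#' Keeps genes with at least \code{min_reads} reads in at least
#' \code{min_samples} samples (both boundaries inclusive).
#'
#' @param counts count matrix or SummarizedExperiment
#' @param cfg a \code{\link{geneFilterConfig}}
#' @return object of the same type, subset to the retained genes
#' @export
filterMinCounts <- function(counts, cfg = geneFilterConfig()) {
    m <- .countsOf(counts)
    keep <- rowSums(m >= cfg$min_reads) >= cfg$min_samples
    .msg("count filter (>=%d reads in >=%d samples): %d retained, %d removed",
         cfg$min_reads, cfg$min_samples, sum(keep), sum(!keep))
    counts[keep, , drop = FALSE]
}

#' Identify genes with a single-sample expression outlier
#'
#' Per gene, z-scores of normalized expression across samples; a gene is
#' flagged iff any |z| exceeds \code{z_max}. Constant genes (sd = 0) have
#' all z defined as 0 and are never flagged.
#'
#' @param expr genes-by-samples normalized (log-CPM) matrix
#' @param cfg a \code{\link{geneFilterConfig}}
#' @return character vector of flagged gene ids
#' @export
filterSingleOutlier <- function(expr, cfg = geneFilterConfig()) {
    stopifnot(ncol(expr) >= 3)
    mu <- rowMeans(expr)
    s <- apply(expr, 1L, stats::sd)
    z <- abs(expr - mu) / ifelse(s == 0, Inf, s)
    flagged <- rownames(expr)[apply(z > cfg$z_max, 1L, any)]
    .msg("outlier filter (|z| > %g): %d gene(s) removed", cfg$z_max,
         length(flagged))
    flagged
}

#' Assemble the analysis gene set
#'
#' The union of a differential-expression gene list and a mitochondrial
#' gene list, intersected with the genes surviving the expression filters.
#'
#' @param deg_ids,mito_ids character id vectors (either may be empty, not
#'   both)
#' @param filtered_ids ids of genes surviving the count and outlier filters
#' @return character vector of gene ids, in \code{filtered_ids} order
#' @export
selectGeneSet <- function(deg_ids, mito_ids, filtered_ids) {
    u <- union(deg_ids, mito_ids)
    if (length(u) == 0L) stop("both gene lists are empty")
    out <- intersect(filtered_ids, u)
    if (length(out) == 0L)
        stop("gene lists share no ids with the filtered expression matrix")
    .msg("gene set: union %d, final (filtered) %d", length(u), length(out))
    out
}

#' Prepare expression for the eQTL scan
#'
#' Subsets the count matrix to the union of the two gene lists, applies
#' the minimum-count filter on raw counts, computes TMM factors and
#' log2-CPM on the retained genes, removes single-observation outlier
#' genes on the normalized scale, and returns the final normalized matrix.
#'
#' @param counts SummarizedExperiment with a \code{"counts"} assay and
#'   gene coordinates in \code{rowRanges}
#' @param deg_ids,mito_ids gene lists; defaults use all genes (no list
#'   pre-selection)
#' @param cfg a \code{\link{geneFilterConfig}}
#' @return list: \code{expr} (log2-CPM matrix of the final gene set),
#'   \code{se} (the corresponding SummarizedExperiment subset),
#'   \code{factors} (TMM factors), \code{audit} (data.frame gene_id,
#'   reason for every removed gene)
#' @export
prepareExpression <- function(counts, deg_ids = rownames(counts),
                              mito_ids = character(),
                              cfg = geneFilterConfig()) {
    ids0 <- rownames(counts)
    u <- union(deg_ids, mito_ids)
    inset <- intersect(ids0, u)
    if (length(inset) == 0L) stop("gene lists share no ids with the counts")
    dropped <- setdiff(ids0, u)
    audit <- data.frame(gene_id = dropped,
                        reason = rep("not_in_gene_lists", length(dropped)),
                        stringsAsFactors = FALSE)
    sub <- counts[inset, ]
    kept <- filterMinCounts(sub, cfg)
    cut <- setdiff(rownames(sub), rownames(kept))
    audit <- rbind(audit, data.frame(
        gene_id = cut, reason = rep("min_count_filter", length(cut)),
        stringsAsFactors = FALSE))
    factors <- tmmFactors(kept)
    expr <- logNormalize(kept, factors)
    out_ids <- filterSingleOutlier(expr, cfg)
    audit <- rbind(audit, data.frame(gene_id = out_ids,
                                     reason = rep("single_outlier",
                                                  length(out_ids)),
                                     stringsAsFactors = FALSE))
    final <- setdiff(rownames(kept), out_ids)
    if (length(final) == 0L) stop("no genes survive the expression filters")
    list(expr = expr[final, , drop = FALSE], se = kept[final, ],
         factors = factors, audit = audit)
}
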