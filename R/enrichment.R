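#' Surplus of low p-values over the uniform expectation
#'
#' max(0, round(#\{p < alpha\} - alpha N)): the number of low p-values in
#' excess of what a uniform p-value distribution would produce.
#'
#' @param pvals p-value vector (NA dropped)
#' @param alpha cutoff, default 0.01
#' @return integer surplus count
#' @export
surplusLowP <- function(pvals, alpha = 0.01) {
    p <- pvals[!is.na(pvals)]
    as.integer(max(0, round(sum(p < alpha) - alpha * length(p))))
}

#' Select the k most significant pairs of one scan partition
#'
#' @param records scan records from a single (model x class) partition
#' @param k number of pairs; ties in p are broken by (snp_id, gene_id)
#'   lexicographic order for determinism
#' @return the k selected record rows (gene multiset preserved)
#' @export
selectTopPairs <- function(records, k) {
    avail <- records[!is.na(records$p), , drop = FALSE]
    if (k > nrow(avail))
        stop("k = ", k, " exceeds the ", nrow(avail),
             " testable records in the partition")
    o <- order(avail$p, avail$snp_id, avail$gene_id)
    avail[o[seq_len(k)], , drop = FALSE]
}

#' Fisher's exact enrichment of a gene category among selected pairs
#'
#' The 2x2 table is [pairs whose gene is in the category, pairs whose gene
#' is not; background genes in the category, background genes not]. Pairs
#' are counted with multiplicity (a gene hit by several eQTLs counts each
#' time) while the background is a plain gene set — the construction
#' behind published trans-eQTL category tables that report "N eQTLs
#' matching each category" against a gene-set background. Two-sided test,
#' so both enrichment and depletion register.
#'
#' @param top_genes character vector of the selected pairs' gene ids,
#'   with multiplicity
#' @param category character set of category member gene ids
#' @param background character background gene ids (set; deduplicated)
#' @return list(n_matched, fold, p, table)
#' @export
fisherEnrichment <- function(top_genes, category, background) {
    stopifnot(length(top_genes) > 0, length(background) > 0)
    background <- unique(background)
    a <- sum(top_genes %in% category)
    b <- length(top_genes) - a
    cc <- sum(background %in% category)
    d <- length(background) - cc
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE,
                  dimnames = list(c("pairs", "background"),
                                  c("in_category", "not_in_category")))
    p <- stats::fisher.test(tab)$p.value
    if (cc == 0)
        return(list(n_matched = a, fold = NA_real_, p = p, table = tab,
                    reason = "category absent from background"))
    fold <- (a / (a + b)) / (cc / (cc + d))
    list(n_matched = a, fold = fold, p = p, table = tab,
         reason = NA_character_)
}

#' Category enrichment of the surplus-based top trans-eQTL set
#'
#' Selects the top pairs of one scan partition (by default as many as the
#' surplus of p-values below \code{alpha} over the uniform expectation)
#' and tests each category's representation among the selected pairs
#' against one or two backgrounds, mirroring a two-background enrichment
#' table (analysis gene set and all expressed genes).
#'
#' @param scan an \linkS4class{EqtlScan}
#' @param categories named list of character gene-id sets
#' @param background_analysis gene ids of the analysis set
#' @param background_expressed optional wider background (all expressed
#'   genes)
#' @param model,class partition selectors, default linear/trans
#' @param alpha low-p cutoff for the surplus, default 0.01
#' @param k number of top pairs; default = the surplus
#' @return data.frame, one row per category: category, n_matched_pairs,
#'   fold_vs_background, p_vs_background and, when
#'   \code{background_expressed} is given, fold_vs_expressed,
#'   p_vs_expressed
#' @export
enrichmentAnalysis <- function(scan, categories, background_analysis,
                               background_expressed = NULL,
                               model = "linear", class = "trans",
                               alpha = 0.01, k = NULL) {
    rec <- scanRecords(scan)
    rec <- rec[rec$model == model & rec$class == class, , drop = FALSE]
    if (!nrow(rec)) stop("empty partition: ", model, " ", class)
    if (is.null(k)) k <- surplusLowP(rec$p, alpha)
    if (k < 1) stop("no surplus of low p-values; nothing to select")
    top <- selectTopPairs(rec, k)
    rows <- lapply(names(categories), function(nm) {
        fe <- fisherEnrichment(top$gene_id, categories[[nm]],
                               background_analysis)
        row <- data.frame(category = nm, n_matched_pairs = fe$n_matched,
                          fold_vs_background = fe$fold,
                          p_vs_background = fe$p,
                          stringsAsFactors = FALSE)
        if (!is.null(background_expressed)) {
            fe2 <- fisherEnrichment(top$gene_id, categories[[nm]],
                                    background_expressed)
            row$fold_vs_expressed <- fe2$fold
            row$p_vs_expressed <- fe2$p
        }
        row
    })
    out <- do.call(rbind, rows)
    attr(out, "k") <- k
    out
}

#' SNP overlap with QTL regions
#'
#' A SNP "locus" is its position extended by \code{flank} bp both ways
#' (inclusive boundaries); overlap is tested against each region on the
#' same chromosome.
#'
#' @param snp_chrom,snp_pos SNP coordinates
#' @param qtl_regions \code{GRanges} of QTL intervals (1-based inclusive)
#' @param flank bp added on both sides, default 1e5
#' @return list(overlap = logical, hits = integer indices into
#'   \code{qtl_regions})
#' @export
snpQtlOverlap <- function(snp_chrom, snp_pos, qtl_regions, flank = 1e5) {
    q <- GenomicRanges::GRanges(snp_chrom, IRanges::IRanges(
        start = max(1, snp_pos - flank), end = snp_pos + flank))
    ## chromosomes absent from the region list are simply non-overlapping
    ov <- suppressWarnings(GenomicRanges::findOverlaps(q, qtl_regions))
    hits <- S4Vectors::subjectHits(ov)
    list(overlap = length(hits) > 0, hits = hits)
}

#' Gene overlap with QTL regions
#'
#' The unextended gene interval is intersected with the QTL regions.
#'
#' @param gene_chrom,gene_start,gene_end gene interval (1-based inclusive)
#' @param qtl_regions \code{GRanges} of QTL intervals
#' @return list(overlap, hits) as \code{\link{snpQtlOverlap}}
#' @export
geneQtlOverlap <- function(gene_chrom, gene_start, gene_end, qtl_regions) {
    q <- GenomicRanges::GRanges(gene_chrom, IRanges::IRanges(
        start = gene_start, end = gene_end))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(q, qtl_regions))
    hits <- S4Vectors::subjectHits(ov)
    list(overlap = length(hits) > 0, hits = hits)
}

#' Annotate scan records with QTL-region overlap flags
#'
#' @param scan an \linkS4class{EqtlScan}
#' @param gt the scanned \linkS4class{GenotypeMatrix}
#' @param gene_map data.frame (gene_id, chrom, start, end)
#' @param qtl_regions \code{GRanges} of QTL intervals
#' @param flank SNP flank in bp, default 1e5
#' @return data.frame (snp_id, gene_id, model, snp_in_qtl, gene_in_qtl)
#' @export
annotateQtlOverlap <- function(scan, gt, gene_map, qtl_regions, flank = 1e5) {
    rec <- scanRecords(scan)
    smap <- snpMap(gt)
    sr <- GenomicRanges::GRanges(smap$chrom, IRanges::IRanges(
        start = pmax(1, smap$pos - flank), end = smap$pos + flank))
    snp_hit <- suppressWarnings(GenomicRanges::countOverlaps(sr, qtl_regions)) > 0
    names(snp_hit) <- smap$snp_id
    gr <- GenomicRanges::GRanges(gene_map$chrom, IRanges::IRanges(
        start = gene_map$start, end = gene_map$end))
    gene_hit <- suppressWarnings(GenomicRanges::countOverlaps(gr, qtl_regions)) > 0
    names(gene_hit) <- gene_map$gene_id
    data.frame(snp_id = rec$snp_id, gene_id = rec$gene_id,
               model = rec$model,
               snp_in_qtl = unname(snp_hit[rec$snp_id]),
               gene_in_qtl = unname(gene_hit[rec$gene_id]),
               stringsAsFactors = FALSE)
}
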