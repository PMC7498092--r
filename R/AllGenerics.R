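#' Accessors for GenotypeMatrix and EqtlScan
#'
#' \code{dosages()} returns the SNPs-by-samples dosage matrix;
#' \code{snpMap()} the SNP map (snp_id, chrom, pos);
#' \code{scanRecords()} the per-pair record table of a scan;
#' \code{scanSummary()} its summary list.
#'
#' @param x a \linkS4class{GenotypeMatrix} or \linkS4class{EqtlScan}
#' @return see individual descriptions
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(x)
    SummarizedExperiment::assay(x, "dosage"))

#' @rdname accessors
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' @rdname accessors
#' @export
setMethod("snpMap", "GenotypeMatrix", function(x) {
    rr <- SummarizedExperiment::rowRanges(x)
    data.frame(snp_id = names(rr),
               chrom = as.character(GenomicRanges::seqnames(rr)),
               pos = GenomicRanges::start(rr),
               row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setGeneric("scanRecords", function(x) standardGeneric("scanRecords"))

#' @rdname accessors
#' @export
setMethod("scanRecords", "EqtlScan", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("scanSummary", function(x) standardGeneric("scanSummary"))

#' @rdname accessors
#' @export
setMethod("scanSummary", "EqtlScan", function(x) x@summary)
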