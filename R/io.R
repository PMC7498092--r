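## Plain-text readers and writers for all pipeline artifacts. All formats
## are TSV/CSV (gzip handled transparently by R's connections when the
## path ends in .gz).

#' Write / read a genotype dosage table
#'
#' Rows are SNPs: snp_id, chrom, pos, then one dosage column per sample.
#'
#' @param gt a \linkS4class{GenotypeMatrix}
#' @param path output file (.tsv or .tsv.gz)
#' @return \code{writeGenotypesTsv}: invisibly, the path;
#'   \code{readGenotypesTsv}: a \linkS4class{GenotypeMatrix}
#' @export
writeGenotypesTsv <- function(gt, path) {
    m <- snpMap(gt)
    out <- cbind(m, as.data.frame(dosages(gt)))
    utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeGenotypesTsv
#' @export
readGenotypesTsv <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    stopifnot(all(c("snp_id", "chrom", "pos") %in% names(tab)))
    d <- as.matrix(tab[, setdiff(names(tab), c("snp_id", "chrom", "pos")),
                       drop = FALSE])
    rownames(d) <- tab$snp_id
    if (!all(d %in% c(0, 1, 2)))
        stop("genotype file contains values other than 0/1/2 ",
             "(missing genotypes are not supported)")
    GenotypeMatrix(d, chrom = as.character(tab$chrom), pos = tab$pos)
}

#' Write / read a count table with gene coordinates
#'
#' Rows are genes: gene_id, chrom, start, end, then one count column per
#' sample.
#'
#' @param se SummarizedExperiment with assay \code{"counts"} and gene
#'   coordinates in \code{rowRanges}
#' @param path file path
#' @return \code{writeCountsTsv}: invisibly, the path;
#'   \code{readCountsTsv}: a RangedSummarizedExperiment
#' @export
writeCountsTsv <- function(se, path) {
    rr <- SummarizedExperiment::rowRanges(se)
    out <- cbind(data.frame(gene_id = rownames(se),
                            chrom = as.character(GenomicRanges::seqnames(rr)),
                            start = GenomicRanges::start(rr),
                            end = GenomicRanges::end(rr)),
                 as.data.frame(SummarizedExperiment::assay(se, "counts")))
    utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCountsTsv
#' @export
readCountsTsv <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(tab)))
    m <- as.matrix(tab[, setdiff(names(tab),
                                 c("gene_id", "chrom", "start", "end")),
                       drop = FALSE])
    rownames(m) <- tab$gene_id
    makeCountExperiment(m, as.character(tab$chrom), tab$start, tab$end)
}

#' Read a covariate table
#'
#' TSV with columns sample_id, breed, batch, rin, age_days.
#'
#' @param path file path
#' @return data.frame with breed and batch as factors
#' @export
readCovariatesTsv <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    stopifnot(all(c("sample_id", "breed", "batch") %in% names(tab)))
    tab$breed <- factor(tab$breed)
    tab$batch <- factor(tab$batch)
    tab
}

#' Read a pedigree CSV (animal,sire,dam; 0 = unknown)
#'
#' @param path file path
#' @return data.frame of character columns
#' @export
readPedigreeCsv <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    stopifnot(all(c("animal", "sire", "dam") %in% names(tab)))
    tab
}

#' Read a one-id-per-line gene list
#'
#' @param path file path
#' @return character vector
#' @export
readGeneList <- function(path) {
    x <- readLines(path)
    x <- trimws(x)
    x[nzchar(x)]
}

#' Read a two-column category membership table
#'
#' TSV with columns category_id, gene_id (header optional if named so).
#'
#' @param path file path
#' @return named list of character gene-id vectors
#' @export
readCategoryTsv <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    stopifnot(all(c("category_id", "gene_id") %in% names(tab)))
    lapply(split(tab$gene_id, tab$category_id), unique)
}

#' Read QTL regions from a BED file
#'
#' BED half-open 0-based intervals are converted to 1-based inclusive
#' \code{GRanges} (rtracklayer does this conversion).
#'
#' @param path BED file path
#' @return \code{GRanges}
#' @export
readQtlBed <- function(path) {
    if (requireNamespace("rtracklayer", quietly = TRUE))
        return(rtracklayer::import(path, format = "BED"))
    tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    GenomicRanges::GRanges(tab[[1]], IRanges::IRanges(start = tab[[2]] + 1L,
                                                      end = tab[[3]]))
}

#' Convert a minimal VCF to a GenotypeMatrix
#'
#' Supports biallelic sites with GT fields and no missing genotypes; the
#' dosage counts ALT alleles and is re-oriented to the minor allele by
#' \code{\link{recodeToMinor}} downstream.
#'
#' @param path VCF file path
#' @return a \linkS4class{GenotypeMatrix}
#' @export
readVcfDosages <- function(path) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gtf <- vcfR::extract.gt(v, element = "GT")
    fix <- vcfR::getFIX(v)
    if (any(is.na(gtf)) || any(grepl("\\.", gtf)))
        stop("missing genotypes are not supported")
    if (any(nchar(fix[, "ALT"]) != 1 | grepl(",", fix[, "ALT"])))
        stop("only biallelic SNPs are supported")
    count_alt <- function(x) {
        a <- strsplit(x, "[/|]")
        vapply(a, function(z) sum(z == "1"), numeric(1))
    }
    d <- t(apply(gtf, 1L, count_alt))
    colnames(d) <- colnames(gtf)
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
    rownames(d) <- ids
    GenotypeMatrix(d, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]))
}

#' Write a kinship matrix as TSV with id header row/column
#'
#' @param K square matrix with dimnames
#' @param path file path
#' @return \code{writeKinshipTsv}: invisibly, the path;
#'   \code{readKinshipTsv}: the matrix
#' @export
writeKinshipTsv <- function(K, path) {
    utils::write.table(cbind(sample_id = rownames(K), as.data.frame(K)),
                       file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeKinshipTsv
#' @export
readKinshipTsv <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    K <- as.matrix(tab[, -1, drop = FALSE])
    rownames(K) <- tab[[1]]
    K
}
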