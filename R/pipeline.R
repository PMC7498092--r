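#' Run the full eQTL study pipeline
#'
#' Orchestrates genotype QC, expression normalisation and filtering,
#' kinship construction, the all-pairs scan, the genotype-permutation
#' validation, category enrichment and QTL-region annotation on files in
#' the package's plain-text formats, writing all stage outputs and a run
#' manifest (input checksums, config echo, derived seeds, stage row
#' counts) sufficient to re-run bit-identically.
#'
#' @param config either a path to a YAML file or a list with elements:
#'   \code{genotypes}, \code{counts}, \code{covariates}, \code{pedigree}
#'   (file paths); optional \code{deg_list}, \code{mito_list},
#'   \code{categories}, \code{qtl_bed} (paths); \code{out_dir}; optional
#'   \code{seed} (default 1), \code{maf_min} (0.3), \code{ld_r2_min}
#'   (0.9), \code{min_reads} (5), \code{min_samples} (11), \code{z_max}
#'   (3), \code{generations} (4), \code{cis_distance} (1e6),
#'   \code{n_iterations} (1000), \code{alpha_low} (0.01),
#'   \code{order_ranks} (1,10,100), \code{enrich_alpha} (0.01),
#'   \code{enrich_k} (explicit top-pair count; default surplus-based),
#'   \code{qtl_flank} (1e5).
#' @return the manifest list, invisibly; all outputs under
#'   \code{config$out_dir}
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    defaults <- list(seed = 1L, maf_min = 0.3, ld_r2_min = 0.9,
                     min_reads = 5, min_samples = 11, z_max = 3,
                     generations = 4, cis_distance = 1e6,
                     n_iterations = 1000L, alpha_low = 0.01,
                     order_ranks = c(1L, 10L, 100L), enrich_alpha = 0.01,
                     qtl_flank = 1e5)
    for (nm in names(defaults))
        if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    req <- c("genotypes", "counts", "covariates", "pedigree", "out_dir")
    miss <- setdiff(req, names(config))
    if (length(miss)) stop("config missing: ", paste(miss, collapse = ", "))
    infiles <- unlist(config[intersect(names(config),
                                       c("genotypes", "counts", "covariates",
                                         "pedigree", "deg_list", "mito_list",
                                         "categories", "qtl_bed"))])
    absent <- infiles[!file.exists(infiles)]
    if (length(absent)) stop("input file(s) not found: ",
                             paste(absent, collapse = ", "))
    out <- config$out_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(config = config,
                     input_checksums = as.list(tools::md5sum(infiles)),
                     stages = list())
    stage <- function(name, expr) {
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
        .msg("stage %s done in %.1fs", name, proc.time()[["elapsed"]] - t0)
        res
    }

    ## --- genotype QC ---
    gt0 <- stage("read_genotypes", readGenotypesTsv(config$genotypes))
    qc <- stage("qc", genotypeQc(gt0, qcThresholds(config$maf_min,
                                                   config$ld_r2_min)))
    gt <- qc$genotypes
    writeGenotypesTsv(gt, file.path(out, "genotypes_tags.tsv"))
    utils::write.table(qc$blocks, file.path(out, "ld_blocks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$qc <- list(n_input = nrow(gt0), n_tags = nrow(gt))

    ## --- expression ---
    counts <- stage("read_counts", readCountsTsv(config$counts))
    covariates <- stage("read_covariates", readCovariatesTsv(config$covariates))
    deg <- if (!is.null(config$deg_list)) readGeneList(config$deg_list)
           else rownames(counts)
    mito <- if (!is.null(config$mito_list)) readGeneList(config$mito_list)
            else character()
    prep <- stage("normalize", prepareExpression(
        counts, deg, mito, geneFilterConfig(config$min_reads,
                                            config$min_samples,
                                            config$z_max)))
    utils::write.table(prep$audit, file.path(out, "gene_filter_audit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
        cbind(gene_id = rownames(prep$expr), as.data.frame(prep$expr)),
        file.path(out, "expression_logcpm.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    manifest$stages$normalize <- list(n_input = nrow(counts),
                                      n_final = nrow(prep$expr))

    ## --- kinship ---
    ped <- stage("read_pedigree", readPedigreeCsv(config$pedigree))
    samples <- covariates$sample_id
    K <- stage("kinship", kinshipMatrix(ped, samples, config$generations))
    writeKinshipTsv(K, file.path(out, "kinship.tsv"))

    ## --- scan ---
    rr <- SummarizedExperiment::rowRanges(prep$se)
    gene_map <- data.frame(gene_id = rownames(prep$se),
                           chrom = as.character(GenomicRanges::seqnames(rr)),
                           start = GenomicRanges::start(rr),
                           end = GenomicRanges::end(rr),
                           stringsAsFactors = FALSE)
    design <- studyDesign(covariates)
    scan_cfg <- scanConfig(cis_distance = config$cis_distance)
    scan <- stage("scan", runScan(prep$expr, gene_map, gt, design, K,
                                  scan_cfg))
    writeScanTsv(scan, file.path(out, "scan_records.tsv"))
    manifest$stages$scan <- list(
        n_genes = nrow(prep$expr), n_snps = nrow(gt),
        n_pairs_per_model = scanPairCount(nrow(prep$expr), nrow(gt)),
        partitions = scanSummary(scan)$partitions)

    ## --- permutation validation ---
    boot <- stage("bootstrap", bootstrapNull(
        prep$expr, gene_map, gt, design, K, scan_cfg,
        bootstrapConfig(config$n_iterations, config$alpha_low,
                        config$order_ranks,
                        deriveSeed(config$seed, "bootstrap")),
        observed = scan))
    utils::write.table(
        cbind(iteration = seq_len(nrow(boot$null_counts)),
              as.data.frame(boot$null_counts)),
        file.path(out, "bootstrap_counts.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    bs <- list(observed_counts = as.list(boot$observed_counts),
               z = as.list(boot$z),
               normal_tail_p = as.list(boot$normal_tail_p),
               exceedance = as.data.frame(boot$exceedance))
    jsonlite::write_json(bs, file.path(out, "bootstrap_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", na = "null")
    manifest$stages$bootstrap <- list(n_iterations = config$n_iterations)

    ## --- enrichment ---
    if (!is.null(config$categories)) {
        cats <- readCategoryTsv(config$categories)
        lin_trans <- scanRecords(scan)
        lin_trans <- lin_trans$p[lin_trans$model == "linear" &
                                     lin_trans$class == "trans"]
        k <- if (!is.null(config$enrich_k)) config$enrich_k
             else surplusLowP(lin_trans, config$enrich_alpha)
        if (k >= 1) {
            enr <- stage("enrich", enrichmentAnalysis(
                scan, cats, background_analysis = rownames(prep$expr),
                background_expressed = rownames(filterMinCounts(
                    counts, geneFilterConfig(config$min_reads,
                                             config$min_samples,
                                             config$z_max))),
                alpha = config$enrich_alpha, k = k))
            utils::write.table(enr, file.path(out, "enrichment.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            manifest$stages$enrich <- list(k = attr(enr, "k"),
                                           n_categories = nrow(enr))
        } else {
            writeLines(paste("no surplus of low p-values at alpha",
                             config$enrich_alpha,
                             "- enrichment not computed"),
                       file.path(out, "enrichment.tsv"))
            manifest$stages$enrich <- list(k = 0, n_categories = 0L)
        }
    }

    ## --- QTL annotation ---
    if (!is.null(config$qtl_bed)) {
        qtl <- readQtlBed(config$qtl_bed)
        ann <- stage("annotate", annotateQtlOverlap(scan, gt, gene_map, qtl,
                                                    config$qtl_flank))
        utils::write.table(ann, file.path(out, "qtl_overlap.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        manifest$stages$annotate <- list(
            n_snp_hits = sum(ann$snp_in_qtl[!duplicated(ann$snp_id)]))
    }

    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", na = "null", force = TRUE)
    invisible(manifest)
}

#' Write scan records as a sorted TSV
#'
#' Records are sorted by p within (model, class) partition.
#'
#' @param scan an \linkS4class{EqtlScan}
#' @param path file path
#' @return invisibly, the path
#' @export
writeScanTsv <- function(scan, path) {
    rec <- scanRecords(scan)
    rec <- rec[order(rec$model, rec$class, rec$p), ]
    utils::write.table(rec, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Summarise a completed pipeline run
#'
#' Reads the stage outputs under \code{out_dir} and writes a compact
#' report: per-partition p-value histogram bin counts, the top records
#' per partition with FDR, the permutation summary, and the enrichment
#' table when present.
#'
#' @param out_dir the pipeline output directory
#' @param n_top records per partition in the top table, default 10
#' @return list with elements \code{histograms}, \code{top_records},
#'   \code{bootstrap}, \code{enrichment} (also written under
#'   \code{out_dir/report})
#' @export
reportPipeline <- function(out_dir, n_top = 10) {
    scan_path <- file.path(out_dir, "scan_records.tsv")
    if (!file.exists(scan_path))
        stop("missing stage output: scan (", scan_path, ")")
    rec <- utils::read.table(scan_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    rep_dir <- file.path(out_dir, "report")
    dir.create(rep_dir, showWarnings = FALSE)
    part <- paste(rec$model, rec$class)
    breaks <- seq(0, 1, by = 0.05)
    histograms <- do.call(rbind, lapply(unique(part), function(pt) {
        p <- rec$p[part == pt & !is.na(rec$p)]
        data.frame(partition = pt, bin_lo = utils::head(breaks, -1),
                   bin_hi = breaks[-1],
                   count = as.vector(table(cut(p, breaks,
                                               include.lowest = TRUE))))
    }))
    utils::write.table(histograms, file.path(rep_dir, "pvalue_histograms.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    top <- do.call(rbind, lapply(split(rec, part), function(r) {
        utils::head(r[order(r$p), ], n_top)
    }))
    utils::write.table(top, file.path(rep_dir, "top_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    boot_path <- file.path(out_dir, "bootstrap_summary.json")
    boot <- if (file.exists(boot_path)) jsonlite::read_json(boot_path)
            else NULL
    enr_path <- file.path(out_dir, "enrichment.tsv")
    enrichment <- if (file.exists(enr_path))
        utils::read.table(enr_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
    else NULL
    if (is.null(enrichment))
        writeLines("no categories supplied; enrichment not run",
                   file.path(rep_dir, "enrichment.txt"))
    list(histograms = histograms, top_records = top, bootstrap = boot,
         enrichment = enrichment)
}
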