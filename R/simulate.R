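#' Configuration of the synthetic study generator
#'
#' Defines the dimensions and statistical structure of a simulated
#' genotype + RNA-seq study: two breed groups (11 + 27 animals by default,
#' matching a two-breed pig cohort), tag-SNP-style genotypes organised in
#' LD blocks, a multi-generation pedigree, covariates (breed, 5-level batch,
#' RIN, age), and negative-binomial counts with planted cis/trans genetic
#' effects.
#'
#' @param n_samples_group1,n_samples_group2 animals per breed group.
#' @param n_snps,n_genes study dimensions.
#' @param n_chromosomes autosomes to spread SNPs and genes over.
#' @param ld_block_size_mean mean LD-block size (1 = independent SNPs).
#' @param ld_flip_prob per-founder-allele flip probability for block copies;
#'   small values keep within-block dosage R^2 near 1.
#' @param target_maf_min founder minor-allele frequencies are drawn above
#'   this plus a 0.05 margin so a MAF filter at this level is satisfiable.
#' @param breed_freq_delta maximal founder allele-frequency difference
#'   between the two breed pools (breed-genotype confounding, as in real
#'   two-breed designs).
#' @param n_generations pedigree depth above the study animals.
#' @param founders_only if TRUE all study animals are unrelated founders
#'   (additive relationship matrix = identity).
#' @param n_cis_effects,n_trans_effects planted associations within /
#'   beyond 1 Mb of the target gene.
#' @param effect_size_sd planted |effect| in units of the per-gene residual
#'   log2-expression standard deviation (per minor-allele copy for linear
#'   effects).
#' @param dominant_fraction fraction of planted effects that are
#'   genotype-class shifts (carriers vs non-carriers) rather than
#'   dosage-linear; these are the effects an ANOVA model is built for.
#' @param target_category_fraction fraction of genes marked as members of
#'   a designated functional category (0 disables the mechanism). The
#'   membership is recorded in the truth ledger so category-enrichment
#'   behaviour can be tested against ground truth.
#' @param target_category_bias sampling weight of category members when
#'   trans-effect target genes are drawn (1 = no preference; 3 means
#'   category members are three times as likely to carry a trans effect).
#' @param dispersion negative-binomial dispersion of counts (0 = Poisson).
#' @param covariate_effect_sds named vector of per-gene effect sds (log2
#'   units) for \code{breed}, \code{batch}, \code{rin}, \code{age}.
#' @param polygenic_sd sd (log2 units) of the per-gene polygenic term whose
#'   covariance across animals is proportional to the pedigree A-matrix
#'   (0 disables it).
#' @param mean_library_size mean sequencing depth.
#' @param baseline_log2cpm range of per-gene baseline expression (log2 CPM).
#' @param seed integer seed; all generator stages derive their own seeds
#'   from it, so identical configs give identical output.
#' @return a validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(n_samples_group1 = 11, n_samples_group2 = 27,
                             n_snps = 300, n_genes = 100, n_chromosomes = 18,
                             ld_block_size_mean = 3, ld_flip_prob = 0.01,
                             target_maf_min = 0.3, breed_freq_delta = 0.1,
                             n_generations = 4, founders_only = FALSE,
                             n_cis_effects = 5, n_trans_effects = 5,
                             effect_size_sd = 2, dominant_fraction = 0,
                             target_category_fraction = 0,
                             target_category_bias = 1,
                             dispersion = 0.08,
                             covariate_effect_sds = c(breed = 0.5, batch = 0.3,
                                                      rin = 0.2, age = 0.1),
                             polygenic_sd = 0.25,
                             mean_library_size = 2e6,
                             baseline_log2cpm = c(5, 10),
                             seed = 1L) {
    cfg <- list(n_samples_group1 = as.integer(n_samples_group1),
                n_samples_group2 = as.integer(n_samples_group2),
                n_snps = as.integer(n_snps), n_genes = as.integer(n_genes),
                n_chromosomes = as.integer(n_chromosomes),
                ld_block_size_mean = ld_block_size_mean,
                ld_flip_prob = ld_flip_prob,
                target_maf_min = target_maf_min,
                breed_freq_delta = breed_freq_delta,
                n_generations = as.integer(n_generations),
                founders_only = isTRUE(founders_only),
                n_cis_effects = as.integer(n_cis_effects),
                n_trans_effects = as.integer(n_trans_effects),
                effect_size_sd = effect_size_sd,
                dominant_fraction = dominant_fraction,
                target_category_fraction = target_category_fraction,
                target_category_bias = target_category_bias,
                dispersion = dispersion,
                covariate_effect_sds = covariate_effect_sds,
                polygenic_sd = polygenic_sd,
                mean_library_size = mean_library_size,
                baseline_log2cpm = baseline_log2cpm,
                seed = as.integer(seed))
    with(cfg, {
        stopifnot(n_samples_group1 >= 1, n_samples_group2 >= 1,
                  n_snps >= 1, n_genes >= 1, n_chromosomes >= 1,
                  ld_block_size_mean >= 1, n_generations >= 0,
                  n_cis_effects >= 0, n_trans_effects >= 0,
                  dispersion >= 0, polygenic_sd >= 0,
                  effect_size_sd >= 0, mean_library_size > 0)
    })
    .checkFraction(cfg$target_maf_min, "target_maf_min", 0, 0.5)
    .checkFraction(cfg$ld_flip_prob, "ld_flip_prob", 0, 0.5)
    .checkFraction(cfg$dominant_fraction, "dominant_fraction")
    .checkFraction(cfg$target_category_fraction, "target_category_fraction")
    stopifnot(cfg$target_category_bias >= 0)
    stopifnot(all(c("breed", "batch", "rin", "age") %in%
                      names(cfg$covariate_effect_sds)))
    if (cfg$n_cis_effects + cfg$n_trans_effects > cfg$n_genes)
        stop("more planted effects than genes")
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Simulate a multi-generation two-breed pedigree
#'
#' Builds \code{n_generations} ancestral generations per breed plus the
#' study animals as the final generation. Parent pairs are reused within a
#' generation so full sibs occur among the study animals. With
#' \code{founders_only = TRUE}, all study animals have unknown parents.
#'
#' @param cfg a \code{\link{simulationConfig}}
#' @return data.frame (animal, sire, dam), \code{"0"} = unknown parent,
#'   parents listed before offspring. Attributes \code{samples} (study
#'   sample ids, group 1 first) and \code{animal_breed} (named vector) are
#'   attached.
#' @export
simulatePedigree <- function(cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    n1 <- cfg$n_samples_group1; n2 <- cfg$n_samples_group2
    samples <- sprintf("S%02d", seq_len(n1 + n2))
    breeds <- rep(c("Duroc", "Landrace"), c(n1, n2))
    names(breeds) <- samples
    if (cfg$founders_only || cfg$n_generations == 0L) {
        ped <- data.frame(animal = samples, sire = "0", dam = "0",
                          stringsAsFactors = FALSE)
        attr(ped, "samples") <- samples
        attr(ped, "animal_breed") <- breeds
        return(ped)
    }
    withSeed(deriveSeed(cfg$seed, "pedigree"), {
        rows <- list()
        animal_breed <- character()
        for (b in c("Duroc", "Landrace")) {
            n_final <- if (b == "Duroc") n1 else n2
            gen_size <- max(6L, n_final)
            prev <- character(0)
            for (g in seq_len(cfg$n_generations + 1L) - 1L) {
                final <- g == cfg$n_generations
                n_g <- if (final) n_final else gen_size
                ids <- if (final) samples[breeds == b]
                       else sprintf("%s_g%d_%02d", substr(b, 1, 1), g, seq_len(n_g))
                if (g == 0L) {
                    sire <- dam <- rep("0", n_g)
                } else {
                    half <- ceiling(length(prev) / 2)
                    males <- prev[seq_len(half)]
                    females <- prev[-seq_len(half)]
                    n_pairs <- max(2L, floor(min(length(males), length(females)) * 0.7))
                    pair_s <- sample(males, n_pairs, replace = length(males) < n_pairs)
                    pair_d <- sample(females, n_pairs, replace = length(females) < n_pairs)
                    pick <- sample.int(n_pairs, n_g, replace = TRUE)
                    sire <- pair_s[pick]; dam <- pair_d[pick]
                }
                rows[[length(rows) + 1L]] <- data.frame(
                    animal = ids, sire = sire, dam = dam, stringsAsFactors = FALSE)
                animal_breed[ids] <- b
                prev <- ids
            }
        }
        ped <- do.call(rbind, rows)
        rownames(ped) <- NULL
        attr(ped, "samples") <- samples
        attr(ped, "animal_breed") <- animal_breed
        ped
    })
}

#' Simulate LD-blocked genotype dosages through a pedigree
#'
#' Founder alleles are drawn per LD block at a breed-specific frequency and
#' transmitted through the pedigree by Mendelian sampling; all SNPs of a
#' block share one meiosis draw (complete within-block linkage) and block
#' copies differ from the block seed SNP only by rare founder-allele flips,
#' so within-block dosage R^2 stays near 1 while offspring genotypes are
#' always compatible with their parents.
#'
#' @param cfg a \code{\link{simulationConfig}}
#' @param pedigree output of \code{\link{simulatePedigree}}
#' @return a \linkS4class{GenotypeMatrix} over the study samples; attribute
#'   \code{block_assignments} maps snp_id to simulated block index.
#' @export
simulateGenotypes <- function(cfg, pedigree) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    samples <- attr(pedigree, "samples")
    breeds <- attr(pedigree, "animal_breed")
    if (is.null(samples) || is.null(breeds))
        stop("pedigree must come from simulatePedigree()")
    withSeed(deriveSeed(cfg$seed, "genotypes"), {
        ## block sizes
        sizes <- integer(0)
        while (sum(sizes) < cfg$n_snps)
            sizes <- c(sizes, 1L + stats::rpois(cfg$n_snps,
                                                max(0, cfg$ld_block_size_mean - 1)))
        cum <- cumsum(sizes)
        sizes <- sizes[seq_len(which(cum >= cfg$n_snps)[1L])]
        sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - cfg$n_snps)
        sizes <- sizes[sizes > 0L]
        n_blocks <- length(sizes)
        block_chrom <- rep_len(seq_len(cfg$n_chromosomes), n_blocks)
        ## seed frequencies per block and breed
        p0 <- stats::runif(n_blocks, min(cfg$target_maf_min + 0.05, 0.5), 0.5)
        delta <- stats::runif(n_blocks, 0, cfg$breed_freq_delta)
        p_breed <- cbind(Duroc = pmin(pmax(p0 - delta / 2, 0.05), 0.95),
                         Landrace = pmin(pmax(p0 + delta / 2, 0.05), 0.95))
        ## pedigree indices (parents precede offspring)
        animals <- pedigree$animal
        idx <- seq_along(animals); names(idx) <- animals
        sire_i <- ifelse(pedigree$sire == "0", 0L, idx[pedigree$sire])
        dam_i <- ifelse(pedigree$dam == "0", 0L, idx[pedigree$dam])
        n_an <- length(animals)
        an_breed <- breeds[animals]

        dosage <- matrix(0L, nrow = cfg$n_snps, ncol = length(samples),
                         dimnames = list(sprintf("snp%05d", seq_len(cfg$n_snps)),
                                         samples))
        chrom <- character(cfg$n_snps); pos <- integer(cfg$n_snps)
        block_of <- integer(cfg$n_snps)
        ## per-chromosome running position for ordered block placement
        next_start <- stats::setNames(rep(1, cfg$n_chromosomes),
                                      as.character(seq_len(cfg$n_chromosomes)))
        row0 <- 0L
        for (bl in seq_len(n_blocks)) {
            m <- sizes[bl]
            A1 <- matrix(0L, n_an, m); A2 <- matrix(0L, n_an, m)
            for (i in seq_len(n_an)) {
                if (sire_i[i] == 0L) {
                    p <- p_breed[bl, an_breed[i]]
                    seed1 <- stats::rbinom(1L, 1L, p)
                    seed2 <- stats::rbinom(1L, 1L, p)
                    if (m > 1L) {
                        f1 <- stats::rbinom(m - 1L, 1L, cfg$ld_flip_prob)
                        f2 <- stats::rbinom(m - 1L, 1L, cfg$ld_flip_prob)
                        A1[i, ] <- c(seed1, xor(seed1, f1))
                        A2[i, ] <- c(seed2, xor(seed2, f2))
                    } else {
                        A1[i, 1L] <- seed1; A2[i, 1L] <- seed2
                    }
                } else {
                    A1[i, ] <- if (stats::runif(1) < 0.5) A1[sire_i[i], ]
                               else A2[sire_i[i], ]
                    A2[i, ] <- if (stats::runif(1) < 0.5) A1[dam_i[i], ]
                               else A2[dam_i[i], ]
                }
            }
            rows <- row0 + seq_len(m)
            dosage[rows, ] <- t(A1[idx[samples], , drop = FALSE] +
                                A2[idx[samples], , drop = FALSE])
            ch <- as.character(block_chrom[bl])
            offs <- cumsum(sample(500:5000, m, replace = TRUE))
            pos[rows] <- as.integer(next_start[ch] + offs)
            next_start[ch] <- next_start[ch] + offs[m] +
                sample(200000:800000, 1L)
            chrom[rows] <- ch
            block_of[rows] <- bl
            row0 <- row0 + m
        }
        gm <- GenotypeMatrix(dosage, chrom = chrom, pos = pos)
        ba <- data.frame(snp_id = rownames(dosage), block = block_of,
                         stringsAsFactors = FALSE)
        attr(gm, "block_assignments") <- ba[match(rownames(gm), ba$snp_id), ]
        gm
    })
}

#' Simulate study covariates
#'
#' Breed follows group membership (group 1 first); batch has 5 levels
#' (sampling days) assigned at random; RIN is drawn around 8 (sd 0.5) and
#' age around 170 days (sd 10), typical for slaughter-weight pigs.
#'
#' @param cfg a \code{\link{simulationConfig}}
#' @param samples character vector of sample ids, group 1 first
#' @return data.frame (sample_id, breed, batch, rin, age_days); the factor
#'   levels and draw parameters are attached as attribute \code{params}.
#' @export
simulateCovariates <- function(cfg, samples) {
    stopifnot(inherits(cfg, "SimulationConfig"),
              length(samples) == cfg$n_samples_group1 + cfg$n_samples_group2)
    withSeed(deriveSeed(cfg$seed, "covariates"), {
        n <- length(samples)
        breed <- factor(rep(c("Duroc", "Landrace"),
                            c(cfg$n_samples_group1, cfg$n_samples_group2)))
        batch <- factor(sample(rep_len(paste0("batch", 1:5), n)),
                        levels = paste0("batch", 1:5))
        rin <- round(pmin(pmax(stats::rnorm(n, 8, 0.5), 5), 10), 1)
        age <- as.integer(round(stats::rnorm(n, 170, 10)))
        out <- data.frame(sample_id = samples, breed = breed, batch = batch,
                          rin = rin, age_days = age, stringsAsFactors = FALSE)
        attr(out, "params") <- list(rin_mean = 8, rin_sd = 0.5,
                                    age_mean = 170, age_sd = 10,
                                    n_batches = 5)
        out
    })
}

#' Wrap a count matrix and gene coordinates as a SummarizedExperiment
#'
#' @param counts genes-by-samples integer matrix with dimnames
#' @param chrom,start,end gene coordinates (1-based, inclusive)
#' @param colData optional per-sample data.frame
#' @return a RangedSummarizedExperiment with assay \code{"counts"}
#' @export
makeCountExperiment <- function(counts, chrom, start, end, colData = NULL) {
    counts <- as.matrix(counts)
    stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
              length(chrom) == nrow(counts), all(start <= end),
              all(counts >= 0))
    rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, end = end))
    names(rr) <- rownames(counts)
    args <- list(assays = list(counts = counts), rowRanges = rr)
    if (!is.null(colData)) args$colData <- S4Vectors::DataFrame(colData)
    do.call(SummarizedExperiment::SummarizedExperiment, args)
}

#' Simulate RNA-seq counts with planted genetic effects
#'
#' Counts are negative-binomial on a log2 link. The linear predictor of
#' gene g in sample s is baseline + planted genotype effects (dosage-linear
#' or carrier-shift) + per-gene covariate effects + an optional polygenic
#' term with covariance proportional to the pedigree A-matrix; library-size
#' offsets enter multiplicatively. Planted effect sizes are expressed in
#' units of the per-gene residual log2 sd (\code{effect_size_sd}), so an
#' acceptance check of "effects at 2 residual sd" is a direct configuration.
#'
#' @param cfg a \code{\link{simulationConfig}}
#' @param genotypes a \linkS4class{GenotypeMatrix} over the study samples
#' @param covariates output of \code{\link{simulateCovariates}}
#' @param pedigree output of \code{\link{simulatePedigree}}
#' @return list with \code{counts} (RangedSummarizedExperiment, assay
#'   \code{"counts"}, gene coordinates, covariates in \code{colData}) and
#'   \code{truth} (the planted-effect ledger: planted_pairs,
#'   covariate_effects, block_assignments, noise_sd, library_sizes).
#' @export
simulateExpression <- function(cfg, genotypes, covariates, pedigree) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    G <- dosages(genotypes)
    samples <- colnames(G)
    if (!identical(samples, covariates$sample_id))
        stop("dimension mismatch on axis 'samples': genotype columns and ",
             "covariate rows disagree")
    if (!all(samples %in% pedigree$animal))
        stop("dimension mismatch on axis 'samples': study samples missing ",
             "from pedigree")
    n <- length(samples); ng <- cfg$n_genes
    smap <- snpMap(genotypes)
    withSeed(deriveSeed(cfg$seed, "expression"), {
        gene_id <- sprintf("gene%04d", seq_len(ng))
        ## genes share the genomic span the SNPs cover, so cis pairs occur
        ## at a realistic rate
        span <- tapply(smap$pos, smap$chrom, max)
        g_chrom <- sample(names(span), ng, replace = TRUE)
        g_start <- as.integer(stats::runif(ng, 1, span[g_chrom] + 1e6))
        g_len <- as.integer(stats::runif(ng, 1e3, 1e5))

        ## choose planted pairs; cis genes are relocated next to their SNP,
        ## trans genes moved off the SNP's chromosome if needed
        n_eff <- cfg$n_cis_effects + cfg$n_trans_effects
        planted <- NULL
        category_genes <- if (cfg$target_category_fraction > 0)
            sort(sample.int(ng, round(cfg$target_category_fraction * ng)))
        else integer(0)
        if (n_eff > 0) {
            ## cis targets uniform; trans targets drawn with configurable
            ## preference for the designated category
            cis_genes <- if (cfg$n_cis_effects > 0)
                sample.int(ng, cfg$n_cis_effects) else integer(0)
            pool <- setdiff(seq_len(ng), cis_genes)
            trans_genes <- integer(0)
            if (cfg$n_trans_effects > 0) {
                inA <- intersect(pool, category_genes)
                outA <- setdiff(pool, category_genes)
                if (length(inA) && cfg$target_category_bias != 1) {
                    ## stratified allocation: category members carry
                    ## bias-times the per-gene chance of a trans effect
                    q <- length(inA) / length(pool)
                    b <- cfg$target_category_bias
                    nA <- round(cfg$n_trans_effects * b * q / (1 + (b - 1) * q))
                    nA <- min(max(nA, 0L), length(inA),
                              cfg$n_trans_effects)
                    nO <- cfg$n_trans_effects - nA
                    if (nO > length(outA))
                        stop("not enough genes outside the category")
                    trans_genes <- c(sample(inA, nA), sample(outA, nO))
                } else {
                    trans_genes <- sample(pool, cfg$n_trans_effects)
                }
            }
            eff_genes <- c(cis_genes, trans_genes)
            eff_snps <- sample.int(nrow(smap), n_eff, replace = n_eff > nrow(smap))
            cls <- rep(c("cis", "trans"),
                       c(cfg$n_cis_effects, cfg$n_trans_effects))
            for (i in seq_len(n_eff)) {
                gi <- eff_genes[i]; si <- eff_snps[i]
                if (cls[i] == "cis") {
                    g_chrom[gi] <- smap$chrom[si]
                    g_start[gi] <- as.integer(max(1, smap$pos[si] +
                                                      round(stats::runif(1, -5e5, 5e5))))
                } else if (g_chrom[gi] == smap$chrom[si]) {
                    others <- setdiff(as.character(seq_len(cfg$n_chromosomes)),
                                      smap$chrom[si])
                    if (!length(others))
                        stop("cannot place a trans gene with a single chromosome")
                    g_chrom[gi] <- sample(others, 1L)
                }
            }
            type <- ifelse(stats::runif(n_eff) < cfg$dominant_fraction,
                           "dominant", "linear")
            sign <- sample(c(-1, 1), n_eff, replace = TRUE)
            planted <- data.frame(snp_id = smap$snp_id[eff_snps],
                                  gene_id = gene_id[eff_genes],
                                  gene_idx = eff_genes, snp_idx = eff_snps,
                                  sign = sign, type = type, class = cls,
                                  stringsAsFactors = FALSE)
        }
        g_end <- g_start + g_len

        ## baseline expression and residual sd per gene
        b <- stats::runif(ng, cfg$baseline_log2cpm[1], cfg$baseline_log2cpm[2])
        mu_bar <- cfg$mean_library_size / 1e6 * 2^b
        ## residual sd of log2 expression: counting + overdispersion noise
        ## plus the polygenic component; planted effects are scaled to it
        noise_sd <- sqrt((1 / mu_bar + cfg$dispersion) / log(2)^2 +
                             cfg$polygenic_sd^2)

        ## covariate design pieces (standardised numeric covariates)
        sds <- cfg$covariate_effect_sds
        breed_ind <- as.numeric(covariates$breed == levels(covariates$breed)[2])
        batch_ind <- stats::model.matrix(~ 0 + batch, data = covariates)
        zscale <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x)
                              else x * 0
        rin_z <- zscale(covariates$rin)
        age_z <- zscale(covariates$age_days)
        beta_breed <- stats::rnorm(ng, 0, sds[["breed"]])
        beta_batch <- matrix(stats::rnorm(ng * ncol(batch_ind), 0, sds[["batch"]]),
                             ng, ncol(batch_ind))
        beta_rin <- stats::rnorm(ng, 0, sds[["rin"]])
        beta_age <- stats::rnorm(ng, 0, sds[["age"]])

        eta <- outer(beta_breed, breed_ind) + beta_batch %*% t(batch_ind) +
            outer(beta_rin, rin_z) + outer(beta_age, age_z)

        ## polygenic term: per-gene MVN(0, polygenic_sd^2 * A)
        if (cfg$polygenic_sd > 0) {
            A <- aMatrix(truncatePedigree(pedigree, samples,
                                          cfg$n_generations), samples)
            U <- chol(A + diag(1e-8, n))
            eta <- eta + cfg$polygenic_sd *
                (matrix(stats::rnorm(ng * n), ng, n) %*% U)
        }

        ## planted genetic effects
        if (!is.null(planted)) {
            planted$effect_size <- planted$sign * cfg$effect_size_sd *
                noise_sd[planted$gene_idx]
            for (i in seq_len(nrow(planted))) {
                gdos <- G[planted$snp_idx[i], ]
                x <- if (planted$type[i] == "dominant") as.numeric(gdos > 0) else gdos
                eta[planted$gene_idx[i], ] <- eta[planted$gene_idx[i], ] +
                    planted$effect_size[i] * x
            }
            ## record the class implied by the final coordinates at the 1 Mb rule
            planted$class <- classifyCisTrans(
                smap$chrom[planted$snp_idx], smap$pos[planted$snp_idx],
                g_chrom[planted$gene_idx], g_start[planted$gene_idx],
                g_end[planted$gene_idx])
        }

        lib <- exp(stats::rnorm(n, log(cfg$mean_library_size), 0.15))
        mu <- (2^(b + eta)) * rep(lib / 1e6, each = ng)
        cnt <- if (cfg$dispersion > 0)
            stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
        else stats::rpois(length(mu), mu)
        counts <- matrix(as.integer(cnt), ng, n,
                         dimnames = list(gene_id, samples))

        se <- makeCountExperiment(counts, g_chrom, g_start, g_end,
                                  colData = covariates)
        truth <- list(
            planted_pairs = if (is.null(planted)) planted else
                planted[, c("snp_id", "gene_id", "effect_size", "type", "class")],
            covariate_effects = list(breed = beta_breed, batch = beta_batch,
                                     rin = beta_rin, age = beta_age),
            block_assignments = attr(genotypes, "block_assignments"),
            category_genes = gene_id[category_genes],
            noise_sd = stats::setNames(noise_sd, gene_id),
            baseline_log2cpm = stats::setNames(b, gene_id),
            library_sizes = stats::setNames(lib, samples))
        list(counts = se, truth = truth)
    })
}

#' Simulate a complete study
#'
#' Runs \code{\link{simulatePedigree}}, \code{\link{simulateGenotypes}},
#' \code{\link{simulateCovariates}} and \code{\link{simulateExpression}}
#' under seeds derived from \code{cfg$seed}.
#'
#' @param cfg a \code{\link{simulationConfig}}
#' @return list (config, pedigree, genotypes, covariates, counts, truth)
#' @export
simulateStudy <- function(cfg) {
    ped <- simulatePedigree(cfg)
    gt <- simulateGenotypes(cfg, ped)
    cov <- simulateCovariates(cfg, attr(ped, "samples"))
    ex <- simulateExpression(cfg, gt, cov, ped)
    list(config = cfg, pedigree = ped, genotypes = gt, covariates = cov,
         counts = ex$counts, truth = ex$truth)
}

#' Write a simulated study to plain-text files
#'
#' Writes genotypes, counts, covariates, pedigree and the truth ledger in
#' the package's TSV/CSV formats (see the readers in \code{io.R}).
#'
#' @param study output of \code{\link{simulateStudy}}
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of file paths written
#' @export
writeSimulatedStudy <- function(study, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
               counts = file.path(dir, "counts.tsv"),
               covariates = file.path(dir, "covariates.tsv"),
               pedigree = file.path(dir, "pedigree.csv"),
               truth = file.path(dir, "truth_pairs.tsv"))
    writeGenotypesTsv(study$genotypes, paths["genotypes"])
    writeCountsTsv(study$counts, paths["counts"])
    utils::write.table(study$covariates, paths["covariates"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.csv(study$pedigree, paths["pedigree"], quote = FALSE,
                     row.names = FALSE)
    tp <- study$truth$planted_pairs
    if (is.null(tp)) tp <- data.frame(snp_id = character(), gene_id = character(),
                                      effect_size = numeric(), type = character(),
                                      class = character())
    utils::write.table(tp, paths["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(paths)
}
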