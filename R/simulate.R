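#' Simulation configuration
#'
#' Bundles the parameters of the synthetic cohort generator. Defaults encode
#' the study conditions the downstream estimators are validated against: a
#' two-batch cohort, SNP panel with uniform minor-allele frequencies on
#' [0.05, 0.5] and moderate within-block linkage disequilibrium, a
#' zero-inflated compositional microbiome with a mixed detection-rate
#' profile, and a trait decomposed into batch, polygenic, microbial and
#' residual components at heritability `h2_true` and microbiability
#' `m2_true`.
#'
#' @param n_individuals cohort size.
#' @param n_snps number of simulated SNPs.
#' @param maf_range pair of allele frequencies in (0, 0.5].
#' @param ld_rho per-block autocorrelation of the latent haplotype Gaussians,
#'   in [0, 1).
#' @param block_size SNPs per LD block.
#' @param n_asvs number of simulated taxa.
#' @param detection_profile list of `c(fraction_of_taxa, detection_rate)`
#'   pairs; fractions must sum to 1, rates in (0, 1]. The default mixes a
#'   core of near-ubiquitous taxa with intermediate and rare fractions, the
#'   shape 16S surveys of gut segments typically show.
#' @param overdispersion standard deviation of the log-normal abundance noise.
#' @param h2_true,m2_true variance fractions in [0, 1], summing to at most 1.
#' @param n_causal_snps,n_causal_taxa causal feature counts (`NULL` for
#'   n_causal_taxa means all taxa contribute).
#' @param batch_levels number of rearing batches (fixed effect levels).
#' @param batch_sd standard deviation of the batch effects on the trait.
#' @param seed master seed; per-table child streams are derived from it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_individuals = 600, n_snps = 2000,
                       maf_range = c(0.05, 0.5), ld_rho = 0.3,
                       block_size = 100, n_asvs = 300,
                       detection_profile = list(c(0.25, 0.95),
                                                c(0.35, 0.55),
                                                c(0.40, 0.20)),
                       overdispersion = 1.5,
                       h2_true = 0.25, m2_true = 0,
                       n_causal_snps = 200, n_causal_taxa = NULL,
                       batch_levels = 2, batch_sd = 0.5, seed = 1) {
  check_fraction(h2_true, "h2_true"); check_fraction(m2_true, "m2_true")
  if (h2_true + m2_true > 1)
    stop("h2_true + m2_true must not exceed 1", call. = FALSE)
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing pair within (0, 0.5]", call. = FALSE)
  if (ld_rho < 0 || ld_rho >= 1)
    stop("ld_rho must be in [0, 1)", call. = FALSE)
  prof <- do.call(rbind, lapply(detection_profile, function(p) {
    if (length(p) != 2L) stop("detection_profile entries are (fraction, rate) pairs",
                              call. = FALSE)
    p
  }))
  if (abs(sum(prof[, 1]) - 1) > 1e-8)
    stop("detection_profile taxon fractions must sum to 1", call. = FALSE)
  if (any(prof[, 2] <= 0 | prof[, 2] > 1))
    stop("detection rates must lie in (0, 1]", call. = FALSE)
  structure(list(n_individuals = n_individuals, n_snps = n_snps,
                 maf_range = maf_range, ld_rho = ld_rho,
                 block_size = block_size, n_asvs = n_asvs,
                 detection_profile = detection_profile,
                 overdispersion = overdispersion,
                 h2_true = h2_true, m2_true = m2_true,
                 n_causal_snps = n_causal_snps, n_causal_taxa = n_causal_taxa,
                 batch_levels = batch_levels, batch_sd = batch_sd,
                 seed = seed),
            class = "sim_config")
}

#' Simulate diploid SNP dosages with block-wise linkage disequilibrium
#'
#' Genotypes arise from a Gaussian copula: within each block of consecutive
#' SNPs, each of the two haplotype-level latent Gaussian vectors follows an
#' AR(1) process with autocorrelation `ld_rho`; thresholding a latent value
#' at the normal quantile of the SNP's allele frequency yields the allele,
#' and the diploid dosage is the sum of the two haplotypes. Blocks (and
#' chromosomes) are independent.
#'
#' @param n individuals (`>= 2`).
#' @param m SNPs (`>= 1`).
#' @param maf_range pair of allele frequencies in (0, 0.5]; per-SNP
#'   frequencies are drawn uniformly on this interval.
#' @param ld_rho adjacent-SNP latent correlation in [0, 1).
#' @param block_size SNPs per independent LD block.
#' @param n_chr number of chromosomes the panel is split across.
#' @param seed RNG seed.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5), ld_rho = 0,
                               block_size = 100, n_chr = 1, seed = 1) {
  stopifnot(n >= 2, m >= 1)
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5))
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  if (ld_rho < 0 || ld_rho >= 1)
    stop("ld_rho must be in [0, 1)", call. = FALSE)
  with_seed(seed, {
    maf <- stats::runif(m, maf_range[1], maf_range[2])
    chrom <- ceiling(seq_len(m) / ceiling(m / n_chr))
    # block index: consecutive runs of block_size, never spanning chromosomes
    blk <- ave(seq_len(m), chrom,
               FUN = function(i) (seq_along(i) - 1L) %/% block_size)
    blk_id <- paste(chrom, blk)
    thr <- stats::qnorm(maf)
    dos <- matrix(0L, n, m)
    for (b in unique(blk_id)) {
      idx <- which(blk_id == b)
      for (hap in 1:2) {
        Z <- matrix(stats::rnorm(n * length(idx)), n, length(idx))
        if (ld_rho > 0 && length(idx) > 1) {
          for (j in 2:length(idx))
            Z[, j] <- ld_rho * Z[, j - 1] + sqrt(1 - ld_rho^2) * Z[, j]
        }
        dos[, idx] <- dos[, idx] +
          (Z <= matrix(thr[idx], n, length(idx), byrow = TRUE))
      }
    }
    pos <- ave(seq_len(m), chrom, FUN = seq_along) * 1000L
    meta <- data.frame(id = sprintf("snp%d", seq_len(m)),
                       chrom = as.character(chrom), pos = pos,
                       ref = "A", alt = "G")
    genotype_matrix(dos, meta, sample_ids = sprintf("S%04d", seq_len(n)))
  })
}

#' Simulate a zero-inflated compositional microbiome
#'
#' Each taxon receives a target detection rate from `detection_profile`; a
#' sample carries the taxon with that probability, and carried abundances are
#' log-normal around a taxon-specific baseline with standard deviation
#' `overdispersion` on the log scale. Rows are closed to sum 1 over detected
#' taxa. A sample detecting nothing is given its most prevalent taxon so
#' closure is always defined.
#'
#' @param n samples (`>= 2`).
#' @param k taxa (`>= 1`).
#' @param detection_profile list of `c(fraction, rate)` pairs (fractions sum
#'   to 1, rates in (0, 1]).
#' @param overdispersion log-scale abundance noise SD.
#' @param seed RNG seed.
#' @return An [abundance_table()].
#' @export
simulate_microbiome <- function(n, k,
                                detection_profile = list(c(0.25, 0.95),
                                                         c(0.35, 0.55),
                                                         c(0.40, 0.20)),
                                overdispersion = 1.5, seed = 1) {
  stopifnot(n >= 2, k >= 1)
  if (length(detection_profile) == 0)
    stop("detection_profile must not be empty", call. = FALSE)
  prof <- do.call(rbind, detection_profile)
  if (abs(sum(prof[, 1]) - 1) > 1e-8 || any(prof[, 2] <= 0 | prof[, 2] > 1))
    stop("detection_profile fractions must sum to 1 with rates in (0, 1]",
         call. = FALSE)
  with_seed(seed, {
    counts <- round(prof[, 1] * k)
    counts[length(counts)] <- k - sum(counts[-length(counts)])
    rate <- rep(prof[, 2], counts)
    baseline <- stats::rnorm(k, 0, 2)           # taxon abundance heterogeneity
    present <- matrix(stats::rbinom(n * k, 1, rep(rate, each = n)), n, k)
    empty <- rowSums(present) == 0
    if (any(empty)) present[empty, which.max(rate)] <- 1L
    raw <- present * exp(matrix(baseline, n, k, byrow = TRUE) +
                           overdispersion * matrix(stats::rnorm(n * k), n, k))
    rel <- raw / rowSums(raw)
    meta <- data.frame(id = sprintf("ASV%04d", seq_len(k)), level = "ASV")
    abundance_table(rel, meta, sample_ids = sprintf("S%04d", seq_len(n)))
  })
}

#' Simulate a phenotype over genotype and microbiome layers
#'
#' The quantitative trait is the sum of batch fixed effects, a polygenic
#' component (Gaussian effects on standardized causal dosages), a microbial
#' component (Gaussian effects on standardized taxon abundances) and a
#' Gaussian residual. Each random component is rescaled so its realized
#' sample variance equals the configured fraction of the total non-fixed
#' variance (`h2_true`, `m2_true`, and `1 - h2_true - m2_true`). The ordinal
#' grade is the tertile coding {0, 1, 2} of the latent trait, mimicking a
#' three-level histology score.
#'
#' @param G a [genotype_matrix()].
#' @param A an [abundance_table()] sharing `G`'s sample IDs, or `NULL` when
#'   `m2_true = 0`.
#' @param cfg a [sim_config()].
#' @return A `cohort_bundle` list: `genotypes`, `abundances`, `phenotypes`
#'   (data.frame `sample_id`, `trait`, `grade`, `batch`), and `truths`
#'   (realized variance fractions plus the causal effect vectors).
#' @export
simulate_phenotype <- function(G, A = NULL, cfg = sim_config()) {
  n <- nrow(G$dosages)
  if (cfg$m2_true > 0 && is.null(A))
    stop("m2_true > 0 requires an abundance table", call. = FALSE)
  if (!is.null(A) && !identical(G$sample_ids, A$sample_ids))
    stop("genotype and abundance sample IDs differ (alignment error)",
         call. = FALSE)
  with_seed(derive_seed(cfg$seed, 3L), {
    batch <- factor(sample(seq_len(cfg$batch_levels), n, replace = TRUE))
    beff <- stats::rnorm(cfg$batch_levels, 0, cfg$batch_sd)
    fixed <- beff[as.integer(batch)]

    scale_to <- function(x, v) {
      s <- stats::sd(x)
      if (s == 0) return(x)
      x / s * sqrt(v)
    }

    g <- rep(0, n); beta_g <- NULL; causal_snps <- NULL
    if (cfg$h2_true > 0) {
      sds <- apply(G$dosages, 2, stats::sd)
      poly <- which(sds > 0)
      causal_snps <- sort(sample(poly, min(cfg$n_causal_snps, length(poly))))
      Z <- scale(G$dosages[, causal_snps, drop = FALSE])
      beta_g <- stats::rnorm(length(causal_snps))
      g <- scale_to(drop(Z %*% beta_g), cfg$h2_true)
    }

    mcomp <- rep(0, n); beta_m <- NULL; causal_taxa <- NULL
    if (cfg$m2_true > 0) {
      sds <- apply(A$rel_abundance, 2, stats::sd)
      avail <- which(sds > 0)
      n_ct <- if (is.null(cfg$n_causal_taxa)) length(avail)
              else min(cfg$n_causal_taxa, length(avail))
      causal_taxa <- sort(sample(avail, n_ct))
      Zm <- scale(A$rel_abundance[, causal_taxa, drop = FALSE])
      beta_m <- stats::rnorm(n_ct)
      mcomp <- scale_to(drop(Zm %*% beta_m), cfg$m2_true)
    }

    e <- scale_to(stats::rnorm(n), 1 - cfg$h2_true - cfg$m2_true)
    y <- fixed + g + mcomp + e

    tot <- stats::var(g + mcomp + e)
    grade <- as.integer(cut(y, breaks = stats::quantile(y, c(0, 1/3, 2/3, 1)),
                            include.lowest = TRUE)) - 1L
    pheno <- data.frame(sample_id = G$sample_ids, trait = y, grade = grade,
                        batch = batch)
    truths <- list(h2_realized = stats::var(g) / tot,
                   m2_realized = stats::var(mcomp) / tot,
                   causal_snps = causal_snps, beta_g = beta_g,
                   causal_taxa = causal_taxa, beta_m = beta_m,
                   batch_effects = beff)
    structure(list(genotypes = G, abundances = A, phenotypes = pheno,
                   truths = truths),
              class = "cohort_bundle")
  })
}

#' Simulate a full cohort from a configuration
#'
#' Convenience wrapper generating genotypes, microbiome and phenotypes from
#' one [sim_config()], with per-table child seeds derived from the master
#' seed.
#'
#' @param cfg a [sim_config()].
#' @return A `cohort_bundle` (see [simulate_phenotype()]).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  G <- simulate_genotypes(cfg$n_individuals, cfg$n_snps, cfg$maf_range,
                          cfg$ld_rho, cfg$block_size,
                          seed = derive_seed(cfg$seed, 1L))
  A <- simulate_microbiome(cfg$n_individuals, cfg$n_asvs,
                           cfg$detection_profile, cfg$overdispersion,
                           seed = derive_seed(cfg$seed, 2L))
  simulate_phenotype(G, A, cfg)
}

#' Simulate an expression count matrix with planted eQTL
#'
#' Counts for each gene are negative-binomial around
#' `exp(baseline + effect * standardized dosage)` for any planted effect,
#' supporting cis and trans eQTL power and calibration studies.
#'
#' @param G a [genotype_matrix()].
#' @param gene_annotation data.frame with columns `gene_id`, `chrom`, `tss`
#'   (1-based), optionally `strand` and `length` (bp; generated if absent).
#' @param eqtl_plan data.frame with columns `gene_id`, `variant_id`,
#'   `effect` (log-scale per dosage SD), `mode` (`"cis"`/`"trans"`), or
#'   `NULL` for a global null.
#' @param base_log_mean mean of the per-gene baseline log expression.
#' @param dispersion negative-binomial size parameter.
#' @param seed RNG seed.
#' @return List with `counts` (genes x samples integer matrix), `lengths`
#'   (bp), and the annotation.
#' @export
simulate_expression <- function(G, gene_annotation, eqtl_plan = NULL,
                                base_log_mean = log(200), dispersion = 10,
                                seed = 1) {
  n <- nrow(G$dosages)
  ng <- nrow(gene_annotation)
  if (!is.null(eqtl_plan)) {
    if (!all(eqtl_plan$gene_id %in% gene_annotation$gene_id))
      stop("eqtl_plan references unknown genes", call. = FALSE)
    if (!all(eqtl_plan$variant_id %in% G$variant_meta$id))
      stop("eqtl_plan references unknown variants", call. = FALSE)
  }
  with_seed(seed, {
    baseline <- stats::rnorm(ng, base_log_mean, 1)
    eta <- matrix(baseline, ng, n)
    if (!is.null(eqtl_plan)) {
      for (r in seq_len(nrow(eqtl_plan))) {
        gi <- match(eqtl_plan$gene_id[r], gene_annotation$gene_id)
        vi <- match(eqtl_plan$variant_id[r], G$variant_meta$id)
        x <- G$dosages[, vi]
        x[is.na(x)] <- mean(x, na.rm = TRUE)
        if (stats::sd(x) == 0) next
        eta[gi, ] <- eta[gi, ] + eqtl_plan$effect[r] * drop(scale(x))
      }
    }
    counts <- matrix(stats::rnbinom(ng * n, mu = exp(eta), size = dispersion),
                     ng, n, dimnames = list(gene_annotation$gene_id,
                                            G$sample_ids))
    lengths <- if ("length" %in% names(gene_annotation)) gene_annotation$length
               else round(stats::runif(ng, 500, 10000))
    names(lengths) <- gene_annotation$gene_id
    list(counts = counts, lengths = lengths, annotation = gene_annotation)
  })
}
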