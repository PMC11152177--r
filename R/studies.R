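#' Heritability parameter-recovery study
#'
#' Repeatedly simulates a cohort at a known heritability (polygenic trait on
#' an LD-structured SNP panel, batch fixed effects, no microbial component)
#' and re-estimates it by GRM REML with the batch covariate. The vector of
#' estimates summarizes the estimator's bias and spread under the stated
#' conditions.
#'
#' @param h2_true simulated heritability.
#' @param n_rep replicate cohorts.
#' @param n,m,n_causal cohort size, SNP count, causal SNP count.
#' @param seed master seed; replicate i uses a derived child seed.
#' @return Numeric vector of `n_rep` REML estimates.
#' @export
recover_h2 <- function(h2_true, n_rep = 30, n = 600, m = 2000,
                       n_causal = 200, seed = 1) {
  vapply(seq_len(n_rep), function(i) {
    cfg <- sim_config(n_individuals = n, n_snps = m, h2_true = h2_true,
                      m2_true = 0, n_causal_snps = n_causal,
                      seed = derive_seed(seed, 100 + i))
    b <- simulate_cohort(cfg)
    estimate_h2(b$phenotypes$trait,
                data.frame(batch = b$phenotypes$batch),
                build_grm(b$genotypes))$ratio
  }, numeric(1))
}

#' Microbiability parameter-recovery study
#'
#' Repeatedly simulates a cohort at a known microbiability (trait built from
#' standardized taxon abundances over a zero-inflated compositional
#' microbiome, no genetic component) and re-estimates it by MRM REML with
#' batch and leading genetic principal-component covariates.
#'
#' @param m2_true simulated microbiability.
#' @param n_rep replicate cohorts.
#' @param n,k,m cohort size, taxon count, SNP count (for the PC covariates).
#' @param n_pcs genetic PCs included as covariates.
#' @param seed master seed.
#' @return Numeric vector of `n_rep` REML estimates.
#' @export
recover_m2 <- function(m2_true, n_rep = 30, n = 600, k = 300, m = 1000,
                       n_pcs = 5, seed = 2) {
  vapply(seq_len(n_rep), function(i) {
    cfg <- sim_config(n_individuals = n, n_snps = m, n_asvs = k,
                      h2_true = 0, m2_true = m2_true,
                      seed = derive_seed(seed, 300 + i))
    b <- simulate_cohort(cfg)
    mrm <- build_mrm(filter_asvs(b$abundances))
    pcs <- genetic_pcs(build_grm(b$genotypes), k = n_pcs)
    estimate_m2(b$phenotypes$trait,
                data.frame(batch = b$phenotypes$batch, pcs$pcs),
                mrm)$ratio
  }, numeric(1))
}

#' Permutation-null microbiability study
#'
#' Simulates one cohort whose trait is independent of the microbiome
#' (`h2 = m2 = 0`) and runs the phenotype-permutation test, returning the
#' full [permute_m2()] result; the mean of the permuted estimates is the
#' expected microbiability under no true microbial signal.
#'
#' @param n cohort size.
#' @param k taxon count.
#' @param n_perm permutations.
#' @param seed master seed.
#' @return A `permutation_result`.
#' @export
permutation_null_study <- function(n = 500, k = 300, n_perm = 200, seed = 3) {
  cfg <- sim_config(n_individuals = n, n_snps = 200, n_asvs = k,
                    h2_true = 0, m2_true = 0, seed = derive_seed(seed, 400L))
  b <- simulate_cohort(cfg)
  mrm <- build_mrm(filter_asvs(b$abundances))
  X <- build_design(data.frame(batch = b$phenotypes$batch), n)
  permute_m2(b$phenotypes$trait, X, mrm, n_perm = n_perm,
             seed = derive_seed(seed, 401L))
}
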