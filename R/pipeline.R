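#' Default analysis configuration
#'
#' Thresholds mirror the standard QC and mapping settings of the analysis:
#' call rates above 90%, MAF above 1%, ASV prevalence/abundance filters
#' (1%, 1e-6), detection strata at 60%/30%, a 1 Mb cis window, a 5 Mb trans
#' exclusion, simpleM with c = 0.995, and alpha = 0.05. Unknown keys are
#' rejected.
#'
#' @param ... overrides for any default key.
#' @return Named list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    sample_call_rate = 0.9, snp_call_rate = 0.9, maf_min = 0.01,
    asv_min_sample_fraction = 0.01, asv_min_mean_abundance = 1e-6,
    detect_high = 0.6, detect_low = 0.3,
    cis_window = 1e6, trans_exclusion = 5e6, trans_maf = 0.05,
    simplem_c = 0.995, simplem_block = 1000, alpha = 0.05,
    sparse_cutoff = 0.05, n_pcs = 5, n_perm = 0, seed = 1,
    out_dir = NULL, sim = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "analysis_config")
}

#' Load an analysis configuration from YAML
#'
#' @param path YAML file; keys as in [analysis_config()].
#' @return `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  do.call(analysis_config, yaml::read_yaml(path))
}

.stage <- function(manifest, name, files, t0) {
  manifest$stages[[name]] <- list(
    outputs = as.list(tools::md5sum(files)),
    seconds = round(as.numeric(Sys.time()) - t0, 3))
  manifest
}

#' Run the end-to-end analysis on a synthetic cohort
#'
#' Orchestrates the stages in dependency order: cohort generation, genotype
#' and taxon QC, GRM/MRM construction, genetic PCs, REML heritability and
#' microbiability (with an optional permutation null), mixed-model GWAS
#' with simpleM thresholds, and detection-stratified taxon associations.
#' Every stage writes TSV outputs to `out_dir` and records md5 checksums
#' and wall-clock time in the JSON manifest, so a rerun with the same
#' configuration reproduces identical checksums for the deterministic
#' stages.
#'
#' @param config an [analysis_config()]; `config$sim` holds the
#'   [sim_config()] for the synthetic cohort and `config$out_dir` the
#'   output directory.
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = analysis_config()) {
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(tool = "hologreml",
                   version = as.character(utils::packageVersion("hologreml")),
                   seed = config$seed, stages = list())
  cfg_path <- out("config.yaml")
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, TRUE)], cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))

  sim <- if (is.null(config$sim)) sim_config(seed = config$seed)
         else config$sim
  t0 <- as.numeric(Sys.time())
  bundle <- simulate_cohort(sim)
  write_dosage_tsv(bundle$genotypes, out("genotypes.tsv"))
  write_abundance_tsv(bundle$abundances, out("abundances.tsv"))
  utils::write.table(bundle$phenotypes, out("phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- .stage(manifest, "simulate",
                     out(c("genotypes.tsv", "abundances.tsv",
                           "phenotypes.tsv")), t0)

  t0 <- as.numeric(Sys.time())
  G <- filter_genotypes(bundle$genotypes, config$sample_call_rate,
                        config$snp_call_rate, config$maf_min)
  A <- filter_asvs(bundle$abundances, config$asv_min_sample_fraction,
                   config$asv_min_mean_abundance)
  grm <- build_grm(G)
  mrm <- build_mrm(A)
  pcs <- genetic_pcs(grm, k = config$n_pcs)
  write_kernel(grm, out("grm.tsv"))
  write_kernel(mrm, out("mrm.tsv"))
  manifest <- .stage(manifest, "kernels", out(c("grm.tsv", "mrm.tsv")), t0)

  keep <- match(G$sample_ids, bundle$phenotypes$sample_id)
  ph <- bundle$phenotypes[keep, ]
  covar_h2 <- data.frame(batch = ph$batch)
  covar_m2 <- data.frame(batch = ph$batch, pcs$pcs)

  t0 <- as.numeric(Sys.time())
  h2 <- estimate_h2(ph$trait, covar_h2, grm)
  m2 <- estimate_m2(ph$trait, covar_m2, mrm)
  vc <- data.frame(component = c("h2", "m2"),
                   ratio = c(h2$ratio, m2$ratio),
                   se = c(h2$se_ratio, m2$se_ratio),
                   loglik = c(h2$loglik, m2$loglik),
                   p_perm = NA_real_)
  if (config$n_perm > 0) {
    pm <- permute_m2(ph$trait, build_design(covar_m2, nrow(ph)), mrm,
                     n_perm = config$n_perm,
                     seed = derive_seed(config$seed, 10L))
    vc$p_perm[vc$component == "m2"] <- pm$p_value
  }
  utils::write.table(vc, out("varcomp.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- .stage(manifest, "varcomp", out("varcomp.tsv"), t0)

  t0 <- as.numeric(Sys.time())
  gw <- lmm_gwas(ph$trait, covar_m2, G, grm)
  m_eff <- simple_m_eff(G, config$simplem_c, config$simplem_block)
  thr <- significance_thresholds(m_eff, config$alpha)
  utils::write.table(gw, out("gwas.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(m_eff = thr$m_eff,
                            genome_wide = thr$genome_wide,
                            suggestive = thr$suggestive),
                       out("thresholds.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest <- .stage(manifest, "gwas", out(c("gwas.tsv", "thresholds.json")),
                     t0)

  t0 <- as.numeric(Sys.time())
  strata <- stratify_taxa(A, config$detect_high, config$detect_low)
  assoc <- taxon_phenotype_association(A, ph$grade, strata)
  div <- alpha_diversity(A)
  utils::write.table(assoc, out("taxon_assoc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(div, out("alpha_diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- .stage(manifest, "microbe",
                     out(c("taxon_assoc.tsv", "alpha_diversity.tsv")), t0)

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
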