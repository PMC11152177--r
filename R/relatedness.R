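#' Filter genotypes by call rate and minor-allele frequency
#'
#' Applies the standard variant-level QC: samples whose call rate is not
#' strictly above `sample_call_rate` are removed first, then SNPs failing
#' the call-rate or MAF rule (both strict inequalities) are removed, and
#' allele frequencies are recomputed on the surviving set. The applied
#' thresholds and removal counts are attached as the `"qc_log"` attribute.
#'
#' @param G a [genotype_matrix()].
#' @param sample_call_rate keep samples with call rate strictly above this.
#' @param snp_call_rate keep SNPs with call rate strictly above this.
#' @param maf_min keep SNPs with minor-allele frequency strictly above this.
#' @return The filtered [genotype_matrix()].
#' @export
filter_genotypes <- function(G, sample_call_rate = 0.9, snp_call_rate = 0.9,
                             maf_min = 0.01) {
  check_fraction(sample_call_rate, "sample_call_rate")
  check_fraction(snp_call_rate, "snp_call_rate")
  check_fraction(maf_min, "maf_min")
  X <- G$dosages
  scr <- rowMeans(!is.na(X))
  keep_s <- scr > sample_call_rate
  if (!any(keep_s))
    stop(sprintf("all %d samples removed at sample call rate > %g",
                 nrow(X), sample_call_rate), call. = FALSE)
  X <- X[keep_s, , drop = FALSE]
  vcr <- colMeans(!is.na(X))
  af <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep_v <- vcr > snp_call_rate & maf > maf_min & !is.na(maf)
  out <- genotype_matrix(X[, keep_v, drop = FALSE],
                         G$variant_meta[keep_v, , drop = FALSE],
                         sample_ids = G$sample_ids[keep_s])
  attr(out, "qc_log") <- list(
    order = c("samples", "snps"),
    sample_call_rate = sample_call_rate, snp_call_rate = snp_call_rate,
    maf_min = maf_min,
    samples_removed = sum(!keep_s), snps_removed = sum(!keep_v))
  out
}

#' Filter taxa by prevalence and mean relative abundance
#'
#' Removes taxa present in fewer than `min_sample_fraction` of samples or
#' with mean relative abundance below `min_mean_abundance`. Rows are *not*
#' re-closed to 1: retained taxa keep their original relative scale.
#'
#' @param A an [abundance_table()].
#' @param min_sample_fraction minimum detection fraction (taxa strictly below
#'   are removed).
#' @param min_mean_abundance minimum mean relative abundance.
#' @return The filtered [abundance_table()] (rows may no longer sum to 1).
#' @export
filter_asvs <- function(A, min_sample_fraction = 0.01,
                        min_mean_abundance = 1e-6) {
  stopifnot(min_sample_fraction >= 0, min_mean_abundance >= 0)
  det <- colMeans(A$rel_abundance > 0)
  mab <- colMeans(A$rel_abundance)
  keep <- det >= min_sample_fraction & mab >= min_mean_abundance
  if (!any(keep)) warning("no taxa survive filtering", call. = FALSE)
  vals <- A$rel_abundance[, keep, drop = FALSE]
  out <- structure(list(rel_abundance = vals,
                        taxon_meta = transform(
                          A$taxon_meta[keep, , drop = FALSE],
                          detection = colMeans(vals > 0)),
                        sample_ids = A$sample_ids),
                   class = "abundance_table")
  attr(out, "qc_log") <- list(min_sample_fraction = min_sample_fraction,
                              min_mean_abundance = min_mean_abundance,
                              taxa_removed = sum(!keep))
  out
}

#' Build the genomic relationship matrix
#'
#' VanRaden-type GRM: for individuals i, j over N non-monomorphic SNPs,
#' \deqn{g_{ij} = \frac{1}{N} \sum_v
#'   \frac{(x_{iv} - 2\bar p_v)(x_{jv} - 2\bar p_v)}{2\bar p_v(1-\bar p_v)}}
#' with \eqn{\bar p_v} the observed alternate-allele frequency. Missing
#' dosages are mean-imputed to \eqn{2\bar p_v} before centering (so they
#' contribute zero). The GRM is invariant to flipping which allele is
#' counted, since centering and the variance denominator are both
#' flip-symmetric.
#'
#' @param G a [genotype_matrix()].
#' @return A [relationship_matrix()] of kind `"GRM"`.
#' @export
build_grm <- function(G) {
  X <- G$dosages
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1 & !is.na(p)
  if (!any(poly)) stop("all SNPs monomorphic; GRM undefined", call. = FALSE)
  if (any(!poly))
    warning(sprintf("%d monomorphic SNP(s) excluded from the GRM", sum(!poly)),
            call. = FALSE)
  X <- X[, poly, drop = FALSE]; p <- p[poly]
  W <- sweep(X, 2L, 2 * p, `-`)
  W[is.na(W)] <- 0                          # mean imputation after centering
  W <- sweep(W, 2L, sqrt(2 * p * (1 - p)), `/`)
  K <- tcrossprod(W) / ncol(W)
  relationship_matrix(force_sym(K), G$sample_ids, kind = "GRM")
}

#' Sparsify a GRM at a relatedness cutoff
#'
#' Off-diagonal entries below `cutoff` are set to zero; the diagonal is
#' preserved. This is the sparse-GRM construction used by fastGWA-style
#' mixed models on cohorts of mostly unrelated individuals.
#'
#' @param K a [relationship_matrix()] of kind `"GRM"`.
#' @param cutoff relatedness threshold (`>= 0`).
#' @return A [relationship_matrix()] of kind `"sparse-GRM"`.
#' @export
sparsify_grm <- function(K, cutoff = 0.05) {
  stopifnot(cutoff >= 0)
  V <- kernel_values(K)
  d <- diag(V)
  V[V < cutoff] <- 0
  diag(V) <- d
  relationship_matrix(V, if (inherits(K, "relationship_matrix")) K$sample_ids
                         else rownames(V),
                      kind = "sparse-GRM")
}

#' Build the microbial relationship matrix
#'
#' Taxon abundances are zero-centered and scaled to unit *population*
#' variance (divisor n), and the MRM is the average cross-product
#' \deqn{m_{ij} = \frac{1}{N_s}\sum_a z_{ia} z_{ja}.}
#' The population divisor makes the mean diagonal exactly 1. Zero-variance
#' taxa are excluded with a warning.
#'
#' @param A an [abundance_table()].
#' @return A [relationship_matrix()] of kind `"MRM"`.
#' @export
build_mrm <- function(A) {
  X <- A$rel_abundance
  st <- standardize_cols(X, population = TRUE)
  ok <- st$sd > 0
  if (!any(ok)) stop("all taxa constant; MRM undefined", call. = FALSE)
  if (any(!ok))
    warning(sprintf("%d zero-variance taxa excluded from the MRM", sum(!ok)),
            call. = FALSE)
  Z <- st$z[, ok, drop = FALSE]
  M <- tcrossprod(Z) / ncol(Z)
  relationship_matrix(force_sym(M), A$sample_ids, kind = "MRM")
}

#' Genetic principal components
#'
#' Principal components of the standardized dosage matrix, computed from the
#' eigendecomposition of the GRM (component i is the i-th eigenvector scaled
#' by the root of its eigenvalue). Used as population-structure covariates.
#' Sign convention: the largest-magnitude loading of each component is
#' positive.
#'
#' @param G a [genotype_matrix()] or a precomputed [relationship_matrix()].
#' @param k number of components (`< n`).
#' @return List with `pcs` (n x k matrix) and `varexp` (fraction of kernel
#'   trace per component, non-increasing).
#' @export
genetic_pcs <- function(G, k = 5) {
  K <- if (inherits(G, "relationship_matrix")) kernel_values(G)
       else kernel_values(build_grm(G))
  n <- nrow(K)
  if (k >= n) stop("k must be smaller than the number of individuals",
                   call. = FALSE)
  e <- eigen(K, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  flip <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  V <- sweep(V, 2L, ifelse(flip == 0, 1, flip), `*`)
  pcs <- sweep(V, 2L, sqrt(vals[seq_len(k)]), `*`)
  rownames(pcs) <- rownames(K)
  colnames(pcs) <- paste0("PC", seq_len(k))
  list(pcs = pcs, varexp = vals[seq_len(k)] / sum(vals))
}
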