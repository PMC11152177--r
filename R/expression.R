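#' Transcripts per million
#'
#' Length-normalized within-sample abundance: reads per base, rescaled so
#' each sample sums to one million.
#'
#' @param counts genes x samples nonnegative integer matrix.
#' @param lengths gene lengths in bp (`> 0`).
#' @return genes x samples TPM matrix.
#' @export
tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("gene lengths must be positive", call. = FALSE)
  rate <- counts / lengths
  sweep(rate, 2L, colSums(rate), `/`) * 1e6
}

# Upper-quartile of the count distribution scaled by library size; used to
# pick the TMM reference sample.
.factor_quantile <- function(counts, lib, p = 0.75) {
  apply(counts, 2, function(x) stats::quantile(x, probs = p)) / lib
}

# Trimmed mean of M-values for one sample against the reference.
.tmm_pair <- function(obs, ref, n_o, n_r, logratio_trim = 0.3,
                      sum_trim = 0.05) {
  logR <- log2((obs / n_o) / (ref / n_r))
  absE <- (log2(obs / n_o) + log2(ref / n_r)) / 2
  v <- (n_o - obs) / n_o / obs + (n_r - ref) / n_r / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1;      hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
          rank(absE) >= loS & rank(absE) <= hiS
  f <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Between-sample normalization factors: the reference is the sample whose
#' upper-quartile count (library-size scaled) is closest to the mean; for
#' every other sample the factor is the doubly trimmed (30% on log-ratios M,
#' 5% on average log-abundance A), precision-weighted mean of M against the
#' reference; factors are rescaled to multiply to one.
#'
#' @param counts genes x samples count matrix.
#' @param logratio_trim,sum_trim trim fractions on M and A.
#' @return Named vector of positive scaling factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  f75 <- .factor_quantile(counts, lib)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    if (i == ref) return(1)
    .tmm_pair(counts[, i], counts[, ref], lib[i], lib[ref],
              logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Filter and normalize an expression matrix
#'
#' Keeps genes whose TPM and raw read count both clear their thresholds in
#' at least `sample_fraction` of samples, then computes TMM scaling factors
#' on the retained counts and recomputes TPM over the retained genes.
#'
#' @param counts genes x samples count matrix.
#' @param lengths gene lengths in bp.
#' @param tpm_min minimum TPM (default 0.1).
#' @param read_min minimum raw reads (default 6).
#' @param sample_fraction minimum fraction of samples meeting both
#'   thresholds (default 0.2).
#' @return `expression_matrix` list: `counts`, `lengths`, `tpm`,
#'   `tmm_factors`, `n_removed`.
#' @export
filter_normalize_expression <- function(counts, lengths, tpm_min = 0.1,
                                        read_min = 6, sample_fraction = 0.2) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("gene lengths must be positive", call. = FALSE)
  tp <- tpm(counts, lengths)
  ok <- rowMeans(tp >= tpm_min & counts >= read_min) >= sample_fraction
  counts_f <- counts[ok, , drop = FALSE]
  lengths_f <- lengths[ok]
  structure(list(counts = counts_f, lengths = lengths_f,
                 tpm = tpm(counts_f, lengths_f),
                 tmm_factors = tmm_factors(counts_f),
                 n_removed = sum(!ok)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d filtered out)\n",
              nrow(x$counts), ncol(x$counts), x$n_removed))
  invisible(x)
}

# Regression-scale expression: log2 of TMM-scaled counts-per-million + 1,
# standardized per gene. Returns genes x samples.
expression_regression_scale <- function(E) {
  eff_lib <- colSums(E$counts) * E$tmm_factors
  cpm <- sweep(E$counts, 2L, eff_lib, `/`) * 1e6
  le <- log2(cpm + 1)
  t(scale(t(le)))
}

#' Principal components of the normalized expression matrix
#'
#' Hidden-factor covariates for eQTL mapping: the leading sample-space
#' principal components of the standardized log-expression matrix.
#'
#' @param E an `expression_matrix`.
#' @param k number of components.
#' @return samples x k matrix.
#' @export
expression_pcs <- function(E, k = 3) {
  Z <- expression_regression_scale(E)
  Z <- Z[stats::complete.cases(Z), , drop = FALSE]
  pr <- stats::prcomp(t(Z), center = TRUE, scale. = FALSE)
  pcs <- pr$x[, seq_len(min(k, ncol(pr$x))), drop = FALSE]
  colnames(pcs) <- paste0("ePC", seq_len(ncol(pcs)))
  pcs
}
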