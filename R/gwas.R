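#' Mixed-model single-variant association scan
#'
#' Fits \eqn{y = W\alpha + x\beta + u + \varepsilon} with
#' \eqn{u \sim N(0, \sigma^2_k K)} per SNP. Variance components are
#' estimated once under the null (no SNP) by [reml_fit()] and reused for
#' every variant (the EMMAX approximation); the model is then whitened by
#' the eigendecomposition of \eqn{\hat\sigma^2_k K + \hat\sigma^2_e I} and
#' each SNP is tested by generalized least squares. Two p-values are
#' reported: the likelihood-ratio p (`p_lrt`, statistic
#' \eqn{2(\ell_1-\ell_0)} at the null variance components, chi-square 1 df —
#' the headline `p_value`) and the Wald p from the t reference with per-SNP
#' residual variance (`p_wald`). With `K = I` and no covariates the Wald p
#' reduces exactly to ordinary least squares.
#'
#' Missing dosages are mean-imputed; monomorphic SNPs yield `NA` statistics
#' with `flag = "monomorphic"`.
#'
#' @param y numeric trait vector.
#' @param W covariate data.frame or matrix (`NULL` for intercept only);
#'   intercept added if a data.frame is given.
#' @param G a [genotype_matrix()].
#' @param K kernel aligned with `y` ([relationship_matrix()] or matrix).
#' @param exact re-estimate the variance components per SNP with the variant
#'   in the fixed effects (GEMMA-style); slower, default off.
#' @return data.frame with one row per SNP: `id`, `chrom`, `pos`, `af`,
#'   `beta`, `se`, `lrt_stat`, `p_value` (LRT), `p_wald`, `flag`.
#' @export
lmm_gwas <- function(y, W = NULL, G, K, exact = FALSE) {
  X <- G$dosages
  n <- length(y)
  stopifnot(nrow(X) == n)
  Kv <- kernel_values(K)
  Wd <- if (is.data.frame(W) || is.null(W)) build_design(W, n) else as.matrix(W)

  if (max(abs(Kv - diag(n))) < 1e-10) {
    # identity kernel: the polygenic term is indistinguishable from the
    # residual, so the model degenerates to ordinary least squares
    r0 <- qr.resid(qr(Wd), y)
    null_fit <- list(sigma2_kernel = 0,
                     sigma2_resid = sum(r0^2) / (n - ncol(Wd)))
  } else {
    null_fit <- reml_fit(y, Wd, Kv, se = FALSE)
  }
  ek <- eigen(force_sym(Kv), symmetric = TRUE)
  lam <- null_fit$sigma2_kernel * pmax(ek$values, 0) + null_fit$sigma2_resid
  Ai <- 1 / sqrt(lam)
  ty <- Ai * drop(crossprod(ek$vectors, y))
  tW <- Ai * crossprod(ek$vectors, Wd)

  # residualize the whitened trait and dosages against covariates
  qw <- qr(tW)
  ry <- qr.resid(qw, ty)
  rss0 <- sum(ry^2)

  af <- colMeans(X, na.rm = TRUE) / 2
  Ximp <- X
  if (anyNA(Ximp)) {
    for (j in which(colSums(is.na(Ximp)) > 0))
      Ximp[is.na(Ximp[, j]), j] <- 2 * af[j]
  }
  tX <- Ai * crossprod(ek$vectors, Ximp)
  rX <- qr.resid(qw, tX)

  xx <- colSums(rX^2)
  xy <- drop(crossprod(rX, ry))
  mono <- apply(Ximp, 2, stats::sd) == 0 | xx < 1e-12
  beta <- xy / xx
  rss1 <- pmax(rss0 - beta^2 * xx, 0)
  p_alt <- ncol(Wd) + 1
  df <- n - p_alt
  sigma2 <- rss1 / df
  se_ <- sqrt(sigma2 / xx)
  tstat <- beta / se_
  p_wald <- 2 * stats::pt(-abs(tstat), df)
  lrt <- rss0 - rss1
  p_lrt <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  if (exact) {
    for (j in which(!mono)) {
      fit_j <- reml_fit(y, cbind(Wd, Ximp[, j]), Kv, se = FALSE)
      lam_j <- fit_j$sigma2_kernel * pmax(ek$values, 0) + fit_j$sigma2_resid
      Aij <- 1 / sqrt(lam_j)
      tyj <- Aij * drop(crossprod(ek$vectors, y))
      tWj <- Aij * crossprod(ek$vectors, Wd)
      txj <- Aij * drop(crossprod(ek$vectors, Ximp[, j]))
      qwj <- qr(tWj)
      ryj <- qr.resid(qwj, tyj); rxj <- qr.resid(qwj, txj)
      xxj <- sum(rxj^2)
      beta[j] <- sum(rxj * ryj) / xxj
      r1 <- sum(ryj^2) - beta[j]^2 * xxj
      se_[j] <- sqrt(max(r1, 0) / df / xxj)
      lrt[j] <- sum(ryj^2) - r1
      p_lrt[j] <- stats::pchisq(lrt[j], 1, lower.tail = FALSE)
      p_wald[j] <- 2 * stats::pt(-abs(beta[j] / se_[j]), df)
    }
  }

  beta[mono] <- se_[mono] <- lrt[mono] <- p_lrt[mono] <- p_wald[mono] <- NA_real_
  data.frame(id = G$variant_meta$id, chrom = G$variant_meta$chrom,
             pos = G$variant_meta$pos, af = af,
             beta = beta, se = se_, lrt_stat = lrt,
             p_value = p_lrt, p_wald = p_wald,
             flag = ifelse(mono, "monomorphic", ""),
             row.names = NULL)
}

#' Effective number of independent tests (simpleM)
#'
#' Splits the panel into blocks of consecutive SNPs (never spanning
#' chromosomes), computes each block's SNP-SNP composite correlation matrix,
#' and counts the minimal number of leading eigenvalues whose cumulative sum
#' reaches a fraction `c` of the total. The effective test count
#' \eqn{M_{eff}} is the sum over blocks; it never exceeds the SNP count.
#' Missing dosages are mean-imputed; a single-SNP block contributes 1.
#'
#' @param G a [genotype_matrix()].
#' @param c variance fraction threshold in (0, 1] (default 0.995, the
#'   conventional default of the eigenvalue-correction method).
#' @param block_size SNPs per block.
#' @return Integer effective number of tests.
#' @export
simple_m_eff <- function(G, c = 0.995, block_size = 1000) {
  if (c <= 0 || c > 1) stop("c must be in (0, 1]", call. = FALSE)
  X <- G$dosages
  af <- colMeans(X, na.rm = TRUE) / 2
  if (anyNA(X)) {
    for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- 2 * af[j]
  }
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  X <- X[, keep, drop = FALSE]
  chrom <- G$variant_meta$chrom[keep]
  if (ncol(X) == 0) return(0L)
  blk <- ave(seq_len(ncol(X)), chrom,
             FUN = function(i) (seq_along(i) - 1L) %/% block_size)
  blk_id <- paste(chrom, blk)
  m_eff <- 0L
  for (b in unique(blk_id)) {
    idx <- which(blk_id == b)
    if (length(idx) == 1L) { m_eff <- m_eff + 1L; next }
    R <- stats::cor(X[, idx, drop = FALSE])
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    m_eff <- m_eff + which(cumsum(ev) / sum(ev) >= c)[1]
  }
  as.integer(m_eff)
}

#' Genome-wide and suggestive significance thresholds
#'
#' Effective-test Bonferroni thresholds: genome-wide
#' \eqn{\alpha / M_{eff}} and suggestive \eqn{1 / M_{eff}}.
#'
#' @param m_eff effective number of tests (`>= 1`).
#' @param alpha family-wise error rate (default 0.05).
#' @return List of class `threshold_set`: `m_eff`, `genome_wide`,
#'   `suggestive`.
#' @export
significance_thresholds <- function(m_eff, alpha = 0.05) {
  if (m_eff < 1) stop("m_eff must be at least 1", call. = FALSE)
  check_fraction(alpha, "alpha", lo = 1e-12, hi = 1)
  structure(list(m_eff = m_eff, genome_wide = alpha / m_eff,
                 suggestive = 1 / m_eff),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("M_eff = %s: genome-wide %.3g, suggestive %.3g\n",
              format(x$m_eff, big.mark = ","), x$genome_wide, x$suggestive))
  invisible(x)
}
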