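# Shared machinery: residualize a matrix against covariates and run
# column-by-column simple regressions of each response on each predictor.
.residualize <- function(M, C) {
  if (is.null(C)) return(scale(M, scale = FALSE))
  qr.resid(qr(cbind(1, C)), M)
}

# Per-pair regression of each column of Ey (n x g) on each column of Ex
# (n x m), both already residualized against the same covariates.
# Returns list of g x m matrices beta, se, p with df residual degrees.
.pairwise_lm <- function(Ey, Ex, df) {
  xx <- colSums(Ex^2)
  cross <- crossprod(Ey, Ex)                    # g x m
  beta <- sweep(cross, 2L, xx, `/`)
  yy <- colSums(Ey^2)
  rss <- pmax(outer(yy, rep(1, ncol(Ex))) - beta^2 *
                matrix(xx, nrow(beta), ncol(beta), byrow = TRUE), 0)
  se <- sqrt(sweep(rss / df, 2L, xx, `/`))
  tt <- beta / se
  p <- 2 * stats::pt(-abs(tt), df)
  list(beta = beta, se = se, p = p)
}

#' Map cis eQTL with permutation empirical p-values
#'
#' For each gene, tests every variant whose position lies within `window`
#' bp of the transcription start site (inclusive) by linear regression of
#' standardized log2 expression on dosage, adjusting for covariates. The
#' per-gene empirical p-value compares the observed minimum nominal p
#' against minima from permutations of the expression vector:
#' \eqn{p_{emp} = (1 + \#\{\min p_{perm} \le \min p_{obs}\})/(n_{perm}+1)}.
#'
#' @param E an `expression_matrix` (see [filter_normalize_expression()]).
#' @param G a [genotype_matrix()] with samples matching `E`'s columns.
#' @param tss data.frame with `gene_id`, `chrom`, `tss` (1-based position).
#'   Genes without an annotated TSS are skipped with a warning.
#' @param window cis window half-width in bp (default 1e6).
#' @param covariates samples x q numeric matrix (e.g. genetic PCs, batch
#'   dummies, expression PCs), or `NULL`.
#' @param n_perm permutations per gene for the empirical p (default 200).
#' @param seed RNG seed.
#' @return data.frame of records: `gene_id`, `variant_id`, `distance`
#'   (signed bp, pos - TSS), `mode = "cis"`, `beta`, `se`, `p_value`,
#'   `emp_p` (per-gene, repeated across the gene's records).
#' @export
map_cis_eqtl <- function(E, G, tss, window = 1e6, covariates = NULL,
                         n_perm = 200, seed = 1) {
  stopifnot(window > 0)
  genes <- rownames(E$counts)
  missing_tss <- setdiff(genes, tss$gene_id)
  if (length(missing_tss) > 0)
    warning(sprintf("%d gene(s) without annotated TSS skipped",
                    length(missing_tss)), call. = FALSE)
  genes <- intersect(genes, tss$gene_id)
  Z <- expression_regression_scale(E)            # genes x samples
  X <- G$dosages
  af <- colMeans(X, na.rm = TRUE) / 2
  if (anyNA(X)) for (j in which(colSums(is.na(X)) > 0))
    X[is.na(X[, j]), j] <- 2 * af[j]
  n <- nrow(X)
  q <- if (is.null(covariates)) 0 else ncol(covariates)
  df <- n - 2 - q
  Ex_all <- .residualize(X, covariates)
  out <- vector("list", length(genes))
  with_seed(seed, {
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      ann <- tss[tss$gene_id == g, ][1, ]
      sel <- which(G$variant_meta$chrom == ann$chrom &
                     abs(G$variant_meta$pos - ann$tss) <= window)
      if (length(sel) == 0) next
      yv <- Z[g, ]
      if (anyNA(yv) || stats::sd(yv) == 0) next
      Ey <- .residualize(matrix(yv, ncol = 1), covariates)
      fit <- .pairwise_lm(Ey, Ex_all[, sel, drop = FALSE], df)
      obs_min <- min(fit$p[1, ], na.rm = TRUE)
      perm_min <- vapply(seq_len(n_perm), function(i) {
        yp <- yv[sample.int(n)]
        Ep <- .residualize(matrix(yp, ncol = 1), covariates)
        min(.pairwise_lm(Ep, Ex_all[, sel, drop = FALSE], df)$p[1, ],
            na.rm = TRUE)
      }, numeric(1))
      emp_p <- (1 + sum(perm_min <= obs_min)) / (n_perm + 1)
      out[[gi]] <- data.frame(
        gene_id = g, variant_id = G$variant_meta$id[sel],
        distance = G$variant_meta$pos[sel] - ann$tss, mode = "cis",
        beta = fit$beta[1, ], se = fit$se[1, ], p_value = fit$p[1, ],
        emp_p = emp_p, row.names = NULL)
    }
  })
  do.call(rbind, out)
}

#' Map trans eQTL
#'
#' Tests gene-variant pairs where the variant lies on a different
#' chromosome than the gene's TSS or more than `exclusion` bp away from it,
#' restricted to variants with MAF above `maf_min`. Nominal p-values only.
#' Variants between the cis window and the trans exclusion distance belong
#' to neither map.
#'
#' @inheritParams map_cis_eqtl
#' @param exclusion distance beyond which a same-chromosome variant is
#'   trans-eligible (default 5e6).
#' @param maf_min minimum minor-allele frequency (strict, default 0.05).
#' @return data.frame of records with `mode = "trans"` and nominal
#'   statistics.
#' @export
map_trans_eqtl <- function(E, G, tss, exclusion = 5e6, maf_min = 0.05,
                           covariates = NULL) {
  stopifnot(exclusion > 0)
  genes <- intersect(rownames(E$counts), tss$gene_id)
  Z <- expression_regression_scale(E)
  X <- G$dosages
  af <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  if (anyNA(X)) for (j in which(colSums(is.na(X)) > 0))
    X[is.na(X[, j]), j] <- 2 * af[j]
  n <- nrow(X)
  q <- if (is.null(covariates)) 0 else ncol(covariates)
  df <- n - 2 - q
  common <- which(maf > maf_min & apply(X, 2, stats::sd) > 0)
  if (length(common) == 0) return(NULL)
  Ex <- .residualize(X[, common, drop = FALSE], covariates)
  keep_g <- genes[apply(Z[genes, , drop = FALSE], 1,
                        function(z) !anyNA(z) && stats::sd(z) > 0)]
  if (length(keep_g) == 0) return(NULL)
  Ey <- .residualize(t(Z[keep_g, , drop = FALSE]), covariates)
  fit <- .pairwise_lm(Ey, Ex, df)
  out <- vector("list", length(keep_g))
  for (gi in seq_along(keep_g)) {
    ann <- tss[tss$gene_id == keep_g[gi], ][1, ]
    vm <- G$variant_meta[common, ]
    elig <- vm$chrom != ann$chrom | abs(vm$pos - ann$tss) > exclusion
    if (!any(elig)) next
    out[[gi]] <- data.frame(
      gene_id = keep_g[gi], variant_id = vm$id[elig],
      distance = ifelse(vm$chrom[elig] == ann$chrom,
                        vm$pos[elig] - ann$tss, NA_real_),
      mode = "trans", beta = fit$beta[gi, elig], se = fit$se[gi, elig],
      p_value = fit$p[gi, elig], row.names = NULL)
  }
  do.call(rbind, out)
}

#' Summary-data-based Mendelian randomization test
#'
#' Treats the top eQTL as an instrumental variable for gene expression and
#' tests whether expression mediates the variant-trait association. With
#' eQTL and GWAS z-scores \eqn{z_e = b_e/se_e}, \eqn{z_g = b_g/se_g}, the
#' effect of expression on the trait is \eqn{b_{xy} = b_g / b_e} and the
#' statistic
#' \deqn{T_{SMR} = \frac{z_e^2 z_g^2}{z_e^2 + z_g^2}}
#' is compared to a chi-square with 1 df. \eqn{T_{SMR}} is bounded above by
#' the smaller of the two squared z-scores: a weak instrument caps the
#' evidence regardless of GWAS strength.
#'
#' @param b_eqtl,se_eqtl top-eQTL effect and standard error (vectors
#'   allowed).
#' @param b_gwas,se_gwas GWAS effect and standard error at the same variant.
#' @return data.frame: `b_xy`, `t_smr`, `p_smr`, `flag`
#'   (`"zero-instrument"` when `b_eqtl = 0`, where `b_xy` is undefined and
#'   `t_smr = 0`).
#' @export
smr_test <- function(b_eqtl, se_eqtl, b_gwas, se_gwas) {
  if (any(se_eqtl <= 0) || any(se_gwas <= 0))
    stop("standard errors must be positive", call. = FALSE)
  z_e <- b_eqtl / se_eqtl
  z_g <- b_gwas / se_gwas
  denom <- z_e^2 + z_g^2
  t_smr <- ifelse(denom == 0, 0, (z_e^2 * z_g^2) / denom)
  b_xy <- ifelse(b_eqtl == 0, NA_real_, b_gwas / b_eqtl)
  data.frame(b_xy = b_xy, t_smr = t_smr,
             p_smr = stats::pchisq(t_smr, df = 1, lower.tail = FALSE),
             flag = ifelse(b_eqtl == 0, "zero-instrument", ""),
             row.names = NULL)
}

#' Batch SMR over matched GWAS and eQTL summary statistics
#'
#' For each gene, selects its top eQTL (smallest nominal p), joins the GWAS
#' record for the same variant, runs [smr_test()], and attaches
#' Benjamini-Hochberg q-values over all tested genes.
#'
#' @param eqtl data.frame of eQTL records (`gene_id`, `variant_id`, `beta`,
#'   `se`, `p_value`).
#' @param gwas data.frame of GWAS records (`id`, `beta`, `se`).
#' @return data.frame: `gene_id`, `variant_id`, `b_xy`, `t_smr`, `p_smr`,
#'   `fdr_q`, `flag`.
#' @export
run_smr <- function(eqtl, gwas) {
  top <- do.call(rbind, lapply(split(eqtl, eqtl$gene_id),
                               function(d) d[which.min(d$p_value), ]))
  m <- match(top$variant_id, gwas$id)
  ok <- !is.na(m)
  top <- top[ok, ]; m <- m[ok]
  res <- smr_test(top$beta, top$se, gwas$beta[m], gwas$se[m])
  out <- data.frame(gene_id = top$gene_id, variant_id = top$variant_id,
                    res, row.names = NULL)
  out$fdr_q <- bh_fdr(out$p_smr)
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (a validated wrapper around [stats::p.adjust()]).
#'
#' @param p vector of p-values in [0, 1].
#' @return Vector of q-values, `q >= p` element-wise, capped at 1.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
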