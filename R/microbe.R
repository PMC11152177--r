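#' Alpha diversity (Shannon and Gini-Simpson)
#'
#' Row-renormalizes the abundance table over its retained taxa and computes
#' Shannon entropy (nats) and the Gini-Simpson index \eqn{1 - \sum p^2} per
#' sample via `vegan`. Samples whose row is all zero get `NA` with a
#' warning.
#'
#' @param A an [abundance_table()].
#' @return data.frame: `sample_id`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(A) {
  X <- A$rel_abundance
  rs <- rowSums(X)
  if (any(rs == 0))
    warning(sprintf("%d sample(s) with zero total abundance; NA returned",
                    sum(rs == 0)), call. = FALSE)
  P <- X / ifelse(rs == 0, NA, rs)
  data.frame(sample_id = A$sample_ids,
             shannon = vegan::diversity(P, index = "shannon"),
             simpson = vegan::diversity(P, index = "simpson"),
             row.names = NULL)
}

#' Detection-rate stratification of taxa
#'
#' Assigns each taxon exactly one coding based on its detection rate (the
#' fraction of samples with nonzero abundance): detected in at least `high`
#' of samples, analyzed quantitatively with zeros recoded to missing
#' (`"quantitative-with-NA"`); detected in `[low, high)`, dichotomized to
#' presence/absence (`"binary"`); below `low`, excluded.
#'
#' @param A an [abundance_table()].
#' @param high upper detection threshold (default 0.6).
#' @param low lower detection threshold (default 0.3).
#' @return data.frame: `taxon`, `level`, `detection`, `coding`.
#' @export
stratify_taxa <- function(A, high = 0.6, low = 0.3) {
  if (!(low >= 0 && low < high && high <= 1))
    stop("need 0 <= low < high <= 1", call. = FALSE)
  det <- colMeans(A$rel_abundance > 0)
  coding <- ifelse(det >= high, "quantitative-with-NA",
                   ifelse(det >= low, "binary", "excluded"))
  data.frame(taxon = A$taxon_meta$id, level = A$taxon_meta$level,
             detection = det, coding = coding, row.names = NULL)
}

#' Detection-stratified taxon-phenotype association
#'
#' Correlates each retained taxon with the phenotype under its stratum
#' coding: high-detection taxa quantitatively with zeros as missing
#' (pairwise deletion), mid-detection taxa as presence/absence. The
#' correlation method for the high-detection stratum follows
#' `method_policy`: `"rank"` uses Spearman throughout (the convention for
#' ordinal traits); `"pearson-high"` uses Pearson for the
#' quantitative-with-NA stratum and Spearman for the binary stratum (the
#' convention for continuous biochemical indicators). Q-values are
#' Benjamini-Hochberg within each taxonomic level.
#'
#' @param A an [abundance_table()].
#' @param phenotype numeric vector aligned with `A`'s samples.
#' @param strata output of [stratify_taxa()] (computed with defaults when
#'   `NULL`).
#' @param method_policy `"rank"` or `"pearson-high"`.
#' @param min_pairs minimum complete pairs to report an estimate
#'   (default 10).
#' @return data.frame of `taxon`, `level`, `detection`, `coding`, `method`,
#'   `estimate`, `p_value`, `q_value`, `flag`.
#' @export
taxon_phenotype_association <- function(A, phenotype, strata = NULL,
                                        method_policy = c("rank",
                                                          "pearson-high"),
                                        min_pairs = 10) {
  method_policy <- match.arg(method_policy)
  n <- nrow(A$rel_abundance)
  stopifnot(length(phenotype) == n)
  if (stats::sd(phenotype, na.rm = TRUE) == 0)
    stop("phenotype is constant", call. = FALSE)
  if (is.null(strata)) strata <- stratify_taxa(A)
  res <- lapply(seq_len(nrow(strata)), function(j) {
    coding <- strata$coding[j]
    base <- data.frame(taxon = strata$taxon[j], level = strata$level[j],
                       detection = strata$detection[j], coding = coding,
                       method = NA_character_, estimate = NA_real_,
                       p_value = NA_real_, flag = "")
    if (coding == "excluded") return(base)
    x <- A$rel_abundance[, j]
    if (coding == "quantitative-with-NA") {
      x[x == 0] <- NA
      method <- if (method_policy == "pearson-high") "pearson" else "spearman"
    } else {
      x <- as.numeric(x > 0)
      method <- "spearman"
    }
    ok <- !is.na(x) & !is.na(phenotype)
    base$method <- method
    if (sum(ok) < min_pairs) { base$flag <- "too-few-pairs"; return(base) }
    if (stats::sd(x[ok]) == 0) { base$flag <- "degenerate-coding"; return(base) }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], phenotype[ok], method = method, exact = FALSE))
    base$estimate <- unname(ct$estimate)
    base$p_value <- ct$p.value
    base
  })
  out <- do.call(rbind, res)
  out$q_value <- NA_real_
  for (lev in unique(out$level)) {
    sel <- out$level == lev & !is.na(out$p_value)
    if (any(sel)) out$q_value[sel] <- bh_fdr(out$p_value[sel])
  }
  out
}
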