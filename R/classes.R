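#' Construct a genotype matrix object
#'
#' Container for an individuals-by-SNPs alternate-allele dosage matrix with
#' per-variant metadata. Dosages are 0, 1, 2 or `NA` (missing call).
#'
#' @param dosages numeric matrix, individuals in rows, SNPs in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param variant_meta data.frame with one row per SNP: columns `id`, `chrom`,
#'   `pos` (1-based), `ref`, `alt`. The observed alternate-allele frequency
#'   `af` is recomputed from non-missing calls if absent.
#' @param sample_ids character vector of individual identifiers.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variant_meta, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  stopifnot(nrow(variant_meta) == ncol(dosages),
            length(sample_ids) == nrow(dosages))
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA", call. = FALSE)
  rownames(dosages) <- sample_ids
  if (is.null(colnames(dosages))) colnames(dosages) <- variant_meta$id
  variant_meta$af <- colMeans(dosages, na.rm = TRUE) / 2
  structure(list(dosages = dosages, variant_meta = variant_meta,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Construct an abundance table object
#'
#' Samples-by-taxa relative abundance table. Rows sum to 1 over detected taxa
#' at construction; downstream filters may break closure deliberately (the
#' original relative scale is retained after taxon removal).
#'
#' @param rel_abundance numeric matrix, samples in rows, taxa in columns,
#'   entries `>= 0`.
#' @param taxon_meta data.frame with one row per taxon: `id`, `level`
#'   (taxonomic level tag). Per-taxon `detection` (fraction of samples with
#'   nonzero abundance) is recomputed.
#' @param sample_ids character vector of sample identifiers.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(rel_abundance, taxon_meta = NULL,
                            sample_ids = rownames(rel_abundance)) {
  rel_abundance <- as.matrix(rel_abundance)
  if (any(rel_abundance < 0, na.rm = TRUE))
    stop("abundances must be non-negative", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(rel_abundance)))
  if (is.null(taxon_meta)) {
    ids <- colnames(rel_abundance)
    if (is.null(ids)) ids <- paste0("ASV", seq_len(ncol(rel_abundance)))
    taxon_meta <- data.frame(id = ids, level = "ASV")
  }
  stopifnot(nrow(taxon_meta) == ncol(rel_abundance),
            length(sample_ids) == nrow(rel_abundance))
  rownames(rel_abundance) <- sample_ids
  colnames(rel_abundance) <- taxon_meta$id
  taxon_meta$detection <- colMeans(rel_abundance > 0)
  structure(list(rel_abundance = rel_abundance, taxon_meta = taxon_meta,
                 sample_ids = sample_ids),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (median detection %.2f)\n",
              nrow(x$rel_abundance), ncol(x$rel_abundance),
              stats::median(x$taxon_meta$detection)))
  invisible(x)
}

#' Construct a relationship matrix object
#'
#' Symmetric n-by-n similarity kernel used as the covariance structure of a
#' random effect: a genomic relationship matrix (GRM), its sparsified form,
#' or a microbial relationship matrix (MRM).
#'
#' @param values symmetric numeric matrix.
#' @param sample_ids character vector of identifiers (row/col order).
#' @param kind one of `"GRM"`, `"sparse-GRM"`, `"MRM"`.
#' @return An object of class `relationship_matrix`.
#' @export
relationship_matrix <- function(values, sample_ids = rownames(values),
                                kind = c("GRM", "sparse-GRM", "MRM")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("kernel must be square", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-8)
    stop("kernel must be symmetric", call. = FALSE)
  values <- force_sym(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(list(values = values, sample_ids = sample_ids, kind = kind),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  n <- nrow(x$values)
  cat(sprintf("%s kernel: %d x %d, mean diagonal %.4f\n",
              x$kind, n, n, mean(diag(x$values))))
  invisible(x)
}

#' @export
dim.relationship_matrix <- function(x) dim(x$values)

# Internal: accept either a relationship_matrix or a bare matrix.
kernel_values <- function(K) {
  if (inherits(K, "relationship_matrix")) K$values else as.matrix(K)
}
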