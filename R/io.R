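#' Read genotypes from VCF or dosage TSV
#'
#' VCF GT fields map to alternate-allele dosage (0/0 -> 0, 0/1 -> 1,
#' 1/1 -> 2); half-calls and missing genotypes become `NA`. Multi-allelic
#' sites are skipped with a warning (or split if `multiallelic = "split"`,
#' counting each alternate allele separately). Positions are 1-based. The
#' dosage TSV format has samples in rows, a leading `sample_id` column and
#' one column per variant; variant metadata may ride in a sidecar file
#' written by [write_dosage_tsv()].
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage"`.
#' @param multiallelic `"skip"` (default) or `"split"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage"),
                           multiallelic = c("skip", "split")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") return(.read_vcf(path, multiallelic))
  .read_dosage_tsv(path)
}

.read_vcf <- function(path, multiallelic) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    if (multiallelic == "skip") {
      warning(sprintf("%d multi-allelic site(s) skipped", sum(multi)),
              call. = FALSE)
      v <- v[!multi, ]
      fix <- fix[!multi, , drop = FALSE]
    } else {
      fix$ALT[multi] <- vapply(strsplit(fix$ALT[multi], ","), `[`, "", 1)
    }
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  to_dosage <- function(g) {
    g <- gsub("\\|", "/", g)
    ifelse(g %in% c("0/0"), 0,
           ifelse(g %in% c("0/1", "1/0"), 1,
                  ifelse(g == "1/1", 2, NA)))
  }
  dos <- t(apply(gt, 2, to_dosage))
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = ncol(gt))
  colnames(dos) <- rownames(gt)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  meta <- data.frame(id = ids, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT)
  genotype_matrix(dos, meta, sample_ids = colnames(gt))
}

.read_dosage_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  if (names(d)[1] != "sample_id")
    stop("dosage TSV must start with a sample_id column", call. = FALSE)
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample IDs in dosage TSV", call. = FALSE)
  dos <- as.matrix(d[, -1, drop = FALSE])
  meta_path <- paste0(path, ".variants")
  meta <- if (file.exists(meta_path)) utils::read.delim(meta_path)
          else data.frame(id = colnames(dos), chrom = "1",
                          pos = seq_len(ncol(dos)), ref = "A", alt = "G")
  meta$chrom <- as.character(meta$chrom)
  genotype_matrix(dos, meta, sample_ids = as.character(d$sample_id))
}

#' Write genotypes as a minimal VCF
#'
#' VCFv4.2 with a GT FORMAT field only; missing dosages become `./.`.
#'
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  meta <- G$variant_meta
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", G$sample_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(meta)), function(v) {
    g <- G$dosages[, v]
    calls <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(meta$chrom[v], meta$pos[v], meta$id[v], meta$ref[v], meta$alt[v],
            ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write genotypes as a dosage TSV (with a variant metadata sidecar)
#'
#' @param G a [genotype_matrix()].
#' @param path output path; metadata goes to `<path>.variants`.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(G, path) {
  d <- data.frame(sample_id = G$sample_ids, G$dosages, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(G$variant_meta, paste0(path, ".variants"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a typed, validated table
#'
#' Enforces the presence of required columns, a non-duplicated ID column,
#' and numeric types where declared; violations raise errors naming the
#' offending column (and cell for type errors).
#'
#' @param path TSV path.
#' @param required character vector of required column names.
#' @param id_col name of the identifier column (checked for duplicates);
#'   `NULL` to skip.
#' @param numeric_cols columns that must parse as numeric.
#' @return data.frame.
#' @export
read_table_checked <- function(path, required = character(),
                               id_col = "sample_id",
                               numeric_cols = character()) {
  d <- utils::read.delim(path, check.names = FALSE,
                         colClasses = "character")
  miss <- setdiff(required, names(d))
  if (length(miss) > 0)
    stop(sprintf("missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!is.null(id_col) && id_col %in% names(d) &&
      anyDuplicated(d[[id_col]]))
    stop(sprintf("duplicate IDs in column '%s'", id_col), call. = FALSE)
  for (cn in intersect(numeric_cols, names(d))) {
    v <- suppressWarnings(as.numeric(d[[cn]]))
    bad <- which(is.na(v) & !(d[[cn]] %in% c("", "NA")))
    if (length(bad) > 0)
      stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                   cn, bad[1], d[[cn]][bad[1]]), call. = FALSE)
    d[[cn]] <- v
  }
  d
}

#' Write an abundance table as TSV
#'
#' Samples in rows, leading `sample_id` column, one column per taxon.
#'
#' @param A an [abundance_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(A, path) {
  d <- data.frame(sample_id = A$sample_ids, A$rel_abundance,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance table from TSV
#'
#' @param path TSV with `sample_id` column and numeric taxon columns.
#' @return An [abundance_table()].
#' @export
read_abundance_tsv <- function(path) {
  d <- read_table_checked(path, required = "sample_id")
  mat <- as.matrix(
    as.data.frame(lapply(d[, -1, drop = FALSE], as.numeric)))
  colnames(mat) <- names(d)[-1]
  abundance_table(mat, sample_ids = as.character(d$sample_id))
}

#' Write a relationship matrix
#'
#' Dense kernels go to a full TSV with sample IDs; sparse kernels to an
#' id-id-value triplet file (only nonzero entries, lower triangle including
#' the diagonal), the GCTA `.grm.sp`-like flavor.
#'
#' @param K a [relationship_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(K, path) {
  if (K$kind == "sparse-GRM") {
    idx <- which(lower.tri(K$values, diag = TRUE) & K$values != 0,
                 arr.ind = TRUE)
    d <- data.frame(id1 = K$sample_ids[idx[, 1]],
                    id2 = K$sample_ids[idx[, 2]],
                    value = K$values[idx])
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    d <- data.frame(sample_id = K$sample_ids, K$values, check.names = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read TSS annotation from GFF3 or BED
#'
#' GFF3 (1-based, `gene` features): the TSS is the `start` on the + strand
#' and the `end` on the - strand. BED (0-based half-open): TSS is
#' `start + 1` on + and `end` on -.
#'
#' @param path annotation path (`.gff`/`.gff3` or `.bed`).
#' @return data.frame: `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss <- function(path) {
  if (grepl("\\.bed$", path)) {
    d <- utils::read.delim(path, header = FALSE)
    strand <- if (ncol(d) >= 6) as.character(d[[6]]) else "+"
    data.frame(gene_id = as.character(d[[4]]), chrom = as.character(d[[1]]),
               tss = ifelse(strand == "-", d[[3]], d[[2]] + 1L),
               strand = strand)
  } else {
    d <- utils::read.delim(path, header = FALSE, comment.char = "#")
    d <- d[d[[3]] == "gene", , drop = FALSE]
    ids <- sub(".*ID=([^;]+).*", "\\1", d[[9]])
    data.frame(gene_id = ids, chrom = as.character(d[[1]]),
               tss = ifelse(d[[7]] == "-", d[[5]], d[[4]]),
               strand = as.character(d[[7]]))
  }
}
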