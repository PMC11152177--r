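test_that("genotype filters drop low call rate and low MAF variants", {
  dos <- rbind(c(0, 1, 2, NA), c(1, 1, 2, NA), c(2, 1, 2, 0),
               c(0, 1, 2, 0), c(1, 1, 2, 0), c(0, 1, 2, 0),
               c(0, 1, 2, 0), c(0, 1, 2, 0), c(0, 1, 2, 0), c(0, 1, 2, 0))
  # snp4 call rate 0.8 -> removed; snp3 has MAF 0 -> removed; snp2 (all
  # heterozygous) has MAF 0.5 and survives
  meta <- data.frame(id = paste0("s", 1:4), chrom = "1", pos = 1:4,
                     ref = "A", alt = "G")
  G <- genotype_matrix(dos, meta)
  out <- filter_genotypes(G, sample_call_rate = 0, snp_call_rate = 0.9,
                          maf_min = 0.01)
  expect_identical(out$variant_meta$id, c("s1", "s2"))
  log <- attr(out, "qc_log")
  expect_identical(log$order, c("samples", "snps"))
  expect_identical(log$snps_removed, 2L)

  # MAF 0.005 removed at 1% threshold
  dos2 <- matrix(0, 100, 2); dos2[1, 1] <- 1; dos2[1:30, 2] <- 1
  G2 <- genotype_matrix(dos2, data.frame(id = c("a", "b"), chrom = "1",
                                         pos = 1:2, ref = "A", alt = "G"))
  out2 <- filter_genotypes(G2, 0, 0, maf_min = 0.01)
  expect_identical(out2$variant_meta$id, "b")

  # all-pass input is returned unchanged
  G3 <- tiny_genotypes(n = 30, m = 20, maf_range = c(0.25, 0.35))
  out3 <- filter_genotypes(G3)
  expect_identical(out3$dosages, G3$dosages)

  # idempotence
  out4 <- filter_genotypes(out, 0, 0.9, 0.01)
  expect_identical(out4$dosages, out$dosages)
})

test_that("taxon filters apply prevalence OR abundance rules, no reclosure", {
  mat <- matrix(0, 200, 3,
                dimnames = list(NULL, c("rare", "faint", "core")))
  mat[1, 1] <- 0.5                         # detection 0.5% -> removed
  mat[, 2] <- 5e-7                         # mean 5e-7 -> removed
  mat[, 3] <- 0.1                          # kept
  A <- abundance_table(mat)
  out <- filter_asvs(A, min_sample_fraction = 0.01,
                     min_mean_abundance = 1e-6)
  expect_identical(colnames(out$rel_abundance), "core")
  expect_true(all(out$rel_abundance[, 1] == 0.1))  # not re-closed
  out2 <- filter_asvs(out, 0.01, 1e-6)             # idempotent
  expect_identical(out2$rel_abundance, out$rel_abundance)
})

test_that("GRM matches the hand-evaluated formula", {
  G <- genotype_matrix(matrix(c(0, 2, 2, 0), 2, 2),
                       data.frame(id = c("a", "b"), chrom = "1", pos = 1:2,
                                  ref = "A", alt = "G"),
                       sample_ids = c("i1", "i2"))
  K <- build_grm(G)
  expect_equal(unname(K$values), matrix(c(2, -2, -2, 2), 2, 2))

  # exhaustive one-SNP oracle over all 3x3 genotype pairs
  for (x1 in 0:2) for (x2 in 0:2) {
    dos <- matrix(c(x1, x2), 2, 1)
    p <- mean(dos) / 2
    if (p == 0 || p == 1) next
    K1 <- build_grm(genotype_matrix(dos, data.frame(id = "v", chrom = "1",
                                                    pos = 1, ref = "A",
                                                    alt = "G")))
    hand <- outer(c(x1, x2) - 2 * p, c(x1, x2) - 2 * p) / (2 * p * (1 - p))
    expect_equal(unname(K1$values), hand, tolerance = 1e-12)
  }
})

test_that("GRM of an unrelated HWE cohort has unit diagonal, zero off-diagonal", {
  G <- simulate_genotypes(500, 5000, maf_range = c(0.05, 0.5), ld_rho = 0,
                          seed = 31)
  K <- build_grm(G)
  expect_lt(abs(mean(diag(K$values)) - 1), 0.05)
  off <- K$values[upper.tri(K$values)]
  expect_lt(abs(mean(off)), 0.01)
  expect_identical(unname(K$values), unname(t(K$values)))  # exact symmetry

  # duplicated individuals have g_ij = g_ii = g_jj
  dup <- G$dosages[c(1, 1, 2:20), ]
  Gd <- genotype_matrix(dup, G$variant_meta)
  Kd <- suppressWarnings(build_grm(Gd))$values
  expect_equal(Kd[1, 2], Kd[1, 1])
  expect_equal(Kd[1, 2], Kd[2, 2])
})

test_that("GRM handles missingness and degenerate input", {
  G <- tiny_genotypes(50, 40, seed = 32)
  d <- G$dosages; d[sample(length(d), 100)] <- NA
  Gm <- genotype_matrix(d, G$variant_meta)
  K <- build_grm(Gm)
  expect_true(all(is.finite(K$values)))
  mono <- genotype_matrix(matrix(2, 5, 2),
                          data.frame(id = c("a", "b"), chrom = "1",
                                     pos = 1:2, ref = "A", alt = "G"))
  expect_error(build_grm(mono), "monomorphic")
})

test_that("sparsification zeroes small off-diagonals only", {
  K <- random_kernel(20, seed = 33)
  S <- sparsify_grm(K, cutoff = 0.05)
  expect_identical(diag(S$values), diag(K$values))
  # never increases any |entry|
  expect_true(all(abs(S$values) <= abs(K$values) + 1e-15))
  expect_identical(S$kind, "sparse-GRM")
  # specific cutoff behavior
  V <- diag(2) * 0.98; V[1, 2] <- V[2, 1] <- 0.03
  S2 <- sparsify_grm(relationship_matrix(V, c("a", "b"), "GRM"), 0.05)
  expect_identical(S2$values[1, 2], 0)
  V[1, 2] <- V[2, 1] <- 0.2
  S3 <- sparsify_grm(relationship_matrix(V, c("a", "b"), "GRM"), 0.05)
  expect_identical(S3$values[1, 2], 0.2)
  expect_identical(S3$values[1, 1], 0.98)
})

test_that("MRM matches hand fixture and standardization identities", {
  A <- abundance_table(matrix(c(0.2, 0.4), 2, 1),
                       sample_ids = c("s1", "s2"))
  M <- build_mrm(A)
  expect_equal(unname(M$values), matrix(c(1, -1, -1, 1), 2, 2),
               tolerance = 1e-12)

  A2 <- simulate_microbiome(80, 40, seed = 34)
  M2 <- build_mrm(A2)
  expect_lt(abs(mean(diag(M2$values)) - 1), 1e-9)   # forced by 1/n variance
  expect_identical(unname(M2$values), unname(t(M2$values)))

  # relabeling equivariance: permuting samples permutes rows/cols
  idx <- sample(80)
  A3 <- abundance_table(A2$rel_abundance[idx, ], A2$taxon_meta,
                        A2$sample_ids[idx])
  M3 <- build_mrm(A3)
  expect_equal(unname(M3$values), unname(M2$values[idx, idx]),
               tolerance = 1e-12)

  expect_error(build_mrm(abundance_table(matrix(0.5, 4, 2))), "constant")
})

test_that("genetic PCs are orthogonal and separate subpopulations", {
  pop1 <- simulate_genotypes(60, 300, maf_range = c(0.05, 0.2), seed = 35)
  pop2 <- simulate_genotypes(60, 300, maf_range = c(0.35, 0.5), seed = 36)
  dos <- rbind(pop1$dosages, pop2$dosages)
  G <- genotype_matrix(dos, pop1$variant_meta,
                       sample_ids = sprintf("P%03d", 1:120))
  pc <- suppressWarnings(genetic_pcs(G, k = 4))
  xp <- crossprod(pc$pcs)
  expect_lt(max(abs(xp[upper.tri(xp)])), 1e-8)
  expect_true(all(diff(pc$varexp) <= 1e-12))
  expect_lte(sum(pc$varexp), 1)
  lab <- rep(0:1, each = 60)
  expect_gt(abs(cor(pc$pcs[, 1], lab)), 0.9)
  expect_error(suppressWarnings(genetic_pcs(tiny_genotypes(10, 5), k = 10)),
               "smaller")
})
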