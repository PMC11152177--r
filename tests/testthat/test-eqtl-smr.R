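test_that("TPM columns close to one million and expression filters apply", {
  set.seed(91)
  cnt <- matrix(rnbinom(100 * 8, mu = 50, size = 5), 100, 8)
  len <- round(runif(100, 500, 5000))
  tp <- tpm(cnt, len)
  expect_lt(max(abs(colSums(tp) - 1e6)), 1e-3)

  # a gene below both thresholds everywhere is removed
  cnt2 <- rbind(cnt, low = 1)
  len2 <- c(len, 50000)          # long + 1 read -> tiny TPM
  E <- filter_normalize_expression(cnt2, len2, tpm_min = 0.1, read_min = 6,
                                   sample_fraction = 0.2)
  expect_false("low" %in% rownames(E$counts))
  expect_true(all(E$tmm_factors > 0))
  expect_error(filter_normalize_expression(cnt, rep(0, 100)), "positive")
})

test_that("TMM factors are unity for identical columns and match edgeR", {
  cnt <- matrix(rep(rpois(300, 40), 5), 300, 5)
  f <- tmm_factors(cnt)
  expect_equal(unname(f), rep(1, 5), tolerance = 1e-9)

  set.seed(92)
  cnt2 <- matrix(rnbinom(400 * 6, mu = rexp(400, 1 / 80), size = 4), 400, 6)
  cnt2[1:40, 1:2] <- cnt2[1:40, 1:2] * 4
  f2 <- tmm_factors(cnt2)
  ref <- edgeR::calcNormFactors(edgeR::DGEList(cnt2))$samples$norm.factors
  expect_equal(unname(f2), ref, tolerance = 1e-6)
})

test_that("cis window is inclusive and planted effects reach the floor p", {
  G <- simulate_genotypes(500, 50, maf_range = c(0.2, 0.5), ld_rho = 0,
                          seed = 93)
  # snp positions are 1000 * index; put the TSS so snp10 sits exactly at
  # TSS + window
  ann <- data.frame(gene_id = c("gA", "gB"), chrom = "1",
                    tss = c(5000, 30000))
  plan <- data.frame(gene_id = "gB", variant_id = "snp30", effect = 1.0,
                     mode = "cis")
  ex <- simulate_expression(G, ann, plan, seed = 94)
  E <- filter_normalize_expression(ex$counts, ex$lengths)
  cis <- map_cis_eqtl(E, G, ann, window = 5000, n_perm = 200, seed = 95)
  gA <- cis[cis$gene_id == "gA", ]
  expect_true("snp10" %in% gA$variant_id)     # distance == window included
  expect_false("snp11" %in% gA$variant_id)
  expect_true(all(abs(gA$distance) <= 5000))

  gB <- cis[cis$gene_id == "gB", ]
  expect_equal(gB$emp_p[1], 1 / 201)          # add-one floor
  expect_identical(gB$variant_id[which.min(gB$p_value)], "snp30")
})

test_that("cis empirical p-values are roughly uniform with no effects", {
  G <- simulate_genotypes(200, 60, seed = 96)
  ann <- data.frame(gene_id = paste0("g", 1:12), chrom = "1",
                    tss = seq(4000, 59000, length.out = 12))
  ex <- simulate_expression(G, ann, NULL, seed = 97)
  E <- filter_normalize_expression(ex$counts, ex$lengths)
  cis <- map_cis_eqtl(E, G, ann, window = 8000, n_perm = 60, seed = 98)
  emp <- unique(cis[, c("gene_id", "emp_p")])$emp_p
  expect_gt(mean(emp), 0.2)                   # no pile-up at the floor
  expect_true(all(emp > 0))
})

test_that("trans eligibility excludes the near-TSS gap and different chromosomes qualify", {
  G <- simulate_genotypes(300, 80, n_chr = 2, maf_range = c(0.2, 0.5),
                          seed = 99)
  ann <- data.frame(gene_id = paste0("g", 1:5), chrom = "1",
                    tss = c(1000, 12000, 25000, 31000, 39000))
  ex <- simulate_expression(G, ann, NULL, seed = 100)
  E <- filter_normalize_expression(ex$counts, ex$lengths)
  tr_all <- map_trans_eqtl(E, G, ann, exclusion = 20000, maf_min = 0.05)
  tr <- tr_all[tr_all$gene_id == "g1", ]
  vm <- G$variant_meta[match(tr$variant_id, G$variant_meta$id), ]
  same <- vm$chrom == "1"
  expect_true(all(abs(vm$pos[same] - 1000) > 20000))
  expect_true(any(vm$chrom == "2"))
  cis_all <- map_cis_eqtl(E, G, ann, window = 5000, n_perm = 10, seed = 101)
  cis <- cis_all[cis_all$gene_id == "g1", ]
  # disjoint partitions; the 5kb-20kb gap belongs to neither
  expect_length(intersect(paste(cis$gene_id, cis$variant_id),
                          paste(tr$gene_id, tr$variant_id)), 0)
  gap <- G$variant_meta$id[G$variant_meta$chrom == "1" &
                             abs(G$variant_meta$pos - 1000) > 5000 &
                             abs(G$variant_meta$pos - 1000) <= 20000]
  expect_false(any(gap %in% c(cis$variant_id, tr$variant_id)))
})

test_that("planted trans effect at 20% variance is genome-wide significant", {
  G <- simulate_genotypes(500, 40, n_chr = 2, maf_range = c(0.2, 0.5),
                          seed = 102)
  ann <- data.frame(gene_id = paste0("g", 1:4), chrom = "1",
                    tss = c(1000, 5000, 9000, 15000))
  # effect on chromosome 2 explaining ~20% of log-expression variance
  plan <- data.frame(gene_id = "g1", variant_id = "snp25", effect = 0.5,
                     mode = "trans")
  ex <- simulate_expression(G, ann, plan, dispersion = 50, seed = 103)
  E <- filter_normalize_expression(ex$counts, ex$lengths)
  tr <- map_trans_eqtl(E, G, ann, exclusion = 5000, maf_min = 0.05)
  expect_lt(tr$p_value[tr$gene_id == "g1" & tr$variant_id == "snp25"],
            3.32e-7)
})

test_that("SMR statistic matches the closed form and its limits", {
  r <- smr_test(0.5, 0.05, 0.2, 0.04)
  expect_equal(r$b_xy, 0.4)
  expect_equal(r$t_smr, 20)
  expect_equal(r$p_smr, pchisq(20, 1, lower.tail = FALSE))

  # null outcome
  r0 <- smr_test(0.5, 0.05, 0, 0.04)
  expect_equal(r0$b_xy, 0)
  expect_equal(r0$t_smr, 0)
  expect_equal(r0$p_smr, 1)

  # symmetry in the two z-scores
  ra <- smr_test(3, 1, 7, 1)
  rb <- smr_test(7, 1, 3, 1)
  expect_equal(ra$t_smr, rb$t_smr)

  # bounded by the weaker z^2; tends to z_g^2 for an infinite instrument
  set.seed(104)
  for (i in 1:20) {
    be <- rnorm(1); bg <- rnorm(1)
    r1 <- smr_test(be, 0.1, bg, 0.2)
    expect_lte(r1$t_smr, min((be / 0.1)^2, (bg / 0.2)^2) + 1e-9)
  }
  rl <- smr_test(1e6, 1, 2, 1)
  expect_equal(rl$t_smr, 4, tolerance = 1e-9)

  # zero instrument: undefined ratio, flagged, t = 0
  rz <- smr_test(0, 0.1, 1, 0.1)
  expect_true(is.na(rz$b_xy))
  expect_equal(rz$t_smr, 0)
  expect_identical(rz$flag, "zero-instrument")
  expect_error(smr_test(1, 0, 1, 1), "positive")
})

test_that("batch SMR picks top eQTL per gene and attaches q-values", {
  eqtl <- data.frame(gene_id = rep(c("g1", "g2"), each = 2),
                     variant_id = c("v1", "v2", "v3", "v4"),
                     beta = c(0.5, 0.2, 0.1, 0.6), se = 0.05,
                     p_value = c(1e-8, 1e-3, 0.2, 1e-6))
  gwas <- data.frame(id = c("v1", "v4"), beta = c(0.2, 0.01),
                     se = c(0.04, 0.05))
  out <- run_smr(eqtl, gwas)
  expect_identical(out$variant_id, c("v1", "v4"))
  expect_equal(out$t_smr[1], 20)
  expect_true(all(out$fdr_q >= out$p_smr))
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.3, 0.04, 0.9, 0.02)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  # permutation invariance after re-sorting
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
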