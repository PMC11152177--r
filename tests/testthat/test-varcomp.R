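test_that("reml_fit matches a brute-force grid search of the profile likelihood", {
  set.seed(41)
  for (i in 1:6) {
    n <- 30
    K <- random_kernel(n, rank = 15, seed = 40 + i)
    r_true <- runif(1)
    L <- t(chol(r_true * K$values + (1 - r_true) * diag(n) + 1e-8 * diag(n)))
    y <- drop(L %*% rnorm(n)) + 0.5
    X <- cbind(1, rnorm(n))
    fit <- reml_fit(y, X, K)
    grid <- seq(0, 1, by = 0.001)
    gll <- vapply(grid, reml_ll_oracle, numeric(1), y = y,
                  design = X, K = K$values)
    expect_lt(abs(fit$ratio - grid[which.max(gll)]), 0.002)
    # the returned optimum is at least as good as every grid point
    expect_gte(fit$loglik, max(gll) - 1e-6)
  }
})

test_that("reml_fit recovers simulated variance ratios", {
  est <- vapply(1:15, function(i) {
    n <- 400
    K <- random_kernel(n, rank = 300, seed = 100 + i)
    set.seed(200 + i)
    L <- t(chol(0.5 * K$values + 0.5 * diag(n) + 1e-8 * diag(n)))
    y <- drop(L %*% rnorm(n))
    reml_fit(y, NULL, K, se = FALSE)$ratio
  }, numeric(1))
  expect_gt(mean(est), 0.45)
  expect_lt(mean(est), 0.55)

  # pure-noise null: estimates near zero on average
  null_est <- vapply(1:15, function(i) {
    K <- random_kernel(300, rank = 200, seed = 300 + i)
    set.seed(400 + i)
    reml_fit(rnorm(300), NULL, K, se = FALSE)$ratio
  }, numeric(1))
  expect_lt(mean(null_est), 0.05)
})

test_that("ratio is invariant to affine trait and kernel rescaling", {
  K <- random_kernel(80, rank = 50, seed = 51)
  set.seed(52)
  y <- drop(t(chol(0.4 * K$values + 0.6 * diag(80) + 1e-8 * diag(80))) %*%
              rnorm(80))
  f1 <- reml_fit(y, NULL, K)
  f2 <- reml_fit(3 * y - 7, NULL, K)
  expect_equal(f1$ratio, f2$ratio, tolerance = 1e-5)
  expect_equal(f2$sigma2_kernel, 9 * f1$sigma2_kernel, tolerance = 1e-3)

  # doubling the kernel halves sigma2_kernel, preserving the fitted V
  f3 <- reml_fit(y, NULL, 2 * K$values)
  expect_equal(2 * f3$sigma2_kernel, f1$sigma2_kernel, tolerance = 1e-3)
  expect_equal(f3$loglik, f1$loglik, tolerance = 1e-6)
})

test_that("reml_fit rejects degenerate inputs and flags boundaries", {
  expect_error(reml_fit(rnorm(20), NULL, diag(20)), "identity")
  X <- cbind(1, 1:20, 2 * (1:20))
  expect_error(reml_fit(rnorm(20), X, random_kernel(20, seed = 53)),
               "rank deficient")
  # covariate-only trait: kernel fraction at the zero boundary
  set.seed(54)
  batch <- rep(0:1, 40)
  y <- 2 * batch + rnorm(80, sd = 0.1)
  f <- reml_fit(y, cbind(1, batch), random_kernel(80, rank = 40, seed = 55))
  expect_true(f$converged)
  expect_lt(f$ratio, 0.1)
})

test_that("h2 and m2 wrappers recover the simulated truths", {
  b <- tiny_cohort(n = 500, m = 1500, k = 100, h2 = 0.4, m2 = 0,
                   seed = 61, n_causal_snps = 150)
  fit <- estimate_h2(b$phenotypes$trait,
                     data.frame(batch = b$phenotypes$batch),
                     build_grm(b$genotypes))
  expect_lt(abs(fit$ratio - 0.4), 0.25)   # single replicate, wide SE
  expect_identical(attr(fit, "label"), "h2")

  b2 <- tiny_cohort(n = 500, m = 400, k = 150, h2 = 0, m2 = 0.3, seed = 62)
  mrm <- build_mrm(b2$abundances)
  pcs <- genetic_pcs(build_grm(b2$genotypes), 5)
  cov2 <- data.frame(batch = b2$phenotypes$batch, pcs$pcs)
  fit2 <- estimate_m2(b2$phenotypes$trait, cov2, mrm)
  expect_lt(abs(fit2$ratio - 0.3), 0.2)

  # m2 invariant to rescaling abundances before MRM construction
  A10 <- abundance_table(b2$abundances$rel_abundance * 10,
                         b2$abundances$taxon_meta, b2$abundances$sample_ids)
  fit3 <- estimate_m2(b2$phenotypes$trait, cov2, build_mrm(A10))
  expect_equal(fit3$ratio, fit2$ratio, tolerance = 1e-6)
})

test_that("permutation test detects real microbiability and is calibrated", {
  b <- tiny_cohort(n = 400, m = 300, k = 150, h2 = 0, m2 = 0.3, seed = 71)
  mrm <- build_mrm(b$abundances)
  X <- model.matrix(~ batch, b$phenotypes)
  pr <- permute_m2(b$phenotypes$trait, X, mrm, n_perm = 200, seed = 72)
  expect_lte(pr$p_value, 0.05)
  expect_identical(length(pr$permuted_ratios), 200L)
  expect_gt(pr$p_value, 0)                      # add-one rule: never zero
  expect_equal(pr$p_value,
               (1 + sum(pr$permuted_ratios >= pr$observed_ratio)) / 201)

  # identical seed reproduces the permutation stream
  pr2 <- permute_m2(b$phenotypes$trait, X, mrm, n_perm = 200, seed = 72)
  expect_identical(pr$permuted_ratios, pr2$permuted_ratios)
})

test_that("permutation p-values are valid (never anti-conservative) under the null", {
  # boundary-clamped ratio estimates put a point mass of observed ratios at
  # zero, which maps to p = 1 under the add-one rule; the null p-value
  # distribution is therefore super-uniform, and validity (P(p <= a) <= a)
  # is the property a permutation test must satisfy
  ps <- vapply(1:40, function(i) {
    b <- tiny_cohort(n = 150, m = 60, k = 80, h2 = 0, m2 = 0,
                     seed = 700 + i)
    mrm <- build_mrm(b$abundances)
    permute_m2(b$phenotypes$trait, model.matrix(~ batch, b$phenotypes),
               mrm, n_perm = 60, seed = 800 + i)$p_value
  }, numeric(1))
  for (a in c(0.05, 0.1, 0.25, 0.5)) {
    half <- 2.576 * sqrt(a * (1 - a) / 40)
    expect_lte(mean(ps <= a), a + half)
  }
  expect_gt(mean(ps), 0.4)       # not systematically small
  expect_true(all(ps > 0 & ps <= 1))
})
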