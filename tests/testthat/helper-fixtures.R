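# Small cohorts reused across tests.

tiny_genotypes <- function(n = 40, m = 30, seed = 11, ...) {
  simulate_genotypes(n, m, seed = seed, ...)
}

tiny_cohort <- function(n = 150, m = 300, k = 60, h2 = 0.3, m2 = 0.2,
                        seed = 21, ...) {
  simulate_cohort(sim_config(n_individuals = n, n_snps = m, n_asvs = k,
                             h2_true = h2, m2_true = m2, seed = seed, ...))
}

# Independent REML profile log-likelihood oracle: generic determinant/solve
# evaluation on the covariate-orthogonal space, sharing no code with
# reml_fit's eigendecomposition path.
reml_ll_oracle <- function(r, y, design, K) {
  n <- length(y)
  Q <- qr.Q(qr(design), complete = TRUE)[, (ncol(design) + 1):n,
                                         drop = FALSE]
  V <- r * K + (1 - r) * diag(n)
  Vp <- crossprod(Q, V %*% Q)
  q <- ncol(Q)
  z <- drop(crossprod(Q, y))
  # a rank-deficient kernel makes V singular at r = 1; the restricted
  # likelihood is -Inf there
  Vi_z <- tryCatch(solve(Vp, z), error = function(e) NULL)
  if (is.null(Vi_z)) return(-Inf)
  s2t <- sum(z * Vi_z) / q
  ld <- determinant(Vp, logarithm = TRUE)$modulus
  if (s2t <= 0) return(-Inf)
  -0.5 * (q * log(2 * pi * s2t) + as.numeric(ld) + q)
}

# Random positive semidefinite kernel with unit mean diagonal.
random_kernel <- function(n, rank = n, seed = 1) {
  set.seed(seed)
  W <- matrix(rnorm(n * rank), n, rank)
  K <- tcrossprod(scale(W)) / rank
  relationship_matrix((K + t(K)) / 2, paste0("S", seq_len(n)), "GRM")
}
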