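#' Exact profile REML for a single-kernel variance-component model
#'
#' Fits \eqn{y = X b + g + e} with \eqn{g \sim N(0, \sigma^2_k K)} and
#' \eqn{e \sim N(0, \sigma^2_e I)} by restricted maximum likelihood. The
#' data are projected onto the orthogonal complement of the fixed-effect
#' design (which is what REML is), the projected kernel is eigendecomposed
#' once, the total variance \eqn{\sigma^2_t = \sigma^2_k + \sigma^2_e} is
#' profiled out in closed form, and the variance ratio
#' \eqn{r = \sigma^2_k / \sigma^2_t} is maximized on \eqn{[0, 1]} by a
#' coarse grid followed by golden-section refinement. Boundary estimates
#' (r = 0 or 1) are returned converged with a boundary flag.
#'
#' The ratio is the heritability when `K` is a GRM and the microbiability
#' when `K` is an MRM.
#'
#' @param y numeric trait vector.
#' @param X fixed-effect design matrix including the intercept (`NULL` for
#'   intercept only); must have full column rank.
#' @param K a [relationship_matrix()] or bare symmetric kernel matrix
#'   aligned with `y`.
#' @param se compute an approximate standard error of the ratio from the
#'   curvature of the profile REML log-likelihood (`NA` at a boundary).
#' @return A `varcomp_result`: `sigma2_kernel`, `sigma2_resid`, `ratio`,
#'   `se_ratio`, `loglik`, `converged`, `boundary`, `n_iter`.
#' @export
reml_fit <- function(y, X = NULL, K, se = TRUE) {
  Kv <- kernel_values(K)
  n <- length(y)
  stopifnot(nrow(Kv) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("fixed-effect design is rank deficient", call. = FALSE)
  p <- ncol(X)
  if (n <= p + 1)
    stop("need more observations than fixed effects", call. = FALSE)
  if (max(abs(Kv - diag(n))) < 1e-10)
    stop("kernel equals the identity; variance components not identifiable",
         call. = FALSE)

  Q <- qr.Q(qrX, complete = TRUE)[, (p + 1):n, drop = FALSE]
  Kp <- force_sym(crossprod(Q, Kv %*% Q))
  ev <- eigen(Kp, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  z <- drop(crossprod(ev$vectors, crossprod(Q, y)))
  q <- n - p
  z2 <- z^2

  n_eval <- 0L
  profile_ll <- function(r) {
    n_eval <<- n_eval + 1L
    w <- r * d + (1 - r)
    if (any(w <= 0)) return(-Inf)
    s2t <- sum(z2 / w) / q
    if (s2t <= 0) return(-Inf)
    -0.5 * (q * log(2 * pi * s2t) + sum(log(w)) + q)
  }

  grid <- seq(0, 1, length.out = 21)
  gll <- vapply(grid, profile_ll, numeric(1))
  i <- which.max(gll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(profile_ll, c(lo, hi), maximum = TRUE, tol = 1e-9)
  r_hat <- opt$maximum; ll <- opt$objective
  # the interior optimum can sit at the interval edge; check the boundaries
  for (rb in c(0, 1)) {
    llb <- profile_ll(rb)
    if (llb > ll) { r_hat <- rb; ll <- llb }
  }
  r_hat <- min(max(r_hat, 0), 1)

  w <- r_hat * d + (1 - r_hat)
  s2t <- sum(z2 / pmax(w, .Machine$double.eps)) / q
  boundary <- r_hat < 1e-4 || r_hat > 1 - 1e-4

  se_ratio <- NA_real_
  if (se && !boundary) {
    h <- min(1e-4, r_hat / 2, (1 - r_hat) / 2)
    d2 <- (profile_ll(r_hat + h) - 2 * ll + profile_ll(r_hat - h)) / h^2
    if (is.finite(d2) && d2 < 0) se_ratio <- sqrt(-1 / d2)
  }

  structure(list(sigma2_kernel = r_hat * s2t,
                 sigma2_resid = (1 - r_hat) * s2t,
                 ratio = r_hat, se_ratio = se_ratio, loglik = ll,
                 converged = TRUE, boundary = boundary, n_iter = n_eval),
            class = "varcomp_result")
}

#' @export
print.varcomp_result <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("%s = %.4f (SE %.4f), sigma2_kernel = %.4f, sigma2_resid = %.4f\n",
              if (is.null(lab)) "ratio" else lab,
              x$ratio, x$se_ratio, x$sigma2_kernel, x$sigma2_resid))
  cat(sprintf("REML loglik = %.4f%s\n", x$loglik,
              if (x$boundary) " (boundary estimate)" else ""))
  invisible(x)
}

# Build a fixed-effect design from a covariate data.frame (factors expanded
# to dummies) with an intercept.
build_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1,
                                         dimnames = list(NULL, "(Intercept)")))
  cv <- as.data.frame(covariates)
  stats::model.matrix(~ ., data = cv)
}

#' Estimate SNP heritability
#'
#' REML fit of the trait on a GRM kernel with the stated covariates
#' (typically batch plus leading genetic principal components); the ratio is
#' labelled \eqn{h^2}.
#'
#' @param y numeric trait vector (or a cohort phenotype data.frame with a
#'   `trait` column).
#' @param covariates data.frame of covariates (factors allowed); intercept
#'   added automatically. `NULL` for intercept only.
#' @param grm a [relationship_matrix()] of kind `"GRM"`.
#' @return A `varcomp_result` labelled `h2`.
#' @export
estimate_h2 <- function(y, covariates = NULL, grm) {
  if (is.data.frame(y)) y <- y$trait
  fit <- reml_fit(y, build_design(covariates, length(y)), grm)
  attr(fit, "label") <- "h2"
  fit
}

#' Estimate microbiability
#'
#' REML fit of the trait on an MRM kernel; covariates conventionally include
#' batch and the leading genetic principal components so host-genetic
#' structure is corrected before attributing variance to the microbiome.
#' The ratio is labelled \eqn{m^2}. The estimate is invariant to rescaling
#' all abundances before MRM construction, since the MRM standardizes taxa.
#'
#' @inheritParams estimate_h2
#' @param mrm a [relationship_matrix()] of kind `"MRM"`.
#' @return A `varcomp_result` labelled `m2`.
#' @export
estimate_m2 <- function(y, covariates = NULL, mrm) {
  if (is.data.frame(y)) y <- y$trait
  fit <- reml_fit(y, build_design(covariates, length(y)), mrm)
  attr(fit, "label") <- "m2"
  fit
}

#' Permutation null for microbiability
#'
#' Shuffles the phenotype (jointly with its covariate rows) against the
#' kernel `n_perm` times, refits REML each time, and reports the one-sided
#' permutation p-value with the add-one rule
#' \eqn{p = (1 + \#\{m^2_{perm} \ge m^2_{obs}\}) / (n_{perm} + 1)}, which can
#' never be exactly zero. Failed permutation fits are dropped with a warning
#' and the p-value is computed over the successes.
#'
#' @param y numeric trait vector.
#' @param X fixed-effect design matrix (intercept included), or `NULL`.
#' @param M kernel ([relationship_matrix()] or matrix).
#' @param n_perm number of permutations (`>= 1`).
#' @param seed RNG seed.
#' @return A `permutation_result`: `observed_ratio`, `permuted_ratios`,
#'   `p_value`, `n_perm`, `seed`.
#' @export
permute_m2 <- function(y, X = NULL, M, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  obs <- reml_fit(y, X, M, se = FALSE)$ratio
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      tryCatch(reml_fit(y[idx], X[idx, , drop = FALSE], M, se = FALSE)$ratio,
               error = function(e) NA_real_)
    }, numeric(1))
  })
  n_fail <- sum(is.na(perm))
  if (n_fail > 0)
    warning(sprintf("%d permutation fit(s) failed and were excluded", n_fail),
            call. = FALSE)
  ok <- perm[!is.na(perm)]
  p <- (1 + sum(ok >= obs)) / (length(ok) + 1)
  structure(list(observed_ratio = obs, permuted_ratios = perm,
                 p_value = p, n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("observed ratio %.4f; permutation p = %.4g (%d permutations, mean null %.4f)\n",
              x$observed_ratio, x$p_value, x$n_perm,
              mean(x$permuted_ratios, na.rm = TRUE)))
  invisible(x)
}
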