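#' @keywords internal
"_PACKAGE"

# Child seeds are derived from one master seed so each generated table has its
# own reproducible stream. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 1009 + stream) %% 2147483647)
}

# Run expr under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

# Symmetrize a numeric matrix (guards against floating-point asymmetry from
# crossprod chains).
force_sym <- function(M) (M + t(M)) / 2

# Column standardization with optional population (1/n) variance divisor.
standardize_cols <- function(X, population = FALSE) {
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, `-`)
  denom <- if (population) n else n - 1L
  sd_ <- sqrt(colSums(Xc^2) / denom)
  list(z = sweep(Xc, 2L, sd_, `/`), mean = mu, sd = sd_)
}
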