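`%||%` <- function(a, b) if (is.null(a)) b else a

#' Harmonic number
#'
#' Partial sum of the harmonic series, \eqn{a_n = \sum_{i=1}^{n} 1/i}. The
#' Watterson estimator divides the segregating-site count by \eqn{a_{n-1}}.
#'
#' @param n Non-negative integer.
#' @return Numeric scalar.
#' @keywords internal
harmonic_number <- function(n) {
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(0)
  sum(1 / seq_len(n))
}

# Run `code` under a temporary RNG state seeded with `seed`; NULL seed means
# use (and advance) the current RNG stream.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Deterministically derive k child seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, k) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Effective sample size via the initial positive sequence of autocorrelations.
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(0)
  rho <- as.numeric(stats::acf(x, lag.max = min(n - 1, 1000), plot = FALSE)$acf)[-1]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
  n / (1 + 2 * sum(rho))
}

# Posterior mode by kernel density argmax, restricted to the prior support.
posterior_mode <- function(x, lo = min(x), hi = max(x)) {
  if (length(unique(x)) == 1) return(x[1])
  d <- stats::density(x, from = lo, to = hi)
  d$x[which.max(d$y)]
}

assert_number <- function(x, name, lo = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x))
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  if (x < lo || (!allow_zero && x == lo))
    stop(sprintf("`%s` must be %s %s", name, if (allow_zero) ">=" else ">", lo),
         call. = FALSE)
  invisible(x)
}
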