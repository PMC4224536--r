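#' Watterson's moment estimator of theta
#'
#' \eqn{\hat\theta_W = S / a_{n-1}} with \eqn{a_{n-1} = \sum_{i=1}^{n-1} 1/i},
#' from `S` segregating sites in `n` sequences. With `L` supplied the
#' per-site value `S / (a_{n-1} L)` is returned.
#'
#' @param S Number of segregating sites (>= 0).
#' @param n Number of sequences (>= 2).
#' @param L Optional alignment length for a per-site estimate.
#' @return Numeric theta estimate (per locus, or per site when `L` given).
#' @examples
#' watterson_theta(16, 18)          # 4.652 per locus
#' watterson_theta(16, 18, L = 512) # 0.00909 per site
#' @export
watterson_theta <- function(S, n, L = NULL) {
  assert_number(S, "S", lo = 0)
  if (!is.numeric(n) || n < 2) stop("n must be >= 2")
  est <- S / harmonic_number(n - 1)
  if (!is.null(L)) {
    assert_number(L, "L", lo = 1)
    est <- est / L
  }
  est
}

#' Theta from stepwise-model equilibrium heterozygosity
#'
#' Inverts the Ohta-Kimura single-step equilibrium
#' \eqn{H = 1 - 1/\sqrt{1 + 2\theta}}:
#' \eqn{\hat\theta = ((1/(1-H))^2 - 1)/2}.
#'
#' @param H Expected heterozygosity in `[0, 1)`.
#' @return Theta estimate (per locus).
#' @examples
#' smm_theta_from_heterozygosity(0.695)  # ~4.875
#' @export
smm_theta_from_heterozygosity <- function(H) {
  assert_number(H, "H", lo = 0)
  if (H >= 1) stop("H must be < 1")
  ((1 / (1 - H))^2 - 1) / 2
}

#' Theta from allele-size variance
#'
#' Under the stepwise mutation model the expected within-population variance
#' of allele size equals \eqn{\theta/2}, so \eqn{\hat\theta = 2 V}.
#'
#' @param V Sample variance of allele sizes (>= 0).
#' @return Theta estimate (per locus).
#' @export
smm_theta_from_size_variance <- function(V) {
  assert_number(V, "V", lo = 0)
  2 * V
}
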