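#' Expected heterozygosity per microsatellite locus
#'
#' Nei's unbiased gene diversity per locus,
#' \eqn{\hat H = \frac{n_g}{n_g - 1}(1 - \sum_k p_k^2)} with \eqn{n_g} the
#' number of sampled allele copies (2 per complete genotype), plus the plain
#' \eqn{1 - \sum p_k^2} variant so either convention can be matched.
#'
#' @param gm A [genotype_matrix()].
#' @return A list with `per_locus` (named vector, unbiased), `per_locus_plain`
#'   (no small-sample correction), `mean`, `range`, and `n_alleles`
#'   (allele counts per locus). Loci with fewer than 2 typed individuals are
#'   dropped with a warning.
#' @examples
#' gm <- genotype_matrix(c("a", "b"), c("L1", "L1"), c(1, 3), c(2, 4))
#' expected_heterozygosity(gm)$per_locus  # (4/3) * (1 - 4 * 0.25^2) = 1
#' @export
expected_heterozygosity <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  loci <- gm_loci(gm)
  h <- h_plain <- n_alleles <- stats::setNames(numeric(length(loci)), loci)
  keep <- logical(length(loci))
  for (i in seq_along(loci)) {
    alleles <- locus_alleles(gm, loci[i])
    ng <- length(alleles)
    if (ng < 4) {  # fewer than 2 complete diploid genotypes
      warning("locus '", loci[i], "' has fewer than 2 typed individuals; excluded")
      next
    }
    p <- table(alleles) / ng
    h_plain[i] <- 1 - sum(p^2)
    h[i] <- ng / (ng - 1) * h_plain[i]
    n_alleles[i] <- length(p)
    keep[i] <- TRUE
  }
  h <- h[keep]; h_plain <- h_plain[keep]; n_alleles <- n_alleles[keep]
  if (!length(h)) stop("no locus with enough data")
  list(per_locus = h, per_locus_plain = h_plain, mean = mean(h),
       range = range(h), n_alleles = n_alleles)
}

# collapse identical sequences; returns haplotype counts
haplotype_counts <- function(aln) {
  table(apply(aln$seq, 1, paste0, collapse = ""))
}

#' Haplotype (gene) diversity with standard deviation
#'
#' Collapses identical sequences into haplotypes with frequencies `p_i` and
#' returns \eqn{H_s = \frac{n}{n-1}(1 - \sum p_i^2)} with the sampling
#' standard deviation from Nei's (1987) variance formula.
#'
#' @param aln A [seq_alignment()] with at least 2 sequences.
#' @return List with `Hs`, `sd`, and `n_haplotypes`.
#' @export
haplotype_diversity <- function(aln) {
  stopifnot(inherits(aln, "seq_alignment"))
  n <- n_sequences(aln)
  if (n < 2) stop("haplotype diversity needs at least 2 sequences")
  p <- as.numeric(haplotype_counts(aln)) / n
  s2 <- sum(p^2)
  Hs <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  list(Hs = Hs, sd = sqrt(max(v, 0)), n_haplotypes = length(p))
}

#' Nucleotide diversity per site with standard deviation
#'
#' Mean proportion of differing sites over all unordered sequence pairs,
#' with the standard deviation from the usual (Nei 1987) approximation
#' combining sampling and stochastic variance:
#' \eqn{V(\pi) = \frac{n+1}{3(n-1)}\frac{\pi}{L} +
#'      \frac{2(n^2+n+3)}{9n(n-1)}\pi^2}.
#'
#' @param aln A [seq_alignment()] with at least 2 equal-length sequences.
#' @return List with `pi`, `sd`, and `n_pairs`.
#' @export
nucleotide_diversity <- function(aln) {
  stopifnot(inherits(aln, "seq_alignment"))
  n <- n_sequences(aln)
  if (n < 2) stop("nucleotide diversity needs at least 2 sequences")
  L <- alignment_length(aln)
  diffs <- 0
  for (i in 1:(n - 1))
    for (j in (i + 1):n)
      diffs <- diffs + sum(aln$seq[i, ] != aln$seq[j, ])
  n_pairs <- n * (n - 1) / 2
  pi_site <- diffs / n_pairs / L
  v <- (n + 1) / (3 * (n - 1)) * pi_site / L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi_site^2
  list(pi = pi_site, sd = sqrt(v), n_pairs = n_pairs)
}

#' Segregating-site summary of an alignment
#'
#' Counts variable columns (S), classifies each biallelic variable column as
#' a transition (A/G or C/T) or a transversion, reports multiallelic columns
#' separately, and counts distinct haplotypes after exact-match collapse.
#'
#' @param aln A [seq_alignment()] with at least 2 sequences.
#' @return List with `S`, `transitions`, `transversions`, `multiallelic`,
#'   and `n_haplotypes`.
#' @export
site_summary <- function(aln) {
  stopifnot(inherits(aln, "seq_alignment"))
  if (n_sequences(aln) < 2) stop("site summary needs at least 2 sequences")
  ti <- tv <- multi <- 0L
  S <- 0L
  for (col in seq_len(alignment_length(aln))) {
    obs <- unique(aln$seq[, col])
    if (length(obs) < 2) next
    S <- S + 1L
    if (length(obs) > 2) {
      multi <- multi + 1L
    } else if (paste(sort(obs), collapse = "") %in% c("AG", "CT")) {
      ti <- ti + 1L
    } else {
      tv <- tv + 1L
    }
  }
  list(S = S, transitions = ti, transversions = tv, multiallelic = multi,
       n_haplotypes = length(haplotype_counts(aln)))
}

#' Combined diversity report for both marker types
#'
#' Convenience wrapper returning every index the downstream report uses, as
#' one list that serializes cleanly to JSON.
#'
#' @param aln A [seq_alignment()] (mtDNA haplotypes) or `NULL`.
#' @param gm A [genotype_matrix()] (microsatellites) or `NULL`.
#' @return A `diversity_summary` list with components `sequences` (Hs, pi,
#'   site summary, Watterson theta per locus and per site) and
#'   `microsatellites` (expected heterozygosity, allele counts).
#' @export
diversity_summary <- function(aln = NULL, gm = NULL) {
  out <- list()
  if (!is.null(aln)) {
    hd <- haplotype_diversity(aln)
    nd <- nucleotide_diversity(aln)
    ss <- site_summary(aln)
    n <- n_sequences(aln)
    out$sequences <- list(
      n = n, L = alignment_length(aln),
      Hs = hd$Hs, Hs_sd = hd$sd, pi = nd$pi, pi_sd = nd$sd,
      S = ss$S, transitions = ss$transitions, transversions = ss$transversions,
      multiallelic = ss$multiallelic, n_haplotypes = ss$n_haplotypes,
      watterson_per_locus = watterson_theta(ss$S, n),
      watterson_per_site = watterson_theta(ss$S, n, L = alignment_length(aln)))
  }
  if (!is.null(gm)) {
    he <- expected_heterozygosity(gm)
    out$microsatellites <- list(
      n_individuals = length(unique(gm$individual)),
      n_loci = length(gm_loci(gm)),
      Hexp_per_locus = as.list(he$per_locus),
      Hexp_per_locus_plain = as.list(he$per_locus_plain),
      Hexp_mean = he$mean, Hexp_range = he$range,
      n_alleles = as.list(he$n_alleles),
      smm_theta_from_H = smm_theta_from_heterozygosity(he$mean))
  }
  structure(out, class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  if (!is.null(x$sequences)) {
    s <- x$sequences
    cat(sprintf("mtDNA: n=%d, L=%d | Hs = %.3f +/- %.3f | pi = %.4f +/- %.4f\n",
                s$n, s$L, s$Hs, s$Hs_sd, s$pi, s$pi_sd))
    cat(sprintf("       S = %d (%d Ti, %d Tv, %d multiallelic), %d haplotypes\n",
                s$S, s$transitions, s$transversions, s$multiallelic,
                s$n_haplotypes))
  }
  if (!is.null(x$microsatellites)) {
    m <- x$microsatellites
    cat(sprintf("microsatellites: %d individuals x %d loci | mean Hexp = %.3f (%.3f-%.3f)\n",
                m$n_individuals, m$n_loci, m$Hexp_mean,
                m$Hexp_range[1], m$Hexp_range[2]))
  }
  invisible(x)
}
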