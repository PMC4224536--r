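test_that("expected heterozygosity matches hand-computed values", {
  # 2 individuals, genotypes (1/2) and (3/4): 4 alleles at 1/4 each;
  # unbiased estimator (4/3)*(1 - 4*(1/4)^2) = 1
  gm <- gm_from(list(L1 = rbind(c(1, 2), c(3, 4))))
  he <- expected_heterozygosity(gm)
  expect_equal(unname(he$per_locus["L1"]), 1.0)
  expect_equal(unname(he$per_locus_plain["L1"]), 0.75)

  # single allele -> 0
  gm2 <- gm_from(list(L1 = rbind(c(5, 5), c(5, 5), c(5, 5))))
  expect_equal(unname(expected_heterozygosity(gm2)$per_locus["L1"]), 0)

  # two alleles at 0.5/0.5, large n -> ~0.5
  a <- cbind(rep(c(10, 11), 200), rep(c(11, 10), 200))
  he3 <- expected_heterozygosity(gm_from(list(L1 = a)))
  expect_equal(unname(he3$per_locus["L1"]), 0.5, tolerance = 2e-3)
})

test_that("heterozygosity drops loci without data and handles missing cells", {
  gm <- gm_from(list(L1 = rbind(c(1, 2), c(1, 3), c(2, 3)),
                     L2 = rbind(c(1, 2), c(NA, 2), c(1, NA))))
  expect_warning(he <- expected_heterozygosity(gm), "L2")
  expect_false("L2" %in% names(he$per_locus))
})

test_that("haplotype diversity matches Nei's estimator and SD formula", {
  expect_equal(haplotype_diversity(aln_from("AAA", "AAA", "AAA"))$Hs, 0)
  all_unique <- aln_from("AAAA", "AAAT", "AATT", "ATTT", "TTTT")
  expect_equal(haplotype_diversity(all_unique)$Hs, 1.0)

  # n = 4 with haplotype counts (2,1,1): (4/3)*(1 - 0.375) = 0.8333
  hd <- haplotype_diversity(aln_from("AAAA", "AAAA", "AATT", "TTTT"))
  expect_equal(hd$Hs, 5 / 6, tolerance = 1e-12)
  expect_equal(hd$n_haplotypes, 3)
  # Nei (1987) variance, computed by hand for p = (0.5, 0.25, 0.25)
  p <- c(0.5, 0.25, 0.25); n <- 4; s2 <- sum(p^2)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  expect_equal(hd$sd, sqrt(v))

  expect_error(haplotype_diversity(aln_from("AAAA")), "2 sequences")
})

test_that("nucleotide diversity is the mean pairwise difference per site", {
  expect_equal(nucleotide_diversity(aln_from("ACGT", "ACGT"))$pi, 0)
  expect_equal(nucleotide_diversity(aln_from("AAAAAAAAAA", "AAAAAAAAAT"))$pi, 0.1)
  # three sequences of length 8 with pairwise differences 2, 2, 0
  aln <- aln_from("AAAAAAAA", "AAAAAATT", "AAAAAATT")
  expect_equal(nucleotide_diversity(aln)$pi, (2 + 2 + 0) / 3 / 8)
  expect_error(seq_alignment(c("a", "b"), c("AAA", "AAAA")), "ragged|length")
})

test_that("site summary classifies transitions and transversions", {
  mono <- site_summary(aln_from("ACGT", "ACGT"))
  expect_equal(mono$S, 0)
  expect_equal(mono$n_haplotypes, 1)

  # one A/G column (transition), one A/T column (transversion)
  s <- site_summary(aln_from("AA", "GA", "GT"))
  expect_equal(s$S, 2)
  expect_equal(s$transitions, 1)
  expect_equal(s$transversions, 1)

  # a three-base column is counted in S but reported as multiallelic
  s3 <- site_summary(aln_from("A", "C", "G"))
  expect_equal(s3$S, 1)
  expect_equal(s3$multiallelic, 1)
  expect_equal(s3$transitions + s3$transversions, 0)
})

test_that("diversity indices are invariant under sample relabeling", {
  d <- simulate_dataset(sim_config(seed = 31, n_tips = 8, n_individuals = 12,
                                   n_loci = 2, L = 60))
  aln <- d$alignment
  perm <- withr::with_seed(1, sample(nrow(aln$seq)))
  aln2 <- seq_alignment(paste0("x", seq_len(nrow(aln$seq))),
                        aln$seq[perm, , drop = FALSE])
  expect_equal(haplotype_diversity(aln2)$Hs, haplotype_diversity(aln)$Hs)
  expect_equal(nucleotide_diversity(aln2)$pi, nucleotide_diversity(aln)$pi)
  expect_equal(expected_heterozygosity(d$genotypes)$mean,
               expected_heterozygosity(d$genotypes[sample(nrow(d$genotypes)), ])$mean)
})

test_that("pi <= S/L always, with equality at n = 2", {
  for (s in 1:8) {
    d <- simulate_dataset(sim_config(seed = 100 + s, n_tips = 6,
                                     n_individuals = 2, n_loci = 1, L = 50,
                                     theta_seq = 0.03))
    aln <- d$alignment
    pi <- nucleotide_diversity(aln)$pi
    S <- site_summary(aln)$S
    expect_lte(pi, S / 50 + 1e-12)
    two <- seq_alignment(aln$labels[1:2], aln$seq[1:2, , drop = FALSE])
    expect_equal(nucleotide_diversity(two)$pi, site_summary(two)$S / 50)
  }
})

test_that("simulated Ti:Tv event ratio tracks R", {
  # at R = 33 transversions are rare; pool many replicates and compare the
  # observed biallelic Ti fraction with R/(R+1)
  counts <- withr::with_seed(9, {
    ti <- tv <- 0
    for (i in 1:40) {
      g <- simulate_genealogy(10)
      s <- site_summary(evolve_sequences(g, 400, 0.02, R = 33))
      ti <- ti + s$transitions; tv <- tv + s$transversions
    }
    c(ti, tv)
  })
  p_hat <- counts[1] / sum(counts)
  p_exp <- 33 / 34
  se <- sqrt(p_exp * (1 - p_exp) / sum(counts))
  expect_lt(abs(p_hat - p_exp), 4 * se + 0.01)
})
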