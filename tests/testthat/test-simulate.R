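test_that("sequence evolution honours the zero-mutation and bias limits", {
  g <- simulate_genealogy(8, seed = 1)
  aln <- evolve_sequences(g, 100, theta_seq = 0, R = 33, seed = 2)
  expect_equal(length(unique(apply(aln$seq, 1, paste0, collapse = ""))), 1)
  expect_error(evolve_sequences(g, 100, theta_seq = -1), "theta_seq")

  # transversion fraction of single mutation events is 1/(R+1)
  for (R in c(1, 1000)) {
    events <- withr::with_seed(5, vapply(1:4000, function(i) {
      before <- 1L  # A
      after <- neratio:::mutate_sequence(before, 1, R)
      after %in% c(2L, 4L)  # C or T: transversion from A
    }, TRUE))
    expect_lt(abs(mean(events) - 1 / (R + 1)),
              3 * sqrt(1 / (R + 1) / 4000) + 1e-3)
  }
})

test_that("segregating sites match the Watterson expectation", {
  # oracle: E[S] = theta * L * a_{n-1}; MC tolerance from the replicate SD
  n <- 10; L <- 300; theta <- 0.01
  reps <- 400
  S <- withr::with_seed(11, vapply(seq_len(reps), function(i) {
    g <- simulate_genealogy(n)
    site_summary(evolve_sequences(g, L, theta, R = 33))$S
  }, 0))
  expected <- theta * L * sum(1 / (1:(n - 1)))
  expect_lt(abs(mean(S) - expected), 3 * sd(S) / sqrt(reps))
})

test_that("stepwise mutation keeps the +/-1 parity property and SMM variance", {
  g <- simulate_genealogy(6, seed = 3)
  x <- evolve_microsatellites(g, 5, seed = 4)
  steps <- attr(x, "n_steps")
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal((x[i] - x[j]) %% 2, (steps[i] + steps[j]) %% 2)

  expect_equal(as.integer(evolve_microsatellites(g, 0, 20, seed = 5)),
               rep(20L, 6))

  # E[(Xi - Xj)^2] = theta for a random pair
  reps <- 3000; theta <- 5
  d2 <- withr::with_seed(6, vapply(seq_len(reps), function(i) {
    g2 <- simulate_genealogy(2)
    diff(as.integer(evolve_microsatellites(g2, theta, 50)))^2
  }, 0))
  expect_lt(abs(mean(d2) - theta), 3 * sd(d2) / sqrt(reps))
})

test_that("simulate_dataset is seed-deterministic and correctly shaped", {
  cfg <- sim_config(seed = 5, n_tips = 6, n_individuals = 10, n_loci = 3, L = 80)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(d1$alignment, f1); write_fasta(d2$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- tempfile(); g2 <- tempfile()
  write_genotypes(d1$genotypes, g1); write_genotypes(d2$genotypes, g2)
  expect_identical(readLines(g1), readLines(g2))

  expect_equal(nrow(d1$alignment$seq), 6)
  expect_equal(ncol(d1$alignment$seq), 80)
  expect_equal(nrow(d1$genotypes), 10 * 3)
  expect_true(all(c(d1$genotypes$allele1, d1$genotypes$allele2) >= 1))
})

test_that("the default configuration matches the study dimensions", {
  d <- simulate_dataset(sim_config(seed = 9))
  expect_equal(length(unique(d$genotypes$individual)), 96)
  expect_equal(length(unique(d$genotypes$locus)), 7)
  expect_equal(nrow(d$genotypes), 96 * 7)
  expect_equal(dim(d$alignment$seq), c(18L, 512L))
})

test_that("theta_msat near 4.9 reproduces the observed mean heterozygosity", {
  # SMM equilibrium: H = 1 - 1/sqrt(1 + 2*theta); at theta = 4.9, H = 0.6957
  H <- withr::with_seed(21, vapply(1:4, function(i) {
    d <- simulate_dataset(sim_config(seed = sample.int(1e6, 1), n_individuals = 48,
                                     n_loci = 7, n_tips = 4, L = 10,
                                     theta_msat = 4.9))
    expected_heterozygosity(d$genotypes)$mean
  }, 0))
  expect_lt(abs(mean(H) - (1 - 1 / sqrt(1 + 2 * 4.9))), 0.08)
})

test_that("sim_config round-trips through key=value and JSON files", {
  cfg <- sim_config(seed = 77, n_tips = 12, theta_seq = 0.02)
  path <- tempfile()
  write_sim_config(cfg, path)
  expect_equal(read_sim_config(path), cfg)

  jpath <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), jpath, auto_unbox = TRUE, digits = NA)
  expect_equal(read_sim_config(jpath), cfg)

  writeLines(c("n_tips = 5"), path)
  expect_error(read_sim_config(path), "seed")
})
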