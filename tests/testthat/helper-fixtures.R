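# small builders used across test files

aln_from <- function(...) {
  seqs <- c(...)
  seq_alignment(paste0("s", seq_along(seqs)), seqs)
}

# genotype table from a per-locus list of 2-column allele matrices
gm_from <- function(loci) {
  rows <- lapply(names(loci), function(l) {
    a <- loci[[l]]
    data.frame(individual = paste0("i", seq_len(nrow(a))), locus = l,
               allele1 = a[, 1], allele2 = a[, 2])
  })
  df <- do.call(rbind, rows)
  genotype_matrix(df$individual, df$locus, df$allele1, df$allele2)
}

# explicit 3-tip genealogy: tips 1,2 join at t1 (node 4), with 3 at t2 (node 5)
gen3 <- function(t1 = 0.5, t2 = 1.5) {
  new_genealogy(3, rbind(c(1L, 2L), c(4L, 3L)), c(0, 0, 0, t1, t2))
}

fast_opts <- function(seed = 1L, ...) {
  mcmc_options(warmup = 2000L, burn_in = 5000L, n_samples = 500L, thin = 10L,
               seed = seed, ...)
}
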