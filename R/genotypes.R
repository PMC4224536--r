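#' Diploid microsatellite genotype table
#'
#' Long-format table of diploid allele sizes (repeat counts): one row per
#' (individual, locus) with two integer alleles. Either allele may be `NA`;
#' a genotype with any `NA` counts as missing for the diversity estimators.
#'
#' @param individuals Character vector (one entry per row).
#' @param loci Character vector (one entry per row).
#' @param allele1,allele2 Positive integer allele sizes (`NA` allowed).
#' @return A `genotype_matrix`, a data frame with columns
#'   `individual`, `locus`, `allele1`, `allele2`.
#' @export
genotype_matrix <- function(individuals, loci, allele1, allele2) {
  df <- data.frame(individual = as.character(individuals),
                   locus = as.character(loci),
                   allele1 = as.integer(allele1),
                   allele2 = as.integer(allele2),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("individual", "locus")]))
    stop("duplicate (individual, locus) rows in genotype table")
  sizes <- c(df$allele1, df$allele2)
  if (any(sizes < 1, na.rm = TRUE))
    stop("allele sizes must be positive integers")
  class(df) <- c("genotype_matrix", "data.frame")
  df
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d loci (%d complete genotypes)\n",
              length(unique(x$individual)), length(unique(x$locus)),
              sum(stats::complete.cases(x[c("allele1", "allele2")]))))
  invisible(x)
}

gm_loci <- function(gm) unique(gm$locus)

# All non-missing allele copies at one locus (genotypes with any NA dropped).
locus_alleles <- function(gm, locus) {
  sub <- gm[gm$locus == locus, ]
  ok <- !is.na(sub$allele1) & !is.na(sub$allele2)
  c(sub$allele1[ok], sub$allele2[ok])
}

#' Read / write genotype tables
#'
#' Tab-separated files with header `individual  locus  allele1  allele2`;
#' allele sizes are integers, missing cells are `NA`. Round-trips exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param path File path.
#' @return `read_genotypes` returns a `genotype_matrix`; `write_genotypes`
#'   returns `path` invisibly.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("individual", "locus", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop("genotype table must have columns ", paste(need, collapse = ", "))
  for (col in c("allele1", "allele2")) {
    raw <- df[[col]]
    val <- suppressWarnings(as.integer(raw))
    bad <- which(!is.na(raw) & raw != "NA" & raw != "" & is.na(val))
    if (length(bad))
      stop(sprintf("non-integer allele in %s at line %d (individual '%s', locus '%s'): '%s'",
                   path, bad[1] + 1L, df$individual[bad[1]], df$locus[bad[1]], raw[bad[1]]))
    df[[col]] <- val
  }
  genotype_matrix(df$individual, df$locus, df$allele1, df$allele2)
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  utils::write.table(as.data.frame(gm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Evolve microsatellite allele sizes along a genealogy
#'
#' Strict stepwise mutation model: mutations arrive on each lineage as a
#' Poisson process with rate `theta_msat/2` per coalescent time unit and each
#' mutation changes the repeat count by +1 or -1 with equal probability.
#' Under this scaling the expected squared size difference between two tips
#' equals `theta_msat`.
#'
#' @param genealogy A [new_genealogy()] object.
#' @param theta_msat Per-locus population-scaled mutation rate (>= 0).
#' @param ancestral_size Repeat count at the root (default 20).
#' @param seed Optional integer seed.
#' @return Integer vector of allele sizes, one per tip, with attribute
#'   `n_steps` giving the number of mutation steps from the root to each tip
#'   (useful for checking the +/-1 parity property).
#' @export
evolve_microsatellites <- function(genealogy, theta_msat, ancestral_size = 20,
                                   seed = NULL) {
  validate_genealogy(genealogy)
  assert_number(theta_msat, "theta_msat", lo = 0)
  assert_number(ancestral_size, "ancestral_size", lo = 1)
  with_seed_opt(seed, {
    n <- genealogy$n_tips
    n_nodes <- 2 * n - 1
    size <- integer(n_nodes)
    steps <- integer(n_nodes)
    rt <- root_node(genealogy)
    size[rt] <- as.integer(ancestral_size)
    internal <- order(genealogy$node_time[(n + 1):n_nodes], decreasing = TRUE) + n
    for (node in internal) {
      for (child in genealogy$children[node - n, ]) {
        dt <- genealogy$node_time[node] - genealogy$node_time[child]
        k <- stats::rpois(1, theta_msat / 2 * dt)
        up <- if (k > 0) stats::rbinom(1, k, 0.5) else 0L
        size[child] <- size[node] + 2L * up - k
        steps[child] <- steps[node] + k
      }
    }
    structure(size[seq_len(n)], n_steps = steps[seq_len(n)])
  })
}
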