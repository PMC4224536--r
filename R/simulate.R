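#' Simulation configuration
#'
#' Describes one synthetic single-population dataset: an mtDNA control-region
#' style alignment (one haploid locus) plus a panel of unlinked autosomal
#' microsatellites genotyped in diploid individuals. Defaults emulate the
#' motivating study system: 18 sequenced haplotypes of 512 nt with Ti/Tv
#' ratio 33 and per-site diversity near 0.009 (the Watterson value implied by
#' 16 segregating sites in 18 sequences), and 96 diploids at 7 loci with
#' `theta_msat = 4.9`, the stepwise-model value whose equilibrium expected
#' heterozygosity 1 - 1/sqrt(1 + 2*theta) is 0.695.
#'
#' @param seed Integer seed (mandatory; drives every random draw).
#' @param n_tips Number of haploid mtDNA lineages sampled.
#' @param n_individuals Number of diploid individuals genotyped.
#' @param n_loci Number of unlinked microsatellite loci.
#' @param L Sequence length in sites.
#' @param R Transition/transversion event ratio.
#' @param theta_seq Per-site theta for the sequence locus.
#' @param theta_msat Per-locus theta for each microsatellite.
#' @param ancestral_size Root repeat count for microsatellites.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, n_tips = 18, n_individuals = 96, n_loci = 7,
                       L = 512, R = 33, theta_seq = 0.009, theta_msat = 4.9,
                       ancestral_size = 20) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory in a sim_config")
  cfg <- list(seed = as.integer(seed), n_tips = as.integer(n_tips),
              n_individuals = as.integer(n_individuals),
              n_loci = as.integer(n_loci), L = as.integer(L), R = as.numeric(R),
              theta_seq = as.numeric(theta_seq),
              theta_msat = as.numeric(theta_msat),
              ancestral_size = as.integer(ancestral_size))
  assert_number(cfg$theta_seq, "theta_seq", lo = 0)
  assert_number(cfg$theta_msat, "theta_msat", lo = 0)
  assert_number(cfg$L, "L", lo = 1)
  assert_number(cfg$R, "R", lo = 0, allow_zero = FALSE)
  if (cfg$n_tips < 2) stop("n_tips must be >= 2")
  if (cfg$n_individuals < 1 || cfg$n_loci < 1)
    stop("n_individuals and n_loci must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Read / write a simulation configuration file
#'
#' Plain `key = value` text (lines starting with `#` ignored), or a JSON
#' object if the file starts with `{`. The `seed` key is mandatory.
#'
#' @param path File path.
#' @param cfg A [sim_config()].
#' @return `read_sim_config` returns a `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  first <- trimws(paste(txt, collapse = " "))
  if (startsWith(first, "{")) {
    vals <- jsonlite::fromJSON(paste(txt, collapse = "\n"))
  } else {
    txt <- trimws(txt)
    txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
    parts <- strsplit(txt, "=", fixed = TRUE)
    if (any(lengths(parts) != 2))
      stop("malformed config line: '", txt[which(lengths(parts) != 2)[1]], "'")
    vals <- lapply(parts, function(p) as.numeric(trimws(p[2])))
    names(vals) <- vapply(parts, function(p) trimws(p[1]), "")
  }
  if (is.null(vals$seed)) stop("config must specify a seed")
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, format, "", scientific = FALSE)), path)
  invisible(path)
}

#' Simulate a complete two-marker dataset
#'
#' Draws one Kingman genealogy for the haploid mtDNA locus (`n_tips`
#' lineages) and an independent genealogy of `2 * n_individuals` tips for
#' each microsatellite locus; consecutive tips are paired into diploid
#' genotypes (random mating). A microsatellite locus whose simulated allele
#' sizes dip below 1 repeat is rejected and re-simulated with a fresh derived
#' seed (rare at realistic theta with the default ancestral size of 20).
#' Identical configurations give byte-identical output files.
#'
#' @param config A [sim_config()].
#' @return A list with elements `alignment` ([seq_alignment()]),
#'   `genotypes` ([genotype_matrix()]), and `config`.
#' @examples
#' d <- simulate_dataset(sim_config(seed = 1, n_tips = 6, n_individuals = 10,
#'                                  n_loci = 2, L = 100))
#' d$alignment
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 2L * (config$n_loci + 1L))
  g_mt <- simulate_genealogy(config$n_tips, seed = seeds[1])
  aln <- evolve_sequences(g_mt, config$L, config$theta_seq, config$R,
                          seed = seeds[2])
  aln$labels <- paste0("hap", seq_len(config$n_tips))
  rownames(aln$seq) <- aln$labels

  ind <- paste0("ind", seq_len(config$n_individuals))
  rows <- vector("list", config$n_loci)
  for (j in seq_len(config$n_loci)) {
    locus_seed <- seeds[2 * j + 1] %% (.Machine$integer.max - 101L)
    for (attempt in 1:100) {
      sub <- derive_seeds(locus_seed + attempt - 1L, 2L)
      g <- simulate_genealogy(2L * config$n_individuals, seed = sub[1])
      sizes <- evolve_microsatellites(g, config$theta_msat,
                                      config$ancestral_size, seed = sub[2])
      if (all(sizes >= 1)) break
      if (attempt == 100) stop("locus re-simulation limit reached; ",
                               "increase ancestral_size")
    }
    odd <- seq(1, 2L * config$n_individuals, by = 2)
    rows[[j]] <- data.frame(individual = ind,
                            locus = paste0("locus", j),
                            allele1 = as.integer(sizes[odd]),
                            allele2 = as.integer(sizes[odd + 1]),
                            stringsAsFactors = FALSE)
  }
  gt <- do.call(rbind, rows)
  list(alignment = aln,
       genotypes = genotype_matrix(gt$individual, gt$locus,
                                   gt$allele1, gt$allele2),
       config = config)
}
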