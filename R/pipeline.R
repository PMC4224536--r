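#' Pipeline configuration
#'
#' One object describing an end-to-end run: where the data come from
#' (synthetic simulation, files on disk, or no data at all when explicit
#' theta priors are given), the MCMC settings for both markers, the mutation
#' rate priors, and the output directory. Exactly one data source may be
#' active.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Global integer seed; every stage seed is derived from it and
#'   echoed in the report.
#' @param sim A [sim_config()] for synthetic mode, or `NULL`.
#' @param fasta,genotypes Input file paths for file mode, or `NULL`.
#' @param theta_n_prior,theta_m_prior Explicit uniform bounds `c(lo, hi)`;
#'   when both are given the data stages are skipped entirely
#'   (replication mode). When `NULL` they are built from the 95% credible
#'   intervals of the fitted theta posteriors.
#' @param mu_n_prior,mu_m_prior Mutation-rate prior bounds (defaults: the
#'   published literature ranges).
#' @param seq_prior,msat_prior Uniform theta priors for the two coalescent
#'   MCMC runs.
#' @param R Transition/transversion ratio for the sequence likelihood.
#' @param mcmc_seq,mcmc_msat [mcmc_options()] for the two samplers (their
#'   seeds are overridden by seeds derived from `seed`).
#' @param n_ratio_samples Monte-Carlo draws for the ratio posterior.
#' @param ratio_mode `"published"` or `"adjusted"` (see
#'   [sample_ratio_posterior()]).
#' @param generation_time Years per generation (used in adjusted mode).
#' @param round_priors Round CI-derived theta prior bounds to the nearest
#'   multiple of half the power of ten below the CI width (the convention
#'   that turns a CI of 10.2-16.6 into bounds 10.0-16.5 and 0.012-0.048
#'   into 0.01-0.05).
#' @param log_level `"info"` (stage progress on stderr) or `"quiet"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed,
                            sim = NULL, fasta = NULL, genotypes = NULL,
                            theta_n_prior = NULL, theta_m_prior = NULL,
                            mu_n_prior = c(1e-5, 1e-3),
                            mu_m_prior = c(1e-8, 1e-7),
                            seq_prior = c(0, 0.1), msat_prior = c(0, 100),
                            R = 33,
                            mcmc_seq = mcmc_options(),
                            mcmc_msat = mcmc_options(),
                            n_ratio_samples = 1e5,
                            ratio_mode = "published",
                            generation_time = 3,
                            round_priors = FALSE,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  have_priors <- !is.null(theta_n_prior) && !is.null(theta_m_prior)
  have_files <- !is.null(fasta) || !is.null(genotypes)
  have_sim <- !is.null(sim)
  if (have_sim + have_files + have_priors != 1)
    stop("exactly one of {synthetic mode (sim), file mode (fasta+genotypes), ",
         "replication mode (both explicit theta priors)} must be active")
  if (have_files && (is.null(fasta) || is.null(genotypes)))
    stop("file mode needs both `fasta` and `genotypes`")
  if (have_sim) stopifnot(inherits(sim, "sim_config"))
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 fasta = fasta, genotypes = genotypes,
                 theta_n_prior = theta_n_prior, theta_m_prior = theta_m_prior,
                 mu_n_prior = mu_n_prior, mu_m_prior = mu_m_prior,
                 seq_prior = seq_prior, msat_prior = msat_prior, R = R,
                 mcmc_seq = mcmc_seq, mcmc_msat = mcmc_msat,
                 n_ratio_samples = n_ratio_samples, ratio_mode = ratio_mode,
                 generation_time = generation_time,
                 round_priors = round_priors, log_level = log_level),
            class = "pipeline_config")
}

# Round CI bounds to the grid the source analysis evidently used: the
# nearest multiple of half the power of ten below the interval width.
round_prior_bounds <- function(bounds) {
  step <- 10^floor(log10(bounds[2] - bounds[1])) / 2
  round(bounds / step) * step
}

pipe_log <- function(cfg, fmt, ...) {
  if (cfg$log_level == "info") message(sprintf(paste0("[neratio] ", fmt), ...))
}

#' Validate a pipeline report against the bundled schema
#'
#' The schema (`inst/extdata/report_schema.json`) lists the required
#' top-level fields and the required fields of the `ratio` block, with their
#' types. Called on every [run_pipeline()] report before it is written.
#'
#' @param report A report list as produced by [run_pipeline()].
#' @return `TRUE` invisibly; errors describing the first violation otherwise.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::fromJSON(system.file("extdata", "report_schema.json",
                                           package = "neratio"),
                               simplifyDataFrame = FALSE)
  check <- function(obj, fields, where) {
    for (f in fields) {
      if (is.null(obj[[f$name]]))
        stop("report field missing: ", where, f$name)
      ok <- switch(f$type,
                   list = is.list(obj[[f$name]]),
                   number = is.numeric(obj[[f$name]]),
                   string = is.character(obj[[f$name]]),
                   TRUE)
      if (!ok) stop("report field ", where, f$name, " must be of type ", f$type)
    }
  }
  check(report, schema$fields, "")
  check(report$ratio, schema$ratio_fields, "ratio$")
  invisible(TRUE)
}

theta_block <- function(post) {
  list(mean = post$mean, mode = post$mode,
       ci = as.numeric(post$ci), ess = post$ess,
       prior_bounds = as.numeric(post$prior_bounds),
       acceptance = as.list(post$acceptance),
       flags = as.list(post$flags))
}

#' Run the full pipeline
#'
#' Executes, in order: data acquisition (simulation, file input, or neither),
#' diversity indices, Bayesian theta estimation for both markers, prior
#' construction (uniform theta priors from the 95% credible intervals of the
#' theta posteriors, unless explicit bounds were configured), and the
#' Monte-Carlo ratio posterior. Writes `report.json` (deterministic:
#' byte-identical for identical configurations), `report.txt` (with a
#' timestamp), data files in synthetic mode, and theta trace files under
#' `traces/`.
#'
#' @param config A [pipeline_config()].
#' @return The report list, invisibly, with the fitted objects attached as
#'   attribute `objects`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 4L)
  seeds <- list(sim = seeds[1], theta_seq = seeds[2], theta_msat = seeds[3],
                ratio = seeds[4])
  aln <- gm <- NULL
  div <- thetas <- list()

  if (!is.null(config$sim)) {
    pipe_log(config, "simulating synthetic dataset (seed %d)", config$sim$seed)
    d <- simulate_dataset(config$sim)
    aln <- d$alignment; gm <- d$genotypes
    write_fasta(aln, file.path(config$out_dir, "sequences.fasta"))
    write_genotypes(gm, file.path(config$out_dir, "genotypes.tsv"))
  } else if (!is.null(config$fasta)) {
    pipe_log(config, "reading %s and %s", config$fasta, config$genotypes)
    aln <- read_fasta(config$fasta)
    gm <- read_genotypes(config$genotypes)
  }

  theta_n_prior <- config$theta_n_prior
  theta_m_prior <- config$theta_m_prior
  if (!is.null(aln)) {
    pipe_log(config, "computing diversity indices")
    div <- diversity_summary(aln, gm)

    pipe_log(config, "sequence theta MCMC (prior U[%g, %g])",
             config$seq_prior[1], config$seq_prior[2])
    opt_s <- config$mcmc_seq; opt_s$seed <- seeds$theta_seq
    post_seq <- bayes_theta_sequences(aln, config$seq_prior, config$R, opt_s)
    pipe_log(config, "  mean %.4g, CI (%.4g, %.4g), acc(theta) %.2f",
             post_seq$mean, post_seq$ci[1], post_seq$ci[2],
             post_seq$acceptance[["theta"]])

    pipe_log(config, "microsatellite theta MCMC (prior U[%g, %g])",
             config$msat_prior[1], config$msat_prior[2])
    opt_m <- config$mcmc_msat; opt_m$seed <- seeds$theta_msat
    post_msat <- bayes_theta_microsatellites(gm, config$msat_prior, opt_m)
    pipe_log(config, "  mean %.4g, CI (%.4g, %.4g), acc(theta) %.2f",
             post_msat$mean, post_msat$ci[1], post_msat$ci[2],
             post_msat$acceptance[["theta"]])

    tr_dir <- file.path(config$out_dir, "traces")
    dir.create(tr_dir, showWarnings = FALSE)
    utils::write.table(data.frame(sample = seq_along(post_seq$samples),
                                  theta = post_seq$samples),
                       file.path(tr_dir, "theta_seq.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample = seq_along(post_msat$samples),
                                  theta = post_msat$samples),
                       file.path(tr_dir, "theta_msat.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    thetas <- list(sequence = theta_block(post_seq),
                   microsatellite = theta_block(post_msat))

    theta_n_prior <- theta_n_prior %||% as.numeric(post_msat$ci)
    theta_m_prior <- theta_m_prior %||% as.numeric(post_seq$ci)
    if (config$round_priors) {
      theta_n_prior <- round_prior_bounds(theta_n_prior)
      theta_m_prior <- round_prior_bounds(theta_m_prior)
    }
  }

  prior <- prior_spec(theta_n = theta_n_prior, theta_m = theta_m_prior,
                      mu_n = config$mu_n_prior, mu_m = config$mu_m_prior,
                      generation_time = config$generation_time)
  pipe_log(config, "ratio posterior: %g draws (mode %s)",
           config$n_ratio_samples, config$ratio_mode)
  rp <- sample_ratio_posterior(prior, config$n_ratio_samples,
                               seed = seeds$ratio, mode = config$ratio_mode)
  rs <- summary(rp)

  report <- list(
    pipeline = list(
      package_version = as.character(utils::packageVersion("neratio")),
      mode = if (!is.null(config$sim)) "synthetic"
             else if (!is.null(config$fasta)) "files" else "replication",
      out_dir = config$out_dir),
    seeds = c(list(global = config$seed), seeds),
    diversity = if (length(div)) unclass(div) else NULL,
    theta = if (length(thetas)) thetas else NULL,
    priors = list(theta_n = prior$theta_n, theta_m = prior$theta_m,
                  mu_n = prior$mu_n, mu_m = prior$mu_m,
                  generation_time = prior$generation_time,
                  rounded = isTRUE(config$round_priors)),
    ratio = list(mean = rs$mean, sd = rs$sd, ci = as.numeric(rs$ci),
                 reduction_mean = rs$reduction_mean,
                 reduction_range = as.numeric(rs$reduction_range),
                 ne_mean = rs$ne_mean, nef_mean = rs$nef_mean,
                 n_samples = rs$n_samples, mode = rs$mode,
                 analytic_mean = analytic_mean_ratio(prior,
                                                     mode = config$ratio_mode)),
    notes = paste("theta_m is estimated per site from sequence data while",
                  "mu_m is a per-locus literature rate; the published",
                  "computation combines them as printed, and this unit",
                  "ambiguity is reproduced, not silently corrected."))
  report <- report[!vapply(report, is.null, TRUE)]
  validate_report(report)

  json_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt <- c(sprintf("neratio pipeline report (%s)", format(Sys.time())),
           sprintf("global seed: %d", config$seed),
           sprintf("theta_n prior: U[%g, %g]   theta_m prior: U[%g, %g]",
                   prior$theta_n[1], prior$theta_n[2],
                   prior$theta_m[1], prior$theta_m[2]),
           sprintf("mu_n prior: U[%g, %g]      mu_m prior: U[%g, %g]",
                   prior$mu_n[1], prior$mu_n[2],
                   prior$mu_m[1], prior$mu_m[2]),
           utils::capture.output(print(rs)),
           report$notes)
  writeLines(txt, file.path(config$out_dir, "report.txt"))
  pipe_log(config, "report written to %s", json_path)
  attr(report, "objects") <- list(alignment = aln, genotypes = gm, ratio = rp)
  invisible(report)
}
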