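#' MCMC options
#'
#' Tuning knobs for the single-chain Metropolis-Hastings sampler over
#' (genealogy, theta). Defaults are a desk-scale emulation of the study's
#' long coalescent runs: the posterior target is identical, only chain
#' length differs. Total iterations are `burn_in + n_samples * thin`.
#'
#' @param warmup Initialization iterations during which theta is held fixed
#'   at its moment-based starting value and only the latent genealogies
#'   move; lets the trees adapt to the data before the joint chain starts.
#' @param burn_in Iterations discarded before recording.
#' @param n_samples Number of recorded theta draws.
#' @param thin Record every `thin`-th post-burn-in iteration.
#' @param theta_step Random-walk s.d. for theta, as a fraction of the prior
#'   width (proposals are reflected at the prior bounds).
#' @param time_step Log-scale window width for node-time / tree-scale moves.
#' @param seed Integer seed; identical options give identical chains.
#' @return An `mcmc_options` list.
#' @export
mcmc_options <- function(burn_in = 20000L, n_samples = 2000L, thin = 50L,
                         warmup = 50000L, theta_step = 0.05, time_step = 0.7,
                         seed = 1L) {
  if (burn_in < 0 || warmup < 0 || n_samples < 1 || thin < 1)
    stop("burn_in and warmup must be >= 0; n_samples and thin must be positive")
  structure(list(burn_in = as.integer(burn_in),
                 n_samples = as.integer(n_samples), thin = as.integer(thin),
                 warmup = as.integer(warmup),
                 theta_step = theta_step, time_step = time_step,
                 seed = as.integer(seed)),
            class = "mcmc_options")
}

# ---- elementary proposals (pure functions; unit Hastings terms returned) ---

# Reflect x into [lo, hi] (folding preserves symmetry of the random walk).
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + if (y > w) 2 * w - y else y
}

# Set the time of a non-root internal node (slide within its free interval).
move_slide <- function(g, node, t_new) {
  g$node_time[node] <- t_new
  g
}

slide_interval <- function(g, node) {
  par <- genealogy_parent(g)
  c(max(g$node_time[g$children[node - g$n_tips, ]]), g$node_time[par[node]])
}

# Multiplicative move on the root's excess time above its older child.
# log-Hastings = u (Jacobian of scaling one coordinate by exp(u)).
move_root <- function(g, u) {
  rt <- root_node(g)
  base <- max(g$node_time[g$children[rt - g$n_tips, ]])
  g$node_time[rt] <- base + (g$node_time[rt] - base) * exp(u)
  list(g = g, log_hastings = u)
}

# Scale all node times by exp(u); log-Hastings = (n_tips - 1) * u.
move_scale <- function(g, u) {
  g$node_time <- g$node_time * exp(u)
  list(g = g, log_hastings = (g$n_tips - 1) * u)
}

# Narrow exchange: swap a child of internal node p with p's sibling s.
# Valid when time[s] < time[p]; returns NULL when the draw is invalid
# (counted as a rejection). Times are untouched, so both the coalescent
# density and the Hastings ratio are unchanged.
move_exchange <- function(g, p, child_idx) {
  n <- g$n_tips
  par <- genealogy_parent(g)
  if (par[p] == 0) return(NULL)
  gp <- par[p]
  sib <- setdiff(g$children[gp - n, ], p)
  if (g$node_time[sib] >= g$node_time[p]) return(NULL)
  ch <- g$children[p - n, child_idx]
  g$children[gp - n, g$children[gp - n, ] == sib] <- ch
  g$children[p - n, child_idx] <- sib
  g
}

# ---- data-driven starting tree -------------------------------------------

# UPGMA topology on a distance matrix. Node times either drawn from the
# Kingman prior (assigned in merge order, so parents stay older than
# children) or supplied as data-derived heights. Initialization only; the
# stationary distribution is untouched.
upgma_genealogy <- function(d, n, heights = NULL) {
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  children <- matrix(0L, n - 1, 2)
  for (r in seq_len(n - 1)) {
    m <- hc$merge[r, ]
    children[r, ] <- ifelse(m < 0, -m, n + m)
  }
  times <- if (is.null(heights)) cumsum(stats::rexp(n - 1, rate = choose(n:2, 2)))
           else heights(hc$height)
  # enforce strictly increasing positive times along the merge order
  # hclust merges children before parents, so strictly increasing times
  # along the merge order imply parent > child everywhere
  eps <- max(times[n - 1], 1e-3) * 1e-4
  for (r in seq_len(n - 1)) {
    prev <- if (r > 1) times[r - 1] else 0
    times[r] <- max(times[r], prev + eps, eps)
  }
  new_genealogy(n, children, c(numeric(n), times))
}

# Data-consistent starting tree for the Brownian sampler: UPGMA heights are
# mean absolute allele differences; under Brownian motion E|diff| at
# divergence v is sqrt(2v/pi) with v = theta * t, so t = pi h^2 / (2 theta).
bm_start_genealogy <- function(x, theta_hat) {
  upgma_genealogy(abs(outer(x, x, "-")), length(x),
                  heights = function(h) pi * h^2 / (2 * max(theta_hat, 1e-3)))
}

# ---- the sampler ----------------------------------------------------------

# Production sampler: the whole Metropolis-Hastings loop runs in C++
# (src/engine.cpp) so that topology mixing on ~200-tip genealogies is
# affordable. `data` is a list of per-locus NumericVectors (type "bm") or of
# lists with $patterns/$weights (type "k2p"). Cross-checked against the R
# reference engine below in the test suite.
run_theta_mcmc <- function(gens, data, type = c("bm", "k2p"), bounds,
                           options = mcmc_options(), prior_only = FALSE,
                           theta_init = NULL, nugget = 0, discretize = 0L,
                           R = 33, move_weights = numeric(0)) {
  type <- match.arg(type)
  theta_init <- theta_init %||% mean(bounds)
  res <- with_seed_opt(options$seed,
    mcmc_engine_cpp(lapply(gens, `[[`, "children"),
                    lapply(gens, `[[`, "node_time"),
                    data, if (type == "bm") 0L else 1L,
                    nugget, discretize, R, bounds, theta_init,
                    options$warmup %||% 0L,
                    options$burn_in, options$n_samples, options$thin,
                    options$theta_step, options$time_step, prior_only,
                    move_weights))
  res$gens <- lapply(seq_along(gens), function(j)
    new_genealogy(gens[[j]]$n_tips, res$children[[j]], res$times[[j]]))
  res
}

# Reference implementation of the same sampler in pure R, kept for
# validation: move-level reversibility tests and engine cross-checks target
# this function. `loglik(j, gen, theta)` returns the locus-j log-likelihood.
# Moves: reflected/multiplicative random walk on theta; node-time slides;
# narrow exchanges; per-locus tree scaling; and a "ridge" move scaling all
# times by f and theta by 1/f, which leaves every branch's mutational length
# (theta/2 * dt) -- and hence the likelihood -- exactly invariant.
run_theta_mcmc_r <- function(gens, loglik, bounds, options = mcmc_options(),
                             prior_only = FALSE, theta_init = NULL) {
  lo <- bounds[1]; hi <- bounds[2]
  if (!(hi > lo) || lo < 0) stop("prior bounds must satisfy 0 <= lo < hi")
  n_loci <- length(gens)
  with_seed_opt(options$seed, {
    theta <- theta_init %||% ((lo + hi) / 2)
    theta <- min(max(theta, lo + 1e-3 * (hi - lo)), hi - 1e-3 * (hi - lo))
    ll_of <- function(j, g, th) if (prior_only) 0 else loglik(j, g, th)
    ll <- vapply(seq_len(n_loci), function(j) ll_of(j, gens[[j]], theta), 0)
    lpc <- vapply(gens, coalescent_log_density, 0)
    m_internal <- vapply(gens, function(g) g$n_tips - 1L, 0L)

    moves <- c("theta", "thetam", "slide", "exchange", "scale", "ridge")
    w <- c(0.22, 0.13, 0.30, 0.15, 0.10, 0.10)
    n_iter <- options$burn_in + options$n_samples * options$thin
    samples <- numeric(options$n_samples)
    acc <- att <- stats::setNames(numeric(length(moves)), moves)
    step_theta <- options$theta_step * (hi - lo)
    ts <- options$time_step
    k_rec <- 0L

    for (it in seq_len(n_iter)) {
      mv <- sample(moves, 1, prob = w)
      att[mv] <- att[mv] + 1
      if (mv %in% c("theta", "thetam")) {
        # additive reflected walk covers the prior; the multiplicative walk
        # (log-Hastings u) traverses orders of magnitude under wide priors
        if (mv == "theta") {
          th_new <- reflect_into(theta + stats::rnorm(1, 0, step_theta), lo, hi)
          logh <- 0
        } else {
          u <- stats::rnorm(1, 0, 0.4)
          th_new <- theta * exp(u)
          logh <- u
          if (th_new <= lo || th_new >= hi) th_new <- NA
        }
        if (!is.na(th_new)) {
          ll_new <- vapply(seq_len(n_loci),
                           function(j) ll_of(j, gens[[j]], th_new), 0)
          if (log(stats::runif(1)) < sum(ll_new) - sum(ll) + logh) {
            theta <- th_new; ll <- ll_new; acc[mv] <- acc[mv] + 1
          }
        }
      } else if (mv == "ridge") {
        u <- stats::runif(1, -ts / 2, ts / 2)
        th_new <- theta * exp(-u)
        if (th_new > lo && th_new < hi) {
          gens_new <- lapply(gens, function(g) { g$node_time <- g$node_time * exp(u); g })
          lpc_new <- vapply(gens_new, coalescent_log_density, 0)
          logr <- sum(lpc_new) - sum(lpc) + (sum(m_internal) - 1) * u
          if (log(stats::runif(1)) < logr) {
            theta <- th_new; gens <- gens_new; lpc <- lpc_new
            acc[mv] <- acc[mv] + 1
          }
        }
      } else {
        j <- if (n_loci == 1) 1L else sample.int(n_loci, 1)
        g <- gens[[j]]
        n <- g$n_tips
        if (mv == "slide") {
          node <- n + sample.int(n - 1, 1)
          if (node == root_node(g)) {
            prop <- move_root(g, stats::runif(1, -ts, ts))
            g_new <- prop$g; logh <- prop$log_hastings
          } else {
            iv <- slide_interval(g, node)
            g_new <- move_slide(g, node, stats::runif(1, iv[1], iv[2]))
            logh <- 0
          }
        } else if (mv == "scale") {
          prop <- move_scale(g, stats::runif(1, -ts / 2, ts / 2))
          g_new <- prop$g; logh <- prop$log_hastings
        } else {  # exchange
          g_new <- if (n < 3) NULL
                   else move_exchange(g, n + sample.int(n - 1, 1),
                                      sample.int(2, 1))
          logh <- 0
        }
        if (!is.null(g_new)) {  # invalid exchange draws count as rejections
          ll_new <- ll_of(j, g_new, theta)
          lpc_new <- coalescent_log_density(g_new)
          if (log(stats::runif(1)) < ll_new - ll[j] + lpc_new - lpc[j] + logh) {
            gens[[j]] <- g_new; ll[j] <- ll_new; lpc[j] <- lpc_new
            acc[mv] <- acc[mv] + 1
          }
        }
      }
      if (it > options$burn_in &&
          (it - options$burn_in) %% options$thin == 0) {
        k_rec <- k_rec + 1L
        samples[k_rec] <- theta
      }
    }
    list(samples = samples, acceptance = ifelse(att > 0, acc / att, NA),
         gens = gens)
  })
}

# ---- posterior container --------------------------------------------------

new_theta_posterior <- function(samples, prior_bounds, acceptance, options,
                                marker) {
  e <- ess(samples)
  ci <- stats::quantile(samples, c(0.025, 0.975), names = FALSE)
  flags <- character()
  if (e < 100) flags <- c(flags, "low-ess")
  w <- diff(prior_bounds)
  if (mean(samples < prior_bounds[1] + 0.01 * w) > 0.5)
    flags <- c(flags, "boundary-pileup-low")
  structure(list(samples = samples,
                 mean = mean(samples),
                 mode = posterior_mode(samples, prior_bounds[1], prior_bounds[2]),
                 ci = ci, ess = e, prior_bounds = prior_bounds,
                 acceptance = acceptance, options = options,
                 marker = marker, flags = flags),
            class = "theta_posterior")
}

#' @export
print.theta_posterior <- function(x, ...) {
  cat(sprintf("<theta_posterior> [%s] mean %.4g, mode %.4g, 95%% CI (%.4g, %.4g)\n",
              x$marker, x$mean, x$mode, x$ci[1], x$ci[2]))
  cat(sprintf("  %d samples, ESS %.0f, prior U[%.4g, %.4g]%s\n",
              length(x$samples), x$ess, x$prior_bounds[1], x$prior_bounds[2],
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Equal-tail credible interval from posterior samples
#'
#' Empirical order-statistic quantiles (linear interpolation) at
#' `(1 - level)/2` and `1 - (1 - level)/2`.
#'
#' @param posterior A `theta_posterior` or a numeric vector of draws
#'   (at least 100).
#' @param level Coverage level in (0, 1].
#' @return Numeric `(lo, hi)`.
#' @export
credible_interval <- function(posterior, level = 0.95) {
  x <- if (inherits(posterior, "theta_posterior")) posterior$samples else posterior
  if (length(x) < 100) stop("need at least 100 post-burn-in samples")
  if (level <= 0 || level > 1) stop("level must be in (0, 1]")
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), names = FALSE)
}

# ---- user-facing samplers -------------------------------------------------

#' Bayesian theta from a sequence alignment
#'
#' Single-chain Metropolis-Hastings over (genealogy, theta): the genealogy
#' moves by node-time slides, narrow exchanges and scalings; theta by a
#' reflected random walk under a uniform prior. The sequence likelihood is
#' Felsenstein pruning under a Kimura two-parameter model with
#' transition/transversion event ratio `R`; genealogy times carry a Kingman
#' coalescent prior, with mutation rate `theta/2` per site per time unit, so
#' the estimated theta is the per-site pairwise diversity parameter.
#'
#' @param aln A [seq_alignment()] with at least 3 sequences.
#' @param prior_bounds Uniform prior `(lo, hi)` for per-site theta
#'   (default `c(0, 0.1)`, the study's sequence prior).
#' @param R Transition/transversion ratio (default 33).
#' @param options An [mcmc_options()].
#' @param prior_only Disable the likelihood (sampler-validation mode; the
#'   posterior must then reproduce the uniform prior).
#' @return A `theta_posterior`. Non-convergence is flagged in `$flags`
#'   (`"low-ess"`), never thrown.
#' @export
bayes_theta_sequences <- function(aln, prior_bounds = c(0, 0.1), R = 33,
                                  options = mcmc_options(),
                                  prior_only = FALSE) {
  stopifnot(inherits(aln, "seq_alignment"))
  n <- n_sequences(aln)
  if (n < 3) stop("need at least 3 sequences")
  codes <- matrix(match(aln$seq, BASES), nrow = n)
  key <- apply(codes, 2, paste, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  tip_patterns <- codes[, first, drop = FALSE]
  weights <- as.numeric(tab)
  L <- alignment_length(aln)

  # proportion of differing sites as UPGMA distance
  pd <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    pd[i, j] <- pd[j, i] <- mean(codes[i, ] != codes[j, ])

  S <- site_summary(aln)$S
  theta_init <- watterson_theta(S, n, L = L)

  g0 <- with_seed_opt(derive_seeds(options$seed, 1), upgma_genealogy(pd, n))
  res <- run_theta_mcmc(list(g0),
                        data = list(list(patterns = tip_patterns,
                                         weights = weights)),
                        type = "k2p", R = R,
                        bounds = prior_bounds, options = options,
                        prior_only = prior_only, theta_init = theta_init)
  new_theta_posterior(res$samples, prior_bounds, res$acceptance, options,
                      marker = "sequence")
}

#' Bayesian theta from diploid microsatellite genotypes
#'
#' Same MCMC skeleton as [bayes_theta_sequences()], with one latent
#' genealogy per locus (each diploid genotype contributes two tip lineages)
#' and a Brownian-motion approximation to the stepwise mutation model: tip
#' allele sizes are modelled as Brownian motion on the genealogy with
#' variance accumulating at `theta/2` per coalescent time unit, root state
#' integrated out (REML form). Loci are independent given the shared theta.
#'
#' @param gm A [genotype_matrix()].
#' @param prior_bounds Uniform prior `(lo, hi)` for per-locus theta
#'   (default `c(0, 100)`, the study's microsatellite prior). A floor of
#'   `1e-6` is applied internally because the Brownian density is singular
#'   at theta = 0.
#' @param options An [mcmc_options()].
#' @param prior_only Disable the likelihood (sampler-validation mode).
#' @param contrast How each pruning contrast enters the likelihood. Repeat
#'   counts are whole numbers, so exact allele ties are common, and a plain
#'   Gaussian density (`"gaussian"`) rewards collapsing tied alleles into
#'   zero-variance clusters without bound. `"skellam"` (default) scores a
#'   contrast of size c at variance v with the exact displacement
#'   distribution of a +/-1 stepwise walk, \eqn{e^{-v} I_{|c|}(v)} -- correct
#'   leptokurtosis at small v, Gaussian in the large-v limit; `"binned"`
#'   uses the unit-bin normal integral (bounded but still light-tailed at
#'   small v).
#' @param nugget Extra variance attached to each tip; only useful as a
#'   tie-regularization with `contrast = "gaussian"` (1/12 is the rounding
#'   variance of an integer observation).
#' @param n_chains Number of independent chains, run from different
#'   starting genealogies and pooled. Latent-genealogy mixing on ~200-tip
#'   trees is the slow direction of this posterior; pooling independent
#'   starts widens under-converged intervals instead of narrowing them and
#'   exposes disagreement through the `"chains-disagree"` flag (split-R-hat
#'   style between/within variance check).
#' @return A `theta_posterior` (theta per locus). Monomorphic data pile up
#'   at the lower bound and are flagged `"boundary-pileup-low"`.
#' @export
bayes_theta_microsatellites <- function(gm, prior_bounds = c(0, 100),
                                        options = mcmc_options(),
                                        prior_only = FALSE,
                                        contrast = c("skellam", "binned",
                                                     "gaussian"),
                                        nugget = 0, n_chains = 1L) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(gm, "genotype_matrix"))
  loci <- gm_loci(gm)
  values <- lapply(loci, function(l) locus_alleles(gm, l))
  keep <- lengths(values) >= 4
  if (!all(keep)) warning("dropping loci with < 2 typed individuals: ",
                          paste(loci[!keep], collapse = ", "))
  values <- values[keep]
  if (!length(values)) stop("no usable locus")
  lo_eff <- max(prior_bounds[1], 1e-6)
  bounds <- c(lo_eff, prior_bounds[2])

  # median across loci: a single deep-genealogy locus can inflate the mean
  # variance severalfold and strand the warm-up far above the posterior
  v_bar <- stats::median(vapply(values, stats::var, 0))
  theta_init <- smm_theta_from_size_variance(v_bar)

  chain_seeds <- derive_seeds(options$seed, 2L * n_chains)
  chains <- vector("list", n_chains)
  acceptance <- NULL
  for (ch in seq_len(n_chains)) {
    # start from UPGMA topologies on JITTERED allele-size distances with
    # coalescent-prior node times: exact-tie clusters in a plain UPGMA
    # start strand the chain in an overfitted low-theta basin, while fully
    # random topologies need very long relaxation; jitter of up to two
    # repeat units (about one mutation step) breaks the tie clusters but
    # keeps the coarse structure (see the methods vignette)
    gens <- with_seed_opt(chain_seeds[2 * ch - 1],
                          lapply(values, function(x) {
                            n <- length(x)
                            d <- abs(outer(x, x, "-")) +
                              matrix(stats::runif(n * n, 0, 2), n)
                            d <- (d + t(d)) / 2
                            diag(d) <- 0
                            upgma_genealogy(d, n)
                          }))
    opt_ch <- options
    opt_ch$seed <- chain_seeds[2 * ch]
    # tree moves are cheap under the incremental pruning cache while theta
    # moves recompute every locus; weight the chain toward tree mixing,
    # which is the limiting factor on ~200-tip genealogies
    res <- run_theta_mcmc(gens, data = lapply(values, as.numeric),
                          type = "bm", nugget = nugget,
                          discretize = switch(contrast, gaussian = 0L,
                                              binned = 1L, skellam = 2L),
                          bounds = bounds, options = opt_ch,
                          prior_only = prior_only, theta_init = theta_init,
                          move_weights = if (prior_only) numeric(0)
                                         else c(0.025, 0.015, 0.26, 0.14,
                                                0.09, 0.085, 0.085, 0.30))
    chains[[ch]] <- res$samples
    acceptance <- if (is.null(acceptance)) res$acceptance
                  else acceptance + res$acceptance
  }
  post <- new_theta_posterior(unlist(chains), prior_bounds,
                              acceptance / n_chains, options,
                              marker = "microsatellite")
  post$ess <- sum(vapply(chains, ess, 0))
  if (n_chains > 1) {
    m <- vapply(chains, mean, 0)
    w <- mean(vapply(chains, stats::var, 0))
    if (stats::var(m) > w)  # between-chain exceeds within-chain variance
      post$flags <- c(post$flags, "chains-disagree")
  }
  post
}
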