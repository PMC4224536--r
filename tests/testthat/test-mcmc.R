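# ---- likelihood oracles ---------------------------------------------------

test_that("K2P pruning likelihood matches phangorn on random trees", {
  skip_if_not_installed("phangorn")
  withr::with_seed(42, {
    for (R in c(1, 33)) {
      tree <- ape::rcoal(6)
      g <- simulate_genealogy(6, seed = 17)
      aln <- evolve_sequences(g, 60, 0.05, R = R, seed = 18)
      # evaluate MY likelihood on an ape tree by converting it to a genealogy
      # with theta chosen so branch distances equal theta/2 * dt
      theta <- 0.04
      codes <- matrix(match(aln$seq, neratio:::BASES), nrow = 6)
      key <- apply(codes, 2, paste, collapse = ",")
      tab <- table(key)
      patterns <- codes[, match(names(tab), key), drop = FALSE]
      wts <- as.numeric(tab)

      # my genealogy -> ll via exported pruning
      ll_mine <- neratio:::k2p_loglik_cpp(patterns, wts, g$children,
                                          g$node_time, theta, R)

      # phangorn oracle on the same tree: edge lengths in expected
      # substitutions per site are theta/2 * dt; Q order AC,AG,AT,CG,CT,GT
      ph <- as.phylo(g)
      ph$edge.length <- ph$edge.length * theta / 2
      dat <- phangorn::phyDat(setNames(strsplit(apply(aln$seq, 1, paste0,
                                                      collapse = ""), ""),
                                       aln$labels), type = "DNA")
      names(dat) <- paste0("t", 1:6)
      fit <- phangorn::pml(ph, dat, bf = rep(0.25, 4),
                           Q = c(1, 2 * R, 1, 1, 2 * R, 1))
      expect_equal(ll_mine, as.numeric(fit$logLik), tolerance = 1e-6)
    }
  })
})

test_that("Brownian REML pruning equals the flat-prior multivariate normal", {
  # oracle: integrate the root state out of the full MVN analytically
  mvn_reml <- function(x, V) {
    n <- length(x)
    A <- cbind(-1, diag(n - 1))    # contrasts x_i - x_1
    y <- as.numeric(A %*% x)
    S <- A %*% V %*% t(A)
    -0.5 * ((n - 1) * log(2 * pi) + determinant(S)$modulus +
            t(y) %*% solve(S, y))
  }
  withr::with_seed(7, {
    for (rep in 1:5) {
      n <- 6
      g <- simulate_genealogy(n)
      x <- rnorm(n, 20, 3)
      theta <- runif(1, 0.5, 10)
      # shared-path covariance: V_ij = theta/2 * (tmrca - t_ij)
      ph <- as.phylo(g)
      vcv <- ape::vcv(ph) * theta / 2
      ll_oracle <- as.numeric(mvn_reml(x, vcv))
      ll_mine <- neratio:::bm_reml_loglik_cpp(x, g$children, g$node_time, theta)
      expect_equal(ll_mine, ll_oracle, tolerance = 1e-8)
    }
  })
})

test_that("Skellam contrast model is exact for a two-tip comparison", {
  # oracle: for two tips split by time t, the allele difference is the net
  # displacement of a +/-1 walk with Poisson(theta*t) steps: Skellam pmf
  g2 <- new_genealogy(2, matrix(c(1L, 2L), 1), c(0, 0, 1))
  for (theta in c(0.5, 4, 20)) {
    for (k in 0:4) {
      ll <- neratio:::bm_reml_loglik_cpp(c(20, 20 + k), g2$children,
                                         g2$node_time, theta, 0, 2L)
      expect_equal(exp(ll), exp(-theta) * besselI(theta, k), tolerance = 1e-10)
    }
  }
  # probabilities over integer displacements sum to 1 (doubling the
  # positive side, k = 0 counted once)
  p <- vapply(0:60, function(k)
    exp(neratio:::bm_reml_loglik_cpp(c(20, 20 + k), g2$children,
                                     g2$node_time, 6, 0, 2L)), 0)
  expect_equal(2 * sum(p) - p[1], 1, tolerance = 1e-8)
})

test_that("discretized Brownian likelihood is bounded and tie-consistent", {
  g <- gen3(0.5, 1.5)
  # identical tips: probability of a tie rises monotonically as theta -> 0
  lls <- vapply(c(5, 1, 0.1, 0.01), function(th)
    neratio:::bm_reml_loglik_cpp(c(20, 20, 20), g$children, g$node_time,
                                 th, 0, TRUE), 0)
  expect_true(all(diff(lls) > 0))
  expect_lte(max(lls), 0)  # probabilities, not densities
  # far-apart tips at tiny variance are (log-)impossible, not NaN
  ll_far <- neratio:::bm_reml_loglik_cpp(c(10, 30, 20), g$children,
                                         g$node_time, 1e-4, 0, TRUE)
  expect_true(is.finite(ll_far) || ll_far == -Inf)
})

test_that("two equal tips make the continuous Brownian likelihood favor theta -> 0", {
  g2 <- new_genealogy(2, matrix(c(1L, 2L), 1), c(0, 0, 1))
  ll <- vapply(c(2, 0.5, 0.1, 0.01), function(th)
    neratio:::bm_reml_loglik_cpp(c(20, 20), g2$children, g2$node_time, th), 0)
  expect_true(all(diff(ll) > 0))
})

# ---- sampler validity -----------------------------------------------------

test_that("both samplers recover their uniform priors in prior-only mode", {
  g <- simulate_genealogy(10, seed = 1)
  aln <- evolve_sequences(g, 100, 0.02, seed = 2)
  opts <- mcmc_options(warmup = 0, burn_in = 2000, n_samples = 5000,
                       thin = 10, seed = 9)
  ps <- bayes_theta_sequences(aln, c(0, 0.1), options = opts, prior_only = TRUE)
  expect_lt(abs(ps$mean - 0.05), 4 * 0.1 / sqrt(12) / sqrt(max(ps$ess, 1)))
  expect_gt(ps$ess, 30)

  gm <- simulate_dataset(sim_config(seed = 3, n_tips = 4, n_individuals = 10,
                                    n_loci = 2, L = 20))$genotypes
  pm <- bayes_theta_microsatellites(gm, c(0, 100), options = opts,
                                    prior_only = TRUE)
  expect_lt(abs(pm$mean - 50), 4 * 100 / sqrt(12) / sqrt(max(pm$ess, 1)))
})

test_that("chains are deterministic under the seed", {
  g <- simulate_genealogy(8, seed = 4)
  aln <- evolve_sequences(g, 120, 0.03, seed = 5)
  p1 <- bayes_theta_sequences(aln, options = fast_opts(seed = 33))
  p2 <- bayes_theta_sequences(aln, options = fast_opts(seed = 33))
  expect_identical(p1$samples, p2$samples)
  p3 <- bayes_theta_sequences(aln, options = fast_opts(seed = 34))
  expect_false(identical(p1$samples, p3$samples))
})

test_that("elementary proposals are reversible with antisymmetric Hastings terms", {
  g <- simulate_genealogy(9, seed = 6)
  u <- 0.3

  sc <- neratio:::move_scale(g, u)
  back <- neratio:::move_scale(sc$g, -u)
  expect_equal(back$g$node_time, g$node_time)
  expect_equal(sc$log_hastings + back$log_hastings, 0)
  expect_equal(sc$log_hastings, (g$n_tips - 1) * u)

  rm1 <- neratio:::move_root(g, u)
  rm2 <- neratio:::move_root(rm1$g, -u)
  expect_equal(rm2$g$node_time, g$node_time)
  expect_equal(rm1$log_hastings + rm2$log_hastings, 0)

  # narrow exchange is an involution with symmetric proposal probability
  par <- neratio:::genealogy_parent(g)
  internal <- which(par > 0 & seq_along(par) > g$n_tips)
  for (p in internal) {
    for (ci in 1:2) {
      g2 <- neratio:::move_exchange(g, p, ci)
      if (is.null(g2)) next
      g3 <- neratio:::move_exchange(g2, p, ci)
      expect_equal(g3$children, g$children)
    }
  }

  # theta reflection stays inside the bounds and is symmetric
  for (x in c(-0.4, 0.02, 0.097, 0.31)) {
    y <- neratio:::reflect_into(x, 0, 0.1)
    expect_gte(y, 0); expect_lte(y, 0.1)
  }
})

test_that("the C++ engine and the R reference engine sample the same posterior", {
  # small two-locus Brownian problem both engines can mix easily
  withr::with_seed(10, {
    gens <- lapply(1:2, function(i) simulate_genealogy(6))
    xs <- lapply(gens, function(g) {
      as.numeric(evolve_microsatellites(g, 4, 30))
    })
  })
  bounds <- c(1e-6, 50)
  opts_cpp <- mcmc_options(warmup = 0, burn_in = 10000, n_samples = 4000,
                           thin = 10, seed = 2)
  res_cpp <- neratio:::run_theta_mcmc(gens, xs, "bm", bounds, opts_cpp,
                                      theta_init = 4)
  opts_r <- mcmc_options(warmup = 0, burn_in = 10000, n_samples = 4000,
                         thin = 10, seed = 3)
  res_r <- neratio:::run_theta_mcmc_r(
    gens, function(j, g, th)
      neratio:::bm_reml_loglik_cpp(xs[[j]], g$children, g$node_time, th),
    bounds, opts_r, theta_init = 4)
  m1 <- mean(res_cpp$samples); m2 <- mean(res_r$samples)
  se <- sqrt(var(res_cpp$samples) / neratio:::ess(res_cpp$samples) +
             var(res_r$samples) / neratio:::ess(res_r$samples))
  expect_lt(abs(m1 - m2), 4 * se)
})

test_that("monomorphic data collapse the posterior toward zero variation", {
  aln <- aln_from(rep("ACGTACGTACGTACGTACGT", 10))
  p <- bayes_theta_sequences(aln, options = fast_opts(seed = 8))
  # posterior median below the Watterson value a single segregating site
  # would imply
  expect_lt(median(p$samples), watterson_theta(1, 10, L = 20))

  gm <- gm_from(list(L1 = cbind(rep(20, 12), rep(20, 12))))
  pm <- bayes_theta_microsatellites(gm, c(0, 100), options = fast_opts(seed = 9))
  expect_true("boundary-pileup-low" %in% pm$flags)
})

test_that("credible_interval implements equal-tail order-statistic quantiles", {
  expect_equal(credible_interval(1:100, 0.95),
               quantile(1:100, c(0.025, 0.975), names = FALSE))
  expect_equal(credible_interval(1:100, 1), c(1, 100))
  expect_equal(credible_interval(rep(3.3, 200)), c(3.3, 3.3))
  expect_error(credible_interval(1:10), "100")
})

test_that("posterior mean of theta tracks the Watterson estimator across datasets", {
  # moment-estimator agreement invariant: r > 0.8 over replicates spanning
  # theta in [0.005, 0.05]
  withr::with_seed(123, {
    thetas <- seq(0.005, 0.05, length.out = 15)
    est <- t(vapply(thetas, function(th) {
      g <- simulate_genealogy(12)
      aln <- evolve_sequences(g, 300, th)
      S <- site_summary(aln)$S
      p <- bayes_theta_sequences(aln, options = mcmc_options(
        warmup = 2000, burn_in = 8000, n_samples = 800, thin = 10,
        seed = round(th * 1e4)))
      c(watterson = watterson_theta(S, 12, L = 300), bayes = p$mean)
    }, c(watterson = 0, bayes = 0)))
  })
  expect_gt(cor(est[, "watterson"], est[, "bayes"]), 0.8)
})
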