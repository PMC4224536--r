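paper_priors <- function() prior_spec()  # defaults are the published bounds

test_that("degenerate ideal priors give ratio exactly 2 and reduction 0", {
  pr <- prior_spec(theta_n = c(4, 4 + 1e-12), theta_m = c(1, 1 + 1e-12),
                   mu_n = c(1e-4, 1e-4 + 1e-16), mu_m = c(1e-4, 1e-4 + 1e-16))
  rp <- sample_ratio_posterior(pr, 1000, seed = 1)
  expect_equal(rp$ratio, rep(2, 1000), tolerance = 1e-9)
  s <- summary(rp)
  expect_equal(s$reduction_mean, 0)
  expect_equal(s$reduction_range, c(0, 0))
  expect_equal(analytic_mean_ratio(pr), 2, tolerance = 1e-6)
})

test_that("closed-form mean matches its hand-derived value and scaling laws", {
  pr <- paper_priors()
  # E[ratio] = E[theta_n] E[mu_m] E[1/theta_m] E[1/mu_n] / 2 with
  # E[1/U(a,b)] = log(b/a)/(b-a)
  byhand <- 13.25 * 5.5e-8 * (log(5) / 0.04) * (log(100) / 9.9e-4) / 2
  expect_equal(analytic_mean_ratio(pr), byhand)
  expect_equal(byhand, 0.0682, tolerance = 1e-3)

  pr2 <- prior_spec(mu_m = c(2e-8, 2e-7))
  expect_equal(analytic_mean_ratio(pr2), 2 * analytic_mean_ratio(pr))
})

test_that("Monte-Carlo mean converges to the analytic oracle", {
  pr <- paper_priors()
  rp <- sample_ratio_posterior(pr, 2e5, seed = 42)
  expect_lt(abs(mean(rp$ratio) - analytic_mean_ratio(pr)),
            4 * sd(rp$ratio) / sqrt(nrow(rp)))
})

test_that("draws satisfy the row-wise effective-size identities", {
  rp <- sample_ratio_posterior(paper_priors(), 5000, seed = 3)
  expect_equal(rp$Ne, rp$theta_n / (4 * rp$mu_n))
  expect_equal(rp$Nef, rp$theta_m / (2 * rp$mu_m))
  expect_equal(rp$ratio, rp$Ne / rp$Nef)
  expect_equal(rp$reduction, 100 * (1 - rp$ratio / 2))
  expect_true(all(rp$ratio > 0))
})

test_that("generation-time mode multiplies the ratio by T", {
  pr <- paper_priors()
  rp_pub <- sample_ratio_posterior(pr, 2000, seed = 5, mode = "published")
  rp_adj <- sample_ratio_posterior(pr, 2000, seed = 5, mode = "adjusted")
  expect_equal(rp_adj$ratio, rp_pub$ratio * 3, tolerance = 1e-12)
  expect_equal(analytic_mean_ratio(pr, "adjusted"),
               3 * analytic_mean_ratio(pr, "published"))
})

test_that("raising theta_n raises the mean ratio; raising mu_n lowers it", {
  base <- analytic_mean_ratio(paper_priors())
  up_thn <- analytic_mean_ratio(prior_spec(theta_n = c(20, 26.5)))
  up_mun <- analytic_mean_ratio(prior_spec(mu_n = c(1e-4, 1e-2)))
  expect_gt(up_thn, base)
  expect_lt(up_mun, base)
  # and the same ordering holds for the Monte-Carlo means
  m <- function(pr) mean(sample_ratio_posterior(pr, 5e4, seed = 11)$ratio)
  expect_gt(m(prior_spec(theta_n = c(20, 26.5))), m(paper_priors()))
})

test_that("summary matches brute-force recomputation on an explicit draw set", {
  rp <- sample_ratio_posterior(paper_priors(), 5, seed = 21)
  s <- summary(rp)
  r <- rp$ratio
  expect_equal(s$mean, mean(r))
  expect_equal(s$sd, sqrt(mean((r - mean(r))^2)))
  expect_equal(s$ci, quantile(r, c(0.025, 0.975), names = FALSE))
  expect_equal(s$reduction_mean, round(100 * (1 - mean(r) / 2)))
  expect_equal(s$reduction_range,
               round(100 * (1 - quantile(r, c(0.975, 0.025), names = FALSE) / 2)))
  # mean reduction equals reduction of the mean (linearity)
  expect_equal(mean(rp$reduction), 100 * (1 - mean(r) / 2))
})

test_that("ratio posterior is deterministic under the seed", {
  s1 <- summary(sample_ratio_posterior(paper_priors(), 1e4, seed = 9))
  s2 <- summary(sample_ratio_posterior(paper_priors(), 1e4, seed = 9))
  expect_identical(s1$mean, s2$mean)
  expect_identical(s1$ci, s2$ci)
})

test_that("effective_size implements the ploidy-factor equations", {
  expect_equal(effective_size(13.23, 1e-4, 4), 33075)
  expect_equal(effective_size(0.0238, 1e-7, 2), 119000)
  expect_equal(effective_size(4e-4, 1e-4, 4), 1)
  expect_error(effective_size(1, 0, 4), "mu")
  expect_error(effective_size(1, 1e-4, 3), "ploidy_factor")
})

test_that("prior_spec validates bounds", {
  expect_error(prior_spec(theta_n = c(5, 2)), "theta_n")
  expect_error(prior_spec(mu_m = c(0, 1e-7)), "mu_m")
  expect_error(sample_ratio_posterior(list(), 10), "prior_spec")
})
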