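test_that("simulate_genealogy rejects invalid inputs and builds valid trees", {
  expect_error(simulate_genealogy(1), "n_tips")
  expect_error(new_genealogy(3, rbind(c(1L, 2L), c(4L, 3L)), c(0, 0, 0.1, 0.5, 1.5)),
               "time 0")

  for (n in c(2, 5, 18, 40)) {
    g <- simulate_genealogy(n, seed = n)
    expect_equal(nrow(g$children), n - 1)
    par <- neratio:::genealogy_parent(g)
    nonroot <- which(par > 0)
    expect_true(all(g$node_time[par[nonroot]] > g$node_time[nonroot]))
    expect_true(ape::is.ultrametric(as.phylo(g)))
  }
})

test_that("genealogy is reproducible under a seed", {
  expect_identical(simulate_genealogy(12, seed = 7), simulate_genealogy(12, seed = 7))
  g1 <- simulate_genealogy(12, seed = 7)
  g2 <- simulate_genealogy(12, seed = 8)
  expect_false(identical(g1$node_time, g2$node_time))
})

test_that("expected TMRCA matches the coalescent sum 2/(k(k-1))", {
  # oracle: E[TMRCA] = sum over k of E[Exp(k(k-1)/2)]; variance is the sum
  # of squared means, giving the Monte-Carlo tolerance
  for (n in c(2, 10)) {
    mu <- sum(2 / ((2:n) * (1:(n - 1))))
    v <- sum((2 / ((2:n) * (1:(n - 1))))^2)
    reps <- 3000
    roots <- withr::with_seed(42 + n, {
      vapply(seq_len(reps), function(i) max(simulate_genealogy(n)$node_time), 0)
    })
    expect_lt(abs(mean(roots) - mu), 3 * sqrt(v / reps))
  }
  expect_equal(sum(2 / ((2:10) * (1:9))), 1.8)  # the n = 10 oracle value
})

test_that("coalescent log-density integrates interval rates correctly", {
  # hand computation for the explicit 3-tip tree: -3*t1 - 1*(t2 - t1)
  g <- gen3(0.5, 1.5)
  expect_equal(neratio:::coalescent_log_density(g), -3 * 0.5 - (1.5 - 0.5))
})
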