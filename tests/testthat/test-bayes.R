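test_that("quadrature matches the conjugate closed form when sigma is fixed", {
  # one worked case: y = 1.0, sigma = 0.5, prior mu ~ N(1.2, 1)
  d <- infer_halflife_distribution(observation(10^1.0),
                                   prior = prior_spec(1.2, 1, 0.5, 0))
  expect_equal(d$mu_mean, 1.04, tolerance = 1e-3)
  expect_equal(d$mu_std, sqrt(0.2), tolerance = 1e-3)
  expect_equal(d$sigma_mean, 0.5)
  expect_equal(d$n, 1L)

  set.seed(7)
  for (i in 1:100) {
    m0 <- rnorm(1, 1, 0.5); s0 <- runif(1, 0.5, 2); sig <- runif(1, 0.2, 1)
    y <- rnorm(sample(1:10, 1), m0, 1)
    d <- infer_halflife_distribution(observation(10^y),
                                     prior = prior_spec(m0, s0, sig, 0))
    o <- oracle_conjugate(y, m0, s0, sig)
    expect_lt(abs(d$mu_mean - o$mean), 1e-3)
    expect_lt(abs(d$mu_std - o$sd), 1e-3)
  }
})

test_that("data swamp the prior and posteriors contract like sigma/sqrt(n)", {
  obs <- observation(rep(10^2, 50))
  d <- infer_halflife_distribution(obs)
  expect_lt(abs(d$mu_mean - 2.0), 0.02)

  set.seed(11)
  sig_star <- 0.4
  ns <- c(4, 16, 64, 256)
  mean_mustd <- vapply(ns, function(n) {
    mean(vapply(1:50, function(i) {
      y <- rnorm(n, 1.5, sig_star)
      infer_halflife_distribution(observation(10^y))$mu_std
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_mustd) < 0))
  expect_lt(abs(mean_mustd[4] / (sig_star / sqrt(256)) - 1), 0.3)
})

test_that("with one observation mu_std sits strictly between 0 and s0", {
  set.seed(3)
  for (i in 1:20) {
    s0 <- runif(1, 0.4, 2)
    d <- infer_halflife_distribution(observation(10^rnorm(1, 1.2, 1)),
                                     prior = prior_spec(1.2, s0))
    expect_gt(d$mu_std, 0)
    expect_lt(d$mu_std, s0)
  }
})

test_that("censored observations match an independent brute-force posterior", {
  prior <- prior_spec()
  # one right-censored observation "> 100 d" pushes the posterior mean up
  obs <- observation(100, "right")
  d <- infer_halflife_distribution(obs, prior)
  o <- oracle_grid_posterior(obs, prior$m0, prior$s0, prior$sigma0, prior$tau0)
  expect_gt(d$mu_mean, prior$m0)
  expect_lt(abs(d$mu_mean - o$mu_mean), 2e-3)
  expect_lt(abs(d$mu_std - o$mu_std), 2e-3)
  expect_gt(o$predictive_exceedance(2.0), 0.5)

  # a mixed exact/censored compound agrees too
  obs2 <- observation(c(30, 80, 200), c("exact", "left", "right"))
  d2 <- infer_halflife_distribution(obs2, prior)
  o2 <- oracle_grid_posterior(obs2, prior$m0, prior$s0, prior$sigma0, prior$tau0)
  expect_lt(abs(d2$mu_mean - o2$mu_mean), 2e-3)
  expect_lt(abs(d2$mu_std - o2$mu_std), 2e-3)
  expect_lt(abs(d2$sigma_mean - o2$sigma_mean), 2e-3)
})

test_that("inference is invariant to observation order", {
  set.seed(21)
  obs <- observation(10^rnorm(12, 1.5, 0.5),
                     sample(c("exact", "left", "right"), 12, TRUE,
                            prob = c(0.7, 0.15, 0.15)))
  d1 <- infer_halflife_distribution(obs)
  d2 <- infer_halflife_distribution(obs[sample(12), ])
  expect_lt(abs(d1$mu_mean - d2$mu_mean), 1e-12)
  expect_lt(abs(d1$mu_std - d2$mu_std), 1e-12)
  expect_lt(abs(d1$sigma_mean - d2$sigma_mean), 1e-12)
})

test_that("degenerate inputs are handled explicitly", {
  expect_error(infer_halflife_distribution(observation(numeric(0))),
               "at least one observation")
  # data far outside the grid triggers the resolution error (sigma fixed so
  # the posterior cannot absorb the outlier as experimental variability)
  expect_error(infer_halflife_distribution(observation(10^9.5),
                                           prior = prior_spec(1.2, 1, 0.3, 0)),
               "posterior mass")
  # contradictory censored-only data: warning, but a proper posterior
  expect_warning(
    d <- infer_halflife_distribution(observation(c(100, 1), c("right", "left"))),
    "contradictory")
  expect_true(is.finite(d$mu_mean) && d$mu_std > 0)
})

test_that("point classification follows the inclusive REACH thresholds", {
  expect_equal(classify_with_ci(halflife_distribution(0.19, 0.97, 0.3, 1)), "nP")
  # the same compound crosses into P once the upper 95% CI is used
  expect_equal(classify_with_ci(halflife_distribution(0.19, 0.97, 0.3, 1),
                                use_upper_ci = TRUE), "P")
  expect_equal(classify_with_ci(halflife_distribution(2.75, 0.14, 0.3, 5)), "vP")
  expect_equal(classify_with_ci(halflife_distribution(2.75, 0.14, 0.3, 5),
                                use_upper_ci = TRUE), "vP")
  # boundary is inclusive
  expect_equal(classify_with_ci(halflife_distribution(log10(120), 0.5, 0.3, 1)), "P")
  expect_equal(classify_with_ci(halflife_distribution(log10(180), 0.5, 0.3, 1)), "vP")
})

test_that("curate_records tabulates posteriors for a synthetic table", {
  cur <- shared_curated()
  sim <- shared_sim()
  expect_equal(nrow(cur), length(sim$records))
  expect_true(all(cur$mu_std > 0 & cur$sigma_mean > 0))
  expect_true(all(cur$class_mean %in% c("nP", "P", "vP")))
  # posterior means track the ground truth reasonably at these replicate counts
  expect_lt(sqrt(mean((cur$mu_mean - sim$truth$mu_star)^2)), 0.3)
})
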