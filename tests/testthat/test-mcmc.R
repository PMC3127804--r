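small_records <- function(n = 80, model = observer_model(7), seed = 15) {
  cfg <- schedule_config(n_days = 1, blocks_per_day = 1,
                         trials_per_block = n, training_days_excluded = 0)
  stim <- generate_schedule(cfg, seed = seed)
  set.seed(seed + 1)
  simulate_responses(stim, rand_theta(model), model, seed = seed + 2)
}

test_that("log_posterior is the sum of per-trial densities plus the prior", {
  m7 <- observer_model(7)
  rec <- small_records(10)
  set.seed(44)
  theta <- rand_theta(m7)
  bounds <- default_bounds(m7)
  prior_const <- -sum(log(bounds$upper - bounds$lower))

  one <- log_posterior(theta, rec[1, , drop = FALSE], m7)
  expect_equal(one, response_likelihood(rec[1, , drop = FALSE], theta, m7) +
                 prior_const, tolerance = 1e-12)

  # brute-force product over 10 records, trial by trial
  brute <- sum(vapply(seq_len(10), function(i) {
    response_likelihood(rec[i, , drop = FALSE], theta, m7)
  }, numeric(1)))
  lp <- log_posterior(theta, rec, m7)
  expect_lt(abs(lp - (brute + prior_const)) / abs(lp), 1e-10)

  # out-of-bounds theta has zero prior support
  theta_out <- theta; theta_out[["sigma_d"]] <- 50
  expect_identical(log_posterior(theta_out, rec, m7), -Inf)
  expect_error(log_posterior(theta, rec[0, ], m7), "record")
})

test_that("the fast fitting likelihood equals the reference likelihood", {
  for (id in c(1, 4, 7, 12)) {
    model <- observer_model(id)
    rec <- small_records(60, model, seed = id)
    set.seed(id * 3)
    theta <- rand_theta(model)
    expect_equal(sizedist:::make_loglik(rec, model)(theta),
                 sum(response_likelihood(rec, theta, model)),
                 tolerance = 1e-10)
  }
})

test_that("metropolis_hastings recovers a standard normal target", {
  run <- metropolis_hastings(function(z) -0.5 * z^2,
                             init = c(x = 2), chains = 2,
                             burnin = 2000, samples = 50000, seed = 8)
  x <- as.vector(run$samples)
  n_eff <- sum(vapply(1:2, function(ch) {
    unname(coda::effectiveSize(coda::mcmc(run$samples[, 1, ch])))
  }, numeric(1)))
  expect_lt(abs(mean(x)), 4 / sqrt(n_eff))
  expect_lt(abs(sd(x) - 1), 0.05)
  # burn-in adaptation lands acceptance near the 20-40% band
  expect_true(all(run$acceptance > 0.1 & run$acceptance < 0.55))
})

test_that("improving proposals are always accepted", {
  # identity target: record every evaluated candidate; any proposal above the
  # current state improves the target and must be accepted
  path <- numeric(0)
  run <- metropolis_hastings(function(z) { path <<- c(path, z); z },
                             init = c(x = 0), chains = 1,
                             burnin = 0, samples = 500, scale = 0.5, seed = 2)
  x <- run$samples[, 1, 1]
  prev <- c(0, x[-length(x)])
  proposals <- tail(path, 500) # path starts with probe + init evaluations
  improving <- proposals > prev
  expect_gt(sum(improving), 100)
  expect_true(all(x[improving] == proposals[improving]))
})

test_that("the MH acceptance rule has the right stationary law on 3 states", {
  # discrete 3-state target, uniform proposal, 1e6 steps
  p <- c(0.6, 0.3, 0.1)
  set.seed(77)
  steps <- 1e6
  prop <- sample.int(3, steps, replace = TRUE)
  u <- runif(steps)
  counts <- integer(3)
  s <- 1L
  for (t in seq_len(steps)) {
    j <- prop[t]
    if (u[t] < p[j] / p[s]) s <- j
    counts[s] <- counts[s] + 1L
  }
  expect_lt(max(abs(counts / steps - p)), 1e-2)
})

test_that("robust mean trims outliers and tracks the median", {
  set.seed(6)
  x <- rnorm(10000)
  expect_lt(abs(robust_mean(matrix(x, ncol = 1)) - mean(x)), 0.01)

  # an outlier block (a stray chain) moves the plain mean, not the trim
  y <- c(rnorm(9000, 0, 0.5), rep(50, 1000))
  expect_gt(abs(mean(y)), 4)
  expect_lt(abs(robust_mean(matrix(y, ncol = 1))), 0.2)

  z <- rlnorm(20000, 0, 0.4) # unimodal, skewed
  expect_lt(abs(robust_mean(matrix(z, ncol = 1)) - median(z)), 0.05)
})

test_that("split R-hat flags separated chains and passes mixed ones", {
  set.seed(10)
  good <- matrix(rnorm(4000), ncol = 4)
  expect_lt(split_rhat(good), 1.02)
  bad <- cbind(rnorm(1000), rnorm(1000) + 3)
  expect_gt(split_rhat(bad), 1.5)
})

test_that("active-set sizes drive the sampler dimensionality", {
  for (id in 1:12) {
    model <- observer_model(id)
    b <- default_bounds(model)
    expect_identical(nrow(b), count_free_parameters(model))
    expect_identical(b$param, active_params(model))
  }
})

test_that("a short fit runs end to end and respects its bounds", {
  m4 <- observer_model(4) # simplest: 6 parameters
  rec <- small_records(120, m4, seed = 33)
  fit <- fit_model(rec, m4, sampler = sampler_config(chains = 2, burnin = 300,
                                                     samples = 300),
                   seed = 9)
  expect_s3_class(fit, "mcmc_fit")
  expect_identical(dim(fit$samples), c(300L, 6L, 2L))
  pooled <- pooled_samples(fit)
  b <- default_bounds(m4)
  for (j in seq_len(ncol(pooled))) {
    expect_true(all(pooled[, j] >= b$lower[j] & pooled[, j] <= b$upper[j]))
  }
  expect_true(all(names(fit$theta_bar) == active_params(m4)))
  ci <- credible_interval(fit)
  expect_true(all(fit$theta_bar >= ci["lower", ] - 1e-9 &
                    fit$theta_bar <= ci["upper", ] + 1e-9))
  # deterministic under the same seed
  fit2 <- fit_model(rec, m4, sampler = sampler_config(chains = 2, burnin = 300,
                                                      samples = 300),
                    seed = 9)
  expect_identical(fit$samples, fit2$samples)
})
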