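make_stim <- function(n, d = 6.0, s = 3.0, condition = "haptic") {
  data.frame(d_true = rep(d, n), s_true = rep(s, n),
             condition = rep(condition, length.out = n),
             stringsAsFactors = FALSE)
}

test_that("sense implements the log-linear generative equations", {
  # zero-noise: phi = s - d, h = s exactly
  out <- sense(make_stim(3), noise_model(0, 0))
  expect_equal(out$phi, rep(-3, 3))
  expect_equal(out$h, rep(3, 3))

  # no-haptic trials never carry h, whatever the noise
  out0 <- sense(make_stim(4, condition = "no_haptic"), noise_model(0.3, 0.3))
  expect_true(all(is.na(out0$h)))

  # Monte-Carlo moments at 1e5 draws, 4 SE tolerance
  sp <- 0.12; sh <- 0.07; n <- 1e5
  set.seed(41)
  mc <- sense(make_stim(n), noise_model(sp, sh))
  expect_lt(abs(mean(mc$phi) - (-3)), 4 * sp / sqrt(n))
  expect_lt(abs(sd(mc$phi) - sp), 4 * sp / sqrt(2 * n))
  expect_lt(abs(mean(mc$h) - 3), 4 * sh / sqrt(n))
  expect_lt(abs(sd(mc$h) - sh), 4 * sh / sqrt(2 * n))

  bad <- make_stim(1); bad$d_true <- NaN
  expect_error(sense(bad, noise_model(0.1, 0.1)), "finite")
})

test_that("posterior weights reproduce the worked example and normalization", {
  kn <- observer_knowledge(sigma_phi = 0.05, sigma_h = 0.1,
                           mu_d = 6, sigma_d = 0.3, mu_s = 3, sigma_s = 0.3)
  w <- posterior_weights(kn, use_haptic = TRUE)
  # frozen from the grid-integration oracle (and hand arithmetic:
  # D = 0.0081 + 0.0009 + 0.000225 + 0.000025 + 0.0009 = 0.01015)
  expect_equal(w$w_phi, 0.0090 / 0.01015, tolerance = 1e-6)
  expect_equal(w$w_h, 0.0081 / 0.01015, tolerance = 1e-6)
  expect_equal(w$w_s, 0.0009 / 0.01015, tolerance = 1e-6)
  expect_equal(w$w_d, 0.00115 / 0.01015, tolerance = 1e-6)
  expect_equal(w$var_post, 0.3^2 * w$w_d)
  or <- grid_posterior(-3.02, 3.05, kn)
  bel <- compute_posterior(-3.02, 3.05, kn, use_haptic = TRUE)
  expect_equal(bel$mu_post, or$mu, tolerance = 1e-6)
  expect_equal(bel$var_post, or$var, tolerance = 1e-4)

  # normalization identities over random parameter draws
  set.seed(7)
  for (i in 1:200) {
    kn <- rand_knowledge()
    wh <- posterior_weights(kn, use_haptic = TRUE)
    expect_equal(wh$w_h + wh$w_s + wh$w_d, 1, tolerance = 1e-12)
    expect_equal(wh$w_phi, wh$w_h + wh$w_s, tolerance = 1e-12)
    expect_equal(wh$var_post, kn$sigma_d^2 * wh$w_d, tolerance = 1e-12)
    w0 <- posterior_weights(kn, use_haptic = FALSE)
    expect_equal(w0$w_s, w0$w_phi, tolerance = 1e-12)
    expect_equal(w0$w_phi + w0$w_d, 1, tolerance = 1e-12)
    # haptic benefit: integrating the cue always shrinks the posterior
    expect_lt(wh$var_post, w0$var_post)
  }
})

test_that("posterior limits: flat haptic channel and flat distance prior", {
  set.seed(11)
  for (i in 1:50) {
    kn <- rand_knowledge()
    phi <- rnorm(1, -3, 0.2); h <- rnorm(1, 3, 0.2)
    kn_flat_h <- observer_knowledge(kn$sigma_phi, 1e6, kn$mu_d, kn$sigma_d,
                                    kn$mu_s, kn$sigma_s)
    a <- compute_posterior(phi, h, kn_flat_h, use_haptic = TRUE)
    b <- compute_posterior(phi, knowledge = kn, use_haptic = FALSE)
    expect_lt(abs(a$mu_post - b$mu_post), 1e-6)
    expect_lt(abs(a$var_post - b$var_post), 1e-6)
    expect_lt(max(abs(a$weights[c("w_phi", "w_d")] -
                        b$weights[c("w_phi", "w_d")])), 1e-6)
  }
  kn_flat_d <- observer_knowledge(0.05, 0.1, 6, 1e6, 3, 0.3)
  w <- posterior_weights(kn_flat_d, use_haptic = TRUE)
  expect_lt(w$w_d, 1e-6)
  bel <- compute_posterior(-3.02, 3.01, kn_flat_d, use_haptic = TRUE)
  # with no prior pull on d, only cues and the size prior set the mean
  expect_equal(bel$mu_post,
               -w$w_phi * -3.02 + w$w_h * 3.01 + w$w_s * 3, tolerance = 1e-9)

  expect_error(observer_knowledge(-0.1, 0.1, 6, 0.3, 3, 0.3), "sigma_phi")
  expect_error(observer_knowledge(0.1, 0.1, 6, -0.3, 3, 0.3), "prior SDs")
})

test_that("closed-form posterior matches grid integration on random tuples", {
  set.seed(23)
  for (i in 1:20) {
    kn <- rand_knowledge()
    d <- runif(1, 5.8, 6.4); s <- runif(1, 2.8, 3.6)
    phi <- s - d + rnorm(1, 0, kn$sigma_phi)
    h <- s + rnorm(1, 0, kn$sigma_h)
    use_h <- i %% 2 == 0
    bel <- compute_posterior(phi, if (use_h) h else NULL, kn, use_haptic = use_h)
    oracle <- grid_posterior(phi, if (use_h) h else NULL, kn)
    expect_lt(abs(bel$mu_post - oracle$mu) / max(abs(oracle$mu), 1), 1e-3)
    expect_lt(abs(bel$var_post - oracle$var) / oracle$var, 1e-3)
  }
})

test_that("decision rules have the stated response distributions", {
  kn <- observer_knowledge(0.08, 0.1, 6, 0.25, 3.2, 0.3)
  bel <- compute_posterior(rep(-3.0, 1), rep(3.0, 1), kn, use_haptic = TRUE)

  # MAP with no motor noise is deterministic at the posterior mean
  r <- decide(bel, decision_policy("MAP"), sigma_m = 0)
  expect_identical(r, bel$mu_post)

  n <- 1e5
  bel_n <- compute_posterior(rep(-3.0, n), rep(3.0, n), kn, use_haptic = TRUE)
  sm <- 0.03
  # K = 1: response variance is var_post + sigma_m^2
  set.seed(5)
  r1 <- decide(bel_n, decision_policy("sample_average", K = 1), sm)
  v1 <- bel_n$var_post + sm^2
  expect_lt(abs(var(r1) - v1), 4 * v1 * sqrt(2 / n))
  # K = 4: SD shrinks to sqrt(var_post/4 + sigma_m^2)
  r4 <- decide(bel_n, decision_policy("sample_average", K = 4), sm)
  v4 <- bel_n$var_post / 4 + sm^2
  expect_lt(abs(var(r4) - v4), 4 * v4 * sqrt(2 / n))
  expect_lt(abs(mean(r4) - bel$mu_post), 4 * sqrt(v4 / n))

  expect_error(decision_policy("sample_average", K = 0.4), "K")
})

test_that("K posterior draws average like one draw from the K-exponentiated posterior", {
  # analytically both are Normal(mu, var/K); check the Monte-Carlo law
  kn <- observer_knowledge(0.08, 0.1, 6, 0.25, 3.2, 0.3)
  n <- 1e5; K <- 6
  bel <- compute_posterior(rep(-3.0, n), rep(3.0, n), kn, use_haptic = TRUE)
  set.seed(9)
  avg <- decide(bel, decision_policy("sample_average", K = K), sigma_m = 0)
  # one draw from the renormalized K-th power of N(mu, var) is N(mu, var/K)
  expect_lt(ks_stat_normal(avg, bel$mu_post[1], bel$var_post / K),
            1.63 / sqrt(n))
})

test_that("response likelihood matches the generative simulation", {
  set.seed(31)
  for (model_id in c(7, 2)) {
    model <- observer_model(model_id)
    theta <- rand_theta(model)
    d <- 6.1; s <- 3.3
    n <- 1e5
    stim <- make_stim(n, d, s, condition = c("haptic", "no_haptic"))
    sim <- simulate_responses(stim, theta, model)
    mv <- sizedist:::response_moments(stim$d_true, stim$s_true, stim$condition,
                                      theta, model)
    for (cond in c("haptic", "no_haptic")) {
      idx <- stim$condition == cond
      m <- mv$m[idx][1]; v <- mv$v[idx][1]
      nn <- sum(idx)
      expect_lt(abs(mean(sim$r[idx]) - m), 4 * sqrt(v / nn))
      expect_lt(abs(sd(sim$r[idx]) - sqrt(v)), 4 * sqrt(v) / sqrt(2 * nn))
      expect_lt(ks_stat_normal(sim$r[idx], m, v), 1.63 / sqrt(nn))
    }
    # and response_likelihood uses exactly those moments
    rec <- sim[1:5, ]
    expect_equal(response_likelihood(rec, theta, model),
                 dnorm(rec$r, mv$m[1:5], sqrt(mv$v[1:5]), log = TRUE))
  }
})

test_that("near-degenerate noise concentrates responses at the analytic mean", {
  m8 <- observer_model(8) # haptic MAP observer
  theta <- c(sigma_phi = 0.1, sigma_h_true = 1e-12, sigma_h = 0.1,
             mu_d = 6, sigma_d = 0.25, mu_s = 3.2, sigma_s = 0.3,
             sigma_m = 0)
  stim <- make_stim(4, 6.1, 3.3)
  # zero image/haptic/motor noise: r lands exactly on m
  theta0 <- theta; theta0[["sigma_phi"]] <- 1e-12
  sim <- simulate_responses(stim, theta0, m8, seed = 1)
  mv <- sizedist:::response_moments(stim$d_true, stim$s_true, stim$condition,
                                    theta0, m8)
  expect_equal(sim$r, mv$m, tolerance = 1e-8)
})

test_that("flat haptic channel collapses the haptic model onto the no-haptic one", {
  m5 <- observer_model(5)   # haptic, both knowledges free, sampling
  m1 <- observer_model(1)   # its no-haptic counterpart
  shared <- c(sigma_phi_true = 0.09, sigma_phi = 0.12, mu_d = 6,
              sigma_d = 0.25, mu_s = 3.2, sigma_s = 0.3, sigma_m = 0.03,
              K = 3)
  th5 <- c(shared, sigma_h_true = 1e6, sigma_h = 1e6)[active_params(m5)]
  th1 <- shared[active_params(m1)]
  rec <- make_stim(6, 6.1, 3.3, condition = c("haptic", "no_haptic"))
  rec$r <- rnorm(6, 2.9, 0.1) + 3
  expect_lt(max(abs(response_likelihood(rec, th5, m5) -
                      response_likelihood(rec, th1, m1))), 1e-6)
})

test_that("condition variance ordering separates sampling from MAP observers", {
  cfg <- schedule_config(n_days = 1, training_days_excluded = 0)
  stim <- generate_schedule(cfg, seed = 61)
  # strongly informative haptic cue, few samples averaged
  theta_s <- c(sigma_phi = 0.05, sigma_h_true = 0.05, sigma_h = 0.06,
               mu_d = 6.12, sigma_d = 0.22, mu_s = 3.29, sigma_s = 0.31,
               sigma_m = 0.01, K = 1)
  m7 <- observer_model(7)
  mv <- sizedist:::response_moments(stim$d_true, stim$s_true, stim$condition,
                                    theta_s[active_params(m7)], m7)
  v_h <- mv$v[stim$condition == "haptic"][1]
  v_0 <- mv$v[stim$condition == "no_haptic"][1]
  expect_lt(v_h, v_0) # sampling observer: haptic trials less variable
  sim <- simulate_responses(stim, theta_s[active_params(m7)], m7, seed = 3)
  res <- sim$r - mv$m
  expect_lt(var(res[stim$condition == "haptic"]),
            var(res[stim$condition == "no_haptic"]))

  # MAP observer, same knowledge: prior doesn't vary between trials, so
  # no-haptic responses are LESS variable than haptic ones
  m8 <- observer_model(8)
  theta_m <- theta_s[active_params(m8)]
  mv8 <- sizedist:::response_moments(stim$d_true, stim$s_true, stim$condition,
                                     theta_m, m8)
  expect_gt(mv8$v[stim$condition == "haptic"][1],
            mv8$v[stim$condition == "no_haptic"][1])
})

test_that("simulated data's average log-likelihood peaks near the generating theta", {
  cfg <- schedule_config(n_days = 1, training_days_excluded = 0)
  stim <- generate_schedule(cfg, seed = 17)
  m7 <- observer_model(7)
  set.seed(29)
  theta <- rand_theta(m7)
  rec <- simulate_responses(stim, theta, m7, seed = 19)
  ll_star <- sum(response_likelihood(rec, theta, m7))
  # coarse grid around theta*: +/- 40% on each parameter, one at a time
  for (p in names(theta)) {
    for (f in c(0.6, 1.4)) {
      th <- theta
      th[[p]] <- th[[p]] * f
      if (p == "K" && th[[p]] < 1) th[[p]] <- 1
      expect_lte(sum(response_likelihood(rec, th, m7)), ll_star + 2,
                 label = sprintf("loglik at %s x %.1f", p, f))
    }
  }
})
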