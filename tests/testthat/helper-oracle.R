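# Independent 2-D grid-integration oracle for the perceptual posterior.
# Integrates p(d | phi[, h]) ∝ ∫ N(phi; s-d, v_phi) [N(h; s, v_h)] N(s; mu_s, v_s)
#                                N(d; mu_d, v_d) ds
# on a dense (d, s) grid and returns the marginal mean/variance over d.
# Deliberately shares no code with posterior_weights()/compute_posterior().
grid_posterior <- function(phi, h = NULL, knowledge, step = 0.002, span = 6) {
  sig <- c(knowledge$sigma_phi, knowledge$sigma_d, knowledge$sigma_s,
           if (!is.null(h)) knowledge$sigma_h)
  half <- span * max(sig)
  d_centers <- c(knowledge$mu_d,
                 if (!is.null(h)) h - phi else knowledge$mu_s - phi)
  s_centers <- c(knowledge$mu_s, if (!is.null(h)) h)
  d_grid <- seq(min(d_centers) - half, max(d_centers) + half, by = step)
  s_grid <- seq(min(s_centers) - half, max(s_centers) + half, by = step)

  post_d <- numeric(length(d_grid))
  # accumulate the s-marginal in blocks to bound memory
  blocks <- split(seq_along(s_grid), ceiling(seq_along(s_grid) / 400))
  prior_d <- stats::dnorm(d_grid, knowledge$mu_d, knowledge$sigma_d)
  for (idx in blocks) {
    s <- s_grid[idx]
    sm <- matrix(s, nrow = length(d_grid), ncol = length(s), byrow = TRUE)
    lik <- stats::dnorm(phi, sm - d_grid, knowledge$sigma_phi) *
      stats::dnorm(sm, knowledge$mu_s, knowledge$sigma_s)
    if (!is.null(h)) lik <- lik * stats::dnorm(h, sm, knowledge$sigma_h)
    post_d <- post_d + rowSums(lik)
  }
  post_d <- post_d * prior_d
  z <- sum(post_d)
  mu <- sum(d_grid * post_d) / z
  list(mu = mu, var = sum((d_grid - mu)^2 * post_d) / z)
}

# Random observer knowledge with moderate SDs (keeps the oracle grid small).
rand_knowledge <- function(with_haptic = TRUE) {
  observer_knowledge(
    sigma_phi = runif(1, 0.02, 0.25),
    sigma_h = if (with_haptic) runif(1, 0.02, 0.25) else NA_real_,
    mu_d = runif(1, 5.5, 6.5), sigma_d = runif(1, 0.05, 0.35),
    mu_s = runif(1, 2.8, 3.8), sigma_s = runif(1, 0.05, 0.35)
  )
}

# A complete random theta for a model, in a plausible range.
rand_theta <- function(model) {
  full <- c(sigma_phi_true = runif(1, 0.03, 0.2),
            sigma_phi = runif(1, 0.03, 0.25),
            sigma_h_true = runif(1, 0.03, 0.15),
            sigma_h = runif(1, 0.03, 0.3),
            mu_d = runif(1, 5.8, 6.4), sigma_d = runif(1, 0.1, 0.4),
            mu_s = runif(1, 3.0, 3.6), sigma_s = runif(1, 0.1, 0.4),
            sigma_m = runif(1, 0.01, 0.08),
            K = sample(1:8, 1))
  full[active_params(model)]
}

# theta* of the reference parameter-recovery world: model-7 structure with
# priors matched to the log-statistics of the analysis stimuli.
reference_theta <- function(stats) {
  c(sigma_phi = 0.1, sigma_h_true = 0.08, sigma_h = 0.2,
    mu_d = stats$mean_log_distance, sigma_d = stats$sd_log_distance,
    mu_s = stats$mean_log_size, sigma_s = stats$sd_log_size,
    sigma_m = 0.02, K = 4)
}

# Kolmogorov-Smirnov statistic of draws against N(m, sqrt(v)).
ks_stat_normal <- function(x, m, v) {
  x <- sort(x)
  n <- length(x)
  p <- stats::pnorm(x, m, sqrt(v))
  max(pmax(abs(p - (seq_len(n) - 1) / n), abs(p - seq_len(n) / n)))
}
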