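#' Parameter bounds for the bounded-uniform prior
#'
#' The parameter prior is uniform over a deliberately wide box: SDs (and any
#' coupled true/assumed SD) on [1e-4, 10] log units, prior means mu_d and
#' mu_s on [0, 12] log-mm (about 1 mm to 160 m), and K on [1, 1000]. The
#' prior is uniform on the original parameter scale; sampling happens in log
#' space for the positive parameters with the Jacobian applied.
#'
#' @param model an \code{observer_model}.
#' @return Data frame with columns \code{param}, \code{lower}, \code{upper}.
#' @export
default_bounds <- function(model) {
  p <- active_params(model)
  lower <- ifelse(p %in% c("mu_d", "mu_s"), 0,
                  ifelse(p == "K", 1, 1e-4))
  upper <- ifelse(p %in% c("mu_d", "mu_s"), 12,
                  ifelse(p == "K", 1000, 10))
  data.frame(param = p, lower = lower, upper = upper,
             stringsAsFactors = FALSE)
}

log_prior <- function(theta, bounds) {
  th <- theta[bounds$param]
  if (any(th < bounds$lower) || any(th > bounds$upper)) return(-Inf)
  -sum(log(bounds$upper - bounds$lower))
}

#' Log-posterior of a parameter vector
#'
#' Sum over independent trials of the per-trial response log-density plus the
#' log of the bounded-uniform prior (-Inf outside the bounds).
#'
#' @param theta named parameter vector.
#' @param records trial records (post training exclusion).
#' @param model an \code{observer_model}.
#' @param bounds prior box as from [default_bounds()].
#' @return Scalar log-posterior (up to nothing: the prior is normalized).
#' @export
log_posterior <- function(theta, records, model, bounds = default_bounds(model)) {
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  lp <- log_prior(theta, bounds)
  if (!is.finite(lp)) return(-Inf)
  lp + sum(response_likelihood(records, theta, model))
}

# Condition-split closure over the data: returns function(theta) -> total
# log-likelihood. This is the MCMC hot path; it must agree with
# sum(response_likelihood()) to ~1e-10 (tested).
make_loglik <- function(records, model) {
  hap <- model$use_haptic & records$condition == "haptic"
  d0 <- records$d_true[!hap]; s0 <- records$s_true[!hap]; r0 <- records$r[!hap]
  dh <- records$d_true[hap]; sh <- records$s_true[hap]; rh <- records$r[hap]
  n0 <- length(r0); nh <- length(rh)
  sampling <- model$decision_rule == "sample_average"
  free_phi <- "sigma_phi_true" %in% active_params(model)
  free_h <- "sigma_h_true" %in% active_params(model)
  use_h <- model$use_haptic
  function(theta) {
    s_phi_t <- if (free_phi) theta[["sigma_phi_true"]] else theta[["sigma_phi"]]
    v_phi <- theta[["sigma_phi"]]^2
    v_s <- theta[["sigma_s"]]^2
    v_d <- theta[["sigma_d"]]^2
    mu_s <- theta[["mu_s"]]; mu_d <- theta[["mu_d"]]
    v_m <- theta[["sigma_m"]]^2
    K <- if (sampling) theta[["K"]] else Inf
    ll <- 0
    if (n0 > 0L) {
      D0 <- v_d + v_phi + v_s
      w0 <- v_d / D0
      m0 <- w0 * (d0 - s0 + mu_s) + ((v_phi + v_s) / D0) * mu_d
      v0 <- w0^2 * s_phi_t^2 + (if (sampling) v_d * (v_phi + v_s) / D0 / K else 0) + v_m
      ll <- ll - 0.5 * (n0 * log(2 * pi * v0) + sum((r0 - m0)^2) / v0)
    }
    if (use_h && nh > 0L) {
      s_h_t <- if (free_h) theta[["sigma_h_true"]] else theta[["sigma_h"]]
      v_h <- theta[["sigma_h"]]^2
      D <- v_d * v_s + v_d * v_h + v_phi * v_s + v_phi * v_h + v_s * v_h
      w_phi <- (v_d * v_s + v_d * v_h) / D
      w_h <- v_d * v_s / D
      w_s <- v_d * v_h / D
      w_d <- (v_phi * v_s + v_phi * v_h + v_s * v_h) / D
      mh <- w_phi * dh - w_s * sh + w_s * mu_s + w_d * mu_d
      vh <- w_phi^2 * s_phi_t^2 + w_h^2 * s_h_t^2 +
        (if (sampling) v_d * w_d / K else 0) + v_m
      ll <- ll - 0.5 * (nh * log(2 * pi * vh) + sum((rh - mh)^2) / vh)
    }
    ll
  }
}

# log <-> original scale transforms for the sampler.
to_sampler_space <- function(theta) {
  idx <- names(theta) %in% .positive_params
  theta[idx] <- log(theta[idx])
  theta
}
from_sampler_space <- function(z) {
  idx <- names(z) %in% .positive_params
  z[idx] <- exp(z[idx])
  z
}

#' Component-wise Metropolis-Hastings sampler
#'
#' Gaussian random-walk proposals applied one coordinate at a time, with
#' per-coordinate proposal scales adapted during burn-in toward a 20-40%
#' acceptance rate (multiplicative updates every \code{adapt_interval}
#' iterations) and frozen before any sample is stored.
#'
#' \code{log_target} may return either a scalar log-density or a numeric
#' vector whose first element is the log-density; remaining elements are
#' stored alongside each draw (used by the model-fitting wrapper to record
#' the pure log-likelihood for DIC without recomputation).
#'
#' @param log_target function of a named numeric vector.
#' @param init named numeric vector (single chain) or a chains x p matrix of
#'   per-chain starting points; \code{log_target(init)} must be finite for
#'   every chain.
#' @param chains number of chains (ignored if \code{init} is a matrix).
#' @param burnin,samples iterations discarded / stored per chain.
#' @param scale initial proposal SD (scalar or per-coordinate vector).
#' @param adapt_interval burn-in adaptation window, iterations.
#' @param seed optional integer seed.
#' @return List of class \code{mh_run}: \code{samples} (array
#'   [samples, p, chains] in the space of \code{init}), \code{lp} (matrix
#'   [samples, chains]), \code{aux} (array of extra target values or NULL),
#'   \code{acceptance} (p x chains matrix of post-burn-in acceptance rates),
#'   \code{scales} (final proposal SDs, p x chains).
#' @export
metropolis_hastings <- function(log_target, init, chains = 4L,
                                burnin = 2000L, samples = 1500L,
                                scale = 0.1, adapt_interval = 50L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.matrix(init)) {
    init <- matrix(init, nrow = chains, ncol = length(init), byrow = TRUE,
                   dimnames = list(NULL, names(init)))
  }
  chains <- nrow(init)
  p <- ncol(init)
  pn <- colnames(init)
  eval_target <- function(z) {
    out <- log_target(z)
    as.numeric(out)
  }
  probe <- eval_target(init[1, ])
  n_aux <- length(probe) - 1L
  samp <- array(NA_real_, c(samples, p, chains),
                dimnames = list(NULL, pn, NULL))
  lp_store <- matrix(NA_real_, samples, chains)
  aux_store <- if (n_aux > 0) array(NA_real_, c(samples, n_aux, chains)) else NULL
  acc_store <- matrix(0, p, chains, dimnames = list(pn, NULL))
  scale_store <- matrix(NA_real_, p, chains, dimnames = list(pn, NULL))

  for (ch in seq_len(chains)) {
    z <- init[ch, ]
    names(z) <- pn
    cur <- eval_target(z)
    if (!is.finite(cur[1])) {
      stop("log_target not finite at chain ", ch, " initialization",
           call. = FALSE)
    }
    sc <- rep_len(scale, p)
    win_prop <- integer(p)
    win_acc <- integer(p)
    acc_post <- integer(p)
    total <- burnin + samples
    for (it in seq_len(total)) {
      for (j in seq_len(p)) {
        zj <- z[j]
        z[j] <- zj + stats::rnorm(1, 0, sc[j])
        cand <- eval_target(z)
        if (is.finite(cand[1]) &&
            (cand[1] >= cur[1] || log(stats::runif(1)) < cand[1] - cur[1])) {
          cur <- cand
          if (it <= burnin) win_acc[j] <- win_acc[j] + 1L
          else acc_post[j] <- acc_post[j] + 1L
        } else {
          z[j] <- zj
        }
        if (it <= burnin) win_prop[j] <- win_prop[j] + 1L
      }
      if (it <= burnin && it %% adapt_interval == 0L) {
        rate <- win_acc / pmax(win_prop, 1L)
        sc <- ifelse(rate > 0.4, sc * 1.25,
                     ifelse(rate < 0.2, sc / 1.25, sc))
        win_prop[] <- 0L
        win_acc[] <- 0L
      }
      if (it > burnin) {
        k <- it - burnin
        samp[k, , ch] <- z
        lp_store[k, ch] <- cur[1]
        if (n_aux > 0) aux_store[k, , ch] <- cur[-1]
      }
    }
    acc_store[, ch] <- acc_post / samples
    scale_store[, ch] <- sc
  }
  structure(list(samples = samp, lp = lp_store, aux = aux_store,
                 acceptance = acc_store, scales = scale_store),
            class = "mh_run")
}

# Data-driven initialization: regress the judged log-distance on the true
# log-distance for location parameters, split the residual SD across the
# noise sources, then jitter per chain inside the prior box.
init_theta <- function(records, model, bounds) {
  fit <- stats::lm(r ~ d_true, data = records)
  resid_sd <- max(stats::sd(stats::residuals(fit)), 0.02)
  base <- c(
    sigma_phi_true = resid_sd, sigma_phi = resid_sd,
    sigma_h_true = resid_sd, sigma_h = resid_sd,
    mu_d = mean(records$r),
    sigma_d = max(stats::sd(records$r) * 1.5, 0.1),
    mu_s = mean(records$s_true),
    sigma_s = max(stats::sd(records$s_true) * 1.5, 0.1),
    sigma_m = resid_sd / 2,
    K = 4
  )
  base[active_params(model)]
}

jitter_init <- function(theta0, bounds, log_post, chains) {
  p <- length(theta0)
  init <- matrix(NA_real_, chains, p, dimnames = list(NULL, names(theta0)))
  is_pos <- names(theta0) %in% .positive_params
  for (ch in seq_len(chains)) {
    for (try in 1:50) {
      th <- theta0
      th[is_pos] <- th[is_pos] * exp(stats::rnorm(sum(is_pos), 0, 0.25))
      th[!is_pos] <- th[!is_pos] + stats::rnorm(sum(!is_pos), 0, 0.05)
      th <- pmin(pmax(th, bounds$lower * 1.0001), bounds$upper * 0.9999)
      z <- to_sampler_space(th)
      if (is.finite(log_post(z)[1])) break
    }
    init[ch, ] <- z
  }
  init
}

#' Fit one observer model to trial records by MCMC
#'
#' Builds the bounded-uniform posterior over the model's active parameters
#' and samples it with [metropolis_hastings()] in transformed space (log for
#' SDs and K, raw for the prior means), including the change-of-variables
#' Jacobian so the prior stays uniform on the original scale. The paper-scale
#' configuration (360 chains x 15000 burn-in x 6000 stored) is available via
#' \code{sampler_config("paper")}; the default desk configuration is 8 x
#' 2000 x 1500.
#'
#' @param records trial records with \code{d_true}, \code{s_true},
#'   \code{condition}, \code{r}.
#' @param model an \code{observer_model}.
#' @param sampler a [sampler_config()].
#' @param bounds prior box, as [default_bounds()].
#' @param seed integer seed (drives initialization jitter and all chains).
#' @param init optional named starting vector (original scale).
#' @return Object of class \code{mcmc_fit}: \code{samples} (array
#'   [stored, p, chains] on the original parameter scale), \code{loglik}
#'   (matrix [stored, chains]), \code{lp}, \code{acceptance},
#'   \code{theta_bar} (robust mean), \code{diagnostics} (split R-hat and
#'   effective sample size per parameter), \code{model}, \code{bounds},
#'   \code{sampler}, \code{seed}.
#' @export
fit_model <- function(records, model, sampler = sampler_config(),
                      bounds = default_bounds(model), seed = 1L,
                      init = NULL) {
  if (nrow(records) == 0L) stop("no records to fit", call. = FALSE)
  loglik <- make_loglik(records, model)
  pn <- active_params(model)
  stopifnot(identical(bounds$param, pn))
  is_pos <- pn %in% .positive_params
  lower <- bounds$lower
  upper <- bounds$upper
  prior_const <- -sum(log(upper - lower))
  target <- function(z) {
    th <- z
    th[is_pos] <- exp(th[is_pos])
    if (any(th < lower) || any(th > upper)) return(c(-Inf, -Inf))
    ll <- loglik(th)
    # Jacobian: uniform prior on the original scale, sampled in log space
    c(ll + prior_const + sum(z[is_pos]), ll)
  }
  set.seed(seed)
  theta0 <- if (is.null(init)) init_theta(records, model, bounds) else init[pn]
  zinit <- jitter_init(theta0, bounds, target, sampler$chains)
  run <- metropolis_hastings(target, zinit,
                             burnin = sampler$burnin,
                             samples = sampler$samples,
                             scale = 0.1)
  # back to the original scale
  th_samp <- run$samples
  th_samp[, is_pos, ] <- exp(th_samp[, is_pos, ])
  loglik_mat <- matrix(run$aux[, 1, ], nrow = dim(run$aux)[1])
  rhat <- apply(th_samp, 2, function(m) split_rhat(m))
  ess <- vapply(seq_along(pn), function(j) {
    chains_list <- lapply(seq_len(dim(th_samp)[3]),
                          function(ch) coda::mcmc(th_samp[, j, ch]))
    sum(coda::effectiveSize(coda::mcmc.list(chains_list)))
  }, numeric(1))
  names(ess) <- pn
  fit <- structure(list(samples = th_samp, loglik = loglik_mat, lp = run$lp,
                        acceptance = run$acceptance,
                        diagnostics = list(rhat = rhat, ess = ess),
                        model = model, bounds = bounds, sampler = sampler,
                        seed = as.integer(seed)),
                   class = "mcmc_fit")
  fit$theta_bar <- robust_mean(fit)
  fit
}

#' Sampler configuration
#'
#' @param preset \code{"desk"} (8 chains x 2000 burn-in x 1500 stored;
#'   default, sized for a single CPU) or \code{"paper"} (360 x 15000 x 6000,
#'   the original large-scale configuration).
#' @param chains,burnin,samples overrides of the preset.
#' @return List of class \code{sampler_config}.
#' @export
sampler_config <- function(preset = c("desk", "paper"), chains = NULL,
                           burnin = NULL, samples = NULL) {
  preset <- match.arg(preset)
  cfg <- if (preset == "desk") list(chains = 8L, burnin = 2000L, samples = 1500L)
  else list(chains = 360L, burnin = 15000L, samples = 6000L)
  if (!is.null(chains)) cfg$chains <- as.integer(chains)
  if (!is.null(burnin)) cfg$burnin <- as.integer(burnin)
  if (!is.null(samples)) cfg$samples <- as.integer(samples)
  stopifnot(cfg$chains >= 1, cfg$burnin >= 0, cfg$samples >= 1)
  structure(cfg, class = "sampler_config")
}

#' Pooled posterior samples
#'
#' @param fit an \code{mcmc_fit}.
#' @return Matrix (stored x chains rows, one column per parameter).
#' @export
pooled_samples <- function(fit) {
  stopifnot(inherits(fit, "mcmc_fit"))
  d <- dim(fit$samples)
  m <- do.call(rbind, lapply(seq_len(d[3]), function(ch) fit$samples[, , ch, drop = TRUE]))
  colnames(m) <- dimnames(fit$samples)[[2]]
  m
}

#' Robust point estimate of the fitted parameters
#'
#' Per-parameter 10%-trimmed mean over the pooled post-burn-in samples,
#' which discards outlier parameter values from stray chains.
#'
#' @param fit an \code{mcmc_fit} or a samples matrix (columns = parameters).
#' @param trim fraction trimmed from each tail (default 0.1).
#' @return Named numeric vector.
#' @export
robust_mean <- function(fit, trim = 0.1) {
  m <- if (inherits(fit, "mcmc_fit")) pooled_samples(fit) else as.matrix(fit)
  apply(m, 2, mean, trim = trim)
}

#' Split R-hat convergence diagnostic
#'
#' Each chain is split in half and the standard potential-scale-reduction
#' statistic computed over the split halves.
#'
#' @param x matrix of draws, iterations x chains.
#' @return Scalar R-hat (1 at perfect mixing).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) %/% 2L
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  mu_j <- colMeans(halves)
  var_j <- apply(halves, 2, stats::var)
  W <- mean(var_j)
  B <- n * stats::var(mu_j)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior credible intervals
#'
#' @param fit an \code{mcmc_fit}.
#' @param level interval mass (default 0.95), equal-tailed.
#' @return Matrix with rows \code{lower}, \code{upper}; one column per
#'   parameter.
#' @export
credible_interval <- function(fit, level = 0.95) {
  m <- pooled_samples(fit)
  a <- (1 - level) / 2
  apply(m, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE) |>
    `rownames<-`(c("lower", "upper"))
}

#' @export
print.mcmc_fit <- function(x, ...) {
  cat(sprintf("MCMC fit of observer model %d: %d chains x %d stored\n",
              x$model$id, dim(x$samples)[3], dim(x$samples)[1]))
  cat("theta_bar:\n")
  print(round(x$theta_bar, 4))
  cat("split R-hat:\n")
  print(round(x$diagnostics$rhat, 3))
  invisible(x)
}
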