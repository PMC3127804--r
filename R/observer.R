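#' True sensory and motor noise
#'
#' The tilde-parameters of the generative world: SDs of the log-domain noise
#' actually corrupting the image-size cue, the haptic cue, and the executed
#' response. Distinct from [observer_knowledge()], the observer's *assumed*
#' noise, so that knowledge-inaccurate observers can be expressed.
#'
#' @param sigma_phi_true SD of image-size (log visual angle) noise, log units.
#' @param sigma_h_true SD of haptic size noise, log units; NA for observers
#'   that never receive a haptic channel.
#' @param sigma_m SD of additive motor noise on the executed log-distance,
#'   log-mm.
#' @return A list of class \code{noise_model}.
#' @export
noise_model <- function(sigma_phi_true, sigma_h_true = NA_real_, sigma_m = 0) {
  stopifnot(is.finite(sigma_phi_true), sigma_phi_true >= 0,
            is.na(sigma_h_true) || sigma_h_true >= 0,
            is.finite(sigma_m), sigma_m >= 0)
  structure(list(sigma_phi_true = sigma_phi_true,
                 sigma_h_true = sigma_h_true,
                 sigma_m = sigma_m),
            class = "noise_model")
}

#' Observer's generative knowledge
#'
#' Assumed cue-noise SDs and Gaussian priors over log-distance and log-size
#' used to invert the sensation model. Knowledge-accurate models set these
#' equal to the true SDs; knowledge-inaccurate models free them.
#'
#' @param sigma_phi assumed image-size noise SD (log units), > 0.
#' @param sigma_h assumed haptic noise SD (log units), > 0 or NA when the
#'   observer never integrates the haptic cue.
#' @param mu_d,sigma_d prior mean and SD over log-distance (log-mm).
#' @param mu_s,sigma_s prior mean and SD over log-size (log-mm).
#' @return A list of class \code{observer_knowledge}.
#' @export
observer_knowledge <- function(sigma_phi, sigma_h = NA_real_,
                               mu_d, sigma_d, mu_s, sigma_s) {
  if (!is.finite(sigma_phi) || sigma_phi <= 0) {
    stop("assumed sigma_phi must be > 0", call. = FALSE)
  }
  if (!is.na(sigma_h) && sigma_h <= 0) {
    stop("assumed sigma_h must be > 0 (or NA)", call. = FALSE)
  }
  if (sigma_d <= 0 || sigma_s <= 0) {
    stop("prior SDs must be > 0", call. = FALSE)
  }
  stopifnot(is.finite(mu_d), is.finite(mu_s))
  structure(list(sigma_phi = sigma_phi, sigma_h = sigma_h,
                 mu_d = mu_d, sigma_d = sigma_d,
                 mu_s = mu_s, sigma_s = sigma_s),
            class = "observer_knowledge")
}

#' Decision policy
#'
#' @param rule \code{"MAP"} (respond with the posterior mode) or
#'   \code{"sample_average"} (respond with the mean of \code{K} independent
#'   posterior draws).
#' @param K number of posterior samples averaged; a positive integer when
#'   simulating, treated as a continuous positive value inside the response
#'   likelihood. Ignored for MAP.
#' @return A list of class \code{decision_policy}.
#' @export
decision_policy <- function(rule = c("MAP", "sample_average"), K = NA_real_) {
  rule <- match.arg(rule)
  if (rule == "sample_average" && (!is.finite(K) || K < 1)) {
    stop("K must be >= 1 for the sample-averaging rule", call. = FALSE)
  }
  structure(list(rule = rule, K = K), class = "decision_policy")
}

#' Draw sensations from the generative sensation model
#'
#' Log visual angle follows the small-angle identity angle = size / distance,
#' so phi = s - d plus Gaussian noise; the haptic cue reports log-size plus
#' Gaussian noise and exists only on haptic trials.
#'
#' @param stimuli data frame with columns \code{d_true}, \code{s_true}
#'   (natural logs of mm) and \code{condition} (\code{"haptic"} /
#'   \code{"no_haptic"}).
#' @param noise a [noise_model()].
#' @return \code{stimuli} with columns \code{phi} (log-radians) and \code{h}
#'   (log-mm, NA on no-haptic trials) appended.
#' @export
sense <- function(stimuli, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (!all(c("d_true", "s_true", "condition") %in% names(stimuli))) {
    stop("stimuli must carry d_true, s_true and condition", call. = FALSE)
  }
  if (any(!is.finite(stimuli$d_true)) || any(!is.finite(stimuli$s_true))) {
    stop("non-finite stimulus values", call. = FALSE)
  }
  n <- nrow(stimuli)
  stimuli$phi <- stimuli$s_true - stimuli$d_true +
    stats::rnorm(n, 0, noise$sigma_phi_true)
  h <- rep(NA_real_, n)
  # an NA haptic SD means the haptic channel is not modeled at all (the
  # no-haptic observers); h is then absent even on haptic trials
  hap <- stimuli$condition == "haptic" & !is.na(noise$sigma_h_true)
  if (any(hap)) {
    h[hap] <- stimuli$s_true[hap] +
      stats::rnorm(sum(hap), 0, noise$sigma_h_true)
  }
  stimuli$h <- h
  stimuli
}

#' Posterior cue weights and variance over log-distance
#'
#' Closed form of the explaining-away posterior in the linear-Gaussian model.
#' Haptic form (writing v_* for variances, D for the normalizer
#' v_d v_s + v_d v_h + v_phi v_s + v_phi v_h + v_s v_h):
#' w_phi = (v_d v_s + v_d v_h)/D, w_h = v_d v_s / D, w_s = v_d v_h / D,
#' w_d = (v_phi v_s + v_phi v_h + v_s v_h)/D, with posterior variance
#' v_d w_d. The haptic cue earns weight through its ability to pin down
#' log-size and thereby disambiguate the visual angle. No-haptic form: with
#' D0 = v_d + v_phi + v_s, w_phi = w_s = v_d / D0, w_h = 0,
#' w_d = (v_phi + v_s)/D0, variance v_d (v_phi + v_s)/D0.
#'
#' @param knowledge an [observer_knowledge()].
#' @param use_haptic logical; use the haptic form?
#' @return List with \code{w_phi}, \code{w_h}, \code{w_s}, \code{w_d},
#'   \code{var_post}.
#' @export
posterior_weights <- function(knowledge, use_haptic) {
  stopifnot(inherits(knowledge, "observer_knowledge"))
  v_phi <- knowledge$sigma_phi^2
  v_s <- knowledge$sigma_s^2
  v_d <- knowledge$sigma_d^2
  if (use_haptic) {
    if (is.na(knowledge$sigma_h)) {
      stop("haptic form requested but assumed sigma_h is NA", call. = FALSE)
    }
    v_h <- knowledge$sigma_h^2
    D <- v_d * v_s + v_d * v_h + v_phi * v_s + v_phi * v_h + v_s * v_h
    list(w_phi = (v_d * v_s + v_d * v_h) / D,
         w_h = v_d * v_s / D,
         w_s = v_d * v_h / D,
         w_d = (v_phi * v_s + v_phi * v_h + v_s * v_h) / D,
         var_post = v_d * (v_phi * v_s + v_phi * v_h + v_s * v_h) / D)
  } else {
    D0 <- v_d + v_phi + v_s
    list(w_phi = v_d / D0,
         w_h = 0,
         w_s = v_d / D0,
         w_d = (v_phi + v_s) / D0,
         var_post = v_d * (v_phi + v_s) / D0)
  }
}

#' Perceptual posterior over log-distance
#'
#' Combines the log visual angle, the haptic size cue (when used), and the
#' observer's priors into the Gaussian posterior over log-distance.
#' Haptic form: mu = -w_phi phi + w_h h + w_s mu_s + w_d mu_d. No-haptic
#' form: mu = w_phi (mu_s - phi) + w_d mu_d (the size prior mean stands in
#' for the missing haptic report). Vectorized over sensations.
#'
#' @param phi log visual angle(s).
#' @param h log haptic size(s); required (finite) when \code{use_haptic}.
#' @param knowledge an [observer_knowledge()].
#' @param use_haptic logical; integrate the haptic cue?
#' @return List of class \code{posterior_belief}: \code{mu_post} (vector),
#'   \code{var_post} (scalar), \code{weights} (named vector w_phi, w_h, w_s,
#'   w_d).
#' @export
compute_posterior <- function(phi, h = NULL, knowledge, use_haptic = !is.null(h)) {
  w <- posterior_weights(knowledge, use_haptic)
  if (use_haptic) {
    if (is.null(h) || any(!is.finite(h))) {
      stop("haptic form requires finite h", call. = FALSE)
    }
    mu <- -w$w_phi * phi + w$w_h * h + w$w_s * knowledge$mu_s +
      w$w_d * knowledge$mu_d
  } else {
    mu <- w$w_phi * (knowledge$mu_s - phi) + w$w_d * knowledge$mu_d
  }
  structure(
    list(mu_post = mu, var_post = w$var_post,
         weights = c(w_phi = w$w_phi, w_h = w$w_h, w_s = w$w_s, w_d = w$w_d)),
    class = "posterior_belief"
  )
}

#' Turn a posterior belief into a judged log-distance
#'
#' MAP observers report the posterior mean (mode, for a Gaussian);
#' sample-averaging observers report the mean of K independent posterior
#' draws. Additive Gaussian motor noise is applied either way. In simulation
#' K must resolve to an integer; continuous K values are rounded to the
#' nearest integer >= 1.
#'
#' @param belief a \code{posterior_belief} (its \code{mu_post} may be a
#'   vector; one response per element).
#' @param policy a [decision_policy()].
#' @param sigma_m motor noise SD (log-mm).
#' @return Numeric vector of judged log-distances.
#' @export
decide <- function(belief, policy, sigma_m) {
  stopifnot(inherits(belief, "posterior_belief"),
            inherits(policy, "decision_policy"),
            sigma_m >= 0)
  mu <- belief$mu_post
  n <- length(mu)
  if (policy$rule == "MAP") {
    est <- mu
  } else {
    K <- as.integer(round(policy$K))
    if (K < 1) stop("K must be >= 1", call. = FALSE)
    draws <- matrix(stats::rnorm(n * K, mean = rep(mu, each = K),
                                 sd = sqrt(belief$var_post)),
                    nrow = K)
    est <- colMeans(draws)
  }
  est + stats::rnorm(n, 0, sigma_m)
}

# Closed-form response moments (m, v) per trial for a model + theta.
# Vectorized over trials; weights and v depend only on the condition.
response_moments <- function(d_true, s_true, condition, theta, model) {
  comp <- theta_components(theta, model)
  kn <- comp$knowledge
  nz <- comp$noise
  sampling <- model$decision_rule == "sample_average"
  K <- if (sampling) theta[["K"]] else Inf

  w0 <- posterior_weights(kn, use_haptic = FALSE)
  m <- w0$w_phi * (d_true - s_true + kn$mu_s) + w0$w_d * kn$mu_d
  v <- rep(w0$w_phi^2 * nz$sigma_phi_true^2 +
             (if (sampling) w0$var_post / K else 0) +
             nz$sigma_m^2, length(d_true))

  if (model$use_haptic) {
    hap <- condition == "haptic"
    if (any(hap)) {
      wh <- posterior_weights(kn, use_haptic = TRUE)
      m[hap] <- wh$w_phi * d_true[hap] - wh$w_s * s_true[hap] +
        wh$w_s * kn$mu_s + wh$w_d * kn$mu_d
      v[hap] <- wh$w_phi^2 * nz$sigma_phi_true^2 +
        wh$w_h^2 * nz$sigma_h_true^2 +
        (if (sampling) wh$var_post / K else 0) +
        nz$sigma_m^2
    }
  }
  list(m = m, v = v)
}

#' Per-trial response log-likelihood
#'
#' The full sensation-perception-decision chain is linear-Gaussian, so the
#' judged log-distance given the true scene is exactly Normal(m, v). Haptic
#' trials of a haptic-integrating model: m = w_phi d - w_s s + w_s mu_s +
#' w_d mu_d and v = w_phi^2 sigma_phi_true^2 + w_h^2 sigma_h_true^2 +
#' var_post/K (sampling observers only) + sigma_m^2. All other trials use the
#' no-haptic weights: m = w_phi (d - s + mu_s) + w_d mu_d with the analogous
#' variance. K enters as a continuous positive value, which is what lets the
#' likelihood be fit by MCMC.
#'
#' @param records data frame with \code{d_true}, \code{s_true},
#'   \code{condition} and judged log-distance \code{r}.
#' @param theta named parameter vector (see [active_params()]).
#' @param model an \code{observer_model}.
#' @return Numeric vector of per-trial log-densities of \code{r}.
#' @export
response_likelihood <- function(records, theta, model) {
  theta <- validate_theta(theta, model, allow_zero_sd = TRUE)
  if (any(!is.finite(records$r))) {
    stop("non-finite judged log-distance", call. = FALSE)
  }
  mv <- response_moments(records$d_true, records$s_true, records$condition,
                         theta, model)
  stats::dnorm(records$r, mean = mv$m, sd = sqrt(mv$v), log = TRUE)
}

# Fast unchecked total log-likelihood for the MCMC inner loop.
loglik_total <- function(d_true, s_true, is_haptic, r, theta, model) {
  comp_sigma_phi_true <- if ("sigma_phi_true" %in% names(theta))
    theta[["sigma_phi_true"]] else theta[["sigma_phi"]]
  v_phi <- theta[["sigma_phi"]]^2
  v_s <- theta[["sigma_s"]]^2
  v_d <- theta[["sigma_d"]]^2
  mu_s <- theta[["mu_s"]]
  mu_d <- theta[["mu_d"]]
  sampling <- model$decision_rule == "sample_average"
  K <- if (sampling) theta[["K"]] else Inf
  v_m <- theta[["sigma_m"]]^2

  D0 <- v_d + v_phi + v_s
  w0_phi <- v_d / D0
  w0_d <- (v_phi + v_s) / D0
  var0 <- v_d * (v_phi + v_s) / D0
  m <- w0_phi * (d_true - s_true + mu_s) + w0_d * mu_d
  v0 <- w0_phi^2 * comp_sigma_phi_true^2 +
    (if (sampling) var0 / K else 0) + v_m
  v <- rep.int(v0, length(d_true))

  if (model$use_haptic && any(is_haptic)) {
    sigma_h_true <- if ("sigma_h_true" %in% names(theta))
      theta[["sigma_h_true"]] else theta[["sigma_h"]]
    v_h <- theta[["sigma_h"]]^2
    D <- v_d * v_s + v_d * v_h + v_phi * v_s + v_phi * v_h + v_s * v_h
    w_phi <- (v_d * v_s + v_d * v_h) / D
    w_h <- v_d * v_s / D
    w_s <- v_d * v_h / D
    w_d <- (v_phi * v_s + v_phi * v_h + v_s * v_h) / D
    varh <- v_d * w_d
    m[is_haptic] <- w_phi * d_true[is_haptic] - w_s * s_true[is_haptic] +
      w_s * mu_s + w_d * mu_d
    v[is_haptic] <- w_phi^2 * comp_sigma_phi_true^2 +
      w_h^2 * sigma_h_true^2 + (if (sampling) varh / K else 0) + v_m
  }
  -0.5 * sum(log(2 * pi * v) + (r - m)^2 / v)
}

#' Simulate observer responses for a stimulus list
#'
#' Runs sense -> compute_posterior -> decide trial by trial (vectorized).
#' Haptic integration happens only when the model uses the haptic cue AND the
#' trial is haptic; all other trials use the no-haptic posterior.
#'
#' @param stimuli data frame of scene stimuli (see [generate_schedule()]).
#' @param theta named parameter vector for \code{model}.
#' @param model an \code{observer_model}.
#' @param seed optional integer seed for reproducibility.
#' @return \code{stimuli} with sensations \code{phi}, \code{h} and the judged
#'   log-distance \code{r} appended.
#' @export
simulate_responses <- function(stimuli, theta, model, seed = NULL) {
  if (nrow(stimuli) == 0L) stop("stimuli must be non-empty", call. = FALSE)
  theta <- validate_theta(theta, model, allow_zero_sd = TRUE)
  if (!is.null(seed)) set.seed(seed)
  comp <- theta_components(theta, model)
  out <- sense(stimuli, comp$noise)
  r <- numeric(nrow(out))
  hap <- model$use_haptic & out$condition == "haptic"

  if (any(!hap)) {
    bel <- compute_posterior(out$phi[!hap], knowledge = comp$knowledge,
                             use_haptic = FALSE)
    r[!hap] <- decide(bel, comp$policy, comp$noise$sigma_m)
  }
  if (any(hap)) {
    bel <- compute_posterior(out$phi[hap], out$h[hap],
                             knowledge = comp$knowledge, use_haptic = TRUE)
    r[hap] <- decide(bel, comp$policy, comp$noise$sigma_m)
  }
  out$r <- r
  out
}
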