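#' Deviance of a parameter vector
#'
#' D(theta) = -2 x total response log-likelihood (the prior is excluded).
#'
#' @param theta named parameter vector.
#' @param records trial records.
#' @param model an \code{observer_model}.
#' @return Scalar deviance.
#' @export
deviance_obs <- function(theta, records, model) {
  -2 * sum(response_likelihood(records, theta, model))
}

# DIC decomposition from raw deviance draws and the deviance at a point
# estimate. Shared by dic() and the conjugate-toy tests.
dic_from_deviances <- function(dev_draws, dev_at_point) {
  D_bar <- mean(dev_draws)
  p_D <- D_bar - dev_at_point
  list(D_bar = D_bar, D_at_theta_bar = dev_at_point, p_D = p_D,
       DIC = D_bar + p_D)
}

#' Deviance Information Criterion of a fitted model
#'
#' DIC = D_bar + p_D where D_bar is the posterior-expected deviance and
#' p_D = D_bar - D(theta_bar) the effective number of parameters, with
#' theta_bar the robust (trimmed) posterior mean. Negative p_D (possible
#' under non-convergence or multimodality) is flagged with a warning, not an
#' error; a split R-hat above 1.05 on any parameter likewise warns.
#'
#' @param fit an \code{mcmc_fit} (stores per-draw log-likelihoods, so no
#'   recomputation over draws is needed).
#' @param records the records the model was fitted to (for the deviance at
#'   theta_bar).
#' @param model the fitted \code{observer_model}; defaults to the one stored
#'   in \code{fit}.
#' @return List of class \code{dic_report}: \code{model_id}, \code{D_bar},
#'   \code{D_at_theta_bar}, \code{p_D}, \code{DIC}, \code{theta_bar},
#'   \code{rhat_max}, \code{flags}.
#' @export
dic <- function(fit, records, model = fit$model) {
  stopifnot(inherits(fit, "mcmc_fit"))
  flags <- character(0)
  rhat_max <- max(fit$diagnostics$rhat)
  if (is.finite(rhat_max) && rhat_max > 1.05) {
    flags <- c(flags, "rhat")
    warning(sprintf("model %d: max split R-hat %.3f > 1.05; chains may not have converged",
                    model$id, rhat_max), call. = FALSE)
  }
  theta_bar <- fit$theta_bar
  dec <- dic_from_deviances(as.vector(-2 * fit$loglik),
                            deviance_obs(theta_bar, records, model))
  if (dec$p_D < 0) {
    flags <- c(flags, "negative_p_D")
    warning(sprintf("model %d: negative p_D (%.2f); possible non-convergence or multimodality",
                    model$id, dec$p_D), call. = FALSE)
  }
  structure(c(list(model_id = model$id), dec,
              list(theta_bar = theta_bar, rhat_max = rhat_max, flags = flags)),
            class = "dic_report")
}

#' Rank models by DIC
#'
#' Ascending DIC with differences to the best model and the significance
#' labels used throughout: a DIC gap above 10 is "significant", above 15
#' "highly significant", anything else "n.s." (gaps of 8-9, sometimes called
#' marginally significant, are reported as n.s. with the raw delta printed).
#' Ties are broken by model id, so the ranking is stable under permutation
#' of the input.
#'
#' @param reports list of \code{dic_report} objects (>= 2).
#' @return Data frame sorted by DIC: \code{model_id}, \code{D_bar},
#'   \code{p_D}, \code{DIC}, \code{delta_vs_best}, \code{significance},
#'   \code{flags}.
#' @export
rank_models <- function(reports) {
  if (length(reports) < 2) stop("need at least 2 models to rank", call. = FALSE)
  df <- data.frame(
    model_id = vapply(reports, `[[`, numeric(1), "model_id"),
    D_bar = vapply(reports, `[[`, numeric(1), "D_bar"),
    D_at_theta_bar = vapply(reports, `[[`, numeric(1), "D_at_theta_bar"),
    p_D = vapply(reports, `[[`, numeric(1), "p_D"),
    DIC = vapply(reports, `[[`, numeric(1), "DIC"),
    flags = vapply(reports, function(r) paste(r$flags, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$DIC, df$model_id), , drop = FALSE]
  df$delta_vs_best <- df$DIC - df$DIC[1]
  df$significance <- ifelse(df$delta_vs_best == 0, "best",
                            ifelse(df$delta_vs_best > 15, "highly significant",
                                   ifelse(df$delta_vs_best > 10, "significant",
                                          "n.s.")))
  rownames(df) <- NULL
  df
}

#' Weber fraction of a log-domain noise SD
#'
#' Under multiplicative (log-Gaussian) noise, a 1-SD discrimination
#' criterion corresponds to a just-noticeable relative change of
#' exp(sigma) - 1.
#'
#' @param sigma log-domain SD (>= 0); vectorized.
#' @return Weber fraction(s).
#' @export
weber_fraction <- function(sigma) {
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  exp(sigma) - 1
}

#' Interpretable parameter summary of a fitted model
#'
#' theta_bar with 95% credible intervals, Weber fractions for the sensory
#' SDs, and the fitted prior parameters juxtaposed with the stimulus
#' log-statistics they should resemble.
#'
#' @param fit an \code{mcmc_fit}.
#' @param stimuli stimulus set used, for [stimulus_log_stats()] comparison;
#'   optional.
#' @return Data frame, one row per active parameter: \code{param},
#'   \code{estimate}, \code{ci_lower}, \code{ci_upper},
#'   \code{weber_fraction} (NA for non-sensory parameters),
#'   \code{stimulus_stat} (matching log-statistic for prior parameters, else
#'   NA).
#' @export
parameter_report <- function(fit, stimuli = NULL) {
  tb <- fit$theta_bar
  ci <- credible_interval(fit)
  sensory <- c("sigma_phi_true", "sigma_phi", "sigma_h_true", "sigma_h")
  wf <- ifelse(names(tb) %in% sensory, weber_fraction(pmax(tb, 0)), NA_real_)
  stat <- rep(NA_real_, length(tb))
  if (!is.null(stimuli)) {
    st <- stimulus_log_stats(stimuli)
    map <- c(mu_d = st$mean_log_distance, sigma_d = st$sd_log_distance,
             mu_s = st$mean_log_size, sigma_s = st$sd_log_size)
    hit <- names(tb) %in% names(map)
    stat[hit] <- map[names(tb)[hit]]
  }
  data.frame(param = names(tb), estimate = unname(tb),
             ci_lower = ci["lower", ], ci_upper = ci["upper", ],
             weber_fraction = wf, stimulus_stat = stat,
             row.names = NULL, stringsAsFactors = FALSE)
}
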