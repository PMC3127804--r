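#' Read and validate a pipeline run configuration
#'
#' The run configuration is a YAML document with fields: \code{seed}
#' (integer), \code{output_dir}, \code{schedule} (any [schedule_config()]
#' fields to override), \code{ground_truth} (\code{model_id} and named
#' \code{theta}, for synthetic runs), \code{models} (integer ids in 1..12 to
#' fit), \code{sampler} (\code{preset} and/or \code{chains}, \code{burnin},
#' \code{samples}), and \code{day_filter} (one of
#' \code{"exclude_training"}, \code{"first_day_only"}, \code{"all"}).
#' Validation is structural: unknown fields, out-of-range ids, or malformed
#' entries raise a validation error.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return Validated list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  known <- c("seed", "output_dir", "schedule", "ground_truth", "models",
             "sampler", "day_filter")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown config fields: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  cfg <- list()
  cfg$seed <- as.integer(raw$seed %||% 1L)
  cfg$output_dir <- raw$output_dir %||% "sizedist-out"
  cfg$schedule <- do.call(schedule_config, raw$schedule %||% list())
  cfg$day_filter <- match.arg(raw$day_filter %||% "exclude_training",
                              c("exclude_training", "first_day_only", "all"))
  cfg$models <- as.integer(raw$models %||% c(3L, 7L))
  if (any(cfg$models < 1 | cfg$models > 12)) {
    stop("model ids must be in 1..12", call. = FALSE)
  }
  cfg$sampler <- do.call(sampler_config, raw$sampler %||% list())
  if (!is.null(raw$ground_truth)) {
    gt <- raw$ground_truth
    if (is.null(gt$model_id) || is.null(gt$theta)) {
      stop("ground_truth needs model_id and theta", call. = FALSE)
    }
    model <- observer_model(gt$model_id)
    theta <- unlist(gt$theta)
    validate_theta(theta, model)
    cfg$ground_truth <- list(model = model, theta = theta[active_params(model)])
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hash of a run configuration
#'
#' md5 of the canonical JSON serialization; stamped into every output file's
#' manifest so any report can be traced to its exact inputs.
#'
#' @param config a \code{run_config} (or any serializable list).
#' @return Character md5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

filter_days <- function(records, config) {
  switch(config$day_filter,
         exclude_training = apply_training_exclusion(records, config$schedule),
         first_day_only = records[records$day == 1L, , drop = FALSE],
         all = records)
}

#' Stage 1: simulate a synthetic dataset
#'
#' Wraps [simulate_experiment()]; writes \code{trials.csv} and
#' \code{manifest.json} under the output directory and logs trial counts and
#' stimulus log-statistics.
#'
#' @param config a \code{run_config} with a \code{ground_truth} entry.
#' @param quiet suppress progress messages.
#' @return List: \code{records} (all days), \code{analysis_records} (after
#'   the day filter), \code{manifest}, \code{paths}.
#' @export
run_simulate <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$ground_truth)) {
    stop("run_simulate requires a ground_truth entry", call. = FALSE)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_experiment(config$schedule, config$ground_truth$model,
                             config$ground_truth$theta, seed = config$seed)
  sim$manifest$config_hash <- config_hash(config)
  kept <- filter_days(sim$records, config)
  paths <- list(trials = file.path(config$output_dir, "trials.csv"),
                manifest = file.path(config$output_dir, "manifest.json"))
  write_trials(sim$records, paths$trials)
  write_manifest(sim$manifest, paths$manifest)
  if (!quiet) {
    st <- stimulus_log_stats(kept)
    message(sprintf(
      "simulate: %d trials generated, %d retained (%s); log-distance %.3f +/- %.3f, log-size %.3f +/- %.3f",
      nrow(sim$records), nrow(kept), config$day_filter,
      st$mean_log_distance, st$sd_log_distance,
      st$mean_log_size, st$sd_log_size))
  }
  list(records = sim$records, analysis_records = kept,
       manifest = sim$manifest, paths = paths)
}

#' Stage 2: fit the requested models
#'
#' Fits each model id in \code{config$models} to the day-filtered records,
#' persists the posterior samples (CSV, one file per model, columns
#' \code{chain}, \code{iter}, the active parameters, \code{loglik}) plus a
#' run manifest carrying bounds, sampler settings, seeds and the config
#' hash. Non-convergence (split R-hat > 1.05) produces a warning and a flag,
#' never an abort.
#'
#' @param config a \code{run_config}.
#' @param records trial records; defaults to reading
#'   \code{output_dir/trials.csv} and applying the day filter.
#' @param quiet suppress progress messages.
#' @return Named list of \code{mcmc_fit} objects ("model_<id>").
#' @export
run_fit <- function(config, records = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(records)) {
    records <- filter_days(read_trials(file.path(config$output_dir, "trials.csv")),
                           config)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- list()
  for (i in seq_along(config$models)) {
    id <- config$models[i]
    model <- observer_model(id)
    t0 <- Sys.time()
    fit <- fit_model(records, model, sampler = config$sampler,
                     seed = config$seed + id)
    if (!quiet) {
      message(sprintf("fit: model %d in %.1fs (max R-hat %.3f)",
                      id, as.numeric(Sys.time() - t0, units = "secs"),
                      max(fit$diagnostics$rhat)))
    }
    save_fit(fit, file.path(config$output_dir, sprintf("fit_model_%02d.csv", id)))
    run_manifest <- list(model_id = id, seed = fit$seed,
                         sampler = unclass(config$sampler),
                         bounds = fit$bounds,
                         config_hash = config_hash(config))
    jsonlite::write_json(run_manifest,
                         file.path(config$output_dir,
                                   sprintf("fit_model_%02d_manifest.json", id)),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    fits[[sprintf("model_%d", id)]] <- fit
  }
  fits
}

#' Persist / reload posterior samples
#'
#' CSV schema: \code{chain}, \code{iter}, one column per active parameter,
#' \code{loglik}. \code{load_fit} rebuilds an \code{mcmc_fit} (diagnostics
#' and theta_bar recomputed; acceptance rates are not persisted).
#'
#' @param fit an \code{mcmc_fit}.
#' @param path CSV path.
#' @export
save_fit <- function(fit, path) {
  pn <- dimnames(fit$samples)[[2]]
  d <- dim(fit$samples)
  rows <- do.call(rbind, lapply(seq_len(d[3]), function(ch) {
    data.frame(chain = ch, iter = seq_len(d[1]),
               fit$samples[, , ch, drop = TRUE],
               loglik = fit$loglik[, ch])
  }))
  names(rows) <- c("chain", "iter", pn, "loglik")
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname save_fit
#' @param model the \code{observer_model} the samples belong to.
#' @export
load_fit <- function(path, model) {
  df <- utils::read.csv(path)
  pn <- active_params(model)
  chains <- sort(unique(df$chain))
  n <- sum(df$chain == chains[1])
  samp <- array(NA_real_, c(n, length(pn), length(chains)),
                dimnames = list(NULL, pn, NULL))
  ll <- matrix(NA_real_, n, length(chains))
  for (ch in seq_along(chains)) {
    sub <- df[df$chain == chains[ch], ]
    sub <- sub[order(sub$iter), ]
    samp[, , ch] <- as.matrix(sub[pn])
    ll[, ch] <- sub$loglik
  }
  fit <- structure(list(samples = samp, loglik = ll, lp = NULL,
                        acceptance = NULL,
                        diagnostics = list(
                          rhat = apply(samp, 2, split_rhat),
                          ess = NA),
                        model = model, bounds = default_bounds(model),
                        sampler = NULL, seed = NA_integer_),
                   class = "mcmc_fit")
  fit$theta_bar <- robust_mean(fit)
  fit
}

#' Stage 3: compare fitted models
#'
#' Computes each model's DIC, ranks the family, and writes the DIC report
#' (JSON + formatted text table) and per-model parameter summaries. The
#' report header records the canonical id scheme (odd ids = sample-averaging
#' observers, 1-4 no-haptic, 5-12 haptic) so ids never change meaning across
#' reports.
#'
#' @param fits named list of \code{mcmc_fit} objects from [run_fit()].
#' @param records the records the models were fitted to.
#' @param config a \code{run_config} (for output paths and hash).
#' @param stimuli optional stimulus set for the prior-vs-stimulus comparison
#'   (defaults to \code{records}).
#' @return List: \code{dic_table} (data frame), \code{reports} (raw
#'   \code{dic_report}s), \code{parameters} (per-model data frames).
#' @export
run_compare <- function(fits, records, config, stimuli = records) {
  if (length(fits) == 0) stop("no fitted models supplied", call. = FALSE)
  reports <- lapply(fits, dic, records = records)
  tab <- if (length(reports) >= 2) rank_models(reports) else {
    r <- reports[[1]]
    data.frame(model_id = r$model_id, D_bar = r$D_bar,
               D_at_theta_bar = r$D_at_theta_bar, p_D = r$p_D, DIC = r$DIC,
               flags = paste(r$flags, collapse = ";"),
               delta_vs_best = 0, significance = "best")
  }
  params <- lapply(fits, parameter_report, stimuli = stimuli)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  header <- paste(
    "Canonical model ids: 1-4 no-haptic, 5-12 haptic; odd = sample-averaging,",
    "even = MAP twin; 7 = haptic/inaccurate-haptic/accurate-image/sampling,",
    "11 = accurate-haptic twin of 7, 5 = inaccurate-image variant of 7,",
    "3 = no-haptic variant of 7."
  )
  out <- list(header = header, config_hash = config_hash(config),
              dic_table = tab,
              parameters = lapply(params, function(p) p))
  jsonlite::write_json(out, file.path(config$output_dir, "dic_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  txt <- c(header, "",
           utils::capture.output(print(format(tab, digits = 6))))
  writeLines(txt, file.path(config$output_dir, "dic_report.txt"))
  list(dic_table = tab, reports = reports, parameters = params)
}

#' One-shot recovery run: simulate, fit, compare
#'
#' End-to-end synthetic pipeline mirroring a parameter/model-recovery study:
#' generates data from the configured ground-truth observer, fits the
#' requested candidate models, and writes the DIC and parameter reports.
#' Deterministic under a fixed seed.
#'
#' @param config a \code{run_config} with \code{ground_truth}.
#' @param quiet suppress progress messages.
#' @return List: \code{simulation}, \code{fits}, \code{comparison}.
#' @export
run_recover <- function(config, quiet = FALSE) {
  sim <- run_simulate(config, quiet = quiet)
  fits <- run_fit(config, sim$analysis_records, quiet = quiet)
  cmp <- run_compare(fits, sim$analysis_records, config,
                     stimuli = sim$analysis_records)
  list(simulation = sim, fits = fits, comparison = cmp)
}
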