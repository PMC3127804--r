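#' Experiment schedule configuration
#'
#' Defaults mirror the interception experiment being emulated: 4 days of 4
#' blocks of 80 trials (1280 total), ball diameters uniform on [14, 42] mm,
#' crossing distances uniform on [300, 640] mm, ball speeds uniform on
#' [250, 375] mm/s, haptic and no-haptic trials interleaved in equal
#' proportions, and the first day treated as training and excluded from
#' analysis (leaving 960 trials, 480 per condition).
#'
#' @param n_days number of days.
#' @param blocks_per_day blocks per day.
#' @param trials_per_block trials per block; must be even so each block can
#'   hold an exact half/half condition split.
#' @param distance_range_mm,diameter_range_mm,speed_range_mm_s,angle_range_deg
#'   proper intervals for the uniform stimulus draws.
#' @param training_days_excluded number of leading days dropped by
#'   [apply_training_exclusion()].
#' @return A list of class \code{schedule_config}.
#' @export
schedule_config <- function(n_days = 4, blocks_per_day = 4,
                            trials_per_block = 80,
                            distance_range_mm = c(300, 640),
                            diameter_range_mm = c(14, 42),
                            speed_range_mm_s = c(250, 375),
                            angle_range_deg = c(-8.5, 8.5),
                            training_days_excluded = 1) {
  chk_range <- function(x, nm) {
    if (length(x) != 2 || !all(is.finite(x)) || x[1] > x[2] || x[1] <= 0 && nm != "angle_range_deg") {
      stop(nm, " must be a proper positive interval", call. = FALSE)
    }
  }
  chk_range(distance_range_mm, "distance_range_mm")
  chk_range(diameter_range_mm, "diameter_range_mm")
  chk_range(speed_range_mm_s, "speed_range_mm_s")
  if (length(angle_range_deg) != 2 || angle_range_deg[1] > angle_range_deg[2]) {
    stop("angle_range_deg must be a proper interval", call. = FALSE)
  }
  if (n_days < 1 || blocks_per_day < 1 || trials_per_block < 1) {
    stop("schedule counts must be positive", call. = FALSE)
  }
  if (trials_per_block %% 2 != 0) {
    stop("trials_per_block must be even for an equal condition split",
         call. = FALSE)
  }
  if (training_days_excluded < 0 || training_days_excluded >= n_days) {
    stop("training_days_excluded must lie in [0, n_days)", call. = FALSE)
  }
  structure(list(n_days = as.integer(n_days),
                 blocks_per_day = as.integer(blocks_per_day),
                 trials_per_block = as.integer(trials_per_block),
                 distance_range_mm = distance_range_mm,
                 diameter_range_mm = diameter_range_mm,
                 speed_range_mm_s = speed_range_mm_s,
                 angle_range_deg = angle_range_deg,
                 training_days_excluded = as.integer(training_days_excluded)),
            class = "schedule_config")
}

#' Generate a trial schedule
#'
#' Draws diameters and crossing distances uniformly in mm over their
#' configured ranges, balances conditions exactly half/half inside every
#' block (random order within block), and stores natural logs of the mm
#' draws alongside. Speeds and approach angles are generated for realism but
#' never consumed by any observer model.
#'
#' @param config a [schedule_config()].
#' @param seed optional integer seed.
#' @return Data frame of scene stimuli: \code{day}, \code{block},
#'   \code{trial} (0-based within block), \code{condition},
#'   \code{distance_mm}, \code{diameter_mm}, \code{speed_mm_s},
#'   \code{angle_deg}, \code{d_true}, \code{s_true}.
#' @export
generate_schedule <- function(config = schedule_config(), seed = NULL) {
  stopifnot(inherits(config, "schedule_config"))
  if (!is.null(seed)) set.seed(seed)
  n_block <- config$trials_per_block
  n_total <- config$n_days * config$blocks_per_day * n_block
  day <- rep(seq_len(config$n_days),
             each = config$blocks_per_day * n_block)
  block <- rep(rep(seq_len(config$blocks_per_day), each = n_block),
               times = config$n_days)
  trial <- rep(seq_len(n_block) - 1L,
               times = config$n_days * config$blocks_per_day)
  cond <- unlist(lapply(seq_len(config$n_days * config$blocks_per_day),
                        function(i) {
                          sample(rep(c("haptic", "no_haptic"),
                                     each = n_block %/% 2L))
                        }), use.names = FALSE)
  distance <- stats::runif(n_total, config$distance_range_mm[1],
                           config$distance_range_mm[2])
  diameter <- stats::runif(n_total, config$diameter_range_mm[1],
                           config$diameter_range_mm[2])
  speed <- stats::runif(n_total, config$speed_range_mm_s[1],
                        config$speed_range_mm_s[2])
  angle <- stats::runif(n_total, config$angle_range_deg[1],
                        config$angle_range_deg[2])
  data.frame(day = day, block = block, trial = trial, condition = cond,
             distance_mm = distance, diameter_mm = diameter,
             speed_mm_s = speed, angle_deg = angle,
             d_true = log(distance), s_true = log(diameter),
             stringsAsFactors = FALSE)
}

#' Drop training days
#'
#' Removes every record from the leading training days, preserving order.
#' With the default schedule this leaves 960 of 1280 trials.
#'
#' @param records data frame with a \code{day} column.
#' @param config a [schedule_config()] (only \code{training_days_excluded}
#'   is consulted) or an integer count of excluded days.
#' @return Filtered data frame.
#' @export
apply_training_exclusion <- function(records, config = schedule_config()) {
  n_excl <- if (inherits(config, "schedule_config")) {
    config$training_days_excluded
  } else {
    as.integer(config)
  }
  records[records$day > n_excl, , drop = FALSE]
}

#' Log-domain sample statistics of a stimulus set
#'
#' Mean and SD of log-distance and log-size, the quantities a fitted
#' observer's prior parameters should be compared with.
#'
#' @param stimuli data frame with \code{d_true}, \code{s_true}.
#' @return Named list: \code{mean_log_distance}, \code{sd_log_distance},
#'   \code{mean_log_size}, \code{sd_log_size} (all log-mm).
#' @export
stimulus_log_stats <- function(stimuli) {
  if (nrow(stimuli) == 0L) stop("empty stimulus set", call. = FALSE)
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  list(mean_log_distance = mean(stimuli$d_true),
       sd_log_distance = sd0(stimuli$d_true),
       mean_log_size = mean(stimuli$s_true),
       sd_log_size = sd0(stimuli$s_true))
}

#' Simulate a full synthetic experiment
#'
#' Generates a schedule, simulates responses from a ground-truth observer,
#' and returns the trial records along with a manifest sufficient to
#' reproduce them exactly. Each trial is annotated with the accuracy
#' feedback the apparatus would have given (judged distance within 32 mm of
#' the crossing distance); the feedback is recorded but never fed back into
#' the observer.
#'
#' @param config a [schedule_config()].
#' @param model ground-truth \code{observer_model}.
#' @param theta ground-truth parameter vector for \code{model}.
#' @param seed integer seed driving schedule and responses.
#' @param feedback_window_mm collision feedback half-width, mm.
#' @return List with \code{records} (data frame; schedule columns plus
#'   \code{phi}, \code{h}, \code{r}, \code{judged_mm}, \code{feedback_hit})
#'   and \code{manifest} (list: model_id, theta, seed, config).
#' @export
simulate_experiment <- function(config = schedule_config(), model, theta,
                                seed = 1L, feedback_window_mm = 32) {
  theta <- validate_theta(theta, model, allow_zero_sd = TRUE)
  set.seed(seed)
  sched <- generate_schedule(config)
  rec <- simulate_responses(sched, theta, model)
  rec$judged_mm <- exp(rec$r)
  rec$feedback_hit <- abs(rec$judged_mm - rec$distance_mm) <= feedback_window_mm
  manifest <- list(model_id = model$id,
                   theta = as.list(theta),
                   seed = as.integer(seed),
                   feedback_window_mm = feedback_window_mm,
                   config = unclass(config))
  list(records = rec, manifest = manifest)
}

#' Write / read trial records as CSV
#'
#' The on-disk schema is in natural units: day, block, trial,
#' condition{haptic|no_haptic}, distance_mm, diameter_mm, speed_mm_s,
#' angle_deg, judged_mm. Log columns are reconstructed on read.
#'
#' @param records data frame of trial records (must carry \code{judged_mm}).
#' @param path file path.
#' @return \code{write_trials}: the path, invisibly. \code{read_trials}: data
#'   frame with \code{d_true}, \code{s_true}, \code{r} recomputed from the mm
#'   columns.
#' @export
write_trials <- function(records, path) {
  cols <- c("day", "block", "trial", "condition", "distance_mm",
            "diameter_mm", "speed_mm_s", "angle_deg", "judged_mm")
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop("records missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(records[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  ok <- rec$condition %in% c("haptic", "no_haptic")
  if (!all(ok)) stop("unknown condition labels in ", path, call. = FALSE)
  rec$d_true <- log(rec$distance_mm)
  rec$s_true <- log(rec$diameter_mm)
  rec$r <- log(rec$judged_mm)
  rec
}

#' Write / read a simulation manifest (JSON)
#'
#' @param manifest manifest list from [simulate_experiment()].
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$theta <- unlist(m$theta)
  cfg <- m$config
  m$config <- schedule_config(
    n_days = cfg$n_days, blocks_per_day = cfg$blocks_per_day,
    trials_per_block = cfg$trials_per_block,
    distance_range_mm = cfg$distance_range_mm,
    diameter_range_mm = cfg$diameter_range_mm,
    speed_range_mm_s = cfg$speed_range_mm_s,
    angle_range_deg = cfg$angle_range_deg,
    training_days_excluded = cfg$training_days_excluded
  )
  m
}
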