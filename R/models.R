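#' Candidate observer-model family
#'
#' Each candidate observer answers four structural questions:
#' \enumerate{
#'   \item Q I: is the haptic size cue integrated when available?
#'   \item Q II: is the observer's assumed haptic noise SD equal to the true
#'     one (accurate knowledge), or a free parameter of its own? Only
#'     meaningful for haptic-integrating observers.
#'   \item Q III: is the assumed image-size noise SD equal to the true one?
#'   \item Q IV: are responses MAP estimates, or averages of K posterior
#'     samples?
#' }
#' Merging the Q II variants of non-haptic observers leaves 12 distinct
#' models. Canonical numbering: ids 1-4 are the no-haptic observers and 5-12
#' the haptic ones; odd ids average posterior samples, even ids are their MAP
#' twins. Model 7 is (haptic, inaccurate haptic knowledge, accurate image
#' knowledge, sample-averaging) and model 11 its accurate-haptic counterpart.
#'
#' @param id integer in 1..12.
#' @return An object of class \code{observer_model}: a list with fields
#'   \code{id}, \code{use_haptic}, \code{haptic_knowledge_accurate} (NA for
#'   no-haptic models), \code{image_knowledge_accurate}, and
#'   \code{decision_rule} (\code{"sample_average"} or \code{"MAP"}).
#' @seealso [enumerate_models()], [count_free_parameters()]
#' @export
#' @examples
#' observer_model(7)
observer_model <- function(id) {
  id <- as.integer(id)
  if (length(id) != 1L || is.na(id) || id < 1L || id > 12L) {
    stop("model id must be a single integer in 1..12", call. = FALSE)
  }
  rule <- if (id %% 2L == 1L) "sample_average" else "MAP"
  if (id <= 4L) {
    spec <- list(
      id = id,
      use_haptic = FALSE,
      haptic_knowledge_accurate = NA,
      # ids 1,2: inaccurate image knowledge; ids 3,4: accurate
      image_knowledge_accurate = id >= 3L,
      decision_rule = rule
    )
  } else {
    k <- id - 5L                       # 0..7
    spec <- list(
      id = id,
      use_haptic = TRUE,
      haptic_knowledge_accurate = k >= 4L,   # 5-8 inaccurate, 9-12 accurate
      image_knowledge_accurate = (k %% 4L) >= 2L, # 5,6,9,10 inaccurate
      decision_rule = rule
    )
  }
  structure(spec, class = "observer_model")
}

#' Enumerate the 12 candidate observer models
#'
#' @return A list of 12 \code{observer_model} objects, ids 1..12.
#' @export
enumerate_models <- function() {
  lapply(1:12, observer_model)
}

#' @export
print.observer_model <- function(x, ...) {
  qii <- if (is.na(x$haptic_knowledge_accurate)) "n/a"
  else if (x$haptic_knowledge_accurate) "accurate" else "inaccurate"
  cat(sprintf(
    "observer model %d: %s | haptic knowledge %s | image knowledge %s | %s\n",
    x$id,
    if (x$use_haptic) "haptic" else "no-haptic",
    qii,
    if (x$image_knowledge_accurate) "accurate" else "inaccurate",
    x$decision_rule
  ))
  invisible(x)
}

#' Active parameter names of a model
#'
#' The full parameter pool is \code{sigma_phi_true}, \code{sigma_phi},
#' \code{sigma_h_true}, \code{sigma_h}, \code{mu_d}, \code{sigma_d},
#' \code{mu_s}, \code{sigma_s}, \code{sigma_m}, \code{K}. Accurate-knowledge
#' couplings collapse a true/assumed pair into the single assumed entry;
#' no-haptic observers carry no haptic entries (their likelihood never touches
#' the haptic channel); MAP observers carry no \code{K}.
#'
#' @param model an \code{observer_model}.
#' @return Character vector of active parameter names, in canonical order.
#' @export
active_params <- function(model) {
  stopifnot(inherits(model, "observer_model"))
  p <- character(0)
  if (!model$image_knowledge_accurate) p <- c(p, "sigma_phi_true")
  p <- c(p, "sigma_phi")
  if (model$use_haptic) {
    if (!isTRUE(model$haptic_knowledge_accurate)) p <- c(p, "sigma_h_true")
    p <- c(p, "sigma_h")
  }
  p <- c(p, "mu_d", "sigma_d", "mu_s", "sigma_s", "sigma_m")
  if (model$decision_rule == "sample_average") p <- c(p, "K")
  p
}

#' Number of free parameters of a model
#'
#' Ranges from 6 (no-haptic, accurate image knowledge, MAP) to 10 (haptic,
#' both knowledges inaccurate, sample-averaging).
#'
#' @param model an \code{observer_model}.
#' @return Integer count of active parameters.
#' @export
count_free_parameters <- function(model) {
  length(active_params(model))
}

# Parameters that live on a positive scale (sampled as logs during MCMC).
.positive_params <- c(
  "sigma_phi_true", "sigma_phi", "sigma_h_true", "sigma_h",
  "sigma_d", "sigma_s", "sigma_m", "K"
)

#' Validate a parameter vector against a model
#'
#' Checks that \code{theta} is a named numeric vector carrying exactly the
#' model's active parameters, all finite, SDs positive and \code{K >= 1}.
#'
#' @param theta named numeric vector.
#' @param model an \code{observer_model}.
#' @param allow_zero_sd if TRUE, degenerate zero SDs are tolerated (test use
#'   only; fitting never permits them).
#' @return \code{theta}, invisibly, with entries reordered canonically.
#' @export
validate_theta <- function(theta, model, allow_zero_sd = FALSE) {
  want <- active_params(model)
  if (!is.numeric(theta) || is.null(names(theta))) {
    stop("theta must be a named numeric vector", call. = FALSE)
  }
  missing <- setdiff(want, names(theta))
  extra <- setdiff(names(theta), want)
  if (length(missing)) {
    stop("theta is missing parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(extra)) {
    stop("theta has inactive parameters for model ", model$id, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  theta <- theta[want]
  if (any(!is.finite(theta))) stop("theta entries must be finite", call. = FALSE)
  sds <- intersect(names(theta), .positive_params)
  lo <- if (allow_zero_sd) 0 else .Machine$double.eps
  if (any(theta[setdiff(sds, "K")] < lo)) {
    stop("all SD parameters must be positive", call. = FALSE)
  }
  if ("K" %in% names(theta) && theta[["K"]] < 1) {
    stop("K must be >= 1", call. = FALSE)
  }
  invisible(theta)
}

# Resolve theta into the (true noise, assumed knowledge, policy) triple used
# by the generative simulator. Coupled models reuse the assumed SD as truth.
theta_components <- function(theta, model) {
  g <- function(nm, fallback = NULL) {
    if (nm %in% names(theta)) theta[[nm]]
    else if (!is.null(fallback)) theta[[fallback]]
    else NA_real_
  }
  list(
    noise = noise_model(
      sigma_phi_true = g("sigma_phi_true", "sigma_phi"),
      sigma_h_true = if (model$use_haptic) g("sigma_h_true", "sigma_h") else NA_real_,
      sigma_m = theta[["sigma_m"]]
    ),
    knowledge = observer_knowledge(
      sigma_phi = theta[["sigma_phi"]],
      sigma_h = if (model$use_haptic) theta[["sigma_h"]] else NA_real_,
      mu_d = theta[["mu_d"]], sigma_d = theta[["sigma_d"]],
      mu_s = theta[["mu_s"]], sigma_s = theta[["sigma_s"]]
    ),
    policy = decision_policy(
      rule = model$decision_rule,
      K = if (model$decision_rule == "sample_average") theta[["K"]] else NA_real_
    )
  )
}
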