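#' Build a synthetic-experiment configuration
#'
#' The configuration holds every ground-truth parameter of the synthetic
#' response model: per-feature log-odds effects on correctness, a log-duration
#' effect, a retention (forgetting) rate on log elapsed time, per-subject
#' ability offsets, condition offsets for stimulus manipulations, and the
#' test-session schedule. The response model is
#' \deqn{logit(p) = \beta x + \gamma \log(n_{frames}) - \delta \log(1 + days)
#'   + a_s + b_{foil} + m_{cond}}
#' with p clipped to \code{prob_floor_ceiling}.
#'
#' @param n_subjects number of simulated subjects.
#' @param n_shots_per_episode number of shots per episode (two episodes are
#'   generated: episode 1 supplies targets, episode 2 matched foils).
#' @param n_characters,n_sounds,n_emotions,n_objects sizes of the binary
#'   annotation inventories (defaults 29, 13, 20 and 25).
#' @param true_weights named numeric vector of per-feature log-odds effects.
#'   Names must be annotation feature names; unnamed features get weight 0.
#' @param duration_weight log-odds gain per unit log(frames).
#' @param retention_rate log-odds loss per unit log(1 + elapsed days).
#' @param subject_ability_sd SD of the per-subject log-odds ability offsets.
#' @param foil_bias log-odds offset added on foil trials.
#' @param manipulation_offsets named log-odds shifts per manipulation
#'   condition; must contain "none".
#' @param manipulation_mix named probabilities with which each manipulation is
#'   assigned to trials (default: all trials unmanipulated).
#' @param single_frame_fraction fraction of trials shown as a single frame.
#' @param session_days ordered nominal day labels of the test sessions.
#' @param session_windows two-column matrix (lo, hi) of elapsed-day windows,
#'   one row per session; defaults to the standard windows (e.g. 22-26 h for
#'   the day-1 session).
#' @param repeat_fraction fraction of queried shots re-queried later.
#' @param prob_floor_ceiling length-2 clip bounds for the correctness
#'   probability.
#' @param seed integer master seed; all substreams derive from it.
#' @return an object of class \code{generator_config}.
#' @export
generator_config <- function(n_subjects = 20,
                             n_shots_per_episode = 300,
                             n_characters = 29,
                             n_sounds = 13,
                             n_emotions = 20,
                             n_objects = 25,
                             true_weights = default_true_weights(),
                             duration_weight = 0.35,
                             retention_rate = 0.25,
                             subject_ability_sd = 0.5,
                             foil_bias = 0,
                             manipulation_offsets = c(none = 0,
                                                      no_sound = -0.5,
                                                      horizontal_flip = 0,
                                                      grayscale = 0,
                                                      occlusion = -1.5,
                                                      temporal_reversal = -0.7),
                             manipulation_mix = c(none = 1),
                             single_frame_fraction = 0,
                             session_days = c(0, 1, 7, 30, 90, 365),
                             session_windows = NULL,
                             repeat_fraction = 0.03,
                             prob_floor_ceiling = c(0.02, 0.98),
                             seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_shots_per_episode = as.integer(n_shots_per_episode),
              n_characters = as.integer(n_characters),
              n_sounds = as.integer(n_sounds),
              n_emotions = as.integer(n_emotions),
              n_objects = as.integer(n_objects),
              true_weights = true_weights,
              duration_weight = duration_weight,
              retention_rate = retention_rate,
              subject_ability_sd = subject_ability_sd,
              foil_bias = foil_bias,
              manipulation_offsets = manipulation_offsets,
              manipulation_mix = manipulation_mix,
              single_frame_fraction = single_frame_fraction,
              session_days = session_days,
              session_windows = session_windows %||%
                default_session_windows(session_days),
              repeat_fraction = repeat_fraction,
              prob_floor_ceiling = prob_floor_ceiling,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default ground-truth feature weights
#'
#' A sparse set of positive log-odds effects: action, elicited emotion, a few
#' prominent characters, sounds, emotions and objects carry signal; the rest
#' of the inventory is inert. Shots with salient content are thereby more
#' memorable, mirroring the direction of the reported content effects.
#'
#' @return named numeric vector of log-odds weights.
#' @export
default_true_weights <- function() {
  c(action = 0.6, emotion_elicited = 0.45, emotion_depicted = 0.3,
    indoor = 0.15,
    character_01 = 0.7, character_02 = 0.4, character_03 = 0.3,
    sound_01 = 0.35, sound_02 = 0.2,
    emotion_01 = 0.4, emotion_02 = 0.25,
    object_01 = 0.3, object_02 = 0.2)
}

# Elapsed-day sampling windows for the standard session schedule:
# session 1 within the first hour, session 2 at 22-26 h, then 6-8, 27-33,
# 85-95 and 335-395 days. Unknown labels fall back to +/- 10% of the label.
default_session_windows <- function(session_days) {
  std <- list(`0` = c(0, 1 / 24), `1` = c(22 / 24, 26 / 24),
              `7` = c(6, 8), `30` = c(27, 33), `90` = c(85, 95),
              `365` = c(335, 395))
  w <- t(vapply(session_days, function(d) {
    key <- as.character(d)
    if (!is.null(std[[key]])) std[[key]] else c(d * 0.9, d * 1.1)
  }, numeric(2)))
  colnames(w) <- c("lo", "hi")
  w
}

validate_config <- function(cfg) {
  stop_cfg <- function(field, msg)
    stop(sprintf("invalid generator_config: field '%s' %s", field, msg),
         call. = FALSE)
  for (f in c("n_subjects", "n_shots_per_episode", "n_characters",
              "n_sounds", "n_emotions", "n_objects"))
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 1)
      stop_cfg(f, "must be a positive count")
  if (any(!is.finite(cfg$true_weights)))
    stop_cfg("true_weights", "must be finite")
  for (f in c("duration_weight", "retention_rate", "subject_ability_sd",
              "foil_bias"))
    if (!is.finite(cfg[[f]])) stop_cfg(f, "must be finite")
  if (is.null(names(cfg$manipulation_offsets)) ||
      !"none" %in% names(cfg$manipulation_offsets))
    stop_cfg("manipulation_offsets", "must be named and include 'none'")
  if (!all(names(cfg$manipulation_mix) %in% names(cfg$manipulation_offsets)))
    stop_cfg("manipulation_mix", "names must be known manipulation conditions")
  if (abs(sum(cfg$manipulation_mix) - 1) > 1e-8)
    stop_cfg("manipulation_mix", "probabilities must sum to 1")
  if (cfg$single_frame_fraction < 0 || cfg$single_frame_fraction > 1)
    stop_cfg("single_frame_fraction", "must lie in [0, 1]")
  d <- cfg$session_days
  if (any(d < 0) || any(diff(d) <= 0))
    stop_cfg("session_days", "must be strictly increasing and nonnegative")
  if (cfg$repeat_fraction < 0 || cfg$repeat_fraction >= 1)
    stop_cfg("repeat_fraction", "must lie in [0, 1)")
  fc <- cfg$prob_floor_ceiling
  if (length(fc) != 2 || !(0 < fc[1] && fc[1] < fc[2] && fc[2] < 1))
    stop_cfg("prob_floor_ceiling", "must satisfy 0 < floor < ceiling < 1")
  invisible(cfg)
}

#' Read a generator configuration from JSON or YAML
#'
#' Any field omitted from the file takes its \code{\link{generator_config}}
#' default.
#'
#' @param path path to a .json, .yaml or .yml file.
#' @return a \code{generator_config}.
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (f in c("true_weights", "manipulation_offsets", "manipulation_mix"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  if (!is.null(raw$session_windows))
    raw$session_windows <- matrix(unlist(raw$session_windows),
                                  ncol = 2, byrow = TRUE,
                                  dimnames = list(NULL, c("lo", "hi")))
  known <- names(formals(generator_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(generator_config, raw)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("generator_config:",
      x$n_subjects, "subjects,",
      x$n_shots_per_episode, "shots/episode,",
      length(x$session_days), "sessions (days",
      paste(x$session_days, collapse = ","), "), seed", x$seed, "\n")
  invisible(x)
}

# Deterministic substream seeds so shots/annotations/schedule/responses can be
# regenerated independently from the one master seed. Kept below 2^31.
substream_seed <- function(seed, stream) {
  offset <- c(shots = 101L, annotations = 211L, schedule = 307L,
              responses = 401L, abilities = 503L, foils = 601L)[[stream]]
  as.integer((as.double(seed) * 7919 + offset) %% 2147483647)
}
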