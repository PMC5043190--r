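#' Generate shot tables for two movie episodes
#'
#' Shots tile each episode's frame axis without gaps. Durations are drawn
#' log-uniformly and truncated to 1-90 frames, matching the range of shot
#' lengths produced by cut detection in a fast-paced drama. Frames are
#' 0-based with half-open spans.
#'
#' @param cfg a \code{\link{generator_config}}.
#' @param seed optional override of the shots substream seed.
#' @return list of two data.frames (\code{episode1}, \code{episode2}) with
#'   columns shot_id, episode, start_frame, end_frame, n_frames,
#'   matched_shot_id (NA until \code{\link{match_foils}} fills it in).
#' @export
generate_shots <- function(cfg, seed = NULL) {
  validate_config(cfg)
  set.seed(seed %||% substream_seed(cfg$seed, "shots"))
  one_episode <- function(ep) {
    n <- cfg$n_shots_per_episode
    n_frames <- pmin(90L, pmax(1L, as.integer(floor(
      exp(stats::runif(n, 0, log(91)))))))
    end_frame <- cumsum(n_frames)
    data.frame(shot_id = sprintf("e%d_s%04d", ep, seq_len(n)),
               episode = ep,
               start_frame = c(0L, end_frame[-n]),
               end_frame = end_frame,
               n_frames = n_frames,
               matched_shot_id = NA_character_,
               stringsAsFactors = FALSE)
  }
  list(episode1 = one_episode(1L), episode2 = one_episode(2L))
}

annotation_feature_names <- function(cfg) {
  list(binary = c("action", "indoor", "emotion_depicted", "emotion_elicited",
                  sprintf("character_%02d", seq_len(cfg$n_characters)),
                  sprintf("viewpoint_%02d", seq_len(cfg$n_characters)),
                  sprintf("sound_%02d", seq_len(cfg$n_sounds)),
                  sprintf("emotion_%02d", seq_len(cfg$n_emotions)),
                  sprintf("object_%02d", seq_len(cfg$n_objects))),
       count = c("n_characters_in_shot", "n_objects_in_shot"),
       continuous = c("n_frames", "contrast", "color_content", "sound_level"))
}

#' Generate content annotations for a shot table
#'
#' One feature vector per shot: binary presences for action, indoor setting,
#' depicted/elicited emotion, each character, each character's frontal
#' viewpoint, each sound, emotion and object; counts of characters and
#' objects in the shot; and continuous low-level descriptors (contrast, color
#' content, sound level) plus the shot duration. Per-feature occurrence
#' probabilities are themselves drawn (Beta(1.2, 3)) so that some content is
#' common and some rare, as in real annotation inventories. A character's
#' viewpoint bit can only be set when the character is present.
#'
#' @param shots data.frame of shots (one or both episodes, row-bound).
#' @param cfg a \code{\link{generator_config}}.
#' @param seed optional override of the annotations substream seed.
#' @return data.frame with shot_id plus one column per feature.
#' @export
generate_annotations <- function(shots, cfg, seed = NULL) {
  validate_config(cfg)
  if (nrow(shots) == 0) stop("shots must be nonempty", call. = FALSE)
  set.seed(seed %||% substream_seed(cfg$seed, "annotations"))
  nm <- annotation_feature_names(cfg)
  n <- nrow(shots)
  base_bits <- setdiff(nm$binary, sprintf("viewpoint_%02d",
                                          seq_len(cfg$n_characters)))
  occ <- stats::rbeta(length(base_bits), 1.2, 3)
  names(occ) <- base_bits
  bits <- vapply(base_bits,
                 function(f) stats::rbinom(n, 1L, occ[[f]]),
                 integer(n))
  bits <- matrix(bits, nrow = n, dimnames = list(NULL, base_bits))
  vp <- vapply(seq_len(cfg$n_characters), function(k) {
    as.integer(bits[, sprintf("character_%02d", k)] *
                 stats::rbinom(n, 1L, 0.5))
  }, integer(n))
  vp <- matrix(vp, nrow = n,
               dimnames = list(NULL, sprintf("viewpoint_%02d",
                                             seq_len(cfg$n_characters))))
  char_cols <- sprintf("character_%02d", seq_len(cfg$n_characters))
  obj_cols <- sprintf("object_%02d", seq_len(cfg$n_objects))
  out <- data.frame(shot_id = shots$shot_id, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(bits), as.data.frame(vp))
  out <- out[, c("shot_id", nm$binary)]
  out$n_characters_in_shot <- as.integer(rowSums(bits[, char_cols,
                                                      drop = FALSE]))
  out$n_objects_in_shot <- as.integer(rowSums(bits[, obj_cols, drop = FALSE]))
  out$n_frames <- shots$n_frames
  out$contrast <- stats::runif(n, 0.2, 0.9)
  out$color_content <- stats::runif(n, 0, 1)
  out$sound_level <- stats::rnorm(n, 60, 8)
  rownames(out) <- NULL
  out
}

#' Match target shots to foil shots
#'
#' Greedy one-to-one matching that repeatedly pairs the remaining target/foil
#' combination with the smallest Hamming distance over character-presence and
#' viewpoint bits; ties are broken by smallest absolute duration difference,
#' then by shot id. Mirrors the design goal of foils "as close as possible"
#' in character content with matched average duration.
#'
#' @param targets,foils data.frames of shots with their annotation columns
#'   merged in (must contain n_frames and the character_/viewpoint_ columns).
#' @return list with \code{pairs} (data.frame target_id, foil_id, hamming,
#'   duration_diff), \code{n_unmatched} targets left over, and
#'   \code{mean_duration_diff} between the matched sets.
#' @export
match_foils <- function(targets, foils) {
  if (nrow(targets) == 0 || nrow(foils) == 0)
    stop("targets and foils must be nonempty", call. = FALSE)
  bit_cols <- grep("^(character|viewpoint)_", names(targets), value = TRUE)
  if (length(bit_cols) == 0)
    stop("no character/viewpoint columns found; merge annotations first",
         call. = FALSE)
  tb <- as.matrix(targets[, bit_cols])
  fb <- as.matrix(foils[, bit_cols])
  # pairwise Hamming distance via cross-products of 0/1 matrices
  ham <- tb %*% (1 - t(fb)) + (1 - tb) %*% t(fb)
  ddiff <- abs(outer(targets$n_frames, foils$n_frames, "-"))
  n_pairs <- min(nrow(targets), nrow(foils))
  ord <- order(as.vector(ham), as.vector(ddiff),
               rep(targets$shot_id, ncol(ham)),
               rep(foils$shot_id, each = nrow(ham)))
  t_used <- logical(nrow(targets))
  f_used <- logical(nrow(foils))
  ti <- fi <- integer(n_pairs)
  k <- 0L
  for (idx in ord) {
    i <- (idx - 1L) %% nrow(ham) + 1L
    j <- (idx - 1L) %/% nrow(ham) + 1L
    if (t_used[i] || f_used[j]) next
    k <- k + 1L
    ti[k] <- i; fi[k] <- j
    t_used[i] <- TRUE; f_used[j] <- TRUE
    if (k == n_pairs) break
  }
  pairs <- data.frame(target_id = targets$shot_id[ti],
                      foil_id = foils$shot_id[fi],
                      hamming = ham[cbind(ti, fi)],
                      duration_diff = ddiff[cbind(ti, fi)],
                      stringsAsFactors = FALSE)
  n_unmatched <- nrow(targets) - n_pairs
  if (n_unmatched > 0)
    warning(n_unmatched, " target shot(s) left unmatched (too few foils)",
            call. = FALSE)
  list(pairs = pairs,
       n_unmatched = n_unmatched,
       mean_duration_diff = mean(targets$n_frames[ti]) -
         mean(foils$n_frames[fi]))
}

#' Build a trial schedule (no responses yet)
#'
#' Each subject is scheduled over the configured sessions. Matched pairs are
#' partitioned across sessions; within a session every pair contributes one
#' target and one foil query in pseudo-random order, so target and foil
#' trials are exactly balanced. A fraction \code{repeat_fraction} of the
#' queried shots (split evenly between targets and foils) is re-queried later
#' in the experiment and flagged \code{is_repeat}; a repeat keeps its
#' original presentation mode and manipulation so consistency comparisons are
#' like-for-like. Elapsed days are drawn uniformly within each session's
#' window, one draw per subject and session.
#'
#' @param pairs data.frame with target_id and foil_id columns
#'   (from \code{\link{match_foils}}).
#' @param cfg a \code{\link{generator_config}}.
#' @param seed optional override of the schedule substream seed.
#' @return data.frame of trial skeletons: subject_id, session_label,
#'   elapsed_days, trial_index, shot_id, stimulus_class, presentation_mode,
#'   manipulation, is_repeat.
#' @export
build_trial_schedule <- function(pairs, cfg, seed = NULL) {
  validate_config(cfg)
  if (nrow(pairs) == 0) stop("matched pairs must be nonempty", call. = FALSE)
  set.seed(seed %||% substream_seed(cfg$seed, "schedule"))
  n_sessions <- length(cfg$session_days)
  subj_ids <- sprintf("sub%03d", seq_len(cfg$n_subjects))
  per_subject <- lapply(subj_ids, function(sid) {
    sess_of_pair <- sample(rep(seq_len(n_sessions),
                               length.out = nrow(pairs)))
    sess_days <- stats::runif(n_sessions,
                              cfg$session_windows[, "lo"],
                              cfg$session_windows[, "hi"])
    base <- do.call(rbind, lapply(seq_len(n_sessions), function(s) {
      p <- pairs[sess_of_pair == s, , drop = FALSE]
      if (nrow(p) == 0) return(NULL)
      data.frame(subject_id = sid,
                 session = s,
                 shot_id = c(p$target_id, p$foil_id),
                 stimulus_class = rep(c("target", "foil"), each = nrow(p)),
                 is_repeat = FALSE,
                 stringsAsFactors = FALSE)
    }))
    base$presentation_mode <- ifelse(
      stats::runif(nrow(base)) < cfg$single_frame_fraction,
      "single_frame", "full_shot")
    base$manipulation <- sample(names(cfg$manipulation_mix), nrow(base),
                                replace = TRUE, prob = cfg$manipulation_mix)
    n_rep <- 2L * floor(cfg$repeat_fraction * nrow(base) / 2)
    if (n_rep > 0) {
      # draw repeats from sessions that have a strictly later session (or,
      # with a single session, from anywhere; repeats then follow in-session)
      eligible <- if (n_sessions > 1) which(base$session < n_sessions)
                  else seq_len(nrow(base))
      elig_t <- eligible[base$stimulus_class[eligible] == "target"]
      elig_f <- eligible[base$stimulus_class[eligible] == "foil"]
      half <- n_rep %/% 2L
      if (length(elig_t) < half || length(elig_f) < half)
        stop("repeat_fraction too high for the available trial slots",
             call. = FALSE)
      rep_t <- elig_t[sample.int(length(elig_t), half)]
      rep_f <- elig_f[sample.int(length(elig_f), half)]
      reps <- base[c(rbind(rep_t, rep_f)), , drop = FALSE]
      reps$is_repeat <- TRUE
      # one target and one foil repeat go to the same later session so the
      # per-session target/foil balance is preserved
      dest <- vapply(seq_len(half), function(i) {
        lo <- max(base$session[rep_t[i]], base$session[rep_f[i]]) + 1L
        if (lo > n_sessions) return(n_sessions)  # single-session design
        later <- seq.int(lo, n_sessions)
        later[sample.int(length(later), 1L)]
      }, integer(1))
      reps$session <- rep(dest, each = 2)
      base <- rbind(base, reps)
    }
    # pseudo-random order within session; repeats in a shot's own session
    # are forced after the first presentation
    base <- base[order(base$session, sample.int(nrow(base))), , drop = FALSE]
    dup <- base$is_repeat & duplicated(paste(base$shot_id,
                                             base$stimulus_class),
                                       fromLast = TRUE)
    base <- rbind(base[!dup | !base$is_repeat, , drop = FALSE],
                  base[dup & base$is_repeat, , drop = FALSE])
    base <- base[order(base$session), , drop = FALSE]
    base$trial_index <- stats::ave(seq_len(nrow(base)), base$session,
                                   FUN = seq_along)
    base$session_label <- cfg$session_days[base$session]
    base$elapsed_days <- sess_days[base$session]
    base
  })
  out <- do.call(rbind, per_subject)
  rownames(out) <- NULL
  out[, c("subject_id", "session_label", "elapsed_days", "trial_index",
          "shot_id", "stimulus_class", "presentation_mode", "manipulation",
          "is_repeat")]
}

#' Probability of a correct response under the generative model
#'
#' \code{logit(p) = beta.x + gamma*log(n_frames) - delta*log(1+days) +
#' ability + foil_bias*[foil] + manipulation_offset}, clipped to the
#' configured floor/ceiling. Single-frame trials use n_frames = 1 with the
#' parent shot's content vector.
#'
#' @param vectors annotation rows aligned with \code{trials} (same length).
#' @param trials trial-skeleton rows.
#' @param subject_ability per-trial log-odds ability offsets.
#' @param cfg a \code{\link{generator_config}}.
#' @return numeric vector of correctness probabilities.
#' @export
response_probability <- function(vectors, trials, subject_ability, cfg) {
  validate_config(cfg)
  w <- cfg$true_weights
  unknown <- setdiff(names(w), names(vectors))
  if (length(unknown))
    stop("true_weights name unknown features: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  bad_manip <- setdiff(unique(trials$manipulation),
                       names(cfg$manipulation_offsets))
  if (length(bad_manip))
    stop("unknown manipulation condition(s): ",
         paste(bad_manip, collapse = ", "), call. = FALSE)
  bx <- if (length(w))
    as.matrix(vectors[, names(w), drop = FALSE]) %*% w
  else rep(0, nrow(trials))
  n_frames <- ifelse(trials$presentation_mode == "single_frame",
                     1, vectors$n_frames)
  lg <- as.vector(bx) +
    cfg$duration_weight * log(n_frames) -
    cfg$retention_rate * log1p(trials$elapsed_days) +
    subject_ability +
    cfg$foil_bias * (trials$stimulus_class == "foil") +
    cfg$manipulation_offsets[trials$manipulation]
  p <- stats::plogis(lg)
  pmin(cfg$prob_floor_ceiling[2], pmax(cfg$prob_floor_ceiling[1], p))
}

#' Simulate responses for a trial schedule
#'
#' Correctness is drawn independently per trial with its model probability;
#' the old/new response is then derived from correctness and stimulus class.
#'
#' @param schedule trial skeletons from \code{\link{build_trial_schedule}}.
#' @param vectors annotation table covering every scheduled shot.
#' @param cfg a \code{\link{generator_config}}.
#' @param abilities named per-subject log-odds offsets; drawn
#'   N(0, subject_ability_sd) when NULL.
#' @param seed optional override of the responses substream seed.
#' @return list with \code{trials} (completed trial table) and
#'   \code{abilities} (the ground-truth per-subject offsets).
#' @export
simulate_responses <- function(schedule, vectors, cfg, abilities = NULL,
                               seed = NULL) {
  validate_config(cfg)
  missing_shot <- setdiff(schedule$shot_id, vectors$shot_id)
  if (length(missing_shot))
    stop("no content vector for shot(s): ",
         paste(utils::head(missing_shot, 5), collapse = ", "), call. = FALSE)
  if (is.null(abilities)) {
    set.seed(substream_seed(cfg$seed, "abilities"))
    subj <- unique(schedule$subject_id)
    abilities <- stats::setNames(
      stats::rnorm(length(subj), 0, cfg$subject_ability_sd), subj)
  }
  set.seed(seed %||% substream_seed(cfg$seed, "responses"))
  v <- vectors[match(schedule$shot_id, vectors$shot_id), , drop = FALSE]
  p <- response_probability(v, schedule, abilities[schedule$subject_id], cfg)
  correct <- stats::runif(nrow(schedule)) < p
  trials <- schedule
  trials$p_correct <- p
  trials$correct <- as.integer(correct)
  trials$response <- ifelse(correct == (trials$stimulus_class == "target"),
                            "old", "new")
  list(trials = trials, abilities = abilities)
}

#' Generate a complete synthetic dataset
#'
#' Runs the whole generator: shots for two episodes, content annotations,
#' foil matching (episode 1 targets vs episode 2 foils), trial scheduling
#' and response simulation. All randomness derives from \code{cfg$seed}
#' through named substreams, so the same config reproduces the same dataset
#' byte for byte.
#'
#' @param cfg a \code{\link{generator_config}}.
#' @return an object of class \code{memovie_dataset}: list with shots,
#'   annotations, trials, pairs and truth (config + resolved abilities).
#' @export
simulate_dataset <- function(cfg = generator_config()) {
  validate_config(cfg)
  eps <- generate_shots(cfg)
  shots <- rbind(eps$episode1, eps$episode2)
  ann <- generate_annotations(shots, cfg)
  merged <- merge(shots, ann[, setdiff(names(ann), "n_frames")],
                  by = "shot_id", sort = FALSE)
  m <- match_foils(merged[merged$episode == 1, , drop = FALSE],
                   merged[merged$episode == 2, , drop = FALSE])
  shots$matched_shot_id[match(m$pairs$target_id, shots$shot_id)] <-
    m$pairs$foil_id
  shots$matched_shot_id[match(m$pairs$foil_id, shots$shot_id)] <-
    m$pairs$target_id
  schedule <- build_trial_schedule(m$pairs, cfg)
  sim <- simulate_responses(schedule, ann, cfg)
  structure(list(shots = shots,
                 annotations = ann,
                 trials = sim$trials,
                 pairs = m$pairs,
                 truth = list(config = unclass(cfg),
                              abilities = as.list(sim$abilities))),
            class = "memovie_dataset")
}

#' @export
print.memovie_dataset <- function(x, ...) {
  cat("memovie_dataset:", nrow(x$shots), "shots,",
      length(unique(x$trials$subject_id)), "subjects,",
      nrow(x$trials), "trials\n")
  invisible(x)
}
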