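# small builders shared across test files

# a compact generator config: 20 binary features (action, indoor,
# emotion_depicted, emotion_elicited, 4 characters + 4 viewpoints,
# 2 sounds, 3 emotions, 3 objects)
small_config <- function(seed = 11L, ...) {
  generator_config(n_subjects = 10, n_shots_per_episode = 100,
                   n_characters = 4, n_sounds = 2, n_emotions = 3,
                   n_objects = 3, seed = seed, ...)
}

binary_feature_names <- function(ann) {
  setdiff(names(ann),
          c("shot_id", "n_characters_in_shot", "n_objects_in_shot",
            "n_frames", "contrast", "color_content", "sound_level"))
}

# hand-built trial table: one subject, alternating target/foil,
# correctness supplied or drawn at a fixed rate
flat_trials <- function(n, correct = NULL, p = 0.8, subject = "s1",
                        session = 0, start_index = 1L) {
  cls <- rep(c("target", "foil"), length.out = n)
  if (is.null(correct)) correct <- stats::rbinom(n, 1, p)
  data.frame(subject_id = subject,
             session_label = session,
             elapsed_days = session,
             trial_index = seq.int(start_index, length.out = n),
             shot_id = sprintf("%s_sh%05d", substr(cls, 1, 1), seq_len(n)),
             stimulus_class = cls,
             presentation_mode = "full_shot",
             manipulation = "none",
             is_repeat = FALSE,
             correct = correct,
             response = ifelse(correct == (cls == "target"), "old", "new"),
             stringsAsFactors = FALSE)
}

# trial table where every subject answers every shot once; correctness
# drawn per (subject, shot) from the supplied probability matrix
grid_trials <- function(p_correct, shot_ids = NULL, subject_ids = NULL) {
  ns <- nrow(p_correct); nsh <- ncol(p_correct)
  if (is.null(shot_ids)) shot_ids <- sprintf("sh%05d", seq_len(nsh))
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%03d", seq_len(ns))
  correct <- as.integer(stats::runif(ns * nsh) < as.vector(t(p_correct)))
  data.frame(subject_id = rep(subject_ids, each = nsh),
             session_label = 0,
             elapsed_days = 0,
             trial_index = rep(seq_len(nsh), ns),
             shot_id = rep(shot_ids, ns),
             stimulus_class = "target",
             presentation_mode = "full_shot",
             manipulation = "none",
             is_repeat = FALSE,
             correct = correct,
             response = ifelse(correct == 1, "old", "new"),
             stringsAsFactors = FALSE)
}

# annotation table of pure binary features, no generator involved
random_binary_annotations <- function(n_shots, n_features, prob = 0.5,
                                      prefix = "f") {
  x <- matrix(stats::rbinom(n_shots * n_features, 1, prob), n_shots,
              dimnames = list(NULL, sprintf("%s%02d", prefix,
                                            seq_len(n_features))))
  cbind(data.frame(shot_id = sprintf("sh%05d", seq_len(n_shots)),
                   stringsAsFactors = FALSE),
        as.data.frame(x))
}
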