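#' Write a dataset to a directory of CSV tables
#'
#' Writes shots.csv, annotations.csv and trials.csv (UTF-8, header row, "."
#' decimal, booleans as 0/1, missing values as empty fields) plus truth.json
#' echoing the generator configuration and the resolved per-subject
#' abilities.
#'
#' @param dataset a \code{memovie_dataset} from \code{\link{simulate_dataset}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    lg <- vapply(df, is.logical, logical(1))
    df[lg] <- lapply(df[lg], as.integer)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, na = "")
  }
  wr(dataset$shots, "shots.csv")
  wr(dataset$annotations, "annotations.csv")
  wr(dataset$trials, "trials.csv")
  truth <- dataset$truth
  truth$config$session_windows <- apply(truth$config$session_windows, 1,
                                        as.list)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a dataset from CSV tables, validating referential integrity
#'
#' Reads shots.csv, annotations.csv and trials.csv from a directory (the
#' layout \code{\link{write_dataset}} produces, or any conforming dataset)
#' and validates that every trial's shot resolves, every shot has exactly
#' one annotation row, and (subject, session, trial_index) is unique.
#'
#' @param dir directory containing the three CSV files.
#' @return a \code{memovie_dataset} (truth present only when truth.json
#'   exists).
#' @export
load_dataset <- function(dir) {
  need <- function(path) {
    if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  shots <- need(file.path(dir, "shots.csv"))
  ann <- need(file.path(dir, "annotations.csv"))
  trials <- need(file.path(dir, "trials.csv"))
  req_cols <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop("table ", name, " is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  req_cols(shots, c("shot_id", "episode", "start_frame", "end_frame",
                    "n_frames"), "shots")
  req_cols(ann, "shot_id", "annotations")
  req_cols(trials, c("subject_id", "session_label", "elapsed_days",
                     "trial_index", "shot_id", "stimulus_class",
                     "presentation_mode", "manipulation", "response",
                     "correct", "is_repeat"), "trials")
  dangling <- setdiff(trials$shot_id, shots$shot_id)
  if (length(dangling))
    stop("trials reference unknown shot(s): ",
         paste(utils::head(dangling, 5), collapse = ", "), call. = FALSE)
  if (any(!shots$shot_id %in% ann$shot_id) || anyDuplicated(ann$shot_id))
    stop("every shot must have exactly one annotation row", call. = FALSE)
  key <- paste(trials$subject_id, trials$session_label, trials$trial_index)
  if (anyDuplicated(key))
    stop("duplicate (subject, session, trial_index): ",
         key[which(duplicated(key))[1]], call. = FALSE)
  trials$is_repeat <- as.logical(trials$is_repeat)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  structure(list(shots = shots, annotations = ann, trials = trials,
                 truth = truth),
            class = "memovie_dataset")
}

#' Run the full analysis pipeline on a dataset
#'
#' Executes, in order: trial/subject exclusions, performance summaries,
#' duration and retention curves, consistency analyses, content-property
#' effects, group-level regression, single-trial classification with shuffle
#' null, and the behavior-based upper-bound predictors. All outputs are
#' written as CSV/JSON under \code{out_dir}; the run is deterministic given
#' \code{seed}.
#'
#' @param dataset a \code{memovie_dataset} (or a directory to load one from).
#' @param out_dir report directory.
#' @param seed RNG seed for permutation/classification stages.
#' @param n_perm permutations for the permutation tests.
#' @param n_null_iter iterations for the classifier shuffle null (0 skips).
#' @param run_classifier set FALSE to skip the classification stage.
#' @param properties binary content properties to analyze (default: a small
#'   standard panel plus all character presences).
#' @return named list of the stage results, invisibly; files in
#'   \code{out_dir}.
#' @export
run_pipeline <- function(dataset, out_dir, seed = 1L, n_perm = 1000L,
                         n_null_iter = 0L, run_classifier = TRUE,
                         properties = NULL) {
  if (is.character(dataset)) dataset <- load_dataset(dataset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  set.seed(seed)
  excl <- stage("exclusions", apply_exclusions(dataset$trials))
  jsonlite::write_json(excl$exclusions, file.path(out_dir, "exclusions.json"),
                       auto_unbox = TRUE, digits = NA)
  tr <- excl$trials
  perf <- stage("metrics", compute_performance(tr))
  utils::write.csv(perf$by_subject, file.path(out_dir, "performance.csv"),
                   row.names = FALSE)
  dc <- stage("duration_curve", duration_curve(tr, dataset$shots))
  rc <- stage("retention_curve", retention_curve(tr))
  curves <- rbind(
    data.frame(curve = "duration", bin = dc$bin_labels, pc = dc$pc_per_bin,
               n = dc$n_per_bin, r = dc$r),
    data.frame(curve = "retention", bin = rc$bin_labels, pc = rc$pc_per_bin,
               n = rc$n_per_bin, r = rc$r))
  utils::write.csv(curves, file.path(out_dir, "curves.csv"),
                   row.names = FALSE)
  subjects <- unique(tr$subject_id)
  cons <- stage("consistency", {
    rows <- lapply(subjects, function(s) {
      r <- self_consistency(tr, s, n_mc = 2000L)
      m <- mode_consistency(tr, s, n_mc = 2000L)
      rbind(consistency_row(r, s), consistency_row(m, s))
    })
    do.call(rbind, rows)
  })
  utils::write.csv(cons, file.path(out_dir, "consistency.csv"),
                   row.names = FALSE)
  if (is.null(properties)) {
    properties <- intersect(
      c("action", "indoor", "emotion_depicted", "emotion_elicited",
        grep("^(character|sound|emotion|object)_",
             names(dataset$annotations), value = TRUE)),
      names(dataset$annotations))
  }
  eff <- stage("content_stats",
               effect_table(tr, dataset$annotations, properties,
                            n_perm = n_perm))
  utils::write.csv(eff, file.path(out_dir, "content_effects.csv"),
                   row.names = FALSE)
  labels <- make_labels(tr, level = "mode")
  group_pc <- with(make_labels(tr, level = "mode"),
                   stats::setNames(n_votes_correct / n_votes, shot_id))
  reg <- stage("regression",
               fit_group_regression(dataset$annotations, group_pc,
                                    seed = seed))
  jsonlite::write_json(reg[c("coefficients", "intercept", "cv_folds",
                             "r_squared_cv", "ridge")],
                       file.path(out_dir, "regression.json"),
                       auto_unbox = TRUE, digits = NA)
  cls <- NULL
  if (run_classifier) {
    cls <- stage("classification",
                 classify(dataset$annotations, labels, seed = seed))
    cls_report <- data.frame(feature_set = "ALL",
                             accuracy_mean = cls$accuracy_mean,
                             accuracy_sd = cls$accuracy_sd,
                             n_subsample_reps = cls$n_subsample_reps,
                             cv_folds = cls$cv_folds)
    if (n_null_iter > 0) {
      nl <- stage("shuffle_null",
                  shuffle_null(dataset$annotations, labels,
                               n_iter = n_null_iter,
                               observed_accuracy = cls$accuracy_mean))
      cls_report$null_mean <- nl$null_mean
      cls_report$null_sd <- nl$null_sd
      cls_report$p_vs_null <- nl$p_vs_null
    }
    utils::write.csv(cls_report,
                     file.path(out_dir, "classifier_reports.csv"),
                     row.names = FALSE)
  }
  ub <- stage("upper_bounds", do.call(rbind, c(
    lapply(subjects, function(s) majority_predictor(tr, s)),
    lapply(subjects, function(s) self_predictor(tr, s)))))
  utils::write.csv(ub, file.path(out_dir, "upper_bounds.csv"),
                   row.names = FALSE)
  summary <- list(seed = seed,
                  n_trials = nrow(tr),
                  n_subjects = length(subjects),
                  overall_pc = perf$pooled$mean[perf$pooled$metric == "pc"],
                  classifier_accuracy = if (!is.null(cls))
                    cls$accuracy_mean else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(exclusions = excl$exclusions, performance = perf,
                 duration = dc, retention = rc, consistency = cons,
                 content_effects = eff, regression = reg, classifier = cls,
                 upper_bounds = ub))
}

consistency_row <- function(r, subject, partner = NA_character_) {
  if (r$suppressed)
    data.frame(unit = r$unit, subject_id = subject, partner_id = partner,
               both_correct = NA_real_, both_wrong = NA_real_,
               inconsistent = NA_real_, exp_both_correct = NA_real_,
               exp_both_wrong = NA_real_, exp_inconsistent = NA_real_,
               n = r$n_comparisons, p_value = NA_real_,
               stringsAsFactors = FALSE)
  else
    data.frame(unit = r$unit, subject_id = subject, partner_id = partner,
               both_correct = r$observed[["both_correct"]],
               both_wrong = r$observed[["both_wrong"]],
               inconsistent = r$observed[["inconsistent"]],
               exp_both_correct = r$expected_null[["both_correct"]],
               exp_both_wrong = r$expected_null[["both_wrong"]],
               exp_inconsistent = r$expected_null[["inconsistent"]],
               n = r$n_comparisons, p_value = r$p_value,
               stringsAsFactors = FALSE)
}
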