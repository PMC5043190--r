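#' Build correct/incorrect shot labels
#'
#' Subject level: one label per (subject, shot), the majority of that
#' subject's presentations (ties excluded). Mode level: one label per shot,
#' the majority vote over the subject-level labels (ties excluded). Trials
#' are first restricted to a single presentation condition so labels are
#' never mixed across full-shot and single-frame testing.
#'
#' @param trials a trial table.
#' @param level "subject" or "mode".
#' @param condition presentation mode defining the label set.
#' @return data.frame: shot_id, level, subject_id (NA for mode), label
#'   (1 correct / 0 incorrect), n_votes_correct, n_votes.
#' @export
make_labels <- function(trials, level = c("mode", "subject"),
                        condition = "full_shot") {
  level <- match.arg(level)
  tr <- trials[trials$presentation_mode == condition, , drop = FALSE]
  if (nrow(tr) == 0) {
    warning("no trials in condition ", condition, call. = FALSE)
    return(data.frame(shot_id = character(), level = character(),
                      subject_id = character(), label = integer(),
                      n_votes_correct = integer(), n_votes = integer(),
                      stringsAsFactors = FALSE))
  }
  majority <- function(v) {
    s <- sum(v); n <- length(v)
    if (2 * s == n) NA_integer_ else as.integer(2 * s > n)
  }
  key <- paste(tr$subject_id, tr$shot_id, sep = "\r")
  agg <- data.frame(key = unique(key), stringsAsFactors = FALSE)
  votes <- tapply(tr$correct, key, sum)
  ns <- tapply(tr$correct, key, length)
  lab <- tapply(tr$correct, key, majority)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  subj_lab <- data.frame(
    shot_id = vapply(parts, `[`, "", 2),
    level = "subject",
    subject_id = vapply(parts, `[`, "", 1),
    label = as.integer(lab[agg$key]),
    n_votes_correct = as.integer(votes[agg$key]),
    n_votes = as.integer(ns[agg$key]),
    stringsAsFactors = FALSE)
  subj_lab <- subj_lab[!is.na(subj_lab$label), , drop = FALSE]
  rownames(subj_lab) <- NULL
  if (level == "subject") return(subj_lab)
  votes <- tapply(subj_lab$label, subj_lab$shot_id, sum)
  ns <- tapply(subj_lab$label, subj_lab$shot_id, length)
  lab <- tapply(subj_lab$label, subj_lab$shot_id, majority)
  out <- data.frame(shot_id = names(lab),
                    level = "mode",
                    subject_id = NA_character_,
                    label = as.integer(lab),
                    n_votes_correct = as.integer(votes),
                    n_votes = as.integer(ns),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

feature_matrix <- function(vectors, shot_ids, feature_set = NULL) {
  cols <- setdiff(names(vectors), "shot_id")
  if (!is.null(feature_set)) {
    unknown <- setdiff(feature_set, cols)
    if (length(unknown))
      stop("unknown feature(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cols <- feature_set
  }
  rows <- match(shot_ids, vectors$shot_id)
  if (anyNA(rows))
    stop("labels reference shots missing from the annotation table",
         call. = FALSE)
  x <- as.matrix(vectors[rows, cols, drop = FALSE])
  storage.mode(x) <- "double"
  x
}

#' Cross-validated multivariate linear regression of group memorability
#'
#' Regresses the per-shot proportion of subjects answering correctly on the
#' content features, with k-fold cross-validation; the reported r-squared is
#' the squared correlation between held-out predictions and the actual
#' group accuracies. When there are fewer than 5 shots per feature a small
#' ridge penalty stabilizes the fit (flagged in the result).
#'
#' @param vectors annotation table.
#' @param group_pc named numeric vector (names are shot ids) of per-shot
#'   group accuracy.
#' @param cv_folds number of folds.
#' @param feature_set optional feature subset.
#' @param seed seed for the fold assignment.
#' @return list: coefficients (named, full-data fit), intercept, cv_folds,
#'   r_squared_cv, predictions (held-out, named by shot), ridge flag,
#'   constant_outcome flag.
#' @export
fit_group_regression <- function(vectors, group_pc, cv_folds = 10L,
                                 feature_set = NULL, seed = 1L) {
  x <- feature_matrix(vectors, names(group_pc), feature_set)
  y <- as.numeric(group_pc)
  n <- nrow(x); p <- ncol(x)
  ridge <- n < 5 * p
  lambda <- if (ridge) 1e-3 * n else 0
  fit_fold <- function(xtr, ytr) {
    xd <- cbind(1, xtr)
    if (lambda > 0) {
      b <- solve(crossprod(xd) + diag(c(0, rep(lambda, p))),
                 crossprod(xd, ytr))
    } else {
      # QR with pivoting: aliased (constant/collinear) columns get weight 0
      b <- qr.coef(qr(xd), ytr)
      b[is.na(b)] <- 0
    }
    b
  }
  set.seed(seed)
  fold <- sample(rep(seq_len(cv_folds), length.out = n))
  pred <- numeric(n)
  for (k in seq_len(cv_folds)) {
    te <- fold == k
    b <- fit_fold(x[!te, , drop = FALSE], y[!te])
    pred[te] <- cbind(1, x[te, , drop = FALSE]) %*% b
  }
  constant <- stats::sd(y) == 0 || stats::sd(pred) == 0
  r2 <- if (constant) 0 else stats::cor(pred, y)^2
  b_full <- fit_fold(x, y)
  list(coefficients = stats::setNames(as.numeric(b_full[-1]), colnames(x)),
       intercept = b_full[1],
       cv_folds = cv_folds,
       r_squared_cv = r2,
       predictions = stats::setNames(pred, names(group_pc)),
       ridge = ridge,
       constant_outcome = constant)
}

#' Balance label classes by subsampling the majority class
#'
#' Keeps every member of the minority class and a uniform random sample of
#' the majority class of equal size, so that chance classification accuracy
#' is 50%.
#'
#' @param labels data.frame with a 0/1 \code{label} column.
#' @return the balanced subset of rows.
#' @export
balanced_subsample <- function(labels) {
  n1 <- sum(labels$label == 1); n0 <- sum(labels$label == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present for balanced subsampling",
         call. = FALSE)
  minority <- if (n1 <= n0) 1L else 0L
  n_min <- min(n1, n0)
  maj_idx <- which(labels$label != minority)
  keep <- c(which(labels$label == minority),
            maj_idx[sample.int(length(maj_idx), n_min)])
  labels[sort(keep), , drop = FALSE]
}

svm_weights <- function(model, feat_names) {
  w <- as.numeric(t(model$coefs) %*% model$SV)
  stats::setNames(w, feat_names)
}

# stratified fold ids: classes spread evenly across folds
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Linear-kernel SVM prediction of single-shot memorability
#'
#' The full pipeline: repeated balanced subsampling, stratified k-fold
#' cross-validation with folds assigned by shot, per-fold feature
#' standardization estimated on the training shots only, a linear-kernel
#' support-vector machine (fixed cost 1), and held-out scoring. Accuracy is
#' summarized over repetitions (mean) and over repetition-by-fold accuracies
#' (SD). Weights come from one final fit on a balanced sample of all shots.
#'
#' @param vectors annotation table.
#' @param labels label data.frame from \code{\link{make_labels}} (or any
#'   data.frame with shot_id and 0/1 label).
#' @param feature_set features to use (default: all annotation columns).
#' @param cv_folds folds per repetition.
#' @param n_subsample_reps balanced-subsample repetitions.
#' @param cost SVM regularization constant.
#' @param min_labeled minimum balanced sample size.
#' @param seed RNG seed for subsampling and fold assignment.
#' @return list of class \code{classifier_report}: feature_set,
#'   accuracy_mean, accuracy_sd, fold_accuracies, n_subsample_reps,
#'   cv_folds, weights.
#' @export
classify <- function(vectors, labels, feature_set = NULL, cv_folds = 10L,
                     n_subsample_reps = 25L, cost = 1, min_labeled = 40L,
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x_all <- feature_matrix(vectors, labels$shot_id, feature_set)
  if (2 * min(sum(labels$label == 1), sum(labels$label == 0)) < min_labeled)
    stop("fewer than ", min_labeled, " labeled shots after balancing",
         call. = FALSE)
  rep_acc <- numeric(n_subsample_reps)
  fold_acc <- numeric(0)
  for (r in seq_len(n_subsample_reps)) {
    bal <- balanced_subsample(labels)
    rows <- match(bal$shot_id, labels$shot_id)
    x <- x_all[rows, , drop = FALSE]
    y <- bal$label
    fold <- stratified_folds(y, cv_folds)
    hits <- 0L
    for (k in seq_len(cv_folds)) {
      te <- fold == k
      ctr <- colMeans(x[!te, , drop = FALSE])
      sdr <- apply(x[!te, , drop = FALSE], 2, stats::sd)
      sdr[sdr == 0] <- 1
      xtr <- scale(x[!te, , drop = FALSE], ctr, sdr)
      xte <- scale(x[te, , drop = FALSE], ctr, sdr)
      fit <- e1071::svm(xtr, factor(y[!te], levels = c(0, 1)),
                        kernel = "linear", cost = cost, scale = FALSE)
      pred <- stats::predict(fit, xte)
      hits <- hits + sum(pred == y[te])
      fold_acc <- c(fold_acc, mean(pred == y[te]))
    }
    rep_acc[r] <- hits / length(y)
  }
  bal <- balanced_subsample(labels)
  xb <- x_all[match(bal$shot_id, labels$shot_id), , drop = FALSE]
  ctr <- colMeans(xb); sdr <- apply(xb, 2, stats::sd); sdr[sdr == 0] <- 1
  final <- e1071::svm(scale(xb, ctr, sdr),
                      factor(bal$label, levels = c(0, 1)),
                      kernel = "linear", cost = cost, scale = FALSE)
  structure(list(feature_set = colnames(x_all),
                 accuracy_mean = mean(rep_acc),
                 accuracy_sd = stats::sd(fold_acc),
                 fold_accuracies = fold_acc,
                 n_subsample_reps = n_subsample_reps,
                 cv_folds = cv_folds,
                 weights = svm_weights(final, colnames(x_all))),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("classifier_report:", length(x$feature_set), "feature(s), accuracy",
      sprintf("%.1f%% +/- %.1f%%", 100 * x$accuracy_mean,
              100 * x$accuracy_sd),
      sprintf("(%d reps x %d folds)", x$n_subsample_reps, x$cv_folds), "\n")
  invisible(x)
}

#' Classifier accuracy per individual property, plus all combined
#'
#' Runs \code{\link{classify}} once per single content property and once
#' with all properties combined ("ALL"), the per-property ablation used to
#' rank which content drives memorability.
#'
#' @inheritParams classify
#' @param properties feature names to test individually.
#' @return list with \code{reports} (named list of classifier_reports;
#'   suppressed properties are NULL) and \code{table} (data.frame of
#'   feature_set, accuracy_mean, accuracy_sd).
#' @export
per_property_accuracy <- function(vectors, labels, properties,
                                  cv_folds = 10L, n_subsample_reps = 25L,
                                  cost = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  run_one <- function(fs, name) {
    rows <- match(labels$shot_id, vectors$shot_id)
    if (length(fs) == 1 && length(unique(vectors[[fs]][rows])) < 2)
      return(NULL)  # property constant over labeled shots: uninformative
    classify(vectors, labels, feature_set = fs, cv_folds = cv_folds,
             n_subsample_reps = n_subsample_reps, cost = cost)
  }
  reports <- lapply(properties, function(p) run_one(p, p))
  names(reports) <- properties
  reports$ALL <- run_one(properties, "ALL")
  tab <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    if (is.null(r))
      data.frame(feature_set = nm, accuracy_mean = NA_real_,
                 accuracy_sd = NA_real_, suppressed = TRUE)
    else
      data.frame(feature_set = nm, accuracy_mean = r$accuracy_mean,
                 accuracy_sd = r$accuracy_sd, suppressed = FALSE)
  }))
  list(reports = reports, table = tab)
}

#' Label-shuffle null distribution for classifier accuracy
#'
#' Permutes the labels across shots \code{n_iter} times and re-runs the full
#' classification pipeline (one balanced subsample per iteration), giving
#' the accuracy distribution expected when content carries no information
#' about memorability. By construction its mean is chance (50%).
#'
#' @inheritParams classify
#' @param n_iter number of label permutations (>= 100).
#' @param observed_accuracy optional observed accuracy to test; p uses the
#'   add-one estimator.
#' @return list: null_accuracies, null_mean, null_sd, p_vs_null (NA when no
#'   observed accuracy is supplied).
#' @export
shuffle_null <- function(vectors, labels, feature_set = NULL,
                         n_iter = 1000L, cv_folds = 10L, cost = 1,
                         observed_accuracy = NULL, seed = NULL) {
  if (n_iter < 100) stop("n_iter must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  acc <- vapply(seq_len(n_iter), function(i) {
    shuffled <- labels
    shuffled$label <- labels$label[sample.int(nrow(labels))]
    classify(vectors, shuffled, feature_set = feature_set,
             cv_folds = cv_folds, n_subsample_reps = 1L,
             cost = cost)$accuracy_mean
  }, numeric(1))
  p <- if (is.null(observed_accuracy)) NA_real_
  else (1 + sum(acc >= observed_accuracy - 1e-12)) / (n_iter + 1)
  list(null_accuracies = acc, null_mean = mean(acc),
       null_sd = stats::sd(acc), p_vs_null = p, n_iter = n_iter)
}

#' Majority-of-others upper-bound predictor
#'
#' Predicts a subject's correctness on each shot from the majority
#' correctness of all other subjects on the same shot (ties and shots with
#' fewer than \code{min_voters} other subjects excluded); accuracy is the
#' agreement fraction. A behavior-only bound on what any content-based
#' predictor could achieve.
#'
#' @param trials a trial table.
#' @param subject subject id.
#' @param min_voters minimum other subjects per shot.
#' @param min_predictions minimum shots before reporting.
#' @return data.frame row: model, subject_id, accuracy, n_predictions,
#'   suppressed.
#' @export
majority_predictor <- function(trials, subject, min_voters = 3L,
                               min_predictions = 20L) {
  tr <- trials[trials$subject_id == subject, , drop = FALSE]
  tr <- tr[order(tr$elapsed_days, tr$trial_index), , drop = FALSE]
  key <- paste(tr$shot_id, tr$stimulus_class)
  tr <- tr[!duplicated(key), , drop = FALSE]
  key <- key[!duplicated(key)]
  votes <- mode_correct(trials, exclude_subject = subject,
                        min_voters = min_voters)
  ref <- votes[key]
  ok <- !is.na(ref)
  n <- sum(ok)
  data.frame(model = "majority_based", subject_id = subject,
             accuracy = if (n >= min_predictions)
               mean(tr$correct[ok] == ref[ok]) else NA_real_,
             n_predictions = n,
             suppressed = n < min_predictions,
             stringsAsFactors = FALSE)
}

#' Self-prediction upper bound from repeat trials
#'
#' Predicts correctness on a repeat presentation from the first
#' presentation of the same shot; accuracy is the self-consistency rate
#' (both-correct plus both-wrong fraction).
#'
#' @param trials a trial table.
#' @param subject subject id.
#' @param min_pairs minimum repeat pairs before reporting.
#' @return data.frame row as in \code{\link{majority_predictor}}.
#' @export
self_predictor <- function(trials, subject, min_pairs = 20L) {
  tr <- trials[trials$subject_id == subject, , drop = FALSE]
  pr <- repeat_pairs(tr)
  n <- length(pr$first)
  data.frame(model = "self_prediction", subject_id = subject,
             accuracy = if (n >= min_pairs) mean(pr$first == pr$second)
             else NA_real_,
             n_predictions = n,
             suppressed = n < min_pairs,
             stringsAsFactors = FALSE)
}
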