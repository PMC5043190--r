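MIN_TRIALS_PER_CELL <- 20L

#' Apply the standard trial and subject exclusions
#'
#' Removes the first 5 trials of every subject-session (adaptation period),
#' then drops subjects with fewer than 400 remaining trials, an "old"
#' response rate above 75%, or overall percent correct below 60%.
#'
#' @param trials a trial table.
#' @param n_warmup number of initial trials per session to discard (default 5).
#' @param min_trials minimum trials per subject after warm-up removal.
#' @param max_yes_rate maximum tolerated "old"-response rate.
#' @param min_pc minimum overall percent correct.
#' @return list with \code{trials} (retained rows) and \code{exclusions}
#'   (data.frame subject_id, rule, value).
#' @export
apply_exclusions <- function(trials, n_warmup = 5L, min_trials = 400L,
                             max_yes_rate = 0.75, min_pc = 0.60) {
  empty_report <- data.frame(subject_id = character(), rule = character(),
                             value = numeric(), stringsAsFactors = FALSE)
  if (nrow(trials) == 0)
    return(list(trials = trials, exclusions = empty_report))
  keep <- trials$trial_index > n_warmup
  tr <- trials[keep, , drop = FALSE]
  by_subj <- split(tr, tr$subject_id)
  rep_rows <- lapply(names(by_subj), function(sid) {
    s <- by_subj[[sid]]
    n <- nrow(s)
    yes <- mean(s$response == "old")
    pc <- mean(s$correct)
    if (n < min_trials)
      data.frame(subject_id = sid, rule = "min_trials", value = n)
    else if (yes > max_yes_rate)
      data.frame(subject_id = sid, rule = "response_bias", value = yes)
    else if (pc < min_pc)
      data.frame(subject_id = sid, rule = "low_performance", value = pc)
    else NULL
  })
  report <- do.call(rbind, c(list(empty_report), rep_rows))
  list(trials = tr[!tr$subject_id %in% report$subject_id, , drop = FALSE],
       exclusions = report)
}

#' Sensitivity index d-prime
#'
#' d' = z(p_hit) - z(p_FA), with rates clipped to [1/(2N), 1 - 1/(2N)]
#' (N = number of target or foil trials respectively) before taking the
#' standard-normal quantile, the usual correction for perfect rates in
#' finite samples.
#'
#' @param p_hit,p_fa hit and false-alarm proportions (vectorized).
#' @param n_targets,n_foils trial counts behind each rate.
#' @return numeric d' values.
#' @export
dprime <- function(p_hit, p_fa, n_targets, n_foils) {
  if (any(n_targets <= 0) || any(n_foils <= 0))
    stop("n_targets and n_foils must be positive", call. = FALSE)
  clip <- function(p, n) pmin(1 - 1 / (2 * n), pmax(1 / (2 * n), p))
  stats::qnorm(clip(p_hit, n_targets)) - stats::qnorm(clip(p_fa, n_foils))
}

#' Per-subject performance summaries
#'
#' Percent correct, hit rate, false-alarm rate, d' and "old"-response rate
#' per subject, plus a pooled mean +/- SD across subjects (subjects weighted
#' equally). Cells with fewer than 20 trials are suppressed: their
#' proportions are reported as NA with \code{suppressed = TRUE}.
#'
#' @param trials a trial table.
#' @param filter optional logical vector or predicate function over trial
#'   rows selecting the trials to summarize.
#' @return list with \code{by_subject} (one row per subject) and
#'   \code{pooled} (mean/sd of pc, p_hit, p_fa, d_prime over unsuppressed
#'   subjects).
#' @export
compute_performance <- function(trials, filter = NULL) {
  if (is.function(filter)) trials <- trials[filter(trials), , drop = FALSE]
  else if (!is.null(filter)) trials <- trials[filter, , drop = FALSE]
  by_subj <- split(trials, trials$subject_id)
  rows <- lapply(names(by_subj), function(sid) {
    s <- by_subj[[sid]]
    tgt <- s[s$stimulus_class == "target", , drop = FALSE]
    fl <- s[s$stimulus_class == "foil", , drop = FALSE]
    suppressed <- nrow(s) < MIN_TRIALS_PER_CELL
    rate_ok <- nrow(tgt) >= 1 && nrow(fl) >= 1
    p_hit <- if (rate_ok) mean(tgt$correct) else NA_real_
    p_fa <- if (rate_ok) 1 - mean(fl$correct) else NA_real_
    data.frame(subject_id = sid,
               n_trials = nrow(s),
               pc = if (suppressed) NA_real_ else mean(s$correct),
               p_hit = if (suppressed) NA_real_ else p_hit,
               p_fa = if (suppressed) NA_real_ else p_fa,
               d_prime = if (suppressed || !rate_ok) NA_real_
                         else dprime(p_hit, p_fa, nrow(tgt), nrow(fl)),
               yes_rate = mean(s$response == "old"),
               suppressed = suppressed,
               stringsAsFactors = FALSE)
  })
  by_subject <- do.call(rbind, rows)
  ok <- by_subject[!by_subject$suppressed, , drop = FALSE]
  pooled <- data.frame(
    metric = c("pc", "p_hit", "p_fa", "d_prime"),
    mean = vapply(c("pc", "p_hit", "p_fa", "d_prime"),
                  function(m) mean(ok[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(c("pc", "p_hit", "p_fa", "d_prime"),
                function(m) stats::sd(ok[[m]], na.rm = TRUE), numeric(1)),
    n_subjects = nrow(ok),
    stringsAsFactors = FALSE)
  rownames(pooled) <- NULL
  list(by_subject = by_subject, pooled = pooled)
}

performance_curve <- function(bin_labels, x, pc, n) {
  keep <- n >= MIN_TRIALS_PER_CELL
  bin_labels <- bin_labels[keep]; x <- x[keep]
  pc <- pc[keep]; n <- n[keep]
  r <- NA_real_; p_value <- NA_real_; zero_variance <- FALSE
  if (length(pc) >= 3) {
    if (stats::sd(pc) == 0 || stats::sd(x) == 0) {
      r <- 0; zero_variance <- TRUE
    } else {
      ct <- stats::cor.test(x, pc)
      r <- unname(ct$estimate)
      p_value <- ct$p.value
    }
  }
  structure(list(bin_labels = bin_labels, pc_per_bin = pc, n_per_bin = n,
                 r = r, p_value = p_value, zero_variance = zero_variance),
            class = "performance_curve")
}

#' @export
print.performance_curve <- function(x, ...) {
  cat("performance_curve over", length(x$bin_labels), "bins; r =",
      formatC(x$r, digits = 3), "\n")
  invisible(x)
}

#' Percent correct as a function of shot duration
#'
#' Full-shot trials are binned by the parent shot's frame count (default bin
#' width 30 frames: 1-30, 31-60, 61-90) and percent correct is computed per
#' bin. Pearson r is taken between bin centers and per-bin pc; bins with
#' fewer than 20 trials are dropped.
#'
#' @param trials a trial table.
#' @param shots the shot table (for n_frames).
#' @param bin_frames bin width in frames.
#' @return a \code{performance_curve}.
#' @export
duration_curve <- function(trials, shots, bin_frames = 30L) {
  tr <- trials[trials$presentation_mode == "full_shot", , drop = FALSE]
  nf <- shots$n_frames[match(tr$shot_id, shots$shot_id)]
  bin <- pmin(ceiling(nf / bin_frames), ceiling(90 / bin_frames))
  bins <- sort(unique(bin))
  centers <- (bins - 0.5) * bin_frames
  pc <- vapply(bins, function(b) mean(tr$correct[bin == b]), numeric(1))
  n <- vapply(bins, function(b) sum(bin == b), numeric(1))
  performance_curve(centers, centers, pc, n)
}

#' Percent correct as a function of retention interval
#'
#' Percent correct per nominal session day. The correlation is computed
#' against the session's ordinal rank rather than elapsed days, i.e. test
#' points are treated as equidistant, matching the usual plotting convention
#' for forgetting curves over log-spaced delays.
#'
#' @param trials a trial table.
#' @param mode presentation mode to analyze ("full_shot" or "single_frame").
#' @return a \code{performance_curve} (bin labels are session days).
#' @export
retention_curve <- function(trials, mode = "full_shot") {
  tr <- trials[trials$presentation_mode == mode, , drop = FALSE]
  days <- sort(unique(tr$session_label))
  pc <- vapply(days, function(d) mean(tr$correct[tr$session_label == d]),
               numeric(1))
  n <- vapply(days, function(d) sum(tr$session_label == d), numeric(1))
  performance_curve(days, seq_along(days) - 1, pc, n)
}

#' Two-sided permutation test on a difference of means
#'
#' The statistic is mean(group_a) - mean(group_b); group labels are permuted
#' \code{n_perm} times and the two-sided p-value uses the add-one estimator
#' p = (1 + #\{|perm| >= |obs|\}) / (n_perm + 1), so p is never exactly 0.
#' A Bonferroni-adjusted p for \code{m_comparisons} tests is also returned.
#'
#' @param group_a,group_b numeric outcome vectors.
#' @param n_perm number of permutations (>= 100).
#' @param m_comparisons Bonferroni family size.
#' @return list with observed, p_raw, p_adjusted, n_perm.
#' @export
permutation_test <- function(group_a, group_b, n_perm = 1000L,
                             m_comparisons = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be nonempty", call. = FALSE)
  na <- length(group_a)
  pooled <- c(group_a, group_b)
  obs <- mean(group_a) - mean(group_b)
  tot <- sum(pooled)
  n <- length(pooled)
  # mean_a - mean_b is affine in sum(permuted a): vectorize over permutations
  perm_sums <- vapply(seq_len(n_perm), function(i)
    sum(pooled[sample.int(n, na)]), numeric(1))
  perm_stat <- perm_sums / na - (tot - perm_sums) / (n - na)
  p_raw <- (1 + sum(abs(perm_stat) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(observed = obs,
       p_raw = p_raw,
       p_adjusted = min(1, m_comparisons * p_raw),
       n_perm = n_perm)
}
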