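#' Expected consistency fractions under response independence
#'
#' For one subject with accuracy p the expected (both correct, both wrong,
#' inconsistent) fractions over repeat pairs are (p^2, (1-p)^2, 2p(1-p));
#' for two subjects with accuracies p_i, p_j they are
#' (p_i p_j, (1-p_i)(1-p_j), p_i(1-p_j) + p_j(1-p_i)).
#'
#' @param p one accuracy (self case) or a length-2 vector (pairwise case).
#' @return named numeric triple summing to 1.
#' @export
independence_null <- function(p) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]",
                               call. = FALSE)
  if (length(p) == 1) {
    c(both_correct = p^2, both_wrong = (1 - p)^2,
      inconsistent = 2 * p * (1 - p))
  } else if (length(p) == 2) {
    c(both_correct = p[1] * p[2],
      both_wrong = (1 - p[1]) * (1 - p[2]),
      inconsistent = p[1] * (1 - p[2]) + p[2] * (1 - p[1]))
  } else stop("p must have length 1 or 2", call. = FALSE)
}

consistency_report <- function(unit, a, b, p_null, n_mc, min_pairs) {
  n <- length(a)
  if (n < min_pairs)
    return(structure(list(unit = unit, suppressed = TRUE, n_comparisons = n),
                     class = "consistency_report"))
  observed <- c(both_correct = mean(a == 1 & b == 1),
                both_wrong = mean(a == 0 & b == 0),
                inconsistent = mean(a != b))
  # Monte-Carlo null: independent responders with the given marginal
  # accuracies, n pairs per draw; two-sided on the inconsistent fraction
  p1 <- p_null[1]; p2 <- p_null[length(p_null)]
  null_inc <- (stats::rbinom(n_mc, n, p1 * (1 - p2)) +
                 stats::rbinom(n_mc, n, p2 * (1 - p1))) / n
  expected <- independence_null(p_null)
  dev <- abs(observed["inconsistent"] - expected["inconsistent"])
  p_value <- (1 + sum(abs(null_inc - expected["inconsistent"]) >=
                        dev - 1e-12)) / (n_mc + 1)
  structure(list(unit = unit, suppressed = FALSE,
                 observed = observed, expected_null = expected,
                 n_comparisons = n, p_value = p_value),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  if (x$suppressed) {
    cat("consistency_report (", x$unit, "): suppressed, n =",
        x$n_comparisons, "\n")
  } else {
    cat("consistency_report (", x$unit, "): observed",
        paste(formatC(x$observed, digits = 3), collapse = "/"),
        "vs null", paste(formatC(x$expected_null, digits = 3),
                         collapse = "/"),
        "n =", x$n_comparisons, "p =", format.pval(x$p_value), "\n")
  }
  invisible(x)
}

# first two presentations of every (shot, class) a subject saw >= 2 times
repeat_pairs <- function(tr) {
  key <- paste(tr$shot_id, tr$stimulus_class)
  tr <- tr[order(key, tr$elapsed_days, tr$trial_index), , drop = FALSE]
  key <- paste(tr$shot_id, tr$stimulus_class)
  occ <- stats::ave(seq_along(key), key, FUN = seq_along)
  k1 <- tr[occ == 1 & key %in% key[occ == 2], , drop = FALSE]
  k2 <- tr[occ == 2, , drop = FALSE]
  k1 <- k1[order(paste(k1$shot_id, k1$stimulus_class)), , drop = FALSE]
  k2 <- k2[order(paste(k2$shot_id, k2$stimulus_class)), , drop = FALSE]
  list(first = k1$correct, second = k2$correct)
}

#' Within-subject self-consistency on repeat trials
#'
#' For every shot the subject was queried on at least twice, the first and
#' second presentations are compared on correctness. The observed (both
#' correct, both wrong, inconsistent) fractions are tested against the
#' independence null at the subject's own overall accuracy via Monte-Carlo
#' simulation of independent responders.
#'
#' @param trials a trial table.
#' @param subject subject id.
#' @param n_mc Monte-Carlo draws for the null (default 10000).
#' @param min_pairs minimum repeat pairs before reporting (default 20).
#' @return a \code{consistency_report} (suppressed when too few pairs).
#' @export
self_consistency <- function(trials, subject, n_mc = 10000L,
                             min_pairs = 20L) {
  tr <- trials[trials$subject_id == subject, , drop = FALSE]
  pr <- repeat_pairs(tr)
  p_subj <- mean(tr$correct)
  consistency_report("self", pr$first, pr$second, p_subj, n_mc, min_pairs)
}

# correctness of two subjects on shots both answered under the same
# presentation condition (first presentation each)
shared_first_responses <- function(trials, si, sj) {
  pick <- function(s) {
    tr <- trials[trials$subject_id == s, , drop = FALSE]
    key <- paste(tr$shot_id, tr$stimulus_class, tr$presentation_mode,
                 tr$manipulation)
    tr <- tr[order(key, tr$elapsed_days, tr$trial_index), , drop = FALSE]
    tr$key <- paste(tr$shot_id, tr$stimulus_class, tr$presentation_mode,
                    tr$manipulation)
    tr[!duplicated(tr$key), , drop = FALSE]
  }
  a <- pick(si); b <- pick(sj)
  shared <- intersect(a$key, b$key)
  list(a = a$correct[match(shared, a$key)],
       b = b$correct[match(shared, b$key)],
       p_a = mean(a$correct), p_b = mean(b$correct))
}

#' Between-subject pairwise consistency
#'
#' Over shots queried of both subjects under the same presentation
#' condition, compares their correctness and tests the observed fractions
#' against the pairwise independence null p_i p_j etc.
#'
#' @param trials a trial table.
#' @param subject_i,subject_j subject ids.
#' @inheritParams self_consistency
#' @return a \code{consistency_report}.
#' @export
pairwise_consistency <- function(trials, subject_i, subject_j,
                                 n_mc = 10000L, min_pairs = 20L) {
  sh <- shared_first_responses(trials, subject_i, subject_j)
  consistency_report("pair", sh$a, sh$b, c(sh$p_a, sh$p_b), n_mc, min_pairs)
}

# per-shot majority correctness over subjects (one vote per subject, first
# presentation); ties or fewer than min_voters voters -> NA
mode_correct <- function(trials, exclude_subject = NULL, min_voters = 3L) {
  tr <- trials
  if (!is.null(exclude_subject))
    tr <- tr[tr$subject_id != exclude_subject, , drop = FALSE]
  tr <- tr[order(tr$subject_id, tr$elapsed_days, tr$trial_index), ,
           drop = FALSE]
  key <- paste(tr$shot_id, tr$stimulus_class)
  tr <- tr[!duplicated(paste(tr$subject_id, key)), , drop = FALSE]
  key <- paste(tr$shot_id, tr$stimulus_class)
  votes <- tapply(tr$correct, key, function(v) {
    if (length(v) < min_voters || 2 * sum(v) == length(v)) NA_real_
    else as.numeric(2 * sum(v) > length(v))
  })
  votes
}

#' Consistency of a subject with the mode of all other subjects
#'
#' Each shot's reference label is the majority correctness of all other
#' subjects (ties and shots with fewer than \code{min_voters} other subjects
#' excluded). The null uses p_subject x p_mode, where p_mode is the mode's
#' empirical accuracy: the fraction of shots where the majority of
#' others was correct.
#'
#' @param trials a trial table.
#' @param subject subject id.
#' @param min_voters minimum number of other subjects per shot.
#' @inheritParams self_consistency
#' @return a \code{consistency_report}.
#' @export
mode_consistency <- function(trials, subject, n_mc = 10000L,
                             min_pairs = 20L, min_voters = 3L) {
  tr <- trials[trials$subject_id == subject, , drop = FALSE]
  key <- paste(tr$shot_id, tr$stimulus_class)
  tr <- tr[!duplicated(key), , drop = FALSE]
  key <- key[!duplicated(key)]
  votes <- mode_correct(trials, exclude_subject = subject,
                        min_voters = min_voters)
  ref <- votes[key]
  ok <- !is.na(ref)
  consistency_report("vs_mode", tr$correct[ok], as.numeric(ref[ok]),
                     c(mean(tr$correct), mean(ref[ok])), n_mc, min_pairs)
}
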