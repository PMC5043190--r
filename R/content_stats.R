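#' Performance effect of one binary content property
#'
#' Trials are partitioned by whether the presented shot carries the property;
#' percent correct is computed per subject on each side (subjects are the
#' replication unit) and the two sets of per-subject accuracies are compared
#' with a two-sided permutation test, Bonferroni-adjusted for the batch size.
#' Properties present in fewer than \code{min_shots} shots, or with fewer
#' than 20 trials on either side, are suppressed.
#'
#' @param trials a trial table.
#' @param vectors the annotation table.
#' @param property a binary feature name.
#' @param n_perm permutations for the test.
#' @param m_comparisons Bonferroni family size (number of properties tested
#'   in the batch).
#' @param alpha significance level for the flag after adjustment.
#' @param min_shots minimum number of shots carrying the property.
#' @param targets_only restrict to target trials (default pools targets and
#'   foils).
#' @return a one-row data.frame (a PropertyEffect record); suppressed
#'   records carry a reason instead of p-values.
#' @export
property_effect <- function(trials, vectors, property, n_perm = 1000L,
                            m_comparisons = 1L, alpha = 0.01,
                            min_shots = 10L, targets_only = FALSE) {
  if (!property %in% names(vectors))
    stop("unknown property: ", property, call. = FALSE)
  if (targets_only)
    trials <- trials[trials$stimulus_class == "target", , drop = FALSE]
  present <- vectors[[property]][match(trials$shot_id, vectors$shot_id)]
  n_shots_present <- sum(vectors[[property]] %in% 1 &
                           vectors$shot_id %in% trials$shot_id)
  n_shots_absent <- sum(vectors[[property]] %in% 0 &
                          vectors$shot_id %in% trials$shot_id)
  rec <- data.frame(property = property,
                    pc_present = NA_real_, pc_absent = NA_real_,
                    n_shots_present = n_shots_present,
                    n_shots_absent = n_shots_absent,
                    p_raw = NA_real_, p_adjusted = NA_real_,
                    significant = NA, suppressed = TRUE,
                    reason = "", stringsAsFactors = FALSE)
  if (n_shots_present < min_shots) {
    rec$reason <- "below_occurrence_threshold"
    return(rec)
  }
  if (sum(present == 1) < 20 || sum(present == 0) < 20) {
    rec$reason <- "too_few_trials"
    return(rec)
  }
  pc_side <- function(side) {
    tr <- trials[present == side, , drop = FALSE]
    tapply(tr$correct, tr$subject_id, mean)
  }
  pcs1 <- pc_side(1); pcs0 <- pc_side(0)
  pt <- permutation_test(pcs1, pcs0, n_perm = n_perm,
                         m_comparisons = m_comparisons)
  rec$pc_present <- mean(pcs1); rec$pc_absent <- mean(pcs0)
  rec$p_raw <- pt$p_raw; rec$p_adjusted <- pt$p_adjusted
  rec$significant <- pt$p_adjusted < alpha
  rec$suppressed <- FALSE
  rec
}

#' Compare a continuous/count property between correct and incorrect trials
#'
#' The property's value (of the presented shot) is averaged over correct vs
#' incorrect trials; the difference is tested with a permutation test.
#'
#' @inheritParams property_effect
#' @param property a count or continuous feature name.
#' @return list with mean_correct, mean_incorrect, p (NA and
#'   \code{suppressed = TRUE} when one side has fewer than 20 trials).
#' @export
continuous_effect <- function(trials, vectors, property, n_perm = 1000L) {
  if (!property %in% names(vectors))
    stop("unknown property: ", property, call. = FALSE)
  x <- vectors[[property]][match(trials$shot_id, vectors$shot_id)]
  xc <- x[trials$correct == 1]
  xi <- x[trials$correct == 0]
  if (length(xc) < 20 || length(xi) < 20)
    return(list(mean_correct = NA_real_, mean_incorrect = NA_real_,
                p = NA_real_, suppressed = TRUE))
  if (stats::sd(x) == 0)
    return(list(mean_correct = mean(xc), mean_incorrect = mean(xi),
                p = 1, suppressed = FALSE))
  pt <- permutation_test(xc, xi, n_perm = n_perm)
  list(mean_correct = mean(xc), mean_incorrect = mean(xi),
       p = pt$p_raw, suppressed = FALSE)
}

#' Batch property effects with joint Bonferroni adjustment
#'
#' Runs \code{\link{property_effect}} for each property; the Bonferroni
#' family size is the number of eligible (non-suppressed) properties.
#' Suppressed properties appear in the table with their reason.
#'
#' @inheritParams property_effect
#' @param properties character vector of binary feature names.
#' @return data.frame of PropertyEffect records sorted by adjusted p.
#' @export
effect_table <- function(trials, vectors, properties, n_perm = 1000L,
                         alpha = 0.01, min_shots = 10L,
                         targets_only = FALSE) {
  if (length(properties) == 0)
    stop("properties must be nonempty", call. = FALSE)
  tr <- if (targets_only)
    trials[trials$stimulus_class == "target", , drop = FALSE] else trials
  eligible <- vapply(properties, function(p) {
    pres <- vectors[[p]][match(tr$shot_id, vectors$shot_id)]
    sum(vectors[[p]] %in% 1 & vectors$shot_id %in% tr$shot_id) >=
      min_shots && sum(pres == 1) >= 20 && sum(pres == 0) >= 20
  }, logical(1))
  m <- sum(eligible)
  out <- do.call(rbind, lapply(properties, function(p)
    property_effect(trials, vectors, p, n_perm = n_perm,
                    m_comparisons = m, alpha = alpha, min_shots = min_shots,
                    targets_only = targets_only)))
  out[order(out$suppressed, out$p_adjusted), , drop = FALSE]
}
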