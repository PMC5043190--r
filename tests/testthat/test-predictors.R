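test_that("labels aggregate presentations by majority with ties excluded", {
  tr <- grid_trials(matrix(1, 5, 10))
  tr$correct <- 1
  tr$correct[tr$subject_id %in% c("sub001", "sub002") &
               tr$shot_id == "sh00001"] <- 0
  lab <- make_labels(tr, level = "mode")
  expect_equal(nrow(lab), 10)
  expect_equal(lab$label[lab$shot_id == "sh00001"], 1)  # 3 vs 2
  expect_equal(lab$n_votes_correct[lab$shot_id == "sh00001"], 3)
  # 2-vs-2 tie disappears from mode labels
  tr4 <- grid_trials(matrix(1, 4, 6))
  tr4$correct <- ifelse(tr4$shot_id == "sh00002" &
                          tr4$subject_id %in% c("sub001", "sub002"), 0, 1)
  lab4 <- make_labels(tr4, level = "mode")
  expect_false("sh00002" %in% lab4$shot_id)
  # a subject seeing a shot twice with split outcomes is excluded
  tr2 <- rbind(flat_trials(30, correct = rep(1, 30)),
               flat_trials(30, correct = rep(0, 30), session = 7))
  labs <- make_labels(tr2, level = "subject")
  expect_equal(nrow(labs), 0)
})

test_that("noiseless linear structure is recovered by the regression", {
  set.seed(83)
  ann <- random_binary_annotations(400, 10)
  alpha <- seq(-0.05, 0.08, length.out = 10)
  y <- 0.7 + as.vector(as.matrix(ann[, -1]) %*% alpha)
  names(y) <- ann$shot_id
  fit <- fit_group_regression(ann, y, seed = 1)
  expect_gte(fit$r_squared_cv, 0.99)
  expect_equal(unname(fit$coefficients), alpha, tolerance = 0.01)
  expect_equal(unname(fit$intercept), 0.7, tolerance = 0.01)
  expect_false(fit$ridge)
})

test_that("noise degrades but does not destroy regression recovery", {
  set.seed(85)
  ann <- random_binary_annotations(1000, 20)
  alpha <- seq(0.03, 0.1, length.out = 20)
  y <- 0.6 + as.vector(as.matrix(ann[, -1]) %*% alpha) + rnorm(1000, 0, 0.05)
  names(y) <- ann$shot_id
  fit <- fit_group_regression(ann, y, seed = 1)
  expect_gte(fit$r_squared_cv, 0.8)
})

test_that("pure-noise features yield near-zero held-out r-squared", {
  set.seed(87)
  ann <- random_binary_annotations(1000, 20)
  y <- stats::setNames(runif(1000, 0.5, 1), ann$shot_id)
  fit <- fit_group_regression(ann, y, seed = 1)
  expect_lte(fit$r_squared_cv, 0.1)
  # constant outcome is flagged, not an error
  yc <- stats::setNames(rep(0.8, 1000), ann$shot_id)
  fitc <- fit_group_regression(ann, yc, seed = 1)
  expect_equal(fitc$r_squared_cv, 0)
  expect_true(fitc$constant_outcome)
})

test_that("few shots per feature engage the ridge fallback", {
  set.seed(89)
  ann <- random_binary_annotations(30, 10)
  y <- stats::setNames(runif(30), ann$shot_id)
  fit <- fit_group_regression(ann, y, cv_folds = 5, seed = 1)
  expect_true(fit$ridge)
})

test_that("balanced subsampling equalizes classes", {
  set.seed(91)
  lab <- data.frame(shot_id = sprintf("s%03d", 1:40),
                    label = rep(c(1, 0), c(30, 10)))
  bal <- balanced_subsample(lab)
  expect_equal(sum(bal$label == 1), 10)
  expect_equal(sum(bal$label == 0), 10)
  expect_true(all(lab$shot_id[lab$label == 0] %in% bal$shot_id))
  # already balanced input returns all rows
  lab2 <- data.frame(shot_id = sprintf("s%03d", 1:20),
                     label = rep(c(1, 0), 10))
  expect_setequal(balanced_subsample(lab2)$shot_id, lab2$shot_id)
  # different draws vary the majority subset only
  b1 <- balanced_subsample(lab); b2 <- balanced_subsample(lab)
  expect_true(all(lab$shot_id[lab$label == 0] %in% b1$shot_id))
  expect_error(balanced_subsample(data.frame(shot_id = "a", label = 1)),
               "both classes")
})

test_that("separable labels are classified nearly perfectly", {
  set.seed(93)
  ann <- random_binary_annotations(200, 20)
  beta <- c(rep(2, 5), rep(0, 15))
  sc <- as.vector(as.matrix(ann[, -1]) %*% beta)
  lab <- data.frame(shot_id = ann$shot_id,
                    label = as.integer(sc > stats::median(sc)))
  rep <- classify(ann, lab, n_subsample_reps = 5, seed = 7)
  expect_gte(rep$accuracy_mean, 0.95)
  # informative features dominate the weight vector
  expect_gt(min(abs(rep$weights[1:5])), max(abs(rep$weights[6:20])))
})

test_that("uninformative features give chance accuracy", {
  set.seed(95)
  ann <- random_binary_annotations(300, 10)
  lab <- data.frame(shot_id = ann$shot_id, label = rbinom(300, 1, 0.5))
  rep <- classify(ann, lab, n_subsample_reps = 10, seed = 7)
  se <- sd(rep$fold_accuracies) / sqrt(length(rep$fold_accuracies))
  expect_lt(abs(rep$accuracy_mean - 0.5), max(3 * se, 0.05))
})

test_that("a single binary feature classifies like its best 1-D rule", {
  set.seed(97)
  ann <- random_binary_annotations(400, 3)
  # label = feature f01 with 10% flips
  lab <- data.frame(shot_id = ann$shot_id,
                    label = as.integer(xor(ann$f01 == 1,
                                           runif(400) < 0.1)))
  rep <- classify(ann, lab, feature_set = "f01", n_subsample_reps = 10,
                  seed = 7)
  # oracle: the better of the two label mappings of the feature, evaluated
  # on balanced class frequencies
  p11 <- mean(ann$f01[lab$label == 1])   # P(x=1 | y=1)
  p10 <- mean(ann$f01[lab$label == 0])   # P(x=1 | y=0)
  oracle <- max((p11 + 1 - p10) / 2, (p10 + 1 - p11) / 2)
  expect_lt(abs(rep$accuracy_mean - oracle), 0.05)
  expect_error(classify(ann, lab, feature_set = c("f01", "zzz")), "zzz")
})

test_that("per-property accuracy ranks follow the generative weights", {
  set.seed(99)
  n_shots <- 1200; n_feat <- 10
  ann <- random_binary_annotations(n_shots, n_feat)
  beta <- seq(0, 2, length.out = n_feat)
  x <- as.matrix(ann[, -1])
  p <- plogis(as.vector(x %*% beta) - mean(x %*% beta))
  votes <- rbinom(n_shots, 15, p)  # 15 subjects sharing shot difficulty
  lab <- data.frame(shot_id = ann$shot_id,
                    label = as.integer(votes > 7))
  pp <- per_property_accuracy(ann, lab, colnames(x), n_subsample_reps = 3,
                              seed = 7)
  acc <- pp$table$accuracy_mean[match(colnames(x), pp$table$feature_set)]
  expect_gte(cor(acc, beta, method = "spearman"), 0.7)
  all_acc <- pp$table$accuracy_mean[pp$table$feature_set == "ALL"]
  expect_gte(all_acc, max(acc) - 2 * max(pp$table$accuracy_sd, na.rm = TRUE))
  # a constant property is suppressed
  ann$dead <- 0
  pp2 <- per_property_accuracy(ann, lab, c("f01", "dead"),
                               n_subsample_reps = 2, seed = 7)
  expect_true(pp2$table$suppressed[pp2$table$feature_set == "dead"])
})

test_that("the label-shuffle null is anchored at chance", {
  set.seed(101)
  ann <- random_binary_annotations(120, 8)
  lab <- data.frame(shot_id = ann$shot_id, label = rbinom(120, 1, 0.6))
  nl <- shuffle_null(ann, lab, n_iter = 200, seed = 7)
  se <- nl$null_sd / sqrt(200)
  expect_lt(abs(nl$null_mean - 0.5), max(3 * se, 0.02))
  # separable observed accuracy gets the minimal p
  beta <- rep(3, 8)
  lab2 <- data.frame(shot_id = ann$shot_id,
                     label = as.integer(as.matrix(ann[, -1]) %*% beta >
                                          stats::median(as.matrix(ann[, -1])
                                                        %*% beta)))
  cls <- classify(ann, lab2, n_subsample_reps = 3, seed = 7)
  nl2 <- shuffle_null(ann, lab2, n_iter = 100, seed = 7,
                      observed_accuracy = cls$accuracy_mean)
  expect_equal(nl2$p_vs_null, 1 / 101)
  expect_error(shuffle_null(ann, lab, n_iter = 50), "n_iter")
})

test_that("behavior-based predictors bound and agree with definitions", {
  set.seed(103)
  # all subjects identical: majority predictor is perfect
  tr <- grid_trials(matrix(0.5, 6, 200))
  for (s in unique(tr$subject_id))
    tr$correct[tr$subject_id == s] <- tr$correct[tr$subject_id == "sub001"]
  mp <- majority_predictor(tr, "sub001")
  expect_equal(mp$accuracy, 1)
  # independent probe vs a high-accuracy mode: agreement near
  # p q + (1-p)(1-q)
  voters <- grid_trials(matrix(0.9, 7, 3000))
  probe <- grid_trials(matrix(0.8, 1, 3000), subject_ids = "probe")
  mp2 <- majority_predictor(rbind(voters, probe), "probe")
  p_mode <- pbinom(3, 7, 0.9, lower.tail = FALSE)
  expected <- 0.8 * p_mode + 0.2 * (1 - p_mode)
  expect_lt(abs(mp2$accuracy - expected), 0.03)
  # self predictor equals the self-consistency rate
  first <- rbinom(500, 1, 0.8); second <- rbinom(500, 1, 0.8)
  ptr <- rbind(flat_trials(500, correct = first, session = 0),
               flat_trials(500, correct = second, session = 7))
  sp <- self_predictor(ptr, "s1")
  sc <- self_consistency(ptr, "s1", n_mc = 500)
  expect_equal(sp$accuracy, 1 - sc$observed[["inconsistent"]])
  expect_equal(sp$accuracy, mean(first == second))
  # perfectly consistent responder
  sp2 <- self_predictor(rbind(flat_trials(100, correct = rep(1, 100)),
                              flat_trials(100, correct = rep(1, 100),
                                          session = 7)), "s1")
  expect_equal(sp2$accuracy, 1)
  # suppression without repeats
  expect_true(self_predictor(flat_trials(100), "s1")$suppressed)
})
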