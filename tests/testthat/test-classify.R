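test_that("task datasets filter and binarize per the cascade definitions", {
  x <- matrix(rnorm(16), 8)
  d <- rep(c("benign", "atypia", "dcis", "invasive"), 2)
  t1 <- make_task_dataset(x, d, "invasive_vs_noninvasive")
  expect_equal(nrow(t1$x), 8)
  expect_equal(sum(t1$y == "positive"), 2)
  t2 <- make_task_dataset(x, d, "preinvasive_vs_benign")
  expect_equal(nrow(t2$x), 6)
  expect_identical(as.character(t2$y),
                   ifelse(t2$diagnosis == "benign", "negative", "positive"))
  t3 <- make_task_dataset(x, d, "dcis_vs_atypia")
  expect_equal(nrow(t3$x), 4)
  expect_identical(as.character(t3$y)[t3$diagnosis == "dcis"],
                   c("positive", "positive"))
  expect_error(make_task_dataset(x, rep("benign", 8), "dcis_vs_atypia"),
               "at least 2 samples per class")
})

test_that("balanced subsampling equalizes classes deterministically", {
  y <- factor(rep(c("negative", "positive"), c(30, 10)),
              levels = c("negative", "positive"))
  set.seed(13)
  idx <- balanced_subsample(y)
  expect_length(idx, 20)
  expect_equal(unname(table(y[idx])), c(10L, 10L), ignore_attr = TRUE)
  # already balanced: sizes unchanged
  yb <- factor(rep(c("negative", "positive"), each = 5))
  set.seed(13)
  expect_length(balanced_subsample(yb), 10)
  # same seed, same subset
  set.seed(99); a <- balanced_subsample(y)
  set.seed(99); b <- balanced_subsample(y)
  expect_identical(a, b)
})

test_that("compute_metrics implements the contingency formulas", {
  m <- compute_metrics(rep(c("positive", "negative"), 2),
                       rep(c("positive", "negative"), 2))
  expect_equal(unlist(m[1:3]), c(accuracy = 1, sensitivity = 1, specificity = 1))
  # TP=7, FN=3, TN=90, FP=2
  pred <- c(rep("positive", 7), rep("negative", 3), rep("negative", 90),
            rep("positive", 2))
  truth <- c(rep("positive", 10), rep("negative", 92))
  m <- compute_metrics(pred, truth)
  expect_equal(m$sensitivity, 0.70)
  expect_equal(m$specificity, 90 / 92)
  expect_equal(m$accuracy, 97 / 102)
  expect_identical(c(m$TP, m$TN, m$FP, m$FN), c(7L, 90L, 2L, 3L))
  # zero positives in truth: sensitivity undefined and flagged
  expect_warning(m0 <- compute_metrics(rep("negative", 3), rep("negative", 3)),
                 "sensitivity undefined")
  expect_true(is.nan(m0$sensitivity))
  expect_error(compute_metrics("positive", character(0)), "equal length")
})

test_that("loo_evaluate is deterministic and predicts each sample once", {
  set.seed(14)
  x <- rbind(matrix(rnorm(60, -2), 10), matrix(rnorm(60, 2), 10))
  y <- factor(rep(c("negative", "positive"), each = 10),
              levels = c("negative", "positive"))
  cfg <- eval_config(n_repeats = 1, base_seed = 5)
  r1 <- loo_evaluate(x, y, cfg)
  r2 <- loo_evaluate(x, y, cfg)
  expect_identical(r1$repeats, r2$repeats)
  # prediction count = dataset size per repeat
  with(r1$repeats, expect_equal(TP + TN + FP + FN, 20))
  # metrics recomputed from the stored contingency match to 1e-12
  with(r1$repeats, {
    expect_equal(accuracy, (TP + TN) / (TP + TN + FP + FN), tolerance = 1e-12)
    expect_equal(sensitivity, TP / (TP + FN), tolerance = 1e-12)
    expect_equal(specificity, TN / (TN + FP), tolerance = 1e-12)
  })
  # different base seed changes the subsamples (imbalanced data)
  set.seed(15)
  xi <- rbind(matrix(rnorm(120, -0.5), 30), matrix(rnorm(24, 0.5), 6))
  yi <- factor(rep(c("negative", "positive"), c(30, 6)),
               levels = c("negative", "positive"))
  ra <- loo_evaluate(xi, yi, eval_config(n_repeats = 2, base_seed = 1))
  expect_equal(nrow(ra$repeats), 2)
  expect_true(all(ra$repeats$accuracy >= 0 & ra$repeats$accuracy <= 1))
})

test_that("hierarchical prediction follows the cascade", {
  # well-separated synthetic features for the four categories
  set.seed(16)
  centers <- rbind(benign = c(5, 0, 0), atypia = c(0, 5, 0),
                   dcis = c(0, 0, 5), invasive = c(5, 5, 5))
  d <- rep(rownames(centers), each = 12)
  x <- centers[d, ] + matrix(rnorm(length(d) * 3, sd = 0.3), ncol = 3)
  models <- train_task_models(x, d, eval_config(base_seed = 2))
  pred <- hierarchical_predict(models, x)
  expect_gt(mean(pred == d), 0.95)
  # cascade logic on forced scores: task-1 positive wins regardless
  stub <- models
  pinv <- x[d == "invasive", , drop = FALSE]
  expect_true(all(hierarchical_predict(models, pinv) == "invasive"))
  expect_error(hierarchical_predict(models[1:2], x), "all three task models")
})
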