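# Hierarchical three-task evaluation protocol: balanced subsampling,
# per-fold standardization and PCA, polynomial-kernel SVM, leave-one-out
# cross-validation repeated with fresh subsamples.

#' The three hierarchical diagnostic tasks
#'
#' Mirrors how a pathologist eliminates one diagnosis at a time:
#' (1) invasive vs noninvasive on all categories; (2) preinvasive lesions
#' (atypia and DCIS) vs benign among the noninvasive; (3) DCIS vs atypia.
#'
#' @return Named list of task specs, each with `name`, `include`
#'   (diagnoses entering the task) and `positive` (diagnoses forming the
#'   positive class).
#' @export
diagnosis_tasks <- function() {
  list(
    invasive_vs_noninvasive = list(
      name = "invasive_vs_noninvasive",
      include = c("benign", "atypia", "dcis", "invasive"),
      positive = "invasive"),
    preinvasive_vs_benign = list(
      name = "preinvasive_vs_benign",
      include = c("benign", "atypia", "dcis"),
      positive = c("atypia", "dcis")),
    dcis_vs_atypia = list(
      name = "dcis_vs_atypia",
      include = c("atypia", "dcis"),
      positive = "dcis"))
}

#' Build the binary dataset for one diagnostic task
#'
#' @param x Numeric feature matrix, one ROI per row.
#' @param diagnosis Character vector of consensus diagnoses (one per row).
#' @param task A task spec from [diagnosis_tasks()] (or its name).
#' @return List with the filtered feature matrix `x`, binary factor `y`
#'   (levels `negative` < `positive`), the retained `diagnosis` values and
#'   the `task`.
#' @export
make_task_dataset <- function(x, diagnosis, task) {
  if (is.character(task)) task <- diagnosis_tasks()[[task]]
  if (is.null(task)) stop("unknown task")
  x <- as.matrix(x)
  if (nrow(x) != length(diagnosis))
    stop("`diagnosis` must have one entry per row of `x`")
  bad <- setdiff(unique(diagnosis), .DIAGNOSES)
  if (length(bad))
    stop("unknown diagnosis value(s): ", paste(bad, collapse = ", "))
  keep <- diagnosis %in% task$include
  d <- diagnosis[keep]
  y <- factor(ifelse(d %in% task$positive, "positive", "negative"),
              levels = c("negative", "positive"))
  if (any(table(y) < 2L))
    stop(sprintf("task %s needs at least 2 samples per class (got %d negative, %d positive)",
                 task$name, sum(y == "negative"), sum(y == "positive")))
  list(x = x[keep, , drop = FALSE], y = y, diagnosis = d, task = task)
}

#' Balanced subsample of a binary dataset
#'
#' Downsamples each class without replacement to the minority class size
#' and shuffles the order, so that chance performance is 50% and the
#' classifier has no bias toward the larger class.  Uses R's RNG stream;
#' seed with `set.seed()` for determinism.
#'
#' @param y Binary factor.
#' @return Integer index vector into `y` (balanced, shuffled).
#' @export
balanced_subsample <- function(y) {
  idx <- split(seq_along(y), y)
  if (length(idx) != 2L || any(lengths(idx) == 0L))
    stop("both classes must be present")
  m <- min(lengths(idx))
  picked <- unlist(lapply(idx, function(i) {
    if (length(i) == m) i else sort(sample(i, m))
  }), use.names = FALSE)
  sample(picked, length(picked))
}

#' Evaluation protocol configuration
#'
#' @param n_repeats Number of subsampling repeats (default 100).
#' @param pca_components Principal components retained when a training
#'   fold has fewer samples than features (default 20).
#' @param svm_degree Polynomial kernel degree (default 3).
#' @param svm_cost Soft-margin penalty (default 1).
#' @param svm_coef0 Polynomial kernel offset (default 1; see [svm_fit()]).
#' @param base_seed Base RNG seed; repeat `r` uses `base_seed + r`.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(n_repeats = 100, pca_components = 20,
                        svm_degree = 3, svm_cost = 1, svm_coef0 = 1,
                        base_seed = 1) {
  if (n_repeats < 1) stop("`n_repeats` must be >= 1")
  if (pca_components < 1) stop("`pca_components` must be >= 1")
  structure(list(n_repeats = as.integer(n_repeats),
                 pca_components = as.integer(pca_components),
                 svm_degree = svm_degree, svm_cost = svm_cost,
                 svm_coef0 = svm_coef0, base_seed = as.integer(base_seed)),
            class = "eval_config")
}

# Fit the fold preprocessor on training data: per-feature standardization
# (zero-variance features left unscaled), then PCA to `pca_components`
# when `apply_pca`.  The under-determination decision is made once per
# task (see .pca_active), not per fold, so that every fold of a task uses
# the same feature pipeline.
.fit_transform <- function(xtr, pca_components,
                           apply_pca = nrow(xtr) < ncol(xtr)) {
  ctr <- colMeans(xtr)
  scl <- apply(xtr, 2L, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  xs <- scale(xtr, center = ctr, scale = scl)
  rot <- NULL
  if (apply_pca) {
    pc <- prcomp(xs, center = FALSE, scale. = FALSE)
    k <- min(pca_components, ncol(pc$rotation))
    rot <- pc$rotation[, seq_len(k), drop = FALSE]
    xs <- xs %*% rot
  }
  list(center = ctr, scale = scl, rotation = rot, xtr = xs)
}

# PCA is in effect for a task when its balanced leave-one-out training
# folds are under-determined: the smallest such fold has 2*(minority - 1)
# samples.  Deciding this once per task keeps the feature pipeline
# identical across folds (a per-fold check can straddle the n = p
# boundary depending on the held-out sample's class, which biases the
# two classes differently).
.pca_active <- function(y, n_features) {
  m <- min(table(y))
  2L * (m - 1L) < n_features
}

.apply_transform <- function(tr, x) {
  xs <- scale(x, center = tr$center, scale = tr$scale)
  if (!is.null(tr$rotation)) xs <- xs %*% tr$rotation
  xs
}

#' Classification metrics from a binary contingency
#'
#' Accuracy = (TP + TN) / (TP + TN + FP + FN); sensitivity = TP / (TP +
#' FN); specificity = TN / (TN + FP).  A zero denominator yields `NaN`
#' with a warning.
#'
#' @param predictions,truths Equal-length vectors of class labels.
#' @param positive The positive-class label.
#' @return Named list: `accuracy`, `sensitivity`, `specificity`, `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
compute_metrics <- function(predictions, truths, positive = "positive") {
  if (length(predictions) != length(truths))
    stop("`predictions` and `truths` must have equal length")
  p <- predictions == positive
  t <- truths == positive
  TP <- sum(p & t); TN <- sum(!p & !t)
  FP <- sum(p & !t); FN <- sum(!p & t)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NaN)
    }
    num / den
  }
  list(accuracy = ratio(TP + TN, TP + TN + FP + FN, "accuracy"),
       sensitivity = ratio(TP, TP + FN, "sensitivity"),
       specificity = ratio(TN, TN + FP, "specificity"),
       TP = TP, TN = TN, FP = FP, FN = FN)
}

#' Leave-one-out evaluation with balanced subsampling
#'
#' For each repeat, every sample is held out exactly once; the remaining
#' samples are balanced-subsampled, standardized, projected onto the first
#' `pca_components` principal components when the task's balanced training
#' folds have fewer samples than features (assessed once per task, see
#' Details), and a degree-`svm_degree` polynomial-kernel SVM predicts the
#' held-out sample.  Per-repeat accuracy, sensitivity and
#' specificity are computed over all samples, and their means over repeats
#' reported.  Repeat `r` seeds the RNG with `base_seed + r`, so results
#' are fully deterministic.
#'
#' @param x Feature matrix (rows = samples).
#' @param y Binary factor, levels `c(negative, positive)`.
#' @param config An [eval_config()].
#' @return Object of class `loo_eval`: per-repeat metric data frame
#'   `repeats`, per-repeat `means`, `pooled` metrics from the contingency
#'   summed over repeats, and the `config`.
#' @export
loo_evaluate <- function(x, y, config = eval_config()) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("`y` must be binary")
  if (any(table(y) < 2L)) stop("need at least 2 samples per class")
  n <- nrow(x)
  pos <- levels(y)[2L]
  use_pca <- .pca_active(y, ncol(x))
  reps <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    set.seed(config$base_seed + r)
    pred <- character(n)
    for (i in seq_len(n)) {
      tr_idx <- setdiff(seq_len(n), i)
      sub <- tr_idx[balanced_subsample(y[tr_idx])]
      tries <- 0L
      while (nlevels(droplevels(y[sub])) < 2L && tries < 10L) {
        # degenerate fold: re-subsample with the (advanced) RNG stream
        message("degenerate training fold at sample ", i, "; re-subsampling")
        sub <- tr_idx[balanced_subsample(y[tr_idx])]
        tries <- tries + 1L
      }
      tr <- .fit_transform(x[sub, , drop = FALSE], config$pca_components,
                           apply_pca = use_pca)
      fit <- svm_fit(tr$xtr, y[sub], degree = config$svm_degree,
                     cost = config$svm_cost, coef0 = config$svm_coef0)
      pred[i] <- as.character(
        svm_predict(fit, .apply_transform(tr, x[i, , drop = FALSE])))
    }
    m <- compute_metrics(pred, as.character(y), positive = pos)
    reps[[r]] <- as.data.frame(m)
  }
  repeats <- do.call(rbind, reps)
  repeats$repeat_id <- seq_len(config$n_repeats)
  pooledC <- colSums(repeats[c("TP", "TN", "FP", "FN")])
  pooled <- list(
    accuracy = (pooledC["TP"] + pooledC["TN"]) / sum(pooledC),
    sensitivity = unname(pooledC["TP"] / (pooledC["TP"] + pooledC["FN"])),
    specificity = unname(pooledC["TN"] / (pooledC["TN"] + pooledC["FP"])))
  structure(list(
    repeats = repeats,
    means = list(accuracy = mean(repeats$accuracy),
                 sensitivity = mean(repeats$sensitivity),
                 specificity = mean(repeats$specificity)),
    pooled = lapply(pooled, unname),
    n = n, config = config), class = "loo_eval")
}

#' @export
print.loo_eval <- function(x, ...) {
  cat(sprintf(
    "<loo_eval> n = %d, %d repeats\n  mean accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
    x$n, nrow(x$repeats), x$means$accuracy, x$means$sensitivity,
    x$means$specificity))
  invisible(x)
}

#' Evaluate one diagnostic task end to end
#'
#' Convenience wrapper: [make_task_dataset()] then [loo_evaluate()].
#'
#' @inheritParams make_task_dataset
#' @inheritParams loo_evaluate
#' @return A `loo_eval`, with the task spec attached as `$task`.
#' @export
evaluate_task <- function(x, diagnosis, task, config = eval_config()) {
  ds <- make_task_dataset(x, diagnosis, task)
  res <- loo_evaluate(ds$x, ds$y, config)
  res$task <- ds$task
  res
}

#' Train the three cascade task models
#'
#' Fits one balanced-subsample SVM per task on the full dataset (with the
#' same standardization/PCA policy as the evaluation folds), for use with
#' [hierarchical_predict()].
#'
#' @inheritParams make_task_dataset
#' @param config An [eval_config()]; `base_seed` seeds the subsampling.
#' @return Named list of three fitted task models.
#' @export
train_task_models <- function(x, diagnosis, config = eval_config()) {
  set.seed(config$base_seed)
  lapply(diagnosis_tasks(), function(task) {
    ds <- make_task_dataset(x, diagnosis, task)
    sub <- balanced_subsample(ds$y)
    tr <- .fit_transform(ds$x[sub, , drop = FALSE], config$pca_components,
                         apply_pca = .pca_active(ds$y, ncol(ds$x)))
    fit <- svm_fit(tr$xtr, ds$y[sub], degree = config$svm_degree,
                   cost = config$svm_cost, coef0 = config$svm_coef0)
    list(task = task, transform = tr[c("center", "scale", "rotation")],
         fit = fit)
  })
}

#' Hierarchical diagnosis by the three-task cascade
#'
#' Task 1 positive means invasive; otherwise task 2 negative means benign;
#' otherwise task 3 decides DCIS vs atypia.
#'
#' @param models The three task models from [train_task_models()].
#' @param newx Feature matrix of samples to diagnose.
#' @return Character vector of diagnoses.
#' @export
hierarchical_predict <- function(models, newx) {
  need <- names(diagnosis_tasks())
  if (!all(need %in% names(models)))
    stop("`models` must contain all three task models: ",
         paste(need, collapse = ", "))
  newx <- as.matrix(newx)
  score <- function(m) {
    xs <- .apply_transform(m$transform, newx)
    svm_predict(m$fit, xs) == "positive"
  }
  p1 <- score(models$invasive_vs_noninvasive)
  p2 <- score(models$preinvasive_vs_benign)
  p3 <- score(models$dcis_vs_atypia)
  ifelse(p1, "invasive", ifelse(!p2, "benign", ifelse(p3, "dcis", "atypia")))
}
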