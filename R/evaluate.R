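## Cross-validated performance with optional down-sampling -----------------

#' Build a k-fold plan
#'
#' Partitions the rows into k folds. With `stratified = TRUE` (default)
#' each outcome class is shuffled and dealt round-robin, filling the
#' currently smallest folds first, so per-fold class counts differ by at
#' most one patient from an even split and total fold sizes are as equal
#' as possible (530 rows into 10 folds gives ten folds of 53).
#'
#' @param data data frame with the outcome column, or an outcome vector.
#' @param k number of folds (default 10, `2 <= k <= n`).
#' @param stratified stratify by outcome class.
#' @param seed integer seed.
#' @param outcome outcome column name when `data` is a data frame.
#' @return Integer vector of fold labels in `1:k`, one per row, with
#'   attributes `k`, `stratified`, `seed`.
#' @export
make_folds <- function(data, k = 10, stratified = TRUE, seed = 1L,
                       outcome = "outcome") {
  y <- if (is.data.frame(data)) data[[outcome]] else data
  n <- length(y)
  stopifnot(k >= 2, n >= k)
  set.seed(seed)
  fold <- integer(n)
  fill <- integer(k)
  groups <- if (stratified) split(seq_len(n), y) else list(seq_len(n))
  for (idx in groups) {
    idx <- idx[sample.int(length(idx))]
    ord <- order(fill, seq_len(k))   # smallest folds first, index tiebreak
    assign_to <- rep(ord, length.out = length(idx))
    fold[idx] <- assign_to
    fill <- fill + tabulate(assign_to, nbins = k)
  }
  if (length(unique(y)) > 1) {
    # a class confined to a single fold vanishes from that fold's training set
    tab <- table(fold, y)
    if (any(colSums(tab > 0) == 1))
      stop("a class is absent from some training fold; reduce k")
  }
  structure(fold, k = k, stratified = stratified, seed = seed)
}

#' Down-sample the majority class
#'
#' Subsamples the majority class without replacement to the minority-class
#' size, so the returned rows are exactly balanced. Intended for training
#' folds only; held-out folds must remain untouched. Already balanced input
#' is returned unchanged (same rows, same order).
#'
#' @param data data frame with a binary outcome column.
#' @param seed integer seed.
#' @param outcome outcome column name.
#' @return The balanced subset of `data` (original row names retained).
#' @export
downsample_training <- function(data, seed = 1L, outcome = "outcome") {
  y <- data[[outcome]]
  tab <- table(y)
  if (length(tab) < 2 || any(tab == 0))
    stop("both outcome classes must be present")
  if (tab[1] == tab[2]) return(data)
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  set.seed(seed)
  keep_maj <- sample(which(y == majority), min(tab))
  keep <- sort(c(which(y == minority), keep_maj))
  data[keep, , drop = FALSE]
}

#' Rank-statistic (Mann-Whitney) AUC with tie correction
#'
#' `AUC = (sum of positive-class midranks - n1 (n1 + 1) / 2) / (n1 n0)`;
#' ties receive average ranks, making the estimate invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores numeric predicted scores.
#' @param labels binary labels (1 = positive/severe).
#' @return AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

classification_metrics <- function(prob, y, threshold = 0.5) {
  pred <- as.integer(prob >= threshold)
  c(accuracy = mean(pred == y),
    sensitivity = if (any(y == 1)) mean(pred[y == 1] == 1) else NA_real_,
    specificity = if (any(y == 0)) mean(pred[y == 0] == 0) else NA_real_,
    auc = auc_rank(prob, y))
}

#' k-fold cross-validated performance
#'
#' Fits the ensemble on k-1 folds (optionally down-sampling the majority
#' class of the training rows) and scores the held-out fold: accuracy at a
#' probability threshold of 0.5, sensitivity (recall of the severe class),
#' specificity, and the rank-statistic AUC. Metrics are averaged over
#' folds; a held-out fold containing a single class has no defined AUC and
#' is excluded from the AUC average with a warning. A pooled AUC over all
#' held-out predictions is also reported. Down-sampling and fitting touch
#' training rows only.
#'
#' @param data data frame of predictors plus outcome.
#' @param config a [gbt_config()].
#' @param folds optional fold labels from [make_folds()]; built from
#'   `k` and `seed` when absent.
#' @param k,seed fold plan parameters when `folds` is `NULL`; `seed` also
#'   drives per-fold down-sampling and fitting substreams.
#' @param balance `"none"` or `"downsample"`.
#' @param threshold classification threshold on P(severe).
#' @param outcome outcome column name.
#' @return Object of class `gbt_cv`: `per_fold` data frame, `summary`
#'   (fold-averaged metrics), `pooled_auc`, `balance`, `threshold`,
#'   and `predictions` (row, fold, prob, y).
#' @export
cross_validate <- function(data, config = gbt_config(), folds = NULL,
                           k = 10, balance = c("none", "downsample"),
                           threshold = 0.5, seed = 1L, outcome = "outcome") {
  balance <- match.arg(balance)
  y_all <- data[[outcome]]
  if (is.character(y_all) || is.factor(y_all))
    y_all <- as.integer(as.character(y_all) == "severe")
  if (is.null(folds)) folds <- make_folds(data, k = k, seed = seed,
                                          outcome = outcome)
  k <- max(folds)
  per_fold <- vector("list", k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    train <- data[folds != f, , drop = FALSE]
    test <- data[folds == f, , drop = FALSE]
    if (balance == "downsample")
      train <- downsample_training(train,
                                   seed = substream_seed(seed, paste0("ds", f)),
                                   outcome = outcome)
    cfg <- config; cfg$seed <- substream_seed(seed, paste0("fit", f))
    ens <- fit_gbt(train, cfg, outcome = outcome)
    prob <- predict(ens, test[, setdiff(names(test), outcome),
                              drop = FALSE], type = "prob")
    y <- y_all[folds == f]
    m <- classification_metrics(prob, y, threshold)
    per_fold[[f]] <- data.frame(fold = f, n_test = nrow(test), t(m))
    preds[[f]] <- data.frame(row = which(folds == f), fold = f,
                             prob = prob, y = y)
  }
  per_fold <- do.call(rbind, per_fold)
  preds <- do.call(rbind, preds)
  if (anyNA(per_fold$auc))
    warning(sum(is.na(per_fold$auc)),
            " fold(s) held out a single class; excluded from the AUC average")
  summary <- c(accuracy = mean(per_fold$accuracy),
               sensitivity = mean(per_fold$sensitivity, na.rm = TRUE),
               specificity = mean(per_fold$specificity, na.rm = TRUE),
               auc = mean(per_fold$auc, na.rm = TRUE))
  structure(list(per_fold = per_fold, summary = summary,
                 pooled_auc = auc_rank(preds$prob, preds$y),
                 balance = balance, threshold = threshold,
                 predictions = preds),
            class = "gbt_cv")
}

#' @export
print.gbt_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (balance: %s, threshold %.2f)\n",
              max(x$per_fold$fold), x$balance, x$threshold))
  cat(sprintf("  accuracy %.3f  sensitivity %.3f  specificity %.3f  AUC %.3f (pooled %.3f)\n",
              x$summary["accuracy"], x$summary["sensitivity"],
              x$summary["specificity"], x$summary["auc"], x$pooled_auc))
  invisible(x)
}

#' ROC curve points from cross-validated predictions
#'
#' Sweeps the classification threshold over the pooled held-out
#' predictions of a [cross_validate()] run.
#'
#' @param cv a `gbt_cv` object.
#' @param path optional CSV path (`threshold`, `tpr`, `fpr`).
#' @return A `data.frame` with one row per distinct threshold.
#' @export
roc_points <- function(cv, path = NULL) {
  p <- cv$predictions
  th <- sort(unique(c(0, p$prob, 1)), decreasing = TRUE)
  out <- do.call(rbind, lapply(th, function(t) {
    pred <- p$prob >= t
    data.frame(threshold = t,
               tpr = mean(pred[p$y == 1]),
               fpr = mean(pred[p$y == 0]))
  }))
  if (!is.null(path)) write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}

#' Select the number of trees by cross-validated deviance
#'
#' Fits the full-`n_trees` ensemble on each training split and evaluates
#' the staged held-out Bernoulli deviance; the selected size `M*` is the
#' stage minimising the fold-averaged deviance (0 = intercept only; ties
#' resolved to the smallest stage). `config$n_trees` is the search
#' ceiling.
#'
#' @inheritParams cross_validate
#' @return Object of class `gbt_m_selection`: `best_m`, `cv_deviance`
#'   (length `n_trees + 1`, stage 0 first), `per_fold` deviance matrix.
#' @export
select_n_trees <- function(data, config = gbt_config(), folds = NULL,
                           k = 10, seed = 1L, outcome = "outcome") {
  if (is.null(folds)) folds <- make_folds(data, k = k, seed = seed,
                                          outcome = outcome)
  k <- max(folds)
  dev <- matrix(NA_real_, k, config$n_trees + 1)
  for (f in seq_len(k)) {
    train <- data[folds != f, , drop = FALSE]
    test <- data[folds == f, , drop = FALSE]
    cfg <- config; cfg$seed <- substream_seed(seed, paste0("fit", f))
    ens <- fit_gbt(train, cfg, outcome = outcome)
    dev[f, ] <- staged_deviance(ens, test, outcome = outcome)
  }
  mean_dev <- colMeans(dev)
  best_m <- which.min(mean_dev) - 1L   # which.min takes the first minimum
  structure(list(best_m = best_m, cv_deviance = mean_dev, per_fold = dev),
            class = "gbt_m_selection")
}

#' @export
print.gbt_m_selection <- function(x, ...) {
  cat(sprintf("Selected %d trees (held-out deviance %.4f; intercept-only %.4f)\n",
              x$best_m, min(x$cv_deviance), x$cv_deviance[1]))
  invisible(x)
}
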