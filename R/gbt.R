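## Gradient boosted trees for a binary outcome (Bernoulli deviance) --------

#' Training configuration for the boosted ensemble
#'
#' Hyperparameters of [fit_gbt()]. Defaults: 100 trees, shrinkage 0.01,
#' depth 2 (so pairwise interactions are expressible), minimum terminal node
#' size 10, bag fraction 0.5. The number of trees is best chosen by
#' cross-validated deviance via [select_n_trees()].
#'
#' @param n_trees number of boosting iterations M (>= 1).
#' @param shrinkage learning rate in (0, 1].
#' @param max_depth maximum number of split levels per tree (1 = stumps).
#' @param min_node_size minimum observations per terminal node.
#' @param bag_fraction fraction of training rows subsampled (without
#'   replacement) per tree; 1 disables subsampling and makes the fit
#'   RNG-free.
#' @param seed integer seed for the subsampling stream.
#' @return An object of class `gbt_config`.
#' @export
gbt_config <- function(n_trees = 100, shrinkage = 0.01, max_depth = 2,
                       min_node_size = 10, bag_fraction = 0.5, seed = 1L) {
  stopifnot(n_trees >= 1, shrinkage > 0, shrinkage <= 1, max_depth >= 1,
            min_node_size >= 1, bag_fraction > 0, bag_fraction <= 1)
  structure(list(n_trees = as.integer(n_trees), shrinkage = shrinkage,
                 max_depth = as.integer(max_depth),
                 min_node_size = as.integer(min_node_size),
                 bag_fraction = bag_fraction, seed = as.integer(seed)),
            class = "gbt_config")
}

# Extract the numeric predictor matrix and 0/1 outcome from a data frame.
gbt_xy <- function(data, outcome) {
  if (!outcome %in% names(data)) stop("outcome column not found: ", outcome)
  y <- data[[outcome]]
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "severe")
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2)
    stop("outcome has a single class; both classes are required")
  feats <- setdiff(names(data), outcome)
  X <- as.matrix(data[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing predictor values are not supported")
  list(X = X, y = y, features = feats)
}

#' Construct a boosted ensemble object
#'
#' Low-level constructor, exported so that ensembles can be built by hand
#' (e.g. audit fixtures encoding a known margin function). Each tree is a
#' numeric matrix with one row per node and columns `feature` (1-based
#' index into `feature_names`, 0 for a leaf), `threshold` (descend left
#' when `x <= threshold`), `value` (leaf log-odds contribution), `left`,
#' `right` (1-based node rows, 0 for none) and `improvement` (squared-error
#' reduction of the split).
#'
#' @param intercept log-odds intercept F0.
#' @param shrinkage learning rate applied to every tree's contribution.
#' @param trees list of node matrices.
#' @param feature_names character vector naming the predictor columns.
#' @param config optional [gbt_config()] stored for provenance.
#' @return An object of class `gbt_ensemble`.
#' @export
gbt_ensemble <- function(intercept, shrinkage, trees, feature_names,
                         config = NULL) {
  for (T in trees) {
    stopifnot(is.matrix(T), ncol(T) == 6)
    leaf <- T[, 1] == 0
    if (any(T[, 6] < 0)) stop("split improvements must be non-negative")
    if (any(!is.finite(T[leaf, 3]))) stop("leaf values must be finite")
  }
  structure(list(intercept = intercept, shrinkage = shrinkage,
                 trees = trees, feature_names = feature_names,
                 config = config),
            class = "gbt_ensemble")
}

#' Fit a gradient boosted tree ensemble
#'
#' Stagewise fit for a binary outcome under Bernoulli deviance. The
#' intercept is the log-odds of the training prevalence; each iteration
#' fits a depth-limited least-squares regression tree to the pseudo-
#' residuals `y - p`, replaces every terminal value by the one-step Newton
#' estimate `sum(y - p) / sum(p (1 - p))` over its training points, and
#' adds `shrinkage * tree` to the model. Split search is exhaustive over
#' midpoints of sorted unique values, with ties broken by lowest feature
#' index then lowest threshold, so refits are deterministic given the seed.
#' Every split records its squared-error improvement, the quantity the
#' relative-importance measure aggregates.
#'
#' @param data data frame of numeric predictors plus the outcome column
#'   (0/1 or `"mild"`/`"severe"`). Missing predictor values are rejected.
#' @param config a [gbt_config()].
#' @param outcome name of the outcome column.
#' @return A [gbt_ensemble()] with `feature_names` in `data`'s column
#'   order.
#' @seealso [predict.gbt_ensemble()], [staged_deviance()],
#'   [relative_importance()]
#' @export
#' @examples
#' d <- cohort_model_frame(generate_cohort(cohort_spec(seed = 3)))
#' ens <- fit_gbt(d, gbt_config(n_trees = 20, shrinkage = 0.1))
#' head(predict(ens, d))
fit_gbt <- function(data, config = gbt_config(), outcome = "outcome") {
  stopifnot(inherits(config, "gbt_config"))
  xy <- gbt_xy(data, outcome)
  set.seed(config$seed)
  fit <- fit_gbt_cpp(xy$X, xy$y, config$n_trees, config$max_depth,
                     config$shrinkage, config$min_node_size,
                     config$bag_fraction)
  gbt_ensemble(fit$intercept, config$shrinkage, fit$trees, xy$features,
               config = config)
}

ensemble_matrix <- function(ensemble, newdata) {
  miss <- setdiff(ensemble$feature_names, names(newdata))
  if (length(miss))
    stop("newdata lacks required features: ", paste(miss, collapse = ", "))
  X <- as.matrix(newdata[, ensemble$feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing predictor values are not supported")
  X
}

#' Predict from a boosted ensemble
#'
#' @param object a [gbt_ensemble()].
#' @param newdata data frame containing every feature used by the model.
#' @param type `"prob"` for P(severe) or `"margin"` for the log-odds
#'   `F0 + shrinkage * sum of tree outputs`.
#' @param ... unused.
#' @return Numeric vector.
#' @export
predict.gbt_ensemble <- function(object, newdata,
                                 type = c("prob", "margin"), ...) {
  type <- match.arg(type)
  X <- ensemble_matrix(object, newdata)
  m <- predict_margin_cpp(object$trees, object$intercept, object$shrinkage, X)
  if (type == "margin") m else logistic(m)
}

#' @export
print.gbt_ensemble <- function(x, ...) {
  cat("Gradient boosted tree ensemble\n")
  cat(sprintf("  trees: %d  shrinkage: %g  intercept (log-odds): %.4f\n",
              length(x$trees), x$shrinkage, x$intercept))
  cat(sprintf("  features: %s\n", paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' Mean Bernoulli deviance of an ensemble per boosting stage
#'
#' Returns the length-`M + 1` sequence of mean deviances
#' `-2 mean(y log p + (1 - y) log(1 - p))` after 0 (intercept only),
#' 1, ..., M trees. Probabilities are clipped to `[1e-12, 1 - 1e-12]`
#' before taking logs.
#'
#' @param ensemble a [gbt_ensemble()].
#' @param data data frame with the features and outcome.
#' @param outcome outcome column name.
#' @return Numeric vector of length `n_trees + 1`.
#' @export
staged_deviance <- function(ensemble, data, outcome = "outcome") {
  xy <- gbt_xy(data, outcome)
  M <- staged_margins(ensemble, data)
  apply(M, 2, function(m) bernoulli_deviance(xy$y, logistic(m)))
}

#' Staged margins of an ensemble
#'
#' The `n x (n_trees + 1)` matrix of log-odds predictions after 0
#' (intercept only), 1, ..., M trees — the trace [staged_deviance()] and
#' [select_n_trees()] are built on.
#'
#' @inheritParams staged_deviance
#' @return Numeric matrix.
#' @export
staged_margins <- function(ensemble, data, outcome = "outcome") {
  X <- ensemble_matrix(ensemble, data)
  staged_margin_cpp(ensemble$trees, ensemble$intercept,
                    ensemble$shrinkage, X)
}

bernoulli_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Serialise an ensemble to JSON / restore it
#'
#' Stores the intercept, shrinkage, feature names, training configuration
#' and every tree's node table (feature, threshold, value, children,
#' improvement) so a fit can be archived and reloaded reproducibly.
#'
#' @param ensemble a [gbt_ensemble()].
#' @param path JSON file path.
#' @return `write_ensemble_json` returns `path` invisibly;
#'   `read_ensemble_json` returns the restored [gbt_ensemble()].
#' @export
write_ensemble_json <- function(ensemble, path) {
  obj <- list(intercept = ensemble$intercept,
              shrinkage = ensemble$shrinkage,
              feature_names = ensemble$feature_names,
              config = unclass(ensemble$config),
              trees = lapply(ensemble$trees, function(T) {
                colnames(T) <- c("feature", "threshold", "value",
                                 "left", "right", "improvement")
                as.data.frame(T)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_ensemble_json
#' @export
read_ensemble_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trees <- lapply(obj$trees, function(d) {
    T <- as.matrix(d[, c("feature", "threshold", "value", "left", "right",
                         "improvement")])
    dimnames(T) <- NULL
    T
  })
  cfg <- if (!is.null(obj$config))
    do.call(gbt_config, obj$config[c("n_trees", "shrinkage", "max_depth",
                                     "min_node_size", "bag_fraction",
                                     "seed")])
  gbt_ensemble(obj$intercept, obj$shrinkage, trees, obj$feature_names,
               config = cfg)
}
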