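## Friedman relative importance, partial dependence, pairwise H-statistic --

#' Relative importance of each predictor
#'
#' Friedman's measure for boosted trees: for each variable, the sum over
#' all splits on that variable of the squared-error improvement the split
#' achieved, averaged over trees; the raw values are then normalised so the
#' largest equals 100. A variable never selected for splitting has
#' importance exactly 0.
#'
#' @param ensemble a fitted [gbt_ensemble()] with at least one tree.
#' @return A `data.frame` of class `gbt_importance` with columns
#'   `variable`, `raw` (mean summed squared improvement) and `relative`
#'   (scaled to max 100), sorted by decreasing importance.
#' @export
#' @examples
#' d <- cohort_model_frame(generate_cohort(cohort_spec(seed = 3)))
#' ens <- fit_gbt(d, gbt_config(n_trees = 30, shrinkage = 0.1))
#' relative_importance(ens)
relative_importance <- function(ensemble) {
  stopifnot(inherits(ensemble, "gbt_ensemble"))
  M <- length(ensemble$trees)
  if (M == 0) stop("ensemble has no trees")
  p <- length(ensemble$feature_names)
  raw <- setNames(numeric(p), ensemble$feature_names)
  for (T in ensemble$trees) {
    sp <- T[, 1] > 0
    if (any(sp)) {
      agg <- tapply(T[sp, 6], T[sp, 1], sum)
      idx <- as.integer(names(agg))
      raw[idx] <- raw[idx] + agg
    }
  }
  raw <- raw / M
  if (max(raw) > 0) {
    rel <- 100 * raw / max(raw)
  } else {
    warning("no splits in the ensemble; all importances are zero")
    rel <- raw
  }
  out <- data.frame(variable = names(raw), raw = unname(raw),
                    relative = unname(rel))
  out <- out[order(-out$raw, out$variable), ]
  rownames(out) <- NULL
  class(out) <- c("gbt_importance", "data.frame")
  out
}

# Unique rows of data[, vars] with empirical frequencies, plus the map from
# data rows back to grid rows.
observed_grid <- function(data, vars) {
  key <- do.call(paste, c(data[vars], sep = "\r"))
  u <- !duplicated(key)
  grid <- as.matrix(data[u, vars, drop = FALSE])
  storage.mode(grid) <- "double"
  rowmap <- match(key, key[u])
  w <- tabulate(rowmap, nbins = nrow(grid))
  list(grid = grid, rowmap = rowmap, weight = w / length(rowmap))
}

#' Partial dependence of the model margin
#'
#' Friedman's partial dependence on the log-odds scale: the value at a
#' point `v` is the mean over the data rows of the ensemble margin with the
#' target variables overwritten by `v`. By default the evaluation points
#' are the observed values of the target variables (weighted by empirical
#' frequency), and the returned values are centred to weighted mean zero.
#'
#' @param ensemble a [gbt_ensemble()].
#' @param vars one or two distinct feature names.
#' @param data data frame supplying both the background distribution and
#'   (by default) the evaluation points.
#' @param grid optional matrix/data.frame of evaluation points (one column
#'   per variable in `vars`); when supplied, values are centred with equal
#'   weights.
#' @return A `data.frame` with the evaluation points, their `weight`, and
#'   the centred partial dependence `pd`.
#' @export
partial_dependence <- function(ensemble, vars, data, grid = NULL) {
  stopifnot(inherits(ensemble, "gbt_ensemble"),
            length(vars) %in% c(1, 2), !anyDuplicated(vars))
  miss <- setdiff(vars, ensemble$feature_names)
  if (length(miss)) stop("unknown variable: ", paste(miss, collapse = ", "))
  X <- ensemble_matrix(ensemble, data)
  cols <- match(vars, ensemble$feature_names)
  if (is.null(grid)) {
    og <- observed_grid(data, vars)
    g <- og$grid; w <- og$weight
  } else {
    g <- as.matrix(grid); storage.mode(g) <- "double"
    w <- rep(1 / nrow(g), nrow(g))
  }
  pd <- pd_margin_cpp(ensemble$trees, ensemble$intercept,
                      ensemble$shrinkage, X, as.integer(cols), g)
  pd <- pd - sum(pd * w)
  out <- as.data.frame(g)
  names(out) <- vars
  out$weight <- w
  out$pd <- pd
  out
}

# Row-level centred partial-dependence values for the H-statistic: one
# value per data row, centred to mean zero over rows.
pd_rowwise <- function(ensemble, vars, data, X, cols) {
  og <- observed_grid(data, vars)
  pd <- pd_margin_cpp(ensemble$trees, ensemble$intercept,
                      ensemble$shrinkage, X, as.integer(cols), og$grid)
  v <- pd[og$rowmap]
  v - mean(v)
}

#' Friedman-Popescu pairwise interaction H-statistic
#'
#' Measures the interaction strength between two predictors as the share of
#' the two-way partial-dependence variance not explained additively:
#' `H^2 = sum_i (F_jk(x_ij, x_ik) - F_j(x_ij) - F_k(x_ik))^2 /
#'        sum_i F_jk(x_ij, x_ik)^2`,
#' with all partial dependences centred and the sums running over the
#' observed data points. The reported statistic is `H = sqrt(H^2)`, clipped
#' into `[0, 1]` (tiny negative numerators from floating-point cancellation
#' are truncated). For an additive model (e.g. depth-1 trees) H is 0; a
#' pure interaction with vanishing marginal effects gives H of 1. A zero
#' denominator (the pair never influences the model) yields `H = 0` with
#' `degenerate = TRUE`.
#'
#' @param ensemble a [gbt_ensemble()].
#' @param j,k distinct feature names.
#' @param data data frame of observed points.
#' @param squared return `H^2` in `$statistic` instead of H (default
#'   `FALSE`, the convention matching published HFMD interaction values).
#' @return An object of class `gbt_interaction`: list with `pair`, `h`,
#'   `h_squared`, `statistic`, `numerator`, `denominator`, `degenerate`.
#' @export
h_statistic <- function(ensemble, j, k, data, squared = FALSE) {
  if (identical(j, k)) stop("j and k must be distinct features")
  X <- ensemble_matrix(ensemble, data)
  cj <- match(j, ensemble$feature_names)
  ck <- match(k, ensemble$feature_names)
  if (is.na(cj) || is.na(ck)) stop("unknown variable in pair")
  fj <- pd_rowwise(ensemble, j, data, X, cj)
  fk <- pd_rowwise(ensemble, k, data, X, ck)
  fjk <- pd_rowwise(ensemble, c(j, k), data, X, c(cj, ck))
  num <- sum((fjk - fj - fk)^2)
  den <- sum(fjk^2)
  degenerate <- den < 1e-300
  h2 <- if (degenerate) 0 else max(num, 0) / den
  h <- min(sqrt(h2), 1)
  structure(list(pair = c(j, k), h = h, h_squared = min(h2, 1),
                 statistic = if (squared) min(h2, 1) else h,
                 numerator = num, denominator = den,
                 degenerate = degenerate),
            class = "gbt_interaction")
}

#' @export
print.gbt_interaction <- function(x, ...) {
  cat(sprintf("H(%s, %s) = %.4f%s\n", x$pair[1], x$pair[2], x$h,
              if (x$degenerate) " (degenerate: zero denominator)" else ""))
  invisible(x)
}

#' Export a gridded two-way partial-dependence surface
#'
#' Evaluates the centred two-way partial dependence of a pair on a regular
#' grid (binary variables contribute {0, 1}; continuous variables an
#' evenly spaced grid over their observed range), suitable for CSV export
#' and interaction-surface plots. Centring is to equal-weight mean zero
#' over the grid cells.
#'
#' @param ensemble a [gbt_ensemble()].
#' @param j,k distinct feature names.
#' @param data data frame of observed points (background distribution).
#' @param n_grid grid points per continuous axis.
#' @param path optional CSV path; written when supplied.
#' @return A `data.frame` with columns `j`, `k` values and `pd`.
#' @export
export_interaction_surface <- function(ensemble, j, k, data, n_grid = 20,
                                       path = NULL) {
  if (identical(j, k)) stop("j and k must be distinct features")
  axis_points <- function(v) {
    x <- data[[v]]
    if (all(x %in% c(0, 1))) c(0, 1)
    else seq(min(x), max(x), length.out = n_grid)
  }
  grid <- expand.grid(axis_points(j), axis_points(k),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- c(j, k)
  out <- partial_dependence(ensemble, c(j, k), data, grid = grid)
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  out
}
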