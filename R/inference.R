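## Permutation tests and bootstrap confidence intervals --------------------

#' Add-one permutation p-value
#'
#' Rank of the observed statistic among the null draws with the add-one
#' rule: `p = (1 + #(null >= observed)) / (1 + B)`. Ties count as at least
#' as extreme, so the p-value is never 0 and equals 1 when every null draw
#' ties or exceeds the observed value.
#'
#' @param observed observed statistic.
#' @param nulls numeric vector of B null-draw statistics.
#' @return p-value in `(0, 1]`.
#' @export
#' @examples
#' permutation_pvalue(5, rep(1, 99))   # 0.01
permutation_pvalue <- function(observed, nulls) {
  (1 + sum(nulls >= observed)) / (1 + length(nulls))
}

# Derived seed vectors: one stream for the label permutations, one for the
# ensemble refits (fresh fitting randomness keeps the observed statistic
# and the null draws exchangeable under the null).
inference_seeds <- function(seed, B) {
  set.seed(seed)
  list(fit = sample.int(2147483646L, B + 1),
       perm = sample.int(2147483646L, B),
       retry = sample.int(2147483646L, B))
}

refit_with_retry <- function(data, config, outcome, fit_seed, retry_seed) {
  cfg <- config; cfg$seed <- fit_seed
  tryCatch(fit_gbt(data, cfg, outcome = outcome), error = function(e) {
    message("refit failed (", conditionMessage(e), "); retrying with next substream")
    cfg$seed <- retry_seed
    fit_gbt(data, cfg, outcome = outcome)
  })
}

#' Outcome-permutation test for variable importance
#'
#' Tests, per predictor, whether its raw importance exceeds what arises
#' with no predictor-outcome association: for each of B permutations the
#' outcome labels are shuffled (predictors fixed), the ensemble is refitted
#' with the same hyperparameters and a permutation-specific fitting seed,
#' and each variable's raw importance is recorded; the add-one rank rule
#' gives the p-value. Everything is deterministic given `seed`.
#'
#' @param data data frame of predictors plus outcome.
#' @param config a [gbt_config()] used for the observed fit and every
#'   refit.
#' @param B number of permutations (>= 19; 999 is a sensible default for
#'   reporting, smaller values for simulation studies).
#' @param seed master seed for permutations and refits.
#' @param outcome outcome column name.
#' @return Object of class `gbt_perm_importance`: data frame `results`
#'   (`variable`, `observed` raw importance, `p_value`), the `B x p` null
#'   matrix, `B` and `seed`.
#' @export
permutation_test_importance <- function(data, config = gbt_config(),
                                        B = 999, seed = 1L,
                                        outcome = "outcome") {
  stopifnot(B >= 19)
  sds <- inference_seeds(seed, B)
  obs_ens <- refit_with_retry(data, config, outcome, sds$fit[1], sds$retry[1])
  obs_imp <- relative_importance(obs_ens)
  obs <- setNames(obs_imp$raw, obs_imp$variable)[
    setdiff(names(data), outcome)]
  nulls <- matrix(NA_real_, B, length(obs),
                  dimnames = list(NULL, names(obs)))
  perm_data <- data
  for (b in seq_len(B)) {
    set.seed(sds$perm[b])
    perm_data[[outcome]] <- sample(data[[outcome]])
    ens_b <- refit_with_retry(perm_data, config, outcome,
                              sds$fit[b + 1], sds$retry[b])
    imp_b <- relative_importance(ens_b)
    nulls[b, ] <- setNames(imp_b$raw, imp_b$variable)[colnames(nulls)]
  }
  p <- vapply(names(obs), function(v) permutation_pvalue(obs[[v]], nulls[, v]),
              numeric(1))
  structure(list(results = data.frame(variable = names(obs),
                                      observed = unname(obs),
                                      p_value = unname(p)),
                 nulls = nulls, B = B, seed = seed),
            class = "gbt_perm_importance")
}

#' Outcome-permutation test for a pairwise H-statistic
#'
#' Same permutation engine as [permutation_test_importance()] with the
#' test statistic `H(j, k)` computed on each refitted ensemble at the
#' original predictor values.
#'
#' @inheritParams permutation_test_importance
#' @param j,k distinct feature names.
#' @return Object of class `gbt_perm_h`: `observed` H, `nulls` (length B),
#'   `p_value`, `pair`, `B`, `seed`.
#' @export
permutation_test_h <- function(data, config = gbt_config(), j, k,
                               B = 999, seed = 1L, outcome = "outcome") {
  stopifnot(B >= 19)
  if (identical(j, k)) stop("j and k must be distinct features")
  sds <- inference_seeds(seed, B)
  feats <- data[, setdiff(names(data), outcome), drop = FALSE]
  obs_ens <- refit_with_retry(data, config, outcome, sds$fit[1], sds$retry[1])
  obs <- h_statistic(obs_ens, j, k, feats)$statistic
  nulls <- numeric(B)
  perm_data <- data
  for (b in seq_len(B)) {
    set.seed(sds$perm[b])
    perm_data[[outcome]] <- sample(data[[outcome]])
    ens_b <- refit_with_retry(perm_data, config, outcome,
                              sds$fit[b + 1], sds$retry[b])
    nulls[b] <- h_statistic(ens_b, j, k, feats)$statistic
  }
  structure(list(observed = obs, nulls = nulls,
                 p_value = permutation_pvalue(obs, nulls),
                 pair = c(j, k), B = B, seed = seed),
            class = "gbt_perm_h")
}

#' Percentile-bootstrap confidence interval for a pairwise H-statistic
#'
#' Resamples cohort rows with replacement, refits the ensemble and
#' recomputes `H(j, k)` on each resample; the interval is the nearest-rank
#' percentile interval at the requested level (for `B_boot = 1000` and
#' level 0.95: the 25th and 976th order statistics), with the lower bound
#' floored at 0 — which is how published intervals with a lower bound of
#' exactly 0 arise. A degenerate resample with a single outcome class is
#' redrawn from the next substream (with a message).
#'
#' @inheritParams permutation_test_h
#' @param B_boot number of bootstrap resamples (>= 100).
#' @param level confidence level (default 0.95).
#' @return Object of class `gbt_bootstrap_ci`: `observed`, `lower`,
#'   `upper`, `level`, `draws`, `B_boot`, `seed`.
#' @export
bootstrap_ci_h <- function(data, config = gbt_config(), j, k,
                           B_boot = 1000, level = 0.95, seed = 1L,
                           outcome = "outcome") {
  stopifnot(B_boot >= 100, level > 0, level < 1)
  set.seed(seed)
  boot_seeds <- sample.int(2147483646L, 2 * B_boot)
  fit_seeds <- sample.int(2147483646L, B_boot + 1)
  cfg <- config; cfg$seed <- fit_seeds[B_boot + 1]
  obs_ens <- fit_gbt(data, cfg, outcome = outcome)
  obs <- h_statistic(obs_ens, j, k,
                     data[, setdiff(names(data), outcome), drop = FALSE])$statistic
  n <- nrow(data)
  draws <- numeric(B_boot)
  si <- 0
  for (b in seq_len(B_boot)) {
    repeat {
      si <- si + 1
      if (si > length(boot_seeds)) {  # extend the substream if exhausted
        set.seed(substream_seed(seed, paste0("extend", si)))
        boot_seeds <- c(boot_seeds, sample.int(2147483646L, B_boot))
      }
      set.seed(boot_seeds[si])
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(data[[outcome]][idx])) > 1) break
      message("degenerate bootstrap resample (single class); redrawing")
    }
    d_b <- data[idx, , drop = FALSE]
    cfg$seed <- fit_seeds[b]
    ens_b <- fit_gbt(d_b, cfg, outcome = outcome)
    draws[b] <- h_statistic(ens_b, j, k,
                            d_b[, setdiff(names(d_b), outcome),
                                drop = FALSE])$statistic
  }
  s <- sort(draws)
  lo_idx <- max(1L, floor((1 - level) / 2 * B_boot))
  hi_idx <- B_boot - lo_idx + 1L
  structure(list(observed = obs, lower = max(0, s[lo_idx]),
                 upper = s[hi_idx], level = level, draws = draws,
                 B_boot = B_boot, seed = seed, pair = c(j, k)),
            class = "gbt_bootstrap_ci")
}

#' @export
print.gbt_perm_importance <- function(x, ...) {
  cat(sprintf("Outcome-permutation importance test (B = %d)\n", x$B))
  r <- x$results[order(-x$results$observed), ]
  r$p <- format_p_value(r$p_value)
  print(r[, c("variable", "observed", "p")], row.names = FALSE)
  invisible(x)
}

#' @export
print.gbt_bootstrap_ci <- function(x, ...) {
  cat(sprintf("H(%s, %s) = %.3f, %d%% CI: %.3f-%.3f (B = %d)\n",
              x$pair[1], x$pair[2], x$observed, round(100 * x$level),
              x$lower, x$upper, x$B_boot))
  invisible(x)
}
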