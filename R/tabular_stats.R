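## Group-comparison statistics for 2x2 tables and summary-level t-tests ----

#' Pearson chi-square test for a 2x2 table
#'
#' Computes the Pearson chi-square statistic without continuity correction,
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, its upper-tail p-value on 1
#' degree of freedom, and the odds ratio `ad / bc`. The uncorrected Pearson
#' test is the default because it reproduces published mild/severe HFMD
#' comparison p-values at printed precision; Fisher's exact test is
#' available as an alternative.
#'
#' @param a,b,c,d cell counts: group-1 positive/negative, group-2
#'   positive/negative. A length-4 vector may be passed as `a`.
#' @param method `"pearson"` (default, no continuity correction) or
#'   `"fisher"` (exact test; statistic reported as `NA`).
#' @return A list with `statistic`, `p_value` and `odds_ratio`
#'   (`Inf` when `bc = 0` with `ad > 0`, `0` when `ad = 0` with `bc > 0`,
#'   `NaN` when both vanish — flagged, never an error).
#' @export
#' @examples
#' chi_square_2x2(8, 337, 14, 171)   # p = 0.004 at 3 dp
chi_square_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                           method = c("pearson", "fisher")) {
  method <- match.arg(method)
  if (is.null(b)) { d <- a[4]; c <- a[3]; b <- a[2]; a <- a[1] }
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("2x2 table has a zero margin")
  if (method == "fisher") {
    ft <- stats::fisher.test(m)
    stat <- NA_real_
    p <- ft$p.value
  } else {
    n <- sum(counts)
    stat <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  or <- if (b * c == 0 && a * d == 0) NaN
        else if (b * c == 0) Inf
        else (a * d) / (b * c)
  list(statistic = stat, p_value = p, odds_ratio = or)
}

#' Column percentage, rounded half-up to one decimal
#'
#' `100 * count / group_size`, rounded half-up (so 57.25 -> 57.3) to match
#' the convention of published "n (%)" table cells.
#'
#' @param count,group_size non-negative count and positive group size with
#'   `count <= group_size`.
#' @return The percentage, one decimal place.
#' @export
#' @examples
#' percent_of_group(126, 185)  # 68.1
percent_of_group <- function(count, group_size) {
  if (any(group_size <= 0)) stop("group_size must be positive")
  if (any(count < 0 | count > group_size))
    stop("count must lie in [0, group_size]")
  floor(1000 * count / group_size + 0.5) / 10
}

#' Two-sample t-test from summary statistics
#'
#' Computes both the pooled-variance and the Welch (Satterthwaite) variants
#' of the two-sample t-test from group sizes, means and SDs only. Both are
#' reported because published tables rarely identify which was used.
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 per-group size, mean, SD.
#' @return A list with elements `pooled` and `welch`, each a list of
#'   `t`, `df`, `p_value`.
#' @export
#' @examples
#' summary_t_test(345, 27.1, 17.8, 185, 28.4, 22.9)$welch$p_value  # ~0.50
summary_t_test <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  diff <- mean1 - mean2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t_p <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
  df_p <- n1 + n2 - 2
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t_w <- diff / sqrt(v1 + v2)
  df_w <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  two_sided <- function(t, df) 2 * pt(-abs(t), df)
  list(pooled = list(t = t_p, df = df_p, p_value = two_sided(t_p, df_p)),
       welch = list(t = t_w, df = df_w, p_value = two_sided(t_w, df_w)))
}

#' Render a p-value the way clinical tables print it
#'
#' Three decimals, with values below 0.0005 rendered as `"<0.001"`.
#'
#' @param p numeric p-value(s).
#' @return Character vector.
#' @export
format_p_value <- function(p) {
  ifelse(p < 5e-4, "<0.001", sprintf("%.3f", floor(p * 1000 + 0.5) / 1000))
}

#' Group-comparison table for a cohort
#'
#' Builds a mild-vs-severe comparison table in the layout of published
#' cohort descriptions: binary predictors as "n (percent)" per group with
#' an uncorrected Pearson chi-square p-value, continuous predictors as
#' "mean +/- SD" with a Welch t-test p-value.
#'
#' @param cohort an `hfmd_cohort` data frame.
#' @param thresholds a [clinical_thresholds()] object.
#' @return A `data.frame` with columns `variable`, `mild`, `severe`, `p`.
#' @export
cohort_group_table <- function(cohort, thresholds = clinical_thresholds()) {
  mf <- cohort_model_frame(cohort, thresholds)
  sev <- mf$outcome == 1
  n_m <- sum(!sev); n_s <- sum(sev)
  rows <- list()
  for (v in model_features) {
    x <- mf[[v]]
    if (all(x %in% c(0, 1))) {
      a <- sum(x[!sev]); cc <- sum(x[sev])
      p <- tryCatch(chi_square_2x2(a, n_m - a, cc, n_s - cc)$p_value,
                    error = function(e) NA_real_)
      rows[[v]] <- data.frame(
        variable = v,
        mild = sprintf("%d (%.1f%%)", a, percent_of_group(a, n_m)),
        severe = sprintf("%d (%.1f%%)", cc, percent_of_group(cc, n_s)),
        p = if (is.na(p)) NA_character_ else format_p_value(p))
    } else {
      tt <- summary_t_test(n_m, mean(x[!sev]), stats::sd(x[!sev]),
                           n_s, mean(x[sev]), stats::sd(x[sev]))
      rows[[v]] <- data.frame(
        variable = v,
        mild = sprintf("%.2f ± %.2f", mean(x[!sev]), stats::sd(x[!sev])),
        severe = sprintf("%.2f ± %.2f", mean(x[sev]), stats::sd(x[sev])),
        p = format_p_value(tt$welch$p_value))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
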