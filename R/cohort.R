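## Synthetic cohort generation -------------------------------------------

# PatientRecord column order used for every cohort table and CSV.
cohort_columns <- c("age", "sex", "body_temperature", "fever_duration",
                    "wbc", "glucose", "heart_rate", "sbp", "ev71_positive",
                    "mri_cerebrum_cerebellum", "mri_meninges",
                    "mri_brainstem", "mri_spinal_cord", "mri_nerve_roots",
                    "outcome")

# Model predictors derived from a cohort table (14 variables).
model_features <- c("age", "male", "body_temperature", "fever_ge_3_days",
                    "elevated_wbc", "hyperglycemia", "hypertension",
                    "tachycardia", "ev71_positive",
                    "mri_cerebrum_cerebellum", "mri_meninges",
                    "mri_brainstem", "mri_spinal_cord", "mri_nerve_roots")

binary_flag_names <- c("male", "fever_ge_3_days", "elevated_wbc",
                       "hypertension", "hyperglycemia", "tachycardia",
                       "ev71_positive", "mri_cerebrum_cerebellum",
                       "mri_meninges", "mri_brainstem", "mri_spinal_cord",
                       "mri_nerve_roots")

# Group-wise flag prevalences and continuous moments of the default
# calibration: 345 mild vs 185 severe patients, with marginals taken from
# the published mild/severe comparison tables (clinical flags and MRI
# involvement sites) and age (months) / body temperature (degC) moments.
default_prevalence <- list(
  mild = c(male = 245 / 345, fever_ge_3_days = 60 / 345,
           elevated_wbc = 29 / 345, hypertension = 17 / 345,
           hyperglycemia = 51 / 345, tachycardia = 0 / 345,
           ev71_positive = 284 / 345, mri_cerebrum_cerebellum = 8 / 345,
           mri_meninges = 16 / 345, mri_brainstem = 49 / 345,
           mri_spinal_cord = 0 / 345, mri_nerve_roots = 26 / 345),
  severe = c(male = 134 / 185, fever_ge_3_days = 106 / 185,
             elevated_wbc = 126 / 185, hypertension = 22 / 185,
             hyperglycemia = 82 / 185, tachycardia = 10 / 185,
             ev71_positive = 111 / 185, mri_cerebrum_cerebellum = 14 / 185,
             mri_meninges = 20 / 185, mri_brainstem = 44 / 185,
             mri_spinal_cord = 60 / 185, mri_nerve_roots = 28 / 185))

default_continuous <- list(
  age = list(mild = c(mean = 27.1, sd = 17.8),
             severe = c(mean = 28.4, sd = 22.9)),
  body_temperature = list(mild = c(mean = 38.96, sd = 0.64),
                          severe = c(mean = 38.98, sd = 0.62)))

#' Specify a synthetic HFMD cohort
#'
#' Defines the statistical structure of a synthetic cohort. In `marginal`
#' mode every binary flag is drawn independently within outcome group at the
#' configured prevalence and the continuous variables are truncated
#' Gaussians, so the two groups reproduce published mild/severe marginals
#' but carry no planted dependence structure. In `mechanistic` mode the
#' predictors are drawn first (from the mild-group marginals) and the
#' outcome is then drawn from a logistic model
#' `P(severe) = plogis(beta0 + sum beta_j x_j + sum gamma_jk x_j x_k)`,
#' which is the only way to plant recoverable main effects and pairwise
#' interactions. Continuous predictors enter the linear predictor
#' standardised by their configured mild-group mean/SD.
#'
#' Raw measurements (WBC, glucose, fever duration, heart rate, SBP) are
#' synthesised conditionally on their drawn flags, so that
#' [derive_clinical_flags()] recovers exactly the intended flag for every
#' record.
#'
#' @param n_mild,n_severe group sizes (marginal mode) — defaults 345/185; in
#'   mechanistic mode their sum is the cohort size and the realised split is
#'   random.
#' @param prevalence list with named probability vectors `mild` and
#'   `severe` over the binary flags.
#' @param continuous list with per-variable per-group `c(mean, sd)` for
#'   `age` (months) and `body_temperature` (degC).
#' @param mode `"marginal"` or `"mechanistic"`.
#' @param beta0 logistic intercept (mechanistic mode).
#' @param beta named numeric vector of main-effect coefficients over model
#'   features (see [cohort_model_frame()]).
#' @param gamma named numeric vector of pairwise interaction coefficients;
#'   names are `"feature1:feature2"`.
#' @param thresholds [clinical_thresholds()] used when synthesising raw
#'   measurements from flags.
#' @param seed integer cohort-level seed; per-column substreams are derived
#'   from it so adding a column does not perturb the others.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_mild = 50, n_severe = 30, seed = 7)
#' cohort <- generate_cohort(spec)
#' table(cohort$outcome)
cohort_spec <- function(n_mild = 345, n_severe = 185,
                        prevalence = default_prevalence,
                        continuous = default_continuous,
                        mode = c("marginal", "mechanistic"),
                        beta0 = 0, beta = numeric(0), gamma = numeric(0),
                        thresholds = clinical_thresholds(),
                        seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_mild >= 0, n_severe >= 0,
            is.list(prevalence), all(c("mild", "severe") %in% names(prevalence)))
  for (g in c("mild", "severe")) {
    p <- prevalence[[g]]
    if (any(p < 0 | p > 1))
      stop("prevalences must lie in [0, 1]")
    if (!all(binary_flag_names %in% names(p)))
      stop("prevalence vectors must name all binary flags")
  }
  for (v in names(continuous)) for (g in c("mild", "severe"))
    if (continuous[[v]][[g]][["sd"]] <= 0) stop("SDs must be > 0")
  if (length(beta) && is.null(names(beta)))
    stop("beta must be a named vector")
  if (length(gamma) && is.null(names(gamma)))
    stop("gamma must be a named vector with names 'f1:f2'")
  structure(list(n_mild = as.integer(n_mild), n_severe = as.integer(n_severe),
                 prevalence = prevalence, continuous = continuous,
                 mode = mode, beta0 = beta0, beta = beta, gamma = gamma,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Truncated-Gaussian draws by inverse-CDF; deterministic under set.seed.
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  pmin(pmax(qnorm(u, mean, sd), lo), hi)
}

draw_flag <- function(n, p, seed, key) {
  set.seed(substream_seed(seed, key))
  as.integer(runif(n) < p)
}

# Synthesise raw measurements consistent with the drawn flags, so that
# derive_clinical_flags() reproduces them exactly (inclusive/strict
# boundaries respected by epsilon offsets on the open side).
synth_raw <- function(n, flags, age, th, seed, prefix) {
  eps <- 1e-6
  set.seed(substream_seed(seed, paste0(prefix, ".wbc")))
  wbc <- ifelse(flags$elevated_wbc == 1,
                rtrunc_norm(n, 19, 3, th$wbc_cutoff, 60),
                rtrunc_norm(n, 9, 3, 0.5, th$wbc_cutoff - eps))
  set.seed(substream_seed(seed, paste0(prefix, ".glucose")))
  glucose <- ifelse(flags$hyperglycemia == 1,
                    rtrunc_norm(n, 10.5, 1.5, th$glucose_cutoff + eps, 30),
                    rtrunc_norm(n, 5.5, 1.2, 0.5, th$glucose_cutoff))
  set.seed(substream_seed(seed, paste0(prefix, ".fever_duration")))
  fever <- ifelse(flags$fever_ge_3_days == 1,
                  th$fever_days_cutoff + rpois(n, 1.2),
                  sample(seq_len(th$fever_days_cutoff) - 1L, n, replace = TRUE))
  hr_cut <- th$tachycardia_cutoffs[age_class(age)]
  set.seed(substream_seed(seed, paste0(prefix, ".heart_rate")))
  hr <- ifelse(flags$tachycardia == 1,
               rtrunc_norm(n, hr_cut + 20, 12, hr_cut + eps, 260),
               rtrunc_norm(n, hr_cut - 30, 15, 50, hr_cut))
  sbp_exp <- th$sbp_expected(age)
  set.seed(substream_seed(seed, paste0(prefix, ".sbp")))
  sbp <- ifelse(flags$hypertension == 1,
                rtrunc_norm(n, sbp_exp + 30, 8,
                            sbp_exp + th$hypertension_excess + eps,
                            sbp_exp + 70),
                rtrunc_norm(n, sbp_exp, 8, 55,
                            sbp_exp + th$hypertension_excess))
  list(wbc = wbc, glucose = glucose, fever_duration = fever,
       heart_rate = hr, sbp = sbp)
}

draw_group <- function(n, prev, cont, th, seed, prefix) {
  flags <- list()
  for (f in binary_flag_names)
    flags[[f]] <- draw_flag(n, prev[[f]], seed, paste0(prefix, ".", f))
  set.seed(substream_seed(seed, paste0(prefix, ".age")))
  age <- rtrunc_norm(n, cont$age[["mean"]], cont$age[["sd"]], 0, 180)
  set.seed(substream_seed(seed, paste0(prefix, ".body_temperature")))
  temp <- rtrunc_norm(n, cont$body_temperature[["mean"]],
                      cont$body_temperature[["sd"]], 35, 43)
  raw <- synth_raw(n, flags, age, th, seed, prefix)
  data.frame(age = age,
             sex = ifelse(flags$male == 1, "male", "female"),
             body_temperature = temp,
             fever_duration = raw$fever_duration,
             wbc = raw$wbc, glucose = raw$glucose,
             heart_rate = raw$heart_rate, sbp = raw$sbp,
             ev71_positive = flags$ev71_positive,
             mri_cerebrum_cerebellum = flags$mri_cerebrum_cerebellum,
             mri_meninges = flags$mri_meninges,
             mri_brainstem = flags$mri_brainstem,
             mri_spinal_cord = flags$mri_spinal_cord,
             mri_nerve_roots = flags$mri_nerve_roots,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort table
#'
#' Draws a cohort according to a [cohort_spec()]. The same spec (including
#' its seed) always yields the identical table, and [write_cohort()] of it
#' the identical file.
#'
#' @param spec a [cohort_spec()].
#' @return A `data.frame` of class `hfmd_cohort` with the patient-record
#'   columns (demographics, raw measurements, MRI flags) and an `outcome`
#'   column coded `"mild"`/`"severe"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  th <- spec$thresholds
  if (spec$mode == "marginal") {
    parts <- list()
    for (g in c("mild", "severe")) {
      n <- if (g == "mild") spec$n_mild else spec$n_severe
      if (n == 0) next
      cont <- lapply(spec$continuous, function(v) v[[g]])
      d <- draw_group(n, as.list(spec$prevalence[[g]]), cont, th,
                      spec$seed, g)
      d$outcome <- g
      parts[[g]] <- d
    }
    out <- do.call(rbind, parts)
  } else {
    n <- spec$n_mild + spec$n_severe
    cont <- lapply(spec$continuous, function(v) v[["mild"]])
    out <- draw_group(n, as.list(spec$prevalence[["mild"]]), cont, th,
                      spec$seed, "all")
    out$outcome <- "mild"  # placeholder; replaced from the logistic model
    feats <- cohort_model_frame(structure(out, class = c("hfmd_cohort",
                                                         "data.frame")),
                                thresholds = th)
    z <- feats[, model_features, drop = FALSE]
    # standardise continuous features so coefficients are comparable
    for (v in names(spec$continuous)) {
      m <- spec$continuous[[v]][["mild"]]
      col <- if (v == "age") "age" else v
      z[[col]] <- (z[[col]] - m[["mean"]]) / m[["sd"]]
    }
    eta <- rep(spec$beta0, n)
    for (f in names(spec$beta)) {
      if (!f %in% names(z)) stop("unknown feature in beta: ", f)
      eta <- eta + spec$beta[[f]] * z[[f]]
    }
    for (pr in names(spec$gamma)) {
      fk <- strsplit(pr, ":", fixed = TRUE)[[1]]
      if (length(fk) != 2 || !all(fk %in% names(z)))
        stop("unknown feature pair in gamma: ", pr)
      eta <- eta + spec$gamma[[pr]] * z[[fk[1]]] * z[[fk[2]]]
    }
    set.seed(substream_seed(spec$seed, "outcome"))
    out$outcome <- ifelse(runif(n) < logistic(eta), "severe", "mild")
  }
  rownames(out) <- NULL
  structure(out, class = c("hfmd_cohort", "data.frame"))
}

#' Build the model frame of derived predictors
#'
#' Converts a cohort table of raw patient records into the 14-predictor
#' analysis frame: age (months), male sex, body temperature, the five
#' derived clinical flags (prolonged fever, elevated WBC, hyperglycemia,
#' hypertension, tachycardia), EV71 positivity and the five MRI involvement
#' flags, plus a binary `outcome` column (1 = severe). Flag derivation
#' follows [derive_clinical_flags()] exactly (vectorised).
#'
#' @param cohort an `hfmd_cohort` data frame (or any data frame with the
#'   patient-record columns).
#' @param thresholds a [clinical_thresholds()] object.
#' @return A numeric `data.frame` with the predictors and `outcome`.
#' @export
cohort_model_frame <- function(cohort, thresholds = clinical_thresholds()) {
  th <- thresholds
  hr_cut <- th$tachycardia_cutoffs[age_class(cohort$age)]
  data.frame(
    age = cohort$age,
    male = as.integer(cohort$sex == "male"),
    body_temperature = cohort$body_temperature,
    fever_ge_3_days = as.integer(cohort$fever_duration >= th$fever_days_cutoff),
    elevated_wbc = as.integer(cohort$wbc >= th$wbc_cutoff),
    hyperglycemia = as.integer(cohort$glucose > th$glucose_cutoff),
    hypertension = as.integer(cohort$sbp >
                                th$sbp_expected(cohort$age) +
                                th$hypertension_excess),
    tachycardia = as.integer(cohort$heart_rate > hr_cut),
    ev71_positive = as.integer(cohort$ev71_positive),
    mri_cerebrum_cerebellum = as.integer(cohort$mri_cerebrum_cerebellum),
    mri_meninges = as.integer(cohort$mri_meninges),
    mri_brainstem = as.integer(cohort$mri_brainstem),
    mri_spinal_cord = as.integer(cohort$mri_spinal_cord),
    mri_nerve_roots = as.integer(cohort$mri_nerve_roots),
    outcome = as.integer(cohort$outcome == "severe"))
}

#' Recruitment flow: apply the exclusion cascade
#'
#' Computes the recruited count from the screening flow: patients assessed,
#' minus those without laboratory results, minus those without a
#' pre-treatment MRI, minus those already treated elsewhere.
#'
#' @param assessed,missing_labs,no_mri,treated_elsewhere non-negative
#'   counts; alternatively pass a single named list as `assessed`.
#' @return The recruited count (integer).
#' @export
#' @examples
#' apply_exclusion_cascade(1172, 83, 347, 212)  # 530
apply_exclusion_cascade <- function(assessed, missing_labs = 0, no_mri = 0,
                                    treated_elsewhere = 0) {
  if (is.list(assessed)) {
    fl <- assessed
    assessed <- fl$assessed; missing_labs <- fl$missing_labs
    no_mri <- fl$no_mri; treated_elsewhere <- fl$treated_elsewhere
  }
  counts <- c(assessed, missing_labs, no_mri, treated_elsewhere)
  if (any(counts < 0)) stop("flow counts must be non-negative")
  recruited <- assessed - missing_labs - no_mri - treated_elsewhere
  if (recruited < 0)
    stop("inconsistent flow counts: exclusions exceed assessed patients")
  as.integer(recruited)
}

#' Write / read a cohort CSV
#'
#' Cohort interchange format: header row, patient-record columns in fixed
#' order, booleans as 0/1, outcome as `"mild"`/`"severe"`, missing values
#' as empty cells, UTF-8, `.` decimal separator. Writing the same cohort
#' twice produces byte-identical files.
#'
#' @param cohort an `hfmd_cohort` data frame.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(all(cohort_columns %in% names(cohort)))
  write.csv(cohort[, cohort_columns], path, row.names = FALSE, na = "",
            quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(cohort_columns, names(d))
  if (length(missing_cols))
    stop("cohort file lacks columns: ", paste(missing_cols, collapse = ", "))
  structure(d[, cohort_columns], class = c("hfmd_cohort", "data.frame"))
}
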