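test_that("clinical flag derivation honours inclusive/strict boundaries", {
  th <- clinical_thresholds()
  rec <- list(age = 30, wbc = 15.0, glucose = 8.3, fever_duration = 3,
              heart_rate = 140, sbp = 105)
  fl <- derive_clinical_flags(rec, th)
  expect_true(fl[["elevated_wbc"]])        # WBC cutoff inclusive at 15.0
  expect_false(fl[["hyperglycemia"]])      # glucose cutoff strict at 8.3
  expect_true(fl[["fever_ge_3_days"]])     # fever days inclusive at 3
  expect_false(fl[["tachycardia"]])        # toddler cutoff strict at 140
  # toddler expected SBP at 30 months = 85; excess strict at +20
  expect_false(fl[["hypertension"]])
  fl2 <- derive_clinical_flags(modifyList(rec, list(sbp = 105.1)), th)
  expect_true(fl2[["hypertension"]])
})

test_that("tachycardia age classes use the configured cutoffs", {
  th <- clinical_thresholds()
  infant <- derive_clinical_flags(list(age = 6, heart_rate = 150), th)
  expect_false(infant[["tachycardia"]])   # infant cutoff is over 160
  toddler <- derive_clinical_flags(list(age = 20, heart_rate = 150), th)
  expect_true(toddler[["tachycardia"]])
  child <- derive_clinical_flags(list(age = 48, heart_rate = 125), th)
  expect_true(child[["tachycardia"]])
})

test_that("missing measurements give missing flags, never FALSE", {
  fl <- derive_clinical_flags(list(age = 24, wbc = 16), clinical_thresholds())
  expect_true(fl[["elevated_wbc"]])
  expect_true(is.na(fl[["hyperglycemia"]]))
  expect_true(is.na(fl[["tachycardia"]]))
  expect_true(is.na(fl[["hypertension"]]))
})

test_that("flag derivation is deterministic, idempotent and per-record", {
  th <- clinical_thresholds()
  co <- generate_cohort(cohort_spec(n_mild = 40, n_severe = 40, seed = 9))
  mf1 <- cohort_model_frame(co, th)
  mf2 <- cohort_model_frame(co, th)
  expect_identical(mf1, mf2)
  shuffled <- co[rev(seq_len(nrow(co))), ]
  mf3 <- cohort_model_frame(shuffled, th)
  expect_equal(mf3, mf1[rev(seq_len(nrow(mf1))), ], ignore_attr = TRUE)
  # vectorised frame agrees with per-record derivation
  for (i in c(1, 17, 80)) {
    fl <- derive_clinical_flags(as.list(co[i, ]), th)
    expect_equal(unname(mf1$elevated_wbc[i]), as.integer(fl[["elevated_wbc"]]))
    expect_equal(unname(mf1$hypertension[i]), as.integer(fl[["hypertension"]]))
    expect_equal(unname(mf1$tachycardia[i]), as.integer(fl[["tachycardia"]]))
  }
})

test_that("exclusion cascade arithmetic and error handling", {
  expect_identical(apply_exclusion_cascade(1172, 83, 347, 212), 530L)
  expect_identical(apply_exclusion_cascade(100, 0, 0, 0), 100L)
  expect_error(apply_exclusion_cascade(10, 5, 5, 5), "inconsistent")
  expect_error(apply_exclusion_cascade(10, -1, 0, 0), "non-negative")
  expect_identical(apply_exclusion_cascade(list(assessed = 1172,
                                                missing_labs = 83,
                                                no_mri = 347,
                                                treated_elsewhere = 212)),
                   530L)
})

test_that("same spec gives identical tables and byte-identical CSVs", {
  spec <- cohort_spec(n_mild = 60, n_severe = 40, seed = 123)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(c1, f1); write_cohort(c2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_cohort(f1)
  expect_equal(back$outcome, c1$outcome)
  expect_equal(cohort_model_frame(back), cohort_model_frame(c1))
  unlink(c(f1, f2))
})

test_that("raw measurements always reproduce their drawn flags", {
  # prevalences away from 0/1 so both flag states occur
  prev <- mech_prevalence()
  spec <- cohort_spec(n_mild = 500, n_severe = 500, prevalence = prev,
                      seed = 5)
  mf <- cohort_model_frame(generate_cohort(spec))
  # every flag has both states at these prevalences and n
  for (v in c("elevated_wbc", "hyperglycemia", "fever_ge_3_days",
              "mri_spinal_cord"))
    expect_true(all(c(0, 1) %in% mf[[v]]))
})

test_that("marginal calibration: observed prevalences within 3 binomial SDs", {
  n <- 10000
  spec <- cohort_spec(n_mild = n, n_severe = n, seed = 77)
  mf <- cohort_model_frame(generate_cohort(spec))
  sev <- mf$outcome == 1
  prev <- spec$prevalence
  checks <- c("elevated_wbc", "hyperglycemia", "fever_ge_3_days",
              "hypertension", "mri_spinal_cord", "mri_brainstem",
              "ev71_positive", "male")
  for (g in c("mild", "severe")) {
    rows <- if (g == "severe") sev else !sev
    for (v in checks) {
      p <- prev[[g]][[v]]
      tol <- 3 * sqrt(p * (1 - p) / n)
      expect_lt(abs(mean(mf[[v]][rows]) - p), tol + 1e-12)
    }
  }
  # degenerate prevalence 0 gives exactly zero positives
  expect_identical(sum(mf$mri_spinal_cord[!sev]), 0L)
  # continuous moments near the analytic truncated-normal means
  trunc_mean <- function(m, s, lo, hi) {
    a <- (lo - m) / s; b <- (hi - m) / s
    m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  expect_lt(abs(mean(mf$age[!sev]) - trunc_mean(27.1, 17.8, 0, 180)), 0.6)
  expect_lt(abs(mean(mf$body_temperature[sev]) -
                  trunc_mean(38.98, 0.62, 35, 43)), 0.03)
})

test_that("calibrated group sizes reproduce the published table counts", {
  spec <- cohort_spec(seed = 31)
  co <- generate_cohort(spec)
  expect_identical(unname(table(co$outcome)["mild"]), 345L)
  expect_identical(unname(table(co$outcome)["severe"]), 185L)
  mf <- cohort_model_frame(co)
  # spinal cord: structurally impossible in the mild group (prevalence 0)
  expect_identical(sum(mf$mri_spinal_cord[mf$outcome == 0]), 0L)
  # severe-group count near 60 within binomial error (3 SD ~ 19)
  expect_lt(abs(sum(mf$mri_spinal_cord[mf$outcome == 1]) - 60), 20)
})

test_that("mechanistic null model: outcome near 50% and independent of flags", {
  sig <- 0
  for (i in 1:10) {
    mf <- cohort_model_frame(generate_cohort(null_cohort_spec(300 + i, n = 400)))
    expect_lt(abs(mean(mf$outcome) - 0.5), 0.1)
    tab <- table(mf$elevated_wbc, mf$outcome)
    p <- chi_square_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])$p_value
    sig <- sig + (p < 0.05)
  }
  expect_lte(sig, 2)  # non-significant in at least 90% of replicates
})

test_that("mechanistic interactions match the analytic logistic odds ratios", {
  # planted gamma on WBC x hyperglycemia: within-stratum ORs for the WBC
  # flag are exp(beta) and exp(beta + gamma), so the OR ratio is exp(gamma)
  beta_w <- 0.7; gam <- 1.0
  spec <- cohort_spec(n_mild = 20000, n_severe = 20000, mode = "mechanistic",
                      prevalence = mech_prevalence(), beta0 = -1,
                      beta = c(elevated_wbc = beta_w, hyperglycemia = 0.5),
                      gamma = c("elevated_wbc:hyperglycemia" = gam),
                      seed = 99)
  mf <- cohort_model_frame(generate_cohort(spec))
  or_in <- function(stratum) {
    d <- mf[mf$hyperglycemia == stratum, ]
    t <- table(factor(d$elevated_wbc, 0:1), factor(d$outcome, 0:1))
    (t["1", "1"] * t["0", "0"]) / (t["1", "0"] * t["0", "1"])
  }
  log_ratio <- log(or_in(1)) - log(or_in(0))
  cells <- as.vector(table(mf$elevated_wbc, mf$hyperglycemia, mf$outcome))
  se <- sqrt(sum(1 / cells))  # delta-method SE of the log OR ratio
  expect_lt(abs(log_ratio - gam), 4 * se)
})

test_that("invalid specs are rejected", {
  prev <- cohort_spec()$prevalence
  prev$mild[["elevated_wbc"]] <- 1.2
  expect_error(cohort_spec(prevalence = prev), "\\[0, 1\\]")
  cont <- cohort_spec()$continuous
  cont$age$mild[["sd"]] <- 0
  expect_error(cohort_spec(continuous = cont), "SD")
  expect_error(generate_cohort(
    cohort_spec(mode = "mechanistic", beta = c(not_a_feature = 1))),
    "unknown feature")
})
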