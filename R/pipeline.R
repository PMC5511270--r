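## End-to-end orchestration ------------------------------------------------

#' Configuration for a full analysis run
#'
#' Bundles every knob of the pipeline: the cohort source (a [cohort_spec()]
#' to simulate, or a CSV path to load), clinical thresholds, training
#' configuration, inference settings (permutations `B`, bootstrap
#' resamples `B_boot`, CI `level`, the interaction `pairs` to report),
#' evaluation settings (`k` folds, `balance` mode) and a master `seed`.
#'
#' @param out_dir directory for the result bundle (created if absent).
#' @param cohort a [cohort_spec()] or a path to a cohort CSV.
#' @param thresholds a [clinical_thresholds()].
#' @param train a [gbt_config()].
#' @param pairs character vector of `"f1:f2"` interaction pairs to test.
#' @param B permutations for the importance test.
#' @param B_h permutations for each interaction test.
#' @param B_boot bootstrap resamples for each interaction CI.
#' @param level CI level.
#' @param k folds for evaluation.
#' @param balance `"none"` or `"downsample"`.
#' @param seed master seed; all stage substreams derive from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       cohort = cohort_spec(),
                       thresholds = clinical_thresholds(),
                       train = gbt_config(),
                       pairs = c("elevated_wbc:hyperglycemia",
                                 "mri_spinal_cord:fever_ge_3_days",
                                 "mri_brainstem:body_temperature"),
                       B = 999, B_h = 199, B_boot = 200, level = 0.95,
                       k = 10, balance = c("downsample", "none"),
                       seed = 1L) {
  balance <- match.arg(balance)
  stopifnot(inherits(thresholds, "clinical_thresholds"),
            inherits(train, "gbt_config"))
  if (is.character(cohort) && !file.exists(cohort))
    stop("cohort CSV not found: ", cohort)
  structure(list(out_dir = out_dir, cohort = cohort,
                 thresholds = thresholds, train = train, pairs = pairs,
                 B = B, B_h = B_h, B_boot = B_boot, level = level,
                 k = k, balance = balance, seed = as.integer(seed)),
            class = "run_config")
}

# Stable hash of the scientific configuration for the provenance manifest;
# the output directory is location metadata and deliberately excluded, so
# identical analyses in different directories hash identically.
config_hash <- function(config) {
  canon <- config
  canon$out_dir <- NULL
  canon$thresholds$sbp_expected <-
    paste(deparse(config$thresholds$sbp_expected), collapse = "")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canon, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

stage_msg <- function(stage, t0) {
  message(sprintf("[%s] done in %.1fs", stage,
                  as.numeric(proc.time()[3]) - t0))
}

write_results_json <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> describe -> fit -> interpret -> infer -> evaluate
#' -> report. Writes, under `config$out_dir`: `cohort.csv`,
#' `group_table.csv`, `ensemble.json`, `importance.csv` / `.json` (with
#' permutation p-values), `interactions.json` (H, bootstrap CI,
#' permutation p per pair), `surface_<pair>.csv` grids,
#' `performance.json`, `roc.csv` and `manifest.json` (config hash, seed,
#' versions). Re-running with an identical config reproduces identical
#' numbers.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results
#'   (`cohort`, `group_table`, `ensemble`, `importance`, `interactions`,
#'   `performance`, `manifest`).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  seed <- config$seed

  t0 <- as.numeric(proc.time()[3])
  cohort <- if (is.character(config$cohort)) read_cohort(config$cohort)
            else generate_cohort(config$cohort)
  write_cohort(cohort, out("cohort.csv"))
  stage_msg("simulate", t0)

  t0 <- as.numeric(proc.time()[3])
  gt <- cohort_group_table(cohort, config$thresholds)
  write.csv(gt, out("group_table.csv"), row.names = FALSE)
  stage_msg("describe", t0)

  t0 <- as.numeric(proc.time()[3])
  mf <- cohort_model_frame(cohort, config$thresholds)
  cfg <- config$train
  cfg$seed <- substream_seed(seed, "fit")
  ens <- fit_gbt(mf, cfg)
  write_ensemble_json(ens, out("ensemble.json"))
  stage_msg("fit", t0)

  t0 <- as.numeric(proc.time()[3])
  perm <- permutation_test_importance(mf, cfg, B = config$B,
                                      seed = substream_seed(seed, "perm"))
  imp <- relative_importance(ens)
  imp$p_value <- perm$results$p_value[match(imp$variable,
                                            perm$results$variable)]
  write.csv(imp, out("importance.csv"), row.names = FALSE)
  write_results_json(list(B = perm$B, seed = perm$seed, results = imp),
                     out("importance.json"))
  stage_msg("importance", t0)

  t0 <- as.numeric(proc.time()[3])
  feats <- mf[, setdiff(names(mf), "outcome"), drop = FALSE]
  inter <- lapply(config$pairs, function(pr) {
    fk <- strsplit(pr, ":", fixed = TRUE)[[1]]
    h <- h_statistic(ens, fk[1], fk[2], feats)
    ci <- bootstrap_ci_h(mf, cfg, fk[1], fk[2], B_boot = config$B_boot,
                         level = config$level,
                         seed = substream_seed(seed, paste0("boot.", pr)))
    pt <- permutation_test_h(mf, cfg, fk[1], fk[2], B = config$B_h,
                             seed = substream_seed(seed, paste0("permh.", pr)))
    export_interaction_surface(ens, fk[1], fk[2], feats,
                               path = out(paste0("surface_",
                                                 gsub(":", "_x_", pr),
                                                 ".csv")))
    list(pair = pr, h = h$h, ci_lower = ci$lower, ci_upper = ci$upper,
         level = config$level, p_value = pt$p_value,
         B_h = config$B_h, B_boot = config$B_boot)
  })
  write_results_json(inter, out("interactions.json"))
  stage_msg("interactions", t0)

  t0 <- as.numeric(proc.time()[3])
  cv <- cross_validate(mf, cfg, k = config$k, balance = config$balance,
                       seed = substream_seed(seed, "cv"))
  roc_points(cv, out("roc.csv"))
  write_results_json(list(balance = cv$balance, threshold = cv$threshold,
                          summary = as.list(cv$summary),
                          pooled_auc = cv$pooled_auc,
                          per_fold = cv$per_fold),
                     out("performance.json"))
  stage_msg("evaluate", t0)

  manifest <- list(package = "hfmdgbt",
                   package_version =
                     as.character(utils::packageVersion("hfmdgbt")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = seed,
                   config_hash = config_hash(config),
                   files = c("cohort.csv", "group_table.csv",
                             "ensemble.json", "importance.csv",
                             "importance.json", "interactions.json",
                             "performance.json", "roc.csv",
                             "manifest.json"))
  write_results_json(manifest, out("manifest.json"))

  invisible(list(cohort = cohort, group_table = gt, ensemble = ens,
                 importance = imp, interactions = inter, performance = cv,
                 manifest = manifest))
}
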