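test_that("relative importance follows the averaged squared-improvement formula", {
  # single tree with a single split on X1
  stump <- function(f, imp) matrix(c(f, 0.5, NA, 2, 3, imp,
                                     0, 0, -1, 0, 0, 0,
                                     0, 0, 1, 0, 0, 0), ncol = 6, byrow = TRUE)
  ens1 <- gbt_ensemble(0, 1, list(stump(1, 4)), c("X1", "X2", "X3"))
  ri1 <- relative_importance(ens1)
  expect_equal(ri1$relative[ri1$variable == "X1"], 100)
  expect_equal(sum(ri1$relative), 100)
  # tree 1 splits X1 (improvement 9), tree 2 splits X2 (improvement 4):
  # raw = (4.5, 2), normalised = (100, 400/9)
  ens2 <- gbt_ensemble(0, 1, list(stump(1, 9), stump(2, 4)),
                       c("X1", "X2", "X3"))
  ri2 <- relative_importance(ens2)
  expect_equal(ri2$raw[ri2$variable == "X1"], 4.5)
  expect_equal(ri2$raw[ri2$variable == "X2"], 2)
  expect_equal(ri2$relative[ri2$variable == "X2"], 400 / 9)
  expect_equal(round(ri2$relative[ri2$variable == "X2"], 1), 44.4)
  expect_equal(ri2$relative[ri2$variable == "X3"], 0)
})

test_that("empty and split-free ensembles are handled explicitly", {
  expect_error(relative_importance(
    gbt_ensemble(0, 1, list(), "x")), "no trees")
  leaf_only <- gbt_ensemble(0, 1,
                            list(matrix(c(0, 0, 0.5, 0, 0, 0), 1)), "x")
  expect_warning(ri <- relative_importance(leaf_only), "zero")
  expect_equal(ri$relative, 0)
})

test_that("importance agrees with a naive per-tree traversal recount", {
  mf <- cohort_model_frame(generate_cohort(cohort_spec(n_mild = 100,
                                                       n_severe = 100,
                                                       seed = 21)))
  ens <- fit_gbt(mf, sim_config(n_trees = 60, seed = 2))
  got <- relative_importance(ens)
  want <- oracle_importance(ens)
  expect_equal(setNames(got$raw, got$variable)[names(want)], want,
               tolerance = 1e-10)
})

test_that("partial dependence matches the brute-force double loop", {
  mf <- fixture_frame(n = 20, seed = 42)
  ens <- fit_gbt(mf, gbt_config(n_trees = 10, shrinkage = 0.5,
                                bag_fraction = 1, min_node_size = 2))
  feats <- feature_frame(mf)
  for (vars in list("x1", "x3", c("x1", "x2"), c("x3", "x2"))) {
    got <- partial_dependence(ens, vars, feats)
    want <- oracle_pd(ens, vars, feats)
    expect_equal(got$pd, want$pd, tolerance = 1e-10)
    expect_equal(got$weight, want$weight, tolerance = 1e-12)
    # centred to weighted mean zero
    expect_lt(abs(sum(got$pd * got$weight)), 1e-8)
  }
})

test_that("intercept-only ensembles have identically zero centred PD", {
  ens0 <- gbt_ensemble(1.3, 0.1, list(), c("x1", "x2"))
  d <- data.frame(x1 = c(0, 1, 1), x2 = c(5, 2, 2))
  pd <- partial_dependence(ens0, "x1", d)
  expect_equal(pd$pd, rep(0, 2))
})

test_that("depth-1 ensembles are additive: two-way PD is the sum of one-way PDs", {
  mf <- cohort_model_frame(generate_cohort(cohort_spec(n_mild = 90,
                                                       n_severe = 90,
                                                       seed = 13)))
  ens <- fit_gbt(mf, gbt_config(n_trees = 50, shrinkage = 0.3, max_depth = 1,
                                bag_fraction = 1))
  feats <- feature_frame(mf)
  p1 <- partial_dependence(ens, "elevated_wbc", feats)
  p2 <- partial_dependence(ens, "mri_spinal_cord", feats)
  p12 <- partial_dependence(ens, c("elevated_wbc", "mri_spinal_cord"), feats)
  for (g in seq_len(nrow(p12))) {
    v1 <- p1$pd[match(p12$elevated_wbc[g], p1$elevated_wbc)]
    v2 <- p2$pd[match(p12$mri_spinal_cord[g], p2$mri_spinal_cord)]
    # additive up to the (constant) centring offsets
    expect_equal(p12$pd[g] - (v1 + v2),
                 p12$pd[1] - (p1$pd[match(p12$elevated_wbc[1], p1$elevated_wbc)] +
                              p2$pd[match(p12$mri_spinal_cord[1], p2$mri_spinal_cord)]),
                 tolerance = 1e-8)
  }
})

test_that("H is zero for additive (stump) ensembles and one for a pure interaction", {
  mf <- cohort_model_frame(generate_cohort(cohort_spec(n_mild = 90,
                                                       n_severe = 90,
                                                       seed = 13)))
  ens <- fit_gbt(mf, gbt_config(n_trees = 50, shrinkage = 0.3, max_depth = 1,
                                bag_fraction = 1))
  feats <- feature_frame(mf)
  pairs <- combn(c("elevated_wbc", "age", "mri_spinal_cord",
                   "body_temperature"), 2)
  for (j in seq_len(ncol(pairs))) {
    h <- h_statistic(ens, pairs[1, j], pairs[2, j], feats)
    expect_lt(h$h, 1e-8)
  }
  pure <- pure_interaction_ensemble()
  h1 <- h_statistic(pure, "x1", "x2", pm_square())
  expect_equal(h1$h, 1, tolerance = 1e-12)
})

test_that("H is symmetric, bounded, and invariant to binary relabelling", {
  mf <- cohort_model_frame(generate_cohort(interaction_spec(7, n = 400)))
  ens <- fit_gbt(mf, gbt_config(n_trees = 80, shrinkage = 0.1,
                                bag_fraction = 1))
  feats <- feature_frame(mf)
  h_jk <- h_statistic(ens, "elevated_wbc", "hyperglycemia", feats)
  h_kj <- h_statistic(ens, "hyperglycemia", "elevated_wbc", feats)
  expect_equal(h_jk$h, h_kj$h, tolerance = 1e-12)
  expect_gte(h_jk$h, 0); expect_lte(h_jk$h, 1)
  # relabel hyperglycemia 0 <-> 1, refit deterministically: H unchanged
  mf2 <- mf; mf2$hyperglycemia <- 1 - mf2$hyperglycemia
  ens2 <- fit_gbt(mf2, gbt_config(n_trees = 80, shrinkage = 0.1,
                                  bag_fraction = 1))
  h2 <- h_statistic(ens2, "elevated_wbc", "hyperglycemia",
                    feature_frame(mf2))
  expect_equal(h_jk$h, h2$h, tolerance = 1e-8)
  expect_error(h_statistic(ens, "elevated_wbc", "elevated_wbc", feats),
               "distinct")
})

test_that("degenerate pairs (never influencing the model) give H = 0 with a flag", {
  # ensemble that never splits: min_node_size exceeds n
  mf <- fixture_frame(n = 20, seed = 42)
  ens <- fit_gbt(mf, gbt_config(n_trees = 3, min_node_size = 50,
                                bag_fraction = 1))
  h <- h_statistic(ens, "x1", "x2", feature_frame(mf))
  expect_true(h$degenerate)
  expect_equal(h$h, 0)
})

test_that("interaction surfaces: binary grid shape and oracle equivalence", {
  mf <- fixture_frame(n = 20, seed = 42)
  ens <- fit_gbt(mf, gbt_config(n_trees = 10, shrinkage = 0.5,
                                bag_fraction = 1, min_node_size = 2))
  feats <- feature_frame(mf)
  surf <- export_interaction_surface(ens, "x1", "x2", feats)
  expect_equal(nrow(surf), 4)                      # binary x binary
  expect_setequal(surf$x1, c(0, 1))
  # grid export equals the brute-force PD on the same grid, recentred
  grid <- surf[, c("x1", "x2")]
  bf <- vapply(seq_len(4), function(g) {
    d2 <- feats; d2$x1 <- grid$x1[g]; d2$x2 <- grid$x2[g]
    mean(oracle_margin(ens, d2))
  }, numeric(1))
  expect_equal(surf$pd, bf - mean(bf), tolerance = 1e-10)
  path <- tempfile(fileext = ".csv")
  export_interaction_surface(ens, "x1", "x3", feats, n_grid = 5, path = path)
  expect_equal(nrow(read.csv(path)), 10)           # 2 x 5 grid
  unlink(path)
})
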