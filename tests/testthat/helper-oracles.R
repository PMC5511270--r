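# Independent brute-force oracles and shared fixtures.
# Everything here deliberately avoids the package's fast paths: predictions
# walk trees row by row in R, partial dependence is a double loop, and the
# reference stump booster re-derives the whole fitting recursion.

# Walk one tree matrix for a single feature vector.
oracle_tree_value <- function(T, x) {
  node <- 1
  while (T[node, 1] != 0) {
    node <- if (x[T[node, 1]] <= T[node, 2]) T[node, 4] else T[node, 5]
  }
  T[node, 3]
}

oracle_margin <- function(ens, data) {
  X <- as.matrix(data[, ens$feature_names, drop = FALSE])
  vapply(seq_len(nrow(X)), function(i) {
    s <- ens$intercept
    for (T in ens$trees) s <- s + ens$shrinkage * oracle_tree_value(T, X[i, ])
    s
  }, numeric(1))
}

# Brute-force centred partial dependence at the observed points (matching
# the package's evaluation-point and weighting convention).
oracle_pd <- function(ens, vars, data) {
  key <- do.call(paste, c(data[vars], sep = "\r"))
  u <- !duplicated(key)
  grid <- data[u, vars, drop = FALSE]
  w <- as.vector(tabulate(match(key, key[u]), nbins = nrow(grid)))
  w <- w / sum(w)
  vals <- vapply(seq_len(nrow(grid)), function(g) {
    d2 <- data
    for (v in vars) d2[[v]] <- grid[[v]][g]
    mean(oracle_margin(ens, d2))
  }, numeric(1))
  list(grid = grid, weight = w, pd = vals - sum(vals * w))
}

# Naive per-tree recount of raw importances by recursive traversal.
oracle_importance <- function(ens) {
  raw <- setNames(numeric(length(ens$feature_names)), ens$feature_names)
  walk <- function(T, node) {
    if (T[node, 1] == 0) return(invisible(NULL))
    f <- T[node, 1]
    raw[f] <<- raw[f] + T[node, 6]
    walk(T, T[node, 4])
    walk(T, T[node, 5])
  }
  for (T in ens$trees) walk(T, 1)
  raw / length(ens$trees)
}

# Reference booster: depth-1 trees, no subsampling, same split criterion,
# tie-break and Newton leaf rule, re-implemented independently in R.
# Returns the n x (M+1) staged margin matrix.
ref_fit_stumps <- function(X, y, M, nu, min_node = 1) {
  n <- nrow(X)
  p0 <- mean(y)
  Fm <- rep(log(p0 / (1 - p0)), n)
  staged <- matrix(NA_real_, n, M + 1)
  staged[, 1] <- Fm
  for (m in seq_len(M)) {
    pr <- 1 / (1 + exp(-Fm))
    r <- y - pr
    w <- pr * (1 - pr)
    best <- list(imp = 0, f = NA_integer_, thr = NA_real_)
    if (n >= 2 * min_node) {
      for (f in seq_len(ncol(X))) {
        xs <- sort(unique(X[, f]))
        if (length(xs) < 2) next
        for (thr in (xs[-length(xs)] + xs[-1]) / 2) {
          L <- X[, f] <= thr
          nl <- sum(L); nr <- n - nl
          if (nl < min_node || nr < min_node) next
          imp <- sum(r[L])^2 / nl + sum(r[!L])^2 / nr - sum(r)^2 / n
          if (imp > best$imp) best <- list(imp = imp, f = f, thr = thr)
        }
      }
    }
    if (is.na(best$f)) {
      val <- rep(sum(r) / max(sum(w), 1e-12), n)
    } else {
      L <- X[, best$f] <= best$thr
      val <- ifelse(L, sum(r[L]) / max(sum(w[L]), 1e-12),
                    sum(r[!L]) / max(sum(w[!L]), 1e-12))
    }
    Fm <- Fm + nu * val
    staged[, m + 1] <- Fm
  }
  staged
}

# Hand-built ensemble encoding the pure interaction F = x1 * x2 on the
# +/-1-coded square: both marginal PDs vanish by symmetry, so H must be 1.
pure_interaction_ensemble <- function() {
  tree <- matrix(c(
    1, 0, NA,  2, 5, 1,   # split x1 at 0
    2, 0, NA,  3, 4, 1,   # x1 <= 0: split x2
    0, 0,  1,  0, 0, 0,   # x1=-1, x2=-1 -> +1
    0, 0, -1,  0, 0, 0,   # x1=-1, x2=+1 -> -1
    2, 0, NA,  6, 7, 1,   # x1 > 0: split x2
    0, 0, -1,  0, 0, 0,   # x1=+1, x2=-1 -> -1
    0, 0,  1,  0, 0, 0),  # x1=+1, x2=+1 -> +1
    ncol = 6, byrow = TRUE)
  gbt_ensemble(intercept = 0, shrinkage = 1, trees = list(tree),
               feature_names = c("x1", "x2"))
}

pm_square <- function() expand.grid(x1 = c(-1, 1), x2 = c(-1, 1))

# Mechanistic-mode study conditions shared by the recovery and inference
# simulations: planted flags get prevalences in the 0.3-0.45 range so the
# planted terms have non-trivial variance.
mech_prevalence <- function() {
  p <- cohort_spec()$prevalence
  p$mild[c("elevated_wbc", "hyperglycemia", "mri_spinal_cord",
           "fever_ge_3_days")] <- c(0.40, 0.35, 0.30, 0.45)
  p$severe <- p$mild
  p
}

null_cohort_spec <- function(seed, n = 200) {
  cohort_spec(n_mild = n / 2, n_severe = n / 2, mode = "mechanistic",
              beta0 = 0, seed = seed)
}

dominant_effect_spec <- function(seed, n = 2000) {
  cohort_spec(n_mild = n / 2, n_severe = n / 2, mode = "mechanistic",
              prevalence = mech_prevalence(), beta0 = -1,
              beta = c(elevated_wbc = 2.5), seed = seed)
}

interaction_spec <- function(seed, n = 1200, gamma = 2.5) {
  cohort_spec(n_mild = n / 2, n_severe = n / 2, mode = "mechanistic",
              prevalence = mech_prevalence(), beta0 = -1,
              beta = c(elevated_wbc = 0.5, hyperglycemia = 0.5),
              gamma = c("elevated_wbc:hyperglycemia" = gamma), seed = seed)
}

# Fit configuration used throughout the simulation studies.
sim_config <- function(n_trees = 200, seed = 1L) {
  gbt_config(n_trees = n_trees, shrinkage = 0.1, max_depth = 2,
             min_node_size = 10, bag_fraction = 0.5, seed = seed)
}

feature_frame <- function(mf) mf[, setdiff(names(mf), "outcome"), drop = FALSE]

# Small fixed 20-row fixture used by the oracle-equivalence tests.
fixture_frame <- function(n = 20, seed = 42) {
  set.seed(seed)
  data.frame(x1 = rbinom(n, 1, 0.5),
             x2 = rbinom(n, 1, 0.4),
             x3 = round(runif(n, 0, 10), 2),
             outcome = rbinom(n, 1, 0.5))
}
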