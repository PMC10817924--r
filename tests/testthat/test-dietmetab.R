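tiny_settings <- rdcv_settings(n_rep = 1, n_outer = 4, n_inner = 3,
                               n_trees = 30)

test_that("rdCV preconditions are enforced", {
  set.seed(1)
  X <- matrix(rnorm(60 * 20), 60, 20)
  expect_error(rdcv_rf(X[1:30, ], rnorm(30), tiny_settings, seed = 1),
               ">= 50 samples")
  expect_error(rdcv_rf(X[, 1:5], rnorm(60), tiny_settings, seed = 1),
               ">= 10 features")
  expect_error(rdcv_rf(X, rep(1, 60), tiny_settings, seed = 1), "constant")
  expect_error(rdcv_rf(X, rnorm(60),
                       rdcv_settings(n_rep = 1, n_outer = 15, n_inner = 3),
                       seed = 1), "< 5 samples")
  expect_error(rdcv_rf(X, rnorm(60), tiny_settings), "seed")
})

test_that("a response copied from one feature is predicted and selected", {
  set.seed(2)
  n <- 150
  X <- matrix(rnorm(n * 15), n, 15, dimnames = list(NULL, paste0("f", 1:15)))
  y <- X[, 3]
  st <- rdcv_settings(n_rep = 2, n_outer = 4, n_inner = 3, n_trees = 100)
  md <- rdcv_rf(X, y, st, seed = 3)
  expect_gte(md$q2, 0.9)
  expect_true("f3" %in% md$selected)
  expect_equal(unname(md$selection_freq["f3"]), 1)   # kept by every model
})

test_that("outer folds partition the samples in every repetition", {
  set.seed(4)
  X <- matrix(rnorm(60 * 12), 60, 12)
  md <- rdcv_rf(X, rnorm(60), tiny_settings, seed = 5)
  for (fold in md$folds) {
    expect_equal(sort(unique(fold)), 1:4)
    expect_equal(length(fold), 60L)
    # held-out indices of each outer fold are disjoint from its training set
    for (o in 1:4)
      expect_length(intersect(which(fold == o), which(fold != o)), 0)
  }
  # every sample receives exactly one out-of-fold prediction per repetition
  expect_false(anyNA(md$oof))
})

test_that("rdCV runs are reproducible under a fixed seed", {
  set.seed(6)
  X <- matrix(rnorm(60 * 12), 60, 12)
  y <- rnorm(60)
  m1 <- rdcv_rf(X, y, tiny_settings, seed = 7)
  m2 <- rdcv_rf(X, y, tiny_settings, seed = 7)
  expect_equal(m1$q2, m2$q2)
  expect_equal(m1$selected, m2$selected)
})

test_that("permutation p is exactly the rank bound under a strong signal", {
  set.seed(8)
  n <- 60
  X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("f", 1:12)))
  y <- X[, 1]
  md <- rdcv_rf(X, y, tiny_settings, seed = 9)
  pt <- permutation_test(X, y, tiny_settings, n_perm = 20, seed = 9,
                         model = md)
  expect_equal(pt$p_empirical, 1 / 21)
  expect_lt(pt$p_parametric, 1e-6)
  expect_lt(mean(pt$q2_perm), 0.05)   # permuted Q2 centred at/below zero
  expect_error(permutation_test(X, y, tiny_settings, n_perm = 5, seed = 9),
               ">= 20")
})

test_that("partial Spearman reduces to ordinary Spearman without covariates", {
  set.seed(10)
  x <- rnorm(100); y <- 0.5 * x + rnorm(100)
  rec <- partial_spearman(x, y)
  r_ref <- cor(x, y, method = "spearman")
  expect_equal(rec$rho, r_ref, tolerance = 1e-12)
  # independent t-approximation on n - 2 df
  p_ref <- 2 * pt(-abs(r_ref * sqrt(98 / (1 - r_ref^2))), 98)
  expect_equal(rec$p, p_ref, tolerance = 1e-10)
})

test_that("monotone transforms give rank correlation 1", {
  set.seed(11)
  x <- rnorm(500)
  rec <- partial_spearman(exp(x), x,
                          covariates = data.frame(u = rnorm(500)))
  expect_gte(rec$rho, 0.99)
})

test_that("covariate adjustment removes confounded association", {
  set.seed(12)
  n <- 1000
  u <- rnorm(n)
  feature <- u + rnorm(n, 0, 0.3)
  exposure <- u + rnorm(n, 0, 0.3)
  marginal <- abs(cor(feature, exposure, method = "spearman"))
  expect_gt(marginal, 0.8)
  rec <- partial_spearman(feature, exposure,
                          covariates = data.frame(u = u))
  expect_lt(abs(rec$rho), 0.1)
})

test_that("degenerate inputs yield explicit null association records", {
  x <- rnorm(50)
  u <- seq_len(50)
  rec <- partial_spearman(u, x, covariates = data.frame(u = u))
  expect_true(is.na(rec$rho))
  expect_error(partial_spearman(rnorm(10), rnorm(10)), ">= 20")
})

test_that("feature selection unions, validates, deduplicates and is monotone", {
  models <- list(
    alcohol = list(q2 = 0.22, p_permutation = 0.01,
                   selected = c("RN_1", "RN_2")),
    fiber = list(q2 = 0.19, p_permutation = 0.01,
                 selected = c("RN_1", "RP_9")),
    meat = list(q2 = 0.02, p_permutation = NA, selected = "RP_5"))
  assoc <- data.frame(
    feature_id = c("RN_1", "RN_2", "RN_1", "RP_9", "RP_5"),
    exposure = c("alcohol", "alcohol", "fiber", "fiber", "meat"),
    rho = c(0.4, 0.3, 0.35, 0.02, 0.5),
    p = c(1e-4, 1e-3, 1e-3, 0.8, 1e-5))
  sel <- select_diet_features(models, assoc)
  expect_equal(sort(sel$feature_id), c("RN_1", "RN_2"))
  # shared feature appears once with both exposure tags
  expect_equal(sel$exposures[sel$feature_id == "RN_1"], "alcohol,fiber")
  expect_equal(sel$n_exposures[sel$feature_id == "RN_1"], 2L)
  # meat fails the Q2 screen; RP_9 fails partial-Spearman validation
  expect_false(any(c("RP_5", "RP_9") %in% sel$feature_id))
  # relaxing thresholds never shrinks the selection
  sel_relaxed <- select_diet_features(models, assoc, q2_thresh = 0.01,
                                      p_thresh = 0.9)
  expect_true(all(sel$feature_id %in% sel_relaxed$feature_id))
  none <- select_diet_features(models, assoc, q2_thresh = 0.99)
  expect_equal(nrow(none), 0L)
})
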