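test_that("configuration is validated and a seed is mandatory", {
  expect_error(sim_config(n_pairs = 100), "seed")
  expect_error(sim_config(n_pairs = 1, seed = 1), "n_pairs")
  expect_error(sim_config(n_pairs = 10, missing_rate = 1, seed = 1),
               "missing_rate")
  expect_error(sim_config(n_pairs = 10,
                          planted_log_or = c(nonexistent = 0.2), seed = 1),
               "unknown exposures")
  expect_error(
    sim_config(n_pairs = 10,
               planted_factors = list(list(name = "a", foods = 1:3,
                                           loadings = c(0.5, 0.5))),
               seed = 1),
    "inconsistent")
  expect_error(
    sim_config(n_pairs = 10, n_features = 5,
               planted_feature_links = data.frame(feature = 9L,
                                                  exposure = "breakfast_food",
                                                  effect = 1),
               seed = 1),
    "unknown features")
})

test_that("same config and seed give byte-identical written cohorts", {
  cfg <- sim_config(n_pairs = 40, n_features = 20, seed = 123)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    sim <- generate_cohort(cfg)
    sim$metab <- generate_metabolome(sim$cohort, sim$diet, cfg)
    write_cohort(sim, d)
  }
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("matching variables are exactly equal within every pair", {
  sim <- generate_cohort(sim_config(n_pairs = 200, seed = 7))
  co <- sim$cohort
  expect_equal(nrow(co), 400L)
  for (v in c("sex", "cohort", "age")) {
    per_pair <- tapply(co[[v]], co$pair_id, function(x) length(unique(x)))
    expect_true(all(per_pair == 1L), label = v)
  }
  expect_true(all(tapply(co$case, co$pair_id, sum) == 1L))
  expect_true(all(tapply(co$case, co$pair_id, length) == 2L))
})

test_that("frequencies lie on the 9-level ordinal scale", {
  sim <- generate_cohort(sim_config(n_pairs = 100, seed = 3))
  freq <- as.matrix(sim$diet[, grep("^freq_", names(sim$diet))])
  expect_true(all(freq %in% 1:9))
  expect_true(all(sim$diet$energy_kcal > 0))
  amt <- as.matrix(sim$diet[, grep("^amt_", names(sim$diet))])
  expect_true(all(amt >= 0))
})

test_that("ground truth records the planted quantities unchanged", {
  links <- data.frame(feature = c(2L, 5L), exposure = "meat",
                      effect = c(0.8, -0.5))
  cfg <- sim_config(n_pairs = 50, n_features = 10,
                    planted_feature_links = links,
                    planted_log_or = c(meat = log(1.4)), seed = 11)
  sim <- generate_cohort(cfg)
  expect_equal(sim$truth$log_or, c(meat = log(1.4)))
  expect_equal(sim$truth$feature_links, links)
  expect_equal(dim(sim$truth$factor_loadings), c(24L, 4L))
  lam <- sim$truth$factor_loadings
  expect_equal(unname(lam[1:6, "breakfast_food"]), rep(0.75, 6))
})

test_that("null planted effects give case status independent of exposures", {
  betas <- vapply(1:20, function(s) {
    sim <- generate_cohort(sim_config(n_pairs = 300, seed = 9000 + s))
    ex <- attr(sim$diet, "latent_scores")[, "breakfast_food"]
    fit_clogit(sim$cohort, ex, covariates = character(0),
               exposure_name = "bf")$beta
  }, 0)
  # mean of 20 null estimates: se ~ sd(beta_hat)/sqrt(20) ~ 0.08/4.5
  expect_lt(abs(mean(betas)), 0.05)
})

test_that("planted per-SD log odds are recovered by conditional logistic fits", {
  betas <- vapply(1:25, function(s) {
    cfg <- sim_config(n_pairs = 800,
                      planted_log_or = c(meat = log(0.8)), seed = 5000 + s)
    sim <- generate_cohort(cfg)
    ex <- attr(sim$diet, "latent_scores")[, "meat"]
    fit_clogit(sim$cohort, ex, exposure_name = "meat")$beta
  }, 0)
  expect_lt(abs(mean(betas) - log(0.8)), 0.05)
})

test_that("QC injections replicate the pooled profile at the set technical CV", {
  cfg <- sim_config(n_pairs = 300, n_features = 40, qc_cv = 0.10,
                    missing_rate = 0, seed = 21)
  sim <- generate_cohort(cfg)
  mm <- generate_metabolome(sim$cohort, sim$diet, cfg)
  qc <- mm$intensities[mm$sample_meta$sample_id[mm$sample_meta$role == "sQC"], ]
  cvs <- apply(qc, 2L, function(x) sd(x) / mean(x))
  # oracle: direct sd/mean on the generated QC block, target 0.10
  expect_lt(abs(mean(cvs) - 0.10), 0.02)
  expect_true(all(cvs > 0.05 & cvs < 0.2))
})

test_that("planted feature links are monotone; unlinked features are null", {
  links <- data.frame(feature = 1L, exposure = "vegetables", effect = 1)
  cfg <- sim_config(n_pairs = 300, n_features = 50,
                    planted_feature_links = links, feature_noise_sd = 0,
                    missing_rate = 0, seed = 31)
  sim <- generate_cohort(cfg)
  mm <- generate_metabolome(sim$cohort, sim$diet, cfg)
  study <- mm$sample_meta$sample_id[mm$sample_meta$role == "study"]
  z <- attr(sim$diet, "latent_scores")[, "vegetables"]
  # zero-noise monotone transform: Spearman correlation exactly 1
  expect_equal(cor(mm$intensities[study, 1], z, method = "spearman"), 1)

  cfg0 <- sim_config(n_pairs = 300, n_features = 100, missing_rate = 0,
                     seed = 32)
  sim0 <- generate_cohort(cfg0)
  mm0 <- generate_metabolome(sim0$cohort, sim0$diet, cfg0)
  z0 <- attr(sim0$diet, "latent_scores")[, "vegetables"]
  rhos <- abs(cor(mm0$intensities[study, ], z0, method = "spearman"))
  # max over 100 null features at n = 600 stays below 5/sqrt(n)
  expect_lt(max(rhos), 5 / sqrt(600))
})

test_that("missing values are inserted at the configured MCAR rate", {
  cfg <- sim_config(n_pairs = 400, n_features = 60, missing_rate = 0.05,
                    seed = 41)
  sim <- generate_cohort(cfg)
  mm <- generate_metabolome(sim$cohort, sim$diet, cfg)
  study <- mm$sample_meta$sample_id[mm$sample_meta$role == "study"]
  rate <- mean(is.na(mm$intensities[study, ]))
  expect_lt(abs(rate - 0.05), 0.005)
  qc <- mm$sample_meta$sample_id[mm$sample_meta$role == "sQC"]
  expect_false(anyNA(mm$intensities[qc, ]))
  expect_error(generate_metabolome(sim$cohort, sim$diet[1:10, ], cfg),
               "participant ids")
})
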