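test_that("no within-pair exposure contrast gives OR exactly 1", {
  co <- random_pair_cohort(30, seed = 1)
  pair_level <- rnorm(30)
  expo <- pair_level[co$pair_id]   # identical within every pair
  r <- fit_clogit(co, expo, covariates = character(0), exposure_name = "x")
  expect_equal(r$beta, 0)
  expect_equal(r$or, 1)
})

test_that("discordant-pair closed form is matched exactly", {
  d <- discordant_cohort(n_case_exposed = 10, n_control_exposed = 5)
  r <- fit_clogit(d$cohort, d$exposure, covariates = character(0),
                  exposure_name = "binary", standardize = FALSE)
  expect_equal(r$or, 2, tolerance = 1e-6)
  # closed-form discordant-pair estimator: n10/n01
  expect_equal(r$beta, log(10 / 5), tolerance = 1e-6)
})

test_that("conditional fit equals no-intercept logistic on pair differences", {
  co <- random_pair_cohort(120, seed = 9)
  r <- fit_clogit(co, co$x, covariates = c("z1", "z2"),
                  exposure_name = "x", standardize = FALSE)
  oracle <- pairdiff_logit(transform(co, .e = co$x),
                           c(".e", "z1", "z2"))
  expect_equal(r$beta, unname(oracle[".e"]), tolerance = 1e-8)
})

test_that("swapping case and control labels negates the coefficient", {
  co <- random_pair_cohort(80, seed = 13)
  r1 <- fit_clogit(co, co$x, covariates = "z1", exposure_name = "x")
  co2 <- co
  co2$case <- 1L - co2$case
  r2 <- fit_clogit(co2, co2$x, covariates = "z1", exposure_name = "x")
  expect_equal(r1$beta, -r2$beta, tolerance = 1e-8)
})

test_that("per-SD odds ratio is invariant to linear exposure rescaling", {
  co <- random_pair_cohort(100, seed = 17)
  r1 <- fit_clogit(co, co$x, covariates = "z1", exposure_name = "x")
  r2 <- fit_clogit(co, 100 + 3.7 * co$x, covariates = "z1",
                   exposure_name = "x")
  expect_equal(r1$or, r2$or, tolerance = 1e-8)
})

test_that("pair-constant covariates do not move the exposure estimate", {
  co <- random_pair_cohort(100, seed = 21)
  co$age <- rep(sample(40:60, 100, replace = TRUE), each = 2)  # matched
  r1 <- fit_clogit(co, co$x, covariates = "z1", exposure_name = "x")
  r2 <- suppressWarnings(
    fit_clogit(co, co$x, covariates = c("z1", "age"), exposure_name = "x"))
  expect_equal(r1$beta, r2$beta, tolerance = 1e-8)
})

test_that("pairs with missing covariates are dropped pair-wise", {
  co <- random_pair_cohort(60, seed = 23)
  co$z1[co$participant_id %in% c("P0001", "P0004")] <- NA  # pairs 1 and 2
  r <- fit_clogit(co, co$x, covariates = "z1", exposure_name = "x")
  expect_equal(r$n_pairs, 58L)
  expect_error(fit_clogit(co, rep(1, nrow(co)), covariates = "z1",
                          exposure_name = "const"), "SD")
})

test_that("sex strata partition all pairs; site strata exclude unknown", {
  cfg <- sim_config(n_pairs = 250, planted_log_or = c(meat = 0.3), seed = 27)
  sim <- generate_cohort(cfg)
  ex <- attr(sim$diet, "latent_scores")[, "meat"]
  res <- stratified_analysis(sim$cohort, ex, covariates = character(0),
                             exposure_name = "meat")
  n_sex <- sum(res$n_pairs[startsWith(res$stratum, "sex:")])
  expect_equal(n_sex, 250L)
  n_site <- sum(res$n_pairs[startsWith(res$stratum, "site:")])
  n_known <- sum(!is.na(sim$cohort$tumor_site[sim$cohort$case == 1]))
  expect_equal(n_site, n_known)
})

test_that("site-specific planted effects surface in the right stratum", {
  hits_distal <- 0; hits_proximal_null <- 0
  n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_pairs = 800,
                      site_log_or = list(meat = c(proximal = 0, distal = 0.6,
                                                  rectum = 0)),
                      seed = 400 + s)
    sim <- generate_cohort(cfg)
    ex <- attr(sim$diet, "latent_scores")[, "meat"]
    res <- stratified_analysis(sim$cohort, ex, covariates = character(0),
                               exposure_name = "meat", strata = "site")
    di <- res[res$stratum == "site:distal", ]
    pr <- res[res$stratum == "site:proximal", ]
    if (di$ci_low > 1) hits_distal <- hits_distal + 1
    if (pr$ci_low <= 1 && pr$ci_high >= 1)
      hits_proximal_null <- hits_proximal_null + 1
  }
  expect_gt(hits_distal, n_seeds / 2)
  expect_gt(hits_proximal_null, n_seeds / 2)
})

test_that("alcohol exposures drop the alcohol covariate automatically", {
  cfg <- sim_config(n_pairs = 200, seed = 31)
  sim <- generate_cohort(cfg)
  ex <- derive_exposures(sim$diet, default_apriori_defs(24))
  alc <- ex$components_adj$total_alcohol
  r_auto <- fit_clogit(sim$cohort, alc, exposure_name = "total_alcohol")
  r_forced <- fit_clogit(sim$cohort, alc, exposure_name = "total_alcohol",
                         exclude_alcohol = TRUE)
  expect_equal(r_auto$beta, r_forced$beta)
  r_with <- fit_clogit(sim$cohort, alc, exposure_name = "total_alcohol",
                       exclude_alcohol = FALSE)
  expect_false(isTRUE(all.equal(r_auto$beta, r_with$beta)))
})
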