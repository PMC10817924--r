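#' Configuration for the synthetic matched case-control cohort generator
#'
#' Bundles every knob of the simulated study: cohort size, the FFQ food list,
#' planted latent dietary factors (the ground truth that the pattern-derivation
#' stage should recover), hypothesis-driven component definitions, the
#' metabolome layout with planted feature-exposure links, per-SD log-odds for
#' the conditional-logistic outcome model, and QC/missingness structure.
#'
#' @param n_pairs Number of matched case-control pairs (>= 2).
#' @param n_foods Number of FFQ food items.
#' @param planted_factors List of planted latent dietary factors; each element
#'   is a list with `name`, `foods` (indices into `1:n_foods`) and `loadings`
#'   (values in \[0, 1\], same length as `foods`). See
#'   [default_planted_factors()].
#' @param apriori_defs Named list mapping hypothesis-driven component names to
#'   food indices (the synthetic analogue of a food-group table).
#' @param n_features Number of LC-MS metabolite features to simulate.
#' @param planted_feature_links Data frame with columns `feature` (index),
#'   `exposure` (a planted factor or a priori component name) and `effect`
#'   (per-SD shift of log intensity; monotone link). May have zero rows.
#' @param planted_log_or Named numeric vector of per-1-SD log-odds of being
#'   the case within a pair, keyed by exposure name. Empty vector = null model.
#' @param site_log_or Optional named list: exposure name -> numeric vector
#'   `c(proximal=, distal=, rectum=)` of site-specific per-SD log-odds. When
#'   supplied, each pair is first assigned a tumor site and the case label is
#'   drawn under that site's coefficients (for testing site stratification).
#' @param qc_every One pooled study QC (sQC) injection after every `qc_every`
#'   study samples.
#' @param qc_cv Technical noise of sQC injections as a proportion of the
#'   pooled profile (additive normal; realized per-feature CVs sit near this).
#' @param missing_rate Proportion of study-sample intensity cells set missing
#'   completely at random (must be < 1).
#' @param feature_noise_sd Residual SD of log intensities around the planted
#'   exposure signal.
#' @param site_probs Multinomial probabilities for proximal colon, distal
#'   colon and rectum among cases.
#' @param covariate_missing_rate Proportion of lifestyle covariate cells set
#'   missing at random (for exercising pair-wise deletion).
#' @param seed Integer seed; mandatory.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_pairs = 500,
                       n_foods = 24,
                       planted_factors = default_planted_factors(n_foods),
                       apriori_defs = default_apriori_defs(n_foods),
                       n_features = 100,
                       planted_feature_links = data.frame(feature = integer(),
                                                          exposure = character(),
                                                          effect = numeric()),
                       planted_log_or = c(),
                       site_log_or = NULL,
                       qc_every = 10,
                       qc_cv = 0.10,
                       missing_rate = 0.02,
                       feature_noise_sd = 1,
                       site_probs = c(proximal = 0.35, distal = 0.30, rectum = 0.35),
                       covariate_missing_rate = 0,
                       seed = NULL) {
  cfg <- list(n_pairs = as.integer(n_pairs), n_foods = as.integer(n_foods),
              planted_factors = planted_factors, apriori_defs = apriori_defs,
              n_features = as.integer(n_features),
              planted_feature_links = planted_feature_links,
              planted_log_or = planted_log_or, site_log_or = site_log_or,
              qc_every = as.integer(qc_every), qc_cv = qc_cv,
              missing_rate = missing_rate, feature_noise_sd = feature_noise_sd,
              site_probs = site_probs,
              covariate_missing_rate = covariate_missing_rate,
              seed = check_seed(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_pairs < 2L) stop("configuration error: n_pairs must be >= 2")
  if (length(cfg$planted_factors) < 1L)
    stop("configuration error: at least one planted factor is required")
  for (f in cfg$planted_factors) {
    if (!all(c("name", "foods", "loadings") %in% names(f)))
      stop("configuration error: each planted factor needs name/foods/loadings")
    if (length(f$foods) != length(f$loadings))
      stop("configuration error: factor '", f$name,
           "' has inconsistent foods/loadings dimensions")
    if (any(f$foods < 1L | f$foods > cfg$n_foods))
      stop("configuration error: factor '", f$name,
           "' references foods outside 1..n_foods")
    if (!all(is.finite(f$loadings)) || any(f$loadings < 0 | f$loadings > 1))
      stop("configuration error: loadings must be finite and in [0, 1]")
  }
  for (nm in names(cfg$apriori_defs)) {
    idx <- cfg$apriori_defs[[nm]]
    if (any(idx < 1L | idx > cfg$n_foods))
      stop("configuration error: component '", nm,
           "' references foods outside 1..n_foods")
  }
  known <- exposure_names(cfg)
  if (length(cfg$planted_log_or) &&
      !all(names(cfg$planted_log_or) %in% known))
    stop("configuration error: planted_log_or references unknown exposures: ",
         paste(setdiff(names(cfg$planted_log_or), known), collapse = ", "))
  if (!is.null(cfg$site_log_or) &&
      !all(names(cfg$site_log_or) %in% known))
    stop("configuration error: site_log_or references unknown exposures")
  fl <- cfg$planted_feature_links
  if (nrow(fl)) {
    if (any(fl$feature < 1L | fl$feature > cfg$n_features))
      stop("configuration error: feature links reference unknown features")
    if (!all(fl$exposure %in% known))
      stop("configuration error: feature links reference unknown exposures: ",
           paste(setdiff(fl$exposure, known), collapse = ", "))
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("configuration error: missing_rate must lie in [0, 1)")
  if (cfg$qc_every < 2L) stop("configuration error: qc_every must be >= 2")
  invisible(cfg)
}

exposure_names <- function(cfg) {
  c(vapply(cfg$planted_factors, `[[`, "", "name"), names(cfg$apriori_defs))
}

#' Default planted latent dietary factors
#'
#' Four well-separated factors of six foods each (for `n_foods >= 24`),
#' loosely themed after breakfast-food, meat, vegetable and alcohol patterns.
#' Primary loadings of 0.75 leave enough unique variance for a realistic
#' factor-analysis problem while remaining comfortably recoverable.
#'
#' @param n_foods Total number of foods.
#' @param n_factors Number of planted factors.
#' @param foods_per_factor Indicator foods per factor.
#' @param loading Common primary loading value.
#' @return A list suitable for `sim_config(planted_factors = )`.
#' @export
default_planted_factors <- function(n_foods = 24, n_factors = 4,
                                    foods_per_factor = 6, loading = 0.75) {
  if (n_factors * foods_per_factor > n_foods)
    stop("n_factors * foods_per_factor exceeds n_foods")
  nms <- c("breakfast_food", "meat", "vegetables", "alcohol",
           paste0("factor_", seq_len(max(0, n_factors - 4)) + 4L))[seq_len(n_factors)]
  lapply(seq_len(n_factors), function(j) {
    list(name = nms[j],
         foods = ((j - 1L) * foods_per_factor + 1L):(j * foods_per_factor),
         loadings = rep(loading, foods_per_factor))
  })
}

#' Default hypothesis-driven component definitions for synthetic cohorts
#'
#' Small food groups over the synthetic food list, mirroring the structure
#' (not the catalogue) of a real food-group table: a red-meat group, a
#' processed-meat group, their union plus one extra shared food, and a
#' total-alcohol group.
#'
#' @param n_foods Total number of foods (>= 24 for the defaults).
#' @return Named list of food-index vectors.
#' @export
default_apriori_defs <- function(n_foods = 24) {
  if (n_foods < 24) return(list())
  list(red_meat = 7:9,
       processed_meat = 10:11,
       red_and_processed_meat = 7:12,
       total_alcohol = 19:22,
       fruit_and_vegetables = 13:18)
}

# cumulative probabilities of the 9 ordinal frequency levels; fixed so the
# discretization thresholds never depend on the data
freq_cut_probs <- c(0.15, 0.35, 0.55, 0.70, 0.82, 0.90, 0.96, 0.99)

#' Generate a synthetic matched case-control cohort with planted structure
#'
#' Simulates `2 * n_pairs` participants in individually matched 1:1 pairs
#' (sex, cohort label and age equal within pair), FFQ frequencies on the
#' 9-level ordinal scale driven by planted latent dietary factors, per-food
#' amounts, total energy, lifestyle covariates, and a case label drawn from
#' the 1:1 conditional-logistic model
#' `P(first is case) = exp(b'x1) / (exp(b'x1) + exp(b'x2))`
#' with planted per-SD coefficients on standardized exposures. Tumor sites
#' are assigned to cases by fixed multinomial probabilities, optionally with
#' site-specific exposure effects.
#'
#' @param config A [sim_config()].
#' @return A list with components `cohort` (participant table), `diet`
#'   (FFQ frequency levels, amounts in g/day, energy, precomputed calcium and
#'   fiber totals; latent factor scores attached as attribute
#'   `"latent_scores"`), and `truth` (a `ground_truth` object recording all
#'   planted quantities).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  np <- config$n_pairs
  n  <- 2L * np
  p  <- config$n_foods
  foods <- sprintf("food_%02d", seq_len(p))

  pair_id <- rep(seq_len(np), each = 2L)
  participant_id <- sprintf("P%05d", seq_len(n))

  # matching variables: constant within pair by construction
  sex_pair    <- sample(c("female", "male"), np, replace = TRUE)
  cohort_pair <- sample(c("VIP", "MONICA"), np, replace = TRUE,
                        prob = c(0.913, 0.087))
  age_pair    <- sample(40:60, np, replace = TRUE)
  sex    <- rep(sex_pair, each = 2L)
  cohlab <- rep(cohort_pair, each = 2L)
  age    <- rep(age_pair, each = 2L)

  # latent dietary factor scores and food propensities
  K <- length(config$planted_factors)
  fac_names <- vapply(config$planted_factors, `[[`, "", "name")
  scores <- matrix(stats::rnorm(n * K), n, K,
                   dimnames = list(participant_id, fac_names))
  Lambda <- matrix(0, p, K, dimnames = list(foods, fac_names))
  for (j in seq_len(K)) {
    f <- config$planted_factors[[j]]
    Lambda[f$foods, j] <- f$loadings
  }
  unique_sd <- sqrt(pmax(1 - rowSums(Lambda^2), 0.1))
  prop <- scores %*% t(Lambda) +
    matrix(stats::rnorm(n * p), n, p) %*% diag(unique_sd)

  cuts <- stats::qnorm(freq_cut_probs)
  freq_level <- matrix(findInterval(prop, cuts) + 1L, n, p,
                       dimnames = list(participant_id, foods))

  freq_day <- apply(freq_level, 2L, map_frequency_levels)
  portion <- stats::runif(p, 20, 200)   # g per eating occasion, per food
  amount <- freq_day * matrix(portion, n, p, byrow = TRUE) *
    exp(matrix(stats::rnorm(n * p, 0, 0.2), n, p))

  energy <- pmax(800, 1200 + 0.9 * rowSums(amount) + stats::rnorm(n, 0, 200))

  # nutrient totals supplied as precomputed columns (food-composition lookup
  # is out of scope); driven by the first planted factor's foods so they
  # behave like correlated hypothesis-driven components
  src <- config$planted_factors[[1L]]$foods
  calcium_mg <- 4 * rowSums(amount[, src, drop = FALSE]) +
    stats::rnorm(n, 400, 60)
  fiber_g <- 0.05 * rowSums(amount[, src, drop = FALSE]) +
    stats::rnorm(n, 15, 3)

  # alcohol intake in g/day: mixture of true zeros and gamma consumption
  alcohol_g <- ifelse(stats::runif(n) < 0.09, 0,
                      stats::rgamma(n, shape = 2, scale = 2.2))
  if ("total_alcohol" %in% names(config$apriori_defs)) {
    idx <- config$apriori_defs$total_alcohol
    alcohol_g <- ifelse(alcohol_g == 0, 0,
                        alcohol_g + 0.02 * rowSums(amount[, idx, drop = FALSE]))
  }

  bmi <- stats::rnorm(n, 26.4, 4)
  smoking <- sample(c("never", "ex", "current"), n, replace = TRUE,
                    prob = c(0.42, 0.35, 0.23))
  physical_activity <- sample(c("none", "low", "medium", "high"), n,
                              replace = TRUE, prob = c(0.43, 0.26, 0.26, 0.05))
  education <- sample(c("elementary", "secondary", "post-secondary"), n,
                      replace = TRUE, prob = c(0.38, 0.44, 0.18))

  diet <- data.frame(participant_id = participant_id, check.names = FALSE)
  for (j in seq_len(p)) diet[[paste0("freq_", foods[j])]] <- freq_level[, j]
  for (j in seq_len(p)) diet[[paste0("amt_", foods[j])]] <- amount[, j]
  diet$energy_kcal <- energy
  diet$calcium_mg <- calcium_mg
  diet$fiber_g <- fiber_g
  attr(diet, "latent_scores") <- scores

  # exposures for the outcome model, standardized to unit SD
  expo <- exposure_matrix(config, scores, amount, foods)

  # case assignment by the exact 1:1 conditional-logistic probability
  i1 <- seq(1L, n, by = 2L)
  i2 <- i1 + 1L
  site <- rep(NA_character_, n)
  beta <- config$planted_log_or
  if (!is.null(config$site_log_or) && length(config$site_log_or)) {
    pair_site <- sample(names(config$site_probs), np, replace = TRUE,
                        prob = config$site_probs)
    eta <- matrix(0, n, 1L)
    for (nm in names(config$site_log_or)) {
      b_site <- config$site_log_or[[nm]]
      eta <- eta + expo[, nm, drop = FALSE] *
        unname(b_site[rep(pair_site, each = 2L)])
    }
    if (length(beta))
      eta <- eta + expo[, names(beta), drop = FALSE] %*% cbind(unname(beta))
    p_first <- 1 / (1 + exp(eta[i2] - eta[i1]))
    first_is_case <- stats::rbinom(np, 1L, p_first) == 1L
    case_site <- pair_site
  } else {
    if (length(beta)) {
      eta <- expo[, names(beta), drop = FALSE] %*% cbind(unname(beta))
      p_first <- 1 / (1 + exp(eta[i2] - eta[i1]))
    } else {
      p_first <- rep(0.5, np)
    }
    first_is_case <- stats::rbinom(np, 1L, p_first) == 1L
    case_site <- sample(names(config$site_probs), np, replace = TRUE,
                        prob = config$site_probs)
  }
  case <- integer(n)
  case[i1] <- as.integer(first_is_case)
  case[i2] <- as.integer(!first_is_case)
  site[case == 1L] <- case_site

  cohort <- data.frame(participant_id = participant_id, pair_id = pair_id,
                       case = case, sex = sex, cohort = cohlab, age = age,
                       bmi = bmi, smoking = smoking,
                       physical_activity = physical_activity,
                       education = education, energy_kcal = energy,
                       alcohol_g = alcohol_g, tumor_site = site,
                       stringsAsFactors = FALSE)

  if (config$covariate_missing_rate > 0) {
    for (v in c("bmi", "smoking", "physical_activity", "education")) {
      miss <- stats::runif(n) < config$covariate_missing_rate
      cohort[[v]][miss] <- NA
    }
  }

  truth <- structure(list(factor_loadings = Lambda,
                          log_or = config$planted_log_or,
                          site_log_or = config$site_log_or,
                          feature_links = config$planted_feature_links,
                          latent_scores = scores,
                          portions = stats::setNames(portion, foods),
                          seed = config$seed),
                     class = "ground_truth")
  list(cohort = cohort, diet = diet, truth = truth)
}

# participants x exposures matrix (standardized), resolving planted factor
# names to latent scores and a priori component names to amount sums
exposure_matrix <- function(config, scores, amount, foods) {
  nms <- exposure_names(config)
  out <- matrix(0, nrow(scores), length(nms),
                dimnames = list(rownames(scores), nms))
  for (nm in nms) {
    if (nm %in% colnames(scores)) {
      v <- scores[, nm]
    } else {
      v <- rowSums(amount[, config$apriori_defs[[nm]], drop = FALSE])
    }
    s <- stats::sd(v)
    out[, nm] <- if (s > 0) (v - mean(v)) / s else 0
  }
  out
}

#' Generate a synthetic LC-MS metabolite feature matrix
#'
#' Simulates log-normal feature intensities for all study participants, with
#' planted monotone links between selected features and dietary exposures,
#' pooled study-QC (sQC) injections inserted every `qc_every` study samples
#' (replicates of the pooled mean profile plus technical noise of relative
#' magnitude `qc_cv`), and values missing completely at random among study
#' samples at `missing_rate`.
#'
#' @param cohort Cohort table from [generate_cohort()].
#' @param diet Diet matrix from the same call (carries the latent factor
#'   scores needed to resolve factor-named exposures).
#' @param config The same [sim_config()].
#' @return A `metab_matrix` object: list with `intensities` (samples x
#'   features, rownames = sample ids), `sample_meta` (sample id, role,
#'   injection order, participant id) and `feature_meta` (feature id,
#'   ionization mode, retention time, m/z).
#' @export
generate_metabolome <- function(cohort, diet, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$missing_rate >= 1) stop("missing_rate must be < 1")
  if (!identical(cohort$participant_id, diet$participant_id))
    stop("cohort and diet must share participant ids")
  set.seed(child_seed(config$seed, 1L))
  n <- nrow(cohort)
  m <- config$n_features
  feats <- c(sprintf("RP_%04d", seq_len(ceiling(m / 2))),
             sprintf("RN_%04d", seq_len(floor(m / 2))))
  mode <- ifelse(startsWith(feats, "RP"), "positive", "negative")
  mz <- stats::runif(m, 60, 1600)
  rt <- stats::runif(m, 30, 700)

  scores <- attr(diet, "latent_scores")
  foods <- sprintf("food_%02d", seq_len(config$n_foods))
  amount <- as.matrix(diet[, paste0("amt_", foods), drop = FALSE])
  colnames(amount) <- foods
  expo <- exposure_matrix(config, scores, amount, foods)

  base <- stats::runif(m, 10, 14)
  logI <- matrix(base, n, m, byrow = TRUE) +
    matrix(stats::rnorm(n * m, 0, config$feature_noise_sd), n, m)
  fl <- config$planted_feature_links
  if (nrow(fl)) {
    for (r in seq_len(nrow(fl))) {
      logI[, fl$feature[r]] <- logI[, fl$feature[r]] +
        fl$effect[r] * expo[, fl$exposure[r]]
    }
  }
  X <- exp(logI)
  dimnames(X) <- list(cohort$participant_id, feats)

  # sQC injections: replicates of the pooled study profile + technical noise
  n_qc <- max(2L, floor(n / config$qc_every))
  pooled <- colMeans(X)
  QC <- matrix(pooled, n_qc, m, byrow = TRUE) *
    (1 + matrix(stats::rnorm(n_qc * m, 0, config$qc_cv), n_qc, m))
  QC <- pmax(QC, 0)
  qc_ids <- sprintf("sQC_%03d", seq_len(n_qc))
  rownames(QC) <- qc_ids

  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    X[mask] <- NA
  }

  inj_study <- seq_len(n) + (seq_len(n) - 1L) %/% config$qc_every
  inj_qc <- seq_len(n_qc) * (config$qc_every + 1L)
  sample_meta <- data.frame(
    sample_id = c(cohort$participant_id, qc_ids),
    role = rep(c("study", "sQC"), c(n, n_qc)),
    injection_order = c(inj_study, inj_qc),
    participant_id = c(cohort$participant_id, rep(NA_character_, n_qc)),
    stringsAsFactors = FALSE)

  structure(list(intensities = rbind(X, QC),
                 sample_meta = sample_meta,
                 feature_meta = data.frame(feature_id = feats, mode = mode,
                                           rt_s = rt, mz = mz,
                                           stringsAsFactors = FALSE)),
            class = "metab_matrix")
}

#' @export
print.metab_matrix <- function(x, ...) {
  cat("metab_matrix:", sum(x$sample_meta$role == "study"), "study samples,",
      sum(x$sample_meta$role == "sQC"), "sQC injections,",
      nrow(x$feature_meta), "features\n")
  invisible(x)
}

#' Write a synthetic cohort to disk as UTF-8 TSV plus a ground-truth JSON
#'
#' @param sim Result of [generate_cohort()] (optionally with a `metab`
#'   element from [generate_metabolome()]).
#' @param dir Output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "cohort.tsv"), file.path(dir, "diet.tsv"),
             file.path(dir, "ground_truth.json"))
  write_tsv(sim$cohort, paths[1])
  write_tsv(sim$diet, paths[2])
  truth <- sim$truth
  jsonlite::write_json(
    list(factor_loadings = truth$factor_loadings,
         log_or = as.list(truth$log_or),
         feature_links = truth$feature_links,
         seed = truth$seed),
    paths[3], digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(sim$metab)) {
    mm <- sim$metab
    ints <- data.frame(sample_id = rownames(mm$intensities),
                       mm$intensities, check.names = FALSE)
    paths <- c(paths, file.path(dir, c("features.tsv", "sample_meta.tsv",
                                       "feature_meta.tsv")))
    write_tsv(ints, file.path(dir, "features.tsv"))
    write_tsv(mm$sample_meta, file.path(dir, "sample_meta.tsv"))
    write_tsv(mm$feature_meta, file.path(dir, "feature_meta.tsv"))
  }
  invisible(paths)
}
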