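#' Run the full diet-metabolome-CRC analysis pipeline on a synthetic cohort
#'
#' End-to-end orchestration of every stage on generated data with known
#' ground truth: cohort/diet/metabolome simulation; exposure preparation
#' (frequencies per day, energy-density adjustment, a priori components,
#' alcohol categorization); dietary-pattern derivation by the half-split
#' EFA/CFA stability procedure; per-1-SD conditional-logistic risk estimates
#' for every exposure; metabolite QC filtering and RF imputation; rdCV
#' random-forest diet-metabolome models with permutation testing and
#' partial-Spearman validation; feature selection; and PCA triplot
#' integration. All tables are written as deterministic TSV under `out_dir`.
#'
#' @param config A [sim_config()]; its seed drives every stage.
#' @param out_dir Output directory.
#' @param k_range,n_rep Stability-procedure scan (kept desk-scale by
#'   default; the full-scale defaults of [stability_select()] are 2:18 and
#'   5).
#' @param rdcv rdCV settings; see [rdcv_settings()].
#' @param n_perm Permutations for models passing the Q2 screen.
#' @param q2_thresh,p_thresh Selection thresholds (defaults 0.15 and 0.05).
#' @param cv_thresh QC CV filter threshold (default 0.30).
#' @param n_components Triplot components (default 3).
#' @return Invisibly, a list with all intermediate objects and the written
#'   file paths.
#' @export
run_pipeline <- function(config, out_dir,
                         k_range = 2:6, n_rep = 5,
                         rdcv = rdcv_settings(n_rep = 3, n_outer = 5,
                                              n_inner = 4, n_trees = 100),
                         n_perm = 20, q2_thresh = 0.15, p_thresh = 0.05,
                         cv_thresh = 0.30, n_components = 3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_cohort(config)
  sim$metab <- generate_metabolome(sim$cohort, sim$diet, config)
  write_cohort(sim, out_dir)

  expo <- derive_exposures(sim$diet, config$apriori_defs)

  pats <- stability_select(expo$freq_level, k_range = k_range, n_rep = n_rep,
                           seed = child_seed(config$seed, 11L))
  if (!is.null(pats$scores)) {
    sc <- pats$scores
    for (nm in setdiff(names(sc), "participant_id"))
      sc[[nm]] <- energy_adjust(sc[[nm]], sim$diet$energy_kcal)
    write_tsv(sc, file.path(out_dir, "pattern_scores.tsv"))
  } else sc <- NULL

  # exposure table: energy-adjusted pattern scores + a priori components
  exposures <- data.frame(participant_id = sim$cohort$participant_id,
                          stringsAsFactors = FALSE)
  if (!is.null(sc))
    for (nm in setdiff(names(sc), "participant_id"))
      exposures[[nm]] <- sc[[nm]]
  for (nm in setdiff(names(expo$components_adj), "participant_id"))
    exposures[[nm]] <- expo$components_adj[[nm]]
  write_tsv(exposures, file.path(out_dir, "exposures.tsv"))

  risk <- list()
  for (nm in setdiff(names(exposures), "participant_id")) {
    risk[[length(risk) + 1L]] <-
      fit_clogit(sim$cohort, exposures[[nm]], exposure_name = nm)
    risk[[length(risk) + 1L]] <-
      stratified_analysis(sim$cohort, exposures[[nm]], exposure_name = nm)
  }
  risk <- do.call(rbind, risk)
  write_tsv(risk, file.path(out_dir, "risk_estimates.tsv"))

  filt <- cv_filter(sim$metab, threshold = cv_thresh)
  mm <- rf_impute(filt$matrix, seed = child_seed(config$seed, 13L))
  write_tsv(filt$report, file.path(out_dir, "cv_report.tsv"))
  study <- mm$sample_meta$sample_id[mm$sample_meta$role == "study"]
  X <- mm$intensities[study, , drop = FALSE]

  covdf0 <- risk_frame(sim$cohort, rep(0, nrow(sim$cohort)),
                       default_covariates)
  covdf0 <- covdf0[, intersect(default_covariates, names(covdf0)),
                   drop = FALSE]
  models <- list()
  assoc <- list()
  model_rows <- list()
  for (nm in setdiff(names(exposures), "participant_id")) {
    y <- exposures[[nm]]
    md <- rdcv_rf(X, y, rdcv, seed = child_seed(config$seed, 17L))
    md$p_permutation <- NA_real_
    if (md$q2 > q2_thresh) {
      pt <- permutation_test(X, y, rdcv, n_perm = n_perm,
                             seed = child_seed(config$seed, 19L), model = md)
      md$p_permutation <- pt$p_empirical
      md$p_parametric <- pt$p_parametric
    }
    models[[nm]] <- md
    drop_alc <- grepl("alcohol", nm, ignore.case = TRUE)
    cv <- if (drop_alc) covdf0[, setdiff(names(covdf0), "alcohol"),
                               drop = FALSE] else covdf0
    for (ft in md$selected)
      assoc[[length(assoc) + 1L]] <-
        partial_spearman(X[, ft], y, cv, feature_id = ft, exposure_name = nm)
    model_rows[[length(model_rows) + 1L]] <-
      data.frame(exposure = nm, q2 = md$q2, n_var = md$n_var,
                 p_permutation = md$p_permutation, stringsAsFactors = FALSE)
  }
  assoc <- if (length(assoc)) do.call(rbind, assoc) else
    data.frame(feature_id = character(), exposure = character(),
               rho = numeric(), p = numeric())
  write_tsv(do.call(rbind, model_rows), file.path(out_dir, "rdcv_models.tsv"))
  write_tsv(assoc, file.path(out_dir, "feature_associations.tsv"))

  selected <- select_diet_features(models, assoc, q2_thresh, p_thresh)
  write_tsv(selected, file.path(out_dir, "selected_features.tsv"))

  trip <- NULL
  if (nrow(selected) >= 2L) {
    pca <- pca_selected(X[, selected$feature_id, drop = FALSE])
    trip <- component_associations(pca, sim$cohort, exposures,
                                   n_components = n_components)
    export_triplot(trip, out_dir)
  }

  invisible(list(sim = sim, exposures = exposures, patterns = pats,
                 risk = risk, metab = mm, models = models,
                 associations = assoc, selected = selected, triplot = trip,
                 out_dir = out_dir))
}
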