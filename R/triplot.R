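#' PCA on the diet-selected metabolite features
#'
#' Autoscales (zero mean, unit variance) the selected-feature matrix and
#' decomposes it, with a deterministic sign convention (the largest-magnitude
#' loading of each component is positive) so results are reproducible across
#' platforms.
#'
#' @param features Participants x selected-features numeric matrix
#'   (complete, >= 2 features).
#' @return List of class `pca_result`: `loadings` (features x components,
#'   orthonormal columns), `scores` (participants x components),
#'   `explained` (variance proportions, non-increasing), `center`, `scale`.
#' @export
pca_selected <- function(features) {
  X <- as.matrix(features)
  if (ncol(X) < 2L) stop("PCA requires >= 2 features")
  if (anyNA(X)) stop("feature matrix must be complete (impute first)")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant feature(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  Z <- scale(X)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  L <- pc$rotation
  S <- pc$x
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) {
      L[, j] <- -L[, j]
      S[, j] <- -S[, j]
    }
  }
  out <- list(loadings = L, scores = S,
              explained = pc$sdev^2 / sum(pc$sdev^2),
              center = attr(Z, "scaled:center"),
              scale = attr(Z, "scaled:scale"))
  class(out) <- "pca_result"
  out
}

#' Associate PCA component scores with CRC risk and dietary exposures
#'
#' For each of the first `n_components` components: a per-1-SD conditional
#' logistic risk estimate (overall and, optionally, by sex and tumor site)
#' and a covariate-adjusted partial Spearman correlation to every dietary
#' exposure. This is the numerical content of the triplot.
#'
#' @param pca A [pca_selected()] result whose score rows align with (a
#'   subset of) the cohort; rownames are participant ids.
#' @param cohort Cohort table.
#' @param exposures Data frame: `participant_id` plus one numeric column per
#'   dietary exposure.
#' @param covariates Adjustment set for both association types.
#' @param n_components Number of leading components analyzed (default 3).
#' @param stratify Also compute sex- and site-stratified risk estimates.
#' @return A `triplot_result`: `loadings`, `explained`, `scores`, `risk`
#'   (RiskEstimate rows keyed by component), `correlations` (component x
#'   exposure partial Spearman records).
#' @export
component_associations <- function(pca, cohort, exposures,
                                   covariates = default_covariates,
                                   n_components = 3, stratify = TRUE) {
  n_components <- min(n_components, ncol(pca$scores))
  ids <- rownames(pca$scores)
  if (is.null(ids)) stop("pca scores must carry participant ids as rownames")
  sub <- cohort[match(ids, cohort$participant_id), , drop = FALSE]
  if (anyNA(sub$participant_id))
    stop("pca scores contain participants absent from the cohort")
  expo <- exposures[match(ids, exposures$participant_id), , drop = FALSE]
  covdf <- risk_frame(sub, rep(0, nrow(sub)), covariates)
  covdf <- covdf[, intersect(covariates, names(covdf)), drop = FALSE]

  risk <- list()
  cors <- list()
  for (cmp in seq_len(n_components)) {
    sc <- pca$scores[, cmp]
    lab <- paste0("PC", cmp)
    risk[[length(risk) + 1L]] <-
      fit_clogit(sub, sc, covariates, exposure_name = lab)
    if (stratify)
      risk[[length(risk) + 1L]] <-
        stratified_analysis(sub, sc, covariates, exposure_name = lab)
    for (ex in setdiff(names(expo), "participant_id")) {
      drop_alc <- grepl("alcohol", ex, ignore.case = TRUE)
      cv <- if (drop_alc) covdf[, setdiff(names(covdf), "alcohol"),
                                drop = FALSE] else covdf
      cors[[length(cors) + 1L]] <-
        partial_spearman(sc, expo[[ex]], cv, feature_id = lab,
                         exposure_name = ex)
    }
  }
  cors <- do.call(rbind, cors)
  names(cors)[names(cors) == "feature_id"] <- "component"
  out <- list(loadings = pca$loadings[, seq_len(n_components), drop = FALSE],
              explained = pca$explained[seq_len(n_components)],
              scores = pca$scores[, seq_len(n_components), drop = FALSE],
              risk = do.call(rbind, risk), correlations = cors)
  class(out) <- "triplot_result"
  out
}

#' Export a triplot result as plot-ready tables
#'
#' Writes three TSVs keyed by component: metabolite loadings, component x
#' exposure partial correlations, and component odds ratios with standard
#' errors.
#'
#' @param result A `triplot_result`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
export_triplot <- function(result, dir) {
  stopifnot(inherits(result, "triplot_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(loadings = file.path(dir, "triplot_loadings.tsv"),
             correlations = file.path(dir, "triplot_correlations.tsv"),
             odds_ratios = file.path(dir, "triplot_odds_ratios.tsv"))
  ld <- data.frame(feature_id = rownames(result$loadings), result$loadings,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(ld, paths["loadings"])
  write_tsv(result$correlations, paths["correlations"])
  write_tsv(result$risk, paths["odds_ratios"])
  invisible(paths)
}

#' Reload exported triplot tables
#' @param dir Directory written by [export_triplot()].
#' @return List with `loadings`, `correlations`, `odds_ratios` data frames.
#' @export
read_triplot <- function(dir) {
  list(loadings = read_tsv(file.path(dir, "triplot_loadings.tsv")),
       correlations = read_tsv(file.path(dir, "triplot_correlations.tsv")),
       odds_ratios = read_tsv(file.path(dir, "triplot_odds_ratios.tsv")))
}

#' Draw a triplot
#'
#' Base-graphics rendering of the integrated display: feature loadings as
#' black arrows, component-exposure correlations as labelled rays, and
#' per-component odds ratios (overall strata) in the legend.
#'
#' @param result A `triplot_result`.
#' @param components Length-2 integer vector of components to draw.
#' @return `result`, invisibly.
#' @export
plot_triplot <- function(result, components = c(1, 2)) {
  stopifnot(inherits(result, "triplot_result"), length(components) == 2)
  L <- result$loadings[, components, drop = FALSE]
  graphics::plot(0, 0, type = "n", xlim = range(L[, 1]) * 1.4,
                 ylim = range(L[, 2]) * 1.4,
                 xlab = sprintf("PC%d (%.1f%%)", components[1],
                                100 * result$explained[components[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2],
                                100 * result$explained[components[2]]))
  graphics::arrows(0, 0, L[, 1], L[, 2], length = 0.05)
  graphics::text(L[, 1] * 1.1, L[, 2] * 1.1, rownames(L), cex = 0.6)
  cr <- result$correlations
  for (ex in unique(cr$exposure)) {
    r1 <- cr$rho[cr$component == paste0("PC", components[1]) &
                   cr$exposure == ex]
    r2 <- cr$rho[cr$component == paste0("PC", components[2]) &
                   cr$exposure == ex]
    if (length(r1) && length(r2) && !is.na(r1) && !is.na(r2)) {
      graphics::segments(0, 0, r1, r2, col = "blue")
      graphics::text(r1, r2, ex, col = "blue", cex = 0.7, pos = 3)
    }
  }
  invisible(result)
}
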