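#' Settings for repeated double cross-validated random-forest regression
#'
#' @param n_rep Number of repetitions (independent outer-fold reshuffles).
#' @param n_outer Outer folds (held out entirely from tuning and training).
#' @param n_inner Inner folds (variable-elimination tuning).
#' @param var_ratio Proportion of variables kept at each recursive
#'   elimination step (by random-forest importance).
#' @param n_trees Trees per forest.
#' @param min_vars Smallest model size considered.
#' @return A list of class `rdcv_settings`.
#' @export
rdcv_settings <- function(n_rep = 10, n_outer = 6, n_inner = 5,
                          var_ratio = 0.75, n_trees = 300, min_vars = 2) {
  stopifnot(n_outer >= 2, n_inner >= 2, var_ratio > 0, var_ratio < 1,
            min_vars >= 1)
  out <- list(n_rep = as.integer(n_rep), n_outer = as.integer(n_outer),
              n_inner = as.integer(n_inner), var_ratio = var_ratio,
              n_trees = as.integer(n_trees), min_vars = as.integer(min_vars))
  class(out) <- "rdcv_settings"
  out
}

rf_fit <- function(x, y, n_trees, seed) {
  # mtry = p/3, the usual random-forest regression default
  ranger::ranger(x = x, y = y, num.trees = n_trees, importance = "impurity",
                 mtry = max(1L, floor(ncol(x) / 3)), num.threads = 1L,
                 seed = seed, verbose = FALSE)
}

#' Repeated double cross-validated random forest with variable selection
#'
#' Nested (double) cross-validation for associating a metabolite feature
#' matrix with a continuous dietary exposure. Outer-fold samples are never
#' used for tuning or training. Within each outer training set, recursive
#' variable elimination by random-forest importance (keeping `var_ratio` of
#' the variables per step) is tuned by inner cross-validation; the
#' minimal-optimal model size (smallest size attaining the minimum inner
#' error) is refit on the full outer training set and predicts the held-out
#' fold. Predictive performance is
#' `Q2 = 1 - sum((y - yhat_oof)^2) / sum((y - mean(y))^2)`, averaged over
#' repetitions.
#'
#' @param x Samples x features numeric matrix (>= 50 samples, >= 10
#'   features, complete).
#' @param y Continuous response (a dietary exposure) with positive variance.
#' @param settings An [rdcv_settings()] list.
#' @param seed Integer seed (mandatory).
#' @return An `rdcv_model`: `q2` (mean over repetitions), `q2_per_rep`,
#'   `selected` (consensus minimal-optimal feature ids), `n_var` (consensus
#'   size), `selection_freq`, `oof` (out-of-fold prediction matrix), `folds`
#'   (outer fold assignment per repetition, for fold-hygiene audits),
#'   `settings`, `y`.
#' @export
rdcv_rf <- function(x, y, settings = rdcv_settings(), seed = NULL) {
  seed <- check_seed(seed)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  n <- nrow(x); m <- ncol(x)
  if (n < 50L) stop("rdcv_rf requires >= 50 samples")
  if (m < 10L) stop("rdcv_rf requires >= 10 features")
  if (anyNA(x) || anyNA(y)) stop("x and y must be complete")
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (stats::var(y) == 0) stop("response is constant")
  if (floor(n / settings$n_outer) < 5L)
    stop("outer folds would contain < 5 samples")

  set.seed(seed)
  q2_rep <- numeric(settings$n_rep)
  oof <- matrix(NA_real_, n, settings$n_rep)
  folds_log <- vector("list", settings$n_rep)
  model_sizes <- integer(0)
  sel_count <- stats::setNames(numeric(m), colnames(x))
  imp_total <- stats::setNames(numeric(m), colnames(x))
  tss <- sum((y - mean(y))^2)

  for (r in seq_len(settings$n_rep)) {
    fold <- sample(rep_len(seq_len(settings$n_outer), n))
    folds_log[[r]] <- fold
    for (o in seq_len(settings$n_outer)) {
      test_idx <- which(fold == o)
      train_idx <- which(fold != o)
      xt <- x[train_idx, , drop = FALSE]
      yt <- y[train_idx]
      inner <- sample(rep_len(seq_len(settings$n_inner), length(train_idx)))

      # recursive elimination ladder tuned by inner CV
      vars <- colnames(x)
      ladder_vars <- list()
      ladder_err <- numeric(0)
      while (length(vars) >= settings$min_vars) {
        sse <- 0
        imp <- stats::setNames(numeric(length(vars)), vars)
        for (i in seq_len(settings$n_inner)) {
          tr <- inner != i
          fit <- rf_fit(xt[tr, vars, drop = FALSE], yt[tr], settings$n_trees,
                        child_seed(seed, r * 100000L + o * 1000L +
                                     i * 50L + length(vars)))
          pred <- stats::predict(
            fit, data = xt[!tr, vars, drop = FALSE])$predictions
          sse <- sse + sum((yt[!tr] - pred)^2)
          imp <- imp + fit$variable.importance[vars]
        }
        ladder_vars[[length(ladder_vars) + 1L]] <- vars
        ladder_err <- c(ladder_err, sse / length(train_idx))
        if (length(vars) == settings$min_vars) break
        keep <- max(settings$min_vars,
                    floor(settings$var_ratio * length(vars)))
        if (keep >= length(vars)) keep <- length(vars) - 1L
        vars <- names(sort(imp, decreasing = TRUE))[seq_len(keep)]
      }
      # minimal-optimal: smallest size attaining the minimum inner error
      sizes <- lengths(ladder_vars)
      best <- which(ladder_err <= min(ladder_err))
      best <- best[which.min(sizes[best])]
      sel <- ladder_vars[[best]]
      model_sizes <- c(model_sizes, length(sel))
      sel_count[sel] <- sel_count[sel] + 1

      final <- rf_fit(xt[, sel, drop = FALSE], yt, settings$n_trees,
                      child_seed(seed, r * 100000L + o * 1000L + 7L))
      imp_total[sel] <- imp_total[sel] + final$variable.importance[sel]
      oof[test_idx, r] <- stats::predict(
        final, data = x[test_idx, sel, drop = FALSE])$predictions
    }
    q2_rep[r] <- 1 - sum((y - oof[, r])^2) / tss
  }

  n_var <- max(settings$min_vars, as.integer(round(mean(model_sizes))))
  rank_key <- order(-sel_count, -imp_total)
  selected <- colnames(x)[rank_key[seq_len(min(n_var, m))]]

  out <- list(q2 = mean(q2_rep), q2_per_rep = q2_rep, selected = selected,
              n_var = n_var,
              selection_freq = sel_count / (settings$n_rep * settings$n_outer),
              oof = oof, folds = folds_log, settings = settings, y = y,
              seed = seed)
  class(out) <- "rdcv_model"
  out
}

#' @export
print.rdcv_model <- function(x, ...) {
  cat("rdCV random-forest model: Q2 =", round(x$q2, 3), "(",
      x$settings$n_rep, "repetitions );", x$n_var,
      "selected feature(s)\n")
  invisible(x)
}

#' Permutation test of rdCV predictive performance
#'
#' Re-runs the full rdCV procedure on `n_perm` random permutations of the
#' response. The empirical p-value is
#' `(1 + #\{Q2_perm >= Q2_obs\}) / (n_perm + 1)` and is bounded below by
#' `1/(n_perm+1)`; a parametric p-value from a normal fit to the permuted
#' null additionally resolves much smaller tail probabilities.
#'
#' @inheritParams rdcv_rf
#' @param n_perm Number of permutations (>= 20; default 50).
#' @param model Optional fitted `rdcv_model` for the observed data (refit
#'   when omitted).
#' @return List with `p_empirical`, `p_parametric`, `q2_obs`, `q2_perm`.
#' @export
permutation_test <- function(x, y, settings = rdcv_settings(), n_perm = 50,
                             seed = NULL, model = NULL) {
  seed <- check_seed(seed)
  if (n_perm < 20L) stop("n_perm must be >= 20")
  if (is.null(model)) model <- rdcv_rf(x, y, settings, seed = seed)
  q2_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(child_seed(seed, 500000L + b))
    yp <- sample(y)
    q2_perm[b] <- rdcv_rf(x, yp, settings,
                          seed = child_seed(seed, 600000L + b))$q2
  }
  p_emp <- (1 + sum(q2_perm >= model$q2)) / (n_perm + 1)
  mu <- mean(q2_perm); s <- stats::sd(q2_perm)
  p_par <- if (s > 0) stats::pnorm(model$q2, mu, s, lower.tail = FALSE)
  else as.numeric(model$q2 <= mu)
  list(p_empirical = p_emp, p_parametric = p_par, q2_obs = model$q2,
       q2_perm = q2_perm)
}

#' Partial Spearman correlation with covariate adjustment
#'
#' Rank-transforms feature and exposure (average ranks for ties),
#' residualizes both on the covariate design (factors expanded to indicator
#' contrasts), and returns the Pearson correlation of the residuals with a
#' t-approximation p-value on `n - 2 - q` degrees of freedom. With no
#' covariates this is the ordinary Spearman correlation.
#'
#' @param feature Numeric vector (metabolite intensities).
#' @param exposure Numeric vector (dietary exposure).
#' @param covariates Optional data frame of covariates.
#' @param feature_id,exposure_name Labels for the output record.
#' @return A one-row `AssociationRecord` data frame: `feature_id`,
#'   `exposure`, `rho`, `p`, `n`, `covariates`. Zero residual variance
#'   yields an explicit null record (`rho = NA`).
#' @export
partial_spearman <- function(feature, exposure, covariates = NULL,
                             feature_id = "feature",
                             exposure_name = "exposure") {
  stopifnot(length(feature) == length(exposure))
  cc <- stats::complete.cases(feature, exposure)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(feature))
    cc <- cc & stats::complete.cases(covariates)
  }
  n <- sum(cc)
  if (n < 20L) stop("partial Spearman requires >= 20 complete observations")
  rf <- rank(feature[cc])
  re <- rank(exposure[cc])
  q <- 0L
  if (!is.null(covariates) && ncol(covariates) > 0L) {
    cov_cc <- as.data.frame(covariates)[cc, , drop = FALSE]
    # all variables enter on the rank scale (numeric covariates included),
    # the conventional definition of partial Spearman correlation
    for (v in names(cov_cc))
      if (is.numeric(cov_cc[[v]])) cov_cc[[v]] <- rank(cov_cc[[v]])
    X <- stats::model.matrix(~ ., data = cov_cc)
    q <- ncol(X) - 1L
    rf <- stats::lm.fit(X, rf)$residuals
    re <- stats::lm.fit(X, re)$residuals
  } else {
    rf <- rf - mean(rf)
    re <- re - mean(re)
  }
  record <- function(rho, p) data.frame(
    feature_id = feature_id, exposure = exposure_name, rho = rho, p = p,
    n = n, covariates = q, stringsAsFactors = FALSE)
  if (stats::sd(rf) <= 1e-10 * n || stats::sd(re) <= 1e-10 * n)
    return(record(NA_real_, NA_real_))
  rho <- sum(rf * re) / sqrt(sum(rf^2) * sum(re^2))
  df <- n - 2L - q
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  record(rho, 2 * stats::pt(-abs(tval), df))
}

#' Select metabolite features reflecting dietary exposures
#'
#' Union, over the exposures whose rdCV models pass both the Q2 threshold
#' and the permutation p threshold, of their selected features that also
#' validate by partial Spearman correlation (association p below
#' `p_thresh`). Features selected for several exposures are collapsed to
#' unique ids with all exposure tags retained.
#'
#' @param models Named list (by exposure) of lists/`rdcv_model`s carrying
#'   `q2`, `selected`, and `p_permutation`.
#' @param associations `AssociationRecord` data frame from
#'   [partial_spearman()] covering the candidate feature-exposure pairs.
#' @param q2_thresh Q2 threshold (default 0.15).
#' @param p_thresh p-value threshold for both the permutation test and the
#'   partial-Spearman validation (default 0.05).
#' @return Data frame: `feature_id`, `exposures` (comma-joined tags),
#'   `n_exposures`.
#' @export
select_diet_features <- function(models, associations, q2_thresh = 0.15,
                                 p_thresh = 0.05) {
  stopifnot(q2_thresh > 0, q2_thresh < 1, p_thresh > 0, p_thresh < 1)
  tags <- list()
  for (nm in names(models)) {
    md <- models[[nm]]
    if (is.null(md$q2) || md$q2 <= q2_thresh) next
    pp <- md$p_permutation
    if (is.null(pp) || is.na(pp) || pp >= p_thresh) next
    for (ft in md$selected) {
      ok <- associations$feature_id == ft & associations$exposure == nm &
        !is.na(associations$p) & associations$p < p_thresh
      if (any(ok)) tags[[ft]] <- c(tags[[ft]], nm)
    }
  }
  if (!length(tags))
    return(data.frame(feature_id = character(), exposures = character(),
                      n_exposures = integer(), stringsAsFactors = FALSE))
  data.frame(feature_id = names(tags),
             exposures = vapply(tags, function(x)
               paste(sort(unique(x)), collapse = ","), ""),
             n_exposures = vapply(tags, function(x)
               length(unique(x)), 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}
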