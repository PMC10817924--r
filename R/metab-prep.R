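# accept either a metab_matrix or a plain samples x features matrix
as_intensity_matrix <- function(x) {
  if (inherits(x, "metab_matrix")) x$intensities else as.matrix(x)
}

#' Coefficient-of-variation filter on study-QC injections
#'
#' Computes, per feature, CV = sd/mean of the pooled study-QC (sQC)
#' intensities and retains features with CV at or below `threshold`
#' (default 0.30). Features whose sQC mean is zero have an undefined CV and
#' are removed with that reason.
#'
#' @param mm A `metab_matrix` (QC rows identified via `sample_meta$role ==
#'   "sQC"`), or a plain matrix with `qc_rows` given.
#' @param threshold Maximum CV retained (proportion; default 0.30).
#' @param qc_rows Row indices/names of QC injections for plain matrices.
#' @return List with `matrix` (filtered, same class as input) and `report`
#'   (data frame: feature_id, cv, retained, reason).
#' @export
cv_filter <- function(mm, threshold = 0.30, qc_rows = NULL) {
  X <- as_intensity_matrix(mm)
  if (inherits(mm, "metab_matrix"))
    qc_rows <- mm$sample_meta$sample_id[mm$sample_meta$role == "sQC"]
  if (is.null(qc_rows) || length(qc_rows) < 2L)
    stop("at least 2 sQC injections are required to compute CVs")
  Q <- X[qc_rows, , drop = FALSE]
  mu <- colMeans(Q, na.rm = TRUE)
  sdev <- apply(Q, 2L, stats::sd, na.rm = TRUE)
  cv <- ifelse(mu == 0, NA_real_, sdev / mu)
  retained <- !is.na(cv) & cv <= threshold
  report <- data.frame(feature_id = colnames(X), cv = cv,
                       retained = retained,
                       reason = ifelse(retained, "",
                                       ifelse(is.na(cv), "undefined CV",
                                              "CV above threshold")),
                       row.names = NULL, stringsAsFactors = FALSE)
  if (inherits(mm, "metab_matrix")) {
    out <- mm
    out$intensities <- X[, retained, drop = FALSE]
    out$feature_meta <- mm$feature_meta[retained, , drop = FALSE]
    out$feature_meta$qc_cv <- cv[retained]
  } else {
    out <- X[, retained, drop = FALSE]
  }
  list(matrix = out, report = report)
}

#' Iterative random-forest imputation of missing feature intensities
#'
#' missForest-style scheme: missing cells are initialized with feature
#' medians; features are then visited in order of increasing missingness,
#' each regressed on all other features with a random forest fitted on its
#' observed rows, and the missing cells replaced by forest predictions. The
#' sweep repeats until the normalized change in the imputed cells increases
#' (the previous iterate is returned) or `max_iter` is reached. Observed
#' cells are never altered.
#'
#' @param mm A `metab_matrix` or plain samples x features matrix.
#' @param max_iter Maximum number of sweeps (default 10).
#' @param n_trees Trees per forest (default 100).
#' @param seed Integer seed (mandatory; forests are seeded per feature).
#' @return Completed object of the same class as the input.
#' @export
rf_impute <- function(mm, max_iter = 10, n_trees = 100, seed = NULL) {
  seed <- check_seed(seed)
  X <- as_intensity_matrix(mm)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  miss <- is.na(X)
  all_missing <- colSums(!miss) == 0L
  if (any(all_missing))
    stop("feature(s) entirely missing: ",
         paste(colnames(X)[all_missing], collapse = ", "))
  if (any(rowSums(!miss) == 0L))
    stop("sample(s) with no observed values present")
  if (!any(miss)) return(mm)

  # initialize with feature medians
  med <- apply(X, 2L, stats::median, na.rm = TRUE)
  cur <- X
  for (j in which(colSums(miss) > 0L)) cur[miss[, j], j] <- med[j]

  order_j <- order(colSums(miss))
  order_j <- order_j[colSums(miss)[order_j] > 0L]
  prev_delta <- Inf
  best <- cur
  for (it in seq_len(max_iter)) {
    prev <- cur
    for (j in order_j) {
      obs <- !miss[, j]
      dtrain <- data.frame(.y = cur[obs, j], cur[obs, -j, drop = FALSE],
                           check.names = FALSE)
      fit <- ranger::ranger(dependent.variable.name = ".y", data = dtrain,
                            num.trees = n_trees, num.threads = 1L,
                            mtry = max(1L, floor(sqrt(ncol(dtrain) - 1L))),
                            seed = child_seed(seed, it * 1000L + j),
                            verbose = FALSE)
      dpred <- data.frame(cur[!obs, -j, drop = FALSE], check.names = FALSE)
      cur[!obs, j] <- stats::predict(fit, data = dpred)$predictions
    }
    delta <- sum((cur[miss] - prev[miss])^2) / max(sum(cur[miss]^2),
                                                   .Machine$double.eps)
    if (delta >= prev_delta) { cur <- best; break }  # missForest stop rule
    best <- cur
    prev_delta <- delta
  }
  stopifnot(identical(cur[!miss], X[!miss]))  # observed cells untouched
  if (inherits(mm, "metab_matrix")) {
    mm$intensities <- cur
    mm
  } else cur
}
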