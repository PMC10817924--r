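# Maximum-likelihood confirmatory factor analysis on a correlation matrix.
# Identification: factor variances fixed at 1 (so loadings are comparable
# across factors), factor correlations free, uniquenesses free and bounded
# below. Discrepancy F = log det(Sigma) + tr(S Sigma^-1) - log det(S) - p.

cfa_discrepancy <- function(S, Lambda, Phi, psi) {
  Sigma <- Lambda %*% Phi %*% t(Lambda) + diag(psi, nrow(Lambda))
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(list(F = 1e10, Sigma = Sigma, W = NULL))
  Sinv <- chol2inv(ch)
  F <- 2 * sum(log(diag(ch))) + sum(S * Sinv) -
    determinant(S, logarithm = TRUE)$modulus[1] - nrow(S)
  # dF/dSigma, used for all parameter gradients
  W <- Sinv - Sinv %*% S %*% Sinv
  list(F = as.numeric(F), Sigma = Sigma, W = W)
}

#' Confirmatory factor analysis by maximum likelihood
#'
#' Fits a prespecified factor -> foods structure to the sample correlation
#' matrix of a held-out data half (or to a supplied correlation matrix),
#' returning estimated loadings, factor correlations, uniquenesses, fit
#' indices (CFI, TLI, RMSEA, SRMR, ML discrepancy) and regression-method
#' (Thurstone) factor scores.
#'
#' @param data Participants x foods matrix (only foods named in `structure`
#'   are used), or `NULL` if `sample_cov` is given.
#' @param structure Named list: factor name -> character vector of indicator
#'   foods (>= 2 per factor, all present in the data).
#' @param sample_cov Optional correlation matrix replacing `data`.
#' @param n_obs Number of observations when `sample_cov` is used.
#' @param psi_lower Lower bound on uniquenesses (Heywood guard).
#' @param max_iter Optimizer iteration cap.
#' @return A `cfa_fit`: loadings (foods x factors, zeros off-structure),
#'   `Phi`, `psi`, `fit` (named fit-index vector), `discrepancy`, `scores`
#'   (n x factors, zero mean; `NULL` without raw data), `structure`, `n_obs`,
#'   `converged`.
#' @export
cfa_fit <- function(data, structure, sample_cov = NULL, n_obs = NULL,
                    psi_lower = 0.005, max_iter = 500) {
  if (!length(structure)) stop("empty structure")
  lens <- lengths(structure)
  if (any(lens < 2L))
    stop("empirically underidentified model: factor '",
         names(structure)[which(lens < 2L)[1]], "' has fewer than 2 indicators")
  foods <- unique(unlist(structure))
  Z <- NULL
  if (is.null(sample_cov)) {
    data <- as.matrix(data)
    missing_foods <- setdiff(foods, colnames(data))
    if (length(missing_foods))
      stop("structure references foods absent from data: ",
           paste(missing_foods, collapse = ", "))
    Z <- scale(data[, foods, drop = FALSE])
    S <- stats::cor(data[, foods, drop = FALSE])
    n_obs <- nrow(data)
  } else {
    missing_foods <- setdiff(foods, colnames(sample_cov))
    if (length(missing_foods))
      stop("structure references foods absent from data: ",
           paste(missing_foods, collapse = ", "))
    S <- stats::cov2cor(sample_cov[foods, foods, drop = FALSE])
  }
  p <- length(foods)
  k <- length(structure)
  fac_names <- names(structure)

  mask <- matrix(FALSE, p, k, dimnames = list(foods, fac_names))
  for (j in seq_len(k)) mask[structure[[j]], j] <- TRUE
  n_load <- sum(mask)
  phi_idx <- which(lower.tri(matrix(0, k, k)), arr.ind = TRUE)
  n_phi <- nrow(phi_idx)

  if (p * (p + 1) / 2 - (n_load + n_phi + p) < 0)
    stop("empirically underidentified model: ", n_load, " loadings, ",
         n_phi, " factor correlations and ", p, " uniquenesses exceed the ",
         p * (p + 1) / 2, " distinct correlation moments")

  unpack <- function(par) {
    Lambda <- matrix(0, p, k, dimnames = list(foods, fac_names))
    Lambda[mask] <- par[seq_len(n_load)]
    Phi <- diag(k)
    if (n_phi) {
      v <- par[n_load + seq_len(n_phi)]
      Phi[phi_idx] <- v
      Phi[phi_idx[, c(2, 1), drop = FALSE]] <- v
    }
    psi <- exp(par[n_load + n_phi + seq_len(p)])
    list(Lambda = Lambda, Phi = Phi, psi = psi)
  }
  fn <- function(par) {
    th <- unpack(par)
    cfa_discrepancy(S, th$Lambda, th$Phi, th$psi)$F
  }
  gr <- function(par) {
    th <- unpack(par)
    d <- cfa_discrepancy(S, th$Lambda, th$Phi, th$psi)
    if (is.null(d$W)) return(rep(0, length(par)))
    gL <- 2 * d$W %*% th$Lambda %*% th$Phi
    gPhi_full <- t(th$Lambda) %*% d$W %*% th$Lambda
    gPhi <- 2 * gPhi_full[phi_idx]
    gpsi <- diag(d$W) * th$psi
    c(gL[mask], gPhi, gpsi)
  }

  start <- c(rep(0.6, n_load), rep(0, n_phi), rep(log(0.5), p))
  lowerb <- c(rep(-Inf, n_load), rep(-0.95, n_phi), rep(log(psi_lower), p))
  upperb <- c(rep(Inf, n_load), rep(0.95, n_phi), rep(log(5), p))
  opt <- stats::optim(start, fn, gr, method = "L-BFGS-B",
                      lower = lowerb, upper = upperb,
                      control = list(maxit = max_iter, factr = 1e4))
  th <- unpack(opt$par)
  Fmin <- opt$value
  if (!is.finite(Fmin) || Fmin >= 1e9)
    stop("CFA did not converge to a proper solution")

  # sign convention per factor, as in the EFA rotation
  for (j in seq_len(k)) {
    jj <- which.max(abs(th$Lambda[, j]))
    if (th$Lambda[jj, j] < 0) {
      th$Lambda[, j] <- -th$Lambda[, j]
      th$Phi[j, ] <- -th$Phi[j, ]
      th$Phi[, j] <- -th$Phi[, j]
      diag(th$Phi) <- 1
    }
  }

  n_free <- n_load + n_phi + p
  df <- p * (p + 1) / 2 - n_free
  chisq <- max(0, (n_obs - 1) * Fmin)
  Fb <- -determinant(S, logarithm = TRUE)$modulus[1]
  chisq_b <- max(0, (n_obs - 1) * Fb)
  df_b <- p * (p - 1) / 2
  cfi <- if (df > 0)
    1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, .Machine$double.eps)
  else 1
  tli <- if (df > 0 && chisq_b / df_b > 1)
    min(1, ((chisq_b / df_b) - (chisq / df)) / ((chisq_b / df_b) - 1))
  else 1
  rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * (n_obs - 1))) else 0
  Sigma <- th$Lambda %*% th$Phi %*% t(th$Lambda) + diag(th$psi, p)
  res <- S - Sigma
  srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))
  fit <- c(cfi = as.numeric(cfi), tli = as.numeric(tli),
           rmsea = as.numeric(rmsea), srmr = srmr,
           chisq = chisq, df = df, discrepancy = Fmin)

  scores <- NULL
  if (!is.null(Z)) {
    B <- solve(Sigma, th$Lambda %*% th$Phi)   # Thurstone regression weights
    scores <- Z %*% B
    colnames(scores) <- fac_names
    scores <- sweep(scores, 2L, colMeans(scores))  # exact zero mean
  }
  out <- list(loadings = th$Lambda, Phi = th$Phi, psi = th$psi,
              fit = fit, discrepancy = Fmin, scores = scores,
              structure = structure, n_obs = n_obs,
              converged = opt$convergence == 0)
  class(out) <- "cfa_fit"
  out
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat("CFA fit:", length(x$structure), "factor(s),", nrow(x$loadings),
      "foods; CFI =", round(x$fit["cfi"], 3),
      "RMSEA =", round(x$fit["rmsea"], 3),
      "SRMR =", round(x$fit["srmr"], 3), "\n")
  invisible(x)
}

#' Extract participant factor scores from a fitted CFA
#'
#' Regression-method (Thurstone) scores, zero mean by construction, keyed by
#' participant id.
#'
#' @param final_fit A converged [cfa_fit()] estimated from raw data.
#' @param participant_id Optional id vector (defaults to data rownames).
#' @return Data frame: `participant_id` plus one score column per factor.
#' @export
extract_scores <- function(final_fit, participant_id = NULL) {
  stopifnot(inherits(final_fit, "cfa_fit"))
  if (is.null(final_fit$scores))
    stop("fit was estimated from a covariance matrix; no scores available")
  ids <- participant_id %||% rownames(final_fit$scores) %||%
    sprintf("P%05d", seq_len(nrow(final_fit$scores)))
  data.frame(participant_id = ids, final_fit$scores,
             stringsAsFactors = FALSE, check.names = FALSE)
}
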