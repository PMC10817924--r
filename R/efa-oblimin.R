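# oblimin criterion value and gradient at a loading matrix L
# f(L) = sum(L2 * ((I - gamma/p * J) %*% L2 %*% N)) / 4, N = offdiag ones
oblimin_vgQ <- function(L, gamma = 0) {
  k <- ncol(L); p <- nrow(L)
  L2 <- L^2
  N <- matrix(1, k, k) - diag(k)
  M <- if (gamma == 0) L2 %*% N else
    (diag(p) - matrix(gamma / p, p, p)) %*% L2 %*% N
  list(f = sum(L2 * M) / 4, G = L * M)
}

#' Oblique oblimin rotation by gradient projection
#'
#' Rotates an unrotated (e.g. maximum-likelihood) loading matrix toward
#' simple structure with correlated factors, minimizing the oblimin
#' criterion (`gamma = 0` gives direct quartimin, the conventional default)
#' by the gradient-projection algorithm on the oblique manifold. Column
#' signs are fixed so each factor's largest-magnitude loading is positive.
#'
#' @param loadings Foods x k unrotated loading matrix.
#' @param gamma Oblimin family parameter (0 = quartimin).
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the projected gradient norm.
#' @param Tmat Optional starting rotation matrix (k x k, unit columns).
#' @return List with `loadings` (rotated), `Phi` (factor correlations),
#'   `Tmat`, `criterion`, `iterations`, `converged`. For k = 1 the input is
#'   returned unchanged.
#' @export
oblimin_rotate <- function(loadings, gamma = 0, max_iter = 1000, tol = 1e-6,
                           Tmat = NULL) {
  A <- as.matrix(loadings)
  k <- ncol(A)
  if (k < 2L)
    return(list(loadings = A, Phi = diag(k), Tmat = diag(k),
                criterion = oblimin_vgQ(A, gamma)$f, iterations = 0L,
                converged = TRUE))
  if (is.null(Tmat)) Tmat <- diag(k)
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vg <- oblimin_vgQ(L, gamma)
  f <- vg$f
  G <- -t(t(L) %*% vg$G %*% Ti)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < tol) { converged <- TRUE; break }
    al <- 2 * al
    for (i in 0:20) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      vg <- oblimin_vgQ(L, gamma)
      if (vg$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- vg$f
    G <- -t(t(L) %*% vg$G %*% Ti)
  }
  if (!converged && sqrt(sum((G - Tmat %*% diag(colSums(Tmat * G), k))^2)) >= tol)
    stop("oblimin rotation did not converge in ", max_iter, " iterations")
  Phi <- t(Tmat) %*% Tmat
  # sign convention: dominant loading of each factor positive
  for (j in seq_len(k)) {
    if (L[which.max(abs(L[, j])), j] < 0) {
      L[, j] <- -L[, j]
      Phi[j, ] <- -Phi[j, ]
      Phi[, j] <- -Phi[, j]
      Tmat[, j] <- -Tmat[, j]
    }
  }
  dimnames(L) <- dimnames(A)
  list(loadings = L, Phi = Phi, Tmat = Tmat, criterion = f,
       iterations = iter, converged = TRUE)
}

#' Maximum-likelihood exploratory factor analysis with oblimin rotation
#'
#' Fits the ML factor model to the sample correlation matrix
#' (`stats::factanal`) and obliquely rotates the solution with
#' [oblimin_rotate()]. Heywood cases (uniquenesses driven to the lower
#' bound) are flagged with a warning rather than returned silently.
#'
#' @param data Participants x foods numeric matrix (no missing values), or
#'   `NULL` if `covmat` is given.
#' @param k Number of factors (must leave positive model degrees of freedom).
#' @param covmat Optional correlation/covariance matrix in place of `data`.
#' @param n_obs Number of observations when `covmat` is used.
#' @param gamma Oblimin parameter, see [oblimin_rotate()].
#' @param lower Lower bound for uniquenesses (Heywood guard).
#' @return A `factor_solution`: list with `loadings`, `Phi`, `uniquenesses`,
#'   `k`, `criterion` (rotation criterion value), `heywood`, `n_obs`.
#' @export
efa_ml <- function(data, k, covmat = NULL, n_obs = NULL, gamma = 0,
                   lower = 0.005) {
  if (is.null(covmat)) {
    data <- as.matrix(data)
    if (anyNA(data)) stop("data must have no missing entries")
    vars <- apply(data, 2L, stats::var)
    if (any(vars <= 0))
      stop("zero-variance foods: ",
           paste(colnames(data)[vars <= 0], collapse = ", "))
    covmat <- stats::cor(data)
    n_obs <- nrow(data)
  }
  p <- ncol(covmat)
  df <- ((p - k)^2 - p - k) / 2
  if (k >= p || df < 0)
    stop("degenerate factor model: k = ", k, " leaves df = ", df,
         " for ", p, " foods")
  fit <- tryCatch(
    stats::factanal(factors = k, covmat = covmat, n.obs = n_obs,
                    rotation = "none", control = list(lower = lower,
                                                      opt = list(maxit = 2000))),
    error = function(e) stop("ML factor analysis failed for k = ", k, ": ",
                             conditionMessage(e), call. = FALSE))
  A <- matrix(fit$loadings, p, k,
              dimnames = list(colnames(covmat), paste0("F", seq_len(k))))
  heywood <- any(fit$uniquenesses <= lower + 1e-8)
  if (heywood)
    warning("Heywood case: uniqueness at lower bound ", lower,
            " for ", sum(fit$uniquenesses <= lower + 1e-8), " food(s)",
            call. = FALSE)
  rot <- oblimin_rotate(A, gamma = gamma)
  structure(list(loadings = rot$loadings, Phi = rot$Phi,
                 uniquenesses = fit$uniquenesses, k = k,
                 criterion = rot$criterion, heywood = heywood,
                 n_obs = n_obs, converged = fit$converged %||% TRUE),
            class = "factor_solution")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.factor_solution <- function(x, ...) {
  cat("ML factor solution: k =", x$k, "factors,", nrow(x$loadings),
      "foods", if (x$heywood) "(Heywood case flagged)", "\n")
  print(round(x$loadings, 3))
  invisible(x)
}
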