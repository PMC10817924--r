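# shared fixture builders and independent oracles

# minimal matched cohort with a supplied case-only/control-only discordance
# pattern in a binary exposure; remaining pairs concordant-unexposed
discordant_cohort <- function(n_case_exposed, n_control_exposed,
                              n_concordant = 5) {
  np <- n_case_exposed + n_control_exposed + n_concordant
  cohort <- data.frame(
    participant_id = sprintf("P%03d", seq_len(2 * np)),
    pair_id = rep(seq_len(np), each = 2L),
    case = rep(c(1L, 0L), np),
    stringsAsFactors = FALSE)
  expo <- numeric(2 * np)
  expo[cohort$case == 1L][seq_len(n_case_exposed)] <- 1
  expo[cohort$case == 0L][n_case_exposed + seq_len(n_control_exposed)] <- 1
  list(cohort = cohort, exposure = expo)
}

# random cohort with continuous exposure/covariates for equivalence checks
random_pair_cohort <- function(np, seed) {
  set.seed(seed)
  data.frame(
    participant_id = sprintf("P%04d", seq_len(2 * np)),
    pair_id = rep(seq_len(np), each = 2L),
    case = as.vector(replicate(np, sample(c(1L, 0L)))),
    x = stats::rnorm(2 * np),
    z1 = stats::rnorm(2 * np),
    z2 = stats::rnorm(2 * np),
    stringsAsFactors = FALSE)
}

# independent oracle: 1:1 conditional likelihood equals no-intercept
# logistic regression on within-pair (case - control) differences
pairdiff_logit <- function(cohort, vars) {
  d <- lapply(vars, function(v) {
    tapply(cohort[[v]] * ifelse(cohort$case == 1L, 1, -1),
           cohort$pair_id, sum)
  })
  D <- do.call(cbind, d)
  colnames(D) <- vars
  fit <- stats::glm(rep(1, nrow(D)) ~ 0 + D, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-14,
                                                 maxit = 200))
  stats::setNames(unname(stats::coef(fit)), vars)
}

# quartimin criterion value, written independently of the package internals
quartimin_value <- function(L) {
  L2 <- L^2
  k <- ncol(L)
  N <- matrix(1, k, k) - diag(k)
  sum(L2 * (L2 %*% N)) / 4
}

# independent quartimin rotation oracle: direct numeric minimization over
# the oblique rotation matrix (columns on the unit sphere), random restarts
quartimin_oracle <- function(A, n_restarts = 8, seed = 1) {
  k <- ncol(A)
  crit <- function(par) {
    Tm <- matrix(par, k, k)
    Tm <- Tm %*% diag(1 / sqrt(colSums(Tm^2)), k)
    L <- tryCatch(A %*% t(solve(Tm)), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    L2 <- L^2
    N <- matrix(1, k, k) - diag(k)
    sum(L2 * (L2 %*% N)) / 4
  }
  set.seed(seed)
  best <- Inf
  for (r in seq_len(n_restarts)) {
    start <- if (r == 1) as.vector(diag(k)) else stats::rnorm(k * k)
    opt <- stats::optim(start, crit, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (opt$value < best) best <- opt$value
  }
  best
}

# planted-factor data for EFA/CFA recovery checks
planted_factor_data <- function(n, loadings, seed) {
  set.seed(seed)
  p <- nrow(loadings)
  k <- ncol(loadings)
  f <- matrix(stats::rnorm(n * k), n, k)
  e_sd <- sqrt(pmax(1 - rowSums(loadings^2), 0.01))
  x <- f %*% t(loadings) + matrix(stats::rnorm(n * p), n, p) %*% diag(e_sd)
  colnames(x) <- rownames(loadings) %||% sprintf("food_%02d", seq_len(p))
  list(x = x, f = f)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
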