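# EFA (ML + oblimin), the rotation itself, Tucker congruence, and CFA

test_that("Tucker congruence is 1 for self, -1 for negation, 0 orthogonal", {
  v <- c(0.8, 0.6, 0, 0.2)
  expect_equal(tucker_phi(v, v), 1)
  expect_equal(tucker_phi(v, -v), -1)
  expect_equal(tucker_phi(v, 3.7 * v), 1)   # proportionality
  expect_equal(tucker_phi(c(1, 0), c(0, 1)), 0)
})

test_that("near-noiseless one-factor structure is recovered up to sign", {
  lam <- matrix(c(0.9, 0.8, 0.85, 0.7, 0.75), ncol = 1)
  rownames(lam) <- sprintf("food_%02d", 1:5)
  dat <- planted_factor_data(1500, lam * 0.99, seed = 4)
  # tiny uniquenesses keep the correlation matrix non-singular
  sol <- suppressWarnings(efa_ml(dat$x, 1))
  expect_gte(abs(tucker_phi(sol$loadings[, 1], lam[, 1])), 0.999)
})

test_that("two planted factors are recovered with high congruence", {
  lam <- matrix(0, 12, 2)
  lam[1:6, 1] <- 0.8
  lam[7:12, 2] <- 0.7
  rownames(lam) <- sprintf("food_%02d", 1:12)
  dat <- planted_factor_data(2000, lam, seed = 8)
  sol <- efa_ml(dat$x, 2)
  phis <- apply(sol$loadings, 2, function(v)
    max(abs(c(tucker_phi(v, lam[, 1]), tucker_phi(v, lam[, 2])))))
  expect_true(all(phis >= 0.98))
  expect_true(all(sol$uniquenesses > 0 & sol$uniquenesses <= 1))
})

test_that("degenerate factor counts are flagged, not silently returned", {
  set.seed(12)
  x <- matrix(rnorm(100 * 6), 100, 6)
  expect_error(efa_ml(x, 5), "degenerate")
  expect_error(efa_ml(x, 6), "degenerate")
  x[, 1] <- 1
  expect_error(efa_ml(x, 2), "zero-variance")
})

test_that("oblimin rotation: k = 1 identity, fixed point, criterion descent", {
  A1 <- matrix(c(0.8, 0.7, 0.6), ncol = 1)
  r1 <- oblimin_rotate(A1)
  expect_equal(r1$loadings, A1)
  # perfect simple structure is already a minimum of the quartimin criterion
  A2 <- rbind(cbind(c(0.8, 0.7, 0.6), 0), cbind(0, c(0.9, 0.5, 0.4)))
  r2 <- oblimin_rotate(A2)
  expect_lt(abs(r2$criterion - quartimin_value(A2)), 1e-8)
  set.seed(99)
  A3 <- matrix(rnorm(30), 10, 3)
  r3 <- oblimin_rotate(A3)
  expect_lte(r3$criterion, quartimin_value(A3) + 1e-10)
  expect_equal(dim(r3$Phi), c(3L, 3L))
  expect_equal(diag(r3$Phi), rep(1, 3))
  # sign convention: dominant loading positive
  expect_true(all(apply(r3$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("gradient-projection rotation matches an independent minimizer", {
  # quartimin on arbitrary matrices has local minima, so both routes take
  # the best of several starts before being compared
  for (s in 1:3) {
    set.seed(100 + s)
    A <- matrix(rnorm(30), 10, 3)
    starts <- c(list(diag(3)), lapply(1:7, function(i) {
      Tm <- matrix(rnorm(9), 3, 3)
      Tm %*% diag(1 / sqrt(colSums(Tm^2)))
    }))
    gpa <- min(vapply(starts, function(Tm)
      oblimin_rotate(A, Tmat = Tm)$criterion, 0))
    oracle <- quartimin_oracle(A, n_restarts = 8, seed = s)
    expect_lt(abs(gpa - oracle), 1e-4)
  }
})

test_that("CFA recovers a planted structure with good fit", {
  lam <- matrix(0, 9, 2)
  lam[1:5, 1] <- c(0.8, 0.75, 0.7, 0.65, 0.6)
  lam[6:9, 2] <- c(0.8, 0.7, 0.6, 0.5)
  rownames(lam) <- sprintf("food_%02d", 1:9)
  dat <- planted_factor_data(1200, lam, seed = 17)
  struct <- list(one = rownames(lam)[1:5], two = rownames(lam)[6:9])
  fit <- cfa_fit(dat$x, struct)
  expect_true(fit$converged)
  expect_gte(fit$fit["cfi"], 0.95)
  est <- fit$loadings
  expect_lt(max(abs(est[1:5, "one"] - lam[1:5, 1])), 0.1)
  expect_lt(max(abs(est[6:9, "two"] - lam[6:9, 2])), 0.1)
  # scores have zero mean and track the latent factors
  sc <- extract_scores(fit)
  expect_lt(max(abs(colMeans(sc[, -1]))), 1e-10)
  expect_gt(cor(sc$one, dat$f[, 1]), 0.8)
})

test_that("CFA on a model-implied covariance has near-zero discrepancy", {
  lam <- c(0.8, 0.7, 0.6)
  Sigma <- tcrossprod(lam) + diag(1 - lam^2)
  dimnames(Sigma) <- list(sprintf("f%d", 1:3), sprintf("f%d", 1:3))
  fit <- cfa_fit(NULL, list(g = colnames(Sigma)), sample_cov = Sigma,
                 n_obs = 500)
  expect_lt(fit$discrepancy, 1e-6)
})

test_that("CFA contract errors: absent foods and underidentification", {
  set.seed(3)
  x <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(NULL, sprintf("f%d", 1:4)))
  expect_error(cfa_fit(x, list(g = c("f1", "missing_food"))), "absent")
  expect_error(cfa_fit(x, list(g = "f1")), "fewer than 2")
  expect_error(cfa_fit(x, list(g = c("f1", "f2"))), "underidentified")
})
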