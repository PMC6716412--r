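# Gibbs kernels against conjugate closed forms, and sampler behavior.

strata_mat <- function(x, m) matrix(x, m, 3, byrow = TRUE)

test_that("theta update mean matches a direct 3x3 solve oracle", {
  set.seed(71)
  m <- 12
  y <- matrix(runif(m * 4, 0.3, 0.9), m, 4)
  v <- matrix(runif(m * 4, 0.005, 0.05), m, 4)
  mask <- matrix(TRUE, m, 4)
  mask[cbind(sample(m, 6, replace = TRUE), sample(4, 6, replace = TRUE))] <- FALSE
  l1 <- manual_level1(y, v, mask)
  data <- countysae:::level1_data(l1)
  X <- cbind(1, rnorm(m))
  B <- rbind(c(0.5, 0.1), c(0.55, -0.1), c(0.6, 0.05))
  Sigma <- 0.002 * (diag(3) + 0.5)
  lambda <- 0.9

  mu <- update_theta(data, B, lambda, Sigma, X,
                     noise = matrix(0, m, 3))
  Sinv <- solve(Sigma)
  for (i in seq_len(m)) {
    d <- ifelse(mask[i, 1:3], 1 / v[i, 1:3], 0)
    b <- ifelse(mask[i, 1:3], y[i, 1:3] / v[i, 1:3], 0)
    if (mask[i, 4]) {
      d[1] <- d[1] + lambda^2 / v[i, 4]
      b[1] <- b[1] + lambda * y[i, 4] / v[i, 4]
    }
    P <- Sinv + diag(d)
    expect_equal(unname(mu[i, ]),
                 unname(solve(P, Sinv %*% (B %*% X[i, ]) + b)[, 1]),
                 tolerance = 1e-10)
  }
})

test_that("theta update reproduces the conjugate normal posterior", {
  # one county, one observed stratum, replicated into many iid draws
  m <- 20000
  y <- cbind(0.6, 0, 0, 0)[rep(1, m), ]
  v <- cbind(0.01, 1, 1, 1)[rep(1, m), ]
  mask <- cbind(TRUE, FALSE, FALSE, FALSE)[rep(1, m), ]
  data <- countysae:::level1_data(manual_level1(y, v, mask))
  X <- matrix(1, m, 1)
  B <- matrix(c(0.5, 0.5, 0.5), ncol = 1)
  # prior SD 0.1: the [0, pi/2] truncation is 5 SDs away, so the
  # untruncated closed form applies
  Sigma <- diag(0.01, 3)
  set.seed(72)
  draws <- update_theta(data, B, 1, Sigma, X)
  post_prec <- 1 / 0.01 + 1 / 0.01
  post_mean <- (0.5 / 0.01 + 0.6 / 0.01) / post_prec
  expect_equal(mean(draws[, 1]), post_mean, tolerance = 0.01)
  expect_equal(stats::var(draws[, 1]), 1 / post_prec, tolerance = 0.03)
  # unobserved strata revert to the level-2 prior
  expect_equal(mean(draws[, 2]), 0.5, tolerance = 0.01)
  expect_equal(stats::var(draws[, 2]), 0.01, tolerance = 0.03)
})

test_that("posterior means equal the data in the vanishing-variance limit", {
  m <- 4
  set.seed(73)
  y <- matrix(runif(m * 4, 0.4, 0.8), m, 4)
  y[, 4] <- y[, 1]                        # consistent with lambda = 1
  v <- matrix(1e-8, m, 4)
  mask <- matrix(TRUE, m, 4)
  l1 <- manual_level1(y, v, mask)
  spec <- sae_model_spec(matrix(1, m, 1), n_iter = 500, n_burnin = 100,
                         n_chains = 1, seed = 74)
  fit <- suppressWarnings(fit_sae(l1, spec))
  post <- apply(fit$draws$theta, c(2, 3), mean)
  expect_equal(unname(post), unname(y[, 1:3]), tolerance = 1e-3)
})

test_that("sigma update with no residuals reproduces the prior mean", {
  set.seed(75)
  scale <- diag(0.01, 3)
  draws <- replicate(4000, update_sigma(matrix(0, 0, 3), 12, 8 * scale))
  expect_equal(apply(draws, c(1, 2), mean), 8 * scale / (12 - 4),
               tolerance = 0.1)
  d <- replicate(500, update_sigma(matrix(0, 0, 3), 12, 8 * scale,
                                   diagonal = TRUE))
  expect_true(all(d[1, 2, ] == 0))
  expect_equal(mean(d[1, 1, ]), 8 * 0.01 / (12 - 2), tolerance = 0.1)
})

test_that("lambda update concentrates at the truth under abundant data", {
  set.seed(76)
  m <- 300
  theta <- cbind(runif(m, 0.3, 0.7), 0.5, 0.5)
  y <- cbind(0, 0, 0, theta[, 1])        # BRFSS equals lambda * theta, lambda = 1
  v <- cbind(1, 1, 1, 1e-6)[rep(1, m), ]
  mask <- cbind(FALSE, FALSE, FALSE, TRUE)[rep(1, m), ]
  data <- countysae:::level1_data(manual_level1(y, v, mask))
  draws <- replicate(200, update_lambda(theta, data, 1, 0.25))
  expect_true(all(abs(draws - 1) < 0.01))
  expect_true(all(draws > 0))
})

test_that("beta update matches the conjugate regression oracle", {
  set.seed(77)
  m <- 40; p <- 2
  X <- qr.Q(qr(matrix(rnorm(m * p), m, p)))   # orthonormal columns
  theta <- matrix(rnorm(m * 3, 0.5, 0.2), m, 3)
  s2 <- 0.05
  pv <- 4; pm <- 0
  draws <- replicate(5000, update_beta(theta, X, diag(s2, 3),
                                       matrix(pm, 3, p), pv))
  prec <- 1 / s2 + 1 / pv
  oracle_mean <- t(crossprod(X, theta) / s2 / prec)   # 3 x p
  mc_se <- sqrt(1 / prec / 5000)
  expect_equal(apply(draws, c(1, 2), mean), oracle_mean,
               tolerance = 5 * mc_se / max(abs(oracle_mean)))
  expect_equal(apply(draws, c(1, 2), stats::var),
               matrix(1 / prec, 3, p), tolerance = 0.08)
})

test_that("theta kernel is equivariant under county permutation", {
  set.seed(78)
  m <- 20
  y <- matrix(runif(m * 4, 0.4, 0.8), m, 4)
  v <- matrix(runif(m * 4, 0.01, 0.05), m, 4)
  mask <- matrix(runif(m * 4) < 0.8, m, 4)
  mask[rowSums(mask) == 0, 4] <- TRUE
  X <- cbind(1, rnorm(m))
  B <- rbind(c(0.5, 0.05), c(0.55, 0.05), c(0.6, 0.05))
  Sigma <- diag(0.004, 3)
  Z <- matrix(rnorm(m * 3), m, 3)
  perm <- sample(m)

  d0 <- countysae:::level1_data(manual_level1(y, v, mask))
  dp <- countysae:::level1_data(manual_level1(y[perm, ], v[perm, ],
                                              mask[perm, ]))
  t0 <- update_theta(d0, B, 0.9, Sigma, X, noise = Z)
  tp <- update_theta(dp, B, 0.9, Sigma, X[perm, , drop = FALSE],
                     noise = Z[perm, , drop = FALSE])
  expect_equal(unname(tp), unname(t0[perm, ]), tolerance = 1e-12)
})

test_that("counties without in-person samples get proper posteriors", {
  sim <- small_sim(m = 40, seed = 81)
  nd <- direct_estimates(sim$nhis)
  bd <- direct_estimates(sim$brfss)
  l1 <- assemble_level1(nd, bd)
  X <- as.matrix(sim$counties[match(l1$county_id, sim$counties$county_id),
                              paste0("x", 1:3)])
  spec <- sae_model_spec(X, n_iter = 800, n_burnin = 300, n_chains = 2,
                         seed = 82)
  fit <- suppressWarnings(fit_sae(l1, spec))
  brfss_only <- rowSums(l1$mask[, 1:3]) == 0
  expect_gt(sum(brfss_only), 0)
  th <- fit$draws$theta[, brfss_only, , drop = FALSE]
  expect_true(all(is.finite(th)))
  expect_true(all(th >= 0 & th <= pi / 2))
  expect_true(all(apply(th, c(2, 3), stats::sd) > 0))
  expect_true(all(fit$draws$lambda > 0))
  # every retained Sigma draw positive definite
  ev <- apply(fit$draws$Sigma[seq(1, fit$n_draws, by = 50), , ], 1,
              function(S) min(eigen(S, symmetric = TRUE,
                                    only.values = TRUE)$values))
  expect_true(all(ev > 0))
})

test_that("short runs are flagged, never silently accepted", {
  sim <- small_sim(m = 25, seed = 83)
  l1 <- assemble_level1(direct_estimates(sim$nhis),
                        direct_estimates(sim$brfss))
  X <- as.matrix(sim$counties[match(l1$county_id, sim$counties$county_id),
                              paste0("x", 1:3)])
  spec <- sae_model_spec(X, n_iter = 120, n_burnin = 40, n_chains = 2,
                         seed = 84)
  w <- capture_warnings(fit <- fit_sae(l1, spec))
  expect_true(any(grepl("effective draws", w)))
  expect_false(attr(fit$diagnostics, "converged"))
  expect_true(all(c("parameter", "rhat", "ess") %in%
                    names(fit$diagnostics)))
})
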