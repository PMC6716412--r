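# Phone-composition smoothing and the draw-wise back-transform.

test_that("smoothing vanishes for a county with enormous sample", {
  set.seed(101)
  m <- 40
  X <- cbind(1, rnorm(m))
  counts <- t(sapply(seq_len(m), function(i) {
    stats::rmultinom(1, 20, c(0.75, 0.23, 0.02))[, 1]
  }))
  counts[1, ] <- round(1e6 * c(0.5, 0.3, 0.2))
  phi <- smooth_phone_composition(counts, X)
  expect_equal(unname(unlist(phi[1, c("phi_landline", "phi_cellonly",
                                      "phi_nophone")])),
               c(0.5, 0.3, 0.2), tolerance = 0.01)
  mat <- as.matrix(phi[, c("phi_landline", "phi_cellonly", "phi_nophone")])
  expect_equal(rowSums(mat), rep(1, m), tolerance = 1e-9)
  expect_true(all(mat >= 0 & mat <= 1))
})

test_that("unsampled counties receive the regression prediction", {
  set.seed(102)
  m <- 30
  counts <- t(sapply(seq_len(m), function(i) {
    stats::rmultinom(1, 50, c(0.7, 0.27, 0.03))[, 1]
  }))
  counts[c(4, 9), ] <- 0
  # constant covariates: the regression is intercept-only, so the
  # prediction is the pooled national composition
  phi <- smooth_phone_composition(counts, matrix(1, m, 1))
  pooled <- colSums(counts) / sum(counts)
  expect_equal(unname(unlist(phi[4, c("phi_landline", "phi_cellonly",
                                      "phi_nophone")])),
               unname(pooled), tolerance = 1e-3)
  expect_identical(unlist(phi[4, 2:4]), unlist(phi[9, 2:4]))
  expect_error(smooth_phone_composition(matrix(0, 3, 3), matrix(1, 3, 1)),
               "all county counts are zero")
})

test_that("smoothed compositions beat raw shares at small sample sizes", {
  cfg <- generator_config(m_counties = 150, nhis_county_fraction = 1,
                          nhis_mean_n = 15, seed = 103)
  counties <- generate_counties(cfg)
  nhis <- sample_nhis(counties, cfg)
  counts <- phone_counts(nhis, county_id = counties$county_id)
  X <- as.matrix(counties[, paste0("x", 1:3)])
  phi <- smooth_phone_composition(counts, X,
                                  county_id = counties$county_id)
  truth <- as.matrix(counties[, c("phi_landline", "phi_cellonly",
                                  "phi_nophone")])
  smoothed <- as.matrix(phi[, c("phi_landline", "phi_cellonly",
                                "phi_nophone")])
  obs <- rowSums(counts) > 0
  raw <- counts[obs, ] / rowSums(counts)[obs]
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(smoothed[obs, ], truth[obs, ]), rmse(raw, truth[obs, ]))
})

test_that("composition of draws matches hand-computed cases", {
  # constant landline draws: point mass back-transform
  th <- cbind(rep(0.5236, 500), 0.2, 0.9)
  out <- suppressWarnings(compose_county(th, c(1, 0, 0)))
  expect_equal(out$estimate, sin(0.5236)^2, tolerance = 1e-12)
  expect_equal(out$ci_upper - out$ci_lower, 0)

  # equal theta across strata: phi is irrelevant
  th2 <- matrix(rep(seq(0.3, 0.7, length.out = 500), 3), ncol = 3)
  a <- compose_county(th2, c(0.75, 0.232, 0.018))
  b <- compose_county(th2, c(0.1, 0.4, 0.5))
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
  expect_equal(a$estimate, mean(sin(th2[, 1])^2), tolerance = 1e-12)

  # two-point landline posterior: draw-wise mean of sin^2
  two <- suppressWarnings(compose_county(cbind(c(0.4, 0.6), 0, 0),
                                         c(1, 0, 0)))
  expect_equal(two$estimate, (sin(0.4)^2 + sin(0.6)^2) / 2,
               tolerance = 1e-12)
  expect_warning(compose_county(cbind(c(0.4, 0.6), 0, 0), c(1, 0, 0)),
                 "fewer than 400")
  expect_error(compose_county(th, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("estimates are monotone in theta and respect Jensen's direction", {
  set.seed(104)
  th <- matrix(runif(500 * 3, 0.2, 0.5), ncol = 3)
  phi <- c(0.75, 0.232, 0.018)
  base <- compose_county(th, phi)$estimate
  up <- compose_county(th + 0.05, phi)$estimate
  expect_gt(up, base)

  # symmetric draws below pi/4: sin^2 is convex there, so the draw-wise
  # mean exceeds the back-transform of the mean
  sym <- cbind(c(rep(0.2, 250), rep(0.6, 250)), 0.4, 0.4)
  est <- compose_county(sym, c(1, 0, 0))$estimate
  expect_gt(est, sin(0.4)^2)
})

test_that("county composition matches the per-county operation", {
  run <- recovery_run()
  i <- match("c0005", run$fit$county_id)
  one <- compose_county(run$fit$draws$theta[, i, ],
                        unlist(run$phi[match("c0005", run$phi$county_id),
                                       c("phi_landline", "phi_cellonly",
                                         "phi_nophone")]))
  expect_equal(run$saes$estimate[run$saes$county_id == "c0005"],
               one$estimate, tolerance = 1e-12)
  expect_equal(run$saes$ci_lower[run$saes$county_id == "c0005"],
               one$ci_lower, tolerance = 1e-12)
})
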