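# Synthetic two-survey generator: county truth, composition, and the two
# coupled pseudo-surveys.

test_that("generation is deterministic given config and seed", {
  cfg <- generator_config(m_counties = 30, seed = 42)
  a <- simulate_surveys(cfg)
  b <- simulate_surveys(cfg)
  expect_identical(a$counties, b$counties)
  expect_identical(a$nhis, b$nhis)
  expect_identical(a$brfss, b$brfss)
})

test_that("zero-variance intercept-only config collapses to a shared theta", {
  icpt <- asin(sqrt(c(0.2, 0.3, 0.35)))
  cfg <- generator_config(
    m_counties = 25, p_covariates = 1,
    beta_true = matrix(icpt, ncol = 1),
    Sigma_true = diag(1e-12, 3),
    phi_cov_loading = matrix(0, 2, 0), seed = 8
  )
  counties <- generate_counties(cfg)
  for (s in 1:3) {
    expect_equal(counties[[paste0("theta_", c("landline", "cellonly",
                                              "nophone"))[s]]],
                 rep(icpt[s], 25), tolerance = 1e-5)
  }
})

test_that("county truth satisfies its invariants", {
  counties <- generate_counties(generator_config(m_counties = 400, seed = 5))
  phi <- as.matrix(counties[, c("phi_landline", "phi_cellonly",
                                "phi_nophone")])
  expect_true(all(phi >= 0))
  expect_equal(rowSums(phi), rep(1, 400), tolerance = 1e-12)
  th <- as.matrix(counties[, c("theta_landline", "theta_cellonly",
                               "theta_nophone")])
  pi_t <- as.matrix(counties[, c("pi_landline", "pi_cellonly",
                                 "pi_nophone")])
  expect_equal(pi_t, sin(th)^2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(counties$pi_combined, rowSums(phi * pi_t), tolerance = 1e-12)
  expect_true(all(pi_t > 0 & pi_t < 1))
})

test_that("mean phone composition matches the national shares", {
  counties <- generate_counties(generator_config(m_counties = 10000,
                                                 seed = 21))
  phi_bar <- colMeans(as.matrix(counties[, c("phi_landline", "phi_cellonly",
                                             "phi_nophone")]))
  expect_lt(max(abs(phi_bar - c(0.750, 0.232, 0.018))), 0.01)
})

test_that("county random effects reproduce the generating covariance", {
  cfg <- generator_config(m_counties = 20000, seed = 9)
  counties <- generate_counties(cfg)
  X <- as.matrix(counties[, paste0("x", 1:3)])
  th <- as.matrix(counties[, c("theta_landline", "theta_cellonly",
                               "theta_nophone")])
  resid <- th - X %*% t(cfg$beta_true)
  emp <- stats::cov(resid)
  expect_true(all(abs(emp - cfg$Sigma_true) <
                    0.05 * max(abs(cfg$Sigma_true))))
})

test_that("pooled sample prevalences reproduce the phone-status gradient", {
  # landline < cell-only < no-phone, as for adult current smoking
  cfg <- generator_config(m_counties = 300, nhis_county_fraction = 1,
                          nhis_mean_n = 400, seed = 12)
  nhis <- sample_nhis(generate_counties(cfg), cfg)
  pooled <- tapply(nhis$outcome, nhis$stratum, mean)
  expect_lt(pooled[["landline"]], pooled[["cellonly"]])
  expect_lt(pooled[["cellonly"]], pooled[["nophone"]])
})

test_that("NHIS county coverage follows the configured fraction", {
  cfg <- generator_config(m_counties = 40, nhis_county_fraction = 1,
                          seed = 4)
  counties <- generate_counties(cfg)
  nhis <- sample_nhis(counties, cfg)
  expect_setequal(unique(nhis$county_id), counties$county_id)

  cfg25 <- generator_config(m_counties = 40, seed = 4)
  nhis25 <- sample_nhis(generate_counties(cfg25), cfg25)
  expect_equal(length(unique(nhis25$county_id)), 10)

  cfg_bad <- generator_config(m_counties = 3, nhis_county_fraction = 0.1,
                              seed = 4)
  expect_error(sample_nhis(generate_counties(cfg_bad), cfg_bad),
               "no county can be sampled")
})

test_that("zero weight CV gives equal weights", {
  cfg <- generator_config(m_counties = 20, weight_cv = 0, seed = 6)
  sim <- simulate_surveys(cfg)
  expect_true(all(sim$nhis$weight == 1))
  expect_true(all(sim$brfss$weight == 1))
})

test_that("the telephone survey samples the landline stratum everywhere", {
  cfg <- generator_config(m_counties = 35, seed = 13)
  counties <- generate_counties(cfg)
  brfss <- sample_brfss(counties, cfg)
  expect_true(all(brfss$stratum == "landline"))
  expect_setequal(unique(brfss$county_id), counties$county_id)
  expect_true(all(table(brfss$county_id) >= 2))
})

test_that("telephone-survey bias acts multiplicatively on the transformed scale", {
  # lambda = 0.9, theta_L = 0.5236: success probability sin^2(0.47124)
  theta_l <- 0.5236
  cfg <- generator_config(
    m_counties = 1, p_covariates = 1,
    beta_true = matrix(rep(theta_l, 3), ncol = 1),
    Sigma_true = diag(1e-12, 3),
    phi_cov_loading = matrix(0, 2, 0),
    lambda_true = 0.9, brfss_mean_n = 200000, weight_cv = 0, seed = 31
  )
  counties <- generate_counties(cfg)
  brfss <- sample_brfss(counties, cfg)
  p_expected <- sin(0.9 * theta_l)^2        # ~0.2059
  se <- sqrt(p_expected * (1 - p_expected) / nrow(brfss))
  expect_equal(mean(brfss$outcome), p_expected, tolerance = 3 * se / p_expected)

  cfg_bad <- generator_config(
    m_counties = 1, p_covariates = 1,
    beta_true = matrix(rep(1.5, 3), ncol = 1),
    Sigma_true = diag(1e-12, 3),
    phi_cov_loading = matrix(0, 2, 0),
    lambda_true = 1.2, seed = 31
  )
  expect_error(sample_brfss(generate_counties(cfg_bad), cfg_bad),
               "prevalence undefined")
})

test_that("pooled in-person outcomes match the binomial oracle", {
  theta <- asin(sqrt(0.25))
  cfg <- generator_config(
    m_counties = 1, p_covariates = 1, nhis_county_fraction = 1,
    beta_true = matrix(rep(theta, 3), ncol = 1),
    Sigma_true = diag(1e-12, 3),
    phi_cov_loading = matrix(0, 2, 0),
    nhis_mean_n = 300000, weight_cv = 0, seed = 17
  )
  counties <- generate_counties(cfg)
  nhis <- sample_nhis(counties, cfg)
  se <- sqrt(0.25 * 0.75 / nrow(nhis))
  expect_equal(mean(nhis$outcome), 0.25, tolerance = 3 * se / 0.25)
})
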