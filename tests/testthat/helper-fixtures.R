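# Shared fixtures.  The parameter-recovery run (m = 200 counties, the
# default study conditions with lambda_true = 0.9) is expensive, so it is
# computed once per test session and cached; several acceptance properties
# (recovery, shrinkage, funnel, national benchmarking) read from it.

.fixture_cache <- new.env(parent = emptyenv())

# small full-pipeline simulation pieces, sized for unit tests
small_sim <- function(m = 50, seed = 3, ...) {
  cfg <- generator_config(m_counties = m, seed = seed, ...)
  sim <- simulate_surveys(cfg)
  sim$config <- cfg
  sim
}

# build an sae_level1 object directly from matrices (bypasses the survey
# layer for kernel-level tests)
manual_level1 <- function(y, v, mask, county_id = NULL) {
  m <- nrow(y)
  if (is.null(county_id)) county_id <- sprintf("c%04d", seq_len(m))
  comp <- c("nhis_landline", "nhis_cellonly", "nhis_nophone", "brfss")
  dimnames(y) <- dimnames(v) <- dimnames(mask) <- list(county_id, comp)
  structure(
    list(county_id = county_id, y = y, v = v, mask = mask,
         n_eff = 1 / (4 * v), components = comp, min_n = 2L,
         dropped = data.frame(county_id = character(0),
                              reason = character(0))),
    class = "sae_level1"
  )
}

# the shared parameter-recovery run at the default study conditions
recovery_run <- function() {
  if (!is.null(.fixture_cache$recovery)) return(.fixture_cache$recovery)
  cfg <- generator_config(m_counties = 200, seed = 101)
  sim <- simulate_surveys(cfg)
  nhis_direct <- direct_estimates(sim$nhis, "current_smoking_all")
  brfss_direct <- direct_estimates(sim$brfss, "current_smoking_all")
  nhis_county <- direct_estimates(sim$nhis, "current_smoking_all",
                                  by_stratum = FALSE)
  level1 <- assemble_level1(nhis_direct, brfss_direct)
  X <- as.matrix(sim$counties[match(level1$county_id,
                                    sim$counties$county_id),
                              paste0("x", 1:3)])
  spec <- sae_model_spec(X, n_iter = 12000, n_burnin = 3000, thin = 3,
                         n_chains = 2, seed = 2101)
  fit <- suppressWarnings(fit_sae(level1, spec))
  counts <- phone_counts(sim$nhis, county_id = level1$county_id)
  phi <- smooth_phone_composition(counts, X, county_id = level1$county_id)
  saes <- compose_counties(fit, phi, "current_smoking_all")
  truth <- sim$counties$pi_combined[match(saes$county_id,
                                          sim$counties$county_id)]
  report <- validate_sae(saes, fit, brfss_direct, nhis_direct,
                         populations = sim$counties)
  .fixture_cache$recovery <- list(
    config = cfg, sim = sim, nhis_direct = nhis_direct,
    brfss_direct = brfss_direct, nhis_county = nhis_county,
    level1 = level1, X = X, fit = fit, phi = phi, saes = saes,
    truth = truth, report = report
  )
  .fixture_cache$recovery
}
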