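# End-to-end orchestration: simulate -> direct -> transform -> fit ->
# compose -> validate, under a single flat seed expanded into per-stage
# substreams so any stage can be rerun in isolation.

#' Configuration for a full pipeline run
#'
#' @param generator A [generator_config()]; its seed is overridden by the
#'   run seed below so one flat seed controls the whole run.
#' @param outcome Outcome name recorded in outputs (see
#'   [outcome_definitions()]).
#' @param n_iter,n_burnin,n_chains,thin MCMC settings for [fit_sae()].
#' @param priors Named list overriding [sae_model_spec()] prior arguments
#'   (`beta_mean`, `beta_var`, `lambda_mean`, `lambda_var`, `sigma_df`,
#'   `sigma_scale`, `sigma_diagonal`).
#' @param min_n Minimum respondents per county-stratum cell at level 1.
#' @param seed Flat run seed; stages use substreams `seed`, `seed + 1`,
#'   `seed + 2`, `seed + 3` (generation, in-person sampling, telephone
#'   sampling, MCMC).
#' @return Object of class `sae_run_config`.
#' @export
sae_run_config <- function(generator = generator_config(),
                           outcome = "current_smoking_all",
                           n_iter = 3000L, n_burnin = 1000L,
                           n_chains = 2L, thin = 1L,
                           priors = list(), min_n = 2L, seed = 1L) {
  stopifnot(inherits(generator, "generator_config"))
  outcome_definition(outcome)  # validates the name
  structure(
    list(generator = generator, outcome = outcome,
         n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
         n_chains = as.integer(n_chains), thin = as.integer(thin),
         priors = priors, min_n = as.integer(min_n),
         seed = as.integer(seed)),
    class = "sae_run_config"
  )
}

#' Run the full small-area estimation pipeline
#'
#' Generates the synthetic county truth and both pseudo-surveys, computes
#' direct estimates, assembles the transformed level-1 vectors, fits the
#' hierarchical model, smooths phone compositions, composes county SAEs
#' with credible intervals, and runs the validation battery.  Identical
#' configuration and seed give identical outputs.
#'
#' @param config An [sae_run_config()].
#' @param out_dir Optional directory; when given, every intermediate and
#'   final table is written as CSV (each file carries the run seed in a
#'   leading comment line).
#' @param write_microdata Also write the respondent-level microdata CSVs
#'   (they can be large).
#' @param verbose Log stage progress to stderr.
#' @return List with `counties`, `nhis`, `brfss`, `nhis_direct`,
#'   `brfss_direct`, `level1`, `fit`, `phi`, `saes`, `report`, `config`.
#' @export
run_sae_pipeline <- function(config = sae_run_config(), out_dir = NULL,
                             write_microdata = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "sae_run_config"))
  log_stage <- function(...) {
    if (verbose) message(format(Sys.time(), "%H:%M:%S"), " [", ..., "]")
  }
  gen <- config$generator
  gen$seed <- config$seed

  log_stage("simulate")
  counties <- generate_counties(gen)
  nhis <- sample_nhis(counties, gen, seed = config$seed + 1L)
  brfss <- sample_brfss(counties, gen, seed = config$seed + 2L)

  log_stage("direct")
  nhis_direct <- direct_estimates(nhis, config$outcome, by_stratum = TRUE)
  brfss_direct <- direct_estimates(brfss, config$outcome, by_stratum = TRUE)

  log_stage("transform")
  level1 <- assemble_level1(nhis_direct, brfss_direct, min_n = config$min_n)

  log_stage("fit")
  p <- gen$p_covariates
  X <- as.matrix(counties[match(level1$county_id, counties$county_id),
                          paste0("x", seq_len(p)), drop = FALSE])
  spec_args <- c(
    list(covariates = X, n_iter = config$n_iter,
         n_burnin = config$n_burnin, n_chains = config$n_chains,
         thin = config$thin, seed = config$seed + 3L),
    config$priors
  )
  spec <- do.call(sae_model_spec, spec_args)
  fit <- fit_sae(level1, spec)

  log_stage("compose")
  counts <- phone_counts(nhis, county_id = level1$county_id)
  phi <- smooth_phone_composition(counts, X, county_id = level1$county_id)
  saes <- compose_counties(fit, phi, outcome = config$outcome)

  log_stage("validate")
  report <- validate_sae(saes, fit, brfss_direct, nhis_direct,
                         populations = counties)

  result <- list(counties = counties, nhis = nhis, brfss = brfss,
                 nhis_direct = nhis_direct, brfss_direct = brfss_direct,
                 level1 = level1, fit = fit, phi = phi, saes = saes,
                 report = report, config = config)
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir,
                           write_microdata = write_microdata)
  }
  result
}

# write a table as CSV with the run seed recorded in a leading comment line
write_seeded_csv <- function(df, path, seed) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# countysae seed=%d", seed), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a pipeline CSV
#'
#' Reads CSVs written by [run_sae_pipeline()] (skipping the seed comment
#' line).
#' @param path File path.
#' @return Data frame.
#' @export
read_pipeline_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

level1_long <- function(level1) {
  m <- length(level1$county_id)
  data.frame(
    county_id = rep(level1$county_id, times = 4L),
    component = rep(level1$components, each = m),
    y = as.vector(level1$y),
    v = as.vector(level1$v),
    mask = as.vector(level1$mask),
    stringsAsFactors = FALSE
  )
}

hyper_draws_long <- function(fit) {
  n_total <- fit$n_draws
  n_keep <- n_total / fit$n_chains
  p <- dim(fit$draws$beta)[3]
  vals <- cbind(
    matrix(fit$draws$beta, n_total, 3 * p),
    fit$draws$lambda,
    matrix(fit$draws$Sigma, n_total, 9)[, c(1, 4, 7, 5, 8, 9)]
  )
  pn <- c(paste0("beta[", rep(1:3, p), ",", rep(seq_len(p), each = 3), "]"),
          "lambda",
          paste0("Sigma[", c(1, 1, 1, 2, 2, 3), ",",
                 c(1, 2, 3, 2, 3, 3), "]"))
  data.frame(
    parameter = rep(pn, each = n_total),
    chain = rep(rep(seq_len(fit$n_chains), each = n_keep), length(pn)),
    iteration = rep(rep(seq_len(n_keep), fit$n_chains), length(pn)),
    value = as.vector(vals),
    stringsAsFactors = FALSE
  )
}

write_pipeline_outputs <- function(result, out_dir, write_microdata) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- result$config$seed
  w <- function(df, name) {
    write_seeded_csv(df, file.path(out_dir, name), seed)
  }
  w(result$counties, "counties.csv")
  if (write_microdata) {
    w(result$nhis, "nhis_microdata.csv")
    w(result$brfss, "brfss_microdata.csv")
  }
  w(result$nhis_direct, "direct_nhis.csv")
  w(result$brfss_direct, "direct_brfss.csv")
  w(level1_long(result$level1), "level1.csv")
  w(hyper_draws_long(result$fit), "hyperparameter_draws.csv")
  w(result$fit$diagnostics, "mcmc_diagnostics.csv")
  w(result$phi, "phone_composition.csv")
  saes_pct <- data.frame(
    county_id = result$saes$county_id,
    outcome = result$saes$outcome,
    estimate_pct = 100 * result$saes$estimate,
    ci_lower_pct = 100 * result$saes$ci_lower,
    ci_upper_pct = 100 * result$saes$ci_upper,
    stringsAsFactors = FALSE
  )
  w(saes_pct, "county_saes.csv")
  w(result$report$funnel, "validation_funnel.csv")
  w(result$report$funnel_bins, "validation_funnel_bins.csv")
  w(result$report$national_check, "validation_national.csv")
  w(result$report$summaries, "validation_summaries.csv")
  invisible(out_dir)
}
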