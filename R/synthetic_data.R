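# Synthetic two-survey generator: county truth, an in-person survey covering
# all telephone-status strata in ~25% of counties, and a much larger
# landline-only telephone survey whose transformed-scale mean is biased by a
# multiplicative factor lambda.

PHONE_STRATA <- c("landline", "cellonly", "nophone")

#' Configuration for the synthetic two-survey generator
#'
#' Encodes the study conditions the generator emulates: county random effects
#' on the arcsine-square-root (transformed) scale around a covariate
#' regression, phone-status compositions centered at the national household
#' shares 75.0% landline / 23.2% cell-only / 1.8% no phone, an in-person
#' survey (NHIS-like) that by design samples only a fraction of counties but
#' all phone strata, and a telephone survey (BRFSS-like) that samples the
#' landline stratum in every county with roughly tenfold the per-county
#' sample size and a proportionate bias `lambda_true` on the transformed
#' scale.
#'
#' @param m_counties Number of counties.
#' @param p_covariates Number of covariates including the intercept.
#' @param beta_true 3 x p matrix of level-2 regression coefficients (rows:
#'   landline, cellonly, nophone).  The default intercepts place stratum
#'   prevalences at 17.7% / 27.3% / 30.9% — the adult current-smoking
#'   gradient across phone strata — with small positive covariate effects.
#' @param Sigma_true Symmetric positive-definite 3 x 3 covariance of the
#'   county random effects on the transformed scale.  Default: standard
#'   deviation about 0.063 per stratum (county prevalence SD of roughly 5-6
#'   percentage points near p = 0.25) with cross-stratum correlation 0.5.
#' @param lambda_true Multiplicative bias of the telephone survey on the
#'   transformed scale: its county-level transformed mean is
#'   `lambda_true * theta_landline`.
#' @param nhis_county_fraction Fraction of counties the in-person survey
#'   samples (default 0.25; roughly three-quarters of counties have no
#'   sample by design).
#' @param nhis_mean_n,brfss_mean_n Mean per-county respondent counts for a
#'   county of average population; actual counts are Poisson with mean
#'   proportional to county population (truncated at 1 and 2 respondents).
#' @param weight_cv Coefficient of variation of the lognormal survey
#'   weights; the Kish design effect is then approximately `1 + weight_cv^2`.
#' @param phi_center National phone-status composition the county
#'   compositions are centered on (simplex of length 3).
#' @param phi_cov_loading 2 x (p-1) matrix of covariate loadings for the
#'   additive log-ratio (cellonly/landline, nophone/landline) composition
#'   coordinates; lets the phone composition be regressed on covariates.
#' @param phi_resid_sd Residual SDs of the two log-ratio coordinates.
#' @param pop_meanlog,pop_sdlog Lognormal parameters for county adult
#'   populations.
#' @param theta_clip Margin used to clip true transformed means into
#'   `[theta_clip, pi/2 - theta_clip]`, preventing degenerate 0/1
#'   prevalences.
#' @param seed Integer seed; the generator is deterministic given the
#'   configuration and seed.
#' @return An object of class `generator_config` (a validated list).
#' @examples
#' cfg <- generator_config(m_counties = 50, seed = 7)
#' counties <- generate_counties(cfg)
#' head(counties)
#' @export
generator_config <- function(m_counties = 200L,
                             p_covariates = 3L,
                             beta_true = NULL,
                             Sigma_true = NULL,
                             lambda_true = 0.9,
                             nhis_county_fraction = 0.25,
                             nhis_mean_n = 12L,
                             brfss_mean_n = 120L,
                             weight_cv = 0.7,
                             phi_center = c(landline = 0.750,
                                            cellonly = 0.232,
                                            nophone = 0.018),
                             phi_cov_loading = NULL,
                             phi_resid_sd = c(0.15, 0.30),
                             pop_meanlog = log(25000),
                             pop_sdlog = 1.0,
                             theta_clip = 0.02,
                             seed = 1L) {
  m_counties <- as.integer(m_counties)
  p_covariates <- as.integer(p_covariates)
  stopifnot(m_counties >= 1L, p_covariates >= 1L)

  if (is.null(beta_true)) {
    # transformed-scale intercepts at the smoking gradient 17.7/27.3/30.9%
    intercepts <- asin(sqrt(c(0.177, 0.273, 0.309)))
    slopes <- matrix(0.05, nrow = 3, ncol = p_covariates - 1L)
    beta_true <- cbind(intercepts, slopes, deparse.level = 0)
  }
  beta_true <- as.matrix(beta_true)
  if (!all(dim(beta_true) == c(3L, p_covariates))) {
    stop("beta_true must be a 3 x p_covariates matrix", call. = FALSE)
  }

  if (is.null(Sigma_true)) {
    Sigma_true <- 0.002 * (diag(3) + 1)  # diag 0.004, off-diag 0.002
  }
  Sigma_true <- as.matrix(Sigma_true)
  check_spd(Sigma_true, "Sigma_true")

  stopifnot(
    lambda_true > 0,
    nhis_county_fraction > 0, nhis_county_fraction <= 1,
    nhis_mean_n >= 1, brfss_mean_n >= 1,
    weight_cv >= 0,
    length(phi_center) == 3L, all(phi_center > 0),
    abs(sum(phi_center) - 1) < 1e-8,
    length(phi_resid_sd) == 2L, all(phi_resid_sd >= 0),
    theta_clip > 0, theta_clip < pi / 4
  )

  if (is.null(phi_cov_loading)) {
    phi_cov_loading <- matrix(c(0.22, 0.37), nrow = 2,
                              ncol = p_covariates - 1L)
  }
  phi_cov_loading <- matrix(phi_cov_loading, nrow = 2)
  if (ncol(phi_cov_loading) != p_covariates - 1L) {
    stop("phi_cov_loading must have p_covariates - 1 columns", call. = FALSE)
  }

  structure(
    list(
      m_counties = m_counties, p_covariates = p_covariates,
      beta_true = beta_true, Sigma_true = Sigma_true,
      lambda_true = lambda_true,
      nhis_county_fraction = nhis_county_fraction,
      nhis_mean_n = nhis_mean_n, brfss_mean_n = brfss_mean_n,
      weight_cv = weight_cv,
      phi_center = stats::setNames(phi_center, PHONE_STRATA),
      phi_cov_loading = phi_cov_loading,
      phi_resid_sd = phi_resid_sd,
      pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
      theta_clip = theta_clip,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

check_spd <- function(S, name) {
  if (!isSymmetric(S, tol = 1e-10)) {
    stop(name, " must be symmetric", call. = FALSE)
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop(name, " must be positive definite (eigenvalues > 0)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate county-level truth
#'
#' Draws county populations, covariates, phone-status compositions and true
#' stratum prevalences.  Transformed-scale true means are
#' `theta_i = beta_true %*% x_i + u_i` with `u_i ~ MVN(0, Sigma_true)`,
#' clipped into `[theta_clip, pi/2 - theta_clip]`; prevalences are
#' `sin(theta)^2`.  Compositions are additive-logistic-normal around the
#' national shares, mean-corrected on the log-ratio scale and loading on the
#' covariates so they can be recovered by regression.
#'
#' @param config A [generator_config()].
#' @return A data frame of class `county_truth` with one row per county:
#'   `county_id`, `population`, covariates `x1..xp` (x1 is the intercept),
#'   `phi_*` composition, `theta_*` transformed means, `pi_*` prevalences and
#'   the composition-weighted `pi_combined`.
#' @export
generate_counties <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  m <- config$m_counties
  p <- config$p_covariates

  population <- pmax(100, round(stats::rlnorm(m, config$pop_meanlog,
                                              config$pop_sdlog)))
  X <- cbind(1, matrix(stats::rnorm(m * (p - 1L)), nrow = m))
  colnames(X) <- paste0("x", seq_len(p))

  u <- MASS::mvrnorm(m, mu = rep(0, 3), Sigma = config$Sigma_true)
  if (m == 1L) u <- matrix(u, nrow = 1)
  theta <- X %*% t(config$beta_true) + u
  theta <- pmin(pmax(theta, config$theta_clip), pi / 2 - config$theta_clip)
  colnames(theta) <- PHONE_STRATA
  pi_true <- sin(theta)^2

  phi <- draw_phi(m, X, config)
  pi_combined <- rowSums(phi * pi_true)

  out <- data.frame(
    county_id = sprintf("c%04d", seq_len(m)),
    population = population,
    X,
    phi_landline = phi[, 1], phi_cellonly = phi[, 2], phi_nophone = phi[, 3],
    theta_landline = theta[, 1], theta_cellonly = theta[, 2],
    theta_nophone = theta[, 3],
    pi_landline = pi_true[, 1], pi_cellonly = pi_true[, 2],
    pi_nophone = pi_true[, 3],
    pi_combined = pi_combined,
    stringsAsFactors = FALSE
  )
  class(out) <- c("county_truth", "data.frame")
  attr(out, "config") <- config
  out
}

# Additive-logistic-normal composition.  Log-ratios (cellonly/landline,
# nophone/landline) are N(center - total_var/2 + loading %*% x, resid^2);
# the -total_var/2 correction keeps the across-county mean composition at
# the national center despite the lognormal mean shift.
draw_phi <- function(m, X, config) {
  ctr <- log(config$phi_center[2:3] / config$phi_center[1])
  loading <- config$phi_cov_loading
  total_var <- rowSums(loading^2) + config$phi_resid_sd^2
  xs <- X[, -1L, drop = FALSE]
  eta <- matrix(rep(ctr - total_var / 2, each = m), nrow = m) +
    xs %*% t(loading) +
    cbind(stats::rnorm(m, 0, config$phi_resid_sd[1]),
          stats::rnorm(m, 0, config$phi_resid_sd[2]))
  e <- exp(eta)
  denom <- 1 + rowSums(e)
  cbind(landline = 1 / denom, cellonly = e[, 1] / denom,
        nophone = e[, 2] / denom)
}

# mean-1 lognormal weights with a given coefficient of variation
draw_weights <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# expand per-county stratum counts into respondent rows
build_rows <- function(survey_name, county_id, counts, pi_mat, cv,
                       psu_size = 4L) {
  n_by_county <- colSums(counts)
  keep <- n_by_county > 0
  counts <- counts[, keep, drop = FALSE]
  county_id <- county_id[keep]
  pi_mat <- pi_mat[keep, , drop = FALSE]
  n_by_county <- n_by_county[keep]
  k <- length(county_id)
  if (k == 0L) stop("no respondents generated", call. = FALSE)

  cnt_vec <- as.vector(counts)                       # stratum fastest
  stratum <- rep(rep(PHONE_STRATA, k), cnt_vec)
  county <- rep(county_id, n_by_county)
  p_succ <- rep(as.vector(t(pi_mat)), cnt_vec)
  n_tot <- sum(cnt_vec)

  within <- sequence(n_by_county)
  rows <- data.frame(
    survey = survey_name,
    county_id = county,
    stratum = stratum,
    outcome = stats::rbinom(n_tot, 1L, p_succ),
    weight = draw_weights(n_tot, cv),
    design_stratum = county,
    psu = paste0(county, "_p", ceiling(within / psu_size)),
    age = sample(18:84, n_tot, replace = TRUE),
    sex = sample(c("male", "female"), n_tot, replace = TRUE),
    stringsAsFactors = FALSE
  )
  class(rows) <- c("survey_microdata", "data.frame")
  attr(rows, "survey_name") <- survey_name
  rows
}

#' Sample the in-person (NHIS-like) survey
#'
#' A seeded uniform subset of `round(m * nhis_county_fraction)` counties is
#' sampled.  Within a sampled county the respondent count is Poisson with
#' mean proportional to county population (at least 1), respondents are
#' allocated to phone strata in proportion to the county composition, the
#' outcome is Bernoulli with the stratum's true prevalence `sin(theta)^2`,
#' weights are mean-1 lognormal with the configured coefficient of
#' variation, and PSU labels group respondents in clusters of 4.
#'
#' @param counties Output of [generate_counties()].
#' @param config The [generator_config()] used to generate `counties`.
#' @param seed Seed for the sampling stage (default derived from the
#'   config seed so the two surveys use distinct substreams).
#' @return A `survey_microdata` data frame with columns `survey`,
#'   `county_id`, `stratum`, `outcome`, `weight`, `design_stratum`, `psu`,
#'   `age`, `sex`.
#' @export
sample_nhis <- function(counties, config, seed = config$seed + 1L) {
  stopifnot(inherits(counties, "county_truth"))
  set.seed(seed)
  m <- nrow(counties)
  k <- round(m * config$nhis_county_fraction)
  if (k < 1) {
    stop("nhis_county_fraction * m_counties < 1: no county can be sampled",
         call. = FALSE)
  }
  idx <- sort(sample.int(m, k))
  # sampled counties get similar workloads (area-probability designs assign
  # roughly equal interviewer effort per sampled PSU), so no population
  # scaling here -- unlike the telephone survey
  n_i <- pmax(1L, stats::rpois(k, config$nhis_mean_n))

  phi <- as.matrix(counties[idx, paste0("phi_", PHONE_STRATA)])
  counts <- vapply(seq_len(k),
                   function(j) stats::rmultinom(1, n_i[j], phi[j, ])[, 1],
                   integer(3))
  pi_mat <- as.matrix(counties[idx, paste0("pi_", PHONE_STRATA)])
  build_rows("NHIS", counties$county_id[idx], counts, pi_mat,
             config$weight_cv)
}

#' Sample the telephone (BRFSS-like) survey
#'
#' Samples the landline stratum only, in every county.  Respondent counts
#' are Poisson with mean proportional to county population (truncated at 2).
#' The success probability is `sin(lambda_true * theta_landline)^2`, so the
#' county mean on the transformed scale is `lambda_true * theta_landline` —
#' the survey's frame-noncoverage/nonresponse bias acts multiplicatively on
#' the transformed scale.
#'
#' @inheritParams sample_nhis
#' @return A `survey_microdata` data frame (all rows `stratum == "landline"`).
#' @export
sample_brfss <- function(counties, config, seed = config$seed + 2L) {
  stopifnot(inherits(counties, "county_truth"))
  set.seed(seed)
  m <- nrow(counties)
  theta_b <- config$lambda_true * counties$theta_landline
  if (any(theta_b >= pi / 2)) {
    stop("lambda_true * theta_landline >= pi/2 for some county: ",
         "biased prevalence undefined", call. = FALSE)
  }
  pop <- counties$population
  n_i <- pmax(2L, stats::rpois(m, config$brfss_mean_n * pop / mean(pop)))
  counts <- rbind(n_i, 0L, 0L)
  pi_mat <- cbind(sin(theta_b)^2, 0, 0)
  build_rows("BRFSS", counties$county_id, counts, pi_mat, config$weight_cv)
}

#' Generate truth and both pseudo-surveys in one call
#'
#' @param config A [generator_config()].
#' @return A list with elements `counties`, `nhis`, `brfss`.
#' @export
simulate_surveys <- function(config) {
  counties <- generate_counties(config)
  list(
    counties = counties,
    nhis = sample_nhis(counties, config),
    brfss = sample_brfss(counties, config)
  )
}

#' County-by-stratum respondent counts
#'
#' Tabulates microdata respondent counts per county and phone stratum, e.g.
#' as input to [smooth_phone_composition()].
#'
#' @param microdata A `survey_microdata` data frame.
#' @param county_id Counties to tabulate (rows of the result); defaults to
#'   the counties present in the microdata.
#' @return Integer matrix with one row per county (rownames `county_id`) and
#'   columns `landline`, `cellonly`, `nophone`.
#' @export
phone_counts <- function(microdata, county_id = NULL) {
  if (is.null(county_id)) county_id <- sort(unique(microdata$county_id))
  tab <- table(factor(microdata$county_id, levels = county_id),
               factor(microdata$stratum, levels = PHONE_STRATA))
  out <- matrix(as.integer(tab), nrow = length(county_id),
                dimnames = list(county_id, PHONE_STRATA))
  out
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Two-survey synthetic data configuration\n")
  cat(sprintf("  counties: %d  covariates: %d  seed: %d\n",
              x$m_counties, x$p_covariates, x$seed))
  cat(sprintf("  lambda_true: %.3f  NHIS county coverage: %.0f%%\n",
              x$lambda_true, 100 * x$nhis_county_fraction))
  cat(sprintf("  mean county n: NHIS %d, BRFSS %d  weight CV: %.2f\n",
              x$nhis_mean_n, x$brfss_mean_n, x$weight_cv))
  invisible(x)
}
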