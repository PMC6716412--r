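# Internal and external validation battery: funnel ratios of bias-adjusted
# telephone-survey direct estimates to modeled landline estimates, national
# benchmarking of aggregated SAEs, county summary statistics, and weighted
# correlation against external registry rates.

#' Funnel ratios of adjusted direct to modeled landline estimates
#'
#' For each county with a telephone-survey direct estimate, the direct
#' estimate is moved to the transformed scale, divided by the estimated
#' bias factor, back-transformed, and divided by the modeled landline
#' prevalence: `ratio = sin(z / lambda_hat)^2 / modeled`.  If the model
#' holds, ratios converge to 1 as the telephone survey's effective county
#' sample size grows (the funnel shape).
#'
#' @param brfss_direct County-level landline [direct_estimates()] from the
#'   telephone survey (national records ignored).
#' @param lambda_hat Estimated bias factor (> 0), e.g. [lambda_hat()].
#' @param modeled_landline Data frame with `county_id` and `modeled`
#'   (posterior mean landline prevalence).
#' @return Data frame of funnel points: `county_id`, `ratio`,
#'   `brfss_n_eff`.  Counties with a zero modeled estimate are skipped with
#'   a message.
#' @export
funnel_ratios <- function(brfss_direct, lambda_hat, modeled_landline) {
  stopifnot(lambda_hat > 0)
  d <- brfss_direct[brfss_direct$county_id != "NATIONAL", , drop = FALSE]
  idx <- match(d$county_id, modeled_landline$county_id)
  d <- d[!is.na(idx), , drop = FALSE]
  modeled <- modeled_landline$modeled[idx[!is.na(idx)]]

  skip <- modeled <= 0
  if (any(skip)) {
    message(sum(skip), " county(ies) skipped: modeled landline estimate 0")
    d <- d[!skip, , drop = FALSE]
    modeled <- modeled[!skip]
  }
  z <- asin(sqrt(guard_p(d$p_hat, d$n)))
  adjusted <- sin(pmin(z / lambda_hat, pi / 2))^2
  data.frame(
    county_id = d$county_id,
    ratio = adjusted / modeled,
    brfss_n_eff = d$n_eff,
    stringsAsFactors = FALSE
  )
}

#' Binned funnel summary
#'
#' Mean absolute log ratio per effective-sample-size bin; under a
#' well-fitting model this decreases as the bins grow.
#'
#' @param points Funnel points from [funnel_ratios()].
#' @param breaks Bin edges for `brfss_n_eff` (default bins: up to 25,
#'   25-100, above 100).
#' @return Data frame with `bin`, `n_counties`, `mean_abs_log_ratio`.
#' @export
funnel_summary <- function(points, breaks = c(0, 25, 100, Inf)) {
  bin <- cut(points$brfss_n_eff, breaks = breaks, include.lowest = TRUE)
  agg <- tapply(abs(log(points$ratio)), bin, mean)
  data.frame(
    bin = names(agg),
    n_counties = as.integer(table(bin)),
    mean_abs_log_ratio = as.numeric(agg),
    stringsAsFactors = FALSE
  )
}

#' Aggregate county estimates to the national level
#'
#' Population-weighted mean of county estimates, for benchmarking against
#' national direct estimates.
#'
#' @param county_saes A `county_sae` data frame (or anything with
#'   `county_id` and `estimate`).
#' @param populations Data frame with `county_id` and `population`, or a
#'   named numeric vector.
#' @return The population-weighted national estimate.
#' @export
aggregate_national <- function(county_saes, populations) {
  if (is.data.frame(populations)) {
    pop <- stats::setNames(populations$population, populations$county_id)
  } else {
    pop <- populations
  }
  w <- pop[county_saes$county_id]
  if (anyNA(w)) {
    stop("population missing for county(ies): ",
         paste(county_saes$county_id[is.na(w)], collapse = ", "),
         call. = FALSE)
  }
  sum(w * county_saes$estimate) / sum(w)
}

#' Weighted Pearson correlation
#'
#' Pearson correlation with weighted means, variances and covariance; used
#' to relate modeled county prevalences to external county registry rates
#' with inverse-variance weights.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param w Positive weights (default equal, giving the ordinary Pearson
#'   correlation).
#' @return Correlation in `[-1, 1]`.
#' @export
weighted_correlation <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(x) == length(w),
            length(x) >= 3L, all(w > 0))
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) {
    stop("zero weighted variance: correlation undefined", call. = FALSE)
  }
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Summary statistics of county estimates
#'
#' Per outcome: minimum, quartiles, median, maximum, mean and standard
#' deviation across counties.  Quantiles use linear interpolation between
#' order statistics (type 7).
#'
#' @param county_saes A `county_sae` data frame.
#' @return Data frame with one row per outcome.
#' @export
summarize_counties <- function(county_saes) {
  if (nrow(county_saes) == 0L) {
    stop("no county estimates to summarize", call. = FALSE)
  }
  out_names <- unique(county_saes$outcome)
  rows <- lapply(out_names, function(o) {
    e <- county_saes$estimate[county_saes$outcome == o]
    q <- stats::quantile(e, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                         names = FALSE)
    data.frame(outcome = o, min = q[1], q25 = q[2], median = q[3],
               q75 = q[4], max = q[5], mean = mean(e), sd = stats::sd(e),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the validation battery
#'
#' Produces the numeric validation report: funnel points and binned
#' summary, the national benchmarking check (population-weighted aggregate
#' of the SAEs against the national direct estimates from both surveys),
#' per-outcome county summaries, and — when an external county rate table
#' is supplied — the inverse-variance-weighted correlation of the SAEs
#' with the external rates.
#'
#' @param county_saes A `county_sae` data frame from [compose_counties()].
#' @param fit The `sae_fit` the estimates came from.
#' @param brfss_direct,nhis_direct County-level [direct_estimates()] tables
#'   for the telephone and in-person surveys (with national records).
#' @param populations County populations (data frame or named vector).
#' @param external Optional data frame `county_id`, `rate`, `rate_variance`
#'   of external registry rates.
#' @param funnel_breaks Effective-sample-size bin edges for the funnel.
#' @return Object of class `sae_validation`: list with `funnel`,
#'   `funnel_bins`, `national_check`, `summaries`, `external_corr`.
#' @export
validate_sae <- function(county_saes, fit, brfss_direct, nhis_direct,
                         populations, external = NULL,
                         funnel_breaks = c(0, 25, 100, Inf)) {
  modeled <- data.frame(
    county_id = fit$county_id,
    modeled = modeled_stratum_prevalence(fit)[, "landline"],
    stringsAsFactors = FALSE
  )
  funnel <- funnel_ratios(brfss_direct, lambda_hat(fit), modeled)
  bins <- funnel_summary(funnel, breaks = funnel_breaks)

  nat <- function(direct) {
    r <- direct[direct$county_id == "NATIONAL" & direct$stratum == "all", ]
    if (nrow(r) == 0L) return(c(estimate = NA_real_, se = NA_real_))
    c(estimate = r$p_hat[1], se = sqrt(r$var_hat[1]))
  }
  nat_nhis <- nat(nhis_direct)
  nat_brfss <- nat(brfss_direct)
  agg <- aggregate_national(county_saes, populations)
  national_check <- data.frame(
    outcome = county_saes$outcome[1],
    aggregated_sae = agg,
    nhis_direct = nat_nhis["estimate"], nhis_se = nat_nhis["se"],
    brfss_direct = nat_brfss["estimate"], brfss_se = nat_brfss["se"],
    row.names = NULL, stringsAsFactors = FALSE
  )

  external_corr <- NULL
  if (!is.null(external)) {
    merged <- merge(county_saes[, c("county_id", "estimate")], external,
                    by = "county_id")
    external_corr <- data.frame(
      correlation = weighted_correlation(merged$estimate, merged$rate,
                                         1 / merged$rate_variance),
      n_counties = nrow(merged)
    )
  }

  structure(
    list(funnel = funnel, funnel_bins = bins,
         national_check = national_check,
         summaries = summarize_counties(county_saes),
         external_corr = external_corr),
    class = "sae_validation"
  )
}

#' @export
print.sae_validation <- function(x, ...) {
  cat("SAE validation report\n")
  cat("  Funnel (mean |log ratio| by effective-n bin):\n")
  for (i in seq_len(nrow(x$funnel_bins))) {
    cat(sprintf("    %-12s n=%4d  %.4f\n", x$funnel_bins$bin[i],
                x$funnel_bins$n_counties[i],
                x$funnel_bins$mean_abs_log_ratio[i]))
  }
  nc <- x$national_check
  cat(sprintf("  National: aggregated SAE %.1f%% | NHIS-like direct %.1f%% (SE %.2f) | BRFSS-like direct %.1f%% (SE %.2f)\n",
              100 * nc$aggregated_sae, 100 * nc$nhis_direct,
              100 * nc$nhis_se, 100 * nc$brfss_direct, 100 * nc$brfss_se))
  if (!is.null(x$external_corr)) {
    cat(sprintf("  External weighted correlation: %.3f (n = %d counties)\n",
                x$external_corr$correlation, x$external_corr$n_counties))
  }
  invisible(x)
}
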