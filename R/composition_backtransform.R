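# Combine stratum-level posterior draws with county phone-status
# composition weights and back-transform to county prevalence estimates.
# Composition is applied per posterior draw, not to posterior means, so the
# sin^2 nonlinearity is handled inside the posterior.

#' Smooth county phone-status compositions
#'
#' Empirical-Bayes multinomial smoothing of observed county-by-stratum
#' household counts toward a multinomial-logit regression on county
#' covariates.  The regression is fitted to the observed counts; a single
#' Dirichlet concentration `k` is then estimated by maximizing the
#' Dirichlet-multinomial marginal likelihood, and each county's composition
#' is the posterior mean `(counts + k * predicted) / (n + k)`.  Counties
#' with no observed households (most counties, since the in-person survey
#' samples only a quarter of them) receive the regression prediction.
#'
#' @param counts m x 3 matrix of household counts by phone stratum (rows =
#'   counties, e.g. from [phone_counts()]); zero rows allowed.
#' @param covariates m x q covariate matrix aligned to the rows of `counts`
#'   (an intercept column is tolerated and dropped for the regression).
#' @param county_id County identifiers; defaults to `rownames(counts)`.
#' @return Data frame of class `phone_composition`: `county_id`,
#'   `phi_landline`, `phi_cellonly`, `phi_nophone` (simplex rows), `n`
#'   (observed households) and `source` (`"smoothed"`).  The estimated
#'   concentration is attached as attribute `concentration`.
#' @export
smooth_phone_composition <- function(counts, covariates,
                                     county_id = rownames(counts)) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 3L, all(counts >= 0))
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == nrow(counts))
  if (is.null(county_id)) county_id <- as.character(seq_len(nrow(counts)))
  n_i <- rowSums(counts)
  if (sum(n_i) == 0) {
    stop("all county counts are zero: nothing to smooth", call. = FALSE)
  }

  # drop constant columns (intercept); multinom adds its own
  keep <- apply(covariates, 2, function(x) stats::sd(x) > 0)
  Xr <- covariates[, keep, drop = FALSE]
  df <- as.data.frame(Xr)
  if (ncol(df) == 0L) df <- data.frame(.const = rep(1, nrow(counts)))
  # fit the regression on counties with observed households only (zero
  # rows break the multinomial fit); a stratum unseen overall gets a tiny
  # flat pseudo-count so its coefficients stay finite
  obs_rows <- n_i > 0
  counts_fit <- counts[obs_rows, , drop = FALSE]
  if (any(colSums(counts_fit) == 0)) {
    counts_fit <- counts_fit + 0.5 / sum(obs_rows)
  }
  fit <- nnet::multinom(counts_fit ~ ., data = df[obs_rows, , drop = FALSE],
                        trace = FALSE, maxit = 500)
  pred <- stats::predict(fit, newdata = df, type = "probs")
  pred <- matrix(pred, nrow = nrow(counts), ncol = 3L)

  obs <- which(n_i > 0)
  dm_negll <- function(log_k) {
    k <- exp(log_k)
    a <- k * pred[obs, , drop = FALSE]
    -sum(lgamma(k) - lgamma(n_i[obs] + k) +
           rowSums(lgamma(counts[obs, , drop = FALSE] + a) - lgamma(a)))
  }
  opt <- stats::optimize(dm_negll, interval = c(log(0.05), log(1e7)))
  k <- exp(opt$minimum)

  phi <- (counts + k * pred) / (n_i + k)
  phi <- phi / rowSums(phi)

  out <- data.frame(
    county_id = county_id,
    phi_landline = phi[, 1], phi_cellonly = phi[, 2], phi_nophone = phi[, 3],
    n = n_i,
    source = "smoothed",
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("phone_composition", "data.frame")
  attr(out, "concentration") <- k
  out
}

#' Combine one county's posterior draws with its phone composition
#'
#' Per draw, the combined prevalence is
#' `pi = sum_s phi_s * sin(theta_s)^2`; the estimate is the mean over draws
#' and the interval the equal-tailed 2.5/97.5 percentiles.  The composition
#' is treated as fixed known weights (its own uncertainty is not
#' propagated).
#'
#' @param theta_draws draws x 3 matrix of transformed-scale stratum means
#'   for one county (columns landline, cellonly, nophone).
#' @param phi Length-3 composition (nonnegative, summing to 1).
#' @return One-row data frame: `estimate`, `ci_lower`, `ci_upper`,
#'   `posterior_sd`.
#' @examples
#' compose_county(cbind(c(0.4, 0.6), 0, 0), phi = c(1, 0, 0))
#' @export
compose_county <- function(theta_draws, phi) {
  theta_draws <- as.matrix(theta_draws)
  stopifnot(ncol(theta_draws) == 3L, length(phi) == 3L, all(phi >= -1e-12))
  if (abs(sum(phi) - 1) > 1e-9) {
    stop("phi must sum to 1", call. = FALSE)
  }
  if (nrow(theta_draws) < 400L) {
    warning("fewer than 400 posterior draws; interval endpoints unstable",
            call. = FALSE)
  }
  pi_draws <- as.vector(sin(theta_draws)^2 %*% phi)
  ci <- unname(stats::quantile(pi_draws, c(0.025, 0.975), type = 7))
  if (ci[2] - ci[1] <= 0 && length(pi_draws) > 1L) {
    warning("degenerate draws: zero-width credible interval", call. = FALSE)
  }
  data.frame(estimate = mean(pi_draws), ci_lower = ci[1], ci_upper = ci[2],
             posterior_sd = stats::sd(pi_draws))
}

#' County small-area estimates from a fitted model
#'
#' Applies [compose_county()] to every county in the fit, matching each
#' county's phone composition by id.
#'
#' @param fit An `sae_fit` from [fit_sae()].
#' @param phi A `phone_composition` data frame (or any data frame with
#'   `county_id` and `phi_*` columns) covering all counties in the fit.
#' @param outcome Outcome name recorded in the output.
#' @return Data frame of class `county_sae`: `county_id`, `outcome`,
#'   `estimate`, `ci_lower`, `ci_upper`, `posterior_sd` (all prevalence
#'   scale, in `[0, 1]`).
#' @export
compose_counties <- function(fit, phi, outcome = "outcome") {
  stopifnot(inherits(fit, "sae_fit"))
  idx <- match(fit$county_id, phi$county_id)
  if (anyNA(idx)) {
    stop("phone composition missing for county(ies): ",
         paste(fit$county_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  phi_mat <- as.matrix(phi[idx, paste0("phi_", PHONE_STRATA)])
  th <- fit$draws$theta                      # draws x m x 3
  n_draws <- dim(th)[1]
  m <- dim(th)[2]
  # draws x m combined prevalence, composition applied per draw
  P <- sin(th)^2
  pi_draws <- P[, , 1] * rep(phi_mat[, 1], each = n_draws) +
    P[, , 2] * rep(phi_mat[, 2], each = n_draws) +
    P[, , 3] * rep(phi_mat[, 3], each = n_draws)
  if (m == 1L) pi_draws <- matrix(pi_draws, ncol = 1L)

  est <- colMeans(pi_draws)
  ci <- apply(pi_draws, 2, stats::quantile, probs = c(0.025, 0.975),
              type = 7)
  out <- data.frame(
    county_id = fit$county_id,
    outcome = outcome,
    estimate = est,
    ci_lower = ci[1, ],
    ci_upper = ci[2, ],
    posterior_sd = apply(pi_draws, 2, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("county_sae", "data.frame")
  out
}
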