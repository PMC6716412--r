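# Survey-weighted direct estimation with Kish design effects.  The model
# downstream consumes only (p_hat, var_hat, n_eff); variances use the
# Kish-adjusted binomial approximation rather than full Taylor-linearized
# stratified-PSU estimation, and PSU/design-stratum labels are carried in
# the microdata so a linearized estimator could be added without a format
# change.

#' Survey-weighted prevalence
#'
#' Hajek ratio estimator `sum(w * y) / sum(w)`.
#'
#' @param y 0/1 outcome vector.
#' @param w Positive survey weights (default: equal weights).
#' @return The weighted proportion.
#' @examples
#' weighted_prevalence(c(1, 0), w = c(3, 1))  # 0.75
#' @export
weighted_prevalence <- function(y, w = rep(1, length(y))) {
  if (length(y) == 0L) {
    stop("cannot estimate prevalence from an empty sample", call. = FALSE)
  }
  stopifnot(length(w) == length(y), all(w > 0), all(y %in% c(0, 1)))
  sum(w * y) / sum(w)
}

#' Kish design effect of a set of weights
#'
#' `deff = n * sum(w^2) / sum(w)^2`; equals 1 for equal weights and exceeds
#' 1 otherwise (Cauchy-Schwarz).  The effective sample size is `n / deff`.
#'
#' @param w Positive weights.
#' @return The design effect (>= 1).
#' @examples
#' kish_deff(c(1, 3))  # 1.25
#' @export
kish_deff <- function(w) {
  n <- length(w)
  stopifnot(n >= 1L, all(w > 0))
  n * sum(w^2) / sum(w)^2
}

# one estimate record from a set of respondent rows
direct_record <- function(y, w) {
  n <- length(y)
  p_hat <- weighted_prevalence(y, w)
  deff <- kish_deff(w)
  n_eff <- n / deff
  var_hat <- deff * p_hat * (1 - p_hat) / n
  if (p_hat %in% c(0, 1)) {
    # avoid a zero level-1 variance at degenerate sample proportions
    var_hat <- (1 / (4 * n_eff)) * (1 / n)
  }
  c(p_hat = p_hat, var_hat = var_hat, n = n, deff = deff, n_eff = n_eff)
}

#' County and national direct estimates
#'
#' Computes survey-weighted prevalence estimates with variances, Kish design
#' effects and effective sample sizes per county (and phone stratum), plus
#' national records pooling all counties with full weights.  Counties (or
#' county-stratum cells) with no respondents in the outcome denominator
#' yield no record — absence, not zero.
#'
#' @param microdata A `survey_microdata` data frame.
#' @param outcome Optional outcome name or definition row; applies the
#'   outcome's sex/age denominator filter when the microdata carry `age` and
#'   `sex` columns.
#' @param by_stratum If `TRUE` (default), estimates are per county x phone
#'   stratum; otherwise per county pooled across strata (`stratum = "all"`).
#' @param include_national Add pooled national records (per stratum and
#'   overall), flagged by `county_id == "NATIONAL"`.
#' @return Data frame with columns `county_id`, `stratum`, `outcome`,
#'   `p_hat`, `var_hat`, `n`, `deff`, `n_eff`.  `var_hat` is the Kish
#'   approximation `deff * p_hat * (1 - p_hat) / n`; for degenerate
#'   `p_hat` of 0 or 1 it is floored at `1 / (4 * n_eff * n)`.
#' @export
direct_estimates <- function(microdata, outcome = NULL, by_stratum = TRUE,
                             include_national = TRUE) {
  stopifnot(is.data.frame(microdata))
  if (!all(microdata$stratum %in% PHONE_STRATA)) {
    bad <- setdiff(unique(microdata$stratum), PHONE_STRATA)
    stop("unknown phone stratum label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rows <- filter_denominator(microdata, outcome)
  outcome_name <- if (is.null(outcome)) {
    "outcome"
  } else if (is.character(outcome)) outcome else outcome$name
  if (nrow(rows) == 0L) {
    stop("no respondents in the outcome denominator", call. = FALSE)
  }

  key <- if (by_stratum) {
    paste(rows$county_id, rows$stratum, sep = "\r")
  } else {
    paste(rows$county_id, "all", sep = "\r")
  }
  groups <- split(seq_len(nrow(rows)), key)
  est <- t(vapply(groups, function(ii) {
    direct_record(rows$outcome[ii], rows$weight[ii])
  }, numeric(5)))
  parts <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  out <- data.frame(
    county_id = parts[, 1], stratum = parts[, 2], outcome = outcome_name,
    est, row.names = NULL, stringsAsFactors = FALSE
  )

  if (include_national) {
    nat_keys <- if (by_stratum) {
      c(as.list(intersect(PHONE_STRATA, unique(rows$stratum))), list("all"))
    } else {
      list("all")
    }
    nat <- lapply(nat_keys, function(s) {
      ii <- if (identical(s, "all")) seq_len(nrow(rows)) else
        which(rows$stratum == s)
      if (length(ii) == 0L) return(NULL)
      data.frame(county_id = "NATIONAL", stratum = s,
                 outcome = outcome_name,
                 t(direct_record(rows$outcome[ii], rows$weight[ii])),
                 stringsAsFactors = FALSE)
    })
    out <- rbind(out, do.call(rbind, nat))
  }
  out <- out[order(out$county_id, out$stratum), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("direct_estimates", "data.frame")
  out
}
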