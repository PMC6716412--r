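# Arcsine-square-root scale: y = asin(sqrt(p)) stabilizes the sampling
# variance of a proportion to approximately 1/(4 * n_eff), independent of p.

#' Arcsine-square-root transform of a prevalence estimate
#'
#' @param p_hat Prevalence estimate(s) in `[0, 1]`.
#' @param n_eff Effective sample size(s) (> 0), `n / deff`.
#' @return List with `y = asin(sqrt(p_hat))` (radians, in `[0, pi/2]`) and
#'   stabilized sampling variance `v = 1 / (4 * n_eff)`.
#' @examples
#' to_arcsine(0.25, 100)  # y = pi/6, v = 0.0025
#' @export
to_arcsine <- function(p_hat, n_eff) {
  stopifnot(all(p_hat >= 0 & p_hat <= 1))
  if (any(n_eff <= 0)) stop("n_eff must be positive", call. = FALSE)
  list(y = asin(sqrt(p_hat)), v = 1 / (4 * n_eff))
}

#' Back-transform from the arcsine-square-root scale
#'
#' @param y Transformed value(s) in `[0, pi/2]` (radians).
#' @return Prevalence `sin(y)^2`.
#' @export
from_arcsine <- function(y) {
  if (any(y < 0 | y > pi / 2)) {
    stop("y must lie in [0, pi/2]", call. = FALSE)
  }
  sin(y)^2
}

# Anscombe-style guard: a sample proportion of exactly 0 or 1 is shrunk by
# 1/(4n) toward 0.5 before transforming, so the transformed value is finite
# strictly inside (0, pi/2).
guard_p <- function(p_hat, n) {
  adj <- 1 / (4 * n)
  ifelse(p_hat <= 0, adj, ifelse(p_hat >= 1, 1 - adj, p_hat))
}

LEVEL1_COMPONENTS <- c("nhis_landline", "nhis_cellonly", "nhis_nophone",
                       "brfss")

#' Assemble the level-1 observation vectors
#'
#' Builds, per county, the transformed-scale observation vector over the
#' four components (three in-person-survey phone strata and the telephone
#' survey) with its diagonal sampling covariance and a presence mask.
#' Counties appearing in neither survey (or only in cells below `min_n`)
#' are excluded with a logged reason; a county seen only by the telephone
#' survey — the typical case, since roughly three-quarters of counties have
#' no in-person sample — contributes the `brfss` component alone.
#'
#' @param nhis_est,brfss_est County-level [direct_estimates()] tables
#'   (national records are ignored).  `brfss_est` must contain landline
#'   estimates only.
#' @param min_n Minimum respondents per county-stratum cell; cells below it
#'   are dropped from level 1 (their variance is too unstable).
#' @return An object of class `sae_level1`: list with `county_id` and
#'   m x 4 matrices `y` (transformed estimates), `v` (sampling variances,
#'   `1/(4 n_eff)`), `mask` (component presence) and `n_eff`, plus a
#'   `dropped` data frame of excluded counties.
#' @export
assemble_level1 <- function(nhis_est = NULL, brfss_est = NULL, min_n = 2L) {
  comp_tabs <- list()
  county_rows <- function(est) est[est$county_id != "NATIONAL", , drop = FALSE]

  if (!is.null(nhis_est)) {
    ne <- county_rows(nhis_est)
    for (s in PHONE_STRATA) {
      comp_tabs[[paste0("nhis_", s)]] <- ne[ne$stratum == s, , drop = FALSE]
    }
  }
  if (!is.null(brfss_est)) {
    be <- county_rows(brfss_est)
    if (any(be$stratum != "landline")) {
      stop("brfss_est must contain landline-stratum estimates only",
           call. = FALSE)
    }
    comp_tabs[["brfss"]] <- be
  }
  if (length(comp_tabs) == 0L) {
    stop("at least one of nhis_est, brfss_est is required", call. = FALSE)
  }

  all_ids <- sort(unique(unlist(lapply(comp_tabs, `[[`, "county_id"))))
  m <- length(all_ids)
  y <- v <- n_eff <- matrix(NA_real_, m, 4,
                            dimnames = list(all_ids, LEVEL1_COMPONENTS))
  mask <- matrix(FALSE, m, 4, dimnames = list(all_ids, LEVEL1_COMPONENTS))

  for (comp in names(comp_tabs)) {
    tab <- comp_tabs[[comp]]
    tab <- tab[tab$n >= min_n, , drop = FALSE]
    if (nrow(tab) == 0L) next
    i <- match(tab$county_id, all_ids)
    tr <- to_arcsine(guard_p(tab$p_hat, tab$n), tab$n_eff)
    y[i, comp] <- tr$y
    v[i, comp] <- tr$v
    n_eff[i, comp] <- tab$n_eff
    mask[i, comp] <- TRUE
  }

  present <- rowSums(mask) > 0
  dropped <- data.frame(
    county_id = all_ids[!present],
    reason = rep("no component with n >= min_n", sum(!present)),
    stringsAsFactors = FALSE
  )
  if (nrow(dropped) > 0L) {
    message(nrow(dropped), " county(ies) excluded from level 1 ",
            "(no component with n >= ", min_n, ")")
  }

  structure(
    list(
      county_id = all_ids[present],
      y = y[present, , drop = FALSE],
      v = v[present, , drop = FALSE],
      mask = mask[present, , drop = FALSE],
      n_eff = n_eff[present, , drop = FALSE],
      components = LEVEL1_COMPONENTS,
      min_n = min_n,
      dropped = dropped
    ),
    class = "sae_level1"
  )
}

#' @export
print.sae_level1 <- function(x, ...) {
  cat(sprintf("Level-1 transformed observations: %d counties\n",
              length(x$county_id)))
  counts <- colSums(x$mask)
  cat("  components present:",
      paste(sprintf("%s=%d", names(counts), counts), collapse = "  "), "\n")
  if (nrow(x$dropped) > 0L) {
    cat(sprintf("  %d county(ies) dropped\n", nrow(x$dropped)))
  }
  invisible(x)
}
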