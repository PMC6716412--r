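# Two-level hierarchical Bayes model on the arcsine-square-root scale,
# fitted by Gibbs sampling.
#
# Level 1 (sampling model, county i, phone stratum s):
#   y_is ~ N(theta_is, v_is)          in-person survey stratum estimates
#   z_i  ~ N(lambda * theta_iL, w_i)  telephone survey (landline frame),
#                                     lambda = proportionate bias factor
# Level 2 (linking model):
#   theta_i = B x_i + u_i,  u_i ~ MVN(0, Sigma),  theta_i in [0, pi/2]^3
# Priors (diffuse but proper):
#   vec(B) ~ N(beta_mean, beta_var I);  lambda ~ N(lambda_mean, lambda_var)
#   truncated to (0, Inf);  Sigma ~ inverse-Wishart(sigma_df, sigma_scale).
#
# All full conditionals are conjugate (theta: MVN truncated to the box by
# rejection; B: MVN; lambda: truncated normal; Sigma: inverse-Wishart).
# The theta update is vectorized across counties with a closed-form 3x3
# Cholesky, so the sampler runs in plain R at useful speeds.

#' Model specification for the hierarchical SAE model
#'
#' @param covariates m x p numeric matrix of county-level covariates,
#'   including an intercept column, with rows aligned to the counties of the
#'   level-1 object passed to [fit_sae()].
#' @param beta_mean Prior mean for each regression coefficient (scalar or
#'   3 x p matrix).
#' @param beta_var Prior variance of each coefficient.  The default 4
#'   (SD 2) is diffuse on the arcsine scale — the transformed means live in
#'   `[0, pi/2]`, so coefficient magnitudes beyond about 2 are meaningless
#'   and a wider prior only slows mixing of sparsely identified rows.
#' @param lambda_mean,lambda_var Normal prior for the bias factor,
#'   truncated to positive values.  Centered at 1 by default: "no bias"
#'   is the prior default.
#' @param sigma_df,sigma_scale Inverse-Wishart prior for the 3 x 3 random
#'   effect covariance.  The default (df 5, scale 0.01 I) is diffuse but
#'   proper with prior mean 0.01 I.
#' @param sigma_diagonal If `TRUE`, restrict the random-effect covariance to
#'   a diagonal matrix (independent stratum effects); default is the full
#'   correlated covariance.
#' @param n_iter,n_burnin,n_chains,thin,seed MCMC settings.  Two or more
#'   chains are needed for potential-scale-reduction diagnostics.
#' @return Object of class `sae_model_spec`.
#' @export
sae_model_spec <- function(covariates,
                           beta_mean = 0, beta_var = 4,
                           lambda_mean = 1, lambda_var = 0.25,
                           sigma_df = 5, sigma_scale = diag(0.01, 3),
                           sigma_diagonal = FALSE,
                           n_iter = 4000L, n_burnin = 2000L,
                           n_chains = 2L, thin = 1L, seed = 1L) {
  covariates <- as.matrix(covariates)
  stopifnot(
    is.numeric(covariates), all(is.finite(covariates)),
    is.finite(beta_var), beta_var > 0,
    is.finite(lambda_var), lambda_var > 0,
    sigma_df >= 4, all(dim(sigma_scale) == c(3L, 3L)),
    n_burnin < n_iter, n_iter >= 1, thin >= 1, n_chains >= 1
  )
  check_spd(sigma_scale, "sigma_scale")
  p <- ncol(covariates)
  if (is.matrix(beta_mean)) {
    stopifnot(all(dim(beta_mean) == c(3L, p)))
  } else {
    beta_mean <- matrix(beta_mean, 3L, p)
  }
  structure(
    list(
      covariates = covariates,
      beta_mean = beta_mean, beta_var = beta_var,
      lambda_mean = lambda_mean, lambda_var = lambda_var,
      sigma_df = sigma_df, sigma_scale = as.matrix(sigma_scale),
      sigma_diagonal = isTRUE(sigma_diagonal),
      n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
      n_chains = as.integer(n_chains), thin = as.integer(thin),
      seed = as.integer(seed)
    ),
    class = "sae_model_spec"
  )
}

# level-1 data unpacked for the update kernels
level1_data <- function(level1, prior_only = FALSE) {
  y_n <- level1$y[, 1:3, drop = FALSE]
  v_n <- level1$v[, 1:3, drop = FALSE]
  mask_n <- level1$mask[, 1:3, drop = FALSE]
  z <- level1$y[, 4]
  w <- level1$v[, 4]
  has_b <- level1$mask[, 4]
  if (prior_only) {
    mask_n[] <- FALSE
    has_b[] <- FALSE
  }
  list(
    m = length(level1$county_id),
    y_n = ifelse(mask_n, y_n, 0), v_n = ifelse(mask_n, v_n, 1),
    mask_n = mask_n,
    z = ifelse(has_b, z, 0), w = ifelse(has_b, w, 1), has_b = has_b
  )
}

#' Gibbs update of the county mean vectors theta
#'
#' Draws each county's 3-vector of transformed stratum means from its full
#' conditional — a multivariate normal combining the level-2 prior
#' `MVN(B x_i, Sigma)` with the county's unmasked level-1 observations —
#' truncated to `[0, pi/2]^3` by rejection.  Vectorized across counties via
#' a closed-form 3x3 Cholesky.
#'
#' @param data Internal level-1 data list (see [fit_sae()]); exposed so the
#'   kernel can be unit-tested against conjugate closed forms.
#' @param B 3 x p coefficient matrix.
#' @param lambda Bias factor (scalar > 0).
#' @param Sigma 3 x 3 random-effect covariance.
#' @param X m x p covariate matrix.
#' @param noise Optional m x 3 standard-normal matrix consumed for the first
#'   proposal (used to test permutation equivariance); rejection resampling
#'   draws fresh noise.
#' @param max_tries Rejection attempts before clamping to the box.
#' @return m x 3 matrix of sampled theta values inside `[0, pi/2]`.
#' @keywords internal
#' @export
update_theta <- function(data, B, lambda, Sigma, X, noise = NULL,
                         max_tries = 200L) {
  m <- data$m
  Sinv <- chol2inv(chol(Sigma))
  M <- X %*% t(B)

  d <- ifelse(data$mask_n, 1 / data$v_n, 0)
  b <- ifelse(data$mask_n, data$y_n / data$v_n, 0)
  d[, 1] <- d[, 1] + ifelse(data$has_b, lambda^2 / data$w, 0)
  b[, 1] <- b[, 1] + ifelse(data$has_b, lambda * data$z / data$w, 0)

  rhs <- M %*% Sinv + b

  # per-county posterior precision P_i = Sinv + diag(d_i); closed-form
  # lower Cholesky L with vector diagonal terms and scalar off-diagonals
  p11 <- Sinv[1, 1] + d[, 1]; p22 <- Sinv[2, 2] + d[, 2]
  p33 <- Sinv[3, 3] + d[, 3]
  p12 <- Sinv[1, 2]; p13 <- Sinv[1, 3]; p23 <- Sinv[2, 3]
  L11 <- sqrt(p11)
  L21 <- p12 / L11
  L31 <- p13 / L11
  L22 <- sqrt(p22 - L21^2)
  L32 <- (p23 - L31 * L21) / L22
  L33 <- sqrt(p33 - L31^2 - L32^2)
  if (any(!is.finite(L33))) {
    stop("singular precision matrix in theta update (county ",
         paste(which(!is.finite(L33)), collapse = ", "), ")", call. = FALSE)
  }

  # mean: solve L a = rhs, then L' mu = a
  a1 <- rhs[, 1] / L11
  a2 <- (rhs[, 2] - L21 * a1) / L22
  a3 <- (rhs[, 3] - L31 * a1 - L32 * a2) / L33
  mu3 <- a3 / L33
  mu2 <- (a2 - L32 * mu3) / L22
  mu1 <- (a1 - L21 * mu2 - L31 * mu3) / L11

  sample_rows <- function(idx, Z) {
    w3 <- Z[, 3] / L33[idx]
    w2 <- (Z[, 2] - L32[idx] * w3) / L22[idx]
    w1 <- (Z[, 1] - L21[idx] * w2 - L31[idx] * w3) / L11[idx]
    cbind(mu1[idx] + w1, mu2[idx] + w2, mu3[idx] + w3)
  }

  if (is.null(noise)) noise <- matrix(stats::rnorm(m * 3), m, 3)
  theta <- sample_rows(seq_len(m), noise)
  bad <- which(rowSums(theta < 0 | theta > pi / 2) > 0)
  tries <- 0L
  while (length(bad) > 0L && tries < max_tries) {
    theta[bad, ] <- sample_rows(bad,
                                matrix(stats::rnorm(length(bad) * 3),
                                       ncol = 3))
    bad <- bad[rowSums(theta[bad, , drop = FALSE] < 0 |
                         theta[bad, , drop = FALSE] > pi / 2) > 0]
    tries <- tries + 1L
  }
  if (length(bad) > 0L) theta[bad, ] <- pmin(pmax(theta[bad, ], 0), pi / 2)
  theta
}

#' Gibbs update of the regression coefficients B
#'
#' Conjugate multivariate-normal draw of all 3p coefficients jointly, from
#' the multivariate regression of theta on the covariates given Sigma, with
#' independent `N(beta_mean, beta_var)` priors per coefficient.
#'
#' @param theta m x 3 current county means.
#' @param X m x p covariates.
#' @param Sigma 3 x 3 current random-effect covariance.
#' @param prior_mean 3 x p matrix of prior means.
#' @param prior_var Scalar prior variance.
#' @return 3 x p sampled coefficient matrix.
#' @keywords internal
#' @export
update_beta <- function(theta, X, Sigma, prior_mean, prior_var) {
  p <- ncol(X)
  Sinv <- chol2inv(chol(Sigma))
  XtX <- crossprod(X)
  A <- kronecker(Sinv, XtX) + diag(1 / prior_var, 3L * p)
  rhs <- as.vector(crossprod(X, theta %*% Sinv)) +
    as.vector(t(prior_mean)) / prior_var
  U <- chol(A)
  mu <- backsolve(U, forwardsolve(t(U), rhs))
  draw <- mu + backsolve(U, stats::rnorm(3L * p))
  t(matrix(draw, nrow = p, ncol = 3L))
}

#' Gibbs update of the telephone-survey bias factor lambda
#'
#' Conjugate normal draw from the regression of the telephone-survey
#' observations `z_i` on the landline means `theta_iL` with known variances
#' `w_i`, combined with the `N(lambda_mean, lambda_var)` prior and truncated
#' to positive values (inverse-CDF sampling).
#'
#' @param theta m x 3 current county means.
#' @param data Internal level-1 data list.
#' @param prior_mean,prior_var Normal prior parameters.
#' @return Sampled positive scalar.
#' @keywords internal
#' @export
update_lambda <- function(theta, data, prior_mean, prior_var) {
  tl <- theta[, 1]
  hb <- data$has_b
  prec <- sum(ifelse(hb, tl^2 / data$w, 0)) + 1 / prior_var
  mean_post <- (sum(ifelse(hb, tl * data$z / data$w, 0)) +
                  prior_mean / prior_var) / prec
  sd_post <- 1 / sqrt(prec)
  p0 <- stats::pnorm(0, mean_post, sd_post)
  u <- stats::runif(1, p0, 1)
  stats::qnorm(min(u, 1 - 1e-15), mean_post, sd_post)
}

#' Gibbs update of the random-effect covariance Sigma
#'
#' Conjugate inverse-Wishart draw given the level-2 residuals
#' `u_i = theta_i - B x_i`.  With `sigma_diagonal = TRUE` each diagonal
#' entry is drawn from its inverse-gamma full conditional instead.
#'
#' @param resid m x 3 matrix of level-2 residuals.
#' @param prior_df,prior_scale Inverse-Wishart prior parameters.
#' @param diagonal Restrict to a diagonal covariance.
#' @return 3 x 3 sampled covariance matrix.
#' @keywords internal
#' @export
update_sigma <- function(resid, prior_df, prior_scale, diagonal = FALSE) {
  m <- nrow(resid)
  S <- crossprod(resid)
  if (diagonal) {
    shape <- (prior_df + m) / 2
    rate <- (diag(prior_scale) + diag(S)) / 2
    return(diag(rate / stats::rgamma(3L, shape = shape), 3L))
  }
  post_scale <- prior_scale + S
  W <- stats::rWishart(1, df = prior_df + m, Sigma = chol2inv(chol(post_scale)))[, , 1]
  out <- chol2inv(chol(W))
  (out + t(out)) / 2
}

# ---- Collapsed lambda update ---------------------------------------------
# The plain lambda <-> theta alternation mixes very slowly: the telephone
# survey pins the product lambda * theta_landline tightly, so conditioning
# each on the other produces a random walk along the near-confounded ridge.
# fit_sae therefore draws lambda from its full conditional *with theta
# integrated out* and refreshes theta immediately afterwards — a valid
# joint (lambda, theta) block.  The integration treats the level-2 normal
# as untruncated, exact whenever the [0, pi/2] box carries essentially all
# posterior mass, which holds away from degenerate prevalences.

# conditional distribution of theta_landline given B, Sigma and the NHIS
# components only (BRFSS excluded): normal with mean mcond, variance scond2;
# vectorized across counties via the closed-form 3x3 Cholesky
landline_given_nhis <- function(data, B, Sigma, X) {
  Sinv <- chol2inv(chol(Sigma))
  M <- X %*% t(B)
  d <- ifelse(data$mask_n, 1 / data$v_n, 0)
  b <- ifelse(data$mask_n, data$y_n / data$v_n, 0)
  rhs <- M %*% Sinv + b
  p11 <- Sinv[1, 1] + d[, 1]; p22 <- Sinv[2, 2] + d[, 2]
  p33 <- Sinv[3, 3] + d[, 3]
  L11 <- sqrt(p11); L21 <- Sinv[1, 2] / L11; L31 <- Sinv[1, 3] / L11
  L22 <- sqrt(p22 - L21^2); L32 <- (Sinv[2, 3] - L31 * L21) / L22
  L33 <- sqrt(p33 - L31^2 - L32^2)
  a1 <- rhs[, 1] / L11
  a2 <- (rhs[, 2] - L21 * a1) / L22
  a3 <- (rhs[, 3] - L31 * a1 - L32 * a2) / L33
  mu3 <- a3 / L33
  mu2 <- (a2 - L32 * mu3) / L22
  mu1 <- (a1 - L21 * mu2 - L31 * mu3) / L11
  # (P^{-1})_{11} = || L^{-1} e1 ||^2
  g1 <- 1 / L11
  g2 <- -L21 * g1 / L22
  g3 <- -(L31 * g1 + L32 * g2) / L33
  list(mean = mu1, var = g1^2 + g2^2 + g3^2)
}

# lambda | B, Sigma, data with theta integrated out:
#   z_i ~ N(lambda * m_i, lambda^2 * s_i^2 + w_i)
# sampled by univariate slice sampling on (0, Inf)
update_lambda_collapsed <- function(lambda, data, B, Sigma, X,
                                    prior_mean, prior_var) {
  hb <- data$has_b
  if (!any(hb)) {
    p0 <- stats::pnorm(0, prior_mean, sqrt(prior_var))
    u <- stats::runif(1, p0, 1)
    return(stats::qnorm(min(u, 1 - 1e-15), prior_mean, sqrt(prior_var)))
  }
  cond <- landline_given_nhis(data, B, Sigma, X)
  m_i <- cond$mean[hb]; s2_i <- cond$var[hb]
  z <- data$z[hb]; w <- data$w[hb]
  log_target <- function(l) {
    if (l <= 0) return(-Inf)
    tv <- l^2 * s2_i + w
    -0.5 * sum(log(tv) + (z - l * m_i)^2 / tv) -
      0.5 * (l - prior_mean)^2 / prior_var
  }
  slice_sample_1d(lambda, log_target, w0 = 0.05, lower = 0)
}

# standard stepping-out + shrinkage slice sampler (Neal 2003)
slice_sample_1d <- function(x0, log_f, w0 = 0.1, lower = -Inf,
                            upper = Inf, max_steps = 100L) {
  y <- log_f(x0) + log(stats::runif(1))
  L <- x0 - w0 * stats::runif(1)
  R <- L + w0
  j <- max_steps
  while (j > 0L && L > lower && log_f(L) > y) { L <- L - w0; j <- j - 1L }
  j <- max_steps
  while (j > 0L && R < upper && log_f(R) > y) { R <- R + w0; j <- j - 1L }
  L <- max(L, lower); R <- min(R, upper)
  repeat {
    x1 <- stats::runif(1, L, R)
    if (log_f(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

# Scaling move along the lambda ridge.  The telephone likelihood depends on
# (lambda * theta_L) only, so (lambda, theta_L, B_L, Sigma's landline
# row/column) are near-confounded and the componentwise conjugate updates
# crawl along the ridge.  This Metropolis move proposes, with log-symmetric
# c,
#     lambda -> c lambda,  theta_L -> theta_L / c,  B_L -> B_L / c,
#     Sigma  -> D Sigma D  with D = diag(1/c, 1, 1),
# which leaves both the telephone likelihood and the level-2 quadratic form
# exactly invariant; the acceptance ratio involves only the in-person
# landline likelihood, the lambda/B/Sigma priors, the level-2 and prior
# normalizing determinants, and the Jacobian c^(1 - m - p - 4).
ridge_move <- function(theta, B, lambda, Sigma, data, X, spec) {
  tau <- sample(c(0.05, 0.25), 1L)
  c_prop <- exp(stats::rnorm(1, 0, tau))
  m <- data$m
  p <- ncol(X)

  log_part <- function(th_l, b_l, lam, Sig) {
    # in-person landline likelihood
    ll <- -0.5 * sum(ifelse(data$mask_n[, 1],
                            (data$y_n[, 1] - th_l)^2 / data$v_n[, 1], 0))
    # level-2 density
    theta2 <- theta; theta2[, 1] <- th_l
    B2 <- B; B2[1, ] <- b_l
    u <- theta2 - X %*% t(B2)
    ch <- chol(Sig)
    Sinv <- chol2inv(ch)
    logdet <- 2 * sum(log(diag(ch)))
    ll <- ll - 0.5 * m * logdet - 0.5 * sum((u %*% Sinv) * u)
    # priors: B_L row, lambda, inverse-Wishart on Sigma
    ll <- ll - 0.5 * sum((b_l - spec$beta_mean[1, ])^2) / spec$beta_var
    ll <- ll - 0.5 * (lam - spec$lambda_mean)^2 / spec$lambda_var
    if (spec$sigma_diagonal) {
      # product of inverse-gamma priors on the diagonal
      ll <- ll - sum((spec$sigma_df / 2 + 1) * log(diag(Sig)) +
                       diag(spec$sigma_scale) / (2 * diag(Sig)))
    } else {
      ll <- ll - 0.5 * (spec$sigma_df + 4) * logdet -
        0.5 * sum(diag(spec$sigma_scale %*% Sinv))
    }
    ll
  }

  lam_new <- c_prop * lambda
  if (lam_new <= 0) return(list(theta = theta, B = B, lambda = lambda,
                                Sigma = Sigma))
  th_new <- theta[, 1] / c_prop
  if (any(th_new < 0 | th_new > pi / 2)) {
    return(list(theta = theta, B = B, lambda = lambda, Sigma = Sigma))
  }
  b_new <- B[1, ] / c_prop
  d <- c(1 / c_prop, 1, 1)
  Sig_new <- Sigma * tcrossprod(d)
  jac_sigma <- if (spec$sigma_diagonal) 2 else 4
  log_alpha <- log_part(th_new, b_new, lam_new, Sig_new) -
    log_part(theta[, 1], B[1, ], lambda, Sigma) +
    (1 - m - p - jac_sigma) * log(c_prop)
  if (is.finite(log_alpha) && log(stats::runif(1)) < log_alpha) {
    theta[, 1] <- th_new
    B[1, ] <- b_new
    lambda <- lam_new
    Sigma <- Sig_new
  }
  list(theta = theta, B = B, lambda = lambda, Sigma = Sigma)
}

init_chain <- function(data, spec, X) {
  m <- data$m
  p <- ncol(X)
  B <- spec$beta_mean
  for (s in 1:3) {
    obs <- if (s == 1L) data$mask_n[, 1] | data$has_b else data$mask_n[, s]
    yy <- ifelse(data$mask_n[, s], data$y_n[, s],
                 if (s == 1L) data$z else 0)
    if (sum(obs) > p) {
      fit <- stats::lm.fit(X[obs, , drop = FALSE], yy[obs])
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      B[s, ] <- cf
    }
  }
  M <- X %*% t(B)
  theta <- M
  for (s in 1:3) theta[data$mask_n[, s], s] <- data$y_n[data$mask_n[, s], s]
  theta[!data$mask_n[, 1] & data$has_b, 1] <-
    data$z[!data$mask_n[, 1] & data$has_b]
  theta <- pmin(pmax(theta, 0.01), pi / 2 - 0.01)
  Sigma0 <- if (spec$sigma_df > 4) {
    spec$sigma_scale / (spec$sigma_df - 4)
  } else {
    diag(0.01, 3)
  }
  list(B = B, theta = theta, lambda = 1, Sigma = Sigma0)
}

#' Fit the hierarchical SAE model by Gibbs sampling
#'
#' Runs independently seeded Gibbs chains over the conjugate full
#' conditionals ([update_theta()], [update_beta()], [update_lambda()],
#' [update_sigma()]), discards burn-in, thins, and computes Gelman-Rubin
#' potential scale reduction and effective draw counts for the
#' hyperparameters (all B entries, lambda, the unique Sigma entries).  A
#' scale reduction above 1.1 (or fewer than 400 effective draws) raises a
#' warning and is flagged in the returned diagnostics — never a silent
#' success.
#'
#' Counties with no in-person sample still receive proper posteriors for
#' all three strata: information flows through the covariates, the
#' cross-stratum covariance and the bias-adjusted telephone survey.
#'
#' @param level1 An `sae_level1` object from [assemble_level1()].
#' @param spec An [sae_model_spec()]; its covariate rows must align with
#'   `level1$county_id`.
#' @param prior_only If `TRUE`, all level-1 data are masked and the sampler
#'   targets the joint prior (with theta still truncated to its box) — used
#'   for prior-sampling validation.
#' @return Object of class `sae_fit` with combined posterior draws
#'   (`theta`: draws x m x 3; `beta`: draws x 3 x p; `lambda`: draws;
#'   `Sigma`: draws x 3 x 3), a `diagnostics` table, and bookkeeping.
#' @export
fit_sae <- function(level1, spec, prior_only = FALSE) {
  stopifnot(inherits(level1, "sae_level1"), inherits(spec, "sae_model_spec"))
  X <- spec$covariates
  m <- length(level1$county_id)
  if (nrow(X) != m) {
    stop("covariate rows (", nrow(X), ") must align with level-1 counties (",
         m, ")", call. = FALSE)
  }
  if (!prior_only && any(rowSums(level1$mask) == 0)) {
    stop("every retained county needs at least one unmasked component",
         call. = FALSE)
  }
  data <- level1_data(level1, prior_only = prior_only)
  p <- ncol(X)
  n_keep <- length(seq(spec$n_burnin + 1L, spec$n_iter, by = spec$thin))

  set.seed(spec$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_chains)

  hyper_names <- c(
    paste0("beta[", rep(1:3, each = p), ",", rep(1:p, 3), "]"),
    "lambda",
    paste0("Sigma[", c(1, 1, 1, 2, 2, 3), ",", c(1, 2, 3, 2, 3, 3), "]")
  )
  sig_idx <- cbind(c(1, 1, 1, 2, 2, 3), c(1, 2, 3, 2, 3, 3))

  chains <- vector("list", spec$n_chains)
  for (ch in seq_len(spec$n_chains)) {
    set.seed(chain_seeds[ch])
    st <- init_chain(data, spec, X)
    # overdisperse the starting points so scale-reduction diagnostics can
    # detect chains stuck on the lambda ridge
    st$lambda <- st$lambda * exp(stats::rnorm(1, 0, 0.2))
    st$B <- st$B + matrix(stats::rnorm(3L * p, 0, 0.05), 3L, p)
    theta_draws <- array(NA_real_, c(n_keep, m, 3))
    beta_draws <- array(NA_real_, c(n_keep, 3, p))
    Sigma_draws <- array(NA_real_, c(n_keep, 3, 3))
    lambda_draws <- numeric(n_keep)
    hyper <- matrix(NA_real_, n_keep, length(hyper_names),
                    dimnames = list(NULL, hyper_names))
    k <- 0L
    for (it in seq_len(spec$n_iter)) {
      # (lambda, theta) drawn as a joint block: lambda from its full
      # conditional with theta integrated out, then theta refreshed
      st$lambda <- update_lambda_collapsed(st$lambda, data, st$B, st$Sigma,
                                           X, spec$lambda_mean,
                                           spec$lambda_var)
      st$theta <- update_theta(data, st$B, st$lambda, st$Sigma, X)
      st$B <- update_beta(st$theta, X, st$Sigma, spec$beta_mean,
                          spec$beta_var)
      rm_out <- ridge_move(st$theta, st$B, st$lambda, st$Sigma, data, X,
                           spec)
      st$theta <- rm_out$theta
      st$B <- rm_out$B
      st$lambda <- rm_out$lambda
      st$Sigma <- rm_out$Sigma
      st$Sigma <- update_sigma(st$theta - X %*% t(st$B), spec$sigma_df,
                               spec$sigma_scale, spec$sigma_diagonal)
      if (it > spec$n_burnin && (it - spec$n_burnin - 1L) %% spec$thin == 0L) {
        k <- k + 1L
        theta_draws[k, , ] <- st$theta
        beta_draws[k, , ] <- st$B
        Sigma_draws[k, , ] <- st$Sigma
        lambda_draws[k] <- st$lambda
        hyper[k, ] <- c(as.vector(t(st$B)), st$lambda,
                        st$Sigma[sig_idx])
      }
    }
    chains[[ch]] <- list(theta = theta_draws, beta = beta_draws,
                         Sigma = Sigma_draws, lambda = lambda_draws,
                         hyper = hyper)
  }

  diagnostics <- hyper_diagnostics(chains, hyper_names)

  draws <- list(
    theta = do.call(abind1, lapply(chains, `[[`, "theta")),
    beta = do.call(abind1, lapply(chains, `[[`, "beta")),
    Sigma = do.call(abind1, lapply(chains, `[[`, "Sigma")),
    lambda = unlist(lapply(chains, `[[`, "lambda"))
  )
  dimnames(draws$theta)[[3]] <- PHONE_STRATA

  structure(
    list(
      county_id = level1$county_id,
      draws = draws,
      diagnostics = diagnostics,
      n_chains = spec$n_chains,
      n_draws = n_keep * spec$n_chains,
      spec = spec,
      prior_only = prior_only,
      level1 = level1
    ),
    class = "sae_fit"
  )
}

# bind draw arrays along the first (iteration) dimension
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1], 0)),
                           d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

hyper_diagnostics <- function(chains, hyper_names) {
  mcmc_list <- coda::mcmc.list(lapply(chains, function(ch) {
    coda::mcmc(ch$hyper)
  }))
  ess <- coda::effectiveSize(mcmc_list)
  rhat <- rep(NA_real_, length(hyper_names))
  if (length(chains) >= 2L) {
    # constant parameters make gelman.diag unstable; guard them
    sds <- apply(chains[[1]]$hyper, 2, stats::sd)
    varying <- sds > 1e-12
    if (any(varying)) {
      sub <- coda::mcmc.list(lapply(chains, function(ch) {
        coda::mcmc(ch$hyper[, varying, drop = FALSE])
      }))
      gd <- coda::gelman.diag(sub, autoburnin = FALSE, multivariate = FALSE)
      rhat[varying] <- gd$psrf[, 1]
    }
    rhat[!varying] <- 1
  }
  out <- data.frame(parameter = hyper_names, rhat = rhat,
                    ess = as.numeric(ess), stringsAsFactors = FALSE)
  converged <- TRUE
  if (length(chains) >= 2L && any(is.finite(out$rhat) & out$rhat > 1.1)) {
    converged <- FALSE
    warning("Gelman-Rubin scale reduction > 1.1 for: ",
            paste(out$parameter[is.finite(out$rhat) & out$rhat > 1.1],
                  collapse = ", "),
            call. = FALSE)
  }
  if (any(out$ess < 400)) {
    low <- out$parameter[out$ess < 400]
    warning("fewer than 400 effective draws for: ",
            paste(low, collapse = ", "), call. = FALSE)
    converged <- converged && FALSE
  }
  attr(out, "converged") <- converged
  out
}

#' Posterior mean of the bias factor
#' @param fit An `sae_fit`.
#' @return Scalar posterior mean of lambda.
#' @export
lambda_hat <- function(fit) mean(fit$draws$lambda)

#' Posterior mean stratum prevalences
#'
#' Back-transforms theta draws per draw (`sin(theta)^2`) before averaging,
#' so the nonlinearity is handled at the draw level.
#'
#' @param fit An `sae_fit`.
#' @return m x 3 matrix of posterior mean prevalences by phone stratum.
#' @export
modeled_stratum_prevalence <- function(fit) {
  th <- fit$draws$theta
  out <- apply(sin(th)^2, c(2, 3), mean)
  rownames(out) <- fit$county_id
  out
}

#' @export
print.sae_fit <- function(x, ...) {
  cat(sprintf("Hierarchical SAE fit: %d counties, %d draws (%d chain%s)\n",
              length(x$county_id), x$n_draws, x$n_chains,
              if (x$n_chains > 1) "s" else ""))
  cat(sprintf("  lambda: posterior mean %.4f (sd %.4f)\n",
              mean(x$draws$lambda), stats::sd(x$draws$lambda)))
  conv <- attr(x$diagnostics, "converged")
  rh <- x$diagnostics$rhat
  if (any(is.finite(rh))) {
    cat(sprintf("  max Rhat %.3f, min ESS %.0f — %s\n",
                max(rh, na.rm = TRUE), min(x$diagnostics$ess),
                if (isTRUE(conv)) "converged" else "CHECK CONVERGENCE"))
  }
  if (x$prior_only) cat("  (prior-only run: all data masked)\n")
  invisible(x)
}
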