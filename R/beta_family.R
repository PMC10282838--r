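#' Mean/scale parameterization of the beta distribution
#'
#' The beta distribution is parameterized by its mean `mu` in (0, 1) and a
#' scale `sigma` in (0, 1) such that `Var(X) = mu * (1 - mu) * sigma^2`.
#' The implied shape parameters are `shape1 = mu * s` and
#' `shape2 = (1 - mu) * s` with concentration `s = (1 - sigma^2) / sigma^2`,
#' the unique choice consistent with those two moments.
#'
#' @param mu,sigma Numeric vectors, both strictly inside (0, 1); recycled
#'   to a common length.
#' @return A list with components `shape1` and `shape2` (both positive).
#' @export
#' @examples
#' beta_shapes(0.5, sqrt(1 / 3)) # the uniform distribution: shapes (1, 1)
beta_shapes <- function(mu, sigma) {
  if (any(!is.finite(mu) | mu <= 0 | mu >= 1)) {
    stop("'mu' must lie strictly inside (0, 1)")
  }
  if (any(!is.finite(sigma) | sigma <= 0 | sigma >= 1)) {
    stop("'sigma' must lie strictly inside (0, 1)")
  }
  s <- (1 - sigma^2) / sigma^2
  list(shape1 = mu * s, shape2 = (1 - mu) * s)
}

#' Log-likelihood of the mean/scale beta distribution
#'
#' @param y Observations strictly inside (0, 1).
#' @param mu,sigma Distribution parameters; see [beta_shapes()].
#' @return Numeric vector of log-density values.
#' @export
beta_loglik <- function(y, mu, sigma) {
  if (any(!is.finite(y) | y <= 0 | y >= 1)) {
    stop("'y' must lie strictly inside (0, 1)")
  }
  sh <- beta_shapes(mu, sigma)
  stats::dbeta(y, sh$shape1, sh$shape2, log = TRUE)
}

#' CDF of the mean/scale beta distribution
#'
#' @param q Quantiles in `[0, 1]`.
#' @inheritParams beta_loglik
#' @return `P(X <= q)`.
#' @export
beta_cdf <- function(q, mu, sigma) {
  sh <- beta_shapes(mu, sigma)
  stats::pbeta(q, sh$shape1, sh$shape2)
}

# Clip range used inside gradient evaluation only; keeps digamma calls finite
# when an additive predictor wanders far out on the link scale.
.param_eps <- 1e-10

#' Negative gradients of the boosting risk for both additive predictors
#'
#' Returns the derivatives of the per-observation log-likelihood with
#' respect to the two additive predictors `eta_mu` and `eta_sigma`
#' (logit-linked location and scale). These are the working responses the
#' base learners are fitted to in each boosting iteration: the negative
#' gradient of the negative log-likelihood risk.
#'
#' The chain rule composes the beta score in the shape parameters with the
#' mean/scale reparameterization and the logistic inverse link. Parameters
#' are clipped to `[1e-10, 1 - 1e-10]` before evaluation as a numerical
#' guard.
#'
#' @param y Observations strictly inside (0, 1).
#' @param eta_mu,eta_sigma Additive predictor values on the logit scale.
#' @return A list with numeric vectors `g_mu` and `g_sigma`.
#' @export
beta_neg_gradients <- function(y, eta_mu, eta_sigma) {
  if (any(!is.finite(y) | y <= 0 | y >= 1)) {
    stop("'y' must lie strictly inside (0, 1)")
  }
  mu <- pmin(pmax(stats::plogis(eta_mu), .param_eps), 1 - .param_eps)
  sigma <- pmin(pmax(stats::plogis(eta_sigma), .param_eps), 1 - .param_eps)
  s <- (1 - sigma^2) / sigma^2
  a <- mu * s
  b <- (1 - mu) * s
  dig_ab <- digamma(a + b)
  dla <- log(y) - digamma(a) + dig_ab       # d loglik / d shape1
  dlb <- log1p(-y) - digamma(b) + dig_ab    # d loglik / d shape2
  g_mu <- mu * (1 - mu) * s * (dla - dlb)
  # d s / d sigma = -2 / sigma^3; d sigma / d eta_sigma = sigma (1 - sigma)
  g_sigma <- sigma * (1 - sigma) * (-2 / sigma^3) * (mu * dla + (1 - mu) * dlb)
  list(g_mu = g_mu, g_sigma = g_sigma)
}

# Empirical risk: sum of negative log-likelihoods at the current predictors.
beta_risk <- function(y, eta_mu, eta_sigma) {
  mu <- pmin(pmax(stats::plogis(eta_mu), .param_eps), 1 - .param_eps)
  sigma <- pmin(pmax(stats::plogis(eta_sigma), .param_eps), 1 - .param_eps)
  -sum(beta_loglik(y, mu, sigma))
}
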