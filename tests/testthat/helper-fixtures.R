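# Shared fixtures and independent oracles used across the suite.

# Hand-built encoded design over a plain numeric matrix (columns x1, x2, ...),
# bypassing the clinical schema for small algorithmic tests.
toy_design <- function(X) {
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  structure(
    list(x = Xc, centers = ctr, binary_vars = character(),
         numeric_vars = colnames(X)),
    class = "encoded_design"
  )
}

# Simulate from a single-covariate location-scale beta truth.
toy_beta_sample <- function(n, beta_mu = 0.1, beta_sigma = 0.1,
                            a0 = 0, c0 = 0, p_noise = 0) {
  X <- matrix(stats::rnorm(n * (1 + p_noise)), n)
  X[, 1] <- stats::runif(n, -sqrt(3), sqrt(3))
  mu <- stats::plogis(a0 + beta_mu * X[, 1])
  sigma <- stats::plogis(c0 + beta_sigma * X[, 1])
  sh <- beta_shapes(mu, sigma)
  y <- stats::rbeta(n, sh$shape1, sh$shape2)
  list(X = X, y = pmin(pmax(y, 1e-12), 1 - 1e-12), mu = mu, sigma = sigma)
}

# Central finite difference of a scalar function.
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# Independent penalized least-squares solve for a base learner's system.
oracle_pls <- function(X, lambda, z) {
  solve(crossprod(X) + diag(lambda, ncol(X)), crossprod(X, z))
}

# Mean negative log-likelihood computed without the package's risk helper.
oracle_mean_negll <- function(y, eta_mu, eta_sigma) {
  mu <- stats::plogis(eta_mu)
  sigma <- stats::plogis(eta_sigma)
  s <- (1 - sigma^2) / sigma^2
  -mean(stats::dbeta(y, mu * s, (1 - mu) * s, log = TRUE))
}
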