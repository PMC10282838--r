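test_that("offset initialization matches the method-of-moments intercept model", {
  # symmetric sample around 0.5: location offset exactly zero
  y <- c(0.3, 0.4, 0.6, 0.7)
  off <- init_offsets(y)
  expect_equal(off$offset_mu, 0, tolerance = 1e-12)
  # two-point sample: hand arithmetic (unbiased variance 0.02)
  off <- init_offsets(c(0.4, 0.6))
  expect_equal(off$offset_mu, 0, tolerance = 1e-12)
  expect_equal(stats::plogis(off$offset_sigma)^2, 0.08, tolerance = 1e-12)
  # Monte Carlo: draws from a beta(mu = 0.3, sigma = 0.4) recover (0.3, 0.4)
  set.seed(13)
  n <- 1e5
  sh <- beta_shapes(0.3, 0.4)
  y <- stats::rbeta(n, sh$shape1, sh$shape2)
  off <- init_offsets(y)
  se_mu <- stats::sd(y) / sqrt(n) / (0.3 * 0.7) # delta method on the logit
  expect_lt(abs(stats::plogis(off$offset_mu) - 0.3), 3 * se_mu)
  expect_lt(abs(stats::plogis(off$offset_sigma) - 0.4), 0.01)
  expect_warning(init_offsets(rep(0.4, 5)), "clipped")
  expect_error(init_offsets(c(0.2, 1)), "strictly inside")
})

test_that("each boosting step updates exactly one predictor and risk never increases", {
  co <- generate_cohort(synthetic_config(n = 80, seed = 21))
  y <- rescale_total(co$dis_positive, "positive")
  d <- encode_cohort(co)
  bls <- build_baselearners(d)
  state <- panssboost:::new_boost_state(y, bls)
  risk0 <- panssboost:::beta_risk(y, state$eta_mu, state$eta_sigma)
  for (i in 1:10) {
    prev_mu <- state$eta_mu
    prev_sigma <- state$eta_sigma
    state <- boost_step(state, bls)
    changed <- c(mu = any(state$eta_mu != prev_mu),
                 sigma = any(state$eta_sigma != prev_sigma))
    expect_identical(sum(changed), 1L)
    expect_identical(names(changed)[changed], state$history$parameter[i])
  }
  expect_true(all(diff(c(risk0, state$history$risk)) <= 1e-9))
})

test_that("a model at mstop = 0 predicts the offsets everywhere", {
  co <- generate_cohort(synthetic_config(n = 60, seed = 3))
  fit <- fit_factor_model(co, "excited", mstop = 0)
  pr <- predict(fit, co)
  expect_equal(pr$eta_mu, rep(fit$offset_mu, 60), ignore_attr = TRUE)
  expect_equal(pr$eta_sigma, rep(fit$offset_sigma, 60), ignore_attr = TRUE)
  expect_identical(nrow(fit$history), 0L)
})

test_that("prediction recomputes the training predictors from the coefficients", {
  co <- generate_cohort(synthetic_config(n = 100, seed = 8))
  fit <- fit_factor_model(co, "negative", mstop = 40)
  pr <- predict(fit, co)
  expect_lt(max(abs(pr$eta_mu - fit$eta_mu)), 1e-10)
  expect_lt(max(abs(pr$eta_sigma - fit$eta_sigma)), 1e-10)
  # duplicated rows receive identical predictions
  co2 <- co[c(1, 1, 2, 2), ]
  pr2 <- predict(fit, co2)
  expect_identical(pr2$mu[1], pr2$mu[2])
  expect_identical(pr2$mu[3], pr2$mu[4])
})

test_that("never-selected covariates have zero coefficients and no effect", {
  co <- generate_cohort(synthetic_config(n = 120, seed = 9))
  fit <- fit_factor_model(co, "disorganized", mstop = 25)
  vars <- vapply(fit$baselearners, `[[`, "", "variable")
  sel <- unique(fit$history$variable)
  for (j in seq_along(fit$baselearners)) {
    if (!vars[j] %in% sel) {
      expect_identical(sum(abs(fit$coef_mu[[j]])), 0)
      expect_identical(sum(abs(fit$coef_sigma[[j]])), 0)
    }
  }
  # perturbing an unselected covariate leaves predictions unchanged
  unsel <- setdiff(vars, sel)[1]
  skip_if(is.na(unsel))
  co2 <- co
  co2[[unsel]] <- if (unsel %in% binary_predictors())
    1 - co2[[unsel]] else co2[[unsel]] + 3
  expect_equal(predict(fit, co2)$mu, predict(fit, co)$mu, tolerance = 1e-12)
})

test_that("with a dominant signal, location updates concentrate on the true covariate", {
  set.seed(17)
  sim <- toy_beta_sample(500, beta_mu = 1.0, beta_sigma = 0, c0 = stats::qlogis(0.45),
                         p_noise = 4)
  d <- toy_design(sim$X)
  bls <- build_baselearners(d)
  fit <- boost_fit(sim$y, d, bls, mstop = 50)
  h <- fit$history
  mu_sel <- h$variable[h$parameter == "mu"]
  expect_gte(mean(mu_sel == "x1"), 0.9)
  tab <- table(paste(h$parameter, h$variable))
  expect_identical(names(which.max(tab)), "mu x1")
})

test_that("boosting a single linear learner approaches the ML fit with shrinkage en route", {
  set.seed(1)
  sim <- toy_beta_sample(500, beta_mu = 0.1, beta_sigma = 0.1)
  d <- toy_design(sim$X)
  bls <- build_baselearners(d)
  bls <- bls[vapply(bls, `[[`, "", "kind") == "linear"]
  fit <- boost_fit(sim$y, d, bls, mstop = 1000)
  xc <- d$x[, 1]
  est <- c(fit$offset_mu, fit$coef_mu[[1]], fit$offset_sigma, fit$coef_sigma[[1]])
  negll <- function(p) -sum(stats::dbeta(
    sim$y,
    stats::plogis(p[1] + p[2] * xc) * ((1 - stats::plogis(p[3] + p[4] * xc)^2) /
                                         stats::plogis(p[3] + p[4] * xc)^2),
    (1 - stats::plogis(p[1] + p[2] * xc)) *
      ((1 - stats::plogis(p[3] + p[4] * xc)^2) /
         stats::plogis(p[3] + p[4] * xc)^2),
    log = TRUE))
  mle <- stats::optim(est, negll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(max(abs(est[c(2, 4)] - mle$par[c(2, 4)])), 0.02)
  # early stopping shrinks: coefficients at small mstop are strictly smaller
  fit20 <- boost_fit(sim$y, d, bls, mstop = 20)
  expect_lt(abs(fit20$coef_mu[[1]]), abs(mle$par[2]))
  expect_lt(abs(fit20$coef_mu[[1]]), abs(fit$coef_mu[[1]]))
})

test_that("rows at the factor maximum are rejected by model fitting", {
  co <- generate_cohort(synthetic_config(n = 40, seed = 4))
  co$dis_depressed[5] <- 21L # rescaled value exactly 1
  expect_error(fit_factor_model(co, "depressed", mstop = 5), "open interval")
})
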