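test_that("fold assignments partition the rows with balanced sizes", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    k <- sample(2:min(10, n), 1)
    f <- make_folds(n, k)
    expect_length(f, n)
    expect_setequal(unique(f), seq_len(k))
    expect_lte(diff(range(table(f))), 1)
  }
  expect_error(make_folds(5, 1), "\\[2, n\\]")
})

test_that("mstop selection follows the fold-average predictive risk path", {
  co <- generate_cohort(synthetic_config(n = 60, seed = 30))
  # a single-value grid is returned as-is
  m <- select_mstop(co, "negative", grid = 8, k = 3, seed = 42)
  expect_identical(as.integer(m), 8L)
  # the path-tracked held-out risk equals refitting from scratch at each
  # grid value (same folds via the same seed)
  grid <- c(3, 7, 12)
  m <- select_mstop(co, "negative", grid = grid, k = 3, seed = 101)
  cvr <- attr(m, "cv_risk")
  set.seed(101)
  y <- rescale_total(co$dis_negative, "negative")
  folds <- make_folds(60, 3)
  oracle <- sapply(grid, function(g) {
    mean(sapply(1:3, function(i) {
      tr <- which(folds != i)
      d_tr <- encode_cohort(co[tr, ])
      d_te <- encode_cohort(co[-tr, ], centers = d_tr$centers)
      fit <- boost_fit(y[tr], d_tr, build_baselearners(d_tr), mstop = g)
      pr <- predict(fit, d_te)
      oracle_mean_negll(y[-tr], pr$eta_mu, pr$eta_sigma)
    }))
  })
  expect_equal(unname(cvr), oracle, tolerance = 1e-10)
  expect_identical(as.integer(m), as.integer(grid[which.min(oracle)]))
  expect_error(select_mstop(co, "negative", grid = 0:5), "within \\[1, 1000\\]")
})

test_that("strong signal selects a later stopping iteration than pure noise", {
  cfg_sig <- synthetic_config(n = 300, seed = 55)
  co_sig <- generate_cohort(cfg_sig)
  m_sig <- select_mstop(co_sig, "negative", grid = 1:100, k = 5, seed = 7)
  # null truth: no covariate affects the discharge score
  cfg_null <- synthetic_config(
    n = 300, seed = 55,
    coef_mu = stats::setNames(rep(list(stats::setNames(numeric(0),
                                                       character(0))), 5),
                              names(panss_factors())))
  co_null <- generate_cohort(cfg_null)
  m_null <- select_mstop(co_null, "negative", grid = 1:100, k = 5, seed = 7)
  expect_gt(as.integer(m_sig), 1L)
  # under the null the predictive-risk curve is nearly flat: continuing to
  # boost buys almost nothing, while the signal cohort gains substantially
  drop_sig <- attr(m_sig, "cv_risk")[1] - min(attr(m_sig, "cv_risk"))
  drop_null <- attr(m_null, "cv_risk")[1] - min(attr(m_null, "cv_risk"))
  expect_lt(drop_null, drop_sig / 5)
})

test_that("pseudo R2 and RMSE follow their logit-scale definitions", {
  y <- c(0.2, 0.4, 0.6)
  expect_equal(pseudo_r2(y, stats::qlogis(y)), 1)
  expect_equal(pseudo_r2(y, 2 + 3 * stats::qlogis(y)), 1)
  eta <- c(-1.0, -0.5, 0.5)
  # independent correlation computation from raw sums
  z <- stats::qlogis(y)
  r_oracle <- (mean(z * eta) - mean(z) * mean(eta)) /
    sqrt((mean(z^2) - mean(z)^2) * (mean(eta^2) - mean(eta)^2))
  expect_equal(pseudo_r2(y, eta), r_oracle^2, tolerance = 1e-12)
  expect_equal(pseudo_r2(y, eta), 0.9412526, tolerance = 1e-6)
  expect_warning(r0 <- pseudo_r2(y, c(1, 1, 1)), "constant")
  expect_identical(r0, 0)

  expect_identical(rmse_logit(y, stats::qlogis(y)), 0)
  expect_equal(rmse_logit(y, stats::qlogis(y) + 0.7), 0.7, tolerance = 1e-12)
  expect_equal(rmse_logit(y, eta), sqrt(mean((z - eta)^2)), tolerance = 1e-12)
  expect_equal(rmse_logit(y, eta), 0.2360, tolerance = 1e-4)
})

test_that("PIT masses spread uniformly over the CDF jump and sum to one", {
  h <- pit_histogram(data.frame(f_lo = 0.2, f_hi = 0.4), bins = 10)
  expect_equal(h$masses, c(0, 0, 0.5, 0.5, 0, 0, 0, 0, 0, 0))
  expect_equal(sum(h$masses), 1, tolerance = 1e-10)
  # interval straddling bin edges splits proportionally
  h <- pit_histogram(data.frame(f_lo = 0.05, f_hi = 0.45), bins = 10)
  expect_equal(h$masses[1:5], c(0.125, 0.25, 0.25, 0.25, 0.125))
  set.seed(2)
  pit <- data.frame(f_lo = stats::runif(50, 0, 0.5))
  pit$f_hi <- pit$f_lo + stats::runif(50, 0, 0.5)
  h <- pit_histogram(pit, bins = 7)
  expect_true(all(h$masses >= 0))
  expect_equal(sum(h$masses), 1, tolerance = 1e-10)
})

test_that("PIT histograms are uniform under the true model and flag over-forecasting", {
  set.seed(77)
  fn <- "negative"
  for (n in c(200, 2000)) {
    mu <- stats::plogis(stats::rnorm(n, -0.5, 0.5))
    sigma <- rep(0.3, n)
    sh <- beta_shapes(mu, sigma)
    y <- unrescale(pmax(pmin(stats::rbeta(n, sh$shape1, sh$shape2), 1), 1e-12), fn)
    h <- pit_histogram(pit_values(mu, sigma, y, fn))
    dev <- max(abs(h$masses - 0.1))
    if (n == 200) dev200 <- dev else dev2000 <- dev
    if (n == 2000) {
      expect_gt(pit_uniformity_test(h)$p_value, 0.01)
      # inflated location predictions deplete the top bins
      h_inf <- pit_histogram(pit_values(stats::plogis(stats::qlogis(mu) + 0.5),
                                        sigma, y, fn))
      expect_lt(h_inf$masses[10], 0.1)
    }
  }
  expect_lt(dev2000, dev200) # deviation from uniformity shrinks with n
})

test_that("nested CV bookkeeping partitions rows and repeats cleanly", {
  co <- generate_cohort(synthetic_config(n = 20, seed = 12))
  cv <- nested_cv(co, "positive", repeats = 1, k = 2, inner_k = 2,
                  grid = 1:10, seed = 3)
  expect_identical(nrow(cv$results), 2L)
  expect_identical(cv$n_failed, 0L)
  # each fit was tested on the complementary half
  expect_identical(sort(as.integer(table(cv$fold_plan[1, ]))), c(10L, 10L))
  # every row appears in exactly `repeats` test sets
  cv3 <- nested_cv(co, "positive", repeats = 3, k = 2, inner_k = 2,
                   grid = 1:10, seed = 3)
  expect_identical(nrow(cv3$results), 6L)
  # every row lands in exactly one test fold per repeat
  expect_true(all(cv3$fold_plan %in% 1:2))
  expect_identical(nrow(cv3$pit), 3L * 20L)
})

test_that("identical seeds reproduce nested CV end-to-end", {
  co <- generate_cohort(synthetic_config(n = 40, seed = 6))
  cv1 <- nested_cv(co, "depressed", repeats = 1, k = 2, inner_k = 2,
                   grid = 1:15, seed = 9)
  cv2 <- nested_cv(co, "depressed", repeats = 1, k = 2, inner_k = 2,
                   grid = 1:15, seed = 9)
  expect_identical(cv1$results, cv2$results)
  expect_identical(cv1$pit, cv2$pit)
  expect_identical(cv1$selection, cv2$selection)
})

test_that("the loess smoother reproduces polynomials and a direct WLS solve", {
  set.seed(14)
  x <- sort(stats::runif(60, 0, 10))
  expect_equal(loess_smooth(x, rep(2.5, 60))$fitted, rep(2.5, 100),
               tolerance = 1e-8, ignore_attr = TRUE)
  y_lin <- 1.5 - 0.4 * x
  sm <- loess_smooth(x, y_lin)
  expect_equal(sm$fitted, 1.5 - 0.4 * sm$x, tolerance = 1e-8,
               ignore_attr = TRUE)
  # tricube-weighted local quadratic at one grid point, coded independently
  y <- sin(x) + stats::rnorm(60, 0, 0.1)
  span <- 0.75
  sm <- loess_smooth(x, y, span = span)
  x0 <- sm$x[37]
  q <- ceiling(span * length(x))
  d <- abs(x - x0)
  dq <- sort(d)[q]
  w <- pmax(1 - (d / dq)^3, 0)^3
  Xl <- cbind(1, x - x0, (x - x0)^2)
  cf <- solve(crossprod(Xl, w * Xl), crossprod(Xl, w * y))
  expect_equal(sm$fitted[37], cf[1], tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(loess_smooth(x[1:5], y[1:5]), "at least 10")
  expect_error(loess_smooth(x, y, span = 0.01), "too small")
})
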