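#' Random k-fold assignments
#'
#' Folds partition the rows with sizes differing by at most one. Drawn from
#' the current RNG stream (seed the stream upstream for reproducibility).
#'
#' @param n Number of rows.
#' @param k Number of folds.
#' @return Integer vector of fold labels in `1..k`.
#' @export
make_folds <- function(n, k) {
  if (k < 2 || k > n) stop("'k' must be in [2, n]")
  sample(rep(seq_len(k), length.out = n))
}

# Fit the boosting path on a row subset of a cohort and track mean held-out
# negative log-likelihood per iteration on the complementary rows.
path_valid_risk <- function(cohort, y, train_idx, mstop_max, nu) {
  design_tr <- encode_cohort(cohort[train_idx, , drop = FALSE])
  design_te <- encode_cohort(cohort[-train_idx, , drop = FALSE],
                             centers = design_tr$centers)
  bls <- build_baselearners(design_tr)
  fit <- boost_fit(y[train_idx], design_tr, bls, mstop = mstop_max, nu = nu,
                   valid = list(y = y[-train_idx], design = design_te))
  fit$valid_risk
}

#' Select the stopping iteration by k-fold cross-validation
#'
#' For each fold the boosting path is fitted on the remaining folds up to
#' `max(grid)` and the held-out mean negative log-likelihood is recorded
#' along the path; the returned `mstop` is the grid value minimizing the
#' fold-average predictive risk, with ties broken toward the smallest
#' value.
#'
#' @param cohort Cohort data frame.
#' @param factor Factor name or `panss_factor` object.
#' @param grid Integer vector of candidate stopping iterations
#'   (subset of `1..1000`).
#' @param k Number of folds (the fitting procedure uses 10).
#' @param nu Step length.
#' @param seed Optional seed for the fold draw; `NULL` uses the current
#'   RNG stream (as the nested loop does).
#' @return The selected `mstop`, with the fold-average risk curve attached
#'   as attribute `cv_risk` (a numeric vector over `grid`).
#' @export
select_mstop <- function(cohort, factor, grid = 1:1000, k = 10, nu = 0.1,
                         seed = NULL) {
  grid <- sort(unique(as.integer(grid)))
  if (min(grid) < 1 || max(grid) > 1000) stop("'grid' must lie within [1, 1000]")
  if (!is.null(seed)) set.seed(seed)
  f <- factor_definition(factor)
  y <- rescale_total(cohort[[paste0("dis_", f$name)]], f)
  n <- nrow(cohort)
  folds <- make_folds(n, k)
  mmax <- max(grid)
  risk <- matrix(NA_real_, k, mmax)
  for (i in seq_len(k)) {
    yi <- y[folds != i]
    if (stats::var(yi) < 1e-12) {
      warning("fold ", i, " has (near-)constant outcome; fold retained")
    }
    risk[i, ] <- path_valid_risk(cohort, y, which(folds != i), mmax, nu)
  }
  avg <- colMeans(risk)[grid]
  out <- grid[which.min(avg)] # which.min takes the first, i.e. smallest mstop
  attr(out, "cv_risk") <- stats::setNames(avg, grid)
  out
}

#' Pseudo R-squared on the logit scale
#'
#' Squared Pearson correlation between the logit-transformed rescaled
#' outcomes and the fitted location predictor. Returns 0 (with a warning)
#' if either vector is constant.
#'
#' @param y Rescaled outcomes strictly inside (0, 1), length >= 3.
#' @param eta_mu_hat Fitted location predictor (logit scale).
#' @return A value in `[0, 1]`.
#' @export
pseudo_r2 <- function(y, eta_mu_hat) {
  stopifnot(length(y) >= 3, length(eta_mu_hat) == length(y))
  if (any(y <= 0 | y >= 1)) stop("'y' must lie strictly inside (0, 1)")
  z <- stats::qlogis(y)
  if (stats::sd(z) < 1e-12 || stats::sd(eta_mu_hat) < 1e-12) {
    warning("constant vector in pseudo_r2; returning 0")
    return(0)
  }
  stats::cor(z, eta_mu_hat)^2
}

#' Root mean squared error on the rescaled, logit-transformed outcome scale
#'
#' @inheritParams pseudo_r2
#' @return Non-negative RMSE between `logit(y)` and the location predictor.
#' @export
rmse_logit <- function(y, eta_mu_hat) {
  stopifnot(length(y) >= 1, length(eta_mu_hat) == length(y))
  if (any(y <= 0 | y >= 1)) stop("'y' must lie strictly inside (0, 1)")
  sqrt(mean((stats::qlogis(y) - eta_mu_hat)^2))
}

#' Non-randomized PIT values for discretized beta predictions
#'
#' For each observation the discretized predictive distribution gives the
#' cumulative probabilities `F_lo = P(Y <= y - 1)` and `F_hi = P(Y <= y)`
#' at the observed total `y`; the observation's probability integral
#' transform mass is spread uniformly over `[F_lo, F_hi]` (the
#' deterministic version of the randomized PIT for discrete outcomes).
#'
#' @param mu,sigma Predicted beta parameters per observation.
#' @param observed Observed integer totals, attainable for the factor.
#' @param factor Factor name or `panss_factor` object.
#' @return Data frame with columns `f_lo`, `f_hi`.
#' @export
pit_values <- function(mu, sigma, observed, factor) {
  as.data.frame(score_cdf_pair(mu, sigma, observed, factor))
}

#' Aggregate PIT values into a calibration histogram
#'
#' Each observation contributes total mass 1, spread uniformly over its
#' `[f_lo, f_hi]` interval; bins collect the mean mass. A perfectly
#' calibrated forecast yields a uniform histogram; depleted upper bins
#' indicate over-forecasting.
#'
#' @param pit Data frame with columns `f_lo`, `f_hi` (see [pit_values()]).
#' @param bins Number of equal-width bins on `[0, 1]`.
#' @return Object of class `pit_histogram`: list with `edges` (length
#'   `bins + 1`) and `masses` (mean mass per bin, summing to 1).
#' @export
pit_histogram <- function(pit, bins = 10) {
  stopifnot(is.data.frame(pit), all(c("f_lo", "f_hi") %in% names(pit)),
            bins >= 2)
  edges <- seq(0, 1, length.out = bins + 1)
  lo <- pit$f_lo
  hi <- pit$f_hi
  width <- hi - lo
  masses <- numeric(bins)
  point <- width <= 0
  if (any(point)) {
    # zero-width interval (pmf underflow): treat as a point mass at f_hi
    b <- pmin(pmax(ceiling(hi[point] * bins), 1L), bins)
    masses <- masses + tabulate(b, bins)
  }
  if (any(!point)) {
    l <- lo[!point]; h <- hi[!point]; w <- width[!point]
    for (b in seq_len(bins)) {
      overlap <- pmax(0, pmin(h, edges[b + 1]) - pmax(l, edges[b]))
      masses[b] <- masses[b] + sum(overlap / w)
    }
  }
  structure(list(edges = edges, masses = masses / nrow(pit), n = nrow(pit)),
            class = "pit_histogram")
}

#' @export
print.pit_histogram <- function(x, ...) {
  cat("PIT histogram (", length(x$masses), " bins, n = ", x$n, "):\n", sep = "")
  print(round(x$masses, 4))
  invisible(x)
}

#' Chi-square test of PIT uniformity
#'
#' Compares `n` times the bin masses against the uniform expectation
#' `n / bins` with `bins - 1` degrees of freedom. The fractional-mass
#' statistic is the standard plug-in for non-randomized PIT histograms.
#'
#' @param hist A `pit_histogram`.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
pit_uniformity_test <- function(hist) {
  stopifnot(inherits(hist, "pit_histogram"))
  bins <- length(hist$masses)
  expected <- hist$n / bins
  stat <- sum((hist$n * hist$masses - expected)^2 / expected)
  list(statistic = stat, df = bins - 1,
       p_value = stats::pchisq(stat, bins - 1, lower.tail = FALSE))
}

#' Repeated nested cross-validation of the full fitting procedure
#'
#' The outer loop repeats k-fold cross-validation `repeats` times; within
#' each outer training set, `mstop` is tuned by inner k-fold
#' cross-validation ([select_mstop()]), the model is refitted at the tuned
#' value, and train/test pseudo R-squared and RMSE, per-variable selection
#' flags for both additive predictors, and test-set PIT values are
#' recorded. Optimism is reported as mean(train - test) for pseudo
#' R-squared and mean(test - train) for RMSE, so both are positive when
#' apparent performance is optimistic.
#'
#' @param cohort Cohort data frame.
#' @param factor Factor name or `panss_factor` object.
#' @param repeats Number of outer repeats (the fitting procedure uses 100).
#' @param k Outer folds (the fitting procedure uses 10).
#' @param inner_k Inner folds for `mstop` tuning.
#' @param grid Candidate `mstop` grid.
#' @param nu Step length.
#' @param seed Master seed; all fold draws (inner draws re-randomized per
#'   outer fold) flow from it.
#' @return Object of class `nested_cv`: list with `results` (one row per
#'   repeat x fold: mstop, r2_train, r2_test, rmse_train, rmse_test),
#'   `selection` (logical array fit x variable x parameter), `pit`
#'   (pooled test-set PIT values), `optimism`, and the settings.
#' @export
nested_cv <- function(cohort, factor, repeats = 100, k = 10, inner_k = 10,
                      grid = 1:1000, nu = 0.1, seed = 1) {
  stopifnot(repeats >= 1)
  f <- factor_definition(factor)
  set.seed(seed)
  n <- nrow(cohort)
  vars <- c(binary_predictors(), numeric_predictors())
  nfit <- repeats * k
  res <- data.frame(repeat_ = rep(seq_len(repeats), each = k),
                    fold = rep(seq_len(k), repeats),
                    mstop = NA_integer_, r2_train = NA_real_,
                    r2_test = NA_real_, rmse_train = NA_real_,
                    rmse_test = NA_real_)
  selection <- array(FALSE, dim = c(nfit, length(vars), 2),
                     dimnames = list(NULL, vars, c("mu", "sigma")))
  pit_list <- vector("list", nfit)
  fold_plan <- matrix(NA_integer_, repeats, n)
  row <- 0L
  failed <- 0L
  for (r in seq_len(repeats)) {
    folds <- make_folds(n, k)
    fold_plan[r, ] <- folds
    for (i in seq_len(k)) {
      row <- row + 1L
      test_idx <- which(folds == i)
      train <- cohort[-test_idx, , drop = FALSE]
      test <- cohort[test_idx, , drop = FALSE]
      fit_one <- try({
        m <- select_mstop(train, f, grid = grid, k = inner_k, nu = nu)
        model <- fit_factor_model(train, f, mstop = as.integer(m), nu = nu)
        pr_tr <- stats::setNames(
          data.frame(eta_mu = model$eta_mu, eta_sigma = model$eta_sigma,
                     mu = stats::plogis(model$eta_mu),
                     sigma = stats::plogis(model$eta_sigma)),
          c("eta_mu", "eta_sigma", "mu", "sigma"))
        pr_te <- predict(model, test)
        y_tr <- model$y
        y_te <- rescale_total(test[[paste0("dis_", f$name)]], f)
        res$mstop[row] <- as.integer(m)
        res$r2_train[row] <- pseudo_r2(y_tr, pr_tr$eta_mu)
        res$r2_test[row] <- pseudo_r2(y_te, pr_te$eta_mu)
        res$rmse_train[row] <- rmse_logit(y_tr, pr_tr$eta_mu)
        res$rmse_test[row] <- rmse_logit(y_te, pr_te$eta_mu)
        for (p in c("mu", "sigma")) {
          sel_vars <- unique(model$history$variable[model$history$parameter == p])
          selection[row, sel_vars, p] <- TRUE
        }
        pit_list[[row]] <- pit_values(pr_te$mu, pr_te$sigma,
                                      test[[paste0("dis_", f$name)]], f)
        NULL
      }, silent = TRUE)
      if (inherits(fit_one, "try-error")) {
        failed <- failed + 1L
        warning("nested_cv: fit failed for repeat ", r, ", fold ", i, ": ",
                attr(fit_one, "condition")$message)
      }
    }
  }
  ok <- !is.na(res$mstop)
  structure(
    list(
      factor = f$name,
      results = res,
      selection = selection,
      pit = do.call(rbind, pit_list),
      fold_plan = fold_plan,
      optimism = c(
        pseudo_r2 = mean(res$r2_train[ok] - res$r2_test[ok]),
        rmse = mean(res$rmse_test[ok] - res$rmse_train[ok])
      ),
      n_failed = failed,
      settings = list(repeats = repeats, k = k, inner_k = inner_k,
                      grid = range(grid), nu = nu, seed = seed)
    ),
    class = "nested_cv"
  )
}

#' @export
print.nested_cv <- function(x, ...) {
  ok <- !is.na(x$results$mstop)
  cat(sprintf("nested CV (%s factor): %d repeats x %d folds (%d failed)\n",
              x$factor, x$settings$repeats, x$settings$k, x$n_failed))
  cat(sprintf("  pseudo R2: train %.3f, test %.3f (optimism %.3f)\n",
              mean(x$results$r2_train[ok]), mean(x$results$r2_test[ok]),
              x$optimism["pseudo_r2"]))
  cat(sprintf("  RMSE:      train %.3f, test %.3f (optimism %.3f)\n",
              mean(x$results$rmse_train[ok]), mean(x$results$rmse_test[ok]),
              x$optimism["rmse"]))
  invisible(x)
}

#' Locally weighted least squares smoother on a fixed grid
#'
#' Tricube-weighted local quadratic regression (`stats::loess` with an
#' exact direct surface) evaluated on a 100-point grid over the range of
#' `x`; used for the qualitative calibration displays.
#'
#' @param x,y Numeric vectors of equal length (at least 10 points).
#' @param span Smoothing span in (0, 1].
#' @param grid_length Number of evaluation points.
#' @return Data frame with columns `x` (grid) and `fitted`.
#' @export
loess_smooth <- function(x, y, span = 0.75, grid_length = 100) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10) stop("at least 10 points are required")
  if (span <= 0 || span > 1) stop("'span' must lie in (0, 1]")
  if (span * length(x) < 4) stop("'span' too small for a local quadratic fit")
  fit <- stats::loess(y ~ x, span = span, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  gx <- seq(min(x), max(x), length.out = grid_length)
  data.frame(x = gx, fitted = stats::predict(fit, newdata = data.frame(x = gx)))
}
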