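#' Offset (intercept) initialization for the two additive predictors
#'
#' Method-of-moments intercept model: the location offset is the logit of
#' the sample mean and the scale offset is the logit of
#' `sqrt(s^2 / (ybar (1 - ybar)))` with `s^2` the unbiased sample variance,
#' clipped to `[1e-6, 1 - 1e-6]` on the squared scale. A constant outcome
#' yields a clipped scale with a warning.
#'
#' @param y Rescaled outcomes strictly inside (0, 1).
#' @return List with `offset_mu` and `offset_sigma` (logit scale).
#' @export
init_offsets <- function(y) {
  if (any(!is.finite(y) | y <= 0 | y >= 1)) {
    stop("'y' must lie strictly inside (0, 1); totals at the factor maximum ",
         "(rescaled value 1) cannot enter the likelihood")
  }
  ybar <- mean(y)
  s2 <- stats::var(y)
  sig2 <- s2 / (ybar * (1 - ybar))
  if (!is.finite(sig2) || sig2 < 1e-6 || sig2 > 1 - 1e-6) {
    warning("moment estimate of sigma^2 (", signif(sig2, 4),
            ") clipped to [1e-6, 1 - 1e-6]")
    sig2 <- min(max(sig2, 1e-6), 1 - 1e-6)
  }
  list(offset_mu = stats::qlogis(ybar), offset_sigma = stats::qlogis(sqrt(sig2)))
}

new_boost_state <- function(y, baselearners) {
  off <- init_offsets(y)
  n <- length(y)
  zero_coefs <- lapply(baselearners, function(b) numeric(ncol(b$X)))
  structure(
    list(
      y = y,
      offset_mu = off$offset_mu,
      offset_sigma = off$offset_sigma,
      eta_mu = rep(off$offset_mu, n),
      eta_sigma = rep(off$offset_sigma, n),
      coef_mu = zero_coefs,
      coef_sigma = zero_coefs,
      history = list(iteration = integer(), parameter = character(),
                     variable = character(), kind = character(),
                     risk = numeric())
    ),
    class = "boost_state"
  )
}

# Best-fitting base learner for a gradient vector: smallest sse, ties to the
# earlier learner index (which.min does this).
best_fit <- function(baselearners, g) {
  best <- NULL
  best_sse <- Inf
  best_j <- NA_integer_
  for (j in seq_along(baselearners)) {
    ft <- fit_baselearner(baselearners[[j]], g)
    if (ft$sse < best_sse) {
      best <- ft; best_sse <- ft$sse; best_j <- j
    }
  }
  list(index = best_j, fit = best)
}

#' One iteration of non-cyclic component-wise boosting
#'
#' For each distribution parameter the negative-gradient vector at the
#' current state is computed and all base learners are fitted to it; the
#' best fit (smallest squared error) becomes that parameter's candidate
#' update. The candidate additive predictors are formed by adding
#' `nu` times the fitted values, and the single parameter whose damped
#' candidate attains the lower empirical risk (sum of negative
#' log-likelihoods) is updated. Risk ties (difference below 1e-12) go to
#' the location parameter.
#'
#' @param state A `boost_state` as produced internally by [boost_fit()]
#'   (or by `panssboost:::new_boost_state`).
#' @param baselearners List of base learners from [build_baselearners()].
#' @param nu Step length; fixed at one-tenth in the fitting procedure.
#' @return The updated state; the appended history record (iteration,
#'   parameter, variable, kind, risk after update) is in `state$history`.
#' @export
boost_step <- function(state, baselearners, nu = 0.1) {
  stopifnot(inherits(state, "boost_state"))
  g <- beta_neg_gradients(state$y, state$eta_mu, state$eta_sigma)
  cand_mu <- best_fit(baselearners, g$g_mu)
  cand_sigma <- best_fit(baselearners, g$g_sigma)
  eta_mu_new <- state$eta_mu + nu * cand_mu$fit$fitted
  eta_sigma_new <- state$eta_sigma + nu * cand_sigma$fit$fitted
  risk_mu <- beta_risk(state$y, eta_mu_new, state$eta_sigma)
  risk_sigma <- beta_risk(state$y, state$eta_mu, eta_sigma_new)
  if (!is.finite(risk_mu) || !is.finite(risk_sigma)) {
    stop("non-finite candidate risk at iteration ",
         length(state$history$iteration) + 1L,
         " (mu: ", risk_mu, ", sigma: ", risk_sigma, ")")
  }
  take_mu <- risk_mu <= risk_sigma + 1e-12 # ties go to mu
  if (take_mu) {
    j <- cand_mu$index
    state$eta_mu <- eta_mu_new
    state$coef_mu[[j]] <- state$coef_mu[[j]] + nu * cand_mu$fit$coef
    param <- "mu"; risk <- risk_mu
  } else {
    j <- cand_sigma$index
    state$eta_sigma <- eta_sigma_new
    state$coef_sigma[[j]] <- state$coef_sigma[[j]] + nu * cand_sigma$fit$coef
    param <- "sigma"; risk <- risk_sigma
  }
  h <- state$history
  it <- length(h$iteration) + 1L
  h$iteration <- c(h$iteration, it)
  h$parameter <- c(h$parameter, param)
  h$variable <- c(h$variable, baselearners[[j]]$variable)
  h$kind <- c(h$kind, baselearners[[j]]$kind)
  h$risk <- c(h$risk, risk)
  state$history <- h
  attr(state, "last_update") <- list(parameter = param, index = j,
                                     coef = nu * (if (take_mu) cand_mu$fit$coef
                                                  else cand_sigma$fit$coef))
  state
}

#' Fit a boosted location-scale beta regression
#'
#' Runs [boost_step()] `mstop` times from the moment-based offsets. The
#' empirical risk sequence is non-increasing and the fit is deterministic
#' given the data.
#'
#' @param y Rescaled outcomes strictly inside (0, 1).
#' @param design An `encoded_design` for the same rows.
#' @param baselearners Base learners built on `design`.
#' @param mstop Number of boosting iterations, in `[0, 1000]`.
#' @param nu Step length (default one-tenth).
#' @param valid Optional list with components `y` and `design` (an
#'   `encoded_design` of held-out rows encoded with the training centers):
#'   the mean held-out negative log-likelihood after each iteration is then
#'   tracked in the result's `valid_risk`.
#' @param mstop_max Maximum permitted `mstop`.
#' @return An object of class `boosted_lss` with offsets, accumulated
#'   coefficients per base learner and parameter, the selection history
#'   (data frame: iteration, parameter, variable, kind, risk), fitted
#'   additive predictors, and the inputs needed for prediction.
#' @seealso [predict.boosted_lss()], [select_mstop()], [fit_factor_model()]
#' @export
boost_fit <- function(y, design, baselearners, mstop, nu = 0.1, valid = NULL,
                      mstop_max = 1000L) {
  stopifnot(inherits(design, "encoded_design"))
  if (mstop < 0 || mstop > mstop_max || mstop != round(mstop)) {
    stop("'mstop' must be an integer in [0, ", mstop_max, "]")
  }
  if (length(y) != nrow(design$x)) stop("outcome length does not match design")
  state <- new_boost_state(y, baselearners)
  track <- !is.null(valid)
  if (track) {
    Xv <- lapply(baselearners, function(b) b$newdesign(valid$design$x))
    nv <- length(valid$y)
    eta_mu_v <- rep(state$offset_mu, nv)
    eta_sigma_v <- rep(state$offset_sigma, nv)
    valid_risk <- numeric(mstop)
  }
  for (m in seq_len(mstop)) {
    state <- boost_step(state, baselearners, nu)
    if (track) {
      up <- attr(state, "last_update")
      inc <- drop(Xv[[up$index]] %*% up$coef)
      if (up$parameter == "mu") eta_mu_v <- eta_mu_v + inc
      else eta_sigma_v <- eta_sigma_v + inc
      valid_risk[m] <- beta_risk(valid$y, eta_mu_v, eta_sigma_v) / nv
    }
  }
  out <- structure(
    list(
      offset_mu = state$offset_mu,
      offset_sigma = state$offset_sigma,
      coef_mu = state$coef_mu,
      coef_sigma = state$coef_sigma,
      eta_mu = state$eta_mu,
      eta_sigma = state$eta_sigma,
      history = as.data.frame(state$history, stringsAsFactors = FALSE),
      baselearners = baselearners,
      centers = design$centers,
      nu = nu,
      mstop = as.integer(mstop)
    ),
    class = "boosted_lss"
  )
  if (track) out$valid_risk <- valid_risk
  out
}

#' @export
print.boosted_lss <- function(x, ...) {
  sel <- unique(x$history$variable)
  cat(sprintf(
    "boosted location-scale beta regression: mstop = %d, nu = %g\n",
    x$mstop, x$nu))
  cat(sprintf("  offsets (logit): mu = %.4f, sigma = %.4f\n",
              x$offset_mu, x$offset_sigma))
  cat(sprintf("  %d of %d candidate variables selected%s\n",
              length(sel), length(unique(vapply(x$baselearners, `[[`, "",
                                                "variable"))),
              if (length(sel)) paste0(": ",
                paste(utils::head(sel, 8), collapse = ", "),
                if (length(sel) > 8) ", ..." else "") else ""))
  invisible(x)
}

#' Predict distribution parameters from a boosted model
#'
#' @param object A `boosted_lss` model.
#' @param newdata A cohort data frame (encoded internally with the training
#'   centering constants) or an `encoded_design` already encoded with them.
#' @param ... Unused.
#' @return Data frame with per-row `eta_mu`, `eta_sigma`, `mu`, `sigma`.
#' @export
predict.boosted_lss <- function(object, newdata, ...) {
  design <- if (inherits(newdata, "encoded_design")) newdata
            else encode_cohort(newdata, centers = object$centers)
  n <- nrow(design$x)
  eta_mu <- rep(object$offset_mu, n)
  eta_sigma <- rep(object$offset_sigma, n)
  for (j in seq_along(object$baselearners)) {
    cm <- object$coef_mu[[j]]
    cs <- object$coef_sigma[[j]]
    if (all(cm == 0) && all(cs == 0)) next
    Xn <- object$baselearners[[j]]$newdesign(design$x)
    if (any(cm != 0)) eta_mu <- eta_mu + drop(Xn %*% cm)
    if (any(cs != 0)) eta_sigma <- eta_sigma + drop(Xn %*% cs)
  }
  data.frame(eta_mu = eta_mu, eta_sigma = eta_sigma,
             mu = stats::plogis(eta_mu), sigma = stats::plogis(eta_sigma))
}

#' Fit one factor's discharge model from a cohort table
#'
#' Convenience wrapper: rescales the discharge total of the requested
#' factor, encodes the covariates, builds the base learners, and runs
#' [boost_fit()].
#'
#' @param cohort Cohort data frame with the candidate predictors and a
#'   `dis_<factor>` column.
#' @param factor Factor name or `panss_factor` object.
#' @param mstop Number of boosting iterations.
#' @param nu Step length.
#' @return A `boosted_lss` model with the factor and outcome attached.
#' @export
fit_factor_model <- function(cohort, factor, mstop, nu = 0.1) {
  f <- factor_definition(factor)
  ycol <- paste0("dis_", f$name)
  if (!ycol %in% names(cohort)) stop("cohort lacks outcome column '", ycol, "'")
  y <- rescale_total(cohort[[ycol]], f)
  if (any(y >= 1)) {
    stop(sum(y >= 1), " row(s) at the factor maximum (rescaled value 1); ",
         "the beta likelihood requires the open interval - remove them first")
  }
  design <- encode_cohort(cohort)
  bls <- build_baselearners(design)
  model <- boost_fit(y, design, bls, mstop = mstop, nu = nu)
  model$factor <- f
  model$y <- y
  model$cohort <- cohort
  model
}
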