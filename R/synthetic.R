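# Inter-quartile range of the standard normal; converts printed [Q1, Q3]
# summaries into a standard deviation under a two-parameter fit.
.iqr_z <- stats::qnorm(0.75) - stats::qnorm(0.25)

# Continuous version of the rescaling map, for non-integer quartiles.
rescale_cont <- function(y, n) (y - n + 1) / (6 * n + 1)

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the marginal structure of the published admission
#' cohort: Bernoulli probabilities for the nine binary covariates, normal
#' fits to the printed median/IQR for year of admission and age, a
#' log-normal fit for total antipsychotic utilization (PDD:DDD), and
#' per-factor beta distributions (discretized onto attainable totals)
#' matched to the printed admission medians and quartiles. A Gaussian
#' copula correlates the admission factor scores (default: 0.4 between the
#' negative and disorganized factors, which predict each other, all else
#' independent).
#'
#' The true discharge-outcome model is a coefficient map on the encoded
#' covariates (numeric covariates centered at their configured population
#' means): for each factor, `eta_mu = intercept + sum(coef * x)` and
#' similarly for `eta_sigma`; the continuous outcome is drawn from the
#' implied beta distribution and mapped to an integer total by
#' [unrescale()]. The default truth gives each factor's discharge score a
#' single dominant effect of its own admission score (roughly 0.65 logits
#' per admission-score standard deviation), an intercept placing the
#' median discharge severity below admission, and a constant scale of 0.3
#' - the regime the analysis pipeline is designed for, where past scores
#' dominate the prediction of future scores.
#'
#' @param n Number of admissions.
#' @param seed Seed; all randomness in [generate_cohort()] flows from it.
#' @param binary_probs Named Bernoulli probabilities for the nine binary
#'   covariates.
#' @param numeric_params List with `year = c(mean, sd)`, `age = c(mean, sd)`,
#'   `pdd_ddd = c(meanlog, sdlog)`.
#' @param adm_params Named list per factor: `c(mu, sigma)` of the beta
#'   distribution generating admission totals on the rescaled scale.
#' @param adm_cor 5x5 correlation matrix of the Gaussian copula across
#'   admission factors (order: positive, negative, disorganized, excited,
#'   depressed).
#' @param coef_mu,coef_sigma Named list per factor of named coefficient
#'   vectors on encoded covariates for the two additive predictors.
#' @param intercept_mu,intercept_sigma Named numeric vectors per factor.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 320, seed = 1,
                             binary_probs = NULL, numeric_params = NULL,
                             adm_params = NULL, adm_cor = NULL,
                             coef_mu = NULL, coef_sigma = NULL,
                             intercept_mu = NULL, intercept_sigma = NULL) {
  stopifnot(n >= 1)
  factors <- names(.panss_item_map)

  defaults_bin <- c(sex_male = 0.594, schizoaffective = 0.309,
                    prior_clozapine = 0.581, clozapine = 0.203,
                    polypharmacy = 0.519, antidepressant = 0.219,
                    mood_stabilizer = 0.375, benzodiazepine = 0.319,
                    anticholinergic = 0.206)
  if (is.null(binary_probs)) binary_probs <- defaults_bin
  if (!all(binary_predictors() %in% names(binary_probs))) {
    stop("'binary_probs' must name every binary covariate")
  }
  binary_probs <- binary_probs[binary_predictors()]
  if (any(binary_probs < 0 | binary_probs > 1)) {
    stop("Bernoulli probabilities must lie in [0, 1]")
  }

  if (is.null(numeric_params)) {
    numeric_params <- list(
      year = c(mean = 2001.6, sd = (2005.3 - 1998.1) / .iqr_z),
      age = c(mean = 36.5, sd = (44.0 - 27.0) / .iqr_z),
      pdd_ddd = c(meanlog = log(1.81), sdlog = (log(2.75) - log(1.09)) / .iqr_z)
    )
  }

  # admission score summaries (median, Q1, Q3) on the raw total scale
  adm_summaries <- list(
    positive = c(16, 13, 19), negative = c(19, 16, 22.25),
    disorganized = c(11, 9, 13), excited = c(11, 8, 14),
    depressed = c(7, 5, 9)
  )
  if (is.null(adm_params)) {
    adm_params <- lapply(factors, function(fn) {
      n_it <- length(.panss_item_map[[fn]])
      s <- adm_summaries[[fn]]
      mu <- rescale_cont(s[1], n_it)
      sd_r <- (rescale_cont(s[3], n_it) - rescale_cont(s[2], n_it)) / .iqr_z
      sigma <- min(max(sd_r / sqrt(mu * (1 - mu)), 0.05), 0.95)
      c(mu = mu, sigma = sigma)
    })
    names(adm_params) <- factors
  }

  if (is.null(adm_cor)) {
    adm_cor <- diag(5)
    dimnames(adm_cor) <- list(factors, factors)
    adm_cor["negative", "disorganized"] <- 0.4
    adm_cor["disorganized", "negative"] <- 0.4
  }

  # population centers used both by the truth model and as reference values
  centers <- c(
    year = unname(numeric_params$year["mean"]),
    age = unname(numeric_params$age["mean"]),
    pdd_ddd = exp(numeric_params$pdd_ddd[["meanlog"]] +
                    numeric_params$pdd_ddd[["sdlog"]]^2 / 2)
  )
  for (fn in factors) {
    n_it <- length(.panss_item_map[[fn]])
    centers[paste0("adm_", fn)] <-
      adm_params[[fn]][["mu"]] * (6 * n_it + 1) + n_it - 1
  }

  # discharge medians (post-treatment severity sits below admission)
  dis_medians <- c(positive = 12, negative = 16, disorganized = 9,
                   excited = 9, depressed = 6)
  if (is.null(intercept_mu)) {
    intercept_mu <- vapply(factors, function(fn) {
      stats::qlogis(rescale_cont(dis_medians[[fn]],
                                 length(.panss_item_map[[fn]])))
    }, numeric(1))
  }
  if (is.null(intercept_sigma)) {
    intercept_sigma <- stats::setNames(rep(stats::qlogis(0.3), 5), factors)
  }
  if (is.null(coef_mu)) {
    coef_mu <- lapply(factors, function(fn) {
      s <- adm_summaries[[fn]]
      sd_raw <- (s[3] - s[2]) / .iqr_z
      stats::setNames(0.65 / sd_raw, paste0("adm_", fn))
    })
    names(coef_mu) <- factors
  }
  if (is.null(coef_sigma)) {
    coef_sigma <- stats::setNames(
      rep(list(stats::setNames(numeric(0), character(0))), 5), factors)
  }

  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         binary_probs = binary_probs, numeric_params = numeric_params,
         adm_params = adm_params, adm_cor = adm_cor, centers = centers,
         intercept_mu = intercept_mu, intercept_sigma = intercept_sigma,
         coef_mu = coef_mu, coef_sigma = coef_sigma),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("synthetic cohort config: n = %d, seed = %d\n", x$n, x$seed))
  cat("  binary marginals: ",
      paste(sprintf("%s %.1f%%", names(x$binary_probs),
                    100 * x$binary_probs), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# eta vectors implied by the truth coefficient map for one factor.
truth_eta <- function(config, cohort, fn) {
  build <- function(coefs, intercept) {
    eta <- rep(intercept, nrow(cohort))
    for (v in names(coefs)) {
      x <- cohort[[v]]
      if (v %in% names(config$centers)) x <- x - config$centers[[v]]
      eta <- eta + coefs[[v]] * x
    }
    eta
  }
  list(mu = build(config$coef_mu[[fn]], config$intercept_mu[[fn]]),
       sigma = build(config$coef_sigma[[fn]], config$intercept_sigma[[fn]]))
}

#' Generate a synthetic cohort with known truth
#'
#' Draws covariates from the configured marginals, admission factor totals
#' by discretizing correlated beta draws ([unrescale()]), and discharge
#' totals from the configured true location-scale beta model. The same
#' configuration and seed always reproduce the identical table.
#'
#' @param config A `synthetic_config`.
#' @return Data frame of class `synthetic_cohort` with the nine binary
#'   covariates, `year`, `age`, `pdd_ddd`, admission totals `adm_<factor>`,
#'   and discharge totals `dis_<factor>`. The per-row true predictors and
#'   parameters are attached as a data frame in `attr(, "truth")` (columns
#'   `eta_mu_<factor>`, `eta_sigma_<factor>`, `mu_<factor>`,
#'   `sigma_<factor>`).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n
  factors <- names(.panss_item_map)

  cohort <- data.frame(row.names = seq_len(n))
  for (v in binary_predictors()) {
    cohort[[v]] <- stats::rbinom(n, 1L, config$binary_probs[[v]])
  }
  np <- config$numeric_params
  cohort$year <- round(stats::rnorm(n, np$year[["mean"]], np$year[["sd"]]), 1)
  cohort$age <- round(pmax(
    stats::rnorm(n, np$age[["mean"]], np$age[["sd"]]), 18), 1)
  cohort$pdd_ddd <- round(
    stats::rlnorm(n, np$pdd_ddd[["meanlog"]], np$pdd_ddd[["sdlog"]]), 2)

  # correlated admission totals through a Gaussian copula
  L <- chol(config$adm_cor)
  z <- matrix(stats::rnorm(n * 5), n, 5) %*% L
  u <- stats::pnorm(z)
  for (i in seq_along(factors)) {
    fn <- factors[i]
    p <- config$adm_params[[fn]]
    sh <- beta_shapes(p[["mu"]], p[["sigma"]])
    v <- stats::qbeta(u[, i], sh$shape1, sh$shape2)
    v <- pmin(pmax(v, 1e-12), 1)
    cohort[[paste0("adm_", fn)]] <- unrescale(v, fn)
  }

  truth <- data.frame(row.names = seq_len(n))
  for (fn in factors) {
    eta <- truth_eta(config, cohort, fn)
    mu <- stats::plogis(eta$mu)
    sigma <- stats::plogis(eta$sigma)
    sh <- beta_shapes(mu, sigma)
    ycont <- stats::rbeta(n, sh$shape1, sh$shape2)
    ycont <- pmin(pmax(ycont, 1e-12), 1)
    cohort[[paste0("dis_", fn)]] <- unrescale(ycont, fn)
    truth[[paste0("eta_mu_", fn)]] <- eta$mu
    truth[[paste0("eta_sigma_", fn)]] <- eta$sigma
    truth[[paste0("mu_", fn)]] <- mu
    truth[[paste0("sigma_", fn)]] <- sigma
  }
  attr(cohort, "truth") <- truth
  class(cohort) <- c("synthetic_cohort", "data.frame")
  cohort
}

#' Listwise deletion of incomplete admissions
#'
#' Removes every row with at least one missing cell, reporting the number
#' removed; the retained table is what the modelling functions accept.
#'
#' @param cohort Data frame, possibly with missing cells.
#' @return The complete-case subset, with the number of removed rows in
#'   attribute `n_removed`.
#' @export
apply_listwise_deletion <- function(cohort) {
  keep <- stats::complete.cases(cohort)
  removed <- sum(!keep)
  if (removed > 0) {
    message(removed, " of ", nrow(cohort),
            " admission(s) removed by listwise deletion")
  }
  if (!any(keep)) warning("all rows contained missing data; empty table returned")
  out <- cohort[keep, , drop = FALSE]
  attr(out, "n_removed") <- removed
  out
}
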