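#' Variable selection frequency across refitted models
#'
#' For each candidate variable and distribution parameter, the proportion
#' of refitted models in which any base learner of that variable updated
#' that additive predictor at least once before the algorithm stopped.
#'
#' @param models Either a list of `boosted_lss` models (their selection
#'   histories are scanned) or a `nested_cv` object (its stored selection
#'   flags are used; fits that failed are excluded from the denominator).
#' @return Data frame with columns `variable`, `parameter` (`"mu"` or
#'   `"sigma"`), and `frequency` in `[0, 1]`.
#' @export
selection_frequency <- function(models) {
  if (inherits(models, "nested_cv")) {
    ok <- !is.na(models$results$mstop)
    sel <- models$selection[ok, , , drop = FALSE]
    freq <- apply(sel, c(2, 3), mean)
  } else {
    if (!is.list(models) || length(models) == 0 ||
        !all(vapply(models, inherits, logical(1), "boosted_lss"))) {
      stop("'models' must be a non-empty list of boosted_lss models ",
           "or a nested_cv object")
    }
    vars <- unique(vapply(models[[1]]$baselearners, `[[`, "", "variable"))
    freq <- matrix(0, length(vars), 2, dimnames = list(vars, c("mu", "sigma")))
    for (m in models) {
      for (p in c("mu", "sigma")) {
        sel_vars <- unique(m$history$variable[m$history$parameter == p])
        freq[sel_vars, p] <- freq[sel_vars, p] + 1
      }
    }
    freq <- freq / length(models)
  }
  data.frame(
    variable = rep(rownames(freq), 2),
    parameter = rep(colnames(freq), each = nrow(freq)),
    frequency = c(freq[, 1], freq[, 2]),
    row.names = NULL
  )
}

# Default partial-dependence grid: 50 equally spaced points between the 1st
# and 99th percentile for numeric variables; {0, 1} for binary ones.
pd_default_grid <- function(model, variable, grid_length = 50) {
  data <- model$cohort
  if (is.null(data)) stop("model carries no training cohort")
  if (variable %in% binary_predictors()) return(c(0, 1))
  q <- stats::quantile(data[[variable]], c(0.01, 0.99), names = FALSE)
  seq(q[1], q[2], length.out = grid_length)
}

#' Partial dependence of a distribution parameter on one covariate
#'
#' Friedman partial dependence over the empirical covariate distribution:
#' for each grid value the variable is set to that value in every training
#' row, the model predicts, and the predicted parameter is averaged.
#'
#' @param model A `boosted_lss` fitted via [fit_factor_model()] (so that
#'   the training cohort is attached) or any `boosted_lss` plus `data`.
#' @param variable Candidate predictor name.
#' @param grid Grid of values; defaults to 50 points between the 1st and
#'   99th training percentiles (numeric) or `c(0, 1)` (binary).
#' @param parameter `"mu"` or `"sigma"`.
#' @param data Optional cohort data frame to marginalize over (defaults to
#'   the training cohort stored in the model).
#' @return Data frame with columns `variable`, `value` (grid), and the
#'   averaged predicted parameter in column `estimate`.
#' @export
partial_dependence_param <- function(model, variable, grid = NULL,
                                     parameter = c("mu", "sigma"),
                                     data = NULL) {
  parameter <- match.arg(parameter)
  data <- if (is.null(data)) model$cohort else data
  if (is.null(data)) stop("supply 'data' or fit via fit_factor_model()")
  if (!variable %in% c(binary_predictors(), numeric_predictors())) {
    stop("unknown candidate predictor: ", variable)
  }
  if (is.null(grid)) grid <- pd_default_grid(model, variable)
  est <- vapply(grid, function(g) {
    d <- data
    d[[variable]] <- g
    mean(predict(model, d)[[parameter]])
  }, numeric(1))
  data.frame(variable = variable, value = grid, estimate = est)
}

#' Partial dependence of the discretized score probabilities
#'
#' For each grid value, the predicted beta distribution of every training
#' row (with the variable set to that value) is discretized onto the
#' attainable totals via [discretize_pmf()] and the probability masses are
#' averaged, giving the marginal effect of the covariate on the probability
#' of each total.
#'
#' @inheritParams partial_dependence_param
#' @param factor Factor of the outcome; defaults to the factor stored in
#'   the model.
#' @return Long data frame with columns `variable`, `value`, `score`,
#'   `probability`; masses sum to 1 at every grid value.
#' @export
partial_dependence_scores <- function(model, variable, grid = NULL,
                                      factor = NULL, data = NULL) {
  f <- factor_definition(if (is.null(factor)) model$factor else factor)
  data <- if (is.null(data)) model$cohort else data
  if (is.null(data)) stop("supply 'data' or fit via fit_factor_model()")
  if (is.null(grid)) grid <- pd_default_grid(model, variable)
  scores <- attainable_scores(f)
  out <- lapply(grid, function(g) {
    d <- data
    d[[variable]] <- g
    pr <- predict(model, d)
    pmf <- vapply(seq_len(nrow(pr)),
                  function(i) discretize_pmf(pr$mu[i], pr$sigma[i], f),
                  numeric(length(scores)))
    data.frame(variable = variable, value = g, score = scores,
               probability = rowMeans(pmf))
  })
  do.call(rbind, out)
}
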