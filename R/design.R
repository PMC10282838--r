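#' Candidate predictor sets
#'
#' The seventeen admission covariates considered as candidate predictors:
#' nine binary indicators (coded 0/1, not centered) and eight numeric
#' variables (mean-centered), the latter including the five admission factor
#' totals.
#'
#' @name candidate_predictors
#' @return Character vectors of column names.
NULL

#' @rdname candidate_predictors
#' @export
binary_predictors <- function() {
  c("sex_male", "schizoaffective", "prior_clozapine", "clozapine",
    "polypharmacy", "antidepressant", "mood_stabilizer", "benzodiazepine",
    "anticholinergic")
}

#' @rdname candidate_predictors
#' @export
numeric_predictors <- function() {
  c("year", "age", "pdd_ddd",
    paste0("adm_", names(.panss_item_map)))
}

#' Encode a cohort table into a model design
#'
#' Binary covariates are passed through as 0/1 dummies; numeric covariates
#' are mean-centered. When `centers` is supplied (the constants recorded on
#' a training set), new rows are centered with those training constants so
#' that held-out data are encoded consistently.
#'
#' @param cohort Data frame with at least the seventeen candidate predictor
#'   columns (see [binary_predictors()] and [numeric_predictors()]). Missing
#'   values are an error: listwise deletion is a separate upstream step
#'   ([apply_listwise_deletion()]).
#' @param centers Optional named numeric vector of centering constants for
#'   the numeric covariates, as stored in a previous `encoded_design`.
#' @return An object of class `encoded_design`: list with the encoded
#'   matrix `x` (17 columns), `centers`, and the variable metadata.
#' @export
encode_cohort <- function(cohort, centers = NULL) {
  bvars <- binary_predictors()
  nvars <- numeric_predictors()
  missing_cols <- setdiff(c(bvars, nvars), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  sub <- cohort[c(bvars, nvars)]
  if (anyNA(sub)) {
    stop("cohort contains missing values; apply listwise deletion first ",
         "(see apply_listwise_deletion())")
  }
  for (v in bvars) {
    if (!all(sub[[v]] %in% c(0, 1))) {
      stop("binary covariate '", v, "' contains values outside {0, 1}")
    }
  }
  x <- as.matrix(sub)
  storage.mode(x) <- "double"
  if (is.null(centers)) {
    centers <- colMeans(x[, nvars, drop = FALSE])
  } else {
    if (!all(nvars %in% names(centers))) {
      stop("'centers' must name every numeric covariate")
    }
    centers <- centers[nvars]
  }
  x[, nvars] <- sweep(x[, nvars, drop = FALSE], 2L, centers)
  structure(
    list(x = x, centers = centers, binary_vars = bvars, numeric_vars = nvars),
    class = "encoded_design"
  )
}

#' @export
print.encoded_design <- function(x, ...) {
  cat(sprintf("encoded design: %d rows, %d binary + %d numeric covariates\n",
              nrow(x$x), length(x$binary_vars), length(x$numeric_vars)))
  invisible(x)
}

# ---- P-spline machinery -----------------------------------------------------

# Equally spaced cubic B-spline design with linear extension beyond the
# training range (prevents wild polynomial extrapolation on prediction grids).
ps_raw_basis <- function(x, xmin, xmax, nseg, degree) {
  h <- (xmax - xmin) / nseg
  kn <- xmin + h * seq.int(-degree, nseg + degree)
  xc <- pmin(pmax(x, xmin), xmax)
  B <- splines::splineDesign(kn, xc, ord = degree + 1, outer.ok = TRUE)
  lo <- which(x < xmin)
  hi <- which(x > xmax)
  if (length(lo)) {
    b0 <- splines::splineDesign(kn, xmin, ord = degree + 1, outer.ok = TRUE)
    d0 <- splines::splineDesign(kn, xmin, ord = degree + 1, derivs = 1L, outer.ok = TRUE)
    B[lo, ] <- rep(1, length(lo)) %o% drop(b0) + (x[lo] - xmin) %o% drop(d0)
  }
  if (length(hi)) {
    b1 <- splines::splineDesign(kn, xmax, ord = degree + 1, outer.ok = TRUE)
    d1 <- splines::splineDesign(kn, xmax, ord = degree + 1, derivs = 1L, outer.ok = TRUE)
    B[hi, ] <- rep(1, length(hi)) %o% drop(b1) + (x[hi] - xmax) %o% drop(d1)
  }
  B
}

# Reparameterize the difference penalty to a ridge: spectral decomposition of
# t(D) %*% D keeps the penalized directions and rescales them so the penalty
# becomes the identity. The null space (polynomials up to the penalty order)
# is dropped: its constant part belongs to the model offset and its linear
# part to the separate linear base learner, which also makes a target of one
# effective degree of freedom attainable.
ps_null_transform <- function(K, order) {
  D <- diff(diag(K), differences = order)
  e <- eigen(crossprod(D), symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  e$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(e$values[keep]))
}

# Solve sum(d / (d + lambda)) = df for lambda by bisection on log(lambda),
# expanding the bracket if needed. d are the eigenvalues of crossprod(X).
calibrate_lambda <- function(d, df, loglim = c(-12, 12), tol = 1e-8) {
  trace_fun <- function(loglam) sum(d / (d + exp(loglam))) - df
  lo <- loglim[1]; hi <- loglim[2]
  while (trace_fun(hi) > 0 && hi < 60) hi <- hi + 6
  while (trace_fun(lo) < 0 && lo > -60) lo <- lo - 6
  if (trace_fun(lo) < 0 || trace_fun(hi) > 0) {
    stop("degrees-of-freedom calibration failed: target df = ", df,
         " not bracketed; eigenvalue range [", min(d), ", ", max(d), "]")
  }
  r <- stats::uniroot(trace_fun, c(lo, hi), tol = tol)
  exp(r$root)
}

new_baselearner <- function(variable, kind, X, lambda, newdesign,
                            degenerate = FALSE) {
  p <- ncol(X)
  if (degenerate) {
    M <- matrix(0, p, nrow(X))
    df <- 0
  } else {
    M <- solve(crossprod(X) + diag(lambda, p), t(X))
    df <- sum(X * t(M)) # trace of the smoother matrix X (X'X + lambda I)^-1 X'
  }
  structure(
    list(variable = variable, kind = kind, X = X, M = M, lambda = lambda,
         df = df, newdesign = newdesign, degenerate = degenerate),
    class = "baselearner"
  )
}

#' @export
print.baselearner <- function(x, ...) {
  cat(sprintf("base learner: %s (%s), df = %.6f, lambda = %.4g%s\n",
              x$variable, x$kind, x$df, x$lambda,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Build the component-wise base learners for an encoded design
#'
#' One penalized linear base learner (single column, no intercept) is
#' specified for every candidate predictor, and one P-spline base learner
#' for every numeric predictor, giving 25 base learners per additive
#' predictor under the default candidate set. Every base learner is
#' calibrated to one effective degree of freedom (trace of its smoother
#' matrix) so that no learner is preferred merely for being more flexible:
#' a single-column linear learner is an unpenalized rank-one projection
#' (trace exactly 1), and each P-spline's ridge penalty on the
#' difference-penalized directions is tuned by bisection until its trace
#' equals the target.
#'
#' P-splines use cubic B-splines on 20 equally spaced interior knots over
#' the observed range with a second-order difference penalty,
#' reparameterized so that the penalty null space (constant and linear
#' trends, carried by the offset and the linear learner) is excluded.
#' Covariates that are constant in the data yield inert, never-selected
#' learners rather than an error, so that cross-validation folds with a
#' degenerate column remain usable.
#'
#' @param design An `encoded_design` from [encode_cohort()].
#' @param df Target effective degrees of freedom per base learner.
#' @param nseg Number of B-spline segments over the observed range
#'   (20 interior knots = 21 segments).
#' @param degree B-spline degree (3 = cubic).
#' @param penalty_order Order of the difference penalty.
#' @return List of `baselearner` objects (shared by both additive
#'   predictors; coefficients are accumulated per predictor by the
#'   boosting engine).
#' @export
build_baselearners <- function(design, df = 1, nseg = 21, degree = 3,
                               penalty_order = 2) {
  stopifnot(inherits(design, "encoded_design"))
  x <- design$x
  out <- list()
  for (v in colnames(x)) {
    xv <- x[, v]
    v_local <- v
    degen <- sum(xv^2) < 1e-12
    lin_new <- local({
      vv <- v_local
      function(newx) matrix(newx[, vv], ncol = 1L)
    })
    out[[length(out) + 1L]] <- new_baselearner(
      v, "linear", matrix(xv, ncol = 1L), lambda = 0,
      newdesign = lin_new, degenerate = degen
    )
  }
  for (v in design$numeric_vars) {
    xv <- x[, v]
    rng <- range(xv)
    if (diff(rng) < 1e-8) {
      out[[length(out) + 1L]] <- new_baselearner(
        v, "pspline", matrix(0, nrow(x), 1L), lambda = 0,
        newdesign = local(function(newx) matrix(0, nrow(newx), 1L)),
        degenerate = TRUE
      )
      next
    }
    B <- ps_raw_basis(xv, rng[1], rng[2], nseg, degree)
    Z <- ps_null_transform(ncol(B), penalty_order)
    Xt <- B %*% Z
    d <- eigen(crossprod(Xt), symmetric = TRUE, only.values = TRUE)$values
    lambda <- calibrate_lambda(d[d > max(d) * 1e-12], df)
    ps_new <- local({
      vv <- v; r1 <- rng[1]; r2 <- rng[2]; Zl <- Z
      ns <- nseg; dg <- degree
      function(newx) ps_raw_basis(newx[, vv], r1, r2, ns, dg) %*% Zl
    })
    out[[length(out) + 1L]] <- new_baselearner(v, "pspline", Xt, lambda, ps_new)
  }
  bad <- vapply(out, function(b) !b$degenerate && abs(b$df - df) > 1e-6,
                logical(1))
  if (any(bad)) {
    stop("degrees-of-freedom calibration failed for: ",
         paste(vapply(out[bad], `[[`, "", "variable"), collapse = ", "))
  }
  out
}

#' Fit a single base learner to a working response
#'
#' Penalized least squares with the smoothing constant fixed at
#' construction: `coef = (X'X + lambda I)^-1 X' z`.
#'
#' @param bl A `baselearner` from [build_baselearners()].
#' @param z Numeric target vector (typically a negative-gradient vector),
#'   of length equal to the number of design rows.
#' @return List with `coef`, `fitted`, and `sse` (squared error of fitted
#'   against target).
#' @export
fit_baselearner <- function(bl, z) {
  stopifnot(inherits(bl, "baselearner"))
  if (length(z) != nrow(bl$X)) {
    stop("target length ", length(z), " does not match design rows ", nrow(bl$X))
  }
  cf <- drop(bl$M %*% z)
  fitted <- drop(bl$X %*% cf)
  list(coef = cf, fitted = fitted, sse = sum((z - fitted)^2))
}
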