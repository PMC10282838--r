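#' Consensus five-factor PANSS structure
#'
#' The 30 PANSS items (P1-P7, N1-N7, G1-G16, each rated 1 = absent to
#' 7 = extreme) are grouped into five symptom dimensions following the
#' consensus five-factor solution: positive, negative, disorganized,
#' excited, and depressed. Twenty distinct items are assigned; the
#' remaining ten load on no factor.
#'
#' @return A named list of `panss_factor` objects, one per dimension.
#' @seealso [factor_definition()], [factor_total()], [rescale_total()]
#' @export
#' @examples
#' names(panss_factors())
#' panss_factors()$negative
panss_factors <- function() {
  out <- lapply(names(.panss_item_map), factor_definition)
  names(out) <- names(.panss_item_map)
  out
}

.panss_item_map <- list(
  positive     = c("P1", "P3", "P5", "G9"),
  negative     = c("N1", "N2", "N3", "N4", "N6", "G7"),
  disorganized = c("P2", "N5", "G11"),
  excited      = c("P4", "P7", "G8", "G14"),
  depressed    = c("G2", "G3", "G6")
)

new_factor_definition <- function(name, items) {
  stopifnot(is.character(name), length(name) == 1L, length(items) >= 1L)
  structure(
    list(name = name, items = items, n_items = length(items)),
    class = "panss_factor"
  )
}

#' Look up (or pass through) a PANSS factor definition
#'
#' @param factor Either the name of one of the five consensus factors
#'   (`"positive"`, `"negative"`, `"disorganized"`, `"excited"`,
#'   `"depressed"`) or a `panss_factor` object, which is returned unchanged.
#' @return A `panss_factor` object with fields `name`, `items`, `n_items`.
#'   Attainable totals are the integers in `[n_items, 7 * n_items]`.
#' @export
#' @examples
#' factor_definition("disorganized")
factor_definition <- function(factor) {
  if (inherits(factor, "panss_factor")) return(factor)
  if (!is.character(factor) || length(factor) != 1L ||
      !factor %in% names(.panss_item_map)) {
    stop("unknown PANSS factor: ", deparse(factor),
         "; expected one of ", paste(names(.panss_item_map), collapse = ", "))
  }
  new_factor_definition(factor, .panss_item_map[[factor]])
}

#' @export
print.panss_factor <- function(x, ...) {
  cat(sprintf("PANSS factor '%s': items %s (n = %d, totals %d..%d)\n",
              x$name, paste(x$items, collapse = ", "), x$n_items,
              x$n_items, 7L * x$n_items))
  invisible(x)
}

#' Attainable integer totals of a factor
#' @param factor A factor name or `panss_factor` object.
#' @return Integer vector `n:(7n)`.
#' @export
attainable_scores <- function(factor) {
  f <- factor_definition(factor)
  seq.int(f$n_items, 7L * f$n_items)
}

#' Sum item scores into a factor total
#'
#' @param item_scores Named numeric vector (or single-row data frame) of
#'   item scores keyed by item code (e.g. `c(P2 = 3, N5 = 2, G11 = 4)`).
#'   Every item of the factor must be present with an integer score in 1..7.
#' @param factor A factor name or `panss_factor` object.
#' @return The integer total, in `[n, 7n]`.
#' @export
#' @examples
#' factor_total(c(P2 = 3, N5 = 2, G11 = 4), "disorganized")
factor_total <- function(item_scores, factor) {
  f <- factor_definition(factor)
  if (is.data.frame(item_scores)) {
    stopifnot(nrow(item_scores) == 1L)
    item_scores <- unlist(item_scores[1L, , drop = TRUE])
  }
  missing <- setdiff(f$items, names(item_scores))
  if (length(missing)) {
    stop("missing PANSS item(s) for factor '", f$name, "': ",
         paste(missing, collapse = ", "))
  }
  sc <- item_scores[f$items]
  bad <- !is.finite(sc) | sc != round(sc) | sc < 1 | sc > 7
  if (any(bad)) {
    stop("item score out of range [1, 7] or non-integer: ",
         paste(sprintf("%s = %s", f$items[bad], sc[bad]), collapse = ", "))
  }
  as.integer(sum(sc))
}

#' Rescale a factor total to the half-open unit interval
#'
#' A total `y` on a factor with `n` items is mapped to
#' `(y - n + 1) / (7n - n + 1)`, i.e. a value in `(0, 1]`: the minimum
#' total `n` maps to `1/(6n+1) > 0` and the maximum `7n` maps to 1.
#' Values of exactly 1 are representable here but are rejected by the
#' likelihood-based fitting functions, which require the open interval.
#'
#' @param y Integer total(s) in `[n, 7n]`.
#' @param factor A factor name or `panss_factor` object.
#' @return Numeric vector of rescaled values in `(0, 1]`.
#' @export
#' @examples
#' rescale_total(16, "negative") # 11/37
rescale_total <- function(y, factor) {
  f <- factor_definition(factor)
  n <- f$n_items
  bad <- !is.finite(y) | y != round(y) | y < n | y > 7 * n
  if (any(bad)) {
    stop("total(s) outside attainable range [", n, ", ", 7 * n, "] for factor '",
         f$name, "': ", paste(y[bad], collapse = ", "))
  }
  (y - n + 1) / (6 * n + 1)
}

#' Map a unit-interval value back to the nearest attainable total
#'
#' Inverse of [rescale_total()] extended to the whole of `(0, 1]`: returns
#' the attainable integer total whose rescaled value is nearest to `r`,
#' breaking ties toward the smaller total. Round-trips exactly:
#' `unrescale(rescale_total(y, f), f) == y` for every attainable `y`.
#'
#' @param r Numeric vector with values in `(0, 1]`.
#' @param factor A factor name or `panss_factor` object.
#' @return Integer vector of totals.
#' @export
#' @examples
#' unrescale(0.30, "negative")
unrescale <- function(r, factor) {
  f <- factor_definition(factor)
  n <- f$n_items
  if (any(!is.finite(r) | r <= 0 | r > 1)) {
    stop("rescaled value(s) must lie in (0, 1]")
  }
  # continuous preimage of r, then choose the nearer of its two neighbours
  ycont <- r * (6 * n + 1) + n - 1
  lo <- pmin(pmax(floor(ycont), n), 7 * n)
  hi <- pmin(lo + 1, 7 * n)
  pick_hi <- (ycont - lo) > (hi - ycont) # strict: ties go to the smaller score
  as.integer(ifelse(pick_hi, hi, lo))
}

#' Discretize a predictive beta distribution onto attainable totals
#'
#' A continuous beta prediction on the rescaled `(0, 1)` outcome scale is
#' converted to a probability mass function over the attainable integer
#' totals of a factor. Each total `y` receives the beta probability of the
#' interval between bin edges placed midway between consecutive rescaled
#' values, with the outer edges pinned at exactly 0 and 1, so the masses
#' telescope to 1.
#'
#' @param mu,sigma Mean and scale of the beta distribution, both strictly
#'   inside (0, 1); see [beta_shapes()].
#' @param factor A factor name or `panss_factor` object.
#' @return Named numeric vector of probabilities; names are the totals.
#' @export
#' @examples
#' p <- discretize_pmf(0.4, 0.3, "depressed")
#' sum(p)
discretize_pmf <- function(mu, sigma, factor) {
  f <- factor_definition(factor)
  n <- f$n_items
  sh <- beta_shapes(mu, sigma)
  edges <- score_bin_edges(f)
  p <- diff(stats::pbeta(edges, sh$shape1, sh$shape2))
  names(p) <- as.character(attainable_scores(f))
  p
}

# Bin edges for the discretization: interior edges midway between consecutive
# rescaled totals, outer edges at exactly 0 and 1. Length 6n + 2.
score_bin_edges <- function(factor) {
  f <- factor_definition(factor)
  n <- f$n_items
  m <- 6 * n + 1
  c(0, (seq_len(6 * n) + 0.5) / m, 1)
}

# Cumulative discretized probabilities P(Y <= y) for observed totals,
# used by the PIT machinery. Returns cbind(F_lo, F_hi) with
# F_lo = P(Y <= y - 1), F_hi = P(Y <= y).
score_cdf_pair <- function(mu, sigma, y, factor) {
  f <- factor_definition(factor)
  n <- f$n_items
  bad <- !is.finite(y) | y != round(y) | y < n | y > 7 * n
  if (any(bad)) stop("observed total(s) not attainable for factor '", f$name, "'")
  stopifnot(length(mu) == length(y), length(sigma) == length(y))
  edges <- score_bin_edges(f)
  k <- y - n + 1L # index of the observed score, 1..6n+1
  sh <- beta_shapes(mu, sigma)
  f_lo <- stats::pbeta(edges[k], sh$shape1, sh$shape2)
  f_hi <- stats::pbeta(edges[k + 1L], sh$shape1, sh$shape2)
  cbind(f_lo = f_lo, f_hi = f_hi)
}
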