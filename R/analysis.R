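#' Run the end-to-end analysis for one or more factors
#'
#' Composes the full pipeline for each requested factor: tuning of the
#' stopping iteration by inner cross-validation on all data, a final model
#' fit at the tuned value, repeated nested cross-validation for internal
#' validation, variable selection frequencies, partial-dependence curves
#' for the distribution parameters, and a pooled PIT calibration
#' histogram. All artifacts are written to `out_dir` as plain CSV/JSON
#' with a manifest recording the seed and settings, so that a run is
#' reproducible from the manifest alone (outputs of two runs with the same
#' configuration are byte-identical).
#'
#' @param cohort Cohort data frame, or `NULL` to read `input`.
#' @param input Optional path to a cohort CSV in the schema of
#'   [generate_cohort()] (candidate predictors plus `dis_<factor>`
#'   columns). Listwise deletion is applied after reading.
#' @param factors Character vector of factor names (default: all five).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for every random element of the run.
#' @param repeats,outer_k,inner_k Nested cross-validation settings
#'   (the full-scale procedure uses 100, 10, 10).
#' @param grid Candidate `mstop` grid (full scale: `1:1000`).
#' @param nu Step length (fixed at one-tenth in the fitting procedure).
#' @param pd_variables Variables for parameter-scale partial dependence
#'   curves; defaults to every variable selected by the final model.
#' @return Invisibly, a named list per factor with components `model`,
#'   `mstop`, `cv` (the `nested_cv` object), `selection`, and `pit`.
#' @export
run_full_analysis <- function(cohort = NULL, input = NULL,
                              factors = names(.panss_item_map),
                              out_dir, seed = 1,
                              repeats = 100, outer_k = 10, inner_k = 10,
                              grid = 1:1000, nu = 0.1,
                              pd_variables = NULL) {
  if (is.null(cohort)) {
    if (is.null(input)) stop("supply 'cohort' or 'input'")
    cohort <- utils::read.csv(input)
  }
  bad <- setdiff(c(binary_predictors(), numeric_predictors(),
                   paste0("dis_", factors)), names(cohort))
  if (length(bad)) {
    stop("input violates the cohort schema; missing column(s): ",
         paste(bad, collapse = ", "))
  }
  cohort <- apply_listwise_deletion(cohort)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  bundles <- list()
  for (fn in factors) {
    f <- factor_definition(fn)
    fdir <- file.path(out_dir, fn)
    if (!dir.exists(fdir)) dir.create(fdir)
    set.seed(seed)
    mstop <- select_mstop(cohort, f, grid = grid, k = inner_k, nu = nu)
    model <- fit_factor_model(cohort, f, mstop = as.integer(mstop), nu = nu)
    cv <- nested_cv(cohort, f, repeats = repeats, k = outer_k,
                    inner_k = inner_k, grid = grid, nu = nu, seed = seed)
    sel <- selection_frequency(cv)
    hist <- pit_histogram(cv$pit)

    utils::write.csv(model$history, file.path(fdir, "selection_history.csv"),
                     row.names = FALSE)
    utils::write.csv(cv$results, file.path(fdir, "nested_cv_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(sel, file.path(fdir, "selection_frequency.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(bin_lower = hist$edges[-length(hist$edges)],
                 bin_upper = hist$edges[-1], mass = hist$masses),
      file.path(fdir, "pit_histogram.csv"), row.names = FALSE)

    pdv <- if (is.null(pd_variables)) unique(model$history$variable)
           else pd_variables
    if (length(pdv)) {
      pd <- do.call(rbind, lapply(pdv, function(v) {
        rbind(cbind(parameter = "mu",
                    partial_dependence_param(model, v, parameter = "mu")),
              cbind(parameter = "sigma",
                    partial_dependence_param(model, v, parameter = "sigma")))
      }))
      utils::write.csv(pd, file.path(fdir, "partial_dependence.csv"),
                       row.names = FALSE)
    }
    ok <- !is.na(cv$results$mstop)
    jsonlite::write_json(
      list(factor = fn, n = nrow(cohort), mstop = as.integer(mstop),
           pseudo_r2_full = pseudo_r2(model$y, model$eta_mu),
           rmse_full = rmse_logit(model$y, model$eta_mu),
           cv_pseudo_r2_train = mean(cv$results$r2_train[ok]),
           cv_pseudo_r2_test = mean(cv$results$r2_test[ok]),
           cv_rmse_train = mean(cv$results$rmse_train[ok]),
           cv_rmse_test = mean(cv$results$rmse_test[ok]),
           optimism = as.list(cv$optimism)),
      file.path(fdir, "summary.json"), auto_unbox = TRUE, digits = NA)

    bundles[[fn]] <- list(model = model, mstop = as.integer(mstop), cv = cv,
                          selection = sel, pit = hist)
  }
  jsonlite::write_json(
    list(package = "panssboost",
         version = as.character(utils::packageVersion("panssboost")),
         seed = seed, factors = factors, n = nrow(cohort),
         settings = list(repeats = repeats, outer_k = outer_k,
                         inner_k = inner_k, grid = range(grid), nu = nu)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(bundles)
}
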