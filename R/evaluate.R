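#' Validation of the combined equation
#'
#' Leave-one-diet-out cross-validation, leave-one-equation-out sensitivity
#' analysis, and the end-to-end pipeline.
#'
#' @name equation-validation
#' @keywords internal
NULL

#' Predict emissions from energy and fibre content
#'
#' Convenience front end for the two-predictor combined equation:
#' `b0 + b_ME * me + b_NDF * ndf`.
#'
#' @param me_conc Metabolisable energy concentration, MJ/kg DM.
#' @param ndf_pct Neutral detergent fibre, percent of DM.
#' @param eq A `combined_equation` with `ME` and `NDF` slopes; defaults to
#'   the packaged reference coefficients (0.33, 0.31, 3.47).
#' @return Predicted emission, g CH4/kg DM (vectorised).
#' @export
predict_combined <- function(me_conc, ndf_pct, eq = reference_combined()) {
  if (any(!is.finite(me_conc)) || any(!is.finite(ndf_pct)) ||
      any(me_conc < 0) || any(ndf_pct < 0)) {
    stop("me_conc and ndf_pct must be finite and non-negative")
  }
  if (!all(c("ME", "NDF") %in% names(eq$slopes))) {
    stop("equation does not carry ME and NDF slopes")
  }
  eq$intercept + eq$slopes[["ME"]] * me_conc + eq$slopes[["NDF"]] * ndf_pct
}

#' Leave-one-diet-out cross-validation
#'
#' Each diet is held out in turn; the mixed model is refitted on the
#' remaining diets and the held-out records are predicted as the raw-scale
#' fixed-effect part plus the training-estimated random intercept of each
#' equation (the equations are the same groups across diets). Per-diet
#' performance is `R2 = 1 - SSE/SST` over the held-out records (so that
#' between-equation spread within the diet sets the yardstick) and RMSE;
#' squared correlation is available as an alternative.
#'
#' @param preds A `prediction_set` with at least 3 diets.
#' @param predictors Predictor names, e.g. `c("ME", "NDF")`.
#' @param r2_method `"one_minus_sse"` (default) or `"squared_cor"`.
#' @return A `cv_report`: per-diet data frame (`diet_id`, `r2`, `rmse`,
#'   `converged`) with aggregate attributes `mean_r2`, `median_r2`,
#'   `min_r2`, `max_r2`, `mean_rmse`, `min_rmse`, `max_rmse` computed over
#'   the converged rows.
#' @export
loo_diet_cv <- function(preds, predictors,
                        r2_method = c("one_minus_sse", "squared_cor")) {
  r2_method <- match.arg(r2_method)
  ids <- unique(preds$diet_id)
  if (length(ids) < 3L) stop("leave-one-diet-out needs at least 3 diets")
  rows <- lapply(ids, function(d) {
    train <- preds[preds$diet_id != d, ]
    test <- preds[preds$diet_id == d, ]
    fit <- fit_mixed(train, predictors)
    if (!fit$converged) {
      return(data.frame(diet_id = d, r2 = NA_real_, rmse = NA_real_,
                        converged = FALSE, stringsAsFactors = FALSE))
    }
    raw <- back_transform(fit)
    yhat <- predict(raw, test) + unname(fit$u_i[test$eq_id])
    y <- test$ch4_g_per_kg_dm
    r2 <- if (r2_method == "one_minus_sse") {
      1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
    } else {
      stats::cor(y, yhat)^2
    }
    data.frame(diet_id = d, r2 = r2, rmse = sqrt(mean((y - yhat)^2)),
               converged = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(!out$converged)) {
    warning("refit failed to converge for diet(s): ",
            paste(out$diet_id[!out$converged], collapse = ", "),
            "; excluded from aggregates")
  }
  ok <- out[out$converged, ]
  if (nrow(ok) == 0L) stop("no per-diet refit converged")
  structure(out, class = c("cv_report", "data.frame"),
            mean_r2 = mean(ok$r2), median_r2 = stats::median(ok$r2),
            min_r2 = min(ok$r2), max_r2 = max(ok$r2),
            mean_rmse = mean(ok$rmse), min_rmse = min(ok$rmse),
            max_rmse = max(ok$rmse))
}

#' Leave-one-equation-out sensitivity analysis
#'
#' Removes each source equation in turn, refits the mixed model, and
#' tabulates the back-transformed raw-scale coefficients. The reported
#' ranges always bracket the full-data coefficients.
#'
#' @param preds A `prediction_set` with at least 3 equations.
#' @param predictors Predictor names.
#' @return A `sensitivity_report`: one row per removed equation with the
#'   raw intercept and slopes; attributes `full` (full-data coefficients)
#'   and `ranges` (min/max per coefficient over removals and the full fit).
#' @export
sensitivity_loo_equation <- function(preds, predictors) {
  ids <- unique(preds$eq_id)
  if (length(ids) < 3L) stop("sensitivity analysis needs at least 3 equations")
  full <- back_transform(fit_mixed(preds, predictors))
  rows <- lapply(ids, function(e) {
    fit <- fit_mixed(preds[preds$eq_id != e, ], predictors)
    raw <- back_transform(fit)
    cbind(data.frame(eq_removed = e, intercept = raw$intercept,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(raw$slopes)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  coef_cols <- setdiff(names(out), "eq_removed")
  full_vec <- c(intercept = full$intercept, full$slopes)[coef_cols]
  ranges <- data.frame(coefficient = coef_cols,
                       full = unname(full_vec),
                       min = vapply(coef_cols,
                                    function(cl) min(out[[cl]], full_vec[[cl]]), 0),
                       max = vapply(coef_cols,
                                    function(cl) max(out[[cl]], full_vec[[cl]]), 0),
                       stringsAsFactors = FALSE)
  rownames(ranges) <- NULL
  structure(out, class = c("sensitivity_report", "data.frame"),
            full = full_vec, ranges = ranges)
}

#' Run the full combination pipeline
#'
#' Load (or accept) diets and registry, complete the diets, apply every
#' equation, screen collinearity, fit the twelve candidate models, select
#' and back-transform the combined equation, cross-validate and run the
#' sensitivity analysis, writing all tables plus a reproducibility
#' manifest into a run directory.
#'
#' @param out_dir Output directory (created if absent).
#' @param diets A `diet_set`; defaults to the packaged 15 diets.
#' @param registry An `equation_registry`; defaults to the packaged 32.
#' @param completion A [completion_config()]; its seed defaults to `seed`.
#' @param seed Integer seed recorded in the manifest and used for the
#'   completion when `completion` is not supplied.
#' @param model `"auto"` (select by the significance/parsimony rule) or a
#'   candidate model id `"1"`..`"12"` to force.
#' @param exclude_dry Drop dry-cow diets before fitting (default `FALSE`).
#' @param r2_method Passed to [loo_diet_cv()].
#' @return Invisibly, a list with all intermediate results.
#' @export
run_pipeline <- function(out_dir, diets = packaged_diets(),
                         registry = packaged_registry(),
                         completion = NULL, seed = 42L, model = "auto",
                         exclude_dry = FALSE,
                         r2_method = "one_minus_sse") {
  if (is.null(completion)) completion <- completion_config(seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  completed <- step("complete", complete_diets(diets, completion))
  if (exclude_dry) completed <- completed[completed$cohort != "dry", ]
  preds <- step("apply_all", apply_all(registry, completed))
  extremes <- step("diet_extremes", diet_extremes(preds))
  screen <- step("screen", screen_collinearity(
    completed, c("ME", "GE", "NDF", "ADF", "CP", "EE", "FA")))
  fits <- step("fit", lapply(names(candidate_models()), function(id) {
    fit_mixed(preds, candidate_models()[[id]], model_id = id)
  }))
  selection <- step("select", select_model(fits))
  if (!identical(model, "auto")) {
    forced <- which(vapply(fits, function(f)
      identical(as.character(f$model_id), as.character(model)), TRUE))
    if (length(forced) == 0L) stop("pipeline stage 'select' failed: ",
                                   "unknown model id ", model, call. = FALSE)
    slopes <- fits[[forced]]$fixef[fits[[forced]]$fixef$term != "Intercept", ]
    selection$model_id <- as.character(model)
    selection$fit <- fits[[forced]]
    selection$all_significant <- all(abs(slopes$t) > 2)
  }
  combined <- step("back_transform", back_transform(selection$fit))
  cv <- step("cv", loo_diet_cv(preds, selection$fit$predictors,
                               r2_method = r2_method))
  sens <- step("sensitivity",
               sensitivity_loo_equation(preds, selection$fit$predictors))
  model_vif <- step("vif", vif(preds, selection$fit$predictors))

  num <- function(x) round(x, 6)
  write_tab <- function(df, file) {
    utils::write.csv(df, file.path(out_dir, file), row.names = FALSE,
                     quote = FALSE)
  }
  pred_out <- as.data.frame(preds)
  pred_out[-(1:2)] <- lapply(pred_out[-(1:2)], num)
  write_tab(pred_out, "predictions.csv")
  ext_out <- transform(extremes, min = num(min), max = num(max))
  write_tab(ext_out, "diet_extremes.csv")
  write_tab(transform(selection$comparison, r2 = num(r2), rmse = num(rmse),
                      sigma2_equation = num(sigma2_equation),
                      sigma2_resid = num(sigma2_resid)),
            "model_comparison.csv")
  write_tab(data.frame(coefficient = c("intercept", names(combined$slopes)),
                       value = num(c(combined$intercept, combined$slopes))),
            "combined_equation.csv")
  write_tab(data.frame(eq_id = names(selection$fit$u_i),
                       u_i = num(unname(selection$fit$u_i))),
            "random_intercepts.csv")
  cv_out <- as.data.frame(cv)
  cv_out$r2 <- num(cv_out$r2); cv_out$rmse <- num(cv_out$rmse)
  write_tab(cv_out, "cv_per_diet.csv")
  sens_out <- as.data.frame(sens)
  sens_out[-1] <- lapply(sens_out[-1], num)
  write_tab(sens_out, "sensitivity.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("ch4combine")),
    seed = seed,
    completion = completion[setdiff(names(completion), "dmi_by_cohort")],
    dmi_by_cohort = completion$dmi_by_cohort,
    exclude_dry = exclude_dry,
    model = selection$model_id,
    model_forced = !identical(model, "auto"),
    all_slopes_significant = selection$all_significant,
    n_equations = length(registry),
    n_diets = nrow(completed),
    n_predictions = nrow(preds),
    retained_variables = screen$retained,
    vif = as.list(num(model_vif)),
    combined_equation = c(list(intercept = num(combined$intercept)),
                          as.list(num(combined$slopes))),
    sigma2_equation = num(selection$fit$sigma2_equation),
    sigma2_resid = num(selection$fit$sigma2_resid),
    between_equation_sd =
      num(between_equation_sd(selection$fit$sigma2_equation)),
    r2 = num(selection$fit$r2), rmse = num(selection$fit$rmse),
    cv = list(mean_r2 = num(attr(cv, "mean_r2")),
              median_r2 = num(attr(cv, "median_r2")),
              min_r2 = num(attr(cv, "min_r2")),
              max_r2 = num(attr(cv, "max_r2")),
              mean_rmse = num(attr(cv, "mean_rmse")),
              min_rmse = num(attr(cv, "min_rmse")),
              max_rmse = num(attr(cv, "max_rmse"))),
    sensitivity_ranges = attr(sens, "ranges"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(completed = completed, predictions = preds,
                 extremes = extremes, screen = screen, fits = fits,
                 selection = selection, combined = combined, cv = cv,
                 sensitivity = sens, vif = model_vif, manifest = manifest))
}
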