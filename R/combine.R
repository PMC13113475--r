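#' Deriving the combined prediction equation
#'
#' The long equation-by-diet prediction table is modelled with a
#' random-intercept linear mixed model,
#' `y_ij = b0 + b1 * ME_ij + ... + u_i + e_ij`, where `y_ij` is the
#' emission (g CH4/kg DM) predicted by equation `i` for diet `j`,
#' `u_i ~ N(0, sigma_equation^2)` captures between-equation heterogeneity
#' and `e_ij ~ N(0, sigma^2)` is residual error. Predictors are centred
#' and scaled before fitting and the coefficients back-transformed to raw
#' units afterwards.
#'
#' @name equation-combination
#' @keywords internal
NULL

PREDICTOR_COLUMNS <- c(ME = "me_conc", GE = "ge_conc", NDF = "ndf_pct",
                       ADF = "adf_pct", CP = "cp_pct", EE = "ee_pct",
                       FA = "fa_pct", ASH = "ash_pct", FORAGE = "forage_pct",
                       MEI = "mei", DMI = "dmi")

predictor_column <- function(vars, data) {
  cols <- ifelse(vars %in% names(PREDICTOR_COLUMNS),
                 PREDICTOR_COLUMNS[vars], vars)
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop("predictor column(s) not found: ", paste(missing, collapse = ", "))
  }
  stats::setNames(cols, vars)
}

#' Centre and scale predictor columns
#'
#' Each predictor is centred by its mean and divided by its sample
#' (n-1) standard deviation computed over the full long table, one row
#' per prediction record. The response is never standardized.
#'
#' @param preds A `prediction_set` (or any data frame holding the
#'   predictor columns).
#' @param predictors Character vector of predictor names (short names
#'   `ME`, `GE`, `NDF`, `ADF`, `CP`, `EE`, `FA` or raw column names).
#' @return List with `design` (data frame of standardized columns named by
#'   the short names) and `scaling` (a `scaling_params` data frame with
#'   `predictor`, `mean`, `sd`).
#' @export
standardize <- function(preds, predictors) {
  cols <- predictor_column(predictors, preds)
  mu <- vapply(cols, function(cl) mean(preds[[cl]]), 0)
  sdev <- vapply(cols, function(cl) stats::sd(preds[[cl]]), 0)
  zero <- sdev <= 0 | !is.finite(sdev)
  if (any(zero)) {
    stop("zero-variance predictor(s): ",
         paste(names(cols)[zero], collapse = ", "))
  }
  design <- as.data.frame(
    lapply(seq_along(cols),
           function(j) (preds[[cols[j]]] - mu[j]) / sdev[j]))
  names(design) <- names(cols)
  scaling <- data.frame(predictor = names(cols), mean = unname(mu),
                        sd = unname(sdev), stringsAsFactors = FALSE)
  class(scaling) <- c("scaling_params", "data.frame")
  list(design = design, scaling = scaling)
}

#' Invert standardization
#'
#' @param design Data frame of standardized columns as produced by
#'   [standardize()].
#' @param scaling The matching `scaling_params`.
#' @return Data frame on the original scale.
#' @export
invert_standardize <- function(design, scaling) {
  out <- design
  for (j in seq_len(nrow(scaling))) {
    nm <- scaling$predictor[j]
    out[[nm]] <- design[[nm]] * scaling$sd[j] + scaling$mean[j]
  }
  out
}

#' Screen diet variables for collinearity
#'
#' Computes the pairwise Pearson correlation matrix over the diet-level
#' values, groups variables whose absolute correlation exceeds the
#' threshold into clusters (connected components), and retains one
#' representative per cluster by priority order.
#'
#' @param diets A `completed_diet_set` (or `diet_set` if only profile
#'   variables are screened); at least 3 diets.
#' @param variables Predictor names to screen.
#' @param threshold Absolute-correlation cutoff, default 0.75.
#' @param priority Preference order for cluster representatives; earlier
#'   wins. Default keeps NDF over ADF and ME over GE.
#' @return List with `correlation` (matrix), `clusters` (list of grouped
#'   variable sets, singletons omitted) and `retained` (character vector).
#' @export
screen_collinearity <- function(diets, variables,
                                threshold = 0.75,
                                priority = c("NDF", "ME", "GE", "ADF", "CP",
                                             "EE", "FA")) {
  if (nrow(diets) < 3L) stop("need at least 3 diets to screen correlations")
  cols <- predictor_column(variables, diets)
  X <- as.data.frame(lapply(cols, function(cl) diets[[cl]]))
  names(X) <- names(cols)
  const <- vapply(X, function(x) stats::sd(x) == 0, TRUE)
  if (any(const)) {
    stop("constant column(s): ", paste(names(X)[const], collapse = ", "))
  }
  cm <- stats::cor(X)
  adj <- abs(cm) > threshold
  diag(adj) <- FALSE
  # connected components over the high-correlation graph
  comp <- rep(NA_integer_, ncol(cm))
  k <- 0L
  for (i in seq_along(comp)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  groups <- split(colnames(cm), comp)
  clusters <- Filter(function(g) length(g) > 1L, groups)
  pick <- function(g) {
    ranked <- match(g, priority)
    if (all(is.na(ranked))) g[1] else g[which.min(ranked)]
  }
  retained <- unname(vapply(groups, pick, ""))
  retained <- colnames(cm)[colnames(cm) %in% retained] # original order
  list(correlation = cm, clusters = unname(clusters), retained = retained)
}

#' The twelve candidate predictor combinations
#'
#' After collinearity screening, twelve combinations of the surviving
#' dietary variables (always including NDF, and an energy proxy GE or ME
#' in all but two) are fitted and compared.
#'
#' @return Named list of 12 character vectors, names `"1"`..`"12"`.
#' @export
candidate_models <- function() {
  list(`1` = c("ME", "NDF"),
       `2` = c("GE", "NDF"),
       `3` = c("NDF", "EE"),
       `4` = c("ME", "NDF", "FA"),
       `5` = c("ME", "NDF", "EE"),
       `6` = c("ME", "CP", "NDF"),
       `7` = c("GE", "CP", "NDF"),
       `8` = c("GE", "NDF", "FA"),
       `9` = c("GE", "NDF", "EE"),
       `10` = c("CP", "NDF", "FA", "EE"),
       `11` = c("GE", "CP", "NDF", "FA", "EE"),
       `12` = c("ME", "CP", "NDF", "FA", "EE"))
}

#' Fit the random-intercept mixed model
#'
#' Fits (REML, via [lme4::lmer()]) the model
#' `y ~ predictors + (1 | eq_id)` on the long prediction table, with the
#' predictors standardized by default. Reports fixed effects with standard
#' errors and t-values (`estimate/SE`), the random-intercept BLUPs per
#' equation, both variance components, and fit metrics: R-squared as the
#' squared Pearson correlation between observations and fitted values
#' including the random intercepts, and RMSE as the root mean squared
#' residual on the same fitted values.
#'
#' @param preds A `prediction_set` with at least 2 equations and 2 diets.
#' @param predictors Predictor names (see [standardize()]).
#' @param model_id Optional label carried through to reports.
#' @param scale_predictors Standardize before fitting (default `TRUE`).
#'   With `FALSE` the model is fitted on raw columns and the scaling is
#'   the identity, so [back_transform()] returns the fitted coefficients.
#' @param control An [lme4::lmerControl()] for the optimizer.
#' @return A `mixed_fit` object.
#' @export
fit_mixed <- function(preds, predictors, model_id = NA,
                      scale_predictors = TRUE,
                      control = lme4::lmerControl()) {
  if (length(unique(preds$eq_id)) < 2L || length(unique(preds$diet_id)) < 2L) {
    stop("need at least 2 equations and 2 diets to fit the mixed model")
  }
  if (scale_predictors) {
    std <- standardize(preds, predictors)
  } else {
    cols <- predictor_column(predictors, preds)
    design <- as.data.frame(lapply(cols, function(cl) preds[[cl]]))
    names(design) <- names(cols)
    scaling <- data.frame(predictor = names(cols),
                          mean = 0, sd = 1, stringsAsFactors = FALSE)
    class(scaling) <- c("scaling_params", "data.frame")
    std <- list(design = design, scaling = scaling)
  }
  dat <- cbind(data.frame(.y = preds$ch4_g_per_kg_dm,
                          .eq = preds$eq_id,
                          stringsAsFactors = FALSE),
               std$design)
  fml <- stats::as.formula(paste(".y ~",
                                 paste(names(std$design), collapse = " + "),
                                 "+ (1 | .eq)"))
  messages <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = dat, REML = TRUE, control = control),
    warning = function(w) {
      messages <<- c(messages, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      messages <<- c(messages, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  # optimizer status is authoritative; lme4's post-fit gradient/Hessian
  # heuristics are recorded but can false-alarm on near-degenerate data
  # code -4 (NLOPT_ROUNDOFF_LIMITED) means the optimizer stopped at machine
  # precision; the minimum is still valid — seen only on noise-free data
  opt_code <- fit@optinfo$conv$opt
  converged <- (is.null(opt_code) || opt_code %in% c(0L, -4L)) &&
    !any(grepl("pwrssUpdate|step-halving", messages))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  fixef_tab <- data.frame(term = names(est), estimate = unname(est),
                          se = unname(se), t = unname(est / se),
                          stringsAsFactors = FALSE)
  fixef_tab$term[fixef_tab$term == "(Intercept)"] <- "Intercept"
  vc <- lme4::VarCorr(fit)
  sigma2_eq <- as.numeric(vc$.eq)
  sigma2_resid <- stats::sigma(fit)^2
  re <- lme4::ranef(fit)$.eq
  u_i <- stats::setNames(re[["(Intercept)"]], rownames(re))
  fitted_full <- stats::fitted(fit)
  resid <- dat$.y - fitted_full
  result <- structure(list(
    model_id = model_id,
    predictors = predictors,
    fixef = fixef_tab,
    u_i = u_i,
    sigma2_equation = sigma2_eq,
    sigma2_resid = sigma2_resid,
    r2 = stats::cor(fitted_full, dat$.y)^2,
    rmse = sqrt(mean(resid^2)),
    scaling = std$scaling,
    converged = converged,
    boundary = sigma2_eq < 1e-8,
    messages = messages,
    n_obs = nrow(dat),
    fit = fit), class = "mixed_fit")
  result
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("Random-intercept mixed fit",
      if (!is.na(x$model_id)) paste0("(model ", x$model_id, ")"), "\n")
  cat("  predictors:", paste(x$predictors, collapse = " + "), "\n")
  print(transform(x$fixef, estimate = round(estimate, 3),
                  se = round(se, 3), t = round(t, 2)), row.names = FALSE)
  cat(sprintf("  sigma2_equation = %.3f, sigma2_resid = %.3f\n",
              x$sigma2_equation, x$sigma2_resid))
  cat(sprintf("  R2 = %.3f, RMSE = %.3f, converged = %s\n",
              x$r2, x$rmse, x$converged))
  invisible(x)
}

#' Back-transform standardized coefficients to raw units
#'
#' Slopes on the standardized scale are divided by the predictor's
#' standard deviation, `b_raw = b_std / SD(X)`, and the raw intercept
#' reintroduces the predictor means,
#' `b0_raw = b0_std - sum_j b_std_j * mean(X_j) / SD(X_j)`.
#'
#' @param fit A `mixed_fit`.
#' @return A `combined_equation`: raw intercept and slopes (response
#'   g CH4/kg DM; ME in MJ/kg DM, NDF in percent of DM) with provenance.
#' @export
back_transform <- function(fit) {
  if (is.null(fit$scaling)) stop("fit carries no scaling parameters")
  sc <- fit$scaling
  b0 <- fit$fixef$estimate[fit$fixef$term == "Intercept"]
  slopes_std <- fit$fixef[fit$fixef$term != "Intercept", ]
  idx <- match(slopes_std$term, sc$predictor)
  if (any(is.na(idx))) stop("scaling parameters missing for some predictors")
  slopes_raw <- slopes_std$estimate / sc$sd[idx]
  intercept_raw <- b0 - sum(slopes_std$estimate * sc$mean[idx] / sc$sd[idx])
  combined_equation(intercept = intercept_raw,
                    slopes = stats::setNames(slopes_raw, slopes_std$term),
                    model_id = fit$model_id, scaling = sc)
}

#' Construct a combined prediction equation
#'
#' @param intercept Raw-scale intercept, g CH4/kg DM.
#' @param slopes Named numeric vector of raw-scale slopes.
#' @param model_id,scaling Provenance carried along from the fit.
#' @return A `combined_equation`.
#' @export
combined_equation <- function(intercept, slopes, model_id = NA,
                              scaling = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(slopes), !is.null(names(slopes)))
  structure(list(intercept = intercept, slopes = slopes,
                 model_id = model_id, scaling = scaling),
            class = "combined_equation")
}

#' The packaged reference combined equation
#'
#' The published combined prediction:
#' `CH4 (g/kg DM) = 0.33 * ME + 0.31 * NDF + 3.47`, with ME in MJ/kg DM
#' and NDF in percent of DM.
#'
#' @return A `combined_equation` with the printed coefficients.
#' @export
reference_combined <- function() {
  combined_equation(intercept = 3.47, slopes = c(ME = 0.33, NDF = 0.31),
                    model_id = "reference")
}

#' @export
print.combined_equation <- function(x, ...) {
  terms <- paste(sprintf("%.4g * %s", x$slopes, names(x$slopes)),
                 collapse = " + ")
  cat(sprintf("CH4 (g/kg DM) = %s + %.4g\n", terms, x$intercept))
  invisible(x)
}

#' Predict from a combined equation
#'
#' @param object A `combined_equation`.
#' @param newdata Data frame holding the predictor columns (short names
#'   or the prediction-table column names).
#' @param ... Unused.
#' @return Numeric vector, g CH4/kg DM.
#' @export
predict.combined_equation <- function(object, newdata, ...) {
  vars <- names(object$slopes)
  vals <- vapply(vars, function(v) {
    col <- if (v %in% names(newdata)) v else PREDICTOR_COLUMNS[[v]]
    if (is.null(col) || !col %in% names(newdata)) {
      stop("newdata lacks predictor ", v)
    }
    newdata[[col]]
  }, numeric(nrow(newdata)))
  vals <- matrix(vals, nrow = nrow(newdata))
  drop(object$intercept + vals %*% object$slopes)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from the ordinary regression
#' of predictor `j` on the remaining predictors. For two predictors this
#' reduces to `1 / (1 - r^2)`.
#'
#' @param design Data frame holding the predictor columns (long prediction
#'   table or diet-level table).
#' @param predictors At least two predictor names.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design, predictors) {
  if (length(predictors) < 2L) stop("VIF needs at least 2 predictors")
  cols <- predictor_column(predictors, design)
  X <- as.data.frame(lapply(cols, function(cl) design[[cl]]))
  names(X) <- names(cols)
  out <- vapply(names(X), function(v) {
    fml <- stats::as.formula(paste(v, "~",
                                   paste(setdiff(names(X), v),
                                         collapse = " + ")))
    # exact collinearity is detected below; silence lm's perfect-fit note
    r2 <- suppressWarnings(summary(stats::lm(fml, data = X))$r.squared)
    if (r2 > 1 - 1e-10) {
      stop("exact collinearity: predictor ", v,
           " is a linear combination of the others")
    }
    1 / (1 - r2)
  }, 0)
  out
}

#' Select the combined model from a set of candidate fits
#'
#' Default rule: among converged fits whose every slope is significant by
#' the `|t| > 2` screen, prefer the fewest predictors, break ties by lower
#' RMSE, then prefer ME over GE as the energy proxy. If no candidate
#' passes the significance screen the best-RMSE fit is returned flagged.
#'
#' @param fits List of `mixed_fit` objects.
#' @param t_threshold Absolute t-value defining a significant slope.
#' @return List with `model_id`, `fit`, `all_significant`, and
#'   `comparison` (one summary row per candidate).
#' @export
select_model <- function(fits, t_threshold = 2) {
  if (length(fits) == 0L) stop("no fitted candidates supplied")
  comparison <- do.call(rbind, lapply(fits, function(f) {
    slopes <- f$fixef[f$fixef$term != "Intercept", ]
    data.frame(model_id = as.character(f$model_id),
               predictors = paste(f$predictors, collapse = "+"),
               n_predictors = length(f$predictors),
               r2 = f$r2, rmse = f$rmse,
               sigma2_equation = f$sigma2_equation,
               sigma2_resid = f$sigma2_resid,
               all_significant = all(abs(slopes$t) > t_threshold),
               converged = f$converged,
               uses_me = "ME" %in% f$predictors,
               stringsAsFactors = FALSE)
  }))
  rownames(comparison) <- NULL
  pool <- comparison[comparison$all_significant & comparison$converged, ]
  flagged <- nrow(pool) == 0L
  if (flagged) {
    pool <- comparison[comparison$converged, ]
    if (nrow(pool) == 0L) stop("no converged candidate fits")
    chosen <- pool$model_id[which.min(pool$rmse)]
  } else {
    ord <- order(pool$n_predictors, round(pool$rmse, 6), !pool$uses_me)
    chosen <- pool$model_id[ord[1]]
  }
  idx <- which(vapply(fits, function(f) identical(as.character(f$model_id),
                                                 chosen), TRUE))[1]
  list(model_id = chosen, fit = fits[[idx]],
       all_significant = !flagged, comparison = comparison)
}

#' Between-equation standard deviation
#'
#' The square root of the equation-level variance component: the expected
#' spread of predictions attributable to equation identity alone.
#'
#' @param sigma2_equation Variance component (>= 0).
#' @return Its square root, same units as the response.
#' @export
between_equation_sd <- function(sigma2_equation) {
  if (sigma2_equation < 0) stop("variance must be >= 0")
  sqrt(sigma2_equation)
}

#' Published standardized summaries of the twelve candidate models
#'
#' The standardized fixed-effect estimates, standard errors, t-values and
#' fit metrics for the twelve candidate predictor combinations, as
#' published for the original (withheld-DMI) design; shipped for
#' back-transformation and selection-rule checks.
#'
#' @return Data frame, one row per model term.
#' @export
reference_model_summaries <- function() {
  path <- system.file("extdata", "reference_model_summaries.csv",
                      package = "ch4combine", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
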