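# Shared fixtures: everything built in code, cached per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# packaged diets completed under the default configuration (seed 42)
default_completed <- function() {
  memo("completed", complete_diets(packaged_diets(), completion_config()))
}

# the full 32 x 15 prediction table under default completion
default_predictions <- function() {
  memo("predictions", apply_all(packaged_registry(), default_completed()))
}

# hand-built completed diet rows for unit arithmetic, bypassing calibration
make_completed <- function(diet_id, dmi, mei, ndf, adf = 0.82 * ndf,
                           cp = 17, ee = 5, fa = 3, ash = 7.5,
                           forage = 50, ge_offset = 6.5,
                           cohort = "lactating") {
  df <- data.frame(diet_id = as.character(diet_id), cohort = cohort,
                   mei = mei, cp_pct = cp, fa_pct = fa, ee_pct = ee,
                   ndf_pct = ndf, adf_pct = adf, forage_pct = forage,
                   dmi = dmi, me_conc = mei / dmi,
                   ge_conc = mei / dmi + ge_offset, ash_pct = ash,
                   completion_provenance = "measured",
                   stringsAsFactors = FALSE)
  class(df) <- c("completed_diet_set", "diet_set", "data.frame")
  df
}

# a minimal valid registry record
make_record <- function(eq_id, intercept, terms, shape = "LINEAR",
                        output_unit = "G_PER_DAY", source = "toy") {
  ch4combine:::validate_record(list(eq_id = eq_id, source = source,
                                    shape = shape, output_unit = output_unit,
                                    intercept = intercept, terms = terms))
}

toy_registry <- function(records) {
  structure(stats::setNames(records,
                            vapply(records, `[[`, "", "eq_id")),
            class = "equation_registry")
}

# parameter-recovery study: 100 seeded replicates of the generative model
# at the study design (32 equations x 15 diets, truth 3.47/0.33/0.31,
# sigma_equation = sigma_resid = 1.5); raw-scale estimates, raw-scale SEs
# and the equation-level variance component per replicate.
recovery_study <- function() {
  memo("recovery", {
    design <- default_completed()
    t(vapply(1:100, function(s) {
      sim <- simulate_predictions(design, simulation_params(seed = s))
      f <- fit_mixed(sim, c("ME", "NDF"))
      raw <- back_transform(f)
      sl <- f$fixef[f$fixef$term != "Intercept", ]
      se_raw <- sl$se / f$scaling$sd[match(sl$term, f$scaling$predictor)]
      c(me = raw$slopes[["ME"]], ndf = raw$slopes[["NDF"]],
        se_me = se_raw[sl$term == "ME"], se_ndf = se_raw[sl$term == "NDF"],
        sigma2_eq = f$sigma2_equation)
    }, numeric(5)))
  })
}

# mixed_fit stub for selection-rule tests built from a summary row set
stub_fit <- function(model_id, predictors, slopes_t, rmse, r2 = 0.8,
                     converged = TRUE) {
  structure(list(model_id = model_id, predictors = predictors,
                 fixef = data.frame(
                   term = c("Intercept", predictors),
                   estimate = c(19, rep(1, length(predictors))),
                   se = 1, t = c(46, slopes_t),
                   stringsAsFactors = FALSE),
                 u_i = c(a = 0), sigma2_equation = 2, sigma2_resid = 2,
                 r2 = r2, rmse = rmse,
                 scaling = data.frame(predictor = predictors, mean = 0,
                                      sd = 1, stringsAsFactors = FALSE),
                 converged = converged, boundary = FALSE,
                 messages = character(0), n_obs = 480, fit = NULL),
            class = "mixed_fit")
}
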