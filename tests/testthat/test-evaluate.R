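test_that("the reference combined equation predicts as printed", {
  expect_equal(predict_combined(0, 0), 3.47)
  expect_equal(round(predict_combined(11.5, 32.5), 2), 17.34)
  # one extra percent NDF adds exactly the NDF slope
  expect_equal(predict_combined(11.5, 33.5) - predict_combined(11.5, 32.5),
               0.31)
  expect_error(predict_combined(-1, 30), "non-negative")
  expect_error(predict_combined(Inf, 30), "finite")
})

test_that("leave-one-diet-out reports honest per-diet performance", {
  expect_error(
    loo_diet_cv(simulate_predictions(
      make_completed(1:2, dmi = c(20, 21), mei = c(222, 230),
                     ndf = c(33, 40)),
      simulation_params(n_equations = 4, seed = 1)), c("ME", "NDF")),
    "at least 3 diets")

  sim <- simulate_predictions(default_completed(),
                              simulation_params(seed = 31))
  cv <- loo_diet_cv(sim, c("ME", "NDF"))
  expect_equal(nrow(cv), 15L)
  expect_true(all(cv$r2 <= 1))
  expect_true(all(cv$rmse >= 0))
  # aggregates recompute from the per-diet rows
  ok <- cv[cv$converged, ]
  expect_equal(attr(cv, "mean_r2"), mean(ok$r2))
  expect_equal(attr(cv, "median_r2"), median(ok$r2))
  expect_equal(attr(cv, "mean_rmse"), mean(ok$rmse))
  expect_equal(attr(cv, "min_r2"), min(ok$r2))
  expect_equal(attr(cv, "max_r2"), max(ok$r2))
})

test_that("cross-validated fit sits in the variance-ratio envelope", {
  # With sigma_equation = sigma_resid = 1.5 the expected held-out
  # R2 = 1 - E[SSE]/E[SST] is about 1 - sigma^2/(sigma_eq^2 + sigma^2)
  # minus shrinkage and extrapolation losses, i.e. near 0.45; averaging
  # over seeds damps the between-replicate variance-sampling noise.
  means <- vapply(1:3, function(s) {
    sim <- simulate_predictions(default_completed(),
                                simulation_params(seed = 200 + s))
    attr(loo_diet_cv(sim, c("ME", "NDF")), "mean_r2")
  }, 0)
  expect_gt(mean(means), 0.30)
  expect_lt(mean(means), 0.65)
})

test_that("equation-removal sensitivity brackets the full-data fit", {
  design <- default_completed()
  sim <- simulate_predictions(design, simulation_params(n_equations = 8,
                                                        seed = 41))
  sens <- sensitivity_loo_equation(sim, c("ME", "NDF"))
  expect_equal(nrow(sens), 8L)
  rg <- attr(sens, "ranges")
  expect_true(all(rg$min <= rg$full & rg$full <= rg$max))

  # deterministic inputs: removals change nothing
  flat <- simulate_predictions(design,
                               simulation_params(sigma_equation = 0,
                                                 sigma_resid = 0,
                                                 n_equations = 4, seed = 2))
  sflat <- sensitivity_loo_equation(flat, c("ME", "NDF"))
  rgf <- attr(sflat, "ranges")
  expect_lt(max(rgf$max - rgf$min), 1e-6)

  expect_error(
    sensitivity_loo_equation(
      simulate_predictions(design, simulation_params(n_equations = 2,
                                                     seed = 3)),
      c("ME", "NDF")),
    "at least 3 equations")
})

test_that("removing one equation barely moves the fitted coefficients", {
  sim <- simulate_predictions(default_completed(),
                              simulation_params(seed = 51))
  sens <- sensitivity_loo_equation(sim, c("ME", "NDF"))
  expect_equal(nrow(sens), 32L)
  expect_true(all(abs(sens$NDF - 0.31) < 0.1))
})

test_that("a spurious predictor stays non-significant in candidate fits", {
  # data generated from ME + NDF only: with both true drivers in the
  # model, an added fat term has a zero partial effect and should fail
  # the |t| > 2 screen
  sim <- simulate_predictions(default_completed(),
                              simulation_params(seed = 61))
  f5 <- fit_mixed(sim, c("ME", "NDF", "EE"), model_id = 5)
  t_ee <- f5$fixef$t[f5$fixef$term == "EE"]
  expect_lt(abs(t_ee), 2)
})

test_that("the pipeline writes a reproducible run directory", {
  run1 <- tempfile("run1"); run2 <- tempfile("run2")
  r <- run_pipeline(run1, seed = 42)
  expect_equal(r$manifest$n_predictions, 480L)
  expect_equal(r$manifest$model, "1")
  expect_true(all(c("manifest.json", "predictions.csv", "diet_extremes.csv",
                    "model_comparison.csv", "combined_equation.csv",
                    "cv_per_diet.csv", "sensitivity.csv",
                    "random_intercepts.csv") %in% list.files(run1)))
  # between-equation SD in the manifest is the root of the variance
  expect_equal(r$manifest$between_equation_sd,
               round(sqrt(r$selection$fit$sigma2_equation), 6),
               tolerance = 1e-5)
  # same seed, byte-identical numeric tables
  run_pipeline(run2, seed = 42)
  for (f in c("predictions.csv", "combined_equation.csv", "cv_per_diet.csv",
              "sensitivity.csv", "model_comparison.csv")) {
    expect_identical(readLines(file.path(run1, f)),
                     readLines(file.path(run2, f)), label = f)
  }
})

test_that("forcing a candidate model is recorded and screened", {
  run <- tempfile("run3")
  r <- run_pipeline(run, seed = 42, model = "3")
  expect_equal(r$manifest$model, "3")
  expect_true(r$manifest$model_forced)
  expect_equal(r$combined$model_id, "3")
  expect_error(run_pipeline(tempfile(), seed = 42, model = "99"),
               "unknown model")
})
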