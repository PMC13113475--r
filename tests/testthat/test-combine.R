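test_that("standardization centres and scales exactly and inverts", {
  toy <- data.frame(ndf_pct = c(1, 2, 3))
  std <- standardize(toy, "NDF")
  expect_equal(std$scaling$mean, 2)
  expect_equal(std$scaling$sd, 1)
  expect_equal(std$design$NDF, c(-1, 0, 1))

  ps <- default_predictions()
  std <- standardize(ps, c("ME", "NDF"))
  for (v in c("ME", "NDF")) {
    expect_lt(abs(mean(std$design[[v]])), 1e-10)
    expect_lt(abs(sd(std$design[[v]]) - 1), 1e-10)
  }
  back <- invert_standardize(std$design, std$scaling)
  expect_equal(back$ME, ps$me_conc, tolerance = 1e-12)
  expect_equal(back$NDF, ps$ndf_pct, tolerance = 1e-12)

  # stacking the 15 diet values once per equation changes the sample SD
  # only through the (n-1) denominator
  d <- packaged_diets()
  expect_equal(sd(rep(d$ndf_pct, 32)),
               sd(d$ndf_pct) * sqrt(14 * 32 / 479))
  expect_equal(std$scaling$sd[std$scaling$predictor == "NDF"],
               sd(rep(d$ndf_pct, 32)))

  toy$flat <- 5
  expect_error(standardize(toy, c("NDF", "flat")), "flat")
})

test_that("collinearity screening groups interchangeable variables", {
  cd <- default_completed()
  sc <- screen_collinearity(cd, c("ME", "GE", "NDF", "ADF", "CP", "EE", "FA"))
  expect_equal(round(sc$correlation["NDF", "ADF"], 2), 1.00)
  expect_equal(round(sc$correlation["ME", "GE"], 2), 1.00)
  grouped <- vapply(sc$clusters, function(g) all(c("NDF", "ADF") %in% g) ||
                      all(c("ME", "GE") %in% g), TRUE)
  expect_equal(sum(grouped), 2L)
  # priority keeps NDF over ADF and ME over GE
  expect_true(all(c("NDF", "ME") %in% sc$retained))
  expect_false(any(c("ADF", "GE") %in% sc$retained))

  # orthogonal toy columns are never grouped
  toy <- data.frame(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  sc2 <- screen_collinearity(toy, c("a", "b"))
  expect_equal(length(sc2$clusters), 0L)
  expect_equal(sort(sc2$retained), c("a", "b"))

  toy$c <- 3
  expect_error(screen_collinearity(toy, c("a", "c")), "constant")
})

test_that("the twelve candidate predictor sets are as published", {
  cm <- candidate_models()
  expect_equal(length(cm), 12L)
  expect_equal(cm[["1"]], c("ME", "NDF"))
  expect_true(all(vapply(cm, function(v) "NDF" %in% v, TRUE)))
  has_energy <- vapply(cm, function(v) any(c("ME", "GE") %in% v), TRUE)
  expect_equal(names(cm)[!has_energy], c("3", "10"))
})

test_that("with no equation-level variance the fit collapses to OLS", {
  sim <- simulate_predictions(default_completed(),
                              simulation_params(sigma_equation = 0,
                                                sigma_resid = 1.5,
                                                seed = 17))
  f <- fit_mixed(sim, c("ME", "NDF"), scale_predictors = FALSE)
  ols <- lm(ch4_g_per_kg_dm ~ me_conc + ndf_pct, data = sim)
  expect_equal(f$fixef$estimate, unname(coef(ols)), tolerance = 1e-4)
})

test_that("a single replicate recovers the generative coefficients", {
  sim <- simulate_predictions(default_completed(),
                              simulation_params(seed = 101))
  f <- fit_mixed(sim, c("ME", "NDF"))
  raw <- back_transform(f)
  sl <- f$fixef[f$fixef$term != "Intercept", ]
  se_raw <- sl$se / f$scaling$sd[match(sl$term, f$scaling$predictor)]
  expect_lt(abs(raw$slopes[["ME"]] - 0.33), 3 * se_raw[sl$term == "ME"])
  expect_lt(abs(raw$slopes[["NDF"]] - 0.31), 3 * se_raw[sl$term == "NDF"])
  expect_true(f$converged)
  # RMSE is the root mean squared residual against fitted-with-intercepts
  expect_equal(f$rmse^2, mean((sim$ch4_g_per_kg_dm -
                                 fitted(f$fit))^2), tolerance = 1e-6)
})

test_that("noise-free data is fitted perfectly", {
  sim <- simulate_predictions(default_completed(),
                              simulation_params(sigma_equation = 1.2,
                                                sigma_resid = 0, seed = 5))
  f <- fit_mixed(sim, c("ME", "NDF"))
  expect_equal(f$r2, 1, tolerance = 1e-8)
  expect_lt(f$rmse, 1e-8)
})

test_that("the equation-level variance component is recovered", {
  st <- recovery_study()
  mc_se <- sd(st[, "sigma2_eq"]) / sqrt(nrow(st))
  expect_lt(abs(mean(st[, "sigma2_eq"]) - 1.5^2), 3 * mc_se)
})

test_that("fit metrics are invariant to record order", {
  ps <- default_predictions()
  f1 <- fit_mixed(ps, c("ME", "NDF"))
  set.seed(2)
  shuffled <- ps[sample(nrow(ps)), ]
  f2 <- fit_mixed(shuffled, c("ME", "NDF"))
  expect_equal(f1$r2, f2$r2, tolerance = 1e-9)
  expect_equal(f1$rmse, f2$rmse, tolerance = 1e-9)
  expect_equal(f1$fixef$estimate, f2$fixef$estimate, tolerance = 1e-9)
})

test_that("back-transformation reverses the scaling exactly", {
  # hand arithmetic: one predictor, mean 10, SD 2, b* = 4, b0* = 20
  fake <- stub_fit("x", "NDF", slopes_t = 4, rmse = 1)
  fake$fixef$estimate <- c(20, 4)
  fake$scaling <- data.frame(predictor = "NDF", mean = 10, sd = 2,
                             stringsAsFactors = FALSE)
  raw <- back_transform(fake)
  expect_equal(raw$slopes[["NDF"]], 2)
  expect_equal(raw$intercept, 0)

  # identity scaling returns the standardized coefficients unchanged
  fake$scaling <- data.frame(predictor = "NDF", mean = 0, sd = 1,
                             stringsAsFactors = FALSE)
  raw <- back_transform(fake)
  expect_equal(raw$slopes[["NDF"]], 4)
  expect_equal(raw$intercept, 20)

  # prediction with raw coefficients equals standardized-scale prediction
  ps <- default_predictions()
  f <- fit_mixed(ps, c("ME", "NDF"))
  ce <- back_transform(f)
  std <- standardize(ps, c("ME", "NDF"))
  b <- f$fixef$estimate
  pred_std <- b[1] + as.matrix(std$design) %*% b[-1]
  expect_equal(predict(ce, ps), drop(pred_std), tolerance = 1e-8)
})

test_that("raw-scale and standardized fits are equivalent", {
  ps <- default_predictions()
  ce <- back_transform(fit_mixed(ps, c("ME", "NDF")))
  cr <- back_transform(fit_mixed(ps, c("ME", "NDF"),
                                 scale_predictors = FALSE))
  expect_equal(ce$intercept, cr$intercept, tolerance = 1e-6)
  expect_equal(ce$slopes, cr$slopes, tolerance = 1e-6)
})

test_that("variance inflation factors follow the closed form", {
  toy <- data.frame(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(unname(vif(toy, c("a", "b"))), c(1, 1))

  # construct exact correlation r = 0.682 from orthonormal pieces
  x <- c(1, 1, -1, -1) / 2
  z <- c(1, -1, 1, -1) / 2
  r <- 0.682
  toy2 <- data.frame(p = x, q = r * x + sqrt(1 - r^2) * z)
  v <- vif(toy2, c("p", "q"))
  expect_equal(round(unname(v), 2), c(1.87, 1.87))
  expect_equal(unname(v[1]), 1 / (1 - r^2))

  toy2$s <- toy2$p + toy2$q
  expect_error(vif(toy2, c("p", "q", "s")), "collinearity")
})

test_that("model selection follows significance, parsimony, then error", {
  # pattern of the published comparison: all-significant candidates are
  # 1, 2, 4 and 8; the two-predictor ones tie, ME preferred over GE
  ref <- reference_model_summaries()
  fits <- lapply(split(ref, ref$model_id), function(m) {
    slopes <- m[m$term != "Intercept", ]
    stub_fit(as.character(m$model_id[1]), slopes$term, slopes$t,
             rmse = m$rmse[1], r2 = m$r2[1])
  })
  sel <- select_model(fits)
  expect_equal(sel$model_id, "1")
  expect_true(sel$all_significant)
  expect_equal(sort(sel$comparison$model_id[sel$comparison$all_significant]),
               sort(c("1", "2", "4", "8")))

  # single candidate
  one <- select_model(fits["5"])
  expect_equal(one$model_id, "5")

  # equal significance, different RMSE: lower RMSE wins
  pair <- list(stub_fit("a", c("ME", "NDF"), c(5, 5), rmse = 2.0),
               stub_fit("b", c("GE", "NDF"), c(5, 5), rmse = 1.0))
  expect_equal(select_model(pair)$model_id, "b")

  # nothing significant: best-RMSE model returned flagged
  weak <- list(stub_fit("a", c("ME", "NDF"), c(1, 5), rmse = 2.0),
               stub_fit("b", c("GE", "NDF"), c(5, 1), rmse = 1.0))
  sel <- select_model(weak)
  expect_equal(sel$model_id, "b")
  expect_false(sel$all_significant)
})
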