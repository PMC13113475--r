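#!/usr/bin/env Rscript
# Step 4: validate the combined equation.
#
# Leave-one-diet-out cross-validation (refit on 14 diets, predict the
# held-out diet with the training random intercepts) and a
# leave-one-equation-out sensitivity analysis (32 refits).

library(ch4combine)

dir.create("results", showWarnings = FALSE)

completed <- complete_diets(packaged_diets(), completion_config(seed = 42))
preds <- apply_all(packaged_registry(), completed)

cv <- loo_diet_cv(preds, c("ME", "NDF"))
write.csv(format(as.data.frame(cv), digits = 6),
          "results/04_cv_per_diet.csv", row.names = FALSE, quote = FALSE)
cat("leave-one-diet-out cross-validation:\n")
print(transform(as.data.frame(cv), r2 = round(r2, 2), rmse = round(rmse, 2)),
      row.names = FALSE)
cat(sprintf("mean R2 %.2f, median %.2f, range %.2f-%.2f; RMSE %.2f (%.2f-%.2f)\n",
            attr(cv, "mean_r2"), attr(cv, "median_r2"), attr(cv, "min_r2"),
            attr(cv, "max_r2"), attr(cv, "mean_rmse"),
            attr(cv, "min_rmse"), attr(cv, "max_rmse")))

sens <- sensitivity_loo_equation(preds, c("ME", "NDF"))
write.csv(format(as.data.frame(sens), digits = 6),
          "results/04_sensitivity.csv", row.names = FALSE, quote = FALSE)
cat("\nleave-one-equation-out coefficient ranges:\n")
print(transform(attr(sens, "ranges"), full = round(full, 3),
                min = round(min, 3), max = round(max, 3)),
      row.names = FALSE)
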