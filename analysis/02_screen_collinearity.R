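#!/usr/bin/env Rscript
# Step 2: screen the diet variables for collinearity.
#
# Highly correlated pairs (|r| > 0.75) are grouped and one representative
# kept: NDF over ADF, ME over GE. The surviving variables define the
# twelve candidate predictor combinations fitted in step 3.

library(ch4combine)

dir.create("results", showWarnings = FALSE)

completed <- complete_diets(packaged_diets(), completion_config(seed = 42))
sc <- screen_collinearity(completed,
                          c("ME", "GE", "NDF", "ADF", "CP", "EE", "FA"))

write.csv(round(sc$correlation, 3), "results/02_correlation_matrix.csv",
          quote = FALSE)

cat("correlation matrix (diet level):\n")
print(round(sc$correlation, 2))
for (g in sc$clusters) {
  cat("grouped:", paste(g, collapse = " ~ "), "\n")
}
cat("retained:", paste(sc$retained, collapse = ", "), "\n")
cat("candidate combinations:\n")
for (id in names(candidate_models())) {
  cat(sprintf("  model %-2s: %s\n", id,
              paste(candidate_models()[[id]], collapse = " + ")))
}
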