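#!/usr/bin/env Rscript
# Step 4: Monte-Carlo cross-validation of %FAME imputation. Per iteration
# 20% of the complete samples per month lose their %FAME block and are
# reconstructed from their minerals: PPCA by the conditional mean under the
# fitted latent model, PLSR by regression on the mineral block. Writes
# RMSECV and R2 curves (autoscaled scale; original-scale analogues too).

library(pecomics)

seed <- 2303
pm <- read_profile_csv("results/synthetic_profiles.csv")

for (model in c("ppca", "plsr")) {
  run <- run_imputation_validation(pm, model, orders = 1:8,
                                   n_iterations = 20, seed = seed)
  write_report(run$rmsecv, paste0("results/rmsecv_", model))
  write_report(run$r2, paste0("results/r2_", model))
  write_report(run$rmsecv_original,
               paste0("results/rmsecv_original_", model))
  message(sprintf(
    "%-4s: min RMSECV = %.3f at order %d; best R2 = %.1f%% at order %d",
    toupper(model), min(run$rmsecv$mean_metric), run$rmsecv$selected_order,
    max(run$r2$mean_metric), run$r2$selected_order))
}
message("wrote results/{rmsecv,r2}_{ppca,plsr}_curve.csv")
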