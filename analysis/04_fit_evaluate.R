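#!/usr/bin/env Rscript
# Stage 4 — fit both engines with the study presets and cross-validate.
#
# GAM: binomial P-spline smoothers, k = 5, 1:1 pseudo-absences; maxent:
# linear/quadratic/hinge features, 8,000 background points, beta = 1.
# Discrimination is summarized by repeated (3x) stratified 10-fold CV.
# Writes CV summaries, the fitted-model summaries, suitability and
# uncertainty rasters, and variable-importance tables under results/.

suppressPackageStartupMessages(library(duosdm))
seed <- 1L

stack <- read_stack("results/landscape/layers.csv")
occ <- read_occurrences("results/occurrences.csv")
sac <- read_geojson("results/landscape/study_area.geojson")
modeled <- jsonlite::read_json("results/concurvity.json",
                               simplifyVector = TRUE)$modeled
stack <- stack[modeled]

cfg <- default_config(seed = seed, maxent_bootstrap = 100L)
suite <- run_model_suite(occ, stack, sac, cfg)

dir.create("results/maps", showWarnings = FALSE)
write_ascii_grid(suite$gam$prediction$probability, "results/maps/gam_mean.asc")
write_ascii_grid(suite$gam$uncertainty$cv, "results/maps/gam_cv.asc")
write_ascii_grid(suite$maxent$uncertainty$mean, "results/maps/maxent_mean.asc")
write_ascii_grid(suite$maxent$uncertainty$cv, "results/maps/maxent_cv.asc")
write_maxent_lambdas(suite$maxent$fit, "results/maxent_model.lambdas")

cat(sprintf("GAM: mean CV AUC %.3f (se %.3f), TSS %.3f; deviance explained %.1f%%\n",
            suite$gam$cv$mean_auc, suite$gam$cv$se_auc, suite$gam$cv$mean_tss,
            100 * suite$gam$fit$deviance_explained))
cat(sprintf("maxent: mean CV AUC %.3f (se %.3f), TSS %.3f; gain %.3f (unreg. %.3f)\n",
            suite$maxent$cv$mean_auc, suite$maxent$cv$se_auc,
            suite$maxent$cv$mean_tss, suite$maxent$fit$regularized_gain,
            suite$maxent$fit$unregularized_gain))

imp_gam <- suite$gam$importance
utils::write.csv(imp_gam, "results/importance_gam.csv", row.names = FALSE)
cat("\nGAM deviance-drop importance:\n")
print(imp_gam[order(-imp_gam$proportion_of_total),
              c("predictor", "deviance_drop_pct", "proportion_of_total")],
      row.names = FALSE, digits = 3)

pc <- suite$maxent$importance$percent_contribution
pi_ <- suite$maxent$importance$permutation
mx_imp <- merge(pc, pi_[c("predictor", "percent")], by = "predictor",
                suffixes = c("_contribution", "_permutation"))
utils::write.csv(mx_imp, "results/importance_maxent.csv", row.names = FALSE)
cat("\nmaxent importance (percent contribution / permutation):\n")
print(mx_imp[order(-mx_imp$percent_contribution), ], row.names = FALSE,
      digits = 3)

summary_ <- list(
  gam = list(mean_auc = suite$gam$cv$mean_auc, se_auc = suite$gam$cv$se_auc,
             mean_tss = suite$gam$cv$mean_tss,
             deviance_explained = suite$gam$fit$deviance_explained,
             aic = suite$gam$fit$aic),
  maxent = list(mean_auc = suite$maxent$cv$mean_auc,
                se_auc = suite$maxent$cv$se_auc,
                mean_tss = suite$maxent$cv$mean_tss,
                regularized_gain = suite$maxent$fit$regularized_gain,
                unregularized_gain = suite$maxent$fit$unregularized_gain,
                active_features = sum(suite$maxent$fit$lambdas != 0)))
jsonlite::write_json(summary_, "results/model_summary.json",
                     auto_unbox = TRUE, digits = NA)
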