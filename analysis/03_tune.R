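#!/usr/bin/env Rscript
# Stage 3 — tuning loops (scaled-down).
#
# GAM: k in {3, 5, 10} x 30 background-count candidates sampled from
# 30..250, 10 repeats of a 90/10 stratified split each (the full protocol
# uses 50 repeats; 10 keep this driver's runtime in minutes while leaving
# the curve shape intact).  MaxEnt: beta in 1..5 x background counts from
# 1,000..12,000 (6 candidates, 3 repeats).  Writes the record tables and
# the selected settings under results/.

suppressPackageStartupMessages(library(duosdm))
seed <- 1L

stack <- read_stack("results/landscape/layers.csv")
occ <- read_occurrences("results/occurrences.csv")
sac <- read_geojson("results/landscape/study_area.geojson")
modeled <- jsonlite::read_json("results/concurvity.json",
                               simplifyVector = TRUE)$modeled
stack <- stack[modeled]

bias <- build_bias_surface(occ, sac, stack[[1]])
pool <- draw_background(bias, 30000, derive_seed(seed, "pool"))

tg <- tune_gam(occ, pool, stack, repeats = 10L,
               seed = derive_seed(seed, "tune_gam"))
utils::write.csv(tg$records, "results/tuning_gam.csv", row.names = FALSE)
cat("GAM tuning: selected k =", tg$selected$k,
    "with", tg$selected$n_background, "background points\n")
curve <- stats::aggregate(auc ~ n_background, tg$summary, mean)
cat(sprintf("mean AUC: best %.3f, plateau (bg >= 50) %.3f\n",
            max(curve$auc), mean(curve$auc[curve$n_background >= 50])))
by_k <- tapply(tg$summary$auc, tg$summary$k, mean)
cat("mean AUC by k:", paste(sprintf("k=%s %.3f", names(by_k), by_k),
                            collapse = ", "), "\n")

tm <- tune_maxent(occ, pool, stack,
                  bg_counts = c(1000L, 2000L, 4000L, 8000L, 10000L, 12000L),
                  beta_values = 1:5, repeats = 3L, n_hinge_knots = 15L,
                  iterations = 200L, seed = derive_seed(seed, "tune_maxent"))
utils::write.csv(tm$records, "results/tuning_maxent.csv", row.names = FALSE)
cat("maxent tuning: selected beta =", tm$selected$beta,
    "with", tm$selected$n_background, "background points\n")
rng <- range(stats::aggregate(auc ~ n_background, tm$summary, mean)$auc)
cat(sprintf("maxent mean AUC across background counts: %.3f-%.3f\n",
            rng[1], rng[2]))
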