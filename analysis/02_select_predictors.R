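#!/usr/bin/env Rscript
# Stage 2 — collinearity pruning and concurvity screening.
#
# Computes pairwise Pearson correlations over the valid cells; while any
# pair exceeds |r| > 0.7, two single-predictor binomial GAMs decide which
# member to drop (higher AIC loses).  A concurvity check on the GAM fitted
# to the retained set then flags smooths reproducible from the others.
# Writes the selection report to results/selection.json.

suppressPackageStartupMessages(library(duosdm))
seed <- 1L

stack <- read_stack("results/landscape/layers.csv")
occ <- read_occurrences("results/occurrences.csv")
sac <- read_geojson("results/landscape/study_area.geojson")

bias <- build_bias_surface(occ, sac, stack[[1]])
bg <- draw_background(bias, nrow(occ), derive_seed(seed, "select_bg"))
design <- make_design(stack, occ, bg)

sel <- prune_collinear(stack, design, threshold = 0.7, k = 5L)
print(sel)

specs <- lapply(sel$retained, function(p)
  build_smooth(design[[p]], k = 5L, predictor = p))
conc <- concurvity_index(fit_gam(design, specs), threshold = 0.8)
cat("concurvity indices:\n")
print(round(conc, 3))
flagged <- names(conc)[attr(conc, "flagged")]
modeled <- setdiff(sel$retained, flagged)
if (length(flagged))
  cat("removed after concurvity check:", paste(flagged, collapse = ", "), "\n")
cat("modeled predictors:", paste(modeled, collapse = ", "), "\n")

dir.create("results", showWarnings = FALSE)
write_selection_report(sel, "results/selection.json")
jsonlite::write_json(list(concurvity = as.list(conc), modeled = modeled),
                     "results/concurvity.json", auto_unbox = TRUE, digits = NA)
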