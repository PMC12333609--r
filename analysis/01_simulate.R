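#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study system.
#
# Generates the default coastal landscape (a ~159 km^2 wavy alongshore band
# of 250 m cells with a depth gradient, slope derived from depth, fine-scale
# chlorophyll-a elevated around four aquaculture attractors, an independent
# SST-anomaly field, and distance to aquaculture), then samples the study's
# occurrence dataset: 20 "survey" records under a trackline-corridor
# detection surface and 49 "citizen" records under a harbor-hotspot surface.
# Writes the predictor stack, the truth surface, and the occurrence CSV
# under results/.

suppressPackageStartupMessages(library(duosdm))
seed <- 1L
dir.create("results/landscape", recursive = TRUE, showWarnings = FALSE)

params <- landscape_params(seed = derive_seed(seed, "landscape"))
sim <- generate_landscape(params)
biases <- default_bias_surfaces(sim$truth)
occ <- sample_occurrences(sim$truth, 20, 49, biases$survey, biases$citizen,
                          derive_seed(seed, "occurrences"))
occ <- merge_occurrences(occ[occ$source == "survey", ],
                         occ[occ$source == "citizen", ],
                         sim$truth$study_area)

write_stack(sim$stack, "results/landscape")
write_ascii_grid(sim$truth$true_suitability,
                 "results/landscape/true_suitability.asc")
write_geojson(sim$truth$study_area, "results/landscape/study_area.geojson")
write_geojson(sim$truth$aquaculture, "results/landscape/aquaculture.geojson")
write_occurrences(occ, "results/occurrences.csv")
jsonlite::write_json(unclass(params), "results/landscape/params.json",
                     auto_unbox = TRUE, digits = NA)

suit <- sim$truth$true_suitability$values
cat(sprintf("landscape: %d x %d cells, %d valid (%.0f km^2)\n",
            params$n_rows, params$n_cols, sum(is.finite(suit)),
            sum(is.finite(suit)) * (params$cell_size / 1000)^2))
cat(sprintf("true suitability: median %.3f, 95th pct %.3f\n",
            median(suit, na.rm = TRUE), quantile(suit, .95, na.rm = TRUE)))
cat(sprintf("occurrences: %d (%d survey + %d citizen)\n", nrow(occ),
            sum(occ$source == "survey"), sum(occ$source == "citizen")))
cat(sprintf("survey encounter rate at 484.8 km effort: %.4f groups / 100 km\n",
            encounter_rate(sum(occ$source == "survey"), 484.8)))
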