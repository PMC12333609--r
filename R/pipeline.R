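#' Default pipeline configuration
#'
#' All numeric settings of the pipeline in one declarative list.  Every
#' stochastic stage derives its own seed deterministically from the master
#' seed via [derive_seed()], so a config (plus package version) fully
#' reproduces a run.  The modeling presets default to a 1:1 presence to
#' pseudo-absence ratio with basis dimension k = 5 for the GAM, and 8,000
#' background points with regularization multiplier beta = 1 for maxent.
#'
#' @param seed master seed.
#' @param ... named overrides merged into the defaults (nested lists are
#'   merged shallowly via [utils::modifyList()]).
#' @return a `run_config` list.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    stages = c("simulate", "select", "tune", "fit", "ablation"),
    landscape = list(),                 # overrides for landscape_params()
    n_survey = 20L, n_citizen = 49L,
    bias = list(bandwidth = NULL, buffer = 2000, focal_window = 3L),
    pool_size = 30000L,
    selection = list(threshold = 0.7, concurvity_threshold = 0.8),
    gam = list(ratio = 1, k = 5L),
    maxent = list(n_background = 8000L, beta = 1, n_hinge_knots = 30L,
                  iterations = 500L),
    cv_folds = 10L,
    cv_repeats = 3L,
    maxent_bootstrap = 500L,
    tune = list(enabled = FALSE, repeats = 50L),
    ablation = list(enabled = FALSE))
  cfg <- utils::modifyList(cfg, list(...))
  class(cfg) <- "run_config"
  cfg
}

#' Read and write a run configuration as JSON
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `read_config()` returns a `run_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, c(list(seed = cfg$seed),
                            cfg[setdiff(names(cfg), "seed")]))
}

# repeated stratified cross-validation: each repeat redraws the negatives
# from the pool (fresh derived seed) and re-assigns folds, and the per-repeat
# mean AUC/TSS are averaged; at small presence counts a single negative draw
# dominates the CV noise, so repeats estimate the same quantity more stably.
repeat_cv <- function(recipe, stack, presences, pool, n_negative, k, repeats,
                      seed, stage) {
  runs <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    neg <- subsample_pseudo_absences(pool, n_negative, 1,
                                     derive_seed(seed, stage, 2L * r))
    design <- make_design(stack, presences, neg)
    runs[[r]] <- cross_validate(recipe, design, k,
                                derive_seed(seed, stage, 2L * r + 1L))
  }
  aucs <- vapply(runs, `[[`, 0, "mean_auc")
  list(mean_auc = mean(aucs),
       se_auc = if (repeats > 1L) stats::sd(aucs) / sqrt(repeats) else
         runs[[1L]]$se_auc,
       mean_tss = mean(vapply(runs, `[[`, 0, "mean_tss")),
       repeats = runs)
}

#' Fit, cross-validate, predict and summarize both engines
#'
#' The shared modeling core behind [run_pipeline()] and
#' [ablation_citizen_science()]: builds the sampling-bias surface from the
#' supplied presences, draws the background pool, assembles the 1:1
#' pseudo-absence design (GAM) and the background design (maxent), fits
#' both engines with the given presets, cross-validates them, predicts
#' suitability rasters with per-cell uncertainty (analytic for the GAM,
#' bootstrap-replicate for maxent), and computes variable importance.
#'
#' @param presences occurrence data.frame (`x`, `y`).
#' @param stack `predictor_stack` of modeled predictors.
#' @param study_area study-area polygon (`feature_geometry`).
#' @param config a `run_config` (presets and seeds).
#' @param do_uncertainty,do_importance stage switches (default TRUE).
#' @return list with elements `bias`, `pool_seed`, `gam` and `maxent`
#'   (each: `fit`, `cv`, `prediction`, `uncertainty`, `importance`).
#' @export
run_model_suite <- function(presences, stack, study_area, config,
                            do_uncertainty = TRUE, do_importance = TRUE) {
  seed <- config$seed
  bias <- build_bias_surface(presences, study_area, stack[[1L]],
                             config$bias$bandwidth, config$bias$buffer,
                             config$bias$focal_window)
  pool <- draw_background(bias, config$pool_size, derive_seed(seed, "pool"))
  pa <- subsample_pseudo_absences(pool, nrow(presences), config$gam$ratio,
                                  derive_seed(seed, "pseudo_absences"))
  bg <- subsample_pseudo_absences(pool, config$maxent$n_background, 1,
                                  derive_seed(seed, "background"))
  design_gam <- make_design(stack, presences, pa)
  design_mx <- make_design(stack, presences, bg)
  preds <- names(stack)

  reps <- max(1L, if (is.null(config$cv_repeats)) 1L else config$cv_repeats)
  g_recipe <- gam_recipe(k = config$gam$k)
  gam_cv <- repeat_cv(g_recipe, stack, presences, pool, nrow(presences) *
                        config$gam$ratio, config$cv_folds, reps, seed, "cv_gam")
  gam_fit_ <- g_recipe$fit(design_gam)
  gam_out <- list(fit = gam_fit_, cv = gam_cv)
  if (do_uncertainty) {
    pred <- predict_gam(gam_fit_, stack)
    gam_out$prediction <- pred
    gam_out$uncertainty <- uncertainty_maps(mean_grid = pred$probability,
                                            se_grid = pred$standard_error)
  }
  if (do_importance) {
    specs <- lapply(preds, function(p)
      build_smooth(design_gam[[p]], k = config$gam$k, predictor = p))
    gam_out$importance <- deviance_importance(design_gam, specs)
  }

  m_recipe <- maxent_recipe(beta = config$maxent$beta,
                            n_hinge_knots = config$maxent$n_hinge_knots,
                            iterations = config$maxent$iterations)
  mx_cv <- repeat_cv(m_recipe, stack, presences, pool,
                     config$maxent$n_background, config$cv_folds, reps,
                     seed, "cv_maxent")
  bg_tab <- design_mx[design_mx$label == 0, preds, drop = FALSE]
  pr_tab <- design_mx[design_mx$label == 1, preds, drop = FALSE]
  feats <- make_features(bg_tab, preds, config$maxent$n_hinge_knots)
  mx_fit <- fit_maxent(pr_tab, bg_tab, feats, beta = config$maxent$beta,
                       iterations = config$maxent$iterations)
  mx_out <- list(fit = mx_fit, cv = mx_cv)
  if (do_uncertainty) {
    mx_out$prediction <- predict_maxent(mx_fit, stack)
    boot <- bootstrap_predict(pr_tab, bg_tab, feats, stack,
                              n_replicates = config$maxent_bootstrap,
                              beta = config$maxent$beta,
                              iterations = config$maxent$iterations,
                              seed = derive_seed(seed, "maxent_bootstrap"))
    mx_out$uncertainty <- uncertainty_maps(replicates = boot)
  }
  if (do_importance) {
    mx_out$importance <- list(
      percent_contribution = percent_contribution(mx_fit),
      permutation = permutation_importance(mx_fit, pr_tab, bg_tab,
                                           derive_seed(seed, "permutation")))
  }
  list(bias = bias, gam = gam_out, maxent = mx_out,
       n_presences = nrow(presences))
}

#' Ablation: rerun the pipeline without citizen-science records
#'
#' Runs the complete modeling core twice — once with all records, once with
#' survey records only — holding every setting fixed, and reports per-run
#' mean AUC/TSS, mean CV over valid cells, and the per-cell suitability
#' difference (full minus survey-only) for both engines.  An optional
#' region mask (e.g., the citizen-covered sector) adds per-run mean
#' predicted suitability within the region.
#'
#' @param occ merged occurrence data.frame with a `source` column.
#' @param stack `predictor_stack`.
#' @param study_area study-area polygon.
#' @param config a `run_config`.
#' @param region_mask optional logical matrix (grid-shaped) naming the
#'   region of interest.
#' @return list with `full`, `survey_only`, `comparison`.
#' @export
ablation_citizen_science <- function(occ, stack, study_area, config,
                                     region_mask = NULL) {
  survey_only <- occ[occ$source == "survey", , drop = FALSE]
  runs <- list(full = occ, survey_only = survey_only)
  out <- list()
  for (nm in names(runs)) {
    out[[nm]] <- tryCatch(
      run_model_suite(runs[[nm]], stack, study_area, config,
                      do_importance = FALSE),
      error = function(e) list(failed = TRUE, error = conditionMessage(e)))
  }
  summarize <- function(run, engine) {
    if (isTRUE(run$failed)) return(list(failed = TRUE, error = run$error))
    e <- run[[engine]]
    cvv <- e$uncertainty$cv$values
    pv <- if (engine == "gam") e$prediction$probability$values else
      e$prediction$logistic$values
    s <- list(mean_auc = e$cv$mean_auc, mean_tss = e$cv$mean_tss,
              mean_cv_pct = mean(cvv[is.finite(cvv)]),
              n_presences = run$n_presences)
    if (!is.null(region_mask))
      s$region_mean_suitability <- mean(pv[region_mask & is.finite(pv)])
    s
  }
  comparison <- list()
  for (engine in c("gam", "maxent")) {
    comparison[[engine]] <- list(full = summarize(out$full, engine),
                                 survey_only = summarize(out$survey_only, engine))
    if (!isTRUE(out$full$failed) && !isTRUE(out$survey_only$failed)) {
      pf <- if (engine == "gam") out$full[[engine]]$prediction$probability else
        out$full[[engine]]$prediction$logistic
      ps <- if (engine == "gam") out$survey_only[[engine]]$prediction$probability else
        out$survey_only[[engine]]$prediction$logistic
      comparison[[engine]]$difference <-
        rast_grid(pf$values - ps$values, pf$xmin, pf$ymax, pf$dx, pf$dy, pf$crs)
    }
  }
  list(full = out$full, survey_only = out$survey_only, comparison = comparison)
}

#' Run the full pipeline from a configuration
#'
#' Executes the enabled stages in order — simulate, select (collinearity +
#' concurvity screen), bias/background, optional tuning, fit + cross-
#' validate + predict + importance, optional ablation — and returns a run
#' manifest recording the config, per-stage seeds, outputs and wall-clock
#' times.  A stage failure is recorded and downstream stages are skipped.
#'
#' @param config a `run_config` from [default_config()].
#' @return list of class `run_manifest` with elements `config`, `stages`
#'   (per-stage status/timing), and `results`.
#' @export
run_pipeline <- function(config = default_config()) {
  manifest <- list(config = unclass(config), stages = list(), results = list())
  failed <- FALSE
  run_stage <- function(name, fun) {
    if (!(name %in% config$stages) || failed) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      failed <<- TRUE
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res),
                                       seconds = elapsed)
    } else {
      manifest$stages[[name]] <<- list(status = "ok", seconds = elapsed)
      manifest$results[[name]] <<- res
    }
    invisible(NULL)
  }
  env <- new.env()
  run_stage("simulate", function() {
    lp <- do.call(landscape_params,
                  c(config$landscape,
                    if (is.null(config$landscape$seed))
                      list(seed = derive_seed(config$seed, "landscape"))))
    sim <- generate_landscape(lp)
    biases <- default_bias_surfaces(sim$truth)
    occ <- sample_occurrences(sim$truth, config$n_survey, config$n_citizen,
                              biases$survey, biases$citizen,
                              derive_seed(config$seed, "occurrences"))
    occ <- merge_occurrences(occ[occ$source == "survey", ],
                             occ[occ$source == "citizen", ],
                             sim$truth$study_area)
    env$sim <- sim; env$biases <- biases; env$occ <- occ
    list(n_occurrences = nrow(occ),
         source_counts = as.list(attr(occ, "source_counts")))
  })
  run_stage("select", function() {
    pre_bias <- build_bias_surface(env$occ, env$sim$truth$study_area,
                                   env$sim$stack[[1L]],
                                   config$bias$bandwidth, config$bias$buffer,
                                   config$bias$focal_window)
    pre_bg <- draw_background(pre_bias, nrow(env$occ),
                              derive_seed(config$seed, "select_bg"))
    design <- make_design(env$sim$stack, env$occ, pre_bg)
    rep_ <- prune_collinear(env$sim$stack, design,
                            threshold = config$selection$threshold,
                            k = config$gam$k)
    retained <- rep_$retained
    specs <- lapply(retained, function(p)
      build_smooth(design[[p]], k = config$gam$k, predictor = p))
    cfit <- fit_gam(design, specs)
    conc <- concurvity_index(cfit, config$selection$concurvity_threshold)
    flagged <- names(conc)[attr(conc, "flagged")]
    retained <- setdiff(retained, flagged)
    env$stack_sel <- env$sim$stack[retained]
    list(selection = rep_, concurvity = as.list(conc),
         concurvity_removed = flagged, modeled = retained)
  })
  run_stage("tune", function() {
    if (!isTRUE(config$tune$enabled)) return(list(enabled = FALSE))
    bias <- build_bias_surface(env$occ, env$sim$truth$study_area,
                               env$sim$stack[[1L]], config$bias$bandwidth,
                               config$bias$buffer, config$bias$focal_window)
    pool <- draw_background(bias, config$pool_size,
                            derive_seed(config$seed, "pool"))
    tg <- tune_gam(env$occ, pool, env$stack_sel,
                   repeats = config$tune$repeats,
                   seed = derive_seed(config$seed, "tune_gam"))
    list(enabled = TRUE, gam = tg["selected"], gam_summary = tg$summary)
  })
  run_stage("fit", function() {
    if (is.null(env$stack_sel)) env$stack_sel <- env$sim$stack
    run_model_suite(env$occ, env$stack_sel, env$sim$truth$study_area, config)
  })
  run_stage("ablation", function() {
    if (!isTRUE(config$ablation$enabled)) return(list(enabled = FALSE))
    if (is.null(env$stack_sel)) env$stack_sel <- env$sim$stack
    ablation_citizen_science(env$occ, env$stack_sel,
                             env$sim$truth$study_area, config)
  })
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("pipeline run manifest\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-10s %s (%.1fs)%s\n", nm, x$stages[[nm]]$status,
                x$stages[[nm]]$seconds,
                if (!is.null(x$stages[[nm]]$error))
                  paste0(": ", x$stages[[nm]]$error) else ""))
  invisible(x)
}
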