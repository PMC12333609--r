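#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random positive score outranks a random negative
#' score, ties counted 1/2; computed exactly from midranks.
#'
#' @param pos_scores,neg_scores non-empty numeric vectors.
#' @return AUC in [0, 1].
#' @export
auc <- function(pos_scores, neg_scores) {
  n1 <- length(pos_scores); n0 <- length(neg_scores)
  if (n1 == 0L || n0 == 0L) stop("both score vectors must be non-empty")
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True skill statistic with optimized threshold
#'
#' Maximizes sensitivity + specificity - 1 over candidate thresholds (the
#' midpoints between adjacent distinct pooled scores, plus -Inf and +Inf),
#' classifying `score >= threshold` as positive; on ties the smallest
#' maximizing threshold is returned.
#'
#' @param pos_scores,neg_scores non-empty numeric vectors.
#' @return list with `tss` and `threshold`.
#' @export
tss <- function(pos_scores, neg_scores) {
  n1 <- length(pos_scores); n0 <- length(neg_scores)
  if (n1 == 0L || n0 == 0L) stop("both score vectors must be non-empty")
  s <- sort(unique(c(pos_scores, neg_scores)))
  cand <- c(-Inf, if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2, Inf)
  best <- -Inf; best_t <- cand[1L]
  for (t in cand) {
    sens <- mean(pos_scores >= t)
    spec <- mean(neg_scores < t)
    v <- sens + spec - 1
    if (v > best + 1e-15) { best <- v; best_t <- t }
  }
  list(tss = best, threshold = best_t)
}

#' Model recipes for cross-validation and tuning
#'
#' A recipe couples a `fit(design)` function with a `score(model, design)`
#' function returning one suitability score per row.  `gam_recipe()` fits
#' the penalized-spline binomial GAM on all predictors of the design;
#' `maxent_recipe()` fits the maximum-entropy model using the design's
#' label-0 rows as background (features are rebuilt on each training
#' background, so no information leaks across folds).
#'
#' @param k GAM basis dimension per smooth.
#' @param beta maxent regularization multiplier.
#' @param n_hinge_knots hinge knots per direction.
#' @param iterations maxent cycle cap.
#' @param ... passed to [fit_gam()].
#' @return a list with elements `fit`, `score` and `label`.
#' @export
gam_recipe <- function(k = 5L, ...) {
  list(label = sprintf("gam(k=%d)", k),
       fit = function(design) {
         preds <- design_predictors(design)
         specs <- lapply(preds, function(p)
           build_smooth(design[[p]], k = k, predictor = p))
         fit_gam(design, specs, ...)
       },
       score = function(model, design) gam_linpred(model, design)$eta)
}

#' @rdname gam_recipe
#' @export
maxent_recipe <- function(beta = 1, n_hinge_knots = 30L, iterations = 500L) {
  list(label = sprintf("maxent(beta=%g)", beta),
       fit = function(design) {
         preds <- design_predictors(design)
         bg <- design[design$label == 0, preds, drop = FALSE]
         pr <- design[design$label == 1, preds, drop = FALSE]
         feats <- make_features(bg, preds, n_hinge_knots)
         fit_maxent(pr, bg, feats, beta = beta, iterations = iterations)
       },
       score = function(model, design)
         maxent_scores(model, design[design_predictors(design)]))
}

#' Stratified k-fold cross-validation of a model recipe
#'
#' Folds are stratified on the design label; each fold serves once as the
#' test set with the model refit on the remainder.  Folds whose test set
#' loses a class are skipped with a warning.
#'
#' @param recipe a [gam_recipe()]/[maxent_recipe()]-style list.
#' @param design design table from [make_design()].
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return list: `mean_auc`, `se_auc` (sd across folds / sqrt(folds)),
#'   `mean_tss`, `folds` (per-fold data.frame), `n_skipped`.
#' @export
cross_validate <- function(recipe, design, k = 10L, seed = 1L) {
  fold <- stratified_kfold(design$label, k, seed)
  res <- data.frame(fold = integer(), auc = numeric(), tss = numeric(),
                    threshold = numeric(), n_pos = integer(), n_neg = integer())
  n_skipped <- 0L
  for (f in seq_len(k)) {
    test <- design[fold == f, , drop = FALSE]
    train <- design[fold != f, , drop = FALSE]
    attr(test, "predictors") <- attr(train, "predictors") <- design_predictors(design)
    if (length(unique(test$label)) < 2L) {
      warning("fold ", f, " has a single class in test; skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    model <- recipe$fit(train)
    sc <- recipe$score(model, test)
    pos <- sc[test$label == 1]; neg <- sc[test$label == 0]
    t_ <- tss(pos, neg)
    res <- rbind(res, data.frame(fold = f, auc = auc(pos, neg), tss = t_$tss,
                                 threshold = t_$threshold,
                                 n_pos = length(pos), n_neg = length(neg)))
  }
  list(mean_auc = mean(res$auc), se_auc = stats::sd(res$auc) / sqrt(nrow(res)),
       mean_tss = mean(res$tss), folds = res, n_skipped = n_skipped)
}

# stratified train/test split indices (train_frac per class, seeded)
split_train_test <- function(labels, train_frac, seed) {
  with_seed(seed, {
    train <- logical(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_tr <- max(1L, min(length(idx) - 1L, round(train_frac * length(idx))))
      train[sample(idx, n_tr)] <- TRUE
    }
    train
  })
}

tune_loop <- function(settings, presences, pool, stack, repeats, train_frac,
                      seed, make_recipe, draw_negatives) {
  records <- NULL
  counter <- 0L
  for (si in seq_len(nrow(settings))) {
    for (r in seq_len(repeats)) {
      counter <- counter + 1L
      sd_ <- derive_seed(seed, "tune", counter)
      neg <- draw_negatives(settings[si, ], sd_)
      design <- make_design(stack, presences, neg)
      train <- split_train_test(design$label, train_frac, sd_ + 1L)
      tr <- design[train, , drop = FALSE]; te <- design[!train, , drop = FALSE]
      attr(tr, "predictors") <- attr(te, "predictors") <- design_predictors(design)
      recipe <- make_recipe(settings[si, ])
      model <- recipe$fit(tr)
      sc <- recipe$score(model, te)
      pos <- sc[te$label == 1]; neg_sc <- sc[te$label == 0]
      records <- rbind(records, cbind(settings[si, , drop = FALSE],
                                      data.frame(repeat_ = r,
                                                 auc = auc(pos, neg_sc),
                                                 tss = tss(pos, neg_sc)$tss)))
    }
  }
  rownames(records) <- NULL
  records
}

# selection rule shared by both tuning loops: among settings whose mean TSS
# is within tss_slack of the maximum, take the highest mean AUC; ties break
# toward the smaller values of the tie-break columns, in order.
select_setting <- function(records, setting_cols, tie_order, tss_slack = 0.02) {
  agg <- stats::aggregate(records[c("auc", "tss")],
                          records[setting_cols], mean)
  eligible <- agg[agg$tss >= max(agg$tss) - tss_slack, , drop = FALSE]
  eligible <- eligible[order(-eligible$auc,
                             eligible[[tie_order[1L]]],
                             eligible[[tie_order[2L]]]), , drop = FALSE]
  list(selected = eligible[1L, setting_cols, drop = FALSE], summary = agg)
}

#' Tune the GAM over basis dimension and background count
#'
#' For every (k, background count) setting and repeat: draw that many
#' pseudo-absences from the pool, split 90/10 stratified, fit, and score
#' AUC and TSS on the test split.  The selected setting maximizes mean AUC
#' among settings whose mean TSS is within 0.02 of the maximum; ties break
#' toward smaller k, then fewer background points.
#'
#' @param presences occurrence data.frame (`x`, `y`).
#' @param pool background pool from [draw_background()].
#' @param stack `predictor_stack` of the modeled predictors.
#' @param k_values candidate basis dimensions (default 3, 5, 10).
#' @param bg_counts candidate background counts; default 30 values sampled
#'   uniformly (seeded) from 30..250.
#' @param repeats repeats per setting (default 50).
#' @param train_frac training fraction of the random splits (default 0.9).
#' @param seed integer master seed.
#' @return list: `records` (one row per setting x repeat), `selected`,
#'   `summary` (per-setting means).
#' @export
tune_gam <- function(presences, pool, stack, k_values = c(3L, 5L, 10L),
                     bg_counts = NULL, repeats = 50L, train_frac = 0.9,
                     seed = 1L) {
  if (is.null(bg_counts))
    bg_counts <- sort(with_seed(derive_seed(seed, "bg_candidates"),
                                sample(30:250, 30L)))
  if (max(bg_counts) > nrow(pool)) stop("pool too small for largest candidate")
  settings <- expand.grid(k = k_values, n_background = bg_counts,
                          KEEP.OUT.ATTRS = FALSE)
  records <- tune_loop(settings, presences, pool, stack, repeats, train_frac,
                       seed,
                       make_recipe = function(s) gam_recipe(k = s$k),
                       draw_negatives = function(s, sd_)
                         subsample_pseudo_absences(pool, s$n_background,
                                                   ratio = 1, seed = sd_))
  sel <- select_setting(records, c("k", "n_background"),
                        c("k", "n_background"))
  c(list(records = records), sel)
}

#' Tune maxent over background count and regularization multiplier
#'
#' Same scheme as [tune_gam()]: backgrounds subsampled from the pool, 90/10
#' stratified splits, AUC/TSS on test; selection maximizes mean AUC among
#' settings with mean TSS within 0.02 of the maximum, ties toward smaller
#' beta then fewer background points.
#'
#' @inheritParams tune_gam
#' @param bg_counts candidate background counts; default `n_bg_candidates`
#'   values sampled uniformly (seeded) from 1,000..12,000.
#' @param beta_values candidate regularization multipliers (default 1..5).
#' @param n_bg_candidates number of background-count candidates drawn when
#'   `bg_counts` is NULL (default 30).
#' @param n_hinge_knots,iterations passed to the maxent recipe.
#' @return list: `records`, `selected`, `summary`.
#' @export
tune_maxent <- function(presences, pool, stack, bg_counts = NULL,
                        beta_values = 1:5, repeats = 50L, train_frac = 0.9,
                        n_bg_candidates = 30L, n_hinge_knots = 30L,
                        iterations = 500L, seed = 1L) {
  if (is.null(bg_counts))
    bg_counts <- sort(with_seed(derive_seed(seed, "bg_candidates"),
                                sample(1000:12000, n_bg_candidates)))
  if (max(bg_counts) > nrow(pool)) stop("pool too small for largest candidate")
  settings <- expand.grid(beta = beta_values, n_background = bg_counts,
                          KEEP.OUT.ATTRS = FALSE)
  records <- tune_loop(settings, presences, pool, stack, repeats, train_frac,
                       seed,
                       make_recipe = function(s)
                         maxent_recipe(beta = s$beta,
                                       n_hinge_knots = n_hinge_knots,
                                       iterations = iterations),
                       draw_negatives = function(s, sd_)
                         subsample_pseudo_absences(pool, s$n_background,
                                                   ratio = 1, seed = sd_))
  sel <- select_setting(records, c("beta", "n_background"),
                        c("beta", "n_background"))
  c(list(records = records), sel)
}

#' Per-cell uncertainty maps (mean, standard error, CV)
#'
#' Replicate mode summarizes a stack of replicate prediction rasters:
#' per-cell mean, standard error of the mean (`sd / sqrt(R)`), and the
#' coefficient of variation `100 * sd / mean` (describing prediction
#' variability).  Analytic mode passes a (mean, SE) pair through with
#' `CV = 100 * SE / mean`.  CV is nodata where the mean is at or below
#' 1e-9.  The two modes are not comparable; the mode is recorded in the
#' result.
#'
#' @param replicates list of aligned `rast_grid` replicates (>= 2), or NULL.
#' @param mean_grid,se_grid analytic-mode inputs (used when `replicates` is
#'   NULL).
#' @return list of `rast_grid`s `mean`, `standard_error`, `cv` (percent),
#'   plus `mode`.
#' @export
uncertainty_maps <- function(replicates = NULL, mean_grid = NULL,
                             se_grid = NULL) {
  if (!is.null(replicates)) {
    if (length(replicates) < 2L) stop("need at least two replicates")
    ref <- replicates[[1L]]
    for (g in replicates) stop_unless_aligned(ref, g, "replicates")
    R <- length(replicates)
    arr <- vapply(replicates, function(g) g$values,
                  matrix(0, nrow(ref$values), ncol(ref$values)))
    mu <- apply(arr, c(1, 2), mean)
    sd_ <- apply(arr, c(1, 2), stats::sd)
    se <- sd_ / sqrt(R)
    cv <- 100 * sd_ / mu
    cv[!is.finite(mu) | mu <= 1e-9] <- NA_real_
    mk <- function(v) rast_grid(v, ref$xmin, ref$ymax, ref$dx, ref$dy, ref$crs)
    list(mean = mk(mu), standard_error = mk(se), cv = mk(cv),
         mode = "replicate")
  } else {
    if (is.null(mean_grid) || is.null(se_grid))
      stop("supply replicates, or mean_grid and se_grid")
    stop_unless_aligned(mean_grid, se_grid, "mean/se grids")
    cv <- 100 * se_grid$values / mean_grid$values
    cv[!is.finite(mean_grid$values) | mean_grid$values <= 1e-9] <- NA_real_
    list(mean = mean_grid, standard_error = se_grid,
         cv = rast_grid(cv, mean_grid$xmin, mean_grid$ymax, mean_grid$dx,
                        mean_grid$dy, mean_grid$crs),
         mode = "analytic")
  }
}
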