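#' Build a maxent feature set (linear, quadratic, hinge)
#'
#' Per predictor: one linear feature (min-max scaled on the background), one
#' quadratic (the square, min-max scaled on the background squares), and
#' forward hinges `max(0, (x - t) / (max - t))` plus reverse hinges
#' `max(0, (t - x) / (t - min))` at `n_hinge_knots` evenly spaced background
#' quantiles (degenerate knots dropped).  Every feature maps inputs (clamped
#' to the background range) into [0, 1].  Product and threshold features are
#' never generated.  Constant predictors are dropped with a warning.
#'
#' @param background data.frame of background predictor values.
#' @param predictors predictor names (default: all columns except `label`
#'   and `weight`).
#' @param n_hinge_knots hinge knots per direction (default 30).
#' @return object of class `maxent_features`.
#' @export
make_features <- function(background, predictors = NULL, n_hinge_knots = 30L) {
  if (nrow(background) == 0L) stop("background must be non-empty")
  if (is.null(predictors))
    predictors <- setdiff(names(background), c("label", "weight"))
  defs <- NULL
  ranges <- list()
  for (p in predictors) {
    x <- background[[p]]
    mn <- min(x); mx <- max(x)
    if (!(mx > mn)) {
      warning("constant predictor '", p, "': features dropped")
      next
    }
    ranges[[p]] <- c(mn, mx)
    x2 <- x^2
    defs <- rbind(defs,
      data.frame(parent = p, class = "linear", lo = mn, hi = mx,
                 name = paste0(p, ".lin")),
      data.frame(parent = p, class = "quadratic", lo = min(x2), hi = max(x2),
                 name = paste0(p, ".quad")))
    if (n_hinge_knots > 0L) {
      probs <- seq(0, 1, length.out = n_hinge_knots + 2L)[-c(1L, n_hinge_knots + 2L)]
      knots <- unique(unname(stats::quantile(x, probs, type = 7)))
      fwd <- knots[knots < mx & knots > mn]
      if (length(fwd))
        defs <- rbind(defs, data.frame(parent = p, class = "hinge_forward",
                                       lo = fwd, hi = mx,
                                       name = sprintf("%s.hf%.6g", p, fwd)))
      rev_ <- knots[knots > mn & knots < mx]
      if (length(rev_))
        defs <- rbind(defs, data.frame(parent = p, class = "hinge_reverse",
                                       lo = mn, hi = rev_,
                                       name = sprintf("%s.hr%.6g", p, rev_)))
    }
  }
  if (is.null(defs)) stop("no usable predictors")
  rownames(defs) <- NULL
  structure(list(defs = defs, ranges = ranges,
                 predictors = names(ranges)),
            class = "maxent_features")
}

#' @export
print.maxent_features <- function(x, ...) {
  cat(sprintf("maxent_features: %d features over %d predictors (%s)\n",
              nrow(x$defs), length(x$predictors),
              paste(x$predictors, collapse = ", ")))
  invisible(x)
}

#' Evaluate a feature set on a data table
#'
#' Inputs are clamped to the background range of each parent predictor, so
#' all feature values lie in [0, 1].
#'
#' @param features a `maxent_features` object.
#' @param data data.frame providing every parent predictor.
#' @return numeric matrix, one column per feature.
#' @export
featurize <- function(features, data) {
  defs <- features$defs
  out <- matrix(0, nrow(data), nrow(defs),
                dimnames = list(NULL, defs$name))
  xs <- list()
  for (p in features$predictors) {
    r <- features$ranges[[p]]
    xs[[p]] <- pmin(r[2L], pmax(r[1L], data[[p]]))
  }
  for (i in seq_len(nrow(defs))) {
    x <- xs[[defs$parent[i]]]
    out[, i] <- switch(defs$class[i],
      linear = (x - defs$lo[i]) / (defs$hi[i] - defs$lo[i]),
      quadratic = (x^2 - defs$lo[i]) / (defs$hi[i] - defs$lo[i]),
      hinge_forward = pmax(0, (x - defs$lo[i]) / (defs$hi[i] - defs$lo[i])),
      hinge_reverse = pmax(0, (defs$hi[i] - x) / (defs$hi[i] - defs$lo[i])))
  }
  out
}

# regularized gain for given lambdas over precomputed feature matrices
maxent_gain <- function(lambda, pbar, eta_b, beta_j) {
  mx <- max(eta_b)
  logZ <- mx + log(sum(exp(eta_b - mx)))
  sum(lambda * pbar) - logZ + log(length(eta_b)) - sum(beta_j * abs(lambda))
}

#' Fit a maximum-entropy presence-only model
#'
#' Maximizes the L1-regularized training gain
#' `G = mean_presence(lambda . f) - log Z + log N - sum_j beta_j |lambda_j|`
#' (with `Z` the sum of `exp(lambda . f)` over the `N` background points) by
#' cyclic coordinate descent with soft-threshold updates and step halving,
#' so the gain is non-decreasing across updates.  Per-feature regularization
#' is `beta_j = beta * c_class * s_j / sqrt(m)` with `s_j` the presence-
#' sample standard deviation of feature `j` (floored at 1e-3), `c_class` 1
#' for linear/quadratic and 0.5 for hinge features, and `m` the presence
#' count.
#'
#' @param presences,background data.frames of predictor values (presences
#'   >= 1 row, background >= 2 rows).
#' @param features a `maxent_features` object.
#' @param beta regularization multiplier (>= 0).
#' @param iterations cap on full coordinate-descent cycles (default 500).
#' @param tol stop when a full cycle improves the gain by less than this.
#' @return object of class `maxent_fit`.
#' @export
fit_maxent <- function(presences, background, features, beta = 1,
                       iterations = 500L, tol = 1e-7) {
  if (beta < 0) stop("beta must be >= 0")
  if (nrow(presences) < 1L) stop("need at least one presence")
  if (nrow(background) < 2L) stop("need at least two background points")
  Fp <- featurize(features, presences)
  Fb <- featurize(features, background)
  m <- nrow(Fp); N <- nrow(Fb)
  pbar <- colMeans(Fp)
  s <- apply(Fp, 2L, stats::sd)
  s[!is.finite(s)] <- 0
  cc <- ifelse(features$defs$class %in% c("linear", "quadratic"), 1, 0.5)
  beta_j <- beta * cc * pmax(s, 1e-3) / sqrt(m)
  p <- ncol(Fb)
  lambda <- numeric(p)
  eta_b <- numeric(N)
  w <- rep(1, N)            # exp(eta_b - shift)
  sw <- N
  shift <- 0
  gain <- 0                 # gain at lambda = 0
  trace_feat <- integer(0); trace_gain <- numeric(0)
  gain_path <- numeric(0)
  n_cycles <- 0L
  converged <- FALSE
  for (cycle in seq_len(iterations)) {
    n_cycles <- cycle
    gain0 <- gain
    for (j in seq_len(p)) {
      fj <- Fb[, j]
      Ej <- sum(w * fj) / sw
      g <- pbar[j] - Ej
      h <- max(sum(w * fj * fj) / sw - Ej^2, 1e-9)
      z <- h * lambda[j] + g
      lam_new <- sign(z) * max(abs(z) - beta_j[j], 0) / h
      delta <- lam_new - lambda[j]
      if (abs(delta) < 1e-12) next
      for (half in 0:30) {
        wj <- w * exp(delta * fj)
        swj <- sum(wj)
        lam_try <- lambda[j] + delta
        gain_try <- gain +
          delta * pbar[j] - (log(swj) - log(sw)) -
          beta_j[j] * (abs(lam_try) - abs(lambda[j]))
        if (is.finite(gain_try) && gain_try >= gain - 1e-12) break
        delta <- delta / 2
        wj <- NULL
      }
      if (is.null(wj) || gain_try < gain - 1e-12) next
      gchange <- gain_try - gain
      lambda[j] <- lambda[j] + delta
      w <- wj; sw <- swj
      gain <- gain_try
      if (gchange > 0) {
        trace_feat <- c(trace_feat, j)
        trace_gain <- c(trace_gain, gchange)
      }
    }
    # refresh weights from scratch once per cycle to cap numeric drift
    eta_b <- as.vector(Fb %*% lambda)
    shift <- max(eta_b)
    w <- exp(eta_b - shift)
    sw <- sum(w)
    gain <- maxent_gain(lambda, pbar, eta_b, beta_j)
    gain_path <- c(gain_path, gain)
    if (abs(gain - gain0) < tol) { converged <- TRUE; break }
  }
  eta_b <- as.vector(Fb %*% lambda)
  mx <- max(eta_b)
  logZ <- mx + log(sum(exp(eta_b - mx)))
  q <- exp(eta_b - logZ)
  H <- -sum(q * log(pmax(q, 1e-300)))
  reg_gain <- maxent_gain(lambda, pbar, eta_b, beta_j)
  unreg_gain <- reg_gain + sum(beta_j * abs(lambda))
  structure(list(lambdas = stats::setNames(lambda, features$defs$name),
                 beta = beta, beta_j = beta_j, features = features,
                 presence_means = pbar,
                 fitted_expectations = as.vector(q %*% Fb),
                 logZ = logZ, entropy = H, n_background = N, n_presence = m,
                 regularized_gain = reg_gain, unregularized_gain = unreg_gain,
                 trace = data.frame(feature = features$defs$name[trace_feat],
                                    parent = features$defs$parent[trace_feat],
                                    gain_change = trace_gain),
                 gain_path = gain_path,
                 converged = converged, n_cycles = n_cycles),
            class = "maxent_fit")
}

#' @export
print.maxent_fit <- function(x, ...) {
  cat(sprintf("maxent_fit: %d features (%d active), beta = %.3g\n",
              length(x$lambdas), sum(x$lambdas != 0), x$beta))
  cat(sprintf("  regularized gain %.4f, unregularized %.4f, %d cycles%s\n",
              x$regularized_gain, x$unregularized_gain, x$n_cycles,
              if (!x$converged) " (cap reached)" else ""))
  invisible(x)
}

# lambda . f scores for a data.frame of predictor values
maxent_scores <- function(fit, data) {
  as.vector(featurize(fit$features, data) %*% unname(fit$lambdas))
}

#' Predict raw and logistic maxent suitability rasters
#'
#' `raw(x) = exp(lambda . f(x)) / Z` with `Z` the training-background
#' normalizer, and `logistic(x) = eH r / (1 + eH r)` with `eH = exp(H)`, `H`
#' the entropy of the fitted raw distribution over the background (so a
#' zero model scores 0.5 everywhere).  Feature inputs are clamped to the
#' background range; nodata predictor cells are nodata.
#'
#' @param fit a `maxent_fit`.
#' @param stack `predictor_stack` providing all parent predictors.
#' @return list of `rast_grid`s: `raw`, `logistic`.
#' @export
predict_maxent <- function(fit, stack) {
  need <- fit$features$predictors
  miss <- setdiff(need, names(stack))
  if (length(miss)) stop("stack lacks predictors: ", paste(miss, collapse = ", "))
  ref <- stack[[1L]]
  vals <- lapply(stack[need], function(g) as.vector(g$values))
  ok <- Reduce(`&`, lapply(vals, is.finite))
  nd <- as.data.frame(lapply(vals, function(v) v[ok]), optional = TRUE)
  eta <- maxent_scores(fit, nd)
  raw <- exp(eta - fit$logZ)
  ehr <- exp(fit$entropy) * raw
  logistic <- ehr / (1 + ehr)
  fill <- function(v) {
    m <- rep(NA_real_, length(ok)); m[ok] <- v
    rast_grid(matrix(m, nrow(ref$values), ncol(ref$values)),
              ref$xmin, ref$ymax, ref$dx, ref$dy, ref$crs)
  }
  list(raw = fill(raw), logistic = fill(logistic))
}

#' Percent contribution of each predictor to the training gain
#'
#' Positive gain changes recorded during coordinate descent are credited to
#' the updated feature's parent predictor and normalized to sum to 100.
#'
#' @param fit a `maxent_fit`.
#' @return data.frame: `predictor`, `percent`.
#' @export
percent_contribution <- function(fit) {
  preds <- fit$features$predictors
  credit <- stats::setNames(numeric(length(preds)), preds)
  if (nrow(fit$trace)) {
    agg <- tapply(fit$trace$gain_change, fit$trace$parent, sum)
    credit[names(agg)] <- agg
  }
  tot <- sum(credit)
  if (tot <= 0) {
    warning("no positive gain credited; contributions are all zero")
    pct <- credit
  } else pct <- 100 * credit / tot
  data.frame(predictor = preds, percent = unname(pct))
}

#' Permutation importance of each predictor
#'
#' Permutes one predictor at a time across the pooled presence + background
#' rows (seeded), recomputes the training AUC of presence-vs-background
#' scores, and reports the AUC drops (floored at 0) normalized to sum to
#' 100.
#'
#' @param fit a `maxent_fit`.
#' @param presences,background data.frames of predictor values.
#' @param seed integer seed.
#' @return data.frame: `predictor`, `auc_drop`, `percent`.
#' @export
permutation_importance <- function(fit, presences, background, seed = 1L) {
  preds <- fit$features$predictors
  pooled <- rbind(presences[preds], background[preds])
  m <- nrow(presences)
  lab <- rep(c(TRUE, FALSE), c(m, nrow(background)))
  base_scores <- maxent_scores(fit, pooled)
  if (length(unique(base_scores)) == 1L)
    stop("degenerate scores: permutation importance undefined")
  auc0 <- auc(base_scores[lab], base_scores[!lab])
  drops <- stats::setNames(numeric(length(preds)), preds)
  with_seed(seed, {
    for (p in preds) {
      perm <- pooled
      perm[[p]] <- perm[[p]][sample.int(nrow(perm))]
      sc <- maxent_scores(fit, perm)
      drops[p] <- max(0, auc0 - auc(sc[lab], sc[!lab]))
    }
  })
  tot <- sum(drops)
  pct <- if (tot > 0) 100 * drops / tot else drops
  data.frame(predictor = preds, auc_drop = unname(drops),
             percent = unname(pct))
}

#' Bootstrap replicate predictions
#'
#' Each replicate resamples the presences with replacement (same size),
#' refits the model against the fixed background, and predicts the logistic
#' raster.  Replicates are seeded via a per-replicate counter.  Replicates
#' that hit the cycle cap without converging are dropped (error if more
#' than 10% drop).
#'
#' @param presences,background data.frames of predictor values.
#' @param features a `maxent_features` object.
#' @param stack `predictor_stack` for prediction.
#' @param n_replicates number of bootstrap replicates (>= 2).
#' @param beta regularization multiplier.
#' @param iterations coordinate-descent cycle cap per replicate.
#' @param seed integer master seed.
#' @return list of logistic `rast_grid`s, with the number of dropped
#'   replicates in the `"n_dropped"` attribute and the number that stopped
#'   at the cycle cap (still used, as in the reference tool) in
#'   `"n_at_cap"`.
#' @export
bootstrap_predict <- function(presences, background, features, stack,
                              n_replicates = 500L, beta = 1,
                              iterations = 500L, seed = 1L) {
  if (n_replicates < 2L) stop("need at least two replicates")
  out <- vector("list", n_replicates)
  dropped <- 0L
  at_cap <- 0L
  for (r in seq_len(n_replicates)) {
    idx <- with_seed(derive_seed(seed, "bootstrap", r),
                     sample.int(nrow(presences), replace = TRUE))
    fit <- fit_maxent(presences[idx, , drop = FALSE], background, features,
                      beta = beta, iterations = iterations)
    if (!is.finite(fit$regularized_gain)) { dropped <- dropped + 1L; next }
    if (!fit$converged) at_cap <- at_cap + 1L
    pred <- predict_maxent(fit, stack)$logistic
    if (!any(is.finite(pred$values))) { dropped <- dropped + 1L; next }
    out[[r]] <- pred
  }
  out <- Filter(Negate(is.null), out)
  if (dropped > 0.1 * n_replicates)
    stop("more than 10% of bootstrap replicates failed")
  attr(out, "n_dropped") <- dropped
  attr(out, "n_at_cap") <- at_cap
  out
}

#' Write a maxent fit as a lambdas text file plus JSON
#'
#' The lambdas file mirrors the de-facto text format: one line per feature
#' with name, lambda and the scaling constants, followed by the normalizer
#' and entropy.
#'
#' @param fit a `maxent_fit`.
#' @param path output path for the lambdas file; a `.json` sidecar is
#'   written next to it.
#' @export
write_maxent_lambdas <- function(fit, path) {
  defs <- fit$features$defs
  lines <- sprintf("%s, %.10g, %.10g, %.10g", defs$name,
                   unname(fit$lambdas), defs$lo, defs$hi)
  lines <- c(lines, sprintf("linearPredictorNormalizer, %.10g", fit$logZ),
             sprintf("entropy, %.10g", fit$entropy))
  writeLines(lines, path)
  jsonlite::write_json(list(lambdas = as.list(fit$lambdas), beta = fit$beta,
                            logZ = fit$logZ, entropy = fit$entropy,
                            regularized_gain = fit$regularized_gain,
                            unregularized_gain = fit$unregularized_gain),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
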