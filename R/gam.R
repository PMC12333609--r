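#' Presence/background design table
#'
#' Extracts predictor values at presence and background/pseudo-absence
#' points and assembles the model design: one row per point with a 0/1
#' label and unit weight.  Rows falling on nodata cells are dropped with a
#' warning.
#'
#' @param stack a `predictor_stack`.
#' @param presences,background data.frames with columns `x`, `y`.
#' @return data.frame with columns `label`, `weight` and one column per
#'   layer; predictor names in the `"predictors"` attribute.
#' @export
make_design <- function(stack, presences, background) {
  xp <- extract_stack(stack, presences$x, presences$y)
  xb <- extract_stack(stack, background$x, background$y)
  d <- rbind(cbind(label = 1, xp), cbind(label = 0, xb))
  d$weight <- 1
  ok <- stats::complete.cases(d)
  if (!all(ok)) {
    warning(sum(!ok), " point(s) on nodata cells dropped")
    d <- d[ok, , drop = FALSE]
  }
  rownames(d) <- NULL
  attr(d, "predictors") <- names(stack)
  d
}

design_predictors <- function(design) {
  p <- attr(design, "predictors")
  if (is.null(p)) p <- setdiff(names(design), c("label", "weight"))
  p
}

## ---------------------------------------------------------------------------
## P-spline smooth construction

#' Build a penalized B-spline smooth specification
#'
#' A B-spline basis with exactly `k` functions on quantile-spaced anchor
#' knots over the observed range (cubic for `k >= 4`; the order is reduced
#' to `k` for `k = 3` so the basis still sums to one over the data range),
#' with a second-order difference penalty.  Shrinkage uses the
#' double-penalty construction: a second penalty equal to the projection
#' onto the difference-penalty null space, so a term can be shrunk entirely
#' to zero.  Identifiability is enforced downstream by centering the basis
#' columns over the training rows.
#'
#' @param values numeric vector of training predictor values.
#' @param k basis dimension (>= 3); needs at least `k` distinct values.
#' @param predictor name tag for the smooth.
#' @return object of class `smooth_spec`.
#' @export
build_smooth <- function(values, k, predictor = "x") {
  k <- as.integer(k)
  if (k < 3L) stop("k must be >= 3")
  ux <- sort(unique(values[is.finite(values)]))
  if (length(ux) < k) stop("need at least k distinct values")
  ord <- min(4L, k)
  rng <- range(ux)
  # anchor knots t_ord .. t_{k+1} span the data range at quantile positions
  n_anchor <- k + 2L - ord
  anchors <- if (n_anchor == 1L) mean(rng) else
    unname(stats::quantile(ux, probs = seq(0, 1, length.out = n_anchor),
                           type = 7))
  anchors[1L] <- rng[1L]; anchors[n_anchor] <- rng[2L]
  anchors <- cummax(anchors)  # guard against non-monotone quantiles
  lo_sp <- if (n_anchor > 1L) anchors[2L] - anchors[1L] else diff(rng)
  hi_sp <- if (n_anchor > 1L) anchors[n_anchor] - anchors[n_anchor - 1L] else diff(rng)
  lo_sp <- max(lo_sp, 1e-8 + diff(rng) * 1e-6)
  hi_sp <- max(hi_sp, 1e-8 + diff(rng) * 1e-6)
  knots <- c(anchors[1L] - (ord - 1L):1 * lo_sp, anchors,
             anchors[n_anchor] + 1:(ord - 1L) * hi_sp)
  D <- diff(diag(k), differences = 2L)
  S <- crossprod(D)
  # orthonormal basis of the penalty null space (constant + linear sequences)
  U0 <- qr.Q(qr(cbind(rep(1, k), seq_len(k))))
  N <- tcrossprod(U0)
  spec <- structure(list(predictor = predictor, k = k, ord = ord,
                         knots = knots, range = rng, S = S, N = N,
                         colmeans = rep(0, k)),
                    class = "smooth_spec")
  spec$colmeans <- colMeans(eval_smooth_raw(spec, values))
  spec
}

# raw (uncentered) basis evaluation with linear extrapolation outside the
# training range
eval_smooth_raw <- function(spec, x) {
  lo <- spec$range[1L]; hi <- spec$range[2L]
  xc <- pmin(hi, pmax(lo, x))
  B <- splines::splineDesign(spec$knots, xc, ord = spec$ord, outer.ok = TRUE)
  below <- which(x < lo); above <- which(x > hi)
  if (length(below)) {
    d <- splines::splineDesign(spec$knots, rep(lo, length(below)),
                               ord = spec$ord, derivs = 1L, outer.ok = TRUE)
    B[below, ] <- B[below, , drop = FALSE] + d * (x[below] - lo)
  }
  if (length(above)) {
    d <- splines::splineDesign(spec$knots, rep(hi, length(above)),
                               ord = spec$ord, derivs = 1L, outer.ok = TRUE)
    B[above, ] <- B[above, , drop = FALSE] + d * (x[above] - hi)
  }
  B
}

#' Evaluate a smooth basis
#'
#' @param spec a `smooth_spec`.
#' @param x numeric vector of predictor values.
#' @param center subtract the stored training column means (default TRUE).
#' @return basis matrix with `k` columns.
#' @export
eval_smooth <- function(spec, x, center = TRUE) {
  B <- eval_smooth_raw(spec, x)
  if (center) B <- sweep(B, 2L, spec$colmeans)
  B
}

## ---------------------------------------------------------------------------
## Penalized IRLS with GCV-selected smoothing parameters

binom_deviance <- function(y, mu, w) {
  mu <- pmin(1 - 1e-12, pmax(1e-12, mu))
  -2 * sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
}

# penalty matrix for the full coefficient vector given per-term (lambda,
# lambda0) and term column indices
assemble_penalty <- function(specs, idx, lambda, lambda0, p_total) {
  P <- matrix(0, p_total, p_total)
  for (j in seq_along(specs)) {
    ii <- idx[[j]]
    P[ii, ii] <- lambda[j] * specs[[j]]$S + lambda0[j] * specs[[j]]$N
  }
  P
}

irls_fit <- function(X, y, w, P, tol = 1e-8, maxit = 200L) {
  n <- nrow(X)
  mu <- (w * y + 0.5) / (w + 1)
  eta <- stats::qlogis(mu)
  pdev_old <- Inf
  beta <- rep(0, ncol(X))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    mu <- pmin(1 - 1e-10, pmax(1e-10, stats::plogis(eta)))
    W <- w * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    XtW <- t(X * W)
    H <- XtW %*% X + P
    beta_new <- tryCatch(solve(H, XtW %*% z),
                         error = function(e) solve(H + diag(1e-8, ncol(X)),
                                                   XtW %*% z))
    eta <- as.vector(X %*% beta_new)
    beta <- beta_new
    dev <- binom_deviance(y, stats::plogis(eta), w)
    pdev <- dev + as.numeric(t(beta) %*% P %*% beta)
    if (abs(pdev_old - pdev) < tol * (abs(pdev) + 0.1)) { converged <- TRUE; break }
    pdev_old <- pdev
  }
  mu <- pmin(1 - 1e-10, pmax(1e-10, stats::plogis(eta)))
  W <- w * mu * (1 - mu)
  z <- eta + (y - mu) / (mu * (1 - mu))
  list(beta = as.vector(beta), eta = eta, mu = mu, W = W, z = z,
       deviance = binom_deviance(y, mu, w), converged = converged,
       iterations = iter)
}

# GCV score for penalty P on the (fixed) working model
gcv_score <- function(XtWX, XtWz, X, W, z, P) {
  H <- XtWX + P
  beta <- tryCatch(solve(H, XtWz), error = function(e) NULL)
  if (is.null(beta)) return(Inf)
  edf <- sum(diag(solve(H, XtWX)))
  rss <- sum(W * (z - as.vector(X %*% beta))^2)
  n <- length(z)
  n * rss / (n - edf)^2
}

#' Fit a penalized-spline binomial GAM with shrinkage smoothers
#'
#' Maximizes the penalized binomial (logit link) log-likelihood by penalized
#' IRLS.  Each smooth term carries a second-order difference penalty (times
#' `lambda`) plus a null-space shrinkage penalty (times `lambda0`); both are
#' selected by minimizing GCV over a log-spaced grid, coordinate-wise with
#' two sweeps, re-converging IRLS between sweeps.  AIC is
#' `deviance + 2 * edf` with edf the trace of the influence matrix.
#'
#' @param design design table from [make_design()] (needs both labels).
#' @param specs list of `smooth_spec` objects (possibly empty: intercept-
#'   only model).  Unnamed specs are matched by their `predictor` field.
#' @param lambda_grid candidate smoothing parameters (shared by `lambda`
#'   and the shrinkage `lambda0`).
#' @param sweeps GCV coordinate sweeps (default 2).
#' @param tol IRLS penalized-deviance convergence tolerance.
#' @param maxit maximum IRLS iterations.
#' @return object of class `gam_fit`.
#' @export
fit_gam <- function(design, specs = list(),
                    lambda_grid = 10^seq(-4, 4, length.out = 21),
                    sweeps = 2L, tol = 1e-8, maxit = 200L) {
  y <- design$label
  if (length(unique(y)) < 2L && length(specs) > 0L)
    stop("both labels must be present")
  w <- if (is.null(design$weight)) rep(1, nrow(design)) else design$weight
  # design matrix: intercept + centered basis blocks
  Xl <- list(matrix(1, nrow(design), 1L))
  idx <- list()
  pos <- 1L
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    B <- eval_smooth(sp, design[[sp$predictor]])
    Xl[[j + 1L]] <- B
    idx[[j]] <- pos + seq_len(ncol(B))
    pos <- pos + ncol(B)
  }
  X <- do.call(cbind, Xl)
  p_total <- ncol(X)
  nterm <- length(specs)
  lambda <- rep(1, nterm); lambda0 <- rep(1e-4, nterm)
  if (nterm > 0L) {
    for (s in seq_len(sweeps)) {
      P <- assemble_penalty(specs, idx, lambda, lambda0, p_total)
      f <- irls_fit(X, y, w, P, tol, maxit)
      XtWX <- t(X * f$W) %*% X
      XtWz <- t(X * f$W) %*% f$z
      for (j in seq_len(nterm)) {
        sc <- vapply(lambda_grid, function(l) {
          gcv_score(XtWX, XtWz, X, f$W, f$z,
                    assemble_penalty(specs, idx, `[<-`(lambda, j, l),
                                     lambda0, p_total))
        }, numeric(1))
        lambda[j] <- lambda_grid[which.min(sc)]
        sc0 <- vapply(lambda_grid, function(l) {
          gcv_score(XtWX, XtWz, X, f$W, f$z,
                    assemble_penalty(specs, idx, lambda,
                                     `[<-`(lambda0, j, l), p_total))
        }, numeric(1))
        lambda0[j] <- lambda_grid[which.min(sc0)]
      }
    }
  }
  P <- assemble_penalty(specs, idx, lambda, lambda0, p_total)
  f <- irls_fit(X, y, w, P, tol, maxit)
  XtWX <- t(X * f$W) %*% X
  H <- XtWX + P
  Vb <- solve(H)
  edf <- sum(diag(Vb %*% XtWX))
  mu0 <- sum(w * y) / sum(w)
  null_dev <- binom_deviance(y, rep(mu0, length(y)), w)
  sep <- any(f$mu > 1 - 1e-8 | f$mu < 1e-8)
  structure(list(intercept = f$beta[1L],
                 coefficients = lapply(idx, function(ii) f$beta[ii]),
                 beta = f$beta, idx = idx, specs = specs,
                 predictors = vapply(specs, `[[`, "", "predictor"),
                 lambda = lambda, lambda0 = lambda0,
                 Vb = Vb, XtWX = XtWX, X = X, y = y, w = w,
                 edf = edf, null_deviance = null_dev,
                 residual_deviance = f$deviance,
                 deviance_explained = 1 - f$deviance / null_dev,
                 aic = f$deviance + 2 * edf,
                 converged = f$converged, n_iterations = f$iterations,
                 separation_warning = sep),
            class = "gam_fit")
}

#' @export
print.gam_fit <- function(x, ...) {
  cat(sprintf("binomial P-spline GAM: %d smooth term(s), n = %d\n",
              length(x$specs), length(x$y)))
  cat(sprintf("  deviance explained %.3f, AIC %.2f, edf %.2f%s\n",
              x$deviance_explained, x$aic, x$edf,
              if (!x$converged) " (NOT converged)" else ""))
  if (length(x$predictors))
    cat("  lambda: ", paste(sprintf("%s=%.3g/%.3g", x$predictors, x$lambda,
                                    x$lambda0), collapse = ", "), "\n")
  invisible(x)
}

# linear predictor + its standard error for new predictor values (data.frame)
gam_linpred <- function(fit, newdata, se = FALSE) {
  n <- nrow(newdata)
  X <- matrix(1, n, 1L)
  for (j in seq_along(fit$specs))
    X <- cbind(X, eval_smooth(fit$specs[[j]], newdata[[fit$specs[[j]]$predictor]]))
  eta <- as.vector(X %*% fit$beta)
  if (!se) return(list(eta = eta))
  se_eta <- sqrt(pmax(0, rowSums((X %*% fit$Vb) * X)))
  list(eta = eta, se_eta = se_eta)
}

#' Predict probability and standard-error rasters from a GAM fit
#'
#' Per-cell inverse-logit of the linear predictor; the response-scale
#' standard error comes from the delta method on the penalized-fit
#' (Bayesian) coefficient covariance.  Cells with any nodata predictor are
#' nodata.  Cells requiring extrapolation beyond the training range of any
#' smooth are predicted by linear extension of the basis and flagged 0 in
#' the `coverage` raster (1 = inside training range).
#'
#' @param fit a `gam_fit`.
#' @param stack `predictor_stack` providing every fitted predictor.
#' @return list of `rast_grid`s: `probability`, `standard_error`, `coverage`.
#' @export
predict_gam <- function(fit, stack) {
  need <- fit$predictors
  miss <- setdiff(need, names(stack))
  if (length(miss)) stop("stack lacks predictors: ", paste(miss, collapse = ", "))
  ref <- stack[[1L]]
  vals <- lapply(stack, function(g) as.vector(g$values))
  ok <- Reduce(`&`, lapply(vals[need], is.finite),
               rep(TRUE, length(vals[[1L]])))
  if (length(need) == 0L) ok <- is.finite(vals[[1L]])
  nd <- as.data.frame(lapply(vals, function(v) v[ok]), optional = TRUE)
  lp <- gam_linpred(fit, nd, se = TRUE)
  p <- stats::plogis(lp$eta)
  se <- p * (1 - p) * lp$se_eta
  cov_ok <- rep(1, nrow(nd))
  for (sp in fit$specs) {
    x <- nd[[sp$predictor]]
    cov_ok[x < sp$range[1L] | x > sp$range[2L]] <- 0
  }
  fill <- function(v) {
    m <- rep(NA_real_, length(ok)); m[ok] <- v
    rast_grid(matrix(m, nrow(ref$values), ncol(ref$values)),
              ref$xmin, ref$ymax, ref$dx, ref$dy, ref$crs)
  }
  list(probability = fill(p), standard_error = fill(se), coverage = fill(cov_ok))
}

#' Partial response curve of a fitted smooth
#'
#' The centered smooth evaluated on an even grid over its training range,
#' other terms held out, with pointwise standard errors from the term's
#' coefficient covariance block.
#'
#' @param fit a `gam_fit`.
#' @param predictor name of a fitted smooth.
#' @param n_points grid resolution.
#' @return data.frame with columns `x`, `effect` (logit scale), `se`.
#' @export
partial_response <- function(fit, predictor, n_points = 100L) {
  j <- match(predictor, fit$predictors)
  if (is.na(j)) stop("unknown predictor: ", predictor)
  sp <- fit$specs[[j]]
  xg <- seq(sp$range[1L], sp$range[2L], length.out = n_points)
  B <- eval_smooth(sp, xg)
  beta_j <- fit$coefficients[[j]]
  Vj <- fit$Vb[fit$idx[[j]], fit$idx[[j]], drop = FALSE]
  data.frame(x = xg, effect = as.vector(B %*% beta_j),
             se = sqrt(pmax(0, rowSums((B %*% Vj) * B))))
}

#' Leave-one-out deviance-drop variable importance
#'
#' Refits the model without each predictor in turn; the importance of a
#' predictor is the drop in deviance explained (percentage points) and its
#' proportion of the full model's deviance explained.  Because smoothing
#' penalties are re-selected in the reduced models the proportions may sum
#' above 1.
#'
#' @param design design table from [make_design()].
#' @param specs full list of `smooth_spec` objects.
#' @param ... passed to [fit_gam()].
#' @return data.frame: `predictor`, `deviance_drop_pct` (percentage points),
#'   `proportion_of_total`, `converged`; full-model deviance explained in
#'   the `"de_full"` attribute.
#' @export
deviance_importance <- function(design, specs, ...) {
  full <- fit_gam(design, specs, ...)
  de_full <- full$deviance_explained
  out <- data.frame(predictor = vapply(specs, `[[`, "", "predictor"),
                    deviance_drop_pct = NA_real_,
                    proportion_of_total = NA_real_,
                    converged = NA)
  for (j in seq_along(specs)) {
    red <- fit_gam(design, specs[-j], ...)
    out$converged[j] <- red$converged
    if (red$converged) {
      out$deviance_drop_pct[j] <- 100 * (de_full - red$deviance_explained)
      out$proportion_of_total[j] <-
        (de_full - red$deviance_explained) / de_full
    }
  }
  attr(out, "de_full") <- de_full
  attr(out, "fit") <- full
  out
}

#' Resampling-based GAM prediction replicates
#'
#' Optional alternative to the analytic prediction standard errors: each
#' iteration redraws the pseudo-absences from the background pool, refits
#' the GAM, and predicts the probability raster, yielding a replicate stack
#' for [uncertainty_maps()].
#'
#' @param presences occurrence data.frame (`x`, `y`).
#' @param pool background pool from [draw_background()].
#' @param stack `predictor_stack`.
#' @param k basis dimension per smooth.
#' @param ratio pseudo-absence : presence ratio.
#' @param n_iterations number of replicates (default 1000).
#' @param seed integer master seed.
#' @return list of probability `rast_grid`s.
#' @export
gam_resample_predict <- function(presences, pool, stack, k = 5L, ratio = 1,
                                 n_iterations = 1000L, seed = 1L) {
  recipe <- gam_recipe(k = k)
  out <- vector("list", n_iterations)
  for (r in seq_len(n_iterations)) {
    pa <- subsample_pseudo_absences(pool, nrow(presences), ratio,
                                    derive_seed(seed, "gam_resample", r))
    design <- make_design(stack, presences, pa)
    out[[r]] <- predict_gam(recipe$fit(design), stack)$probability
  }
  out
}
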