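# a hand-built feature set with a single linear feature on predictor "x"
single_feature <- function(lo = 0, hi = 1) {
  structure(list(defs = data.frame(parent = "x", class = "linear",
                                   lo = lo, hi = hi, name = "x.lin"),
                 ranges = list(x = c(lo, hi)), predictors = "x"),
            class = "maxent_features")
}

test_that("feature construction scales, counts and drops as specified", {
  bg <- data.frame(x = c(1, 2, 3, 4))
  fs <- make_features(bg, n_hinge_knots = 2L)
  # 1 linear + 1 quadratic + 2 forward + 2 reverse hinges
  expect_equal(nrow(fs$defs), 6)
  F <- featurize(fs, bg)
  expect_true(all(F >= 0 & F <= 1))
  expect_equal(unname(F[4, "x.lin"]), 1)          # x = background max -> 1
  expect_equal(unname(F[1, "x.lin"]), 0)
  # forward hinge is 0 at and below its knot
  fwd <- fs$defs$name[fs$defs$class == "hinge_forward"][1]
  knot <- fs$defs$lo[fs$defs$name == fwd]
  expect_true(all(F[bg$x <= knot, fwd] == 0))
  # inputs beyond the background range are clamped
  F2 <- featurize(fs, data.frame(x = c(-10, 10)))
  expect_equal(F2[, "x.lin"], c(0, 1))
  expect_warning(make_features(data.frame(x = 1:4, const = 1)), "constant")
})

test_that("the single-binary-feature fit matches the closed form ln 16", {
  pres <- data.frame(x = rep(c(1, 0), c(8, 2)))    # presence frequency 0.8
  bg <- data.frame(x = rep(c(1, 0), c(20, 80)))    # background frequency 0.2
  fs <- single_feature()
  fit <- fit_maxent(pres, bg, fs, beta = 0, iterations = 1000)
  expect_equal(unname(fit$lambdas), log(16), tolerance = 1e-3)
  # independent 1-D oracle: direct maximization of the same gain
  gain1 <- function(l) 0.8 * l - log(sum(exp(l * bg$x))) + log(100)
  opt <- stats::optimize(gain1, c(0, 10), maximum = TRUE)
  expect_equal(unname(fit$lambdas), opt$maximum, tolerance = 1e-3)
  # logistic output ranks f = 1 cells above f = 0 cells
  g1 <- rast_grid(matrix(c(0, 1), 2, 2), dx = 100, crs = "local")
  pred <- predict_maxent(fit, predictor_stack(list(x = g1)))
  expect_gt(pred$logistic$values[2, 1], pred$logistic$values[1, 1])
})

test_that("coordinate descent matches a brute-force oracle on tiny problems", {
  for (seed in 1:3) {
    with_seed(seed, {
      bg <- data.frame(x = stats::runif(20))
      pres <- data.frame(x = stats::runif(8, 0.3, 1))
    })
    fs <- structure(list(
      defs = data.frame(parent = "x", class = c("linear", "quadratic"),
                        lo = c(min(bg$x), min(bg$x^2)),
                        hi = c(max(bg$x), max(bg$x^2)),
                        name = c("x.lin", "x.quad")),
      ranges = list(x = range(bg$x)), predictors = "x"),
      class = "maxent_features")
    beta <- 0.5
    fit <- fit_maxent(pres, bg, fs, beta = beta, iterations = 5000, tol = 1e-12)
    Fp <- featurize(fs, pres); Fb <- featurize(fs, bg)
    pbar <- colMeans(Fp)
    s <- pmax(apply(Fp, 2, stats::sd), 1e-3)
    bj <- beta * s / sqrt(nrow(pres))
    negG <- function(l) -(sum(l * pbar) - log(sum(exp(Fb %*% l))) +
                            log(nrow(bg)) - sum(bj * abs(l)))
    # multi-start Nelder-Mead (the L1 kink at 0 can stall a single start)
    opt <- NULL
    for (st in list(c(0, 0), c(1, 1), c(-1, 1), c(2, -2))) {
      o <- stats::optim(st, negG, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 10000))
      if (is.null(opt) || o$value < opt$value) opt <- o
    }
    expect_equal(unname(fit$lambdas), opt$par, tolerance = 1e-3)
  }
})

test_that("presences drawn from the background give a null fit", {
  with_seed(9, {
    bg <- data.frame(a = stats::runif(2000), b = stats::runif(2000))
    pres <- bg[sample.int(2000, 200), ]
  })
  # linear + quadratic features: every lambda stays near zero
  fs_lq <- make_features(bg, n_hinge_knots = 0L)
  fit_lq <- fit_maxent(pres, bg, fs_lq, beta = 1)
  expect_true(all(abs(fit_lq$lambdas) < 0.05))
  expect_lt(fit_lq$regularized_gain, 0.01)
  # with hinge features near-collinear pairs can carry offsetting weights,
  # but the fitted distribution still stays flat: gain ~ 0
  fs <- make_features(bg, n_hinge_knots = 5L)
  fit <- fit_maxent(pres, bg, fs, beta = 1)
  expect_lt(fit$regularized_gain, 0.01)
})

test_that("heavy regularization zeroes every feature and a zero model scores 0.5", {
  tp <- toy_pb(seed = 2)
  fs <- make_features(tp$bg, n_hinge_knots = 5L)
  fit <- fit_maxent(tp$pres, tp$bg, fs, beta = 100)
  expect_true(all(fit$lambdas == 0))
  expect_equal(fit$regularized_gain, 0)
  expect_equal(fit$entropy, log(nrow(tp$bg)))
  g <- rast_grid(matrix(stats::runif(100), 10, 10), dx = 100, crs = "local")
  st <- predictor_stack(list(x1 = g, x2 = g))
  pred <- predict_maxent(fit, st)
  expect_true(all(abs(pred$logistic$values - 0.5) < 1e-12))
  expect_true(all(abs(pred$raw$values - 1 / nrow(tp$bg)) < 1e-15))
})

test_that("the regularized gain is non-decreasing across cycles", {
  tp <- toy_pb(seed = 3)
  fs <- make_features(tp$bg, n_hinge_knots = 10L)
  fit <- fit_maxent(tp$pres, tp$bg, fs, beta = 1)
  expect_true(all(diff(fit$gain_path) > -1e-9))
  expect_gte(fit$regularized_gain, 0)
  expect_gte(fit$unregularized_gain, fit$regularized_gain)
})

test_that("maximum entropy moment-matches presence feature means at beta 0", {
  with_seed(4, {
    bg <- data.frame(x = stats::runif(300))
    keep <- stats::rbinom(300, 1, plogis(3 * bg$x - 1)) == 1
    pres <- bg[sample(which(keep), 60, replace = TRUE), , drop = FALSE]
  })
  fs <- make_features(bg, n_hinge_knots = 2L)   # 6 features
  fit <- fit_maxent(pres, bg, fs, beta = 0, iterations = 20000, tol = 1e-13)
  expect_equal(fit$fitted_expectations, unname(fit$presence_means),
               tolerance = 1e-4)
})

test_that("increasing beta never increases the total L1 norm", {
  tp <- toy_pb(seed = 5)
  fs <- make_features(tp$bg, n_hinge_knots = 8L)
  norms <- vapply(c(0, 0.5, 1, 2, 5), function(b)
    sum(abs(fit_maxent(tp$pres, tp$bg, fs, beta = b)$lambdas)), numeric(1))
  expect_true(all(diff(norms) <= 1e-6))
})

test_that("percent contribution credits the informative predictor and sums to 100", {
  with_seed(6, {
    bg <- data.frame(good = stats::runif(600), noise = stats::runif(600))
    keep <- stats::rbinom(600, 1, bg$good^2) == 1
    pres <- bg[sample(which(keep), 80, replace = TRUE), ]
  })
  fs <- make_features(bg, n_hinge_knots = 5L)
  fit <- fit_maxent(pres, bg, fs, beta = 1)
  pc <- percent_contribution(fit)
  expect_equal(sum(pc$percent), 100, tolerance = 1e-6)
  expect_gt(pc$percent[pc$predictor == "good"], pc$percent[pc$predictor == "noise"])
  # one-predictor model gets all the credit
  fs1 <- make_features(bg["good"], n_hinge_knots = 5L)
  fit1 <- fit_maxent(pres["good"], bg["good"], fs1, beta = 1)
  expect_equal(percent_contribution(fit1)$percent, 100)
})

test_that("permutation importance is zero for absent predictors, 100 when alone", {
  with_seed(7, {
    bg <- data.frame(good = stats::runif(600), noise = stats::runif(600))
    keep <- stats::rbinom(600, 1, bg$good^2) == 1
    pres <- bg[sample(which(keep), 80, replace = TRUE), ]
  })
  fs <- make_features(bg, n_hinge_knots = 3L)
  fit <- fit_maxent(pres, bg, fs, beta = 1)
  # force the noise predictor entirely out of the model
  fit$lambdas[fs$defs$parent == "noise"] <- 0
  pi_ <- permutation_importance(fit, pres, bg, seed = 1)
  expect_equal(pi_$auc_drop[pi_$predictor == "noise"], 0)
  expect_equal(pi_$percent[pi_$predictor == "good"], 100)
  expect_identical(pi_, permutation_importance(fit, pres, bg, seed = 1))
})

test_that("bootstrap replicate predictions are seeded and in (0,1)", {
  tp <- toy_pb(n_pres = 40, n_bg = 200, seed = 8)
  fs <- make_features(tp$bg, n_hinge_knots = 3L)
  g1 <- rast_grid(matrix(stats::runif(64), 8, 8), dx = 100, crs = "local")
  g2 <- rast_grid(matrix(stats::runif(64), 8, 8), dx = 100, crs = "local")
  st <- predictor_stack(list(x1 = g1, x2 = g2))
  r1 <- bootstrap_predict(tp$pres, tp$bg, fs, st, n_replicates = 3, beta = 1,
                          seed = 11)
  r2 <- bootstrap_predict(tp$pres, tp$bg, fs, st, n_replicates = 3, beta = 1,
                          seed = 11)
  expect_identical(r1[[2]]$values, r2[[2]]$values)
  expect_false(identical(r1[[1]]$values, r1[[2]]$values))
  mu <- uncertainty_maps(replicates = r1)$mean$values
  expect_true(all(mu > 0 & mu < 1))
  expect_error(bootstrap_predict(tp$pres, tp$bg, fs, st, n_replicates = 1,
                                 beta = 1, seed = 1), "two replicates")
})

test_that("lambdas files round-trip the fitted model summary", {
  tp <- toy_pb(seed = 10)
  fs <- make_features(tp$bg, n_hinge_knots = 2L)
  fit <- fit_maxent(tp$pres, tp$bg, fs, beta = 1)
  p <- file.path(tempdir(), "model.lambdas")
  write_maxent_lambdas(fit, p)
  expect_true(file.exists(p))
  j <- jsonlite::read_json(sub("lambdas$", "json", p), simplifyVector = TRUE)
  expect_equal(j$regularized_gain, fit$regularized_gain)
  expect_equal(length(j$lambdas), length(fit$lambdas))
})
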