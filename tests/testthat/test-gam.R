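test_that("B-spline bases sum to one over the data range and have k columns", {
  with_seed(1, x <- stats::runif(200, -3, 7))
  for (k in c(3L, 5L, 10L)) {
    sp <- build_smooth(x, k)
    expect_equal(ncol(eval_smooth(sp, x)), k)
    B <- duosdm:::eval_smooth_raw(sp, seq(min(x), max(x), length.out = 50))
    expect_equal(rowSums(B), rep(1, 50), tolerance = 1e-10)
  }
  expect_error(build_smooth(x, 2L), "k must be")
  expect_error(build_smooth(rep(1:3, 10), 5L), "distinct")
})

test_that("the difference penalty annihilates linear coefficient sequences", {
  sp <- build_smooth(stats::runif(50), 6L)
  lin <- 2 + 0.5 * seq_len(6)
  expect_equal(as.numeric(t(lin) %*% sp$S %*% lin), 0, tolerance = 1e-10)
  # ... but the shrinkage penalty does not
  expect_gt(as.numeric(t(lin) %*% sp$N %*% lin), 0)
})

test_that("intercept-only fit recovers the closed-form binomial MLE", {
  d <- data.frame(label = rep(c(1, 0), c(30, 70)), weight = 1)
  attr(d, "predictors") <- character(0)
  f <- fit_gam(d, list())
  expect_equal(stats::plogis(f$intercept), 0.30, tolerance = 1e-8)
  expect_equal(f$deviance_explained, 0, tolerance = 1e-10)
})

test_that("infinite smoothing collapses to the intercept-only deviance", {
  d <- logistic_design(300, a = -0.4, b = 1.5, seed = 3)
  sp <- build_smooth(d$x, 5L, "x")
  f_inf <- fit_gam(d, list(sp), lambda_grid = 1e12)
  mu0 <- mean(d$label)
  dev0 <- -2 * sum(d$label * log(mu0) + (1 - d$label) * log(1 - mu0))
  expect_equal(f_inf$residual_deviance, dev0, tolerance = 1e-6)
})

test_that("a nearly unpenalized fit matches the ML logistic fit on the same basis", {
  d <- logistic_design(150, a = 0, b = 1, seed = 4)
  sp <- build_smooth(d$x, 8L, "x")
  f0 <- fit_gam(d, list(sp), lambda_grid = 1e-10)
  B <- eval_smooth(sp, d$x)
  g <- stats::glm(d$label ~ B, family = stats::binomial())
  expect_equal(f0$residual_deviance, as.numeric(stats::deviance(g)),
               tolerance = 1e-3)
})

test_that("permuted labels give near-zero deviance explained and a flat smooth", {
  d <- logistic_design(500, a = 0, b = 2, seed = 5)
  d$label <- with_seed(6, sample(d$label))
  sp <- build_smooth(d$x, 5L, "x")
  f <- fit_gam(d, list(sp))
  expect_lt(f$deviance_explained, 0.05)
  pr <- partial_response(f, "x")
  expect_true(all(abs(pr$effect) <= 2 * pr$se + 0.05))
})

test_that("a linear logit signal is recovered within 10% of the glm oracle", {
  d <- logistic_design(500, a = -0.5, b = 1.2, seed = 7)
  sp <- build_smooth(d$x, 5L, "x")
  f <- fit_gam(d, list(sp))
  oracle <- stats::glm(label ~ x, family = stats::binomial(), data = d)
  xr <- stats::quantile(d$x, c(0.05, 0.95))
  grid <- seq(xr[1], xr[2], length.out = 100)
  eff <- as.vector(eval_smooth(sp, grid) %*% f$coefficients[[1]])
  slope_fit <- stats::coef(stats::lm(eff ~ grid))[2]
  expect_lt(abs(slope_fit - stats::coef(oracle)[2]) / abs(stats::coef(oracle)[2]),
            0.10)
  # partial response is near-linear over the central 90% of x
  resid <- stats::lm(eff ~ grid)$residuals
  expect_lt(max(abs(resid)), 0.1)
})

test_that("predictions are monotone for a monotone fitted signal, with positive SE", {
  d <- logistic_design(800, a = 0, b = 2, seed = 8)
  sp <- build_smooth(d$x, 5L, "x")
  f <- fit_gam(d, list(sp))
  g <- rast_grid(matrix(seq(-1.8, 1.8, length.out = 100), 10, 10),
                 dx = 100, crs = "local")
  st <- predictor_stack(list(x = g))
  pred <- predict_gam(f, st)
  p <- pred$probability$values
  expect_gt(stats::cor(as.vector(p), as.vector(g$values), method = "spearman"),
            0.99)
  expect_true(all(pred$standard_error$values > 0))
  expect_true(all(p >= 0 & p <= 1))
  # nodata propagates; extrapolated cells are flagged in the coverage layer
  g2 <- g; g2$values[1, 1] <- NA; g2$values[2, 1] <- 10
  pred2 <- predict_gam(f, predictor_stack(list(x = g2)))
  expect_true(is.na(pred2$probability$values[1, 1]))
  expect_equal(pred2$coverage$values[2, 1], 0)
  expect_equal(pred2$coverage$values[5, 5], 1)
})

test_that("intercept-only prediction rasters are constant", {
  d <- data.frame(label = rep(c(1, 0), c(40, 60)), weight = 1)
  attr(d, "predictors") <- character(0)
  f <- fit_gam(d, list())
  g <- rast_grid(matrix(stats::rnorm(100), 10, 10), dx = 100, crs = "local")
  pred <- predict_gam(f, predictor_stack(list(x = g)))
  expect_equal(length(unique(as.vector(pred$probability$values))), 1L)
  expect_equal(length(unique(as.vector(pred$standard_error$values))), 1L)
})

test_that("partial responses are centered over the training design", {
  d <- logistic_design(400, a = 0.3, b = 1, seed = 9)
  sp <- build_smooth(d$x, 5L, "x")
  f <- fit_gam(d, list(sp))
  train_eff <- eval_smooth(sp, d$x) %*% f$coefficients[[1]]
  expect_lt(abs(mean(train_eff)), 1e-8)
  expect_error(partial_response(f, "nope"), "unknown")
})

test_that("deviance importance credits the only predictor fully, noise weakly", {
  d <- logistic_design(500, a = 0, b = 2, seed = 10)
  sp <- build_smooth(d$x, 5L, "x")
  imp1 <- deviance_importance(d, list(sp))
  expect_equal(imp1$proportion_of_total, 1.0, tolerance = 1e-8)
  # add a pure-noise predictor
  d$z <- with_seed(11, stats::rnorm(500))
  attr(d, "predictors") <- c("x", "z")
  spz <- build_smooth(d$z, 5L, "z")
  imp2 <- deviance_importance(d, list(sp, spz))
  expect_lt(imp2$proportion_of_total[imp2$predictor == "z"], 0.05)
  expect_gt(imp2$proportion_of_total[imp2$predictor == "x"], 0.5)
})

test_that("adding a truly predictive term lowers AIC", {
  with_seed(12, {
    x <- stats::runif(500, -2, 2)
    z <- stats::runif(500, -2, 2)
    y <- stats::rbinom(500, 1, stats::plogis(x + 1.5 * z))
  })
  d <- data.frame(label = y, weight = 1, x = x, z = z)
  attr(d, "predictors") <- c("x", "z")
  f_red <- fit_gam(d, list(build_smooth(x, 5L, "x")))
  f_full <- fit_gam(d, list(build_smooth(x, 5L, "x"), build_smooth(z, 5L, "z")))
  expect_lt(f_full$aic, f_red$aic)
})

test_that("fits are invariant to affine predictor rescaling", {
  d <- logistic_design(300, a = 0, b = 1.5, seed = 13)
  f1 <- fit_gam(d, list(build_smooth(d$x, 5L, "x")))
  d2 <- d; d2$x <- 100 * d$x - 7
  f2 <- fit_gam(d2, list(build_smooth(d2$x, 5L, "x")))
  p1 <- stats::plogis(duosdm:::gam_linpred(f1, d)$eta)
  p2 <- stats::plogis(duosdm:::gam_linpred(f2, d2)$eta)
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("GAM fits agree with an mgcv shrinkage-smoother cross-check", {
  skip_if_not_installed("mgcv")
  d <- logistic_design(400, a = -0.3, b = 1.8, seed = 14)
  f <- fit_gam(d, list(build_smooth(d$x, 5L, "x")))
  mg <- mgcv::gam(label ~ s(x, k = 5, bs = "ts"), family = stats::binomial(),
                  data = d)
  p_mine <- stats::plogis(duosdm:::gam_linpred(f, d)$eta)
  p_mgcv <- as.numeric(stats::predict(mg, d, type = "response"))
  expect_gt(stats::cor(p_mine, p_mgcv), 0.98)
  expect_lt(abs(f$deviance_explained -
                  (1 - mg$deviance / mg$null.deviance)), 0.05)
})

test_that("resampling-mode prediction replicates are deterministic", {
  sim <- generate_landscape(small_params(seed = 4))
  b <- default_bias_surfaces(sim$truth)
  occ <- sample_occurrences(sim$truth, 15, 25, b$survey, b$citizen, seed = 2)
  bias <- build_bias_surface(occ, sim$truth$study_area, sim$stack[[1]])
  pool <- draw_background(bias, 2000, seed = 3)
  st <- sim$stack[c("chl", "dist_aqua")]
  r1 <- gam_resample_predict(occ, pool, st, k = 5, n_iterations = 2, seed = 5)
  r2 <- gam_resample_predict(occ, pool, st, k = 5, n_iterations = 2, seed = 5)
  expect_identical(r1[[1]]$values, r2[[1]]$values)
  expect_false(identical(r1[[1]]$values, r1[[2]]$values))
})
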