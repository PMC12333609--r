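# shared in-code fixtures: tiny grids, small landscapes, simple designs

# flat reference grid (all cells valid)
flat_grid <- function(nr = 10, nc = 10, dx = 460, dy = dx, value = 0) {
  rast_grid(matrix(value, nr, nc), xmin = 0, ymax = nr * dy, dx = dx, dy = dy,
            crs = "test-utm")
}

# grid holding z = a*x + b*y (+ c), x/y in meters at cell centers
plane_grid <- function(a, b, c = 0, nr = 12, nc = 12, dx = 460, dy = dx) {
  g <- flat_grid(nr, nc, dx, dy)
  cc <- cell_centers(g)
  g$values <- outer(cc$y, cc$x, function(y, x) a * x + b * y + c)
  g
}

# small fast landscape for pipeline-level tests
small_params <- function(seed = 1L, ...) {
  landscape_params(n_rows = 48L, n_cols = 72L, cell_size = 250,
                   seed = seed, ...)
}

# logistic single-predictor design: y ~ Bernoulli(plogis(a + b*x))
logistic_design <- function(n, a = 0, b = 1, seed = 1L, xname = "x") {
  with_seed(seed, {
    x <- stats::runif(n, -2, 2)
    y <- stats::rbinom(n, 1, stats::plogis(a + b * x))
    d <- data.frame(label = y, weight = 1)
    d[[xname]] <- x
    attr(d, "predictors") <- xname
    d
  })
}

# presence/background tables with one informative predictor each
toy_pb <- function(n_pres = 60, n_bg = 400, seed = 1L) {
  with_seed(seed, {
    bg <- data.frame(x1 = stats::runif(n_bg), x2 = stats::runif(n_bg))
    keep <- stats::rbinom(n_bg, 1, bg$x1) == 1
    pres <- bg[sample(which(keep), n_pres, replace = TRUE), ]
    list(pres = pres, bg = bg)
  })
}
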