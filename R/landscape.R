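#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions have no RNG side effects.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic, collision-spread mapping from (master seed, stage name,
#' counter) to an integer seed below 2^31, so every stochastic pipeline
#' stage gets its own reproducible stream.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @param counter non-negative integer (e.g., repeat index).
#' @return integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, stage, counter = 0L) {
  h <- sum(utf8ToInt(stage) * (31 ^ (seq_along(utf8ToInt(stage)) %% 7)))
  as.integer((as.numeric(master) * 48271 + h * 16807 +
                as.numeric(counter) * 69621) %% 2147483646 + 1)
}

# smooth random field: white noise convolved with a Gaussian kernel
# (separable, reflection-padded), then standardized to mean 0 / sd 1.
smooth_field <- function(nr, nc, range_cells = 10) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  half <- max(1L, ceiling(3 * range_cells))
  k <- stats::dnorm(seq(-half, half), sd = range_cells)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    pad <- c(v[pmin(n, pmax(1, half:1))], v, v[pmin(n, pmax(1, n - 1:half + 1))])
    out <- stats::filter(pad, k, sides = 2)
    as.numeric(out[(half + 1):(half + n)])
  }
  z <- apply(z, 2, conv1)
  z <- t(apply(z, 1, conv1))
  (z - mean(z)) / stats::sd(z)
}

#' Parameters of the synthetic coastal landscape
#'
#' Defaults emulate the scale of a ~159 km^2 coastal study area: a
#' 120 x 180 grid of 250 m cells whose "sea" band of valid cells (a wavy
#' alongshore strip 14 cells wide) covers ~157 km^2, a depth gradient
#' reaching ~100 m offshore, four point "aquaculture" attractors, a
#' chlorophyll-a field elevated near the attractors, and an independent
#' smooth SST-anomaly field.  `coefficients` drive the true suitability
#' surface on the logit scale (see [generate_landscape()]); defaults give a
#' high-signal, hotspot-structured landscape (low median suitability with
#' localized high-suitability patches) in which the chlorophyll coefficient
#' (4 per SD) is twice every other effect.
#'
#' @param n_rows,n_cols grid size in cells (>= 20 each).
#' @param cell_size cell side in meters.
#' @param n_aquaculture number of aquaculture attractor points.
#' @param coefficients named list: `chl`, `sst_anom`, `dist` (per-SD /
#'   per-scale logit slopes), `dist_aqua_scale` (m), `slope_amp`,
#'   `slope_peak`, `slope_width` (degrees), `intercept` (logit).
#' @param noise_sd sd of the smoothed noise added to the depth surface (m).
#' @param correlation_length smoothing range of the depth-noise and
#'   SST-anomaly fields, in cells.
#' @param chl_correlation_length smoothing range of the chlorophyll baseline
#'   field, in cells; chlorophyll is patchy at much finer (sub-km) scales
#'   than the mesoscale SST field, which is what lets a bias-corrected
#'   background design separate habitat signal from sampling density.
#' @param seed integer seed; identical seeds give bit-identical landscapes.
#' @return a `landscape_params` list.
#' @export
landscape_params <- function(n_rows = 120L, n_cols = 180L, cell_size = 250,
                             n_aquaculture = 4L,
                             coefficients = list(), noise_sd = 3,
                             correlation_length = 10,
                             chl_correlation_length = 1.5, seed = 1L) {
  if (n_rows < 20L || n_cols < 20L) stop("grid must be at least 20 x 20")
  if (cell_size <= 0) stop("cell_size must be positive")
  co <- utils::modifyList(list(chl = 4, sst_anom = 2, dist = 2,
                               dist_aqua_scale = 5000, slope_amp = 2,
                               slope_peak = 2.5, slope_width = 1,
                               intercept = -3.5), coefficients)
  if (co$slope_width <= 0) stop("slope_width must be positive")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, n_aquaculture = as.integer(n_aquaculture),
                 coefficients = co, noise_sd = noise_sd,
                 correlation_length = correlation_length,
                 chl_correlation_length = chl_correlation_length,
                 seed = as.integer(seed)),
            class = "landscape_params")
}

#' Generate a synthetic coastal landscape with known true suitability
#'
#' Builds a seed-reproducible predictor stack emulating the retained
#' predictor set of a coastal dolphin habitat study — depth (monotone
#' offshore gradient plus smoothed noise), slope (derived from depth by
#' Horn's method), chlorophyll-a (smooth baseline plus exponential-decay
#' bumps centered on the aquaculture points, so chlorophyll and distance to
#' aquaculture are negatively coupled), SST anomaly (independent smooth
#' field) and distance to aquaculture — together with the true suitability
#' surface
#' `plogis(b_chl*chl_z - b_sst*sst_z - b_dist*dist/scale +
#'  amp*exp(-(slope-peak)^2/(2*width^2)) + intercept)`
#' where `chl_z`, `sst_z` are per-SD standardized fields over the valid
#' cells.  Valid cells form a wavy alongshore band (the "SAC"); everything
#' else is nodata in every layer.
#'
#' @param params a [landscape_params()] object.
#' @return list with elements `stack` (a `predictor_stack`: depth, slope,
#'   chl, sst_anom, dist_aqua), and `truth` (list: `true_suitability`
#'   `rast_grid`, `params`, `aquaculture` points `feature_geometry`,
#'   `study_area` polygon `feature_geometry`, `coast_row` integer vector).
#' @export
generate_landscape <- function(params = landscape_params()) {
  stopifnot(inherits(params, "landscape_params"))
  with_seed(params$seed, {
    nr <- params$n_rows; nc <- params$n_cols; cs <- params$cell_size
    crs <- "synthetic-utm"
    # wavy coastline: land to the south (high row indices), sea to the north
    j <- seq_len(nc)
    coast <- round(0.75 * nr + 0.08 * nr * sin(2.5 * pi * j / nc) +
                     0.04 * nr * sin(7 * pi * j / nc + 1))
    coast <- pmin(nr - 2L, pmax(18L, as.integer(coast)))
    offshore <- outer(seq_len(nr), coast, function(i, cst) cst - i) # cells offshore
    band_w <- 14L
    mask <- offshore >= 1L & offshore <= band_w                     # ~159 km^2
    # full (unmasked) bathymetric surface so slope has no masked-edge loss
    grad_per_cell <- 100 / band_w                                   # ~100 m at band edge
    depth_full <- grad_per_cell * offshore +
      params$noise_sd * smooth_field(nr, nc, params$correlation_length)
    ref <- rast_grid(depth_full, xmin = 0, ymax = nr * cs, dx = cs, crs = crs)
    sa <- derive_slope_aspect(ref)
    mask <- mask & is.finite(sa$slope$values)   # grid border has no slope
    # aquaculture points: alongshore spread, ~1 km offshore, inside the band
    qa <- (seq_len(params$n_aquaculture) - 0.5) / params$n_aquaculture
    aq_col <- pmin(nc, pmax(1L, round(qa * nc + stats::runif(params$n_aquaculture, -3, 3))))
    aq_row <- coast[aq_col] - 4L
    ccx <- (aq_col - 0.5) * cs
    ccy <- nr * cs - (aq_row - 0.5) * cs
    aqua <- feature_geometry("points", cbind(ccx, ccy), "aquaculture", crs)
    dist_aq <- distance_surface(ref, aqua)
    # chlorophyll: positive smooth baseline + decay bumps at the attractors
    chl_base <- 0.15 + 0.3 * exp(0.8 * smooth_field(nr, nc, params$chl_correlation_length))
    chl <- chl_base + 0.35 * exp(-dist_aq$values / 1500)
    sst <- 1 + 0.5 * smooth_field(nr, nc, params$correlation_length)
    # study-area polygon tracing the band outline (cell edges, step curve)
    xs <- as.vector(rbind((j - 1L) * cs, j * cs))
    top_y <- nr * cs - rep((coast - band_w - 1L) * cs, each = 2)
    bot_y <- nr * cs - rep(coast * cs, each = 2)
    poly <- feature_geometry("polygon",
                             cbind(c(xs, rev(xs)), c(top_y, rev(bot_y))),
                             "study-area", crs)
    mk <- function(v) { v[!mask] <- NA_real_; rast_grid(v, 0, nr * cs, cs, crs = crs) }
    stack <- predictor_stack(list(
      depth = mk(depth_full), slope = mk(sa$slope$values), chl = mk(chl),
      sst_anom = mk(sst), dist_aqua = mk(dist_aq$values)))
    zstd <- function(v) {
      ok <- is.finite(v); s <- stats::sd(v[ok])
      out <- v * 0
      if (is.finite(s) && s > 1e-12) out[ok] <- (v[ok] - mean(v[ok])) / s
      out
    }
    cf <- params$coefficients
    eta <- cf$chl * zstd(stack$chl$values) -
      cf$sst_anom * zstd(stack$sst_anom$values) -
      cf$dist * stack$dist_aqua$values / cf$dist_aqua_scale +
      cf$slope_amp * exp(-(stack$slope$values - cf$slope_peak)^2 /
                           (2 * cf$slope_width^2)) +
      cf$intercept
    suit <- stats::plogis(eta)
    suit[!mask] <- NA_real_
    truth <- list(true_suitability = rast_grid(suit, 0, nr * cs, cs, crs = crs),
                  params = params, aquaculture = aqua, study_area = poly,
                  coast_row = coast)
    list(stack = stack, truth = truth)
  })
}

#' Default detection-bias surfaces for the two occurrence sources
#'
#' Survey bias is a trackline-corridor surface (Gaussian alongshore corridor
#' over the western/central sector); citizen bias is a harbor-centered
#' hotspot in the eastern sector.  The two are spatially complementary so
#' the citizen-science ablation has a genuine coverage gap.  Both are masked
#' to the study band and rescaled to max 1.
#'
#' @param truth the `truth` element of [generate_landscape()].
#' @return list with `rast_grid` elements `survey` and `citizen`.
#' @export
default_bias_surfaces <- function(truth) {
  g <- truth$true_suitability
  nr <- nrow(g$values); nc <- ncol(g$values)
  cs <- g$dx
  mask <- is.finite(g$values)
  colm <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  offshore <- outer(seq_len(nr), truth$coast_row, function(i, cst) cst - i)
  # survey: corridor ~1 km offshore, alongshore Gaussian over the west/center
  survey <- exp(-(offshore * cs - 1000)^2 / (2 * 1000^2)) *
    exp(-(colm - 0.35 * nc)^2 / (2 * (0.22 * nc)^2))
  # citizen: hotspot around an eastern "harbor" on the coast
  hx <- 0.82 * nc; hy <- truth$coast_row[round(hx)] - 2L
  rowm <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  d2 <- ((colm - hx) * cs)^2 + ((rowm - hy) * cs)^2
  citizen <- exp(-d2 / (2 * 2000^2))
  wrap <- function(v) {
    v[!mask] <- NA_real_
    v <- v / max(v, na.rm = TRUE)
    rast_grid(v, g$xmin, g$ymax, g$dx, g$dy, g$crs)
  }
  list(survey = wrap(survey), citizen = wrap(citizen))
}

#' Sample presence records from the true suitability under detection bias
#'
#' Presence cells are drawn without replacement with probability
#' proportional to `true suitability x bias`; each record is jittered
#' uniformly within its cell.  Survey and citizen records are drawn from
#' their own bias surfaces and labeled accordingly.
#'
#' @param truth the `truth` element of [generate_landscape()].
#' @param n_survey,n_citizen number of records per source.
#' @param survey_bias,citizen_bias non-negative aligned `rast_grid` bias
#'   surfaces (not all zero).
#' @param seed integer seed.
#' @return an occurrence data.frame with columns `x`, `y`, `date`, `source`,
#'   `validated`, `group_size`.
#' @export
sample_occurrences <- function(truth, n_survey, n_citizen, survey_bias,
                               citizen_bias, seed = 1L) {
  g <- truth$true_suitability
  stop_unless_aligned(g, survey_bias, "bias surfaces")
  stop_unless_aligned(g, citizen_bias, "bias surfaces")
  with_seed(seed, {
    draw <- function(bias, n, source, date_range) {
      if (n == 0L) return(NULL)
      w <- as.vector(g$values * bias$values)
      w[!is.finite(w) | w < 0] <- 0
      if (sum(w > 0) < n)
        stop("requested more points than cells with positive probability")
      cells <- sample.int(length(w), n, replace = FALSE, prob = w)
      nr <- nrow(g$values)
      row <- (cells - 1L) %% nr + 1L
      col <- (cells - 1L) %/% nr + 1L
      x <- g$xmin + (col - 1L) * g$dx + stats::runif(n) * g$dx
      y <- g$ymax - (row - 1L) * g$dy - stats::runif(n) * g$dy
      data.frame(x = x, y = y,
                 date = as.Date(date_range[1]) +
                   sample.int(as.integer(diff(as.Date(date_range))) + 1L, n,
                              replace = TRUE) - 1L,
                 source = source, validated = TRUE,
                 group_size = 1L + stats::rpois(n, 3.8))
    }
    rbind(draw(survey_bias, n_survey, "survey", c("2024-07-01", "2024-09-30")),
          draw(citizen_bias, n_citizen, "citizen", c("2024-07-01", "2024-09-30")))
  })
}
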