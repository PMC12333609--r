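#' Lightweight single-band raster grid
#'
#' `rast_grid()` builds the spatial container used throughout the package: a
#' numeric matrix of cell values with an affine geotransform (projected
#' coordinates, meters) and a CRS tag.  Row 1 is the northernmost row;
#' missing data are stored as `NA`.  Cell coordinates always refer to cell
#' centers.
#'
#' @param values numeric matrix (rows x cols); `NA` marks nodata cells.
#' @param xmin x coordinate (m) of the west edge of the grid.
#' @param ymax y coordinate (m) of the north edge of the grid.
#' @param dx,dy pixel sizes in meters (both > 0; `dy` defaults to `dx`).
#' @param crs free-text CRS tag; grids only interoperate when tags match.
#' @return an object of class `rast_grid`.
#' @export
rast_grid <- function(values, xmin = 0, ymax = nrow(values) * dy, dx = 1,
                      dy = dx, crs = "local") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.finite(dx) || !is.finite(dy) || dx <= 0 || dy <= 0)
    stop("pixel sizes must be positive and finite")
  structure(list(values = values, xmin = xmin, ymax = ymax,
                 dx = dx, dy = dy, crs = crs),
            class = "rast_grid")
}

#' @export
print.rast_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("rast_grid: %d x %d cells, %.6g x %.6g m, crs '%s'\n",
              nrow(v), ncol(v), x$dx, x$dy, x$crs))
  cat(sprintf("  extent : x [%.6g, %.6g]  y [%.6g, %.6g]\n",
              x$xmin, x$xmin + ncol(v) * x$dx, x$ymax - nrow(v) * x$dy, x$ymax))
  ok <- is.finite(v)
  if (any(ok))
    cat(sprintf("  values : [%.6g, %.6g], %d/%d valid\n",
                min(v[ok]), max(v[ok]), sum(ok), length(v)))
  else cat("  values : all nodata\n")
  invisible(x)
}

#' @rdname rast_grid
#' @param x object to test.
#' @export
is_rast_grid <- function(x) inherits(x, "rast_grid")

#' Test whether two grids are aligned
#'
#' Grids are aligned iff they share shape, geotransform and CRS tag; only
#' aligned grids can be stacked or combined cell-wise.
#'
#' @param a,b `rast_grid` objects.
#' @param tol numeric tolerance on the geotransform comparison.
#' @return logical scalar.
#' @export
grids_aligned <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) <= tol && abs(a$ymax - b$ymax) <= tol &&
    abs(a$dx - b$dx) <= tol && abs(a$dy - b$dy) <= tol &&
    identical(a$crs, b$crs)
}

stop_unless_aligned <- function(a, b, what = "grids") {
  if (!grids_aligned(a, b)) stop(what, " are not aligned", call. = FALSE)
  invisible(TRUE)
}

#' Cell-center coordinates
#'
#' @param grid a `rast_grid`.
#' @return `cell_centers()`: list with vectors `x` (per column) and `y`
#'   (per row, north to south).
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  list(x = grid$xmin + (seq_len(nc) - 0.5) * grid$dx,
       y = grid$ymax - (seq_len(nr) - 0.5) * grid$dy)
}

#' Locate points on a grid
#'
#' Maps projected coordinates to (row, col) indices; points outside the grid
#' extent get `NA` indices.
#'
#' @param grid a `rast_grid`.
#' @param x,y numeric vectors of projected coordinates (m).
#' @return data.frame with columns `row`, `col`.
#' @export
cell_of <- function(grid, x, y) {
  col <- floor((x - grid$xmin) / grid$dx) + 1L
  row <- floor((grid$ymax - y) / grid$dy) + 1L
  bad <- col < 1L | col > ncol(grid$values) | row < 1L | row > nrow(grid$values) |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Extract grid values at point locations
#'
#' @param grid a `rast_grid`.
#' @param x,y projected coordinates (m).
#' @return numeric vector (`NA` outside the grid or on nodata cells).
#' @export
extract_at <- function(grid, x, y) {
  rc <- cell_of(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- grid$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Named stack of aligned predictor grids
#'
#' A `predictor_stack` is an ordered named list of mutually aligned
#' `rast_grid` layers: the design space from which presence/background
#' feature tables are extracted.
#'
#' @param ... named `rast_grid` layers, or a single named list of them.
#' @return object of class `predictor_stack`.
#' @export
predictor_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && !is_rast_grid(layers[[1L]])) layers <- layers[[1L]]
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("stack layers must have unique non-empty names")
  if (!all(vapply(layers, is_rast_grid, TRUE)))
    stop("all stack layers must be rast_grid objects")
  ref <- layers[[1L]]
  for (i in seq_along(layers))
    stop_unless_aligned(ref, layers[[i]], paste0("stack layers (", nm[i], ")"))
  structure(layers, class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("predictor_stack with %d layers: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' @export
`[.predictor_stack` <- function(x, i) {
  predictor_stack(unclass(x)[i])
}

#' Extract a design table of predictor values at points
#'
#' @param stack a `predictor_stack`.
#' @param x,y point coordinates (m).
#' @return data.frame with one column per layer; rows follow the input order.
#' @export
extract_stack <- function(stack, x, y) {
  out <- lapply(stack, extract_at, x = x, y = y)
  as.data.frame(out, optional = TRUE)
}

## ---------------------------------------------------------------------------
## Derived predictors

#' Slope and aspect from a bathymetry/elevation grid (Horn's method)
#'
#' Estimates the surface gradient by 8-neighbor finite differences and
#' returns the slope (degrees, >= 0) and the downslope direction (aspect,
#' degrees clockwise from north, in [0, 360)).  Values are treated as
#' elevations; a grid of positive depths yields the same slope and a
#' 180-degree-rotated aspect.  Cells whose 3x3 neighborhood contains nodata
#' (including the grid border) are nodata; flat cells have aspect nodata.
#'
#' @param depth a `rast_grid` of at least 3 x 3 cells.
#' @return list with `rast_grid` elements `slope` and `aspect`.
#' @export
derive_slope_aspect <- function(depth) {
  z <- depth$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3L || nc < 3L) stop("grid must be at least 3 x 3")
  # shifted views: sh(dr, dc) holds the neighbor dr rows south, dc cols east
  sh <- function(dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okr <- rs >= 1L & rs <= nr; okc <- cs >= 1L & cs <= nc
    out[okr, okc] <- z[rs[okr], cs[okc]]
    out
  }
  nw <- sh(-1L, -1L); n_ <- sh(-1L, 0L); ne <- sh(-1L, 1L)
  w_ <- sh(0L, -1L);                     e_ <- sh(0L, 1L)
  sw <- sh(1L, -1L);  s_ <- sh(1L, 0L);  se <- sh(1L, 1L)
  dzdx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * depth$dx)
  dzdy <- ((ne + 2 * n_ + nw) - (se + 2 * s_ + sw)) / (8 * depth$dy)
  bad <- is.na(z) | is.na(dzdx) | is.na(dzdy)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  # aspect: direction of steepest descent, clockwise from north
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  aspect[slope == 0] <- NA_real_
  slope[bad] <- NA_real_; aspect[bad] <- NA_real_
  list(slope = rast_grid(slope, depth$xmin, depth$ymax, depth$dx, depth$dy, depth$crs),
       aspect = rast_grid(aspect, depth$xmin, depth$ymax, depth$dx, depth$dy, depth$crs))
}

#' Euclidean distance surface to a feature geometry
#'
#' Distance (m) from each valid cell center to the nearest feature: for
#' point features the nearest coordinate, for polylines/polygons the nearest
#' boundary segment (polygons are measured to the boundary, not the filled
#' interior).
#'
#' @param reference `rast_grid` supplying the target geometry and nodata mask.
#' @param features a `feature_geometry` (see [feature_geometry()]).
#' @return `rast_grid` of distances in meters.
#' @export
distance_surface <- function(reference, features) {
  stopifnot(inherits(features, "feature_geometry"))
  cc <- cell_centers(reference)
  nr <- nrow(reference$values); nc <- ncol(reference$values)
  px <- rep(cc$x, each = nr)
  py <- rep(cc$y, times = nc)
  co <- features$coords
  if (is.null(co) || nrow(co) == 0L) stop("empty feature set")
  if (features$kind == "points") {
    d2 <- rep(Inf, nr * nc)
    for (i in seq_len(nrow(co)))
      d2 <- pmin(d2, (px - co[i, 1])^2 + (py - co[i, 2])^2)
    d <- sqrt(d2)
  } else {
    d <- dist_to_segments(px, py, co)
  }
  vals <- matrix(d, nr, nc)
  vals[is.na(reference$values)] <- NA_real_
  rast_grid(vals, reference$xmin, reference$ymax, reference$dx, reference$dy,
            reference$crs)
}

# min distance from points (px, py) to the polyline through rows of `co`
dist_to_segments <- function(px, py, co) {
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(co) - 1L)) {
    ax <- co[i, 1]; ay <- co[i, 2]
    bx <- co[i + 1L, 1]; by <- co[i + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    d2 <- pmin(d2, (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
  }
  sqrt(d2)
}

#' Per-cell temporal mean of a series of aligned layers
#'
#' The mean is nodata-aware: a cell is averaged over the days on which it is
#' valid, and is nodata only when missing on every day.
#'
#' @param daily_layers non-empty list of aligned `rast_grid` layers.
#' @return `rast_grid` of per-cell means.
#' @export
temporal_mean <- function(daily_layers) {
  if (length(daily_layers) < 1L) stop("need at least one layer")
  ref <- daily_layers[[1L]]
  for (g in daily_layers) stop_unless_aligned(ref, g, "daily layers")
  sum_ <- matrix(0, nrow(ref$values), ncol(ref$values))
  n_ <- sum_
  for (g in daily_layers) {
    ok <- !is.na(g$values)
    sum_[ok] <- sum_[ok] + g$values[ok]
    n_ <- n_ + ok
  }
  vals <- sum_ / n_
  vals[n_ == 0] <- NA_real_
  rast_grid(vals, ref$xmin, ref$ymax, ref$dx, ref$dy, ref$crs)
}

#' Resample a grid onto the geometry of a target grid
#'
#' Bilinear interpolation of valid source cells at the target cell centers
#' (`method = "bilinear"`, for continuous fields) or nearest-neighbor
#' (`method = "nearest"`, for categorical layers).  Bilinear weights are
#' renormalized over the valid corner cells; target cells outside the source
#' cell-center hull, or with no valid corner, are nodata.
#'
#' @param source,target `rast_grid` objects in the same CRS.
#' @param method `"bilinear"` or `"nearest"`.
#' @return `rast_grid` aligned to `target`.
#' @export
resample_to <- function(source, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (!identical(source$crs, target$crs)) stop("CRS mismatch")
  sx0 <- source$xmin + 0.5 * source$dx          # first cell-center x
  sy0 <- source$ymax - 0.5 * source$dy          # first cell-center y
  nrs <- nrow(source$values); ncs <- ncol(source$values)
  cc <- cell_centers(target)
  nrt <- length(cc$y); nct <- length(cc$x)
  fx <- (cc$x - sx0) / source$dx                # fractional col index (0-based)
  fy <- (sy0 - cc$y) / source$dy                # fractional row index (0-based)
  if (max(fx) < 0 || min(fx) > ncs - 1 || max(fy) < 0 || min(fy) > nrs - 1)
    stop("source and target extents are disjoint")
  FX <- matrix(rep(fx, each = nrt), nrt, nct)
  FY <- matrix(rep(fy, times = nct), nrt, nct)
  if (method == "nearest") {
    ri <- round(FY) + 1; ci <- round(FX) + 1
    ok <- ri >= 1 & ri <= nrs & ci >= 1 & ci <= ncs
    vals <- matrix(NA_real_, nrt, nct)
    vals[ok] <- source$values[cbind(ri[ok], ci[ok])]
  } else {
    c0 <- floor(FX); r0 <- floor(FY)
    wx <- FX - c0; wy <- FY - r0
    vals <- matrix(0, nrt, nct); wsum <- vals
    for (dr in 0:1) for (dc in 0:1) {
      ri <- r0 + dr + 1; ci <- c0 + dc + 1
      w <- (if (dr == 0) 1 - wy else wy) * (if (dc == 0) 1 - wx else wx)
      inb <- ri >= 1 & ri <= nrs & ci >= 1 & ci <= ncs
      v <- matrix(NA_real_, nrt, nct)
      v[inb] <- source$values[cbind(ri[inb], ci[inb])]
      use <- inb & !is.na(v) & w > 0
      vals[use] <- vals[use] + w[use] * v[use]
      wsum[use] <- wsum[use] + w[use]
    }
    vals <- vals / wsum
    vals[wsum == 0] <- NA_real_
    # outside the cell-center hull of the source -> nodata (no extrapolation)
    out <- FX < 0 | FX > ncs - 1 | FY < 0 | FY > nrs - 1
    vals[out] <- NA_real_
  }
  rast_grid(vals, target$xmin, target$ymax, target$dx, target$dy, target$crs)
}

#' Pairwise Pearson correlation between stack layers
#'
#' Each pair is evaluated over the cells valid in both layers (or over
#' `at_cells`, a logical matrix / cell-index vector).  Pairs involving a
#' zero-variance layer are flagged `NA`.
#'
#' @param stack a `predictor_stack` with >= 2 layers.
#' @param at_cells optional logical matrix or integer cell indices selecting
#'   the evaluation cells.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlation <- function(stack, at_cells = NULL) {
  if (length(stack) < 2L) stop("need at least two layers")
  vals <- vapply(stack, function(g) as.vector(g$values),
                 numeric(length(stack[[1L]]$values)))
  if (!is.null(at_cells)) {
    idx <- if (is.logical(at_cells)) which(as.vector(at_cells)) else as.integer(at_cells)
    vals <- vals[idx, , drop = FALSE]
  }
  p <- ncol(vals)
  r <- diag(1, p)
  dimnames(r) <- list(names(stack), names(stack))
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    ok <- is.finite(vals[, i]) & is.finite(vals[, j])
    if (sum(ok) < 3L) { r[i, j] <- r[j, i] <- NA_real_; next }
    xi <- vals[ok, i]; xj <- vals[ok, j]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
    } else r[i, j] <- r[j, i] <- stats::cor(xi, xj)
  }
  r
}

#' Focal (neighborhood) mean smoothing
#'
#' Nodata-aware square moving-window mean; nodata cells stay nodata.
#'
#' @param grid a `rast_grid`.
#' @param window odd window side length in cells (default 3).
#' @return smoothed `rast_grid`.
#' @export
focal_mean <- function(grid, window = 3L) {
  if (window %% 2L != 1L || window < 1L) stop("window must be odd and >= 1")
  h <- (window - 1L) %/% 2L
  z <- grid$values
  nr <- nrow(z); nc <- ncol(z)
  sum_ <- matrix(0, nr, nc); n_ <- sum_
  for (dr in -h:h) for (dc in -h:h) {
    out <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okr <- rs >= 1L & rs <= nr; okc <- cs >= 1L & cs <= nc
    out[okr, okc] <- z[rs[okr], cs[okc]]
    ok <- !is.na(out)
    sum_[ok] <- sum_[ok] + out[ok]
    n_ <- n_ + ok
  }
  vals <- sum_ / n_
  vals[n_ == 0 | is.na(z)] <- NA_real_
  rast_grid(vals, grid$xmin, grid$ymax, grid$dx, grid$dy, grid$crs)
}
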