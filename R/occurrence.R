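#' Merge and validate occurrence records from two sources
#'
#' Concatenates the survey and citizen record tables, keeping only expert-
#' validated records with complete coordinates that fall inside the study
#' area polygon.  Rejected records are reported (with reasons) in the
#' `"rejected"` attribute; per-source retained counts in `"source_counts"`.
#'
#' @param survey,citizen occurrence data.frames (columns `x`, `y`, `date`,
#'   `source`, `validated`, optionally `group_size`); either may be `NULL`
#'   or empty.
#' @param study_area a `feature_geometry` polygon.
#' @return merged occurrence data.frame.
#' @export
merge_occurrences <- function(survey, citizen, study_area) {
  occ <- rbind(survey, citizen)
  if (is.null(occ) || nrow(occ) == 0L) stop("no records supplied")
  if (is.null(occ$validated)) occ$validated <- TRUE
  reason <- rep(NA_character_, nrow(occ))
  bad_xy <- !is.finite(occ$x) | !is.finite(occ$y)
  reason[bad_xy] <- "missing coordinates"
  unval <- !bad_xy & !occ$validated
  reason[unval] <- "not validated"
  outside <- rep(FALSE, nrow(occ))
  ok0 <- !bad_xy & !unval
  outside[ok0] <- !points_in_polygon(occ$x[ok0], occ$y[ok0], study_area)
  reason[outside] <- "outside study area"
  keep <- is.na(reason)
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- data.frame(index = which(!keep),
                                      reason = reason[!keep])
  attr(out, "source_counts") <- table(factor(out$source))
  out
}

#' Encounter rate per unit survey effort
#'
#' @param n number of events (groups sighted, or individuals).
#' @param effort_km on-effort trackline length in km.
#' @param per report the rate per this many km (default 100).
#' @return events per `per` km.
#' @export
encounter_rate <- function(n, effort_km, per = 100) {
  if (effort_km <= 0) stop("effort must be positive")
  per * n / effort_km
}

#' Sampling-bias surface from occurrence density
#'
#' Gaussian kernel density of the occurrence points evaluated at cell
#' centers, focal-mean smoothed, masked to zero outside the union of a
#' buffer around each occurrence and the buffered study-area polygon
#' (boundary and interior), then rescaled so the maximum valid cell equals
#' 1; cells inside the mask are floored at `1e-6` so no reachable cell has
#' exactly zero weight.
#'
#' @param occ occurrence data.frame (columns `x`, `y`).
#' @param sac study-area polygon (`feature_geometry`).
#' @param grid reference `rast_grid` (its nodata mask is respected).
#' @param bandwidth Gaussian KDE bandwidth in meters; `NULL` (the default)
#'   uses the isotropic normal-reference rule
#'   `sqrt((var(x) + var(y)) / 2) * n^(-1/6)`, which keeps the surface an
#'   effort envelope rather than a clone of the presence point pattern at
#'   small n.
#' @param buffer buffer radius in meters around occurrences and the SAC.
#' @param focal_window focal smoothing window side (cells, odd).
#' @param normalize `"max"` (rescale to max 1, the default) or `"sum"`.
#' @return `rast_grid` with values in [0, 1] (max exactly 1 for `"max"`).
#' @export
build_bias_surface <- function(occ, sac, grid, bandwidth = NULL,
                               buffer = 2000, focal_window = 3L,
                               normalize = c("max", "sum")) {
  normalize <- match.arg(normalize)
  if (nrow(occ) < 1L) stop("need at least one occurrence")
  if (is.null(bandwidth))
    bandwidth <- max(grid$dx, sqrt((stats::var(occ$x) + stats::var(occ$y)) / 2) *
                       nrow(occ)^(-1/6))
  if (bandwidth <= 0 || buffer <= 0) stop("bandwidth and buffer must be positive")
  cc <- cell_centers(grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  px <- rep(cc$x, each = nr); py <- rep(cc$y, times = nc)
  dens <- rep(0, nr * nc)
  mind2 <- rep(Inf, nr * nc)
  for (i in seq_len(nrow(occ))) {
    d2 <- (px - occ$x[i])^2 + (py - occ$y[i])^2
    dens <- dens + exp(-d2 / (2 * bandwidth^2))
    mind2 <- pmin(mind2, d2)
  }
  kde <- rast_grid(matrix(dens, nr, nc), grid$xmin, grid$ymax, grid$dx,
                   grid$dy, grid$crs)
  kde$values[is.na(grid$values)] <- NA_real_
  sm <- focal_mean(kde, focal_window)
  inmask <- sqrt(mind2) <= buffer | dist_to_polygon(px, py, sac) <= buffer
  v <- sm$values
  v[!matrix(inmask, nr, nc)] <- 0
  ok <- is.finite(v)
  if (!any(ok & v > 0)) stop("degenerate bias surface: all cells masked")
  if (normalize == "max") {
    v[ok] <- v[ok] / max(v[ok])
    v[ok] <- pmax(v[ok], ifelse(matrix(inmask, nr, nc)[ok], 1e-6, 0))
  } else {
    v[ok] <- pmax(v[ok] / max(v[ok]), ifelse(matrix(inmask, nr, nc)[ok], 1e-6, 0))
    v[ok] <- v[ok] / sum(v[ok])
  }
  rast_grid(v, grid$xmin, grid$ymax, grid$dx, grid$dy, grid$crs)
}

#' Draw background points proportional to a bias surface
#'
#' Cells are drawn with replacement with probability proportional to their
#' bias weight; each point is then placed uniformly within its cell.
#'
#' @param bias `rast_grid` with at least one positive cell.
#' @param n number of points (>= 0).
#' @param seed integer seed.
#' @return data.frame with columns `x`, `y`; attributes `parent_pool_size`
#'   (= `n`) and `seed`.
#' @export
draw_background <- function(bias, n, seed = 1L) {
  w <- as.vector(bias$values)
  w[!is.finite(w) | w < 0] <- 0
  if (n > 0 && sum(w) == 0) stop("degenerate bias surface: no positive weight")
  out <- with_seed(seed, {
    if (n == 0L) data.frame(x = numeric(0), y = numeric(0)) else {
      nr <- nrow(bias$values)
      cells <- sample.int(length(w), n, replace = TRUE, prob = w)
      row <- (cells - 1L) %% nr + 1L
      col <- (cells - 1L) %/% nr + 1L
      data.frame(x = bias$xmin + (col - 1L) * bias$dx + stats::runif(n) * bias$dx,
                 y = bias$ymax - (row - 1L) * bias$dy - stats::runif(n) * bias$dy)
    }
  })
  attr(out, "parent_pool_size") <- n
  attr(out, "seed") <- seed
  out
}

#' Subsample pseudo-absences from a background pool
#'
#' Uniform seeded subsample without replacement of size
#' `round(ratio * n_presences)`.
#'
#' @param pool background data.frame from [draw_background()].
#' @param n_presences number of presence records.
#' @param ratio pseudo-absence : presence ratio (default 1).
#' @param seed integer seed.
#' @return data.frame subset of `pool`.
#' @export
subsample_pseudo_absences <- function(pool, n_presences, ratio = 1, seed = 1L) {
  n <- round(ratio * n_presences)
  if (n > nrow(pool)) stop("requested subsample exceeds pool size")
  idx <- with_seed(seed, sample.int(nrow(pool), n, replace = FALSE))
  out <- pool[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified k-fold assignment
#'
#' Within each class label the records are shuffled (seeded) and assigned
#' round-robin, so per-class fold sizes differ by at most one.
#'
#' @param labels vector of class labels (e.g., 0/1).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `[1, k]`, one per record.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) stop("class '", cl, "' has fewer than k members")
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Read and write occurrence tables as CSV
#'
#' Columns: `x`, `y`, `date`, `source`, `validated`, `group_size`.
#'
#' @param occ occurrence data.frame (for writing).
#' @param path CSV path.
#' @return `read_occurrences()` returns the occurrence data.frame.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(occ$date)) occ$date <- as.Date(occ$date)
  if (is.null(occ$validated)) occ$validated <- TRUE
  occ
}
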