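#' Feature geometry (points, polygon or polyline)
#'
#' Minimal vector-geometry container sharing the raster CRS: a coordinate
#' matrix plus a kind tag.  Polygon rings are stored closed (first vertex
#' repeated last); `feature_geometry()` closes them if needed.
#'
#' @param kind one of `"points"`, `"polygon"`, `"polyline"`.
#' @param coords two-column matrix (or data.frame) of x/y in meters.
#' @param label optional free-text label.
#' @param crs CRS tag.
#' @return object of class `feature_geometry`.
#' @export
feature_geometry <- function(kind = c("points", "polygon", "polyline"),
                             coords, label = "", crs = "local") {
  kind <- match.arg(kind)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must have two columns (x, y)")
  storage.mode(coords) <- "double"
  if (kind == "polygon") {
    if (nrow(coords) < 3L) stop("polygon needs at least 3 vertices")
    if (any(coords[1L, ] != coords[nrow(coords), ]))
      coords <- rbind(coords, coords[1L, ])
  }
  structure(list(kind = kind, coords = unname(coords), label = label, crs = crs),
            class = "feature_geometry")
}

#' @export
print.feature_geometry <- function(x, ...) {
  cat(sprintf("feature_geometry: %s, %d vertices%s\n", x$kind, nrow(x$coords),
              if (nzchar(x$label)) paste0(" ('", x$label, "')") else ""))
  invisible(x)
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' @param x,y point coordinates.
#' @param polygon a `feature_geometry` of kind `"polygon"`.
#' @return logical vector; points on an edge may fall on either side at
#'   floating-point resolution.
#' @export
points_in_polygon <- function(x, y, polygon) {
  stopifnot(polygon$kind == "polygon")
  co <- polygon$coords
  n <- nrow(co) - 1L
  inside <- logical(length(x))
  for (i in seq_len(n)) {
    x1 <- co[i, 1]; y1 <- co[i, 2]
    x2 <- co[i + 1L, 1]; y2 <- co[i + 1L, 2]
    crosses <- ((y1 > y) != (y2 > y))
    if (any(crosses)) {
      xin <- x1 + (y[crosses] - y1) / (y2 - y1) * (x2 - x1)
      inside[crosses] <- xor(inside[crosses], x[crosses] < xin)
    }
  }
  inside
}

#' Distance from points to a polygon (0 inside)
#'
#' Euclidean distance to the polygon boundary for exterior points, 0 for
#' interior points; used to dilate study-area polygons by a buffer.
#'
#' @param x,y point coordinates.
#' @param polygon a `feature_geometry` of kind `"polygon"`.
#' @return numeric vector of distances (m).
#' @export
dist_to_polygon <- function(x, y, polygon) {
  d <- dist_to_segments(x, y, polygon$coords)
  d[points_in_polygon(x, y, polygon)] <- 0
  d
}

## ---------------------------------------------------------------------------
## GeoJSON / WKT I/O

#' Read and write feature geometries as GeoJSON
#'
#' Supports Point/MultiPoint (-> `"points"`), LineString (-> `"polyline"`)
#' and Polygon (outer ring only).  Coordinates are taken verbatim (projected
#' meters), with the CRS carried in a top-level `crs_tag` member.
#'
#' @param path file path.
#' @param geom a `feature_geometry` (for writing).
#' @return `read_geojson()` returns a `feature_geometry`.
#' @export
read_geojson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  g <- if (identical(j$type, "Feature")) j$geometry else j
  crs <- if (!is.null(j$crs_tag)) j$crs_tag else "local"
  label <- if (!is.null(j$properties$label)) j$properties$label else ""
  as_coords <- function(lst)
    do.call(rbind, lapply(lst, function(p) c(p[[1]], p[[2]])))
  co <- g$coordinates
  switch(g$type,
    Point = feature_geometry("points", rbind(c(co[[1]], co[[2]])), label, crs),
    MultiPoint = feature_geometry("points", as_coords(co), label, crs),
    LineString = feature_geometry("polyline", as_coords(co), label, crs),
    Polygon = feature_geometry("polygon", as_coords(co[[1]]), label, crs),
    stop("unsupported GeoJSON geometry type: ", g$type))
}

#' @rdname read_geojson
#' @export
write_geojson <- function(geom, path) {
  co <- geom$coords
  rows <- lapply(seq_len(nrow(co)), function(i) c(co[i, 1], co[i, 2]))
  g <- switch(geom$kind,
    points = if (nrow(co) == 1L) list(type = "Point", coordinates = rows[[1]])
             else list(type = "MultiPoint", coordinates = rows),
    polyline = list(type = "LineString", coordinates = rows),
    polygon = list(type = "Polygon", coordinates = list(rows)))
  out <- list(type = "Feature", geometry = g,
              properties = list(label = geom$label), crs_tag = geom$crs)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write feature geometries as WKT
#'
#' Handles POINT, MULTIPOINT, LINESTRING and POLYGON (outer ring).
#'
#' @param wkt a WKT string (for reading).
#' @param geom a `feature_geometry` (for writing).
#' @param crs CRS tag attached on read.
#' @return `read_wkt()` returns a `feature_geometry`; `write_wkt()` a string.
#' @export
read_wkt <- function(wkt, crs = "local") {
  wkt <- trimws(wkt)
  type <- toupper(sub("\\s*\\(.*$", "", wkt))
  body <- sub("^[A-Za-z ]+\\s*\\(", "", wkt)
  body <- sub("\\)\\s*$", "", body)
  body <- gsub("[()]", "", body)
  parts <- strsplit(strsplit(body, ",")[[1]], "\\s+")
  co <- do.call(rbind, lapply(parts, function(p) as.numeric(p[nzchar(p)])))
  switch(type,
    POINT = feature_geometry("points", co, crs = crs),
    MULTIPOINT = feature_geometry("points", co, crs = crs),
    LINESTRING = feature_geometry("polyline", co, crs = crs),
    POLYGON = feature_geometry("polygon", co, crs = crs),
    stop("unsupported WKT type: ", type))
}

#' @rdname read_wkt
#' @export
write_wkt <- function(geom) {
  fmt <- function(co) paste(sprintf("%.10g %.10g", co[, 1], co[, 2]), collapse = ", ")
  switch(geom$kind,
    points = if (nrow(geom$coords) == 1L)
      sprintf("POINT (%s)", fmt(geom$coords))
    else sprintf("MULTIPOINT (%s)", fmt(geom$coords)),
    polyline = sprintf("LINESTRING (%s)", fmt(geom$coords)),
    polygon = sprintf("POLYGON ((%s))", fmt(geom$coords)))
}

## ---------------------------------------------------------------------------
## Raster I/O: ESRI ASCII grid (AAIGrid text dialect; DX/DY for rectangular
## pixels), with the CRS tag in a .prj sidecar file.

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text single-band raster exchange.  Square-pixel grids use the
#' standard `cellsize` header; rectangular pixels use the `dx`/`dy` header
#' keywords.  The CRS tag is stored in a `.prj` sidecar next to the file.
#'
#' @param grid a `rast_grid` (for writing).
#' @param path file path (conventionally `.asc`).
#' @param nodata nodata sentinel written to file.
#' @return `read_ascii_grid()` returns a `rast_grid`.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", grid$xmin),
           sprintf("yllcorner %.10g", grid$ymax - nr * grid$dy))
  hdr <- c(hdr, if (isTRUE(all.equal(grid$dx, grid$dy)))
    sprintf("cellsize %.10g", grid$dx)
    else c(sprintf("dx %.10g", grid$dx), sprintf("dy %.10g", grid$dy)))
  hdr <- c(hdr, sprintf("NODATA_value %.10g", nodata))
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  prj <- paste0(tools::file_path_sans_ext(path), ".prj")
  writeLines(grid$crs, prj)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 7L)
  kv <- list()
  nhdr <- 0L
  for (ln in lines) {
    p <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(p) == 2L && tolower(p[1]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "dx", "dy",
          "nodata_value")) {
      kv[[tolower(p[1])]] <- as.numeric(p[2])
      nhdr <- nhdr + 1L
    } else break
  }
  nc <- as.integer(kv$ncols); nr <- as.integer(kv$nrows)
  dx <- if (!is.null(kv$cellsize)) kv$cellsize else kv$dx
  dy <- if (!is.null(kv$cellsize)) kv$cellsize else kv$dy
  vals <- scan(path, skip = nhdr, quiet = TRUE)
  v <- matrix(vals, nr, nc, byrow = TRUE)
  if (!is.null(kv$nodata_value)) v[v == kv$nodata_value] <- NA_real_
  prj <- paste0(tools::file_path_sans_ext(path), ".prj")
  crs <- if (file.exists(prj)) readLines(prj, n = 1L) else "local"
  rast_grid(v, kv$xllcorner, kv$yllcorner + nr * dy, dx, dy, crs)
}

#' Read and write a predictor stack via a layer manifest
#'
#' The manifest is a two-column CSV (`name`, `path`) listing one ASCII-grid
#' file per layer; relative paths are resolved against the manifest location.
#'
#' @param stack a `predictor_stack` (for writing).
#' @param dir output directory (for writing).
#' @param manifest manifest CSV path.
#' @return `read_stack()` returns a `predictor_stack`.
#' @export
write_stack <- function(stack, dir, manifest = file.path(dir, "layers.csv")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(stack))
  for (i in seq_along(stack)) {
    paths[i] <- paste0(names(stack)[i], ".asc")
    write_ascii_grid(stack[[i]], file.path(dir, paths[i]))
  }
  utils::write.csv(data.frame(name = names(stack), path = paths),
                   manifest, row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_stack
#' @export
read_stack <- function(manifest) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  base <- dirname(manifest)
  layers <- lapply(tab$path, function(p) {
    if (!file.exists(p)) p <- file.path(base, p)
    read_ascii_grid(p)
  })
  names(layers) <- tab$name
  predictor_stack(layers)
}
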