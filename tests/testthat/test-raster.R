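test_that("slope and aspect of affine surfaces match the closed form", {
  # inclined plane z = 0.1 x: slope atan(0.1), aspect west (descending east)
  g <- plane_grid(a = 0.1, b = 0)
  sa <- derive_slope_aspect(g)
  inner <- sa$slope$values[2:11, 2:11]
  expect_true(all(abs(inner - atan(0.1) * 180 / pi) < 1e-6))
  expect_true(all(abs(sa$aspect$values[2:11, 2:11] - 270) < 1e-6))
  # plane dipping due south: z decreases southward -> aspect 180
  g2 <- plane_grid(a = 0, b = 0.05)
  sa2 <- derive_slope_aspect(g2)
  expect_true(all(abs(sa2$aspect$values[2:11, 2:11] - 180) < 1e-6))
  # generic affine surface
  a <- 0.03; b <- -0.07
  sa3 <- derive_slope_aspect(plane_grid(a, b))
  expect_true(all(abs(sa3$slope$values[2:11, 2:11] -
                        atan(sqrt(a^2 + b^2)) * 180 / pi) < 1e-6))
  exp_aspect <- (atan2(-a, -b) * 180 / pi) %% 360  # downslope, CW from north
  expect_true(all(abs(sa3$aspect$values[2:11, 2:11] - exp_aspect) < 1e-6))
})

test_that("flat surfaces have zero slope and undefined aspect; edges nodata", {
  sa <- derive_slope_aspect(flat_grid(8, 8, value = 42))
  expect_true(all(sa$slope$values[2:7, 2:7] == 0))
  expect_true(all(is.na(sa$aspect$values)))
  expect_true(all(is.na(sa$slope$values[1, ])))   # border
  expect_error(derive_slope_aspect(flat_grid(2, 5)), "3 x 3")
  # nodata in the 3x3 neighborhood propagates
  g <- plane_grid(0.1, 0)
  g$values[5, 5] <- NA
  sa2 <- derive_slope_aspect(g)
  expect_true(all(is.na(sa2$slope$values[4:6, 4:6])))
  expect_false(is.na(sa2$slope$values[8, 8]))
})

test_that("distance surfaces match brute force and decompose over features", {
  ref <- flat_grid(10, 10, dx = 460)
  pt <- feature_geometry("points", cbind(5 * 460 - 230, 5 * 460 - 230))
  d <- distance_surface(ref, pt)
  expect_equal(d$values[6, 5], 0)             # coincident cell center
  expect_equal(d$values[6, 8], 3 * 460)       # 3 columns east
  # brute force equality for random points on a <= 50x50 grid
  with_seed(42, {
    ref2 <- flat_grid(23, 31, dx = 100)
    pts <- cbind(stats::runif(5, 0, 3100), stats::runif(5, 0, 2300))
  })
  d2 <- distance_surface(ref2, feature_geometry("points", pts))
  cc <- cell_centers(ref2)
  brute <- matrix(Inf, 23, 31)
  for (i in 1:23) for (j in 1:31)
    brute[i, j] <- sqrt(min((cc$x[j] - pts[, 1])^2 + (cc$y[i] - pts[, 2])^2))
  expect_equal(d2$values, brute)
  # min decomposition over two single-point surfaces
  dA <- distance_surface(ref2, feature_geometry("points", pts[1, , drop = FALSE]))
  dB <- distance_surface(ref2, feature_geometry("points", pts[2, , drop = FALSE]))
  dAB <- distance_surface(ref2, feature_geometry("points", pts[1:2, ]))
  expect_equal(dAB$values, pmin(dA$values, dB$values))
  expect_error(distance_surface(ref, feature_geometry("points", cbind(numeric(0), numeric(0)))),
               "empty")
})

test_that("polyline distance measures to segments, not vertices", {
  ref <- flat_grid(5, 5, dx = 100)
  # horizontal segment along y = 250 from x = 0 to x = 500
  ln <- feature_geometry("polyline", rbind(c(0, 250), c(500, 250)))
  d <- distance_surface(ref, ln)
  expect_equal(d$values[3, 3], 0)     # row 3 center has y = 250
  expect_equal(d$values[1, 3], 200)   # two rows north
})

test_that("temporal mean is nodata-aware and commutes with constants", {
  g1 <- flat_grid(4, 4, value = 1); g3 <- flat_grid(4, 4, value = 3)
  expect_equal(temporal_mean(list(g1, g3))$values, matrix(2, 4, 4))
  expect_equal(temporal_mean(list(g1))$values, g1$values)
  # cell valid on 2 of 3 days with values 4 and 6 -> 5
  a <- flat_grid(3, 3, value = 4); b <- flat_grid(3, 3, value = 6)
  cna <- flat_grid(3, 3, value = 9); cna$values[2, 2] <- NA
  m <- temporal_mean(list(a, b, cna))
  expect_equal(m$values[2, 2], 5)
  expect_equal(m$values[1, 1], (4 + 6 + 9) / 3)
  allna <- flat_grid(3, 3); allna$values[] <- NA
  expect_true(is.na(temporal_mean(list(allna, allna))$values[1, 1]))
  expect_error(temporal_mean(list(g1, flat_grid(5, 4))), "aligned")
  # adding a constant to every layer shifts the mean by that constant
  shift <- function(g, c) { g$values <- g$values + c; g }
  m2 <- temporal_mean(list(shift(a, 10), shift(b, 10), shift(cna, 10)))
  expect_equal(m2$values, m$values + 10)
})

test_that("bilinear resampling is exact for planes and handles extents", {
  src <- plane_grid(a = 0.2, b = -0.1, c = 5, nr = 20, nc = 20, dx = 100)
  # identity resample
  expect_equal(resample_to(src, src)$values, src$values)
  # coarser target fully inside: plane reproduced at target cell centers
  tgt <- rast_grid(matrix(0, 8, 8), xmin = 200, ymax = 1800, dx = 150,
                   dy = 150, crs = "test-utm")
  out <- resample_to(src, tgt)
  cc <- cell_centers(tgt)
  expect_equal(out$values, outer(cc$y, cc$x, function(y, x) 0.2 * x - 0.1 * y + 5),
               tolerance = 1e-12)
  # constant source -> constant output
  cst <- flat_grid(20, 20, dx = 100, value = 7)
  expect_true(all(resample_to(cst, tgt)$values == 7))
  # disjoint extents error
  far <- rast_grid(matrix(0, 5, 5), xmin = 1e6, ymax = 1e6, dx = 100,
                   dy = 100, crs = "test-utm")
  expect_error(resample_to(src, far), "disjoint")
  # resampling commutes with adding a constant
  src2 <- src; src2$values <- src2$values + 3
  expect_equal(resample_to(src2, tgt)$values, out$values + 3)
})

test_that("pairwise correlation behaves like Pearson r on joint cells", {
  with_seed(7, {
    a <- flat_grid(100, 100, dx = 10)
    a$values <- matrix(stats::rnorm(1e4), 100, 100)
    b <- a; b$values <- matrix(stats::rnorm(1e4), 100, 100)
  })
  st <- predictor_stack(list(a = a, neg = {
    n <- a; n$values <- -a$values; n
  }, b = b))
  r <- pairwise_correlation(st)
  expect_equal(diag(r), c(a = 1, neg = 1, b = 1))
  expect_equal(r["a", "neg"], -1)
  expect_lt(abs(r["a", "b"]), 0.05)   # independent white noise, 10,000 cells
  # affine rescaling invariance (sign flip under negative scale)
  st2 <- predictor_stack(list(a = a, b = {
    s <- b; s$values <- -2.5 * b$values + 3; s
  }))
  expect_equal(pairwise_correlation(st2)["a", "b"], -r["a", "b"])
  # zero-variance layer flagged NA
  st3 <- predictor_stack(list(a = a, c = flat_grid(100, 100, dx = 10, value = 1)))
  expect_true(is.na(pairwise_correlation(st3)["a", "c"]))
})

test_that("ascii grid and feature I/O round-trip", {
  g <- plane_grid(0.01, 0.02, nr = 7, nc = 9, dx = 460, dy = 380)
  g$values[3, 4] <- NA
  p <- file.path(tempdir(), "t.asc")
  write_ascii_grid(g, p)
  g2 <- read_ascii_grid(p)
  expect_equal(g2$values, g$values)
  expect_equal(g2$dx, 460); expect_equal(g2$dy, 380)
  expect_equal(g2$xmin, g$xmin); expect_equal(g2$ymax, g$ymax)
  expect_equal(g2$crs, g$crs)
  # stack manifest round-trip
  st <- predictor_stack(list(z = g, w = plane_grid(0, 0.01, nr = 7, nc = 9,
                                                   dx = 460, dy = 380)))
  mf <- write_stack(st, file.path(tempdir(), "stk"))
  st2 <- read_stack(mf)
  expect_equal(names(st2), c("z", "w"))
  expect_equal(st2$z$values, st$z$values)
  # geojson + wkt
  poly <- feature_geometry("polygon", rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
                           label = "sac", crs = "test-utm")
  gj <- file.path(tempdir(), "t.geojson")
  write_geojson(poly, gj)
  poly2 <- read_geojson(gj)
  expect_equal(poly2$coords, poly$coords)
  expect_equal(poly2$kind, "polygon")
  expect_equal(poly2$label, "sac")
  pts <- feature_geometry("points", cbind(c(1, 2), c(3, 4)))
  expect_equal(read_wkt(write_wkt(pts))$coords, pts$coords)
  expect_equal(read_wkt(write_wkt(poly))$coords, poly$coords)
})

test_that("point-in-polygon and polygon distance are consistent", {
  poly <- feature_geometry("polygon", rbind(c(0, 0), c(100, 0), c(100, 100),
                                            c(0, 100)))
  expect_true(points_in_polygon(50, 50, poly))
  expect_false(points_in_polygon(150, 50, poly))
  expect_equal(dist_to_polygon(c(50, 150), c(50, 50), poly), c(0, 50))
})
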