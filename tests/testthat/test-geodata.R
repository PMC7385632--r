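test_that("ascii grid layout convention: first data row is the north row", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999",
               "1 2", "3 4"), p)
  g <- read_ascii_grid(p)
  expect_equal(g$values[1, 1], 1)  # NW
  expect_equal(g$values[2, 2], 4)  # SE
  expect_equal(g$nrows, 2)
  expect_equal(g$xll, 0)
})

test_that("nodata sentinel becomes NA on read", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 0.5", "NODATA_value -9999",
               "-9999 7"), p)
  g <- read_ascii_grid(p)
  expect_true(is.na(g$values[1, 1]))
  expect_equal(g$values[1, 2], 7)
})

test_that("read/write round trip is the identity on header and values", {
  set.seed(42)
  g <- toy_grid(matrix(rnorm(30), 5, 6), xll = 107.25, yll = 40.5,
                cellsize = 0.125, name = "rt")
  g$values[2, 3] <- NA
  p <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, p)
  g2 <- read_ascii_grid(p, name = "rt")
  expect_identical(g2$values, g$values)
  expect_identical(g2[c("ncols", "nrows", "xll", "yll", "cellsize", "nodata")],
                   g[c("ncols", "nrows", "xll", "yll", "cellsize", "nodata")])

  gc <- toy_grid(matrix(c(1, 2, NA, 4), 2, 2), kind = "categorical")
  pc <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(gc, pc)
  expect_identical(read_ascii_grid(pc, kind = "categorical")$values, gc$values)
})

test_that("malformed headers and ragged rows are named errors", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 1", "cellsize 1", "1 2"), p)
  expect_error(read_ascii_grid(p), "xllcorner")
  writeLines(c("ncols 3", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "1 2 3", "4 5"), p)
  expect_error(read_ascii_grid(p), "row 2")
  expect_error(raster_grid(matrix(numeric(0), 0, 0)), "at least one")
  expect_error(raster_grid(matrix(1.5), kind = "categorical"), "non-integer")
})

test_that("extraction picks the containing cell, east/north on edges", {
  st <- toy_stack(list(const7 = matrix(7, 4, 4),
                       colidx = matrix(rep(1:4, each = 4), 4, 4, byrow = FALSE)))
  # colidx layer: value = column index
  st$layers$colidx$values <- matrix(rep(1:4, times = 4), 4, 4, byrow = TRUE)
  occ <- data.frame(id = c("center", "edge"), lon = c(1.5, 3), lat = c(2.5, 2.5))
  fm <- extract_at_points(st, occ)
  expect_equal(fm$const7, c(7, 7))
  # point on shared vertical edge of columns 3 and 4 belongs to column 4
  expect_equal(fm$colidx[2], 4)
  expect_equal(fm$colidx[1], 2)
})

test_that("extraction agrees with a brute-force point-in-cell search", {
  set.seed(99)
  nr <- 6; nc <- 8
  st <- toy_stack(list(colv = matrix(rep(1:nc, times = nr), nr, nc, byrow = TRUE)),
                  xll = 10, yll = 20, cellsize = 0.5)
  lon <- runif(5, 10, 10 + nc * 0.5)
  lat <- runif(5, 20, 20 + nr * 0.5)
  fm <- extract_at_points(st, data.frame(id = letters[1:5], lon = lon, lat = lat))
  for (i in 1:5) {
    hit <- NA
    for (col in 1:nc) {
      x0 <- 10 + (col - 1) * 0.5
      if (lon[i] >= x0 && lon[i] < x0 + 0.5) hit <- col
    }
    expect_equal(fm$colv[i], hit)
  }
})

test_that("out-of-extent points become error records, not silent drops", {
  st <- toy_stack(list(a = matrix(1, 2, 2)))
  occ <- data.frame(id = c("in", "out"), lon = c(0.5, 9), lat = c(0.5, 0.5))
  expect_warning(fm <- extract_at_points(st, occ), "outside extent")
  expect_equal(nrow(fm), 2)
  expect_true(is.na(fm$a[2]))
  expect_equal(attr(fm, "errors")$id, "out")
  expect_equal(attr(fm, "complete"), c(TRUE, FALSE))
})

test_that("nodata in any layer marks the row incomplete", {
  m <- matrix(1, 2, 2); m[1, 1] <- NA
  st <- toy_stack(list(a = matrix(5, 2, 2), b = m))
  fm <- extract_at_points(st, data.frame(id = "p", lon = 0.5, lat = 1.5))
  expect_false(attr(fm, "complete"))
  expect_equal(fm$a, 5)
})

test_that("zone rasterization matches brute-force center containment", {
  tmpl <- toy_grid(matrix(0, 4, 4))
  left_half <- list(name = "L",
                    rings = list(cbind(c(0, 2, 2, 0, 0), c(0, 0, 4, 4, 0))))
  zr <- rasterize_zones(list(left_half), tmpl)
  expect_equal(sum(zr$values == 1, na.rm = TRUE), 8)
  expect_true(all(is.na(zr$values[, 3:4])))
  # brute force over cell centers
  for (r in 1:4) for (cl in 1:4) {
    cx <- cl - 0.5; cy <- 4 - r + 0.5
    inside <- cx > 0 && cx < 2 && cy > 0 && cy < 4
    expect_equal(!is.na(zr$values[r, cl]), inside)
  }
})

test_that("whole-extent zone covers every cell; degenerate zone covers none", {
  tmpl <- toy_grid(matrix(0, 3, 3))
  all_zone <- list(name = "all",
                   rings = list(cbind(c(0, 3, 3, 0, 0), c(0, 0, 3, 3, 0))))
  zr <- rasterize_zones(list(all_zone), tmpl)
  expect_true(all(zr$values == 1))
  degen <- list(name = "empty",
                rings = list(cbind(c(1, 1, 1), c(1, 1, 1))))
  expect_warning(zr2 <- rasterize_zones(list(degen), tmpl), "no cell center")
  expect_true(all(is.na(zr2$values)))
})

test_that("overlapping zones: first in input order wins, with a warning", {
  tmpl <- toy_grid(matrix(0, 2, 2))
  z1 <- list(name = "a", rings = list(cbind(c(0, 2, 2, 0, 0), c(0, 0, 2, 2, 0))))
  z2 <- list(name = "b", rings = list(cbind(c(0, 1, 1, 0, 0), c(0, 0, 2, 2, 0))))
  expect_warning(zr <- rasterize_zones(list(z1, z2), tmpl), "overlap")
  expect_true(all(zr$values == 1))
})

test_that("geojson zones round-trip through rasterization", {
  p <- withr::local_tempfile(fileext = ".geojson")
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(name = "west"),
    geometry = list(type = "Polygon",
                    coordinates = list(list(list(0, 0), list(1, 0), list(1, 2),
                                            list(0, 2), list(0, 0)))))))
  jsonlite::write_json(gj, p, auto_unbox = TRUE)
  zones <- read_zones_geojson(p)
  expect_equal(zones[[1]]$name, "west")
  zr <- rasterize_zones(zones, toy_grid(matrix(0, 2, 2)))
  expect_equal(sum(zr$values == 1, na.rm = TRUE), 2)
})

test_that("spherical cell areas shrink with latitude as cos(lat)", {
  g <- toy_grid(matrix(0, 2, 1), yll = 40, cellsize = 1)
  a <- cell_areas_km2(g)
  expect_equal(a[2] / a[1], cos(40.5 * pi / 180) / cos(41.5 * pi / 180))
  # one-degree cell near the equator is about (111.2 km)^2
  ge <- toy_grid(matrix(0, 1, 1), yll = -0.5, cellsize = 1)
  expect_equal(cell_areas_km2(ge), (pi / 180 * 6371.0088)^2, tolerance = 1e-6)
})
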