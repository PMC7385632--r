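#' Gridded environmental layer
#'
#' A `raster_grid` is a regular lon/lat grid in the ESRI ASCII registration
#' convention: `xll`/`yll` give the *corner* of the lower-left cell, and the
#' value matrix is stored with row 1 as the northernmost row. Missing cells
#' are held as `NA` internally and serialized as the `nodata` sentinel.
#'
#' @param values numeric matrix, `nrows x ncols`, row 1 = north; `NA` marks
#'   nodata cells.
#' @param xll,yll longitude/latitude of the lower-left corner (decimal
#'   degrees, WGS84 assumed).
#' @param cellsize cell edge length in degrees; must be positive.
#' @param nodata sentinel value written to file for `NA` cells.
#' @param kind `"continuous"` or `"categorical"`; categorical grids must hold
#'   integer codes.
#' @param name factor identifier, e.g. `"TempSeasonality"`.
#' @param units free-text units, e.g. `"mm"`, `"degC x 10"`, `"h x 10"`.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize = 1, nodata = -9999,
                        kind = c("continuous", "categorical"),
                        name = "layer", units = "") {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster_grid: grid must have at least one row and one column")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("raster_grid: cellsize must be a single positive number")
  storage.mode(values) <- "double"
  if (kind == "categorical") {
    v <- values[!is.na(values)]
    if (length(v) && any(v != round(v)))
      stop("raster_grid: categorical grid contains non-integer values")
  }
  structure(
    list(ncols = ncol(values), nrows = nrow(values),
         xll = xll, yll = yll, cellsize = cellsize, nodata = nodata,
         values = values, kind = kind, name = name, units = units),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("raster_grid '%s' (%s): %d x %d cells, cellsize %g deg\n",
              x$name, x$kind, x$nrows, x$ncols, x$cellsize))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]\n",
              x$xll, x$xll + x$ncols * x$cellsize,
              x$yll, x$yll + x$nrows * x$cellsize))
  if (length(v))
    cat(sprintf("  values: [%g, %g], %d nodata cells\n",
                min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-key ESRI ASCII header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`; the last is optional and defaults
#' to -9999) followed by whitespace-separated rows, northernmost row first.
#'
#' @param path file to read.
#' @param kind,name,units metadata attached to the returned grid; `name`
#'   defaults to the file name without extension.
#' @return A [raster_grid].
#' @export
read_ascii_grid <- function(path, kind = c("continuous", "categorical"),
                            name = NULL, units = "") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("read_ascii_grid: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    tok <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("read_ascii_grid: malformed header, missing key(s): ",
         paste(miss, collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- lines[(i + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr)
    stop("read_ascii_grid: expected ", nr, " data rows, found ", length(body))
  vals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    row <- as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]])
    if (length(row) != nc)
      stop("read_ascii_grid: row ", r, " has ", length(row),
           " values, expected ", nc)
    vals[r, ] <- row
  }
  vals[vals == nodata] <- NA_real_
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raster_grid(vals, xll = hdr$xllcorner, yll = hdr$yllcorner,
              cellsize = hdr$cellsize, nodata = nodata,
              kind = kind, name = name, units = units)
}

#' Write an ESRI ASCII grid
#'
#' Continuous layers are written at full double precision (`%.17g`, so a
#' read/write round trip is value-identical); categorical layers as integers.
#'
#' @param grid a [raster_grid].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  fmt <- if (grid$kind == "categorical") "%d" else "%.17g"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.17g", grid$xll),
    sprintf("yllcorner %.17g", grid$yll),
    sprintf("cellsize %.17g", grid$cellsize),
    sprintf("NODATA_value %.17g", grid$nodata)), con)
  if (grid$kind == "categorical") storage.mode(v) <- "integer"
  writeLines(apply(v, 1L, function(r) paste(sprintf(fmt, r), collapse = " ")),
             con)
  invisible(path)
}

#' Bundle aligned layers into a stack
#'
#' All layers must share `ncols`, `nrows`, `xll`, `yll` and `cellsize`
#' (checked to a 1e-9-degree tolerance) and have unique names.
#'
#' @param layers list of [raster_grid] objects.
#' @param category optional character vector tagging each layer (climate,
#'   soil, topography, vegetation, comprehensive-meteorological).
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(layers, category = NULL) {
  stopifnot(length(layers) >= 1L, all(vapply(layers, inherits, TRUE, "raster_grid")))
  nm <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("raster_stack: duplicate layer names")
  names(layers) <- nm
  ref <- layers[[1]]
  for (l in layers[-1]) {
    if (l$ncols != ref$ncols || l$nrows != ref$nrows ||
        abs(l$xll - ref$xll) > 1e-9 || abs(l$yll - ref$yll) > 1e-9 ||
        abs(l$cellsize - ref$cellsize) > 1e-9)
      stop("raster_stack: layer '", l$name, "' is not aligned with '",
           ref$name, "'")
  }
  if (is.null(category)) category <- rep(NA_character_, length(layers))
  structure(list(layers = layers, category = setNames(category, nm)),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack: %d layers, %d x %d cells\n",
              length(x$layers), x$layers[[1]]$nrows, x$layers[[1]]$ncols))
  cat("  ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Layer kinds of a stack
#' @param stack a [raster_stack].
#' @return Named character vector, `"continuous"` or `"categorical"` per layer.
#' @export
stack_kinds <- function(stack)
  vapply(stack$layers, `[[`, "", "kind")

#' Cell values of a stack as a matrix
#'
#' Cells are ordered row-major from the northwest corner (row 1 west to east,
#' then row 2, ...), matching `cell_index()`.
#'
#' @param stack a [raster_stack].
#' @return `ncell x nlayer` numeric matrix with `NA` for nodata.
#' @export
stack_matrix <- function(stack) {
  m <- vapply(stack$layers, function(l) as.vector(t(l$values)),
              numeric(stack$layers[[1]]$nrows * stack$layers[[1]]$ncols))
  colnames(m) <- names(stack$layers)
  m
}

# row/col (1-based, row 1 = north) -> linear cell index used by stack_matrix()
cell_index <- function(grid, row, col) (row - 1L) * grid$ncols + col

# inverse of cell_index
cell_rowcol <- function(grid, idx) {
  row <- (idx - 1L) %/% grid$ncols + 1L
  col <- (idx - 1L) %% grid$ncols + 1L
  cbind(row = row, col = col)
}

# cell containing a lon/lat point; ties on internal edges go east/north.
# Returns NA row/col for points outside the extent.
locate_cells <- function(grid, lon, lat) {
  col <- floor((lon - grid$xll) / grid$cellsize) + 1L
  row <- grid$nrows - floor((lat - grid$yll) / grid$cellsize)
  bad <- col < 1L | col > grid$ncols | row < 1L | row > grid$nrows |
    !is.finite(lon) | !is.finite(lat)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Spherical cell areas by grid row
#'
#' Area of one cell in row `r` (row 1 = north) under a spherical Earth:
#' `(cellsize * pi/180 * R)^2 * cos(lat_r)` with `lat_r` the latitude of the
#' row's cell centers and `R = 6371.0088` km.
#'
#' @param grid a [raster_grid].
#' @return Numeric vector of length `nrows`, km^2 per cell.
#' @export
cell_areas_km2 <- function(grid) {
  lat_center <- grid$yll + (grid$nrows - seq_len(grid$nrows) + 0.5) * grid$cellsize
  (grid$cellsize * pi / 180 * EARTH_RADIUS_KM)^2 * cos(lat_center * pi / 180)
}

#' Read occurrence records
#'
#' Expects a delimited text file with a header row `id,lon,lat`
#' (WGS84 decimal degrees).
#'
#' @param path CSV file.
#' @return `data.frame` with columns `id`, `lon`, `lat`.
#' @export
read_occurrences <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "lon", "lat")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_occurrences: missing column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(d$lon)) || !all(is.finite(d$lat)))
    stop("read_occurrences: non-finite coordinates")
  d[need]
}

#' Extract layer values at occurrence points
#'
#' Each point is assigned the cell containing it (points exactly on an
#' internal cell edge belong to the east/north neighbour, so extraction is
#' deterministic). A row is flagged incomplete when any layer is nodata at
#' that cell. Points outside the grid extent are kept as error records, not
#' silently dropped: their layer values are `NA` and they are listed in the
#' `errors` attribute.
#'
#' @param stack a [raster_stack].
#' @param occurrences data frame with `id`, `lon`, `lat`.
#' @return A `factor_matrix`: data frame of `id` plus one column per layer,
#'   with attributes `kinds` (per-factor kind), `complete` (logical per row)
#'   and `errors` (data frame of out-of-extent points, zero rows if none).
#' @export
extract_at_points <- function(stack, occurrences) {
  ref <- stack$layers[[1]]
  rc <- locate_cells(ref, occurrences$lon, occurrences$lat)
  outside <- is.na(rc[, "row"])
  vals <- matrix(NA_real_, nrow(occurrences), length(stack$layers),
                 dimnames = list(NULL, names(stack$layers)))
  inside <- which(!outside)
  if (length(inside)) {
    ij <- rc[inside, , drop = FALSE]
    for (j in seq_along(stack$layers))
      vals[inside, j] <- stack$layers[[j]]$values[ij]
  }
  out <- data.frame(id = occurrences$id, vals, check.names = FALSE,
                    stringsAsFactors = FALSE)
  errors <- data.frame(id = occurrences$id[outside],
                       lon = occurrences$lon[outside],
                       lat = occurrences$lat[outside],
                       reason = rep("outside grid extent", sum(outside)),
                       stringsAsFactors = FALSE)
  if (nrow(errors))
    warning("extract_at_points: ", nrow(errors), " point(s) outside extent")
  structure(out,
            kinds = stack_kinds(stack),
            complete = !outside & rowSums(is.na(vals)) == 0L,
            errors = errors,
            class = c("factor_matrix", "data.frame"))
}

# Even-odd point-in-polygon test, vectorized over points.
# rings: list of two-column lon/lat matrices (closed or open; closure implied).
points_in_polygon <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- length(x)
    if (n >= 2 && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
    if (n < 3) next
    j <- n
    for (i in seq_len(n)) {
      cross <- ((y[i] > py) != (y[j] > py)) &
        (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
      inside <- xor(inside, cross)
      j <- i
    }
  }
  inside
}

#' Read zone polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon or MultiPolygon features; the zone
#' name is taken from the `name` property.
#'
#' @param path GeoJSON file.
#' @return List of zones, each `list(name, rings)` with `rings` a list of
#'   two-column lon/lat matrices.
#' @export
read_zones_geojson <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(g$features)) stop("read_zones_geojson: not a FeatureCollection")
  zones <- lapply(g$features, function(f) {
    geom <- f$geometry
    ringify <- function(coords) lapply(coords, function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]]))))
    rings <- switch(geom$type,
      Polygon = ringify(geom$coordinates),
      MultiPolygon = unlist(lapply(geom$coordinates, ringify), recursive = FALSE),
      stop("read_zones_geojson: unsupported geometry type: ", geom$type))
    list(name = f$properties$name, rings = rings)
  })
  nm <- vapply(zones, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("read_zones_geojson: duplicate zone names")
  zones
}

#' Rasterize zone polygons onto a template grid
#'
#' Each cell takes the id of the zone containing its center under the
#' even-odd rule; cells in no zone become nodata. When zones overlap, the
#' first zone in input order wins and a warning is issued.
#'
#' @param zones list of zones as returned by [read_zones_geojson()].
#' @param template_grid a [raster_grid] defining the target geometry.
#' @return Categorical [raster_grid] of zone ids (1-based input order), with
#'   zone names in the `zone_names` attribute.
#' @export
rasterize_zones <- function(zones, template_grid) {
  g <- template_grid
  cx <- g$xll + (rep(seq_len(g$ncols), times = g$nrows) - 0.5) * g$cellsize
  cy <- g$yll + (g$nrows - rep(seq_len(g$nrows), each = g$ncols) + 0.5) * g$cellsize
  assigned <- rep(NA_real_, length(cx))
  overlap <- FALSE
  for (z in seq_along(zones)) {
    hit <- points_in_polygon(cx, cy, zones[[z]]$rings)
    if (any(hit & !is.na(assigned))) overlap <- TRUE
    take <- hit & is.na(assigned)
    assigned[take] <- z
    if (!any(hit))
      warning("rasterize_zones: zone '", zones[[z]]$name,
              "' covers no cell center")
  }
  if (overlap)
    warning("rasterize_zones: overlapping zones; first zone in input order wins")
  out <- raster_grid(matrix(assigned, g$nrows, g$ncols, byrow = TRUE),
                     xll = g$xll, yll = g$yll, cellsize = g$cellsize,
                     nodata = g$nodata, kind = "categorical",
                     name = "zones")
  attr(out, "zone_names") <- vapply(zones, `[[`, "", "name")
  out
}
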