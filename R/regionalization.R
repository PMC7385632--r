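#' Jenks natural breaks (Fisher's optimal 1-D partition)
#'
#' Exact dynamic programming minimizing total within-class sum of squared
#' deviations. Breakpoints are reported as `b0 = min(x)` followed by the
#' maximum value of each class, so classes are `[b0,b1), [b1,b2), ...` with
#' the top class closed. Because the DP is O(k n^2), inputs larger than
#' `max_n` values are reduced to a seeded random subsample before the DP.
#'
#' @param values numeric vector; non-finite entries are ignored.
#' @param k number of classes (default 4).
#' @param max_n subsample cap for the DP (default 10000).
#' @param seed seed for the subsample when `length(values) > max_n`.
#' @return numeric vector of `k + 1` breakpoints.
#' @export
jenks_breaks <- function(values, k = 4, max_n = 10000, seed = 1L) {
  x <- values[is.finite(values)]
  if (length(unique(x)) < k)
    stop("jenks_breaks: need at least k = ", k, " distinct finite values")
  if (length(x) > max_n) {
    set.seed(seed)
    x <- sample(x, max_n)
    if (length(unique(x)) < k)
      stop("jenks_breaks: subsample has fewer than k distinct values")
  }
  x <- sort(x)
  ends <- .fisher_jenks_cpp(x, as.integer(k))
  c(x[1], x[ends])
}

#' Labels of the four suitability classes
#' @return character vector, lowest class first.
#' @export
suitability_labels <- function()
  c("unsuitable", "secondarily suitable", "suitable", "optimum")

#' Mask a suitability raster to the range observed at occurrences
#'
#' Cells whose suitability falls outside the \[min, max\] of the values at
#' the occurrence cells become nodata; this confines the regionalization to
#' the conditions actually sampled.
#'
#' @param suitability a continuous [raster_grid].
#' @param occurrences data frame `id`, `lon`, `lat`.
#' @return masked [raster_grid]; attribute `observed_range` holds the bounds.
#' @export
clip_to_observed_range <- function(suitability, occurrences) {
  rc <- locate_cells(suitability, occurrences$lon, occurrences$lat)
  keep <- !is.na(rc[, "row"])
  v <- rep(NA_real_, nrow(occurrences))
  v[keep] <- suitability$values[rc[keep, , drop = FALSE]]
  v <- v[!is.na(v)]
  if (!length(v))
    stop("clip_to_observed_range: no occurrence falls on a valid cell")
  rng <- range(v)
  out <- suitability
  mask <- !is.na(out$values) & (out$values < rng[1] | out$values > rng[2])
  out$values[mask] <- NA_real_
  attr(out, "observed_range") <- rng
  attr(out, "masked_cells") <- sum(mask)
  out
}

#' Classify a suitability raster into ordered classes
#'
#' Interval membership is lower-inclusive (`[b_i, b_{i+1})`) with the top
#' class closed, so a value equal to an internal breakpoint belongs to the
#' class above it. Values outside `[b0, bk]` are clamped into the end
#' classes with a warning. Nodata propagates.
#'
#' @param suitability continuous [raster_grid].
#' @param breaks numeric vector of `k + 1` ascending breakpoints, e.g. from
#'   [jenks_breaks()].
#' @param labels class labels, length `k` (default [suitability_labels()]).
#' @return categorical [raster_grid] with integer codes `0 .. k-1` (lowest
#'   class 0) and a `class_labels` attribute.
#' @export
classify_suitability <- function(suitability, breaks,
                                 labels = suitability_labels()) {
  k <- length(breaks) - 1L
  stopifnot(k >= 1, all(diff(breaks) > 0), length(labels) == k)
  v <- suitability$values
  out_of_range <- !is.na(v) & (v < breaks[1] | v > breaks[k + 1])
  if (any(out_of_range))
    warning("classify_suitability: ", sum(out_of_range),
            " cell(s) outside [b0, bk] clamped into end classes")
  code <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  # findInterval with left-closed intervals; top class absorbs == bk
  cd <- findInterval(v[ok], breaks, rightmost.closed = TRUE, left.open = FALSE) - 1L
  cd[cd < 0L] <- 0L
  cd[cd > k - 1L] <- k - 1L
  code[ok] <- cd
  out <- raster_grid(code, xll = suitability$xll, yll = suitability$yll,
                     cellsize = suitability$cellsize,
                     nodata = suitability$nodata,
                     kind = "categorical", name = "suitability_class")
  attr(out, "class_labels") <- labels
  attr(out, "breaks") <- breaks
  out
}

#' Share of a zone's area in one class
#'
#' The reporting convention of the zonal tables:
#' `round(100 * area / total, digits)`.
#'
#' @param area class area (km^2).
#' @param total zone total area (km^2).
#' @param digits rounding for reporting (default 2).
#' @return percentage.
#' @export
area_percentage <- function(area, total, digits = 2) {
  stopifnot(all(total > 0))
  round(100 * area / total, digits)
}

#' Per-zone class areas and percentages
#'
#' Sums latitude-aware spherical cell areas (see [cell_areas_km2()]) per
#' zone and class. Percentages are `100 * class_area / zone_total` where the
#' zone total counts all classified (non-nodata) cells of the zone; both are
#' rounded to 2 decimals for reporting.
#'
#' @param class_raster categorical [raster_grid] from
#'   [classify_suitability()].
#' @param zone_raster categorical zone-id [raster_grid] from
#'   [rasterize_zones()] (aligned with `class_raster`).
#' @return `zonal_area_table`: data frame with `zone`, `total_km2`, then one
#'   `area/pct` pair per class.
#' @export
zonal_areas <- function(class_raster, zone_raster) {
  if (class_raster$nrows != zone_raster$nrows ||
      class_raster$ncols != zone_raster$ncols)
    stop("zonal_areas: class and zone rasters are not aligned")
  labels <- attr(class_raster, "class_labels")
  if (is.null(labels))
    labels <- paste0("class_", sort(unique(stats::na.omit(as.vector(class_raster$values)))))
  zone_names <- attr(zone_raster, "zone_names")
  area_row <- cell_areas_km2(class_raster)
  areas <- matrix(area_row, class_raster$nrows, class_raster$ncols)
  cls <- as.vector(class_raster$values)
  zn <- as.vector(zone_raster$values)
  ar <- as.vector(areas)
  ok <- !is.na(zn)
  zone_ids <- sort(unique(zn[ok]))
  rows <- lapply(zone_ids, function(z) {
    in_zone <- ok & zn == z & !is.na(cls)
    total <- sum(ar[in_zone])
    if (total == 0) warning("zonal_areas: zone ", z, " has no classified cell")
    row <- list(zone = if (!is.null(zone_names)) zone_names[z] else as.character(z),
                total_km2 = round(total, 2))
    for (ci in seq_along(labels)) {
      a <- sum(ar[in_zone & cls == (ci - 1L)])
      row[[paste0(labels[ci], "_km2")]] <- round(a, 2)
      row[[paste0(labels[ci], "_pct")]] <-
        if (total > 0) area_percentage(a, total) else NA_real_
    }
    as.data.frame(row, check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("zonal_area_table", "data.frame")
  out
}
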