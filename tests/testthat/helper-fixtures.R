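# Shared fixtures built in code.

# small constant-or-pattern grid
toy_grid <- function(values, xll = 0, yll = 0, cellsize = 1, ...) {
  raster_grid(as.matrix(values), xll = xll, yll = yll, cellsize = cellsize, ...)
}

# stack of named layers from a list of matrices
toy_stack <- function(mats, kinds = NULL, xll = 0, yll = 0, cellsize = 1) {
  nm <- names(mats)
  layers <- lapply(seq_along(mats), function(i)
    raster_grid(as.matrix(mats[[i]]), xll = xll, yll = yll,
                cellsize = cellsize,
                kind = if (is.null(kinds)) "continuous" else kinds[[i]],
                name = nm[i]))
  raster_stack(layers)
}

# a compact synthetic world for model-level tests: few factors, one dominant
small_world <- function(seed = 1, nrows = 40, ncols = 40, n_presences = 60,
                        n_factors = 4, dominant_weight = 6) {
  fac <- default_factor_table()[seq_len(n_factors), ]
  w <- setNames(c(dominant_weight, rep(0.5, n_factors - 1)), fac$name)
  cfg <- synthetic_config(
    nrows = nrows, ncols = ncols, factors = fac,
    target_correlation = diag(n_factors),
    true_weights = w, true_intercept = -2.5 * dominant_weight,
    n_presences = n_presences, seed = seed)
  gen <- generate_factor_stack(cfg)
  gen$occ <- generate_occurrences(gen$truth, n_presences, seed = seed + 1)
  gen$config <- cfg
  gen
}

# brute-force total within-class SSE of the best partition of sorted x into
# k contiguous classes (enumerates all compositions)
brute_force_jenks_sse <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  ssq <- function(v) if (length(v) <= 1) 0 else sum((v - mean(v))^2)
  best <- Inf
  cuts <- utils::combn(n - 1, k - 1)
  if (k == 1) return(ssq(x))
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    sse <- sum(vapply(seq_len(k), function(i) ssq(x[(b[i] + 1):b[i + 1]]), 0))
    if (sse < best) best <- sse
  }
  best
}

# SSE of the partition implied by jenks breakpoints; the breakpoints are
# class maxima, so class i is (b[i-1], b[i]] with the bottom closed
jenks_sse <- function(x, breaks) {
  k <- length(breaks) - 1
  cls <- findInterval(x, breaks, left.open = TRUE)
  cls[cls < 1] <- 1; cls[cls > k] <- k
  sum(vapply(split(x, cls), function(v) sum((v - mean(v))^2), 0))
}
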