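#' Correlate factors with compound contents, with significance flags
#'
#' Pearson r per factor x compound, two-tailed p from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df; flags `**` for
#' p <= 0.01, `*` for p <= 0.05.
#'
#' @param factor_matrix data frame of factor values (an `id` column is
#'   ignored).
#' @param contents data frame with `id` plus one column per compound.
#' @return data frame `factor`, `compound`, `n`, `r`, `p`, `flag`;
#'   zero-variance pairs give `NA` with flag `"undefined"`.
#' @export
correlate_with_significance <- function(factor_matrix, contents) {
  fac <- factor_matrix[setdiff(names(factor_matrix), "id")]
  cmp <- contents[setdiff(names(contents), "id")]
  rows <- list()
  for (co in names(cmp)) for (fa in names(fac)) {
    x <- fac[[fa]]; y <- cmp[[co]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3) stop("correlate_with_significance: fewer than 3 complete pairs")
    if (var(x[ok]) == 0 || var(y[ok]) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        factor = fa, compound = co, n = n, r = NA_real_, p = NA_real_,
        flag = "undefined", stringsAsFactors = FALSE)
      next
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    flag <- if (ct$p.value <= 0.01) "**" else if (ct$p.value <= 0.05) "*" else ""
    rows[[length(rows) + 1L]] <- data.frame(
      factor = fa, compound = co, n = n, r = unname(ct$estimate),
      p = ct$p.value, flag = flag, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Bidirectional stepwise linear regression
#'
#' At each step the candidate with the smallest partial-F p-value is added
#' if it is at or below `alpha_enter`; then any included factor whose
#' partial-F p-value exceeds `alpha_remove` is removed (worst first); the
#' loop stops when neither move changes the model. Ordinary least squares
#' throughout.
#'
#' @param response numeric vector (compound content, % w/w).
#' @param factor_matrix data frame of candidate factors (an `id` column is
#'   ignored); categorical factors enter as their numeric codes.
#' @param alpha_enter,alpha_remove entry and removal thresholds (defaults
#'   0.05 and 0.10).
#' @param response_name label stored in the result.
#' @return `regression_model`: list with `response`, `coefficients` (named,
#'   intercept first), `selected`, `r_squared`, `residual_sd`, `trail`
#'   (data frame of `step`, `action`, `factor`, `p`), and the underlying
#'   `lm` fit.
#' @export
stepwise_regression <- function(response, factor_matrix,
                                alpha_enter = 0.05, alpha_remove = 0.10,
                                response_name = "y") {
  X <- factor_matrix[setdiff(names(factor_matrix), "id")]
  d <- data.frame(.y = response, X, check.names = FALSE)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10) stop("stepwise_regression: need at least 10 complete rows")
  candidates <- setdiff(names(d), ".y")
  selected <- character()
  trail <- data.frame(step = integer(), action = character(),
                      factor = character(), p = numeric(),
                      stringsAsFactors = FALSE)
  step_i <- 0L
  fml <- function(vars) {
    rhs <- if (length(vars)) paste(sprintf("`%s`", vars), collapse = " + ") else "1"
    as.formula(paste("`.y` ~", rhs))
  }
  repeat {
    changed <- FALSE
    fit <- lm(fml(selected), data = d)
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      a1 <- add1(fit, scope = fml(candidates), test = "F")
      a1 <- a1[rownames(a1) != "<none>", , drop = FALSE]
      pv <- setNames(a1[["Pr(>F)"]], gsub("`", "", rownames(a1)))
      pv <- pv[names(pv) %in% pool & is.finite(pv)]
      if (length(pv) && min(pv) <= alpha_enter) {
        best <- names(pv)[which.min(pv)]
        step_i <- step_i + 1L
        selected <- c(selected, best)
        trail <- rbind(trail, data.frame(step = step_i, action = "enter",
                                         factor = best, p = min(pv),
                                         stringsAsFactors = FALSE))
        changed <- TRUE
        fit <- lm(fml(selected), data = d)
      }
    }
    if (length(selected)) {
      d1 <- drop1(fit, test = "F")
      d1 <- d1[rownames(d1) != "<none>", , drop = FALSE]
      pv <- setNames(d1[["Pr(>F)"]], gsub("`", "", rownames(d1)))
      pv <- pv[is.finite(pv)]
      while (length(pv) && max(pv) > alpha_remove) {
        worst <- names(pv)[which.max(pv)]
        step_i <- step_i + 1L
        selected <- setdiff(selected, worst)
        trail <- rbind(trail, data.frame(step = step_i, action = "remove",
                                         factor = worst, p = max(pv),
                                         stringsAsFactors = FALSE))
        changed <- TRUE
        fit <- lm(fml(selected), data = d)
        if (!length(selected)) break
        d1 <- drop1(fit, test = "F")
        d1 <- d1[rownames(d1) != "<none>", , drop = FALSE]
        pv <- setNames(d1[["Pr(>F)"]], gsub("`", "", rownames(d1)))
        pv <- pv[is.finite(pv)]
      }
    }
    if (!changed) break
  }
  fit <- lm(fml(selected), data = d)
  if (length(selected) >= 2) {
    mm <- stats::model.matrix(fit)
    if (kappa(mm, exact = TRUE) > 1e10)
      stop("stepwise_regression: selected factors are collinear ",
           "(condition number > 1e10)")
  }
  cf <- coef(fit)
  names(cf) <- gsub("`", "", names(cf))
  sm <- summary(fit)
  structure(list(response = response_name, coefficients = cf,
                 selected = selected, r_squared = sm$r.squared,
                 residual_sd = sm$sigma, trail = trail, fit = fit,
                 n = nrow(d)),
            class = "regression_model")
}

#' @export
print.regression_model <- function(x, ...) {
  cf <- x$coefficients
  terms <- setdiff(names(cf), "(Intercept)")
  eq <- paste0(format(cf[["(Intercept)"]], digits = 4),
               paste0(sprintf(" %s %s*%s", ifelse(cf[terms] < 0, "-", "+"),
                              format(abs(cf[terms]), digits = 4), terms),
                      collapse = ""))
  cat(sprintf("regression_model: %s = %s  (R2 = %.3f, n = %d)\n",
              x$response, eq, x$r_squared, x$n))
  invisible(x)
}

#' Project a fitted content equation onto a raster stack
#'
#' Cellwise linear predictor over the model's factor layers; negative
#' predictions are clamped to zero (mass fractions cannot be negative) and
#' counted; nodata propagates.
#'
#' @param model a `regression_model`, or any named coefficient vector with
#'   an `(Intercept)` element.
#' @param stack a [raster_stack] containing every model factor.
#' @return continuous [raster_grid]; attribute `clamped_cells` counts the
#'   negative predictions clamped to 0.
#' @export
apply_regression_to_stack <- function(model, stack) {
  cf <- if (inherits(model, "regression_model")) model$coefficients else model
  terms <- setdiff(names(cf), "(Intercept)")
  miss <- setdiff(terms, names(stack$layers))
  if (length(miss))
    stop("apply_regression_to_stack: stack lacks layer(s): ",
         paste(miss, collapse = ", "))
  m <- stack_matrix(stack)
  lp <- rep(cf[["(Intercept)"]], nrow(m))
  for (f in terms) lp <- lp + cf[[f]] * m[, f]
  clamped <- sum(!is.na(lp) & lp < 0)
  lp[!is.na(lp) & lp < 0] <- 0
  ref <- stack$layers[[1]]
  out <- raster_grid(matrix(lp, ref$nrows, ref$ncols, byrow = TRUE),
                     xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize,
                     nodata = ref$nodata, kind = "continuous",
                     name = if (inherits(model, "regression_model"))
                       paste0(model$response, "_content") else "content")
  attr(out, "clamped_cells") <- clamped
  out
}

#' Content grade definitions
#'
#' Default tiers follow the published content limits for the two marker
#' compounds: astragaloside IV below 0.04% (secondarily suitable or
#' unsuitable), 0.04-0.12% (suitable), 0.12-0.20% (optimum);
#' calycosin-7-glucoside below 0.06%, 0.06-0.18% and 0.18-0.30%. With
#' `refine = TRUE` the bottom and top tiers are split at their midpoints for
#' a five-grade display scale.
#'
#' @param compound `"astragaloside_iv"` or `"calycosin_7_glucoside"`.
#' @param refine split outer tiers into five display grades (default FALSE).
#' @return list with `breaks` (ascending, starting at 0) and `labels`.
#' @export
content_grades <- function(compound = c("astragaloside_iv",
                                        "calycosin_7_glucoside"),
                           refine = FALSE) {
  compound <- match.arg(compound)
  breaks <- if (compound == "astragaloside_iv") c(0, 0.04, 0.12, 0.20)
            else c(0, 0.06, 0.18, 0.30)
  labels <- c("secondarily-suitable-or-unsuitable", "suitable", "optimum")
  if (refine) {
    b <- breaks
    breaks <- c(b[1], mean(b[1:2]), b[2], b[3], mean(b[3:4]), b[4])
    labels <- c("unsuitable", "secondarily suitable", "suitable",
                "optimum-low", "optimum-high")
  }
  list(breaks = breaks, labels = labels, compound = compound)
}

#' Grade a content raster into suitability tiers
#'
#' Interval membership is lower-inclusive; contents above the top bound go
#' to the top grade with a warning (the bounds come from observed sample
#' limits, so mild extrapolation is expected at raster scale).
#'
#' @param content_raster continuous [raster_grid] of predicted contents.
#' @param grades a [content_grades()] list.
#' @return categorical [raster_grid] with codes `0 ..` (lowest tier 0) and a
#'   `class_labels` attribute.
#' @export
grade_contents <- function(content_raster, grades) {
  k <- length(grades$labels)
  stopifnot(length(grades$breaks) == k + 1)
  v <- content_raster$values
  over <- !is.na(v) & v > grades$breaks[k + 1]
  if (any(over))
    warning("grade_contents: ", sum(over),
            " cell(s) above the top bound assigned the top grade")
  code <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  cd <- findInterval(v[ok], grades$breaks, rightmost.closed = TRUE) - 1L
  cd[cd < 0L] <- 0L
  cd[cd > k - 1L] <- k - 1L
  code[ok] <- cd
  out <- raster_grid(code, xll = content_raster$xll, yll = content_raster$yll,
                     cellsize = content_raster$cellsize,
                     nodata = content_raster$nodata, kind = "categorical",
                     name = paste0(grades$compound, "_grade"))
  attr(out, "class_labels") <- grades$labels
  out
}

#' Overlay optimum suitability with the top grades of both compounds
#'
#' A cell is flagged high-quality when it is in the optimum suitability
#' class *and* in the top grade for astragaloside IV *and* in the top grade
#' for calycosin-7-glucoside ("both contents maximized"). If a zone raster
#' is supplied, the flagged area is summarized per zone.
#'
#' @param class_raster categorical suitability classes from
#'   [classify_suitability()].
#' @param grade_a,grade_c graded content rasters from [grade_contents()].
#' @param zone_raster optional zone-id [raster_grid].
#' @return list with `mask` (categorical 0/1 [raster_grid]) and `summary`
#'   (per-zone data frame of high-quality area, or one overall row).
#' @export
high_quality_overlay <- function(class_raster, grade_a, grade_c,
                                 zone_raster = NULL) {
  same_geom <- function(a, b)
    a$nrows == b$nrows && a$ncols == b$ncols &&
      abs(a$xll - b$xll) < 1e-9 && abs(a$yll - b$yll) < 1e-9 &&
      abs(a$cellsize - b$cellsize) < 1e-9
  if (!same_geom(class_raster, grade_a) || !same_geom(class_raster, grade_c))
    stop("high_quality_overlay: misaligned inputs")
  top <- function(g) length(attr(g, "class_labels")) - 1L
  m <- (class_raster$values == top(class_raster)) &
       (grade_a$values == top(grade_a)) &
       (grade_c$values == top(grade_c))
  mask_vals <- ifelse(is.na(m), NA_real_, as.numeric(m))
  mask <- raster_grid(mask_vals, xll = class_raster$xll,
                      yll = class_raster$yll,
                      cellsize = class_raster$cellsize,
                      nodata = class_raster$nodata,
                      kind = "categorical", name = "high_quality")
  area_row <- cell_areas_km2(mask)
  areas <- matrix(area_row, mask$nrows, mask$ncols)
  if (is.null(zone_raster)) {
    summary <- data.frame(zone = "all",
                          high_quality_km2 = round(sum(areas[which(m)]), 2),
                          cells = sum(m, na.rm = TRUE))
  } else {
    if (!same_geom(class_raster, zone_raster))
      stop("high_quality_overlay: misaligned inputs")
    zn <- zone_raster$values
    zone_names <- attr(zone_raster, "zone_names")
    ids <- sort(unique(zn[!is.na(zn)]))
    summary <- do.call(rbind, lapply(ids, function(z) {
      sel <- !is.na(zn) & zn == z & !is.na(m) & m
      data.frame(zone = if (!is.null(zone_names)) zone_names[z] else as.character(z),
                 high_quality_km2 = round(sum(areas[sel]), 2),
                 cells = sum(sel))
    }))
  }
  list(mask = mask, summary = summary)
}
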