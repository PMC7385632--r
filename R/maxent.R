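#' Sample background cells from a stack
#'
#' Uniform sample without replacement of cells that are valid (no nodata) in
#' every layer. If `n_background` meets or exceeds the number of valid
#' cells, all valid cells are returned.
#'
#' @param stack a [raster_stack].
#' @param n_background requested sample size (default 10000, the
#'   conventional background count of presence-background modelling).
#' @param seed RNG seed.
#' @return list with `cells` (linear indices, `cell_index()` order) and
#'   `raw` (cells x layers value matrix).
#' @export
sample_background <- function(stack, n_background = 10000, seed = 1L) {
  m <- stack_matrix(stack)
  valid <- which(rowSums(is.na(m)) == 0L)
  if (!length(valid)) stop("sample_background: no valid cells in stack")
  set.seed(seed)
  cells <- if (n_background >= length(valid)) valid
           else sort(sample(valid, n_background))
  list(cells = cells, raw = m[cells, , drop = FALSE])
}

# --- feature machinery --------------------------------------------------

# Per-factor feature definitions derived from background data: continuous
# factors are rescaled to [0,1] by their background min/max before linear,
# quadratic and (optionally) hinge transforms; categorical factors get one
# indicator per background level. Constant factors are dropped with a warning.
build_feature_defs <- function(bg_raw, kinds, n_presences, hinge_knots = 31) {
  defs <- list()
  for (f in colnames(bg_raw)) {
    x <- bg_raw[, f]
    x <- x[is.finite(x)]
    if (kinds[[f]] == "categorical") {
      defs[[f]] <- list(kind = "categorical", levels = sort(unique(x)))
    } else {
      rng <- range(x)
      if (rng[1] == rng[2]) {
        warning("build_feature_defs: constant factor '", f, "' dropped")
        defs[[f]] <- list(kind = "continuous", constant = TRUE, rng = rng)
        next
      }
      knots <- if (n_presences >= 15 && hinge_knots > 0)
        seq(0, 1, length.out = hinge_knots + 2)[2:(hinge_knots + 1)]
      else numeric()
      defs[[f]] <- list(kind = "continuous", constant = FALSE, rng = rng,
                        knots = knots)
    }
  }
  defs
}

# feature columns of one factor; returns matrix (possibly 0-col) with
# colnames "<factor>|<class>|<param>", plus attr "unseen" for categorical
eval_factor_features <- function(def, f, x) {
  if (def$kind == "categorical") {
    cols <- vapply(def$levels, function(lv) as.numeric(x == lv),
                   numeric(length(x)))
    colnames(cols) <- sprintf("%s|categorical|%g", f, def$levels)
    attr(cols, "unseen") <- !is.na(x) & !(x %in% def$levels)
    return(cols)
  }
  if (isTRUE(def$constant))
    return(matrix(numeric(0), length(x), 0))
  z <- (x - def$rng[1]) / (def$rng[2] - def$rng[1])
  z <- pmin(1, pmax(0, z))
  cols <- cbind(z, z * z)
  colnames(cols) <- sprintf("%s|%s|0", f, c("linear", "quadratic"))
  if (length(def$knots)) {
    h <- vapply(def$knots, function(k) pmax(0, (z - k) / (1 - k)),
                numeric(length(z)))
    colnames(h) <- sprintf("%s|hinge|%g", f, def$knots)
    cols <- cbind(cols, h)
  }
  cols
}

#' Build the feature matrix for a set of points
#'
#' Continuous factors are rescaled to \[0,1\] by the background min/max held
#' in `defs` before the transforms (values outside the background range are
#' clamped); default classes are linear + quadratic for continuous factors,
#' hinge features at evenly spaced knots when the model was built with at
#' least 15 presences, and one indicator per level for categorical factors.
#'
#' @param defs feature definitions from the fitted model (or built
#'   internally by [maxent()]).
#' @param raw points x factors value matrix.
#' @return feature matrix in \[0,1\] with attributes `factor` and `class`
#'   (per column) and `unseen` (rows holding a categorical level absent from
#'   the background).
#' @export
build_features <- function(defs, raw) {
  pieces <- lapply(names(defs), function(f)
    eval_factor_features(defs[[f]], f, raw[, f]))
  unseen <- Reduce(`|`, c(list(rep(FALSE, nrow(raw))),
                          lapply(pieces, function(p) {
                            u <- attr(p, "unseen")
                            if (is.null(u)) rep(FALSE, nrow(raw)) else u
                          })))
  Fm <- do.call(cbind, pieces)
  info <- do.call(rbind, strsplit(colnames(Fm), "|", fixed = TRUE))
  structure(Fm, factor = info[, 1], class = info[, 2], unseen = unseen)
}

# published default regularization per feature class, interpolated on the
# presence count (flat outside the tabulated range)
beta_default_tables <- list(
  linear      = list(m = c(10, 30, 100),        b = c(1.0, 0.2, 0.05)),
  quadratic   = list(m = c(10, 17, 30, 100),    b = c(1.3, 0.8, 0.5, 0.05)),
  product     = list(m = c(0, 10, 17, 30, 100), b = c(2.6, 1.6, 1.4, 1.0, 0.05)),
  hinge       = list(m = c(0, 1),               b = c(0.5, 0.5)),
  threshold   = list(m = c(0, 100),             b = c(2.0, 1.0)),
  categorical = list(m = c(0, 10, 17),          b = c(0.65, 0.5, 0.25)))

# per-feature L1 penalty: class default scaled by the feature's presence SD
# over sqrt(m), times the user multiplier
default_betas <- function(feature_classes, Fpres, beta_multiplier = 1) {
  m <- nrow(Fpres)
  cls_beta <- vapply(feature_classes, function(cl) {
    tab <- beta_default_tables[[cl]]
    if (is.null(tab)) tab <- beta_default_tables$linear
    stats::approx(tab$m, tab$b, xout = m, rule = 2)$y
  }, 0)
  s <- apply(Fpres, 2L, sd)
  s <- pmax(s, 1e-3)
  cls_beta * s / sqrt(m) * beta_multiplier
}

soft_threshold <- function(x, t) sign(x) * pmax(0, abs(x) - t)

#' Fit an L1-regularized maximum-entropy model
#'
#' Maximizes `mean(presence score) - log Z(lambda) - sum(beta * |lambda|)`
#' (the regularized training gain, reported relative to the uniform
#' background distribution so an all-zero model has gain 0) by cyclic
#' coordinate ascent: each feature gets an analytic Newton step on the
#' smooth part, soft-thresholded for the L1 penalty, with step backtracking
#' so the regularized gain never decreases. Iteration stops when a full
#' cycle improves the gain by less than `convergence`.
#'
#' @param presence_features,background_features feature matrices from
#'   [build_features()]; the background rows must include the presences
#'   (the wrapper [maxent()] appends them).
#' @param beta optional per-feature penalty vector; by default the published
#'   per-class tables interpolated at the presence count, scaled by each
#'   feature's presence SD over `sqrt(m)`.
#' @param beta_multiplier multiplies the default penalties.
#' @param convergence minimal gain improvement per full cycle (default
#'   0.0005).
#' @param max_cycles cap on coordinate cycles (default 500; the iteration
#'   count of the fit is bounded by `max_cycles` times the feature count).
#' @return list with `lambda`, `beta`, `gain`, `gain_trace` (per cycle),
#'   `contrib` (per-feature signed gain increments), `q` (fitted background
#'   distribution), `H` (its entropy), `logZ`, `cycles`, `converged`.
#' @export
fit_maxent <- function(presence_features, background_features,
                       beta = NULL, beta_multiplier = 1,
                       convergence = 5e-4, max_cycles = 500) {
  Fp <- presence_features; Fb <- background_features
  stopifnot(ncol(Fp) == ncol(Fb), nrow(Fp) >= 1)
  J <- ncol(Fb); N <- nrow(Fb)
  classes <- attr(Fb, "class")
  if (is.null(classes)) classes <- rep("linear", J)
  if (is.null(beta)) beta <- default_betas(classes, Fp, beta_multiplier)
  beta <- rep_len(beta, J)
  if (any(beta < 0)) stop("fit_maxent: beta must be non-negative")
  pbar <- colMeans(Fp)
  if (any(!is.finite(pbar))) stop("fit_maxent: non-finite gain: feature '",
                                  colnames(Fp)[which(!is.finite(pbar))[1]],
                                  "' has non-finite presence mean")
  Fsq <- Fb * Fb
  lambda <- numeric(J)
  w <- rep(1, N); Z <- N
  g_cur <- 0
  contrib <- numeric(J)
  gain_trace <- numeric(0)
  converged <- FALSE
  cycles <- 0L
  for (cycle in seq_len(max_cycles)) {
    cycles <- cycle
    g_start <- g_cur
    q_all <- as.vector(crossprod(Fb, w)) / Z
    cand <- which(lambda != 0 | abs(pbar - q_all) > beta + 1e-12)
    for (j in cand) {
      fj <- Fb[, j]
      qj <- sum(w * fj) / Z
      vj <- max(sum(w * Fsq[, j]) / Z - qj * qj, 1e-12)
      lj <- lambda[j]
      target <- soft_threshold(lj + (pbar[j] - qj) / vj, beta[j] / vj)
      delta <- target - lj
      if (delta == 0) next
      delta <- sign(delta) * min(abs(delta), 5)
      g_new <- g_cur; Znew <- Z
      repeat {
        lj_new <- lj + delta
        Znew <- sum(w * exp(delta * fj))
        g_new <- g_cur + delta * pbar[j] - log(Znew / Z) -
          beta[j] * (abs(lj_new) - abs(lj))
        if (g_new >= g_cur - 1e-12) break
        delta <- delta / 2
        if (abs(delta) < 1e-10) break
      }
      if (!is.finite(g_new))
        stop("fit_maxent: non-finite gain: feature '", colnames(Fb)[j], "'")
      if (g_new <= g_cur) next
      dg <- g_new - g_cur
      contrib[j] <- contrib[j] +
        if (abs(lj + delta) >= abs(lj)) dg else -dg
      lambda[j] <- lj + delta
      w <- w * exp(delta * fj)
      Z <- Znew
      g_cur <- g_new
    }
    # renormalize so q = w / Z stays well scaled; gain is tracked incrementally
    w <- w * (N / Z); Z <- N
    gain_trace <- c(gain_trace, g_cur)
    if (g_cur - g_start < convergence) { converged <- TRUE; break }
  }
  q <- w / Z
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  s_bg <- as.vector(Fb %*% lambda)
  smax <- max(s_bg)
  logZ <- smax + log(sum(exp(s_bg - smax)))
  names(lambda) <- colnames(Fb)
  list(lambda = lambda, beta = setNames(beta, colnames(Fb)),
       gain = g_cur, gain_trace = gain_trace,
       contrib = setNames(contrib, colnames(Fb)),
       q = q, H = H, logZ = logZ, cycles = cycles, converged = converged)
}

#' Fit a presence-background niche model to occurrences and a stack
#'
#' Extracts factor values at the occurrence cells, samples a uniform
#' background, appends the presences to the background (the standard
#' presence-background treatment of the normalizer), builds the default
#' feature set and runs [fit_maxent()].
#'
#' @param occurrences data frame `id`, `lon`, `lat`.
#' @param stack a [raster_stack].
#' @param n_background background sample size (default 10000).
#' @param beta_multiplier,convergence,max_cycles passed to [fit_maxent()].
#' @param hinge_knots number of hinge knots per continuous factor (used when
#'   there are at least 15 presences; default 31).
#' @param seed RNG seed for the background sample.
#' @return `maxent_model` object.
#' @export
maxent <- function(occurrences, stack, n_background = 10000,
                   beta_multiplier = 1, convergence = 5e-4, max_cycles = 500,
                   hinge_knots = 31, seed = 1L) {
  fm <- extract_at_points(stack, occurrences)
  complete <- attr(fm, "complete")
  if (!all(complete))
    warning("maxent: ", sum(!complete), " occurrence(s) dropped (nodata or ",
            "outside extent)")
  pres_raw <- as.matrix(fm[complete, names(stack$layers), drop = FALSE])
  if (nrow(pres_raw) < 1) stop("maxent: no usable presence")
  bg <- sample_background(stack, n_background, seed)
  bg_raw <- rbind(bg$raw, pres_raw)
  defs <- build_feature_defs(bg_raw, as.list(stack_kinds(stack)),
                             n_presences = nrow(pres_raw),
                             hinge_knots = hinge_knots)
  Fb <- build_features(defs, bg_raw)
  Fp <- build_features(defs, pres_raw)
  fit <- fit_maxent(Fp, Fb, beta_multiplier = beta_multiplier,
                    convergence = convergence, max_cycles = max_cycles)
  structure(c(fit, list(
    defs = defs,
    feature_factor = attr(Fb, "factor"),
    feature_class = attr(Fb, "class"),
    pres_raw = pres_raw, bg_raw = bg_raw, bg_cells = bg$cells,
    kinds = stack_kinds(stack),
    n_presences = nrow(pres_raw))),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "maxent_model: %d presences, %d background points, %d features (%d active)\n",
    x$n_presences, nrow(x$bg_raw), length(x$lambda), sum(x$lambda != 0)))
  cat(sprintf("  regularized gain %.4f after %d cycles (%s), entropy %.4f\n",
              x$gain, x$cycles,
              if (x$converged) "converged" else "cycle cap reached", x$H))
  invisible(x)
}

# raw maxent scores lambda . f(x) for a raw value matrix; rows with NA or an
# unseen categorical level give NA
maxent_scores <- function(model, raw) {
  Fm <- build_features(model$defs, raw)
  s <- as.vector(Fm %*% model$lambda)
  bad <- attr(Fm, "unseen") | rowSums(is.na(raw[, names(model$defs), drop = FALSE])) > 0
  s[bad] <- NA_real_
  attr(s, "unseen") <- attr(Fm, "unseen")
  s
}

#' Predict suitability over a stack
#'
#' Raw output is `q(x) = exp(lambda . f(x)) / Z` with `Z` the training
#' background normalizer; the logistic output is
#' `exp(H) q / (1 + exp(H) q)` with `H` the entropy of the fitted background
#' distribution (the tau = 0.5 convention, so the all-zero model scores 0.5
#' everywhere). Nodata propagates; cells holding a categorical level unseen
#' in training become nodata with a warning.
#'
#' @param object a `maxent_model`.
#' @param stack a [raster_stack] aligned with the training layers.
#' @param transform `"logistic"` (default) or `"raw"`.
#' @param ... unused.
#' @return continuous [raster_grid] of predictions.
#' @export
predict.maxent_model <- function(object, stack,
                                 transform = c("logistic", "raw"), ...) {
  transform <- match.arg(transform)
  miss <- setdiff(names(object$defs), names(stack$layers))
  if (length(miss))
    stop("predict.maxent_model: stack lacks layer(s): ",
         paste(miss, collapse = ", "))
  raw <- stack_matrix(stack)
  s <- maxent_scores(object, raw)
  if (any(attr(s, "unseen")))
    warning("predict.maxent_model: ", sum(attr(s, "unseen")),
            " cell(s) with unseen category set to nodata")
  q <- exp(s - object$logZ)
  v <- if (transform == "raw") q else {
    eq <- exp(object$H) * q
    eq / (1 + eq)
  }
  ref <- stack$layers[[1]]
  raster_grid(matrix(v, ref$nrows, ref$ncols, byrow = TRUE),
              xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize,
              nodata = ref$nodata, kind = "continuous",
              name = paste0("suitability_", transform))
}

#' Area under the ROC curve by the pairwise statistic
#'
#' Probability that a random presence outscores a random background point,
#' ties credited one half (the Mann-Whitney statistic).
#'
#' @param presence_scores,background_scores numeric score vectors (non-empty;
#'   `NA` removed).
#' @return value in \[0, 1\].
#' @export
auc <- function(presence_scores, background_scores) {
  p <- presence_scores[!is.na(presence_scores)]
  b <- background_scores[!is.na(background_scores)]
  if (!length(p) || !length(b)) stop("auc: empty score set")
  r <- rank(c(p, b))
  (sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2) /
    (as.numeric(length(p)) * length(b))
}

#' Cross-validate a niche model
#'
#' `mode = "cv"` (default) partitions the presences at random into `k` folds
#' whose sizes differ by at most one; each fold in turn is held out, the
#' model is fitted on the remaining presences, and training/test AUC are
#' computed against the fixed background (the sampled background plus all
#' presences). `mode = "split"` performs a single random split with the
#' given test fraction.
#'
#' @param occurrences data frame `id`, `lon`, `lat`.
#' @param stack a [raster_stack].
#' @param k number of folds (default 10).
#' @param seed RNG seed (folds and background).
#' @param mode `"cv"` or `"split"`.
#' @param test_fraction held-out fraction for `mode = "split"` (default 0.1).
#' @param ... passed to [maxent()]/[fit_maxent()] (e.g. `n_background`,
#'   `beta_multiplier`, `convergence`, `max_cycles`).
#' @return `cv_result`: list with per-replicate data frame (`replicate`,
#'   `n_train`, `n_test`, `train_auc`, `test_auc`), `mean_test_auc`,
#'   `sd_test_auc`, `mean_train_auc`.
#' @export
cross_validate <- function(occurrences, stack, k = 10, seed = 1L,
                           mode = c("cv", "split"), test_fraction = 0.1,
                           n_background = 10000, beta_multiplier = 1,
                           convergence = 5e-4, max_cycles = 500,
                           hinge_knots = 31) {
  mode <- match.arg(mode)
  fm <- extract_at_points(stack, occurrences)
  complete <- attr(fm, "complete")
  pres_raw <- as.matrix(fm[complete, names(stack$layers), drop = FALSE])
  n <- nrow(pres_raw)
  if (mode == "cv" && k > n) stop("cross_validate: k exceeds presence count")
  bg <- sample_background(stack, n_background, seed)
  bg_raw <- rbind(bg$raw, pres_raw)
  defs <- build_feature_defs(bg_raw, as.list(stack_kinds(stack)),
                             n_presences = n, hinge_knots = hinge_knots)
  Fb <- build_features(defs, bg_raw)
  Fp <- build_features(defs, pres_raw)
  bg_lambda_scores <- function(lambda) as.vector(Fb %*% lambda)
  set.seed(seed + 1L)
  folds <- if (mode == "cv") sample(rep(seq_len(k), length.out = n))
  else {
    n_test <- max(1L, round(test_fraction * n))
    f <- rep(0L, n); f[sample(n, n_test)] <- 1L
    f
  }
  reps <- sort(unique(folds[folds > 0L]))
  if (mode == "split") reps <- 1L
  rows <- lapply(reps, function(fold) {
    test <- which(folds == fold)
    train <- setdiff(seq_len(n), test)
    fit <- fit_maxent(Fp[train, , drop = FALSE], Fb,
                      beta_multiplier = beta_multiplier,
                      convergence = convergence, max_cycles = max_cycles)
    s_p <- as.vector(Fp %*% fit$lambda)
    s_b <- bg_lambda_scores(fit$lambda)
    data.frame(replicate = fold, n_train = length(train),
               n_test = length(test),
               train_auc = auc(s_p[train], s_b),
               test_auc = auc(s_p[test], s_b))
  })
  res <- do.call(rbind, rows)
  structure(list(replicates = res,
                 mean_test_auc = mean(res$test_auc),
                 sd_test_auc = sd(res$test_auc),
                 mean_train_auc = mean(res$train_auc),
                 k = if (mode == "cv") k else NA_integer_,
                 mode = mode, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%s): mean test AUC %.3f (SD %.3f) over %d replicate(s)\n",
              x$mode, x$mean_test_auc, x$sd_test_auc, nrow(x$replicates)))
  print(x$replicates, row.names = FALSE)
  invisible(x)
}

#' Percent contribution of each factor
#'
#' During the fit, every coordinate update's increase in regularized gain is
#' added to the updated feature's running contribution, or subtracted from
#' it when the update shrank `|lambda|`. Feature totals are floored at zero,
#' summed to factor level and normalized to 100.
#'
#' @param model a `maxent_model`.
#' @return named numeric vector summing to 100 (all zero, with a warning,
#'   for a gainless model).
#' @export
percent_contribution <- function(model) {
  per_feature <- pmax(model$contrib, 0)
  per_factor <- tapply(per_feature, model$feature_factor, sum)
  out <- setNames(rep(0, length(model$defs)), names(model$defs))
  out[names(per_factor)] <- as.numeric(per_factor)
  total <- sum(out)
  if (total <= 0) {
    warning("percent_contribution: model has no positive gain increments")
    return(out)
  }
  100 * out / total
}

#' Permutation importance of each factor
#'
#' For each factor, its raw values are permuted jointly across the training
#' presences and background, the model is re-evaluated (features rebuilt
#' from the permuted values, weights unchanged), and the importance is the
#' drop in training AUC, floored at zero and normalized to 100.
#'
#' @param model a `maxent_model`.
#' @param seed RNG seed for the permutations.
#' @return named numeric vector summing to 100 (zeros if no factor matters).
#' @export
permutation_importance <- function(model, seed = 1L) {
  np <- nrow(model$pres_raw)
  base_p <- maxent_scores(model, model$pres_raw)
  base_b <- maxent_scores(model, model$bg_raw)
  base_auc <- auc(base_p, base_b)
  set.seed(seed)
  drops <- vapply(names(model$defs), function(f) {
    combined <- rbind(model$pres_raw, model$bg_raw)
    combined[, f] <- sample(combined[, f])
    s <- maxent_scores(model, combined)
    max(0, base_auc - auc(s[seq_len(np)], s[-seq_len(np)]))
  }, 0)
  total <- sum(drops)
  if (total <= 0) return(setNames(rep(0, length(drops)), names(drops)))
  100 * drops / total
}

#' Response curve of one factor
#'
#' Model output over an evaluation grid spanning the factor's background
#' range (its background levels, for a categorical factor), holding every
#' other continuous factor at its background mean and every other
#' categorical factor at its background mode.
#'
#' @param model a `maxent_model`.
#' @param factor_name layer name.
#' @param n_grid evaluation points for a continuous factor (default 100).
#' @param transform `"logistic"` or `"raw"`.
#' @return data frame `value`, `response`.
#' @export
response_curve <- function(model, factor_name, n_grid = 100,
                           transform = c("logistic", "raw")) {
  transform <- match.arg(transform)
  if (!factor_name %in% names(model$defs))
    stop("response_curve: unknown factor: ", factor_name)
  def <- model$defs[[factor_name]]
  grid <- if (def$kind == "categorical") def$levels
          else seq(def$rng[1], def$rng[2], length.out = n_grid)
  raw <- matrix(NA_real_, length(grid), length(model$defs),
                dimnames = list(NULL, names(model$defs)))
  for (f in names(model$defs)) {
    x <- model$bg_raw[, f]
    raw[, f] <- if (model$defs[[f]]$kind == "categorical") {
      tab <- table(x)
      as.numeric(names(tab)[which.max(tab)])
    } else mean(x)
  }
  raw[, factor_name] <- grid
  s <- maxent_scores(model, raw)
  q <- exp(s - model$logZ)
  resp <- if (transform == "raw") q else {
    eq <- exp(model$H) * q
    eq / (1 + eq)
  }
  data.frame(value = grid, response = as.numeric(resp))
}

#' Serialize a fitted model to JSON
#'
#' Writes the feature definitions, weights, penalties, normalizer, entropy
#' and rescaling bounds; enough to re-evaluate the model elsewhere.
#'
#' @param model a `maxent_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_maxent_json <- function(model, path) {
  active <- model$lambda != 0
  jsonlite::write_json(list(
    features = data.frame(feature = names(model$lambda),
                          factor = model$feature_factor,
                          class = model$feature_class,
                          lambda = as.numeric(model$lambda),
                          beta = as.numeric(model$beta))[active, ],
    defs = model$defs, logZ = model$logZ, H = model$H, gain = model$gain,
    n_presences = model$n_presences, cycles = model$cycles),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
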