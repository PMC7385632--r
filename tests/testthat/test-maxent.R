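# feature matrix helper for hand-built tests: columns already in [0,1]
bare_features <- function(m, classes = NULL) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  structure(m, factor = colnames(m),
            class = if (is.null(classes)) rep("linear", ncol(m)) else classes)
}

test_that("auc equals the pairwise win count", {
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.3)), 0.75)  # 3 wins of 4 pairs
  expect_equal(auc(c(0.9, 0.8), c(0.5, 0.3)), 1.0)
  expect_equal(auc(c(0.5, 0.5), c(0.5, 0.5)), 0.5)   # all ties
  # random sets against an explicit double loop
  set.seed(17)
  for (i in 1:5) {
    p <- rnorm(7); b <- rnorm(11)
    wins <- mean(outer(p, b, function(x, y)
      (x > y) + 0.5 * (x == y)))
    expect_equal(auc(p, b), wins, tolerance = 1e-12)
  }
})

test_that("auc is invariant under strictly monotone transforms", {
  set.seed(18)
  p <- rnorm(9); b <- rnorm(13)
  a0 <- auc(p, b)
  expect_equal(auc(exp(p), exp(b)), a0)
  expect_equal(auc(2 * p + 5, 2 * b + 5), a0)
})

test_that("full shrinkage gives the uniform model with zero gain", {
  set.seed(19)
  Fb <- bare_features(matrix(runif(60), 20, 3))
  Fp <- Fb[1:5, , drop = FALSE]
  fit <- fit_maxent(bare_features(Fp), Fb, beta = 1e6)
  expect_true(all(fit$lambda == 0))
  expect_equal(fit$gain, 0)
  expect_equal(fit$q, rep(1 / 20, 20))
  expect_equal(fit$H, log(20))
})

test_that("single binary feature recovers the closed-form weight ln 4", {
  # background half 1s half 0s, presence mean 0.8: fitted mass on the f=1
  # cells must be 0.8, so exp(lambda)/(exp(lambda) + 1) = 0.8 per cell pair
  Fb <- bare_features(matrix(rep(c(1, 0), each = 50), ncol = 1))
  Fp <- bare_features(matrix(c(rep(1, 8), rep(0, 2)), ncol = 1))
  fit <- fit_maxent(Fp, Fb, beta = 0, convergence = 1e-12, max_cycles = 2000)
  expect_equal(unname(fit$lambda), log(4), tolerance = 1e-6)
  expect_equal(sum(fit$q[1:50]), 0.8, tolerance = 1e-6)
})

test_that("unregularized fit matches brute-force entropy maximization on 6 cells", {
  # tiny domain, 2 features; oracle: dense grid search over (l1, l2)
  Fb <- bare_features(cbind(f1 = c(0, 0.2, 0.4, 0.6, 0.8, 1.0),
                            f2 = c(1, 0, 1, 0, 1, 0)))
  Fp <- bare_features(Fb[c(4, 5, 6, 6), , drop = FALSE])
  fit <- fit_maxent(Fp, Fb, beta = 0, convergence = 1e-12, max_cycles = 5000)
  obj <- function(l1, l2) {
    s <- Fb[, 1] * l1 + Fb[, 2] * l2
    mean(Fp[, 1]) * l1 + mean(Fp[, 2]) * l2 - log(sum(exp(s))) + log(6)
  }
  # two-stage grid search: coarse sweep, then refinement around the optimum
  grid <- seq(-6, 6, by = 0.01)
  vals <- outer(grid, grid, Vectorize(obj))
  best <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  g1 <- seq(grid[best[1]] - 0.02, grid[best[1]] + 0.02, by = 1e-4)
  g2 <- seq(grid[best[2]] - 0.02, grid[best[2]] + 0.02, by = 1e-4)
  vals2 <- outer(g1, g2, Vectorize(obj))
  best2 <- which(vals2 == max(vals2), arr.ind = TRUE)[1, ]
  l_star <- c(g1[best2[1]], g2[best2[2]])
  q_star <- exp(Fb %*% l_star); q_star <- q_star / sum(q_star)
  expect_lt(max(abs(unname(fit$q) - as.vector(q_star))), 1e-4)
  expect_gte(fit$gain, obj(l_star[1], l_star[2]) - 1e-6)
})

test_that("regularized gain is non-decreasing and q stays normalized", {
  gen <- small_world(seed = 23)
  m <- maxent(gen$occ, gen$stack, n_background = 800, seed = 24)
  expect_true(all(diff(m$gain_trace) >= -1e-9))
  expect_equal(sum(m$q), 1, tolerance = 1e-9)
  expect_true(m$H >= 0)
})

test_that("all-zero model predicts logistic 0.5 and raw sums to 1", {
  gen <- small_world(seed = 25, nrows = 12, ncols = 12, n_presences = 20)
  m <- maxent(gen$occ, gen$stack, n_background = 200, seed = 26,
              beta_multiplier = 1e9)  # forces lambda = 0
  expect_true(all(m$lambda == 0))
  pl <- predict(m, gen$stack, transform = "logistic")
  expect_true(all(abs(pl$values - 0.5) < 1e-12))
  praw <- predict(m, gen$stack, transform = "raw")
  # raw sums to 1 over the training background (here: all cells + presences)
  raw_bg <- exp(as.vector(build_features(m$defs, m$bg_raw) %*% m$lambda) - m$logZ)
  expect_equal(sum(raw_bg), 1, tolerance = 1e-9)
  expect_true(all(praw$values > 0))
})

test_that("logistic output is monotone in the raw output", {
  gen <- small_world(seed = 27)
  m <- maxent(gen$occ, gen$stack, n_background = 500, seed = 28)
  r <- as.vector(predict(m, gen$stack, transform = "raw")$values)
  l <- as.vector(predict(m, gen$stack, transform = "logistic")$values)
  o <- order(r)
  expect_true(all(diff(l[o]) >= -1e-12))
})

test_that("feature construction honours rescaling, quadratics and hinges", {
  set.seed(29)
  bg <- cbind(x = runif(200, 10, 30))
  defs <- build_feature_defs(bg, list(x = "continuous"), n_presences = 20,
                             hinge_knots = 5)
  Fm <- build_features(defs, matrix(c(10, 30, 20), ncol = 1,
                                    dimnames = list(NULL, "x")))
  lin <- Fm[, "x|linear|0"]
  expect_equal(lin[1], max(0, (10 - min(bg)) / diff(range(bg))))
  expect_equal(lin[3], (20 - min(bg)) / diff(range(bg)))
  expect_equal(Fm[, "x|quadratic|0"], lin^2)
  # hinge evaluated below its knot is zero
  hinge_cols <- grep("hinge", colnames(Fm))
  z_low <- lin[1]
  knots <- as.numeric(sub(".*\\|", "", colnames(Fm)[hinge_cols]))
  expect_true(all(Fm[1, hinge_cols][knots > z_low] == 0))
  expect_true(all(Fm >= 0 & Fm <= 1))
})

test_that("cross-validation folds are balanced and reproducible", {
  gen <- small_world(seed = 31, nrows = 30, ncols = 30, n_presences = 63)
  cv1 <- cross_validate(gen$occ, gen$stack, k = 10, seed = 32,
                        n_background = 300, max_cycles = 30)
  expect_equal(sort(cv1$replicates$n_test, decreasing = TRUE),
               c(7, 7, 7, 6, 6, 6, 6, 6, 6, 6))
  expect_equal(cv1$replicates$n_train + cv1$replicates$n_test, rep(63, 10))
  cv2 <- cross_validate(gen$occ, gen$stack, k = 10, seed = 32,
                        n_background = 300, max_cycles = 30)
  expect_identical(cv1$replicates, cv2$replicates)
  expect_true(all(cv1$replicates$test_auc >= 0 & cv1$replicates$test_auc <= 1))
  expect_equal(cv1$mean_test_auc, mean(cv1$replicates$test_auc))
  expect_error(cross_validate(gen$occ, gen$stack, k = 100), "exceeds")
})

test_that("single-split validation holds out the requested fraction", {
  gen <- small_world(seed = 33, nrows = 30, ncols = 30, n_presences = 60)
  cv <- cross_validate(gen$occ, gen$stack, mode = "split", test_fraction = 0.1,
                       seed = 34, n_background = 300, max_cycles = 30)
  expect_equal(nrow(cv$replicates), 1)
  expect_equal(cv$replicates$n_test, 6)
  expect_equal(cv$replicates$n_train, 54)
})

test_that("contributions sum to 100 and credit the dominant factor", {
  gen <- small_world(seed = 35, dominant_weight = 8)
  m <- maxent(gen$occ, gen$stack, n_background = 1000, seed = 36)
  pc <- percent_contribution(m)
  expect_equal(sum(pc), 100, tolerance = 1e-6)
  expect_true(all(pc >= 0))
  expect_equal(names(which.max(pc)), "TempSeasonality")
})

test_that("permutation importance is zero for an inert factor", {
  gen <- small_world(seed = 37)
  m <- maxent(gen$occ, gen$stack, n_background = 800, seed = 38)
  pi <- permutation_importance(m, seed = 39)
  expect_true(all(pi >= 0))
  expect_equal(sum(pi), 100, tolerance = 1e-6)
  # a factor whose every feature weight is zero cannot matter
  inert <- names(m$defs)[vapply(names(m$defs), function(f)
    all(m$lambda[m$feature_factor == f] == 0), TRUE)]
  if (length(inert)) expect_true(all(pi[inert] == 0))
  expect_equal(names(which.max(pi)), "TempSeasonality")
})

test_that("response curves match predictions on constant-other stacks", {
  gen <- small_world(seed = 41, nrows = 20, ncols = 20, n_presences = 40)
  m <- maxent(gen$occ, gen$stack, n_background = 400, seed = 42)
  rc <- response_curve(m, "TempSeasonality", n_grid = 7)
  expect_equal(nrow(rc), 7)
  # replicate by hand: constant-other raw rows through the score path
  raw <- matrix(NA_real_, 7, length(m$defs),
                dimnames = list(NULL, names(m$defs)))
  for (f in names(m$defs)) raw[, f] <- mean(m$bg_raw[, f])
  raw[, "TempSeasonality"] <- rc$value
  s <- as.vector(build_features(m$defs, raw) %*% m$lambda)
  eq <- exp(m$H) * exp(s - m$logZ)
  expect_equal(rc$response, eq / (1 + eq), tolerance = 1e-12)
  expect_true(all(rc$response >= 0 & rc$response <= 1))
})

test_that("background sampling is seeded, valid-only and exhaustive when small", {
  m <- matrix(1, 5, 5); m[1, 1] <- NA
  st <- toy_stack(list(a = m, b = matrix(2, 5, 5)))
  bg <- sample_background(st, n_background = 100, seed = 1)
  expect_equal(length(bg$cells), 24)  # all valid cells
  bg1 <- sample_background(st, n_background = 10, seed = 5)
  bg2 <- sample_background(st, n_background = 10, seed = 5)
  expect_identical(bg1$cells, bg2$cells)
  expect_false(1 %in% bg1$cells)  # the nodata cell
})

test_that("synthetic recovery: the dominant factor ranks first by weight mass", {
  hits <- 0L
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    gen <- small_world(seed = 100 + s, nrows = 30, ncols = 30,
                       n_presences = 80, dominant_weight = 8)
    m <- maxent(gen$occ, gen$stack, n_background = 600, seed = 200 + s,
                max_cycles = 100)
    mass <- tapply(abs(m$lambda), m$feature_factor, sum)
    if (names(which.max(mass)) == "TempSeasonality") hits <- hits + 1L
  }
  expect_gte(hits, round(0.9 * n_seeds))
})
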