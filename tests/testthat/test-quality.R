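test_that("correlation p-values follow the t formula and flag convention", {
  set.seed(51)
  n <- 63
  fm <- data.frame(id = seq_len(n), a = rnorm(n), b = rnorm(n))
  ct <- data.frame(id = seq_len(n), comp = rnorm(n))
  rep <- correlate_with_significance(fm, ct)
  for (i in seq_len(nrow(rep))) {
    r <- rep$r[i]
    t <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(rep$p[i], 2 * pt(-abs(t), n - 2), tolerance = 1e-12)
  }
  # r = 0.50 at n = 63 is significant at the 0.01 level
  t50 <- 0.5 * sqrt(61 / (1 - 0.25))
  expect_lt(2 * pt(-abs(t50), 61), 0.01)
  # a perfectly flagged constructed pair
  y <- fm$a * 0.6 + rnorm(n, sd = 0.5)
  rep2 <- correlate_with_significance(fm, data.frame(id = seq_len(n), y = y))
  strong <- rep2[rep2$factor == "a", ]
  expect_equal(strong$flag, "**")
})

test_that("correlation p-values agree with a permutation oracle", {
  set.seed(52)
  n <- 20
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  rep <- correlate_with_significance(data.frame(x = x),
                                     data.frame(y = y))
  r_obs <- abs(rep$r[1])
  perm <- vapply(1:20000, function(i) abs(cor(x, sample(y))), 0)
  p_perm <- mean(perm >= r_obs - 1e-12)
  expect_equal(rep$p[1], p_perm, tolerance = 0.02)
})

test_that("zero-variance factor yields a flagged undefined entry", {
  fm <- data.frame(flat = rep(1, 10), ok = rnorm(10))
  ct <- data.frame(y = rnorm(10))
  rep <- correlate_with_significance(fm, ct)
  expect_equal(rep$flag[rep$factor == "flat"], "undefined")
  expect_true(is.na(rep$r[rep$factor == "flat"]))
})

test_that("stepwise recovers a noiseless linear truth exactly", {
  set.seed(53)
  n <- 40
  X <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n),
                  x4 = runif(n), x5 = runif(n))
  y <- 1 + 2 * X$x1
  # a perfect fit makes summary.lm warn; that is the point of the case
  m <- suppressWarnings(stepwise_regression(y, X))
  expect_equal(m$selected, "x1")
  expect_equal(unname(m$coefficients[c("(Intercept)", "x1")]), c(1, 2),
               tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
  expect_equal(m$trail$action[1], "enter")
})

test_that("stepwise under the null includes a lone candidate at about alpha", {
  set.seed(54)
  n_rep <- 400
  n <- 30
  hits <- 0L
  for (i in seq_len(n_rep)) {
    X <- data.frame(x = rnorm(n))
    y <- rnorm(n)
    m <- stepwise_regression(y, X)
    if (length(m$selected)) hits <- hits + 1L
  }
  ci <- qbinom(c(0.0005, 0.9995), n_rep, 0.05)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("projection of an equation onto a stack evaluates cellwise", {
  st <- toy_stack(list(Prec4 = matrix(13, 2, 2), Prec10 = matrix(20, 2, 2),
                       TempSeasonality = matrix(11300, 2, 2)))
  cf <- default_content_coefficients()$astragaloside_iv
  g <- apply_regression_to_stack(cf, st)
  expect_equal(g$values, matrix(0.0682, 2, 2), tolerance = 1e-10)
  expect_equal(attr(g, "clamped_cells"), 0)

  # intercept-only model
  g0 <- apply_regression_to_stack(c("(Intercept)" = 0.3), st)
  expect_true(all(g0$values == 0.3))

  # clamping counts negative cells
  stn <- toy_stack(list(Prec4 = matrix(0, 2, 2), Prec10 = matrix(100, 2, 2),
                        TempSeasonality = matrix(14000, 2, 2)))
  gn <- apply_regression_to_stack(cf, stn)
  expect_true(all(gn$values == 0))
  expect_equal(attr(gn, "clamped_cells"), 4)

  expect_error(apply_regression_to_stack(cf, toy_stack(list(a = matrix(1, 2, 2)))),
               "Prec4")
})

test_that("content grading respects tier bounds, lower-inclusive", {
  g <- toy_grid(matrix(c(0.15, 0.04, 0.01, 0.12, 0.039, 0.2), 2, 3, byrow = TRUE))
  gr <- grade_contents(g, content_grades("astragaloside_iv"))
  expect_equal(as.vector(t(gr$values)), c(2, 1, 0, 2, 0, 2))
  # above the top bound: top grade with warning
  go <- toy_grid(matrix(c(0.25, 0.1), 1, 2))
  expect_warning(gro <- grade_contents(go, content_grades("astragaloside_iv")),
                 "top grade")
  expect_equal(as.vector(gro$values), c(2, 1))
  # refined display scale has 5 grades
  g5 <- content_grades("calycosin_7_glucoside", refine = TRUE)
  expect_length(g5$labels, 5)
  expect_equal(g5$breaks, c(0, 0.03, 0.06, 0.18, 0.24, 0.30))
})

test_that("high-quality overlay is the triple intersection", {
  breaks <- c(0, 0.02, 0.18, 0.42, 0.90)
  suit <- classify_suitability(
    toy_grid(matrix(c(0.5, 0.5, 0.1, 0.5, 0.5, 0.1, 0.1, 0.1, 0.1), 3, 3,
                    byrow = TRUE)), breaks)
  ga <- grade_contents(
    toy_grid(matrix(c(0.15, 0.05, 0.15, 0.15, 0.15, 0.15, 0.15, 0.15, 0.15),
                    3, 3, byrow = TRUE)), content_grades("astragaloside_iv"))
  gc_ <- grade_contents(
    toy_grid(matrix(c(0.25, 0.25, 0.25, 0.05, 0.25, 0.25, 0.25, 0.25, 0.25),
                    3, 3, byrow = TRUE)), content_grades("calycosin_7_glucoside"))
  ov <- high_quality_overlay(suit, ga, gc_)
  # only cells (1,1) and (2,2) are optimum in all three layers
  expect_equal(sum(ov$mask$values == 1, na.rm = TRUE), 2)
  expect_equal(ov$mask$values[1, 1], 1)
  expect_equal(ov$mask$values[2, 2], 1)
  expect_equal(ov$mask$values[1, 2], 0)

  # a layer with no optimum empties the mask
  ga0 <- grade_contents(toy_grid(matrix(0.05, 3, 3)),
                        content_grades("astragaloside_iv"))
  ov0 <- high_quality_overlay(suit, ga0, gc_)
  expect_equal(sum(ov0$mask$values == 1, na.rm = TRUE), 0)

  # monotonicity: tightening a grade never adds cells
  expect_lte(sum(ov0$mask$values, na.rm = TRUE),
             sum(ov$mask$values, na.rm = TRUE))

  # misaligned input is an error
  bad <- grade_contents(toy_grid(matrix(0.15, 2, 2)),
                        content_grades("astragaloside_iv"))
  expect_error(high_quality_overlay(suit, bad, gc_), "misaligned")
})

test_that("stepwise on synthetic contents recovers the generating factors", {
  # the three-factor saponin equation at its published R2, on a moderate
  # sample of survey-style sites
  set.seed(61)
  n <- 63
  fm <- data.frame(Prec4 = rnorm(n, 13, 5), Prec10 = rnorm(n, 20, 6),
                   TempSeasonality = rnorm(n, 12000, 800),
                   PH = rnorm(n, 7.2, 0.5), Smean4_10 = rnorm(n, 17500, 1000),
                   Altitude = rnorm(n, 1200, 400), Slope = rnorm(n, 3, 2))
  hits <- 0L
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    ct <- generate_compound_contents(fm, target_r2 = c(0.542, 0.345), seed = s)
    m <- stepwise_regression(ct$astragaloside_iv, fm,
                             response_name = "astragaloside_iv")
    if (all(c("Prec4", "Prec10", "TempSeasonality") %in% m$selected))
      hits <- hits + 1L
  }
  expect_gte(hits, round(0.6 * n_seeds))
})
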