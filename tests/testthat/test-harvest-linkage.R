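test_that("footprint rectangles have the right orientation and area", {
  b0 <- make_buffer(10, 20, heading = 0)          # travelling due north
  expect_equal(range(b0[, "x"]), c(4, 16))        # 12 m across track
  expect_equal(range(b0[, "y"]), c(19.5, 20.5))   # 1 m along track
  b90 <- make_buffer(10, 20, heading = 90)        # travelling due east
  expect_equal(range(b90[, "x"]), c(9.5, 10.5))
  expect_equal(range(b90[, "y"]), c(14, 26))
  for (h in c(0, 33.3, 90, 137, 215.5)) {
    b <- make_buffer(0, 0, heading = h)
    shoelace <- abs(sum(b[-5, "x"] * b[-1, "y"] - b[-1, "x"] * b[-5, "y"]) / 2)
    expect_lt(abs(shoelace - 12), 1e-9)
  }
})

test_that("headings follow consecutive points and pass boundaries", {
  pts <- data.frame(x = c(1, 1, 1, 5, 5, 5), y = c(0, 1, 2, 2, 1, 0),
                    pass = c(1, 1, 1, 2, 2, 2))
  h <- estimate_headings(pts)
  expect_equal(h, c(0, 0, 0, 180, 180, 180))
  # without a pass column, the long jump between passes is detected
  h2 <- estimate_headings(pts[, c("x", "y")])
  expect_equal(h2, c(0, 0, 0, 180, 180, 180))
})

test_that("footprint means are exact on constant fields and at sharp edges", {
  g <- const_grid(0.7, 40, 40, ps = 0.25)          # 10 x 10 m, origin (0,10)
  pts <- data.frame(x = c(5, 5.2), y = c(5, 5.5), heading = c(0, 0))
  out <- extract_buffer_means(list(mean_ndvi = g), pts, width = 4, along = 1)
  expect_equal(out$mean_ndvi, c(0.7, 0.7))

  # 0/1 half-plane split at x = 5: mean 0.5 within one pixel-column
  v <- matrix(0, 40, 40); v[, 21:40] <- 1
  ghalf <- ndvi_grid(v, pixel_size = 0.25, origin = c(0, 10))
  outh <- extract_buffer_means(list(m = ghalf),
                               data.frame(x = 5, y = 5, heading = 0),
                               width = 4, along = 1)
  expect_lt(abs(outh$m - 0.5), 1 / 16 + 1e-9)
})

test_that("points whose footprints miss the raster are dropped and logged", {
  g <- const_grid(0.7, 40, 40, ps = 0.25)
  pts <- data.frame(x = c(5, 50), y = c(5, 5), heading = c(0, 0))
  expect_message(
    out <- extract_buffer_means(list(m = g), pts, width = 4, along = 1),
    "dropped")
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "dropped"), 2L)
})

test_that("footprint means are linear: the sum grid equals the summed means", {
  fs <- field_spec(c(64, 64), 0.5, dates = c(1, 2),
                   marginals = list(c(5, 5), c(8, 3)),
                   spectral_exponent = 2, seed = 3)
  st <- synthesize_season(fs)
  sums <- sum_stack(st)
  pts <- data.frame(x = c(10, 16, 22), y = c(10, 16, 22), heading = 90)
  a <- extract_buffer_means(st, pts, width = 4, along = 1)
  b <- extract_buffer_means(list(s = sums), pts, width = 4, along = 1)
  expect_equal(nrow(a), 3)
  expect_lt(max(abs(a$ndvi_1 + a$ndvi_2 - b$s)), 1e-9)
})

test_that("all-subsets selection finds an exact model and normalizes weights", {
  set.seed(51)
  x1 <- runif(200); x2 <- runif(200)
  y <- 2 * x1
  sel <- all_subsets_lm(y, cbind(x1 = x1, x2 = x2))
  expect_equal(sel$models$model[1], "x1")
  expect_lt(abs(sel$coefficients[["x1"]][["x1"]] - 2), 1e-8)
  expect_equal(sel$models$r_squared[1], 1)
  expect_lt(abs(sum(sel$models$weight) - 1), 1e-9)
  expect_equal(sel$models$delta_aic[1], 0)
  # intercept-only candidate is present with zero R2
  i0 <- sel$models$model == "(intercept only)"
  expect_true(any(i0))
  expect_equal(sel$models$r_squared[i0], 0)
})

test_that("AIC ranking is invariant to affine predictor rescaling", {
  set.seed(52)
  X <- cbind(a = runif(300), b = runif(300), c = runif(300))
  y <- 1 + X[, "a"] - 2 * X[, "b"] + rnorm(300, 0, 0.3)
  s1 <- all_subsets_lm(y, X)
  X2 <- X; X2[, "a"] <- 100 * X2[, "a"] - 7; X2[, "c"] <- X2[, "c"] / 50
  s2 <- all_subsets_lm(y, X2)
  expect_equal(s1$models$model, s2$models$model)
  expect_equal(s1$models$aic, s2$models$aic, tolerance = 1e-8)
})

test_that("exclusive predictor groups and rank deficiency are enforced", {
  set.seed(53)
  x1 <- runif(100); x2 <- runif(100); s <- x1 + x2
  y <- s + rnorm(100, 0, 0.1)
  sel <- all_subsets_lm(y, cbind(x1 = x1, x2 = x2, s = s),
                        exclusive = list(s = c("x1", "x2")))
  expect_false(any(grepl("s", sel$models$model) & grepl("x", sel$models$model)))
  # a duplicated predictor makes some subsets rank-deficient
  expect_message(
    sel2 <- all_subsets_lm(y, cbind(x1 = x1, x1b = x1)),
    "rank-deficient")
  expect_false(any(sel2$models$model == "x1 + x1b"))
})

test_that("single-predictor regressions recover exact and null relationships", {
  set.seed(54)
  x <- runif(50); tab <- data.frame(p1 = x, p2 = runif(50), y = 3 * x - 1)
  r <- suppressWarnings(per_date_regressions(tab, "y", c("p1", "p2")))
  expect_equal(r$r_squared[1], 1)
  expect_lt(r$p_value[1], 1e-10)
  expect_equal(r$slope[1], 3)
  # standardized data: slope equals the correlation coefficient
  zs <- function(v) (v - mean(v)) / sd(v)
  tab2 <- data.frame(x = zs(runif(80)))
  tab2$y <- zs(0.6 * tab2$x + rnorm(80, 0, 0.5))
  r2 <- per_date_regressions(tab2, "y", "x")
  expect_equal(r2$slope, cor(tab2$x, tab2$y), tolerance = 1e-12)
  expect_error(per_date_regressions(data.frame(x = rep(1, 20), y = runif(20)),
                                    "y", "x"), "degenerate")
})
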