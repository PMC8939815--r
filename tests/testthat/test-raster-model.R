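test_that("ASCII grid round-trip preserves values, mask and geometry exactly", {
  set.seed(3)
  v <- matrix(runif(35), 5, 7)
  v[c(2, 9, 33)] <- NA
  g <- ndvi_grid(v, pixel_size = 0.1343, origin = c(1234.56789, 987.654321),
                 date = 140)
  p <- withr::local_tempfile(fileext = ".asc")
  write_grid(g, p)
  g2 <- read_grid(p, date = 140)
  expect_identical(g2$values, g$values)
  expect_identical(valid_mask(g2), valid_mask(g))
  expect_equal(g2$pixel_size, g$pixel_size, tolerance = 0)
  expect_lt(max(abs(g2$origin - g$origin)), 1e-9)
})

test_that("nodata cells are masked on read and written back as nodata", {
  g <- ndvi_grid(matrix(c(0.5, 0.5, 0.5, NA), 2, 2), pixel_size = 1)
  p <- withr::local_tempfile(fileext = ".asc")
  write_grid(g, p)
  g2 <- read_grid(p)
  expect_equal(sum(valid_mask(g2)), 3)
  expect_equal(mean(grid_values(g2)), 0.5)

  all_na <- ndvi_grid(matrix(NA_real_, 3, 3), pixel_size = 2)
  write_grid(all_na, p)
  expect_equal(sum(valid_mask(read_grid(p))), 0)
})

test_that("value-range policing clamps small overshoots and rejects large ones", {
  expect_warning(
    g <- ndvi_grid(matrix(c(1.005, 0.5, 0.5, -0.004), 2, 2), pixel_size = 1),
    "clamped")
  expect_true(all(grid_values(g) >= 0 & grid_values(g) <= 1))
  expect_error(ndvi_grid(matrix(c(1.5, 0.5, 0.5, 0.5), 2, 2), pixel_size = 1),
               "outside")
  expect_error(ndvi_grid(matrix(0.5, 2, 2), pixel_size = -1), "pixel_size")
})

test_that("resampling to the coarsest grid passes shared geometry through", {
  st <- const_stack(c(0.4, 0.6), c(10, 20))
  out <- resample_to_coarsest(st$grids)
  expect_identical(out$grids[[1]]$values, st$grids[[1]]$values)
  expect_identical(out$grids[[2]]$values, st$grids[[2]]$values)
})

test_that("area-weighted resampling preserves constants and averages sub-pixels", {
  # constant fine grid onto an unaligned coarser grid stays constant
  fine <- ndvi_grid(matrix(0.7, 60, 60), pixel_size = 0.11,
                    origin = c(0, 6.6), date = 1)
  coarse <- ndvi_grid(matrix(0.2, 40, 40), pixel_size = 0.1343,
                      origin = c(0, 5.372), date = 2)
  out <- resample_to_coarsest(list(fine, coarse))
  expect_equal(out$grids[[1]]$pixel_size, 0.1343)
  expect_true(all(abs(grid_values(out$grids[[1]]) - 0.7) < 1e-12))

  # hand-computed area weights: 2x2 metre-pixels onto one 2 m cell
  fine2 <- ndvi_grid(matrix(c(0, 1, 0, 1), 2, 2), pixel_size = 1,
                     origin = c(0, 2), date = 1)
  coarse2 <- ndvi_grid(matrix(0.5, 1, 1), pixel_size = 2,
                       origin = c(0, 2), date = 2)
  out2 <- resample_to_coarsest(list(fine2, coarse2))
  expect_equal(out2$grids[[1]]$values[1, 1], 0.5)
})

test_that("resampling conserves the global mean of a fully-valid grid", {
  set.seed(9)
  fine <- ndvi_grid(matrix(runif(64 * 64), 64, 64), pixel_size = 0.5,
                    origin = c(0, 32), date = 1)
  coarse <- ndvi_grid(matrix(0.5, 32, 32), pixel_size = 1,
                      origin = c(0, 32), date = 2)
  out <- resample_to_coarsest(list(fine, coarse))
  expect_lt(abs(mean(grid_values(out$grids[[1]])) - mean(grid_values(fine))),
            1e-9)
})

test_that("disjoint extents are rejected", {
  a <- ndvi_grid(matrix(0.5, 4, 4), pixel_size = 1, origin = c(0, 4), date = 1)
  b <- ndvi_grid(matrix(0.5, 4, 4), pixel_size = 2, origin = c(100, 4), date = 2)
  expect_error(resample_to_coarsest(list(a, b)), "intersection")
})

test_that("daily interpolation is piecewise-linear through the observations", {
  st <- const_stack(c(0.9, 0.8), c(0, 10))
  d <- interpolate_daily(st)
  expect_equal(length(d), 11)
  expect_equal(d$grids[[6]]$values[1, 1], 0.85)     # day 5 midpoint
  expect_identical(d$grids[[1]]$values, st$grids[[1]]$values)  # endpoints exact
  expect_identical(d$grids[[11]]$values, st$grids[[2]]$values)

  st3 <- const_stack(c(0.2, 0.8, 0.2), c(0, 10, 30))
  d3 <- interpolate_daily(st3)
  expect_equal(d3$grids[[21]]$values[1, 1], 0.5)    # day 20 on second segment

  expect_error(interpolate_daily(const_stack(0.5, 5)), "two dates")
})

test_that("pixels missing on any date stay missing on all interpolated days", {
  v1 <- matrix(0.5, 4, 4); v2 <- matrix(0.7, 4, 4)
  v2[2, 3] <- NA
  st <- grid_stack(list(ndvi_grid(v1, 1, date = 0), ndvi_grid(v2, 1, date = 4)))
  d <- interpolate_daily(st)
  expect_true(all(vapply(d$grids, function(g) is.na(g$values[2, 3]), logical(1))))
})

test_that("stack summation matches hand arithmetic and is linear", {
  st <- const_stack(c(0.5, 0.5, 0.5, 0.5), c(1, 2, 3, 4))
  expect_equal(sum_stack(st)$values[1, 1], 2.0)

  st2 <- const_stack(c(0.9, 0.8), c(0, 10))
  daily_sum <- sum_stack(interpolate_daily(st2))
  expect_equal(daily_sum$values[1, 1], 9.35)        # 0.9 + 0.89 + ... + 0.8

  one <- grid_stack(list(const_grid(0.37, date = 1)))
  expect_equal(sum_stack(one)$values, const_grid(0.37)$values)

  # linearity: scaling every date scales the sum
  half <- const_stack(c(0.45, 0.4), c(0, 10))
  expect_equal(sum_stack(half)$values, 0.5 * sum_stack(st2)$values)
})
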