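test_that("synthesis is bit-deterministic given a seed", {
  g1 <- synthesize_grid(c(32, 32), 0.25, b = 2, marginal = c(5, 5), seed = 7)
  g2 <- synthesize_grid(c(32, 32), 0.25, b = 2, marginal = c(5, 5), seed = 7)
  expect_identical(g1$values, g2$values)

  fs <- wheat_season_spec(shape = c(32, 32), seed = 11)
  s1 <- synthesize_season(fs); s2 <- synthesize_season(fs)
  for (i in seq_along(s1$grids))
    expect_identical(s1$grids[[i]]$values, s2$grids[[i]]$values)
})

test_that("the marginal transform delivers the requested Beta distribution", {
  g <- synthesize_grid(c(512, 512), 0.1, b = 0, marginal = c(1, 1), seed = 5)
  x <- sort(grid_values(g))
  n <- length(x)
  ks <- max(abs(x - (seq_len(n) - 0.5) / n)) + 0.5 / n  # sup |ecdf - uniform|
  expect_lt(ks, 0.01)

  g2 <- synthesize_grid(c(512, 512), 0.1, b = 2, marginal = c(20, 2), seed = 5)
  expect_lt(abs(mean(grid_values(g2)) - 20 / 22), 0.005)
})

test_that("Beta MLE recovers the marginal of a synthesized field within 5%", {
  g <- synthesize_grid(c(512, 512), 0.1, b = 2.5, marginal = c(8, 3), seed = 2)
  fit <- fit_beta_mle(grid_values(g))
  expect_lt(abs(fit[["alpha"]] - 8) / 8, 0.05)
  expect_lt(abs(fit[["beta"]] - 3) / 3, 0.05)
})

test_that("fitted spectral exponent matches the requested one", {
  g <- synthesize_grid(c(512, 512), 0.05, b = 2.3, marginal = c(5, 5), seed = 3)
  sp <- radial_psd(g, taper = FALSE)
  dk <- attr(sp, "delta_k"); nyq <- 1 / (2 * 0.05)
  f <- fit_power_law(sp, c(2 * dk, nyq / 2))
  expect_lt(abs(f$b - (-2.3)), 0.15)
})

test_that("cross-date coherence spans rank-identical to independent", {
  base <- list(shape = c(512, 512), pixel_size = 0.1, dates = c(1, 2),
               marginals = list(c(5, 5), c(8, 3)), spectral_exponent = 2)
  co1 <- synthesize_season(do.call(field_spec, c(base, coherence = 1, seed = 4)))
  r1 <- rank(co1$grids[[1]]$values); r2 <- rank(co1$grids[[2]]$values)
  expect_equal(cor(r1, r2), 1)

  # independence bound at the white-noise exponent, where the Spearman
  # sampling distribution concentrates at the 1/sqrt(n) rate; a red spectrum
  # shrinks the effective sample size, so it gets a looser sanity bound
  base0 <- base; base0$spectral_exponent <- 0
  co0 <- synthesize_season(do.call(field_spec, c(base0, coherence = 0, seed = 4)))
  rho0 <- cor(rank(co0$grids[[1]]$values), rank(co0$grids[[2]]$values))
  expect_lt(abs(rho0), 0.02)

  cor2 <- synthesize_season(do.call(field_spec, c(base, coherence = 0, seed = 4)))
  rho2 <- cor(rank(cor2$grids[[1]]$values), rank(cor2$grids[[2]]$values))
  expect_lt(abs(rho2), 0.1)
})

test_that("harvester simulation honors the stated linear model", {
  fs <- field_spec(c(128, 128), 0.5, dates = c(1, 2),
                   marginals = list(c(5, 5), c(8, 3)),
                   spectral_exponent = 2, coherence = 0.5, seed = 6)
  st <- synthesize_season(fs)

  # intercept-only, no noise: every record equals the intercept
  hs0 <- harvest_spec(yield_coefficients = c(1500, 0, 0),
                      gpc_coefficients = c(12, 0, 0), seed = 1)
  h0 <- synthesize_harvest(st, hs0)
  expect_true(all(h0$yield == 1500))
  expect_true(all(h0$gpc == 12))

  # noiseless single-coefficient model is recovered exactly by OLS
  hs1 <- harvest_spec(yield_coefficients = c(100, 250, 0),
                      gpc_coefficients = c(0, 0, 30), seed = 1)
  h1 <- synthesize_harvest(st, hs1)
  f <- lm(yield ~ ndvi_1 + ndvi_2, data = h1)
  expect_lt(abs(coef(f)[["ndvi_1"]] - 250), 1e-8)
  expect_lt(abs(coef(f)[["ndvi_2"]] - 0), 1e-8)
  expect_lt(abs(coef(f)[["(Intercept)"]] - 100), 1e-8)

  # noise calibrated to a target R2 lands near it
  hs2 <- harvest_spec(yield_coefficients = c(0, 400, 300),
                      gpc_coefficients = c(10, 0, 0),
                      target_r2_yield = 0.4, seed = 9)
  h2 <- synthesize_harvest(st, hs2)
  f2 <- summary(lm(yield ~ ndvi_1 + ndvi_2, data = h2))
  expect_gt(f2$r.squared, 0.3)
  expect_lt(f2$r.squared, 0.5)
})

test_that("a field too narrow for one harvester track is rejected", {
  fs <- field_spec(c(64, 16), 0.5, dates = c(1, 2),
                   marginals = list(c(5, 5), c(5, 5)),
                   spectral_exponent = 2, seed = 1)
  st <- synthesize_season(fs)  # 8 m wide < 12 m swath
  hs <- harvest_spec(yield_coefficients = c(0, 0, 0),
                     gpc_coefficients = c(0, 0, 0))
  expect_error(synthesize_harvest(st, hs), "too narrow")
})

test_that("moment matching inverts the Beta mean/sd relationship", {
  p <- beta_from_moments(0.91, 0.014)
  expect_equal(unname(p[1] / sum(p)), 0.91)
  expect_equal(unname(sqrt(prod(p) / (sum(p)^2 * (sum(p) + 1)))), 0.014)
  expect_error(beta_from_moments(0.5, 0.6), "sd")
})
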