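test_that("empirical variogram implements the Matheron estimator", {
  # constant field: gamma = 0 at all lags
  const <- data.frame(x_m = runif(20, 0, 100), y_m = runif(20, 0, 100),
                      vwc = 0.4)
  ev <- empirical_variogram(const)
  expect_true(all(ev$gamma == 0))

  # two cores, value difference d at distance h: one bin, gamma = d^2 / 2
  two <- data.frame(x_m = c(0, 30), y_m = c(0, 40), vwc = c(0.2, 0.5))
  ev2 <- empirical_variogram(two, n_bins = 1, max_lag = 60)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$gamma, 0.3^2 / 2)
  expect_equal(ev2$n_pairs, 1L)

  expect_error(empirical_variogram(two, max_lag = 0), "positive")
  expect_error(empirical_variogram(two[1, ]), "two cores")
})

test_that("variogram fitting recovers known parameters and fixed points", {
  truth <- list(model = "spherical", nugget = 0.05, psill = 0.4, range = 120)
  lags <- seq(10, 300, by = 20)
  tab <- data.frame(lag = lags, gamma = vgm_gamma(truth, lags),
                    n_pairs = 200L)
  fit <- fit_variogram(tab, "spherical")
  expect_equal(fit$nugget, truth$nugget, tolerance = 0.05)
  expect_equal(fit$psill, truth$psill, tolerance = 0.05)
  expect_equal(fit$range, truth$range, tolerance = 0.05)

  # refit on the model's own curve: identical parameters (fixed point)
  tab2 <- data.frame(lag = lags, gamma = vgm_gamma(fit, lags), n_pairs = 200L)
  fit2 <- fit_variogram(tab2, "spherical")
  expect_equal(fit2$range, fit$range, tolerance = 1e-3)

  # exponential family round trip
  truth_e <- list(model = "exponential", nugget = 0, psill = 0.3, range = 80)
  tab_e <- data.frame(lag = lags, gamma = vgm_gamma(truth_e, lags),
                      n_pairs = 100L)
  fit_e <- fit_variogram(tab_e, "exponential")
  expect_equal(fit_e$psill, 0.3, tolerance = 0.03)
  expect_equal(fit_e$range, 80, tolerance = 8)

  # flat table: ~zero sill with a warning
  flat <- data.frame(lag = lags, gamma = 0, n_pairs = 50L)
  expect_warning(fit_f <- fit_variogram(flat, "spherical"), "flat|sill")
  expect_lt(fit_f$psill, 1e-6)
  expect_error(fit_variogram(tab[1:2, ]), "three")
})

test_that("variogram recovery from simulated cores is within 20%", {
  # self-consistency at ~500 cores from a field with known covariance
  cfg <- sim_config(grid_nx = 23, grid_ny = 22, vario_range = 100,
                    vario_sill = 1, vario_nugget = 0, seed = 31)
  m <- gen_moisture_surface(cfg, seed = 31, rescale = FALSE)
  xy <- subplot_centers(23, 22)
  cores <- data.frame(x_m = xy[, 1], y_m = xy[, 2], vwc = as.vector(m$values))
  fit <- fit_variogram(empirical_variogram(cores, n_bins = 14), "exponential")
  expect_equal(fit$psill + fit$nugget, 1, tolerance = 0.35)
  expect_equal(fit$range, 100, tolerance = 40)
})

test_that("ordinary kriging honours unbiasedness and exactness", {
  vg <- list(model = "exponential", nugget = 0, psill = 0.3, range = 80)
  set.seed(21)
  cores <- data.frame(x_m = runif(40, 0, 200), y_m = runif(40, 0, 200),
                      vwc = runif(40, 0.1, 0.6))
  targets <- cbind(runif(30, 0, 200), runif(30, 0, 200))
  kr <- ordinary_krige(cores, vg, targets)
  expect_true(all(abs(colSums(kr$weights) - 1) < 1e-9))

  # nugget = 0: exact interpolation at every core location
  kr_at <- ordinary_krige(cores, vg, cores[, c("x_m", "y_m")])
  expect_equal(kr_at$prediction, cores$vwc, tolerance = 1e-6)

  # single core: every prediction equals its value
  kr1 <- ordinary_krige(cores[1, ], vg, targets)
  expect_true(all(kr1$prediction == cores$vwc[1]))

  # two equidistant cores, symmetric target: prediction is their mean
  two <- data.frame(x_m = c(0, 100), y_m = c(0, 0), vwc = c(0.2, 0.6))
  kr2 <- ordinary_krige(two, vg, cbind(50, 40))
  expect_equal(kr2$prediction, 0.4, tolerance = 1e-9)

  # duplicate cores are averaged with a warning
  dup <- rbind(two, two[1, ])
  expect_warning(kr3 <- ordinary_krige(dup, vg, cbind(50, 40)), "duplicate")
  expect_equal(kr3$prediction, 0.4, tolerance = 1e-9)
})

test_that("torus translation enumerates shifts exhaustively", {
  a <- matrix(c(1, 2, 3, 5), 2)
  b <- matrix(c(2, 1, 4, 3), 2)
  got <- torus_correlation(a, b)
  expect_equal(got$n_shifts, 4)
  # hand enumeration of the 4 cyclic shifts
  shifts <- list(b,
                 b[c(2, 1), ],
                 b[, c(2, 1)],
                 b[c(2, 1), c(2, 1)])
  null_hand <- sapply(shifts, function(s) stats::cor(as.vector(a),
                                                     as.vector(s)))
  expect_equal(sort(got$null_r), sort(null_hand), tolerance = 1e-12)
  expect_equal(got$p, mean(abs(null_hand) >= abs(null_hand[1])))

  # identity map: r = 1 and p bounded below by 1/n_shifts
  self <- torus_correlation(a, a)
  expect_equal(self$r_obs, 1)
  expect_gte(self$p, 1 / self$n_shifts)

  # deterministic: repeated calls identical
  expect_identical(torus_correlation(a, b)$null_r, got$null_r)

  # reflections quadruple the shift count
  refl <- torus_correlation(a, b, mode = "translations+reflections")
  expect_equal(refl$n_shifts, 16)

  # missing cells travel with the map; constant maps error
  am <- a; am[1, 1] <- NA
  big_a <- matrix(rnorm(36), 6); big_b <- matrix(rnorm(36), 6)
  big_a[c(3, 7)] <- NA
  res <- torus_correlation(big_a, big_b)
  expect_true(is.finite(res$r_obs))
  expect_error(torus_correlation(matrix(1, 3, 3), big_b[1:3, 1:3]),
               "constant")
})

test_that("point-core gridding averages cores within subplots", {
  cores <- data.frame(x_m = c(5, 15, 25, 28), y_m = c(5, 5, 5, 8),
                      vwc = c(0.1, 0.3, 0.4, 0.6))
  g <- cores_to_grid(cores, nx = 2, ny = 1, cell = 20)
  expect_equal(g[1, 1], 0.2)   # two cores in subplot 1
  expect_equal(g[2, 1], 0.5)   # two cores in subplot 2
  g2 <- cores_to_grid(cores[1, ], nx = 2, ny = 2, cell = 20)
  expect_equal(sum(is.na(g2)), 3)
})
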