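d2r <- pi / 180

test_that("illumination factor reduces correctly in limiting geometries", {
  expect_equal(illumination_factor(0, 40 * d2r, 1.2), cos(40 * d2r))
  expect_equal(illumination_factor(35 * d2r, 35 * d2r, 0), 1)
  ## direct scalar formula
  a <- 30 * d2r; ts <- 45 * d2r; pt <- 60 * d2r
  expect_equal(illumination_factor(a, ts, pt),
               cos(a) * cos(ts) + sin(a) * sin(ts) * cos(pt))
})

## hillside geometry with varying slope/aspect for regression tests
hillside <- function(rows = 25, cols = 40, ts = 35, phi_s = 150) {
  slope <- matrix(25 * abs(sin(2 * pi * seq_len(cols) / 17)),
                  rows, cols, byrow = TRUE)
  aspect <- matrix((360 * (seq_len(rows) %% 19) / 19) %% 360, rows, cols)
  make_obs(rows, cols, tv = 5, phi_v = 90, ts = ts, phi_s = phi_s,
           slope = 0, aspect = 0) -> base
  observation_stack(base$sensor_zenith, base$sensor_azimuth,
                    base$solar_zenith, base$solar_azimuth, slope, aspect)
}

test_that("exact linear hillsides recover (a, b, C) to 1e-10", {
  obs <- hillside()
  cos_i <- illumination_factor(obs$slope * d2r, obs$solar_zenith * d2r,
                               relative_azimuth(obs$solar_azimuth,
                                                obs$aspect) * d2r)
  a_true <- c(0.10, 0.05, 0.20)
  b_true <- c(0.50, 0.30, 0.15)
  vals <- array(NA_real_, c(25, 40, 3))
  for (k in 1:3) vals[, , k] <- a_true[k] + b_true[k] * cos_i
  cube <- reflectance_cube(vals, wavelengths = c(500, 600, 700))
  fit <- fit_c_factor(cube, obs, min_sample = 100)
  expect_lt(max(abs(fit$a - a_true)), 1e-10)
  expect_lt(max(abs(fit$b - b_true)), 1e-10)
  expect_lt(max(abs(fit$c_factor - a_true / b_true)), 1e-10)
  expect_false(any(fit$degenerate))
})

test_that("constant bands are flagged degenerate and pass through", {
  obs <- hillside()
  cos_i <- illumination_factor(obs$slope * d2r, obs$solar_zenith * d2r,
                               relative_azimuth(obs$solar_azimuth,
                                                obs$aspect) * d2r)
  vals <- array(NA_real_, c(25, 40, 2))
  vals[, , 1] <- 0.1 + 0.5 * cos_i
  vals[, , 2] <- 0.3                    # no cos i dependence at all
  cube <- reflectance_cube(vals, wavelengths = c(500, 600))
  fit <- fit_c_factor(cube, obs, min_sample = 100)
  expect_false(fit$degenerate[1])
  expect_true(fit$degenerate[2])
  corrected <- apply_scs_c(cube, obs, fit)
  expect_identical(corrected$values[, , 2], cube$values[, , 2])
  expect_false(identical(corrected$values[, , 1], cube$values[, , 1]))
})

test_that("flat terrain correction is the identity for any C", {
  obs <- make_obs(10, 10, ts = 42, slope = 0)
  set.seed(5)
  vals <- array(runif(300, 0.05, 0.5), c(10, 10, 3))
  cube <- reflectance_cube(vals, wavelengths = c(500, 600, 700))
  for (C in c(0.05, 0.3, 2)) {
    fit <- structure(list(a = C * rep(0.5, 3), b = rep(0.5, 3),
                          c_factor = rep(C, 3),
                          degenerate = rep(FALSE, 3),
                          fit_sample_size = 100,
                          wavelengths = cube$header$wavelengths),
                     class = "topo_fit")
    out <- apply_scs_c(cube, obs, fit)
    expect_equal(out$values, cube$values, tolerance = 1e-15)
  }
})

test_that("single-pixel correction matches the hand-evaluated formula", {
  ## slope 30, solar zenith 40, sun-facing slope (phi_t = 0), C = 0.3
  obs <- make_obs(1, 1, ts = 40, phi_s = 100, slope = 30, aspect = 100)
  cube <- reflectance_cube(array(0.2, c(1, 1, 1)), wavelengths = 850)
  fit <- structure(list(a = 0.15, b = 0.5, c_factor = 0.3,
                        degenerate = FALSE, fit_sample_size = 10,
                        wavelengths = 850),
                   class = "topo_fit")
  out <- apply_scs_c(cube, obs, fit)
  cos_i <- cos(30 * d2r) * cos(40 * d2r) + sin(30 * d2r) * sin(40 * d2r)
  expected <- 0.2 * (cos(30 * d2r) * cos(40 * d2r) + 0.3) / (cos_i + 0.3)
  expect_equal(out$values[1, 1, 1], expected)
})

test_that("correction factor tends to 1 monotonically as C grows", {
  obs <- make_obs(1, 1, ts = 40, phi_s = 100, slope = 30, aspect = 100)
  cube <- reflectance_cube(array(0.2, c(1, 1, 1)), wavelengths = 850)
  outs <- vapply(10^(0:5), function(C) {
    fit <- structure(list(a = C, b = 1, c_factor = C, degenerate = FALSE,
                          fit_sample_size = 10, wavelengths = 850),
                     class = "topo_fit")
    apply_scs_c(cube, obs, fit)$values[1, 1, 1]
  }, 0)
  dev <- abs(outs - 0.2)
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[6], 1e-6)
})
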