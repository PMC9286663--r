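d2r <- pi / 180

## two-line group with constant NDVI and varying geometry
two_line_group <- function(rows1 = 60, rows2 = 20, cols = 60) {
  mk <- function(rows, x_ul) {
    vals <- array(0.2, c(rows, cols, 3))
    vals[, , 1] <- 0.1          # 660 nm
    vals[, , 2] <- 0.3          # 850 nm -> NDVI = 0.5 everywhere
    cube <- reflectance_cube(vals, wavelengths = c(660, 850, 1650),
                             map_info = list(x_ul = x_ul, y_ul = 0,
                                             pixel_size = 15))
    tv <- matrix(rep(seq(-17, 17, length.out = cols), each = rows),
                 rows, cols)
    obs <- observation_stack(abs(tv),
                             ifelse(tv < 0, 270, 90) * (tv * 0 + 1),
                             matrix(35, rows, cols),
                             matrix(160, rows, cols),
                             matrix(0, rows, cols),
                             matrix(0, rows, cols))
    list(cube = cube, obs = obs)
  }
  list(mk(rows1, 0), mk(rows2, 1e6))
}

test_that("stratified sampling is deterministic and respects exhaustion", {
  grp <- two_line_group()
  ndvi <- lapply(grp, function(l) compute_ndvi(l$cube))
  bins <- build_bins(unlist(ndvi), ndvi_bins("static", 3))
  s1 <- stratified_group_sample(grp, ndvi, bins, per_bin = 500, seed = 42)
  s2 <- stratified_group_sample(grp, ndvi, bins, per_bin = 500, seed = 42)
  expect_identical(s1$geometry, s2$geometry)
  expect_identical(s1$refl, s2$refl)
  s3 <- stratified_group_sample(grp, ndvi, bins, per_bin = 500, seed = 43)
  expect_false(identical(s1$geometry, s3$geometry))
  ## per_bin larger than the population: every eligible pixel, once
  s_all <- stratified_group_sample(grp, ndvi, bins, per_bin = 1e6,
                                   seed = 1)
  expect_equal(nrow(s_all$geometry), 60 * 60 + 20 * 60)
  expect_false(any(duplicated(
    s_all$geometry[c("line", "row", "col")])))
})

test_that("lines contribute in proportion to eligible area", {
  grp <- two_line_group(rows1 = 60, rows2 = 20)  # 3:1 pixel ratio
  ndvi <- lapply(grp, function(l) compute_ndvi(l$cube))
  bins <- build_bins(unlist(ndvi), ndvi_bins("static", 3))
  s <- stratified_group_sample(grp, ndvi, bins, per_bin = 1000, seed = 7)
  share <- mean(s$geometry$line == 1)
  ## binomial-style tolerance around 0.75 at n = 1000
  expect_lt(abs(share - 0.75), 0.06)
})

## hand-built sample set with a single bin and known geometry
manual_samples <- function(n, fiso, fgeo, fvol, seed = 3,
                           single_geometry = FALSE, sigma = 0) {
  set.seed(seed)
  if (single_geometry) {
    ts <- rep(35, n); tv <- rep(10, n); phi <- rep(90, n)
  } else {
    ts <- runif(n, 20, 50); tv <- runif(n, 0, 17); phi <- runif(n, 0, 180)
  }
  kg <- li_kernel(ts * d2r, tv * d2r, phi * d2r)
  kv <- ross_kernel(ts * d2r, tv * d2r, phi * d2r)
  refl <- sapply(seq_along(fiso), function(k)
    fiso[k] + fgeo[k] * kg + fvol[k] * kv + rnorm(n, sd = sigma))
  bins <- ndvi_bins("static", 1)
  bins$edges <- c(0.05, 1)
  bins$centers <- 0.525
  structure(list(
    geometry = data.frame(line = 1L, row = 1L, col = 1L, ndvi = 0.5,
                          bin = 1L, solar_zenith = ts, sensor_zenith = tv,
                          relative_azimuth = phi),
    refl = refl, seed = seed, bins = bins), class = "brdf_samples")
}

test_that("constant reflectance under varied geometry gives a pure isotropic fit", {
  s <- manual_samples(200, fiso = c(0.5, 0.5), fgeo = c(0, 0),
                      fvol = c(0, 0))
  fit <- fit_brdf_coefficients(s)
  expect_equal(unname(fit$coefficients[, 1, ]),
               matrix(c(0.5, 0.5, 0, 0, 0, 0), 2), tolerance = 1e-10)
})

test_that("noiseless forward samples recover their coefficients", {
  s <- manual_samples(200, fiso = c(0.3, 0.4), fgeo = c(0.01, 0.02),
                      fvol = c(0.1, 0.2))
  fit <- fit_brdf_coefficients(s)
  expect_lt(max(abs(fit$coefficients[1, 1, ] - c(0.3, 0.01, 0.1))), 1e-8)
  expect_lt(max(abs(fit$coefficients[2, 1, ] - c(0.4, 0.02, 0.2))), 1e-8)
})

test_that("a single observation geometry is rank-deficient", {
  s <- manual_samples(50, fiso = 0.3, fgeo = 0.01, fvol = 0.1,
                      single_geometry = TRUE)
  expect_error(fit_brdf_coefficients(s), "no bin")
})

test_that("modeled reflectance composes kernels and coefficients", {
  cf <- c(0.3, 0.05, 0.1)
  expect_equal(predict_brdf(0, 0, 0, cf), 0.3)
  expect_equal(predict_brdf(1, 1, 2, c(0.4, 0, 0)), 0.4)
  tv <- 20 * d2r; ts <- 30 * d2r; phi <- 90 * d2r
  expect_equal(predict_brdf(tv, ts, phi, cf),
               0.3 + 0.05 * oracle_li(ts, tv, phi) +
                 0.1 * oracle_ross(ts, tv, phi), tolerance = 1e-12)
})
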