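## Build a small fitted model directly so smoothing behaviour can be
## checked against hand-traced rules.
make_model <- function(coefficients, centers, counts = NULL,
                       smoothing = "linear_interpolation",
                       range = c(0.25, 0.85), lower = 0.05) {
  n_bins <- length(centers)
  bins <- ndvi_bins("static", n_bins, lower_mask = lower)
  bins$edges <- seq(lower, 1, length.out = n_bins + 1L)
  bins$centers <- centers
  if (is.null(counts)) counts <- rep(100L, n_bins)
  structure(list(coefficients = coefficients,
                 se = array(NA_real_, dim(coefficients)),
                 bin_counts = counts, fitted_bins = rep(TRUE, n_bins),
                 bins = bins, wavelengths = seq_len(dim(coefficients)[1]),
                 kernels = kernel_choice(), constants = kernel_constants(),
                 smoothing = smoothing, smoothing_range = range,
                 reference_zenith = NULL, solar_mode = "none",
                 per_bin = 100, seed = 1, topo_fits = NULL,
                 samples = NULL, call = NULL),
            class = "brdf_model")
}

centers6 <- c(0.129, 0.288, 0.446, 0.604, 0.763, 0.921)
cf6 <- array(NA_real_, c(2, 6, 3))
cf6[1, , ] <- cbind(0.2 + 0.05 * (1:6), 0.01 * (1:6), 0.02 * (6:1))
cf6[2, , ] <- cbind(0.4 - 0.02 * (1:6), 0.005 * (6:1), 0.03 * (1:6))

test_that("interpolation reproduces each in-range knot exactly", {
  m <- make_model(cf6, centers6)
  in_rng <- which(centers6 >= 0.25 & centers6 <= 0.85)
  got <- coefficients_at_ndvi(m, centers6[in_rng])
  for (i in seq_along(in_rng))
    expect_equal(unname(got[i, , ]), unname(cf6[, in_rng[i], ]))
})

test_that("regression and interpolation agree when knots are collinear", {
  cf_lin <- array(NA_real_, c(1, 6, 3))
  cf_lin[1, , ] <- cbind(0.1 + 0.3 * centers6, 0.02 - 0.01 * centers6,
                         0.05 + 0.1 * centers6)
  ## between the first and last in-range knot both modes trace the same
  ## straight line (interpolation extends as a constant outside the hull)
  knots <- centers6[centers6 >= 0.25 & centers6 <= 0.85]
  x <- seq(min(knots), max(knots), length.out = 40)
  mi <- make_model(cf_lin, centers6, smoothing = "linear_interpolation")
  mr <- make_model(cf_lin, centers6, smoothing = "linear_regression")
  mw <- make_model(cf_lin, centers6,
                   smoothing = "weighted_linear_regression",
                   counts = c(10L, 400L, 30L, 800L, 50L, 90L))
  expect_equal(coefficients_at_ndvi(mi, x), coefficients_at_ndvi(mr, x),
               tolerance = 1e-10)
  expect_equal(coefficients_at_ndvi(mi, x), coefficients_at_ndvi(mw, x),
               tolerance = 1e-10)
})

test_that("NDVI beyond the smoothing range extends as a constant", {
  m <- make_model(cf6, centers6)
  in_rng <- which(centers6 >= 0.25 & centers6 <= 0.85)
  hi <- max(in_rng)
  lo <- min(in_rng)
  expect_equal(unname(coefficients_at_ndvi(m, 0.95)[1, , ]),
               unname(cf6[, hi, ]))
  expect_equal(unname(coefficients_at_ndvi(m, 0.06)[1, , ]),
               unname(cf6[, lo, ]))
  ## regression mode clamps the abscissa to the smoothing range
  mr <- make_model(cf6, centers6, smoothing = "linear_regression")
  expect_equal(coefficients_at_ndvi(mr, 0.95),
               coefficients_at_ndvi(mr, 0.85))
})

test_that("weighted regression matches an lm oracle", {
  w <- c(10, 400, 30, 800, 50, 90)
  mw <- make_model(cf6, centers6,
                   smoothing = "weighted_linear_regression",
                   counts = as.integer(w))
  in_rng <- which(centers6 >= 0.25 & centers6 <= 0.85)
  x0 <- 0.5
  got <- coefficients_at_ndvi(mw, x0)[1, 1, ]
  for (k in 1:3) {
    fit <- lm(y ~ x, data.frame(x = centers6[in_rng],
                                y = cf6[1, in_rng, k]),
              weights = w[in_rng])
    expect_equal(unname(got[k]),
                 unname(predict(fit, data.frame(x = x0))),
                 tolerance = 1e-10, info = paste("coef", k))
  }
})

test_that("interpolated coefficients are continuous across bin edges", {
  m <- make_model(cf6, centers6)
  edges <- m$bins$edges
  inner <- edges[edges > 0.25 & edges < 0.85]
  eps <- 1e-9
  for (e in inner) {
    jump <- abs(coefficients_at_ndvi(m, e + eps) -
                  coefficients_at_ndvi(m, e - eps))
    expect_lt(max(jump), 1e-7)   # slope * 2e-9 plus rounding
  }
})

test_that("mode none returns bin constants and validates the mask", {
  m <- make_model(cf6, centers6, smoothing = "none")
  mid <- (m$bins$edges[3] + m$bins$edges[4]) / 2
  expect_equal(unname(coefficients_at_ndvi(m, mid)[1, , ]),
               unname(cf6[, 3, ]))
  expect_error(coefficients_at_ndvi(m, 0.01), "mask")
  ## unfit bins borrow the nearest fitted bin (bin 6 -> bin 5)
  m$fitted_bins[6] <- FALSE
  top <- (m$bins$edges[6] + m$bins$edges[7]) / 2
  got <- coefficients_at_ndvi(m, top)[1, , ]
  expect_equal(unname(got), unname(cf6[, 5, ]))
})
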