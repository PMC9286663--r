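test_that("full and empty overlaps are detected from map info", {
  h1 <- scene_header(10, 12, 2, c(500, 600),
                     map_info = list(x_ul = 0, y_ul = 0, pixel_size = 15))
  h2 <- scene_header(10, 12, 2, c(500, 600),
                     map_info = list(x_ul = 0, y_ul = 0, pixel_size = 15))
  full <- find_overlap(h1, h2)
  expect_equal(full$n_pairs, 120)
  expect_equal(full$pairs[, "row_a"], full$pairs[, "row_b"])
  h3 <- scene_header(10, 12, 2, c(500, 600),
                     map_info = list(x_ul = 1e6, y_ul = 0,
                                     pixel_size = 15))
  expect_equal(find_overlap(h1, h3)$n_pairs, 0)
})

test_that("partial overlap indices map the shared map coordinates", {
  h1 <- scene_header(8, 10, 1, 850,
                     map_info = list(x_ul = 0, y_ul = 0, pixel_size = 15))
  h2 <- scene_header(8, 10, 1, 850,
                     map_info = list(x_ul = 6 * 15, y_ul = 0,
                                     pixel_size = 15))
  ov <- find_overlap(h1, h2)
  expect_equal(ov$n_pairs, 8 * 4)
  expect_equal(sort(unique(ov$pairs[, "col_a"])), 7:10)
  expect_equal(sort(unique(ov$pairs[, "col_b"])), 1:4)
  expect_equal(ov$pairs[, "col_a"] - ov$pairs[, "col_b"],
               rep(6L, ov$n_pairs))
  ## generator bookkeeping: offsets determine the shared columns
  grp <- generate_group(synth_spec(rows = 10, cols = 20,
                                   overlap_fraction = 0.25, seed = 2))
  step <- grp$truth$offsets[2] - grp$truth$offsets[1]
  ov12 <- find_overlap(grp$lines[[1]]$cube$header,
                       grp$lines[[2]]$cube$header)
  expect_equal(ov12$n_pairs, 10 * (20 - step))
})

test_that("perfect agreement and constant offsets separate RMSE from MAD", {
  set.seed(31)
  vals <- array(runif(60, 0.1, 0.5), c(5, 6, 2))
  mi <- list(x_ul = 0, y_ul = 0, pixel_size = 15)
  a <- reflectance_cube(vals, wavelengths = c(500, 600), map_info = mi)
  b_same <- reflectance_cube(vals, wavelengths = c(500, 600),
                             map_info = mi)
  pair <- find_overlap(a$header, b_same$header)
  st <- overlap_statistics(a, b_same, pair)
  expect_equal(st$rmse, c(0, 0), tolerance = 1e-14)
  expect_equal(st$mad, c(0, 0), tolerance = 1e-14)
  expect_equal(st$slope, c(1, 1), tolerance = 1e-12)
  expect_equal(st$intercept, c(0, 0), tolerance = 1e-12)
  ## constant offset: MAD sees it, the regression absorbs it
  b_off <- reflectance_cube(vals + 0.01, wavelengths = c(500, 600),
                            map_info = mi)
  st2 <- overlap_statistics(a, b_off, pair)
  expect_equal(st2$mad, c(0.01, 0.01), tolerance = 1e-12)
  expect_equal(st2$rmse, c(0, 0), tolerance = 1e-12)
  expect_equal(st2$slope, c(1, 1), tolerance = 1e-10)
  expect_equal(st2$intercept, c(0.01, 0.01), tolerance = 1e-10)
})

test_that("statistics match explicit spreadsheet-style sums on 10 pairs", {
  x <- c(0.12, 0.18, 0.25, 0.31, 0.09, 0.42, 0.37, 0.21, 0.28, 0.15)
  y <- c(0.14, 0.17, 0.28, 0.30, 0.11, 0.45, 0.35, 0.24, 0.27, 0.18)
  a <- reflectance_cube(array(x, c(10, 1, 1)), wavelengths = 850,
                        map_info = list(x_ul = 0, y_ul = 0,
                                        pixel_size = 15))
  b <- reflectance_cube(array(y, c(10, 1, 1)), wavelengths = 850,
                        map_info = list(x_ul = 0, y_ul = 0,
                                        pixel_size = 15))
  st <- overlap_statistics(a, b, find_overlap(a$header, b$header))
  n <- 10
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  resid <- y - intercept - slope * x
  expect_equal(st$slope, slope, tolerance = 1e-12)
  expect_equal(st$intercept, intercept, tolerance = 1e-12)
  expect_equal(st$rmse, sqrt(mean(resid^2)), tolerance = 1e-12)
  expect_equal(st$mad, mean(abs(y - x)), tolerance = 1e-12)
  expect_equal(st$rmse_diff, sqrt(mean((y - x)^2)), tolerance = 1e-12)
  expect_equal(st$mad_resid, mean(abs(resid)), tolerance = 1e-12)
})

test_that("degenerate predictors fall back to difference metrics", {
  mi <- list(x_ul = 0, y_ul = 0, pixel_size = 15)
  a <- reflectance_cube(array(0.2, c(4, 2, 1)), wavelengths = 850,
                        map_info = mi)
  b <- reflectance_cube(array(0.25, c(4, 2, 1)), wavelengths = 850,
                        map_info = mi)
  st <- overlap_statistics(a, b, find_overlap(a$header, b$header))
  expect_true(st$degenerate_predictor)
  expect_true(is.na(st$slope))
  expect_equal(st$mad, 0.05)
})

test_that("MAD is symmetric under swapping lines; regression RMSE is not", {
  set.seed(77)
  vals_a <- array(runif(40, 0.1, 0.5), c(5, 4, 2))
  vals_b <- vals_a + array(rnorm(40, 0, 0.02), c(5, 4, 2))
  mi <- list(x_ul = 0, y_ul = 0, pixel_size = 15)
  a <- reflectance_cube(vals_a, wavelengths = c(500, 600), map_info = mi)
  b <- reflectance_cube(vals_b, wavelengths = c(500, 600), map_info = mi)
  pair <- find_overlap(a$header, b$header)
  ab <- overlap_statistics(a, b, pair)
  ba <- overlap_statistics(b, a, pair)
  expect_equal(ab$mad, ba$mad, tolerance = 1e-14)
  expect_false(isTRUE(all.equal(ab$rmse, ba$rmse)))
})

test_that("band subsets resolve to nearest bands within tolerance", {
  wl <- seq(400, 2500, by = 10)
  targets <- c(480, 560, 660, 850, 975, 1050, 1150, 1240, 1650, 2215)
  idx <- band_subset(wl, targets)
  expect_length(idx, 10)
  expect_true(all(abs(wl[idx] - targets) <= 5))
  expect_equal(band_subset(c(480, 850), c(480, 850)), c(1L, 2L))
  expect_error(band_subset(c(500, 600), 620.1), "within")
  expect_warning(band_subset(c(500, 600), c(595, 605)), "same band")
})

test_that("group assessment averages pairs and writes reports", {
  grp <- generate_group(synth_spec(rows = 12, cols = 24, seed = 6))
  cubes <- lapply(grp$lines, `[[`, "cube")
  rep <- assess_group(cubes)
  expect_s3_class(rep, "assessment_report")
  expect_equal(nrow(rep$group_mean), 10)
  ## duplicated identical line gives an all-zero pair
  rep0 <- assess_group(list(cubes[[1]], cubes[[1]]))
  expect_lt(max(rep0$group_mean$rmse), 1e-14)
  expect_lt(max(rep0$group_mean$mad), 1e-14)
  csv <- file.path(tempdir(), "assess.csv")
  js <- file.path(tempdir(), "assess.json")
  write_assessment_report(rep, csv, js)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), nrow(rep$per_pair) + nrow(rep$group_mean))
  expect_true(file.exists(js))
})
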