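## Synthetic flight-box generator: groups of overlapping flightlines
## forward-modeled from known BRDF coefficients on a shared "world"
## surface, with cross-track view-zenith sweeps, per-line solar geometry
## spanning a multi-hour window, optional sinusoidal terrain and additive
## Gaussian noise. Every downstream module is testable against the
## recorded truth.

.soil_veg_spectra <- function(wavelengths) {
  ## tabulated endmembers on the common assessment wavelengths,
  ## interpolated to arbitrary grids
  wl0 <- c(400, 480, 560, 660, 850, 975, 1050, 1150, 1240, 1650, 2215, 2500)
  soil0 <- c(0.06, 0.10, 0.14, 0.19, 0.26, 0.28, 0.30, 0.32, 0.33, 0.36,
             0.33, 0.30)
  veg0 <- c(0.03, 0.04, 0.09, 0.05, 0.45, 0.42, 0.43, 0.38, 0.40, 0.23,
            0.12, 0.08)
  list(soil = stats::approx(wl0, soil0, wavelengths, rule = 2)$y,
       veg = stats::approx(wl0, veg0, wavelengths, rule = 2)$y)
}

#' Synthetic flight-box specification
#'
#' Defaults emulate a small airborne flight box: overlapping narrow lines,
#' a +/- 17.5 degree cross-track view-zenith sweep, per-line solar zeniths
#' evenly spaced over 25-45 degrees (a multi-hour acquisition window), and
#' a smooth spatial NDVI field shared by all lines through a common world
#' grid.
#'
#' @param n_lines Number of flightlines (default 3).
#' @param rows,cols Per-line dimensions.
#' @param overlap_fraction Fraction of columns shared between adjacent
#'   lines, in \[0, 1) (default 0.3).
#' @param wavelengths Band grid in nm (default: the 10-band assessment
#'   subset, which brackets the NDVI bands at 660 and 850 nm).
#' @param view_zenith_max Cross-track sweep half-angle, degrees.
#' @param solar_zenith Per-line solar zeniths (degrees); default evenly
#'   spaced over 25-45 (35 for a single line).
#' @param solar_azimuth Per-line solar azimuths (degrees); default evenly
#'   spaced over 120-240.
#' @param terrain `"flat"` or `"hills"` (sinusoidal slope/aspect fields).
#' @param hills_max_slope Maximum terrain slope in degrees for `"hills"`.
#' @param truth `"binned"` (piecewise-constant coefficients per NDVI bin;
#'   the NDVI field is quantized to bin centers, giving exactly
#'   recoverable per-bin truth) or `"smooth"` (coefficients continuous in
#'   NDVI).
#' @param bins An [ndvi_bins()] used to discretize the truth when
#'   `truth = "binned"` (static edges are derived without data).
#' @param kernel_weight_scale Multiplier on the truth `f_geo`/`f_vol`
#'   kernel weights (default 1; 0 yields a purely isotropic, BRDF-free
#'   surface).
#' @param ndvi_range Range of the smooth spatial NDVI field (default
#'   `c(0.06, 0.99)`, a fully vegetated box; lower the first element below
#'   the bin spec's `lower_mask` to include non-vegetated cover that the
#'   correction must pass through unchanged).
#' @param noise_sigma Additive Gaussian noise, reflectance units.
#' @param seed Integer RNG seed.
#' @param pixel_size Metres (default 15, AVIRIS-Classic-like).
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(n_lines = 3, rows = 60, cols = 80,
                       overlap_fraction = 0.3,
                       wavelengths = c(480, 560, 660, 850, 975, 1050,
                                       1150, 1240, 1650, 2215),
                       view_zenith_max = 17.5,
                       solar_zenith = NULL, solar_azimuth = NULL,
                       terrain = c("flat", "hills"),
                       hills_max_slope = 20,
                       truth = c("binned", "smooth"),
                       bins = ndvi_bins("static", 18),
                       ndvi_range = c(0.06, 0.99),
                       kernel_weight_scale = 1,
                       noise_sigma = 0, seed = 1, pixel_size = 15) {
  terrain <- match.arg(terrain)
  truth <- match.arg(truth)
  n_lines <- as.integer(n_lines)
  stopifnot(n_lines >= 1, rows >= 2, cols >= 4,
            overlap_fraction >= 0, overlap_fraction < 1)
  if (is.null(solar_zenith))
    solar_zenith <- if (n_lines == 1) 35
                    else seq(25, 45, length.out = n_lines)
  if (is.null(solar_azimuth))
    solar_azimuth <- if (n_lines == 1) 180
                     else seq(120, 240, length.out = n_lines)
  stopifnot(length(solar_zenith) == n_lines,
            length(solar_azimuth) == n_lines)
  step <- max(1L, as.integer(round(cols * (1 - overlap_fraction))))
  if (n_lines > 1 && step >= cols)
    stop("synth_spec: overlap_fraction leaves no shared columns")
  structure(list(n_lines = n_lines, rows = as.integer(rows),
                 cols = as.integer(cols),
                 overlap_fraction = overlap_fraction, step = step,
                 wavelengths = wavelengths,
                 view_zenith_max = view_zenith_max,
                 solar_zenith = solar_zenith,
                 solar_azimuth = solar_azimuth,
                 terrain = terrain, hills_max_slope = hills_max_slope,
                 truth = truth, bins = bins, ndvi_range = ndvi_range,
                 kernel_weight_scale = kernel_weight_scale,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 pixel_size = pixel_size),
            class = "synth_spec")
}

## truth coefficient builders --------------------------------------------

## per-band kernel-weight ratios vary slowly across the spectrum so that
## no two bands share exactly the same directional shape
.band_ratio_mod <- function(nb) {
  if (nb == 1) return(list(g = 1, v = 1))
  u <- (seq_len(nb) - 1) / (nb - 1)
  list(g = 0.8 + 0.4 * u, v = 1.2 - 0.4 * u)
}

## coefficients at NDVI n (vectorized over n): list of three [length(n),
## nb] matrices. The two NDVI-defining bands share their kernel-weight
## ratios, which makes computed NDVI exactly invariant to the BRDF terms.
.truth_coefficients <- function(n, wavelengths, scale = 1) {
  nb <- length(wavelengths)
  sp <- .soil_veg_spectra(wavelengths)
  i_red <- which.min(abs(wavelengths - 665))
  i_nir <- which.min(abs(wavelengths - 850))
  fiso <- outer(1 - n, sp$soil) + outer(n, sp$veg)
  fiso[, i_red] <- 0.25 * (1 - n)
  fiso[, i_nir] <- 0.25 * (1 + n)
  ## kernel-weight ratios: with crown ratios b/r = 10, h/b = 2 the Li
  ## kernel reaches magnitudes near 10, so realistic f_geo/f_iso ratios
  ## are a few percent; f_vol/f_iso is O(0.1) and grows with canopy cover
  g_n <- 0.015 + 0.015 * n     # f_geo / f_iso
  v_n <- 0.30 + 0.40 * n       # f_vol / f_iso
  mod <- .band_ratio_mod(nb)
  gmat <- outer(g_n, mod$g)
  vmat <- outer(v_n, mod$v)
  gmat[, c(i_red, i_nir)] <- g_n   # shared ratio on the NDVI bands
  vmat[, c(i_red, i_nir)] <- v_n
  list(f_iso = fiso, f_geo = scale * fiso * gmat,
       f_vol = scale * fiso * vmat)
}

## world NDVI field: smooth diagonal waves spanning ndvi_range
.world_ndvi <- function(rows, world_cols, ndvi_range) {
  r <- matrix(seq_len(rows), rows, world_cols)
  c <- matrix(seq_len(world_cols), rows, world_cols, byrow = TRUE)
  u <- 0.5 + 0.5 * sin(2 * pi * (2 * c / world_cols + r / rows))
  ndvi_range[1] + diff(ndvi_range) * u
}

.world_terrain <- function(rows, world_cols, max_slope) {
  r <- matrix(seq_len(rows), rows, world_cols)
  c <- matrix(seq_len(world_cols), rows, world_cols, byrow = TRUE)
  slope <- max_slope * abs(sin(2 * pi * c / 50))
  aspect <- (360 * (0.5 + 0.5 * sin(2 * pi * r / 60))) %% 360
  list(slope = slope, aspect = aspect)
}

#' Generate a synthetic group of overlapping flightlines
#'
#' Per pixel: the NDVI field gives the truth coefficients; kernels are
#' evaluated for the pixel's geometry; reflectance is the kernel model,
#' optionally modulated by inverting the SCS+C correction with the truth C
#' factor on sloped terrain, plus additive Gaussian noise.
#'
#' @param spec A [synth_spec()].
#' @return List with `lines` (each a list of `cube` and `obs`) and
#'   `truth`: bin spec with edges, the truth coefficient array
#'   `[bands, bins, 3]` (binned mode), the world NDVI field, line column
#'   offsets, per-line solar geometry, the pooled mean solar zenith, the
#'   truth topographic C factors, and the seed.
#' @export
generate_group <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  nb <- length(spec$wavelengths)
  offsets <- (seq_len(spec$n_lines) - 1L) * spec$step
  world_cols <- offsets[spec$n_lines] + spec$cols
  ndvi_w <- .world_ndvi(spec$rows, world_cols, spec$ndvi_range)
  bins <- spec$bins
  if (spec$truth == "binned") {
    edges <- seq(bins$lower_mask, 1, length.out = bins$n_bins + 1L)
    bins$edges <- edges
    bins$centers <- (edges[-1] + edges[-length(edges)]) / 2
    b <- findInterval(ndvi_w, edges, rightmost.closed = TRUE)
    quant <- ndvi_w
    veg <- ndvi_w >= bins$lower_mask
    quant[veg] <- bins$centers[b[veg]]
    ndvi_w <- quant
    truth_cf <- .truth_coefficients(bins$centers, spec$wavelengths,
                                    spec$kernel_weight_scale)
    truth_arr <- array(NA_real_, c(nb, bins$n_bins, 3),
                       dimnames = list(NULL, NULL,
                                       c("f_iso", "f_geo", "f_vol")))
    truth_arr[, , 1] <- t(truth_cf$f_iso)
    truth_arr[, , 2] <- t(truth_cf$f_geo)
    truth_arr[, , 3] <- t(truth_cf$f_vol)
  } else {
    bins$edges <- NULL
    truth_arr <- NULL
  }
  terr <- if (spec$terrain == "hills")
    .world_terrain(spec$rows, world_cols, spec$hills_max_slope)
  else list(slope = matrix(0, spec$rows, world_cols),
            aspect = matrix(0, spec$rows, world_cols))
  ## truth topographic C per band (only exercised on sloped terrain)
  c_truth <- 0.2 + 0.6 * (seq_len(nb) - 1) / max(1, nb - 1)
  d2r <- pi / 180
  lines <- vector("list", spec$n_lines)
  for (i in seq_len(spec$n_lines)) {
    wc <- offsets[i] + seq_len(spec$cols)
    n_px <- spec$rows * spec$cols
    ndvi <- ndvi_w[, wc, drop = FALSE]
    slope <- terr$slope[, wc, drop = FALSE]
    aspect <- terr$aspect[, wc, drop = FALSE]
    c0 <- (spec$cols + 1) / 2
    j <- matrix(seq_len(spec$cols), spec$rows, spec$cols, byrow = TRUE)
    tv <- spec$view_zenith_max * abs(j - c0) / (c0 - 1)
    phi_v <- ifelse(j < c0, 270, 90)   # whiskbroom: azimuth flips at nadir
    ts <- matrix(spec$solar_zenith[i], spec$rows, spec$cols)
    phi_s <- matrix(spec$solar_azimuth[i], spec$rows, spec$cols)
    obs <- observation_stack(tv, phi_v, ts, phi_s, slope, aspect,
                             map_info = list(
                               x_ul = offsets[i] * spec$pixel_size,
                               y_ul = 0, pixel_size = spec$pixel_size))
    phi <- relative_azimuth(phi_s, phi_v) * d2r
    kg <- li_kernel(ts * d2r, tv * d2r, phi)
    kv <- ross_kernel(ts * d2r, tv * d2r, phi)
    cf <- .truth_coefficients(as.vector(ndvi), spec$wavelengths,
                              spec$kernel_weight_scale)
    vals <- array(NA_real_, c(spec$rows, spec$cols, nb))
    topo_factor <- NULL
    if (spec$terrain == "hills") {
      cos_i <- illumination_factor(
        slope * d2r, ts * d2r,
        relative_azimuth(phi_s, aspect) * d2r)
      scs <- cos(slope * d2r) * cos(ts * d2r)
    }
    for (k in seq_len(nb)) {
      rho <- cf$f_iso[, k] + cf$f_geo[, k] * as.vector(kg) +
        cf$f_vol[, k] * as.vector(kv)
      if (spec$terrain == "hills")
        rho <- rho * (as.vector(cos_i) + c_truth[k]) /
          (as.vector(scs) + c_truth[k])
      if (spec$noise_sigma > 0)
        rho <- rho + stats::rnorm(n_px, sd = spec$noise_sigma)
      vals[, , k] <- rho
    }
    hdr <- scene_header(spec$rows, spec$cols, nb, spec$wavelengths,
                        map_info = list(
                          x_ul = offsets[i] * spec$pixel_size,
                          y_ul = 0, pixel_size = spec$pixel_size))
    lines[[i]] <- list(
      cube = reflectance_cube(vals, header = hdr,
                              valid_mask = matrix(TRUE, spec$rows,
                                                  spec$cols)),
      obs = obs)
  }
  truth <- list(spec = spec, bins = bins, coefficients = truth_arr,
                ndvi_world = ndvi_w, offsets = offsets,
                solar_zenith = spec$solar_zenith,
                solar_azimuth = spec$solar_azimuth,
                pooled_solar_zenith = mean(spec$solar_zenith),
                c_truth = c_truth, wavelengths = spec$wavelengths,
                seed = spec$seed)
  list(lines = lines, truth = truth)
}

#' Compare fitted BRDF coefficients against generator truth
#'
#' Per band and bin, reports the absolute error of each fitted coefficient
#' against the truth evaluated at the model's bin centers, and (when the
#' model carries standard errors) whether each cell lies within
#' `3 * SE` of truth.
#'
#' @param truth The `truth` element of a [generate_group()] result.
#' @param model A [brdf_fit()] result on the same band grid.
#' @return List: `errors` array `[bands, bins, 3]`, `max_error`,
#'   `within_3se` logical array and `frac_within_3se` (fitted cells only).
#' @export
truth_report <- function(truth, model) {
  stopifnot(inherits(model, "brdf_model"))
  if (!isTRUE(all.equal(truth$wavelengths, model$wavelengths)))
    stop("truth_report: band grids differ")
  centers <- model$bins$centers
  scale <- truth$spec$kernel_weight_scale
  if (is.null(scale)) scale <- 1
  tc <- .truth_coefficients(centers, truth$wavelengths, scale)
  tr <- array(NA_real_, dim(model$coefficients),
              dimnames = dimnames(model$coefficients))
  tr[, , 1] <- t(tc$f_iso); tr[, , 2] <- t(tc$f_geo)
  tr[, , 3] <- t(tc$f_vol)
  err <- abs(model$coefficients - tr)
  err[, !model$fitted_bins, ] <- NA_real_
  within <- err <= 3 * model$se
  list(errors = err, max_error = max(err, na.rm = TRUE),
       within_3se = within,
       frac_within_3se = mean(within, na.rm = TRUE))
}
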