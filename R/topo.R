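## SCS+C topographic correction, applied per flightline before BRDF
## fitting. The empirical C factor comes from a per-band ordinary
## least-squares fit of reflectance on the illumination factor cos i.

#' Illumination factor cos i
#'
#' `cos i = cos a cos theta_s + sin a sin theta_s cos phi_t`, where `a` is
#' terrain slope and `phi_t` the sun-terrain relative azimuth.
#'
#' @param slope Terrain slope in radians, \[0, pi/2\].
#' @param theta_s Solar zenith in radians, \[0, pi/2).
#' @param phi_t Sun-terrain relative azimuth in radians.
#' @return cos i in \[-1, 1\], vectorized.
#' @export
illumination_factor <- function(slope, theta_s, phi_t) {
  cos(slope) * cos(theta_s) + sin(slope) * sin(theta_s) * cos(phi_t)
}

.cos_i_matrix <- function(obs) {
  d2r <- pi / 180
  phi_t <- relative_azimuth(obs$solar_azimuth, obs$aspect) * d2r
  illumination_factor(obs$slope * d2r, obs$solar_zenith * d2r, phi_t)
}

#' Fit the per-band SCS+C correction factor
#'
#' Ordinary least squares of reflectance on cos i over a seeded random
#' sample of valid, vegetated (NDVI >= `ndvi_min`) pixels; `C = a / b`
#' (intercept over slope). Bands whose slope magnitude falls below
#' `b_threshold` are flagged degenerate and pass through uncorrected.
#'
#' @param cube A [reflectance_cube()].
#' @param obs The co-registered [observation_stack()].
#' @param sample Optional integer vector of pixel indices (into the
#'   `[rows, cols]` grid) to fit on; drawn automatically when `NULL`.
#' @param min_sample Minimum fit sample size (default 1000).
#' @param max_sample Cap on the fit sample (default 50000; OLS on more
#'   pixels buys nothing).
#' @param b_threshold Degeneracy threshold on |b| in reflectance units.
#' @param ndvi_min NDVI cutoff for the fit population (default 0.05, the
#'   same mask applied before BRDF fitting).
#' @param seed RNG seed for the pixel sample.
#' @return Object of class `topo_fit`: per-band `a`, `b`, `c_factor`,
#'   logical `degenerate`, and `fit_sample_size`.
#' @export
fit_c_factor <- function(cube, obs, sample = NULL, min_sample = 1000,
                         max_sample = 50000, b_threshold = 1e-6,
                         ndvi_min = 0.05, seed = 1) {
  stopifnot(inherits(cube, "reflectance_cube"),
            inherits(obs, "observation_stack"))
  cos_i <- .cos_i_matrix(obs)
  if (is.null(sample)) {
    eligible <- which(cube$valid_mask & obs$valid_mask & is.finite(cos_i))
    ndvi <- try(compute_ndvi(cube), silent = TRUE)
    if (!inherits(ndvi, "try-error"))
      eligible <- eligible[!is.na(ndvi[eligible]) &
                             ndvi[eligible] >= ndvi_min]
    if (length(eligible) < min_sample)
      stop(sprintf(paste0("fit_c_factor: only %d eligible pixels,",
                          " need >= %d"), length(eligible), min_sample))
    if (length(eligible) > max_sample) {
      set.seed(seed)
      sample <- sort(sample(eligible, max_sample))
    } else sample <- eligible
  }
  ci <- cos_i[sample]
  if (stats::var(ci) <= 0)
    stop("fit_c_factor: cos i has no variance over the fit sample")
  nb <- cube$header$n_bands
  n_px <- prod(dim(cube$valid_mask))
  X <- cbind(1, ci)
  a <- b <- numeric(nb)
  for (k in seq_len(nb)) {
    r <- cube$values[sample + (k - 1L) * n_px]
    cf <- stats::.lm.fit(X, r)$coefficients
    a[k] <- cf[1]; b[k] <- cf[2]
  }
  degenerate <- abs(b) < b_threshold
  c_factor <- ifelse(degenerate, NA_real_, a / b)
  structure(list(a = a, b = b, c_factor = c_factor,
                 degenerate = degenerate,
                 fit_sample_size = length(sample),
                 wavelengths = cube$header$wavelengths),
            class = "topo_fit")
}

#' @export
print.topo_fit <- function(x, ...) {
  cat(sprintf("<topo_fit> %d bands, fit on %d pixels; %d degenerate\n",
              length(x$a), x$fit_sample_size, sum(x$degenerate)))
  invisible(x)
}

#' Apply the SCS+C topographic correction
#'
#' `R_t = R (cos a cos theta_s + C) / (cos i + C)` per band and pixel.
#' Degenerate bands pass through unchanged; pixels where the denominator
#' falls below 1e-8 in magnitude are masked (and counted in the
#' `"masked_denominators"` attribute).
#'
#' @param cube A [reflectance_cube()].
#' @param obs The co-registered [observation_stack()].
#' @param fit A [fit_c_factor()] result for the same band set.
#' @return A corrected [reflectance_cube()].
#' @export
apply_scs_c <- function(cube, obs, fit) {
  stopifnot(inherits(fit, "topo_fit"))
  nb <- cube$header$n_bands
  if (length(fit$a) != nb)
    stop("apply_scs_c: fit band count does not match cube")
  d2r <- pi / 180
  cos_i <- .cos_i_matrix(obs)
  scs <- cos(obs$slope * d2r) * cos(obs$solar_zenith * d2r)
  out <- cube$values
  mask <- cube$valid_mask & obs$valid_mask
  n_bad <- 0L
  for (k in seq_len(nb)) {
    if (fit$degenerate[k]) next
    C <- fit$c_factor[k]
    denom <- cos_i + C
    bad <- mask & abs(denom) < 1e-8
    n_bad <- n_bad + sum(bad)
    factor <- (scs + C) / denom
    sl <- out[, , k]
    apply_px <- mask & !bad
    sl[apply_px] <- sl[apply_px] * factor[apply_px]
    out[, , k] <- sl
    mask[bad] <- FALSE
  }
  if (n_bad > 0)
    warning(sprintf("apply_scs_c: %d pixel-bands masked (cos i + C ~ 0)",
                    n_bad))
  res <- reflectance_cube(out, header = cube$header, valid_mask = mask)
  attr(res, "masked_denominators") <- n_bad
  res
}
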