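## Core group-level BRDF engine: NDVI stratification, stratified sampling
## across the flight box, per-band per-bin least-squares inversion of the
## kernel model rho = f_iso + f_geo K_geo + f_vol K_vol, coefficient
## smoothing across NDVI bins, and application of the nadir /
## reference-solar-zenith correction.

#' Compute NDVI from a reflectance cube
#'
#' `(R_nir - R_red) / (R_nir + R_red)` using the band nearest each target
#' wavelength (850 and 665 nm by default); a band must lie within `tol` nm
#' of each target. Pixels with a non-positive band sum are returned as
#' `NA` (they cannot be meaningfully stratified).
#'
#' @param cube A [reflectance_cube()].
#' @param red,nir Target wavelengths in nm.
#' @param tol Maximum band-to-target distance in nm (default 20).
#' @return Matrix `[rows, cols]` of NDVI in \[-1, 1\], `NA` where masked.
#' @export
compute_ndvi <- function(cube, red = 665, nir = 850, tol = 20) {
  wl <- cube$header$wavelengths
  i_red <- which.min(abs(wl - red))
  i_nir <- which.min(abs(wl - nir))
  if (abs(wl[i_red] - red) > tol || abs(wl[i_nir] - nir) > tol)
    stop(sprintf(paste0("compute_ndvi: no band within %g nm of the",
                        " %g / %g nm targets"), tol, red, nir))
  r <- cube$values[, , i_red]
  n <- cube$values[, , i_nir]
  s <- n + r
  out <- (n - r) / s
  out[!cube$valid_mask | !is.finite(out) | s <= 0] <- NA_real_
  out
}

#' NDVI bin specification
#'
#' Static bins split `[lower_mask, 1]` into equal-width intervals; dynamic
#' bins place edges at equal-count quantiles of the pooled group NDVI
#' restricted to `(lower_mask, dynamic_upper)`, with the last bin extended
#' to 1. Pixels below `lower_mask` (water, bare ground, anomalies) are
#' excluded from fitting and pass through the correction unchanged.
#'
#' @param mode `"dynamic"` (default) or `"static"`.
#' @param n_bins Number of bins (18 recommended; 3 and 8 are common
#'   alternatives for static binning).
#' @param lower_mask NDVI mask threshold (default 0.05).
#' @param dynamic_upper Upper NDVI for dynamic edge placement (default 0.9).
#' @return Object of class `ndvi_bins` (without edges until
#'   [build_bins()] is applied).
#' @export
ndvi_bins <- function(mode = c("dynamic", "static"), n_bins = 18,
                      lower_mask = 0.05, dynamic_upper = 0.9) {
  mode <- match.arg(mode)
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L, lower_mask < dynamic_upper, dynamic_upper <= 1)
  structure(list(mode = mode, n_bins = n_bins, lower_mask = lower_mask,
                 dynamic_upper = dynamic_upper, edges = NULL,
                 centers = NULL),
            class = "ndvi_bins")
}

#' Derive bin edges (and smoothing knots) from pooled NDVI values
#'
#' @param ndvi_values Pooled NDVI sample from the whole group (values below
#'   `lower_mask` are dropped here).
#' @param spec An [ndvi_bins()].
#' @return The spec with `edges` (length `n_bins + 1`, first equals
#'   `lower_mask`, last is 1) and `centers` (edge midpoints for static
#'   bins; per-bin member medians for dynamic bins).
#' @export
build_bins <- function(ndvi_values, spec = ndvi_bins()) {
  stopifnot(inherits(spec, "ndvi_bins"))
  v <- ndvi_values[is.finite(ndvi_values) & ndvi_values >= spec$lower_mask]
  if (length(v) == 0)
    stop("build_bins: no NDVI values above the lower mask")
  if (spec$mode == "static") {
    edges <- seq(spec$lower_mask, 1, length.out = spec$n_bins + 1L)
    centers <- (edges[-1] + edges[-length(edges)]) / 2
  } else {
    w <- v[v < spec$dynamic_upper]
    if (length(unique(w)) < spec$n_bins)
      stop(sprintf(paste0("build_bins: only %d distinct NDVI values below",
                          " dynamic_upper; at most %d bins achievable"),
                   length(unique(w)), max(1L, length(unique(w)))))
    probs <- seq(0, 1, length.out = spec$n_bins + 1L)
    edges <- unname(stats::quantile(w, probs, type = 7))
    edges[1] <- spec$lower_mask
    edges[length(edges)] <- 1
    if (any(diff(edges) <= 0))
      stop(sprintf(paste0("build_bins: tied quantile edges; at most %d",
                          " bins achievable"),
                   sum(diff(unname(stats::quantile(w, probs))) > 0)))
    bin <- findInterval(v, edges, rightmost.closed = TRUE)
    centers <- vapply(seq_len(spec$n_bins), function(b) {
      m <- v[bin == b]
      if (length(m)) stats::median(m) else mean(edges[b + 0:1])
    }, 0)
  }
  spec$edges <- edges
  spec$centers <- centers
  spec
}

.bin_of <- function(ndvi, spec) {
  b <- findInterval(ndvi, spec$edges, rightmost.closed = TRUE)
  b[ndvi < spec$lower_mask | ndvi > 1] <- NA_integer_
  b
}

#' Stratified random sample across a flightline group
#'
#' Draws up to `per_bin` pixels per NDVI bin uniformly at random from the
#' pooled eligible pixels of all lines, so each line contributes in
#' proportion to its eligible area. Reproducible for a fixed seed; bins
#' with fewer pixels than `per_bin` contribute all of them.
#'
#' @param group List of lines, each a list with elements `cube`
#'   ([reflectance_cube()], normally topographically corrected) and `obs`
#'   ([observation_stack()]).
#' @param ndvi_list List of NDVI matrices, one per line (see
#'   [compute_ndvi()]).
#' @param bins An [ndvi_bins()] with edges (see [build_bins()]).
#' @param per_bin Sample cap per bin (default 10000).
#' @param seed Integer RNG seed.
#' @return Object of class `brdf_samples`: data frame `geometry` (line,
#'   row, col, ndvi, bin, solar/sensor zenith, relative azimuth, all
#'   degrees), reflectance matrix `refl` (samples x bands), the seed and
#'   the bin spec.
#' @export
stratified_group_sample <- function(group, ndvi_list, bins,
                                    per_bin = 10000, seed = 1) {
  stopifnot(length(group) >= 1, length(ndvi_list) == length(group),
            !is.null(bins$edges))
  pool <- vector("list", length(group))
  for (i in seq_along(group)) {
    cube <- group[[i]]$cube; obs <- group[[i]]$obs
    ndvi <- ndvi_list[[i]]
    ok <- cube$valid_mask & obs$valid_mask & !is.na(ndvi)
    idx <- which(ok)
    bin <- .bin_of(ndvi[idx], bins)
    keep <- !is.na(bin)
    pool[[i]] <- data.frame(line = i, idx = idx[keep],
                            ndvi = ndvi[idx][keep], bin = bin[keep])
  }
  pool <- do.call(rbind, pool)
  if (nrow(pool) == 0) stop("stratified_group_sample: no eligible pixels")
  set.seed(seed)
  picks <- lapply(seq_len(bins$n_bins), function(b) {
    rows <- which(pool$bin == b)
    if (length(rows) == 0) return(integer(0))
    if (length(rows) <= per_bin) rows else sort(sample(rows, per_bin))
  })
  sel <- pool[unlist(picks), , drop = FALSE]
  nb <- group[[1]]$cube$header$n_bands
  refl <- matrix(NA_real_, nrow(sel), nb)
  geom <- data.frame(line = sel$line, row = NA_integer_,
                     col = NA_integer_, ndvi = sel$ndvi, bin = sel$bin,
                     solar_zenith = NA_real_, sensor_zenith = NA_real_,
                     relative_azimuth = NA_real_)
  for (i in seq_along(group)) {
    rows <- which(sel$line == i)
    if (!length(rows)) next
    cube <- group[[i]]$cube; obs <- group[[i]]$obs
    idx <- sel$idx[rows]
    nr <- cube$header$n_rows
    n_px <- nr * cube$header$n_cols
    geom$row[rows] <- (idx - 1L) %% nr + 1L
    geom$col[rows] <- (idx - 1L) %/% nr + 1L
    geom$solar_zenith[rows] <- obs$solar_zenith[idx]
    geom$sensor_zenith[rows] <- obs$sensor_zenith[idx]
    geom$relative_azimuth[rows] <-
      relative_azimuth(obs$solar_azimuth[idx], obs$sensor_azimuth[idx])
    for (k in seq_len(nb))
      refl[rows, k] <- cube$values[idx + (k - 1L) * n_px]
  }
  structure(list(geometry = geom, refl = refl, seed = seed, bins = bins),
            class = "brdf_samples")
}

#' Fit per-band, per-bin BRDF coefficients by ordinary least squares
#'
#' For each NDVI bin, regresses the sampled (topographically corrected)
#' reflectance of every band on `[1, K_geo, K_vol]`. Bins with fewer than
#' `min_bin_size` samples or a rank-deficient kernel design are flagged
#' unfit; their coefficients are later supplied by smoothing (or the
#' nearest fitted bin).
#'
#' @param samples A [stratified_group_sample()] result.
#' @param choice A [kernel_choice()].
#' @param constants A [kernel_constants()].
#' @param min_bin_size Minimum samples per fitted bin (default 3).
#' @return List with `coefficients` and `se` arrays
#'   `[bands, bins, 3]` (`f_iso`, `f_geo`, `f_vol`), `bin_counts`, and
#'   logical `fitted` per bin.
#' @export
fit_brdf_coefficients <- function(samples, choice = kernel_choice(),
                                  constants = kernel_constants(),
                                  min_bin_size = 3L) {
  stopifnot(inherits(samples, "brdf_samples"))
  g <- samples$geometry
  d2r <- pi / 180
  kg <- li_kernel(g$solar_zenith * d2r, g$sensor_zenith * d2r,
                  g$relative_azimuth * d2r, choice$geometric, constants)
  kv <- ross_kernel(g$solar_zenith * d2r, g$sensor_zenith * d2r,
                    g$relative_azimuth * d2r, choice$volumetric)
  n_bins <- samples$bins$n_bins
  nb <- ncol(samples$refl)
  cf <- array(NA_real_, c(nb, n_bins, 3),
              dimnames = list(NULL, NULL, c("f_iso", "f_geo", "f_vol")))
  se <- cf
  counts <- integer(n_bins)
  fitted <- logical(n_bins)
  for (b in seq_len(n_bins)) {
    rows <- which(g$bin == b)
    counts[b] <- length(rows)
    if (length(rows) < min_bin_size) next
    X <- cbind(1, kg[rows], kv[rows])
    qx <- qr(X)
    if (qx$rank < 3L) next
    Y <- samples$refl[rows, , drop = FALSE]
    beta <- qr.coef(qx, Y)
    cf[, b, ] <- t(beta)
    if (length(rows) > 3L) {
      res <- Y - X %*% beta
      sigma2 <- colSums(res^2) / (length(rows) - 3L)
      xtxi <- chol2inv(qr.R(qx))
      se[, b, ] <- sqrt(outer(sigma2, diag(xtxi)))
    }
    fitted[b] <- TRUE
  }
  if (!any(fitted))
    stop("fit_brdf_coefficients: no bin could be fitted")
  list(coefficients = cf, se = se, bin_counts = counts, fitted = fitted)
}

#' Fit a group-level NDVI-stratified BRDF model
#'
#' The central fitting routine. Optionally applies the SCS+C topographic
#' correction per flightline, computes NDVI, derives bin edges from the
#' pooled group NDVI, draws a stratified random sample across all lines,
#' inverts the kernel model per band and bin, and resolves the reference
#' solar zenith angle.
#'
#' @param group List of lines, each a list with `cube` and `obs` (see
#'   [stratified_group_sample()]); a single `(cube, obs)` line may be
#'   passed directly.
#' @param bins An [ndvi_bins()] specification.
#' @param smoothing Coefficient smoothing across bins: `"none"`,
#'   `"linear_interpolation"` (default), `"linear_regression"` or
#'   `"weighted_linear_regression"`.
#' @param smoothing_range NDVI interval on which smoothing operates
#'   (default `c(0.25, 0.85)`); outside it the smoothed curve is extended
#'   as a constant.
#' @param kernels A [kernel_choice()].
#' @param constants A [kernel_constants()].
#' @param per_bin Stratified sample cap per bin.
#' @param seed Integer RNG seed (drives the topographic fit sample and the
#'   stratified sample).
#' @param topo Apply SCS+C per line before fitting (default `TRUE`).
#' @param topo_opts List of options for [fit_c_factor()].
#' @param solar_ref A [solar_reference()] (default: pooled observed mean).
#' @return Object of class `brdf_model`.
#' @seealso [apply_brdf_correction()], [coefficients_at_ndvi()],
#'   [predict.brdf_model()]
#' @export
brdf_fit <- function(group, bins = ndvi_bins(),
                     smoothing = c("linear_interpolation", "none",
                                   "linear_regression",
                                   "weighted_linear_regression"),
                     smoothing_range = c(0.25, 0.85),
                     kernels = kernel_choice(),
                     constants = kernel_constants(),
                     per_bin = 10000, seed = 1,
                     topo = TRUE, topo_opts = list(),
                     solar_ref = solar_reference("observed_mean")) {
  smoothing <- match.arg(smoothing)
  if (!is.null(group$cube)) group <- list(group)
  stopifnot(length(group) >= 1)
  topo_fits <- NULL
  if (topo) {
    topo_fits <- vector("list", length(group))
    if (is.null(topo_opts$seed)) topo_opts$seed <- seed
    for (i in seq_along(group)) {
      fit <- do.call(fit_c_factor,
                     c(list(cube = group[[i]]$cube, obs = group[[i]]$obs),
                       topo_opts))
      group[[i]]$cube <- apply_scs_c(group[[i]]$cube, group[[i]]$obs, fit)
      topo_fits[[i]] <- fit
    }
  }
  ndvi_list <- lapply(group, function(ln) compute_ndvi(ln$cube))
  pooled <- unlist(lapply(ndvi_list, function(m) m[is.finite(m)]))
  bins <- build_bins(pooled, bins)
  samples <- stratified_group_sample(group, ndvi_list, bins,
                                     per_bin = per_bin, seed = seed)
  fit <- fit_brdf_coefficients(samples, kernels, constants)
  ref <- resolve_reference_zenith(solar_ref,
                                  lapply(group, function(ln) ln$obs))
  structure(list(coefficients = fit$coefficients, se = fit$se,
                 bin_counts = fit$bin_counts, fitted_bins = fit$fitted,
                 bins = bins, wavelengths = group[[1]]$cube$header$wavelengths,
                 kernels = kernels, constants = constants,
                 smoothing = smoothing, smoothing_range = smoothing_range,
                 reference_zenith = ref, solar_mode = solar_ref$mode,
                 per_bin = per_bin, seed = seed,
                 topo_fits = topo_fits, samples = samples,
                 call = match.call()),
            class = "brdf_model")
}

#' Evaluate the (smoothed) BRDF coefficients at given NDVI values
#'
#' With `smoothing = "none"` the containing bin's constants are returned
#' (unfit bins borrow the nearest fitted bin). Interpolation is piecewise
#' linear in the bin-center NDVI restricted to the smoothing range, with
#' constant extension outside it; regression modes fit each coefficient as
#' a straight line in bin center over in-range bins (weighted by bin
#' counts for the weighted variant) and evaluate it at the NDVI clamped to
#' the smoothing range.
#'
#' @param model A [brdf_fit()] result.
#' @param ndvi Numeric vector, all `>= lower_mask` (mask pixels below the
#'   threshold before calling).
#' @return Array `[length(ndvi), bands, 3]`.
#' @export
coefficients_at_ndvi <- function(model, ndvi) {
  stopifnot(inherits(model, "brdf_model"))
  bins <- model$bins
  if (any(!is.finite(ndvi)) || any(ndvi < bins$lower_mask))
    stop("coefficients_at_ndvi: NDVI below the lower mask (or not ",
         "finite); mask such pixels before correction")
  cf <- model$coefficients
  nb <- dim(cf)[1]
  out <- array(NA_real_, c(length(ndvi), nb, 3),
               dimnames = list(NULL, NULL, dimnames(cf)[[3]]))
  fit_idx <- which(model$fitted_bins)
  centers <- bins$centers[fit_idx]
  if (model$smoothing == "none") {
    b <- .bin_of(pmin(ndvi, 1), bins)
    ## unfit bins borrow the nearest fitted bin (by center distance)
    remap <- vapply(seq_len(bins$n_bins), function(bb) {
      if (model$fitted_bins[bb]) bb
      else fit_idx[which.min(abs(bins$centers[fit_idx] -
                                   bins$centers[bb]))]
    }, 0L)
    b <- remap[b]
    for (k in 1:3) out[, , k] <- t(cf[, b, k])
    return(out)
  }
  rng <- model$smoothing_range
  in_rng <- which(centers >= rng[1] & centers <= rng[2])
  knots <- if (length(in_rng) >= 2) fit_idx[in_rng] else fit_idx
  kc <- bins$centers[knots]
  if (model$smoothing == "linear_interpolation") {
    if (length(knots) == 1L) {
      for (k in 1:3) out[, , k] <-
          matrix(cf[, knots, k], length(ndvi), nb, byrow = TRUE)
      return(out)
    }
    for (band in seq_len(nb)) for (k in 1:3)
      out[, band, k] <- stats::approx(kc, cf[band, knots, k],
                                      xout = ndvi, rule = 2)$y
    return(out)
  }
  ## linear regression variants
  x <- pmin(pmax(ndvi, rng[1]), rng[2])
  w <- if (model$smoothing == "weighted_linear_regression")
    model$bin_counts[knots] else rep(1, length(knots))
  X <- cbind(1, kc)
  for (band in seq_len(nb)) for (k in 1:3) {
    y <- cf[band, knots, k]
    cfs <- stats::lm.wfit(X, y, w)$coefficients
    out[, band, k] <- cfs[1] + cfs[2] * x
  }
  out
}

#' Modeled kernel reflectance
#'
#' `rho = f_iso + f_geo K_geo + f_vol K_vol` for arbitrary geometry.
#'
#' @param theta_v,theta_s View and solar zeniths in radians.
#' @param phi Relative azimuth in radians.
#' @param coefficients Either a length-3 vector `(f_iso, f_geo, f_vol)`, a
#'   `[bands, 3]` matrix (one geometry, all bands), or a
#'   `[n, bands, 3]` array with `n = length(theta_v)`.
#' @param choice A [kernel_choice()].
#' @param constants A [kernel_constants()].
#' @return Modeled reflectance: scalar/vector for vector coefficients, a
#'   `[n, bands]` matrix otherwise.
#' @export
predict_brdf <- function(theta_v, theta_s, phi, coefficients,
                         choice = kernel_choice(),
                         constants = kernel_constants()) {
  kg <- li_kernel(theta_s, theta_v, phi, choice$geometric, constants)
  kv <- ross_kernel(theta_s, theta_v, phi, choice$volumetric)
  if (is.null(dim(coefficients))) {
    stopifnot(length(coefficients) == 3L)
    return(coefficients[1] + coefficients[2] * kg + coefficients[3] * kv)
  }
  if (length(dim(coefficients)) == 2L) {
    return(outer(kg * 0 + 1, coefficients[, 1]) +
             outer(kg, coefficients[, 2]) + outer(kv, coefficients[, 3]))
  }
  d <- dim(coefficients)
  stopifnot(length(d) == 3L, d[1] == length(kg) || d[1] == 1L)
  out <- coefficients[, , 1, drop = FALSE] +
    coefficients[, , 2, drop = FALSE] * kg +
    coefficients[, , 3, drop = FALSE] * kv
  matrix(out, d[1], d[2])
}

#' Apply the BRDF correction to a flightline
#'
#' Multiplies each valid vegetated pixel (NDVI at or above the bin spec's
#' lower mask) by `rho(0, theta_ref, phi_n) / rho(theta_v, theta_s, phi)`
#' per band, where `theta_ref` is the model's reference solar zenith (or
#' the pixel's own solar zenith if the model has none). Pixels below the
#' NDVI mask keep their input reflectance.
#'
#' @param cube A (topographically corrected) [reflectance_cube()].
#' @param obs The co-registered [observation_stack()].
#' @param model A [brdf_fit()] result.
#' @param reference_zenith Degrees; overrides the model's stored value.
#'   Use `NULL` to correct each pixel to its own solar zenith.
#' @param phi_n Relative azimuth (degrees) of the nadir-modeled term; at
#'   nadir view both kernels are independent of azimuth, so this is
#'   arbitrary (default 0).
#' @param ndvi Optional precomputed NDVI matrix.
#' @return A corrected [reflectance_cube()]; the count of pixels masked by
#'   the near-zero-denominator guard is in attribute `"masked_model"`.
#' @export
apply_brdf_correction <- function(cube, obs, model,
                                  reference_zenith = model$reference_zenith,
                                  phi_n = 0, ndvi = NULL) {
  stopifnot(inherits(model, "brdf_model"))
  if (!isTRUE(all.equal(model$wavelengths, cube$header$wavelengths)))
    stop("apply_brdf_correction: cube wavelength grid does not match model")
  if (is.null(ndvi)) ndvi <- compute_ndvi(cube)
  mask <- cube$valid_mask & obs$valid_mask
  veg <- mask & !is.na(ndvi) & ndvi >= model$bins$lower_mask & ndvi <= 1
  out <- cube$values
  n_guard <- 0L
  if (any(veg)) {
    idx <- which(veg)
    d2r <- pi / 180
    tv <- obs$sensor_zenith[idx] * d2r
    ts <- obs$solar_zenith[idx] * d2r
    phi <- relative_azimuth(obs$solar_azimuth[idx],
                            obs$sensor_azimuth[idx]) * d2r
    ts_ref <- if (is.null(reference_zenith)) ts
              else rep(reference_zenith * d2r, length(idx))
    cf <- coefficients_at_ndvi(model, ndvi[idx])
    rho_obs <- predict_brdf(tv, ts, phi, cf, model$kernels, model$constants)
    rho_ref <- predict_brdf(rep(0, length(idx)), ts_ref,
                            rep(phi_n * d2r, length(idx)), cf,
                            model$kernels, model$constants)
    guard <- abs(rho_obs) < 1e-6
    ratio <- rho_ref / rho_obs
    ratio[guard] <- NA_real_
    n_guard <- sum(apply(guard, 1, any))
    n_px <- prod(dim(mask))
    for (k in seq_len(dim(cf)[2]))
      out[idx + (k - 1L) * n_px] <- out[idx + (k - 1L) * n_px] * ratio[, k]
    bad_px <- idx[apply(guard, 1, any)]
    mask[bad_px] <- FALSE
    if (n_guard > 0)
      warning(sprintf(paste0("apply_brdf_correction: %d pixels masked",
                             " (modeled reflectance ~ 0)"), n_guard))
  }
  res <- reflectance_cube(out, header = cube$header, valid_mask = mask)
  ## masked-out pixel-bands keep their values; only the mask records them
  attr(res, "masked_model") <- n_guard
  res
}

#' @export
print.brdf_model <- function(x, ...) {
  cat(sprintf("<brdf_model> %s / %s kernels, %d bands, %d NDVI bins (%s)\n",
              x$kernels$geometric, x$kernels$volumetric,
              dim(x$coefficients)[1], x$bins$n_bins, x$bins$mode))
  cat(sprintf("  smoothing: %s on [%.2f, %.2f]; reference solar zenith: %s\n",
              x$smoothing, x$smoothing_range[1], x$smoothing_range[2],
              if (is.null(x$reference_zenith)) "none (per-pixel)"
              else sprintf("%.2f deg (%s)", x$reference_zenith,
                           x$solar_mode)))
  cat(sprintf("  fitted bins: %d / %d; samples: %d (cap %d per bin)\n",
              sum(x$fitted_bins), x$bins$n_bins, sum(x$bin_counts),
              x$per_bin))
  invisible(x)
}

#' @export
summary.brdf_model <- function(object, ...) {
  res <- residuals(object)
  per_band <- if (is.null(res)) NULL else
    data.frame(wavelength = object$wavelengths,
               rmse = sqrt(colMeans(res^2, na.rm = TRUE)))
  out <- list(model = object, per_band_rmse = per_band,
              bin_table = data.frame(bin = seq_len(object$bins$n_bins),
                                     center = object$bins$centers,
                                     count = object$bin_counts,
                                     fitted = object$fitted_bins))
  class(out) <- "summary.brdf_model"
  out
}

#' @export
print.summary.brdf_model <- function(x, ...) {
  print(x$model)
  cat("\nBin occupancy:\n")
  print(x$bin_table, row.names = FALSE)
  if (!is.null(x$per_band_rmse)) {
    cat("\nTraining residual RMSE by band:\n")
    print(x$per_band_rmse, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.brdf_model <- function(object, ...) object$coefficients

#' Predict modeled reflectance from a fitted BRDF model
#'
#' @param object A [brdf_fit()] result.
#' @param theta_v,theta_s,phi Geometry in degrees (vectorized).
#' @param ndvi NDVI values at which the (smoothed) coefficients are taken.
#' @param ... Unused.
#' @return Matrix `[n, bands]` of modeled reflectance.
#' @export
predict.brdf_model <- function(object, theta_v, theta_s, phi, ndvi, ...) {
  n <- max(length(theta_v), length(theta_s), length(phi), length(ndvi))
  d2r <- pi / 180
  cf <- coefficients_at_ndvi(object, rep_len(ndvi, n))
  predict_brdf(rep_len(theta_v, n) * d2r, rep_len(theta_s, n) * d2r,
               rep_len(phi, n) * d2r, cf, object$kernels, object$constants)
}

#' @export
residuals.brdf_model <- function(object, ...) {
  s <- object$samples
  if (is.null(s)) return(NULL)
  g <- s$geometry
  d2r <- pi / 180
  cf <- array(NA_real_, c(nrow(g), dim(object$coefficients)[1], 3))
  ok <- object$fitted_bins[g$bin]
  for (k in 1:3) cf[, , k] <- t(object$coefficients[, g$bin, k])
  pred <- predict_brdf(g$sensor_zenith * d2r, g$solar_zenith * d2r,
                       g$relative_azimuth * d2r, cf,
                       object$kernels, object$constants)
  res <- s$refl - pred
  res[!ok, ] <- NA_real_
  res
}

#' Plot BRDF coefficients against NDVI bin centers
#'
#' Shows the fitted per-bin constants (points) and the smoothed coefficient
#' curves (lines) for one band.
#'
#' @param x A [brdf_fit()] result.
#' @param band Band index (default: band nearest 850 nm).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.brdf_model <- function(x, band = which.min(abs(x$wavelengths - 850)),
                            ...) {
  fit_idx <- which(x$fitted_bins)
  centers <- x$bins$centers[fit_idx]
  pts <- t(x$coefficients[band, fit_idx, ])
  grid <- seq(x$bins$lower_mask, 1, length.out = 200)
  curves <- coefficients_at_ndvi(x, grid)[, band, ]
  graphics::matplot(grid, curves, type = "l", lty = 1,
                    xlab = "NDVI", ylab = "coefficient",
                    main = sprintf("BRDF coefficients, %.0f nm",
                                   x$wavelengths[band]), ...)
  graphics::matpoints(centers, t(pts), pch = 1)
  graphics::legend("topleft", legend = c("f_iso", "f_geo", "f_vol"),
                   col = 1:3, lty = 1, bty = "n")
  invisible(x)
}
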