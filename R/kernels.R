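## Ross (volumetric) and Li (geometric) kernels of the semi-empirical
## kernel-driven BRDF model. All kernel functions take angles in RADIANS;
## degree-to-radian conversion happens exactly once, in kernel_surface()
## and the correction routines.

#' Kernel shape constants
#'
#' Crown shape ratios of the Li kernels: `b_over_r` (vertical-to-horizontal
#' crown radius) and `h_over_b` (height-to-crown radius). Defaults 10 and 2
#' are widely used for vegetation.
#'
#' @param b_over_r,h_over_b Strictly positive ratios.
#' @return Object of class `kernel_constants`.
#' @export
kernel_constants <- function(b_over_r = 10, h_over_b = 2) {
  if (b_over_r <= 0 || h_over_b <= 0)
    stop("kernel_constants: ratios must be strictly positive")
  structure(list(b_over_r = b_over_r, h_over_b = h_over_b),
            class = "kernel_constants")
}

#' Kernel pair choice
#'
#' @param geometric `"li_sparse"` (default) or `"li_dense"`.
#' @param volumetric `"ross_thick"` (default) or `"ross_thin"`.
#' @return Object of class `kernel_choice`.
#' @export
kernel_choice <- function(geometric = c("li_sparse", "li_dense"),
                          volumetric = c("ross_thick", "ross_thin")) {
  structure(list(geometric = match.arg(geometric),
                 volumetric = match.arg(volumetric)),
            class = "kernel_choice")
}

#' Primed (shape-adjusted) zenith angle
#'
#' theta' = arctan((b/r) tan theta), the zenith angle after rescaling the
#' vertical axis by the crown shape ratio.
#'
#' @param theta Zenith in radians, \[0, pi/2).
#' @param constants A [kernel_constants()].
#' @return Radians in \[0, pi/2).
#' @export
primed_angle <- function(theta, constants = kernel_constants()) {
  atan(constants$b_over_r * tan(theta))
}

#' Li geometric kernel
#'
#' Sparse (default) or dense crown-shadowing kernel. The sparse form used
#' here is the non-reciprocal variant (the interception term carries
#' sec theta_v' only). `cos t` is clamped to \[-1, 1\] to guard grazing
#' geometries.
#'
#' @param theta_s,theta_v Solar and view zeniths in radians, \[0, pi/2).
#' @param phi Relative azimuth in radians, \[0, pi\].
#' @param geometric `"li_sparse"` or `"li_dense"`.
#' @param constants A [kernel_constants()].
#' @return K_geo (unitless), vectorized.
#' @export
li_kernel <- function(theta_s, theta_v, phi,
                      geometric = c("li_sparse", "li_dense"),
                      constants = kernel_constants()) {
  geometric <- match.arg(geometric)
  if (any(!is.finite(theta_s) | !is.finite(theta_v) | !is.finite(phi)))
    stop("li_kernel: non-finite inputs")
  ts <- primed_angle(theta_s, constants)
  tv <- primed_angle(theta_v, constants)
  tan_s <- tan(ts); tan_v <- tan(tv)
  sec_s <- 1 / cos(ts); sec_v <- 1 / cos(tv)
  D2 <- tan_s^2 + tan_v^2 - 2 * tan_s * tan_v * cos(phi)
  D2 <- pmax(D2, 0)
  cost <- constants$h_over_b *
    sqrt(D2 + (tan_s * tan_v * sin(phi))^2) / (sec_s + sec_v)
  cost <- pmin(pmax(cost, -1), 1)
  t <- acos(cost)
  O <- (t - sin(t) * cost) / pi * (sec_s + sec_v)
  cos_xi_p <- cos(ts) * cos(tv) + sin(ts) * sin(tv) * cos(phi)
  if (geometric == "li_sparse") {
    O - sec_s - sec_v + 0.5 * (1 + cos_xi_p) * sec_v
  } else {
    (1 + cos_xi_p) * sec_v / (sec_s + sec_v - O) - 2
  }
}

#' Ross volumetric kernel
#'
#' Thick (default, leaf area index >= 1) or thin single-scattering
#' leaf-facet kernel. The phase angle xi uses the unprimed zeniths.
#'
#' @inheritParams li_kernel
#' @param volumetric `"ross_thick"` or `"ross_thin"`.
#' @return K_vol (unitless), vectorized.
#' @export
ross_kernel <- function(theta_s, theta_v, phi,
                        volumetric = c("ross_thick", "ross_thin")) {
  volumetric <- match.arg(volumetric)
  if (any(!is.finite(theta_s) | !is.finite(theta_v) | !is.finite(phi)))
    stop("ross_kernel: non-finite inputs")
  cos_xi <- cos(theta_s) * cos(theta_v) +
    sin(theta_s) * sin(theta_v) * cos(phi)
  cos_xi <- pmin(pmax(cos_xi, -1), 1)
  xi <- acos(cos_xi)
  core <- (pi / 2 - xi) * cos_xi + sin(xi)
  if (volumetric == "ross_thick") {
    core / (cos(theta_s) + cos(theta_v)) - pi / 4
  } else {
    core / (cos(theta_s) * cos(theta_v)) - pi / 2
  }
}

#' Per-pixel kernel values for an observation stack
#'
#' Converts the stack's degree-valued geometry to radians once, derives the
#' relative azimuth, and evaluates both kernels on all valid pixels.
#'
#' @param obs An [observation_stack()].
#' @param choice A [kernel_choice()].
#' @param constants A [kernel_constants()].
#' @return List with matrices `k_geo` and `k_vol` (`NA` where masked) of
#'   class `kernel_values`.
#' @export
kernel_surface <- function(obs, choice = kernel_choice(),
                           constants = kernel_constants()) {
  stopifnot(inherits(obs, "observation_stack"))
  m <- obs$valid_mask
  if (!any(m)) stop("kernel_surface: no valid pixels")
  d2r <- pi / 180
  phi <- relative_azimuth(obs$solar_azimuth[m], obs$sensor_azimuth[m]) * d2r
  ts <- obs$solar_zenith[m] * d2r
  tv <- obs$sensor_zenith[m] * d2r
  kg <- matrix(NA_real_, nrow(m), ncol(m))
  kv <- kg
  kg[m] <- li_kernel(ts, tv, phi, choice$geometric, constants)
  kv[m] <- ross_kernel(ts, tv, phi, choice$volumetric)
  structure(list(k_geo = kg, k_vol = kv, choice = choice,
                 constants = constants),
            class = "kernel_values")
}
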