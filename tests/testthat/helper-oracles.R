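## Independent scalar oracles, transcribed step by step from the kernel
## and correction formulas. Deliberately written as plain per-pixel
## scalar code, separate from the vectorized implementation under test.

oracle_primed <- function(theta, br) atan(br * tan(theta))

oracle_li <- function(ts, tv, phi, br = 10, hb = 2,
                      variant = "sparse") {
  tsp <- oracle_primed(ts, br)
  tvp <- oracle_primed(tv, br)
  D2 <- tan(tsp)^2 + tan(tvp)^2 - 2 * tan(tsp) * tan(tvp) * cos(phi)
  sec_s <- 1 / cos(tsp)
  sec_v <- 1 / cos(tvp)
  cost <- hb * sqrt(max(D2, 0) + (tan(tsp) * tan(tvp) * sin(phi))^2) /
    (sec_s + sec_v)
  cost <- min(max(cost, -1), 1)
  t <- acos(cost)
  O <- (t - sin(t) * cost) / pi * (sec_s + sec_v)
  cxp <- cos(tsp) * cos(tvp) + sin(tsp) * sin(tvp) * cos(phi)
  if (variant == "sparse") {
    O - sec_s - sec_v + 0.5 * (1 + cxp) * sec_v
  } else {
    (1 + cxp) * sec_v / (sec_s + sec_v - O) - 2
  }
}

oracle_ross <- function(ts, tv, phi, variant = "thick") {
  cx <- cos(ts) * cos(tv) + sin(ts) * sin(tv) * cos(phi)
  cx <- min(max(cx, -1), 1)
  xi <- acos(cx)
  core <- (pi / 2 - xi) * cos(xi) + sin(xi)
  if (variant == "thick") core / (cos(ts) + cos(tv)) - pi / 4
  else core / (cos(ts) * cos(tv)) - pi / 2
}

## Meeus-style declination approximation, independent of the Spencer
## series used by the package
oracle_declination <- function(doy) {
  rad <- pi / 180
  -asin(0.39779 * cos(rad * (0.98565 * (doy + 10) +
                               1.914 * sin(rad * 0.98565 * (doy - 2))))) / rad
}

## simple single-geometry observation stack (degrees)
make_obs <- function(rows, cols, tv = 0, phi_v = 90, ts = 30,
                     phi_s = 180, slope = 0, aspect = 0,
                     map_info = NULL) {
  m <- function(x) matrix(x, rows, cols)
  observation_stack(m(tv), m(phi_v), m(ts), m(phi_s), m(slope),
                    m(aspect), map_info = map_info)
}

## cube with constant spectrum on the standard 10-band grid
make_cube <- function(rows, cols, spectrum,
                      wavelengths = c(480, 560, 660, 850, 975, 1050,
                                      1150, 1240, 1650, 2215),
                      map_info = list(x_ul = 0, y_ul = 0,
                                      pixel_size = 15)) {
  nb <- length(spectrum)
  vals <- array(rep(spectrum, each = rows * cols), c(rows, cols, nb))
  reflectance_cube(vals, wavelengths = wavelengths, map_info = map_info)
}
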