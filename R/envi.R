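## ENVI-style raster I/O: header + flat binary in BSQ/BIL/BIP interleaves.
## Internal layout for cube values is always [rows, cols, bands]; interleave
## only matters on disk.

#' Construct a scene header
#'
#' Describes the on-disk layout and georeferencing of an ENVI-style raster.
#' Map info is a minimal affine: upper-left corner of the upper-left pixel,
#' square pixel size in metres, no rotation. All downstream overlap pairing
#' works off this georeferencing.
#'
#' @param n_rows,n_cols,n_bands Raster dimensions (all >= 1).
#' @param wavelengths Band-center wavelengths in nm, strictly increasing,
#'   length `n_bands`.
#' @param interleave One of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_ignore_value Sentinel written for masked pixels
#'   (default -9999, the common ENVI convention).
#' @param map_info List with elements `x_ul`, `y_ul` (map coordinates of the
#'   upper-left corner) and `pixel_size` (metres).
#' @return An object of class `scene_header`.
#' @export
scene_header <- function(n_rows, n_cols, n_bands, wavelengths,
                         interleave = "bsq", data_ignore_value = -9999,
                         map_info = list(x_ul = 0, y_ul = 0, pixel_size = 15)) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n_bands <- as.integer(n_bands)
  if (n_rows < 1L || n_cols < 1L || n_bands < 1L)
    stop("scene_header: dimensions must all be >= 1")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != n_bands)
    stop("scene_header: length(wavelengths) must equal n_bands")
  if (n_bands > 1L && any(diff(wavelengths) <= 0))
    stop("scene_header: wavelengths must be strictly increasing")
  interleave <- match.arg(tolower(interleave), c("bsq", "bil", "bip"))
  structure(list(n_rows = n_rows, n_cols = n_cols, n_bands = n_bands,
                 wavelengths = wavelengths, interleave = interleave,
                 data_ignore_value = as.numeric(data_ignore_value),
                 map_info = map_info),
            class = "scene_header")
}

#' Construct a reflectance cube
#'
#' @param values Numeric array `[rows, cols, bands]` of unitless surface
#'   reflectance (roughly in \[0, 1\]).
#' @param header A [scene_header()]; if `NULL` a default header matching
#'   `values` is built from `wavelengths`.
#' @param wavelengths Used only when `header` is `NULL`.
#' @param valid_mask Logical `[rows, cols]`; defaults to pixels finite in all
#'   bands and free of the ignore sentinel.
#' @param ... Passed to [scene_header()] when building a default header.
#' @return An object of class `reflectance_cube`.
#' @export
reflectance_cube <- function(values, header = NULL, wavelengths = NULL,
                             valid_mask = NULL, ...) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  d <- dim(values)
  if (is.null(header)) {
    if (is.null(wavelengths)) wavelengths <- seq_len(d[3])
    header <- scene_header(d[1], d[2], d[3], wavelengths, ...)
  }
  if (!identical(c(header$n_rows, header$n_cols, header$n_bands),
                 as.integer(d)))
    stop("reflectance_cube: header dimensions do not match values")
  if (is.null(valid_mask)) {
    ig <- header$data_ignore_value
    ok <- is.finite(values) & values != ig
    valid_mask <- apply(ok, c(1, 2), all)
  }
  stopifnot(identical(dim(valid_mask), d[1:2]))
  structure(list(header = header, values = values,
                 valid_mask = valid_mask),
            class = "reflectance_cube")
}

#' @export
print.reflectance_cube <- function(x, ...) {
  h <- x$header
  cat(sprintf("<reflectance_cube> %d x %d pixels, %d bands (%.0f-%.0f nm), %s\n",
              h$n_rows, h$n_cols, h$n_bands, min(h$wavelengths),
              max(h$wavelengths), toupper(h$interleave)))
  cat(sprintf("  valid pixels: %d / %d\n", sum(x$valid_mask),
              length(x$valid_mask)))
  invisible(x)
}

## disk order permutations: internal [rows, cols, bands] <-> on-disk vector
.envi_perm <- list(
  bsq = c(2L, 1L, 3L),   # samples, lines, bands
  bil = c(2L, 3L, 1L),   # samples, bands, lines
  bip = c(3L, 2L, 1L))   # bands, samples, lines

.envi_hdr_path <- function(path) paste0(path, ".hdr")

.format_envi_num <- function(x) {
  ## full precision, no scientific surprises in header round trips
  vapply(x, function(v) format(v, digits = 17, scientific = FALSE,
                               trim = TRUE), "")
}

#' Write a reflectance cube in ENVI-style format
#'
#' Emits `<path>` (flat binary, little-endian) and `<path>.hdr`. Masked
#' pixels are written as the header's data ignore value in every band.
#'
#' @param cube A [reflectance_cube()].
#' @param path Destination binary file (header gets a `.hdr` suffix).
#' @param data_type ENVI data type code: 4 (float32) or 5 (float64,
#'   default, so that synthetic truth survives a round trip exactly).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, data_type = 5L) {
  stopifnot(inherits(cube, "reflectance_cube"))
  if (!data_type %in% c(4L, 5L)) stop("write_cube: data_type must be 4 or 5")
  h <- cube$header
  v <- cube$values
  if (any(!cube$valid_mask)) {
    bad <- which(!cube$valid_mask)           # [rows*cols] indices
    n_px <- h$n_rows * h$n_cols
    idx <- rep(bad, times = h$n_bands) +
      n_px * rep(seq_len(h$n_bands) - 1L, each = length(bad))
    v[idx] <- h$data_ignore_value
  }
  v[!is.finite(v)] <- h$data_ignore_value
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(v, .envi_perm[[h$interleave]])), con,
           size = if (data_type == 5L) 8L else 4L, endian = "little")
  writeLines(.envi_header_text(h, data_type), .envi_hdr_path(path))
  invisible(path)
}

.envi_header_text <- function(h, data_type) {
  mi <- h$map_info
  c("ENVI",
    "description = {brdfcorr raster}",
    paste0("samples = ", h$n_cols),
    paste0("lines = ", h$n_rows),
    paste0("bands = ", h$n_bands),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    paste0("interleave = ", h$interleave),
    "byte order = 0",
    paste0("data ignore value = ", .format_envi_num(h$data_ignore_value)),
    paste0("map info = {Arbitrary, 1, 1, ",
           .format_envi_num(mi$x_ul), ", ", .format_envi_num(mi$y_ul), ", ",
           .format_envi_num(mi$pixel_size), ", ",
           .format_envi_num(mi$pixel_size), ", 0}"),
    "wavelength units = Nanometers",
    paste0("wavelength = {",
           paste(.format_envi_num(h$wavelengths), collapse = ", "), "}"))
}

#' Parse an ENVI header file
#'
#' @param hdr_path Path to a `.hdr` text file.
#' @return Named list of raw key/value strings plus parsed fields.
#' @keywords internal
parse_envi_header <- function(hdr_path) {
  if (!file.exists(hdr_path))
    stop(sprintf("header file not found: %s", hdr_path))
  txt <- readLines(hdr_path, warn = FALSE)
  if (length(txt) == 0L || !grepl("^ENVI", txt[1]))
    stop(sprintf("not an ENVI header (missing ENVI magic): %s", hdr_path))
  keys <- list()
  lines <- txt[-1]
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!grepl("=", ln)) { i <- i + 1L; next }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (grepl("\\{", val) && !grepl("\\}", val)) {
      while (i < length(lines) && !grepl("\\}", val)) {
        i <- i + 1L
        val <- paste(val, trimws(lines[i]))
      }
    }
    keys[[tolower(key)]] <- val
    i <- i + 1L
  }
  need <- function(k) {
    if (is.null(keys[[k]]))
      stop(sprintf("ENVI header %s is missing required key '%s'",
                   hdr_path, k))
    keys[[k]]
  }
  num <- function(k) {
    v <- suppressWarnings(as.numeric(need(k)))
    if (is.na(v)) stop(sprintf("ENVI header key '%s' is not numeric", k))
    v
  }
  brace_vec <- function(s) {
    s <- gsub("[{}]", "", s)
    as.numeric(trimws(strsplit(s, ",")[[1]]))
  }
  out <- list(
    n_cols = as.integer(num("samples")),
    n_rows = as.integer(num("lines")),
    n_bands = as.integer(num("bands")),
    data_type = as.integer(num("data type")),
    interleave = tolower(need("interleave")),
    byte_order = as.integer(num("byte order")),
    data_ignore_value = if (is.null(keys[["data ignore value"]])) -9999
                        else as.numeric(keys[["data ignore value"]]))
  if (!out$interleave %in% c("bsq", "bil", "bip"))
    stop(sprintf("ENVI header key 'interleave' has unsupported value '%s'",
                 out$interleave))
  if (!out$data_type %in% c(4L, 5L))
    stop(sprintf("ENVI header key 'data type' %d unsupported (only 4/5)",
                 out$data_type))
  if (!is.null(keys[["wavelength"]])) {
    out$wavelengths <- brace_vec(keys[["wavelength"]])
  } else {
    out$wavelengths <- seq_len(out$n_bands)
  }
  if (!is.null(keys[["map info"]])) {
    parts <- trimws(strsplit(gsub("[{}]", "", keys[["map info"]]), ",")[[1]])
    out$map_info <- list(x_ul = as.numeric(parts[4]),
                         y_ul = as.numeric(parts[5]),
                         pixel_size = as.numeric(parts[6]))
  } else {
    out$map_info <- list(x_ul = 0, y_ul = 0, pixel_size = 15)
  }
  out
}

.read_envi_values <- function(path, hp) {
  size <- if (hp$data_type == 5L) 8L else 4L
  n <- hp$n_rows * hp$n_cols * hp$n_bands
  expected <- as.numeric(n) * size
  actual <- file.size(path)
  if (is.na(actual) || actual != expected)
    stop(sprintf(paste0("binary size mismatch for %s: header implies %d",
                        " bytes, file has %d"),
                 path, expected, actual))
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = n, size = size, endian = "little")
  perm <- .envi_perm[[hp$interleave]]
  dims <- c(hp$n_rows, hp$n_cols, hp$n_bands)[perm]
  aperm(array(raw, dim = dims), order(perm))
}

#' Read a reflectance cube from ENVI-style files
#'
#' Values are returned untouched (no rescaling); the valid mask is the
#' conjunction of finiteness and absence of the data ignore value across
#' bands.
#'
#' @param path Binary file path (expects `<path>.hdr` alongside).
#' @param scale_divisor Optional divisor for integer-scaled reflectance
#'   products (default 1, i.e. no scaling).
#' @return A [reflectance_cube()].
#' @export
read_cube <- function(path, scale_divisor = 1) {
  if (!file.exists(path)) stop(sprintf("binary file not found: %s", path))
  hp <- parse_envi_header(.envi_hdr_path(path))
  vals <- .read_envi_values(path, hp)
  hdr <- scene_header(hp$n_rows, hp$n_cols, hp$n_bands, hp$wavelengths,
                      interleave = hp$interleave,
                      data_ignore_value = hp$data_ignore_value,
                      map_info = hp$map_info)
  mask <- apply(is.finite(vals) & vals != hp$data_ignore_value, c(1, 2), all)
  if (scale_divisor != 1) vals <- vals / scale_divisor
  reflectance_cube(vals, header = hdr, valid_mask = mask)
}

#' Default AVIRIS obs_ort layer mapping
#'
#' Layer indices of the geometry fields in the 10-layer AVIRIS L1B
#' `obs_ort` convention (path length, to-sensor azimuth, to-sensor zenith,
#' to-sun azimuth, to-sun zenith, phase, slope, aspect, cosine i, UTC time).
#'
#' @return Named integer vector of layer indices.
#' @export
obs_band_map <- function() {
  c(sensor_azimuth = 2L, sensor_zenith = 3L, solar_azimuth = 4L,
    solar_zenith = 5L, slope = 7L, aspect = 8L)
}

#' Construct an observation stack
#'
#' Per-pixel acquisition geometry, all in degrees: sensor (view) and solar
#' zenith/azimuth plus terrain slope and aspect.
#'
#' @param sensor_zenith,sensor_azimuth,solar_zenith,solar_azimuth Numeric
#'   matrices `[rows, cols]`, degrees. Zeniths in \[0, 90), azimuths in
#'   \[0, 360).
#' @param slope,aspect Terrain slope (\[0, 90\]) and aspect, degrees.
#' @param valid_mask Logical matrix; defaults to all-finite, in-range pixels.
#' @param map_info Optional georeferencing (as in [scene_header()]).
#' @return An object of class `observation_stack`.
#' @export
observation_stack <- function(sensor_zenith, sensor_azimuth, solar_zenith,
                              solar_azimuth, slope, aspect,
                              valid_mask = NULL, map_info = NULL) {
  layers <- list(sensor_zenith = sensor_zenith,
                 sensor_azimuth = sensor_azimuth,
                 solar_zenith = solar_zenith,
                 solar_azimuth = solar_azimuth,
                 slope = slope, aspect = aspect)
  d <- dim(sensor_zenith)
  for (nm in names(layers)) {
    if (!identical(dim(layers[[nm]]), d))
      stop("observation_stack: all layers must share one shape")
  }
  fin <- Reduce(`&`, lapply(layers, is.finite))
  rng <- sensor_zenith >= 0 & sensor_zenith < 90 &
    solar_zenith >= 0 & solar_zenith < 90 &
    sensor_azimuth >= 0 & sensor_azimuth < 360 &
    solar_azimuth >= 0 & solar_azimuth < 360 &
    slope >= 0 & slope <= 90
  ## non-finite pixels are missing data (masked); finite but out-of-range
  ## geometry is a data error
  if (any(fin & !rng))
    stop("observation_stack: geometry out of range ",
         "(zeniths must lie in [0, 90), azimuths in [0, 360), ",
         "slope in [0, 90])")
  if (is.null(valid_mask)) valid_mask <- fin
  else valid_mask <- valid_mask & fin
  structure(c(layers, list(valid_mask = valid_mask, map_info = map_info)),
            class = "observation_stack")
}

#' @export
print.observation_stack <- function(x, ...) {
  d <- dim(x$sensor_zenith)
  cat(sprintf("<observation_stack> %d x %d pixels, %d valid\n",
              d[1], d[2], sum(x$valid_mask)))
  rng <- range(x$solar_zenith[x$valid_mask])
  cat(sprintf("  solar zenith %.2f-%.2f deg, view zenith up to %.2f deg\n",
              rng[1], rng[2], max(x$sensor_zenith[x$valid_mask])))
  invisible(x)
}

#' Read an observation stack from an ENVI-style multi-layer file
#'
#' @param path Binary file path (expects `<path>.hdr`).
#' @param band_map Named integer vector mapping field names
#'   (`sensor_zenith`, `sensor_azimuth`, `solar_zenith`, `solar_azimuth`,
#'   `slope`, `aspect`) to layer indices; defaults to the AVIRIS
#'   `obs_ort` ordering ([obs_band_map()]).
#' @return An [observation_stack()].
#' @export
read_observation <- function(path, band_map = obs_band_map()) {
  if (!file.exists(path)) stop(sprintf("binary file not found: %s", path))
  hp <- parse_envi_header(.envi_hdr_path(path))
  need <- c("sensor_zenith", "sensor_azimuth", "solar_zenith",
            "solar_azimuth", "slope", "aspect")
  miss <- setdiff(need, names(band_map))
  if (length(miss))
    stop("read_observation: band_map missing fields: ",
         paste(miss, collapse = ", "))
  if (any(band_map[need] < 1L) || any(band_map[need] > hp$n_bands))
    stop(sprintf(paste0("read_observation: band_map index out of range",
                        " (file has %d layers)"), hp$n_bands))
  vals <- .read_envi_values(path, hp)
  ig <- hp$data_ignore_value
  layer <- function(i) {
    m <- vals[, , band_map[[i]], drop = TRUE]
    m <- matrix(m, hp$n_rows, hp$n_cols)
    m[m == ig] <- NA_real_
    m
  }
  fields <- lapply(need, layer)
  names(fields) <- need
  mask <- Reduce(`&`, lapply(fields, is.finite))
  observation_stack(fields$sensor_zenith, fields$sensor_azimuth,
                    fields$solar_zenith, fields$solar_azimuth,
                    fields$slope, fields$aspect,
                    valid_mask = mask, map_info = hp$map_info)
}

#' Write an observation stack as a 10-layer AVIRIS-style file
#'
#' Layers follow the `obs_ort` convention; layers the stack does not carry
#' (path length, phase, cosine i, UTC time) are written as zeros.
#'
#' @param obs An [observation_stack()].
#' @param path Destination binary file.
#' @param data_type ENVI data type code (4 or 5).
#' @return `path`, invisibly.
#' @export
write_observation <- function(obs, path, data_type = 5L) {
  d <- dim(obs$sensor_zenith)
  v <- array(0, dim = c(d[1], d[2], 10L))
  bm <- obs_band_map()
  for (nm in names(bm)) {
    m <- obs[[nm]]
    m[!obs$valid_mask] <- -9999
    v[, , bm[[nm]]] <- m
  }
  hdr <- scene_header(d[1], d[2], 10L, wavelengths = seq_len(10L),
                      interleave = "bil", data_ignore_value = -9999,
                      map_info = if (is.null(obs$map_info))
                        list(x_ul = 0, y_ul = 0, pixel_size = 15)
                      else obs$map_info)
  cube <- reflectance_cube(v, header = hdr,
                           valid_mask = matrix(TRUE, d[1], d[2]))
  write_cube(cube, path, data_type = data_type)
}
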