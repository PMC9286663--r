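## Overlap-consistency assessment: per-band RMSE, MAD and simple linear
## regression between co-located pixels of adjacent flightlines. Lower
## RMSE/MAD after correction indicates better cross-line consistency.

#' Pair co-located pixels of two georeferenced scenes
#'
#' Pixels are paired when their map coordinates coincide within half a
#' pixel, assuming both scenes sit on a common grid orientation (no
#' rotation). Synthetic scenes from this package are exactly registered by
#' construction.
#'
#' @param header_a,header_b [scene_header()]s with `map_info`.
#' @return Object of class `overlap_pair`: integer matrix `pairs` with
#'   columns `row_a, col_a, row_b, col_b`, and `n_pairs`. Zero rows when
#'   the extents are disjoint.
#' @export
find_overlap <- function(header_a, header_b) {
  ma <- header_a$map_info; mb <- header_b$map_info
  px <- ma$pixel_size
  if (abs(px - mb$pixel_size) > 1e-9 * px)
    stop("find_overlap: pixel sizes differ")
  ## integer column/row offsets of b relative to a, on the shared grid
  dc <- (mb$x_ul - ma$x_ul) / px
  dr <- (ma$y_ul - mb$y_ul) / px   # y decreases downward
  if (abs(dc - round(dc)) > 0.5 - 1e-9 || abs(dr - round(dr)) > 0.5 - 1e-9) {
    ## grids shifted by more than half a pixel never coincide
    return(structure(list(pairs = matrix(integer(0), 0, 4,
                                         dimnames = list(NULL,
                                           c("row_a", "col_a",
                                             "row_b", "col_b"))),
                          n_pairs = 0L), class = "overlap_pair"))
  }
  dc <- as.integer(round(dc)); dr <- as.integer(round(dr))
  cols_a <- max(1L, 1L + dc):min(header_a$n_cols, header_b$n_cols + dc)
  rows_a <- max(1L, 1L + dr):min(header_a$n_rows, header_b$n_rows + dr)
  if (length(cols_a) == 0 || length(rows_a) == 0 ||
      cols_a[1] > cols_a[length(cols_a)] || rows_a[1] > rows_a[length(rows_a)]) {
    pairs <- matrix(integer(0), 0, 4)
  } else {
    grid <- expand.grid(row_a = rows_a, col_a = cols_a)
    pairs <- cbind(row_a = grid$row_a, col_a = grid$col_a,
                   row_b = grid$row_a - dr, col_b = grid$col_a - dc)
  }
  colnames(pairs) <- c("row_a", "col_a", "row_b", "col_b")
  structure(list(pairs = pairs, n_pairs = nrow(pairs)),
            class = "overlap_pair")
}

#' Per-band consistency statistics over an overlap
#'
#' For each band, regresses the values of line b on line a over the paired
#' valid pixels (line a is the predictor by convention; record which line
#' is earlier when calling). Reports the regression RMSE (root mean squared
#' residual), the MAD of raw paired differences, slope and intercept, plus
#' the alternative conventions (`rmse_diff` on raw differences,
#' `mad_resid` on residuals) clearly labeled.
#'
#' @param cube_a,cube_b [reflectance_cube()]s sharing a band set.
#' @param pair A [find_overlap()] result (a-indices into `cube_a`).
#' @param bands Optional integer band indices (default: all bands).
#' @return Data frame, one row per band: `wavelength`, `n`, `rmse`, `mad`,
#'   `slope`, `intercept`, `rmse_diff`, `mad_resid`, and
#'   `degenerate_predictor` (zero predictor variance; difference metrics
#'   only).
#' @export
overlap_statistics <- function(cube_a, cube_b, pair, bands = NULL) {
  stopifnot(inherits(pair, "overlap_pair"))
  if (pair$n_pairs < 2) stop("overlap_statistics: fewer than 2 pairs")
  wl <- cube_a$header$wavelengths
  if (!isTRUE(all.equal(wl, cube_b$header$wavelengths)))
    stop("overlap_statistics: cubes do not share a band set")
  if (is.null(bands)) bands <- seq_along(wl)
  p <- pair$pairs
  ia <- p[, "row_a"] + (p[, "col_a"] - 1L) * cube_a$header$n_rows
  ib <- p[, "row_b"] + (p[, "col_b"] - 1L) * cube_b$header$n_rows
  ok <- cube_a$valid_mask[ia] & cube_b$valid_mask[ib]
  ia <- ia[ok]; ib <- ib[ok]
  if (length(ia) < 2) stop("overlap_statistics: fewer than 2 valid pairs")
  npa <- prod(dim(cube_a$valid_mask)); npb <- prod(dim(cube_b$valid_mask))
  out <- lapply(bands, function(k) {
    x <- cube_a$values[ia + (k - 1L) * npa]
    y <- cube_b$values[ib + (k - 1L) * npb]
    d <- y - x
    degen <- stats::var(x) <= 0
    if (degen) {
      slope <- NA_real_; intercept <- NA_real_
      rmse <- NA_real_; mad_resid <- NA_real_
    } else {
      cf <- stats::.lm.fit(cbind(1, x), y)$coefficients
      intercept <- cf[1]; slope <- cf[2]
      r <- y - (intercept + slope * x)
      rmse <- sqrt(mean(r^2))
      mad_resid <- mean(abs(r))
    }
    data.frame(band = k, wavelength = wl[k], n = length(x),
               rmse = rmse, mad = mean(abs(d)),
               slope = slope, intercept = intercept,
               rmse_diff = sqrt(mean(d^2)), mad_resid = mad_resid,
               degenerate_predictor = degen)
  })
  do.call(rbind, out)
}

#' Select band indices nearest a set of target wavelengths
#'
#' @param wavelengths Band-center wavelengths in nm.
#' @param targets Target wavelengths in nm (e.g. the 10-band assessment
#'   subset 480, 560, 660, 850, 975, 1050, 1150, 1240, 1650, 2215 nm).
#' @param tol Maximum allowed distance in nm (default 20).
#' @return Integer indices, one per target (duplicates allowed, with a
#'   warning).
#' @export
band_subset <- function(wavelengths, targets, tol = 20) {
  idx <- vapply(targets, function(t) {
    i <- which.min(abs(wavelengths - t))
    if (abs(wavelengths[i] - t) > tol)
      stop(sprintf("band_subset: no band within %g nm of %g nm", tol, t))
    i
  }, 0L)
  if (anyDuplicated(idx))
    warning("band_subset: multiple targets map to the same band")
  idx
}

#' Assess overlap consistency across a flightline group
#'
#' Runs [find_overlap()] and [overlap_statistics()] for every pair of
#' lines with overlapping extents (the earlier-listed line is the
#' predictor) and averages the statistics per band across pairs
#' (unweighted mean, as the group summary).
#'
#' @param lines List of [reflectance_cube()]s.
#' @param bands Optional target wavelengths in nm (passed through
#'   [band_subset()]); default: all bands.
#' @return Object of class `assessment_report`: `per_pair` (data frame
#'   with `line_a`, `line_b` columns prepended) and `group_mean`
#'   (per-band unweighted mean across pairs).
#' @export
assess_group <- function(lines, bands = NULL) {
  stopifnot(length(lines) >= 2)
  wl <- lines[[1]]$header$wavelengths
  band_idx <- if (is.null(bands)) seq_along(wl) else band_subset(wl, bands)
  per_pair <- list()
  for (i in seq_along(lines)) for (j in seq_along(lines)) {
    if (j <= i) next
    pair <- find_overlap(lines[[i]]$header, lines[[j]]$header)
    if (pair$n_pairs < 2) next
    st <- overlap_statistics(lines[[i]], lines[[j]], pair, band_idx)
    per_pair[[length(per_pair) + 1L]] <-
      cbind(data.frame(line_a = i, line_b = j), st)
  }
  if (length(per_pair) == 0)
    stop("assess_group: no overlapping line pairs")
  per_pair <- do.call(rbind, per_pair)
  agg <- stats::aggregate(
    per_pair[c("rmse", "mad", "slope", "intercept", "rmse_diff",
               "mad_resid")],
    by = per_pair[c("band", "wavelength")], FUN = mean)
  agg <- agg[order(agg$band), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(per_pair = per_pair, group_mean = agg,
                 predictor = "earlier line (line_a)"),
            class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(sprintf("<assessment_report> %d overlap pair(s), %d band(s)\n",
              length(unique(paste(x$per_pair$line_a, x$per_pair$line_b))),
              nrow(x$group_mean)))
  cat(sprintf("  group-mean RMSE %.5f, MAD %.5f (across bands)\n",
              mean(x$group_mean$rmse, na.rm = TRUE),
              mean(x$group_mean$mad, na.rm = TRUE)))
  invisible(x)
}

#' Write an assessment report as CSV and JSON
#'
#' The CSV holds one row per band per pair plus group-average rows
#' (`line_a = line_b = NA`); the JSON mirrors the full report.
#'
#' @param report An [assess_group()] result.
#' @param path_csv,path_json Destination paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_assessment_report <- function(report, path_csv = NULL,
                                    path_json = NULL) {
  stopifnot(inherits(report, "assessment_report"))
  if (!is.null(path_csv)) {
    gm <- cbind(data.frame(line_a = NA_integer_, line_b = NA_integer_),
                report$group_mean,
                n = NA_integer_, degenerate_predictor = NA)
    gm <- gm[names(report$per_pair)]
    utils::write.csv(rbind(report$per_pair, gm), path_csv,
                     row.names = FALSE)
  }
  if (!is.null(path_json))
    jsonlite::write_json(list(per_pair = report$per_pair,
                              group_mean = report$group_mean,
                              predictor = report$predictor),
                         path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(report)
}
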