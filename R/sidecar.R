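## Model sidecar: a JSON serialization of a fitted brdf_model sufficient
## to re-apply the correction to new lines exactly. Numbers are written at
## full precision and no timestamps are recorded, so identical fits give
## byte-identical sidecars.

#' Write a fitted BRDF model to a JSON sidecar
#'
#' @param model A [brdf_fit()] result.
#' @param path Destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_brdf_model <- function(model, path) {
  stopifnot(inherits(model, "brdf_model"))
  payload <- list(
    format = "brdfcorr-model",
    version = 1L,
    wavelengths = model$wavelengths,
    coefficients = as.vector(model$coefficients),
    coefficients_dim = dim(model$coefficients),
    se = as.vector(model$se),
    bin_counts = model$bin_counts,
    fitted_bins = model$fitted_bins,
    bins = list(mode = model$bins$mode, n_bins = model$bins$n_bins,
                lower_mask = model$bins$lower_mask,
                dynamic_upper = model$bins$dynamic_upper,
                edges = model$bins$edges, centers = model$bins$centers),
    kernels = list(geometric = model$kernels$geometric,
                   volumetric = model$kernels$volumetric,
                   b_over_r = model$constants$b_over_r,
                   h_over_b = model$constants$h_over_b),
    smoothing = model$smoothing,
    smoothing_range = model$smoothing_range,
    reference_zenith = model$reference_zenith,
    solar_mode = model$solar_mode,
    per_bin = model$per_bin,
    seed = model$seed)
  ## 17 significant digits round-trips IEEE doubles exactly, so a reread
  ## sidecar re-applies the fit bit-identically
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a BRDF model sidecar
#'
#' Reconstructs a `brdf_model` usable with [apply_brdf_correction()],
#' [coefficients_at_ndvi()] and [predict.brdf_model()] (training samples
#' and per-line topographic fits are not stored in the sidecar).
#'
#' @param path Path to a sidecar written by [write_brdf_model()].
#' @return A `brdf_model`.
#' @export
read_brdf_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "brdfcorr-model")
    stop(sprintf("%s is not a brdfcorr model sidecar", path))
  dims <- as.integer(p$coefficients_dim)
  cf <- array(as.numeric(p$coefficients), dims,
              dimnames = list(NULL, NULL, c("f_iso", "f_geo", "f_vol")))
  se <- array(as.numeric(p$se), dims, dimnames = dimnames(cf))
  bins <- ndvi_bins(p$bins$mode, p$bins$n_bins, p$bins$lower_mask,
                    p$bins$dynamic_upper)
  bins$edges <- as.numeric(p$bins$edges)
  bins$centers <- as.numeric(p$bins$centers)
  structure(list(coefficients = cf, se = se,
                 bin_counts = as.integer(p$bin_counts),
                 fitted_bins = as.logical(p$fitted_bins),
                 bins = bins, wavelengths = as.numeric(p$wavelengths),
                 kernels = kernel_choice(p$kernels$geometric,
                                         p$kernels$volumetric),
                 constants = kernel_constants(p$kernels$b_over_r,
                                              p$kernels$h_over_b),
                 smoothing = p$smoothing,
                 smoothing_range = as.numeric(p$smoothing_range),
                 reference_zenith = if (is.null(p$reference_zenith)) NULL
                                    else as.numeric(p$reference_zenith),
                 solar_mode = p$solar_mode,
                 per_bin = p$per_bin, seed = p$seed,
                 topo_fits = NULL, samples = NULL, call = NULL),
            class = "brdf_model")
}
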