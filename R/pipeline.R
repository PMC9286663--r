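## Run orchestration: a config file drives the model-estimation and
## model-application workflows (fit -> sidecar -> apply -> assess), with a
## reproducible run manifest. A thin command-line wrapper lives in
## inst/cli/brdfcorr.R.

.default_config <- function() {
  list(
    io = list(lines = list(), output_dir = ".", scale_divisor = 1),
    kernels = list(geometric = "li_sparse", volumetric = "ross_thick",
                   b_over_r = 10, h_over_b = 2),
    topo = list(enabled = TRUE, min_sample = 1000, max_sample = 50000,
                b_threshold = 1e-6, seed = NULL),
    bins = list(mode = "dynamic", n = 18, lower_mask = 0.05,
                dynamic_upper = 0.9),
    smoothing = list(method = "linear_interpolation",
                     range = c(0.25, 0.85)),
    solar_reference = list(mode = "observed_mean", latitude = NULL,
                           date = NULL, season_start = NULL,
                           season_end = NULL, fixed_value = NULL),
    sampling = list(per_bin = 10000, seed = 1),
    assessment = list(band_subset = NULL))
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read and validate a run configuration
#'
#' YAML (`.yaml`/`.yml`) or JSON (`.json`) with sections `io` (the line
#' file list and output directory), `kernels`, `topo`, `bins`,
#' `smoothing`, `solar_reference`, `sampling` and `assessment`; every
#' omitted key falls back to a documented default.
#'
#' @param path Config file path, or a list already in config shape.
#' @param check_files Require each line's reflectance and observation
#'   files to exist (default `TRUE`).
#' @return Config list (class `brdf_config`) with attribute
#'   `"config_hash"` (MD5 of the file, when read from one).
#' @export
read_run_config <- function(path, check_files = TRUE) {
  if (is.list(path)) {
    user <- path
    hash <- NA_character_
    base_dir <- "."
  } else {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    ext <- tolower(tools::file_ext(path))
    user <- switch(ext,
                   yaml = , yml = yaml::read_yaml(path),
                   json = jsonlite::read_json(path, simplifyVector = TRUE),
                   stop(sprintf("unsupported config extension '.%s'", ext)))
    hash <- unname(tools::md5sum(path))
    base_dir <- dirname(normalizePath(path))
  }
  cfg <- .merge_config(.default_config(), user)
  ## line list normalization: allow data-frame-ish or list-of-lists
  ln <- cfg$io$lines
  if (is.data.frame(ln)) ln <- lapply(seq_len(nrow(ln)), function(i)
    as.list(ln[i, , drop = FALSE]))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p) || grepl("^/", p)) p else file.path(base_dir, p)
  }
  ln <- lapply(ln, function(l) {
    if (is.null(l$reflectance) || is.null(l$observation))
      stop("config: every io.lines entry needs 'reflectance' and ",
           "'observation' paths")
    l$reflectance <- resolve(l$reflectance)
    l$observation <- resolve(l$observation)
    l
  })
  if (check_files) {
    for (l in ln) for (p in c(l$reflectance, l$observation)) {
      if (!file.exists(p))
        stop(sprintf("config: referenced file does not exist: %s", p))
      if (!file.exists(paste0(p, ".hdr")))
        stop(sprintf("config: missing header file: %s.hdr", p))
    }
  }
  cfg$io$lines <- ln
  cfg$io$output_dir <- resolve(cfg$io$output_dir)
  attr(cfg, "config_hash") <- hash
  class(cfg) <- c("brdf_config", "list")
  cfg
}

.load_group <- function(cfg) {
  lapply(cfg$io$lines, function(l) {
    bm <- if (is.null(l$band_map)) obs_band_map()
          else unlist(l$band_map)
    list(cube = read_cube(l$reflectance,
                          scale_divisor = cfg$io$scale_divisor),
         obs = read_observation(l$observation, band_map = bm))
  })
}

.solar_ref_from_config <- function(sc) {
  solar_reference(mode = sc$mode, latitude = sc$latitude,
                  date = sc$date, season_start = sc$season_start,
                  season_end = sc$season_end,
                  fixed_value = sc$fixed_value)
}

.write_manifest <- function(cfg, out_dir, extra = list()) {
  manifest <- c(list(
    package = "brdfcorr",
    package_version = as.character(utils::packageVersion("brdfcorr")),
    config_hash = attr(cfg, "config_hash"),
    sampling_seed = cfg$sampling$seed,
    topo_seed = if (is.null(cfg$topo$seed)) cfg$sampling$seed
                else cfg$topo$seed,
    lines = lapply(cfg$io$lines, function(l)
      list(reflectance = l$reflectance, observation = l$observation))),
    extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Fit a group BRDF model from a run configuration
#'
#' Runs the estimation workflow: optional per-line SCS+C correction, NDVI
#' and bin derivation from the pooled group, stratified group sampling,
#' per-band per-bin least squares, smoothing setup and reference-zenith
#' resolution; writes the model sidecar and a run manifest to the output
#' directory.
#'
#' @param config Path to a config file, or a config list.
#' @param model_file Sidecar filename within the output directory.
#' @return The fitted [brdf_fit()] model, invisibly.
#' @export
run_fit <- function(config, model_file = "brdf_model.json") {
  cfg <- if (inherits(config, "brdf_config")) config
         else read_run_config(config)
  if (length(cfg$io$lines) == 0) stop("run_fit: config lists no lines")
  group <- .load_group(cfg)
  model <- brdf_fit(
    group,
    bins = ndvi_bins(cfg$bins$mode, cfg$bins$n, cfg$bins$lower_mask,
                     cfg$bins$dynamic_upper),
    smoothing = cfg$smoothing$method,
    smoothing_range = as.numeric(cfg$smoothing$range),
    kernels = kernel_choice(cfg$kernels$geometric,
                            cfg$kernels$volumetric),
    constants = kernel_constants(cfg$kernels$b_over_r,
                                 cfg$kernels$h_over_b),
    per_bin = cfg$sampling$per_bin, seed = cfg$sampling$seed,
    topo = isTRUE(cfg$topo$enabled),
    topo_opts = list(min_sample = cfg$topo$min_sample,
                     max_sample = cfg$topo$max_sample,
                     b_threshold = cfg$topo$b_threshold,
                     seed = cfg$topo$seed),
    solar_ref = .solar_ref_from_config(cfg$solar_reference))
  out_dir <- cfg$io$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_brdf_model(model, file.path(out_dir, model_file))
  .write_manifest(cfg, out_dir, list(model = model_file))
  invisible(model)
}

#' Apply a fitted model to the configured lines
#'
#' Re-runs the per-line SCS+C correction (when enabled in the config,
#' with the same seeds, hence the same fits as during estimation) and
#' writes one BRDF-corrected ENVI cube per line to the output directory.
#'
#' @param config Path to a config file, or a config list.
#' @param model A [brdf_fit()] result, or the path to a model sidecar;
#'   default: the sidecar in the config's output directory.
#' @param suffix Filename suffix for corrected cubes (default
#'   `"_brdf"`).
#' @return Character vector of written cube paths, invisibly.
#' @export
run_apply <- function(config, model = NULL, suffix = "_brdf") {
  cfg <- if (inherits(config, "brdf_config")) config
         else read_run_config(config)
  out_dir <- cfg$io$output_dir
  if (is.null(model)) model <- file.path(out_dir, "brdf_model.json")
  if (is.character(model)) model <- read_brdf_model(model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  group <- .load_group(cfg)
  topo_seed <- if (is.null(cfg$topo$seed)) cfg$sampling$seed
               else cfg$topo$seed
  paths <- character(length(group))
  for (i in seq_along(group)) {
    cube <- group[[i]]$cube; obs <- group[[i]]$obs
    if (!isTRUE(all.equal(model$wavelengths, cube$header$wavelengths)))
      stop(sprintf(paste0("run_apply: wavelength grid of line %d does",
                          " not match the model"), i))
    if (isTRUE(cfg$topo$enabled)) {
      tf <- fit_c_factor(cube, obs, min_sample = cfg$topo$min_sample,
                         max_sample = cfg$topo$max_sample,
                         b_threshold = cfg$topo$b_threshold,
                         seed = topo_seed)
      cube <- apply_scs_c(cube, obs, tf)
    }
    corrected <- apply_brdf_correction(cube, obs, model)
    base <- basename(cfg$io$lines[[i]]$reflectance)
    paths[i] <- file.path(out_dir, paste0(base, suffix))
    write_cube(corrected, paths[i])
  }
  invisible(paths)
}

#' Assess overlap consistency for the configured group
#'
#' Writes per-band RMSE/MAD/regression reports (CSV + JSON) for the
#' uncorrected input lines and, when corrected cubes are present in the
#' output directory, for the corrected lines as well.
#'
#' @param config Path to a config file, or a config list.
#' @param suffix Corrected-cube suffix used by [run_apply()].
#' @return List with `uncorrected` and (possibly `NULL`) `corrected`
#'   [assess_group()] reports, invisibly.
#' @export
run_assess <- function(config, suffix = "_brdf") {
  cfg <- if (inherits(config, "brdf_config")) config
         else read_run_config(config)
  if (length(cfg$io$lines) < 2)
    stop("run_assess: need at least 2 lines")
  out_dir <- cfg$io$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bands <- cfg$assessment$band_subset
  cubes <- lapply(cfg$io$lines, function(l)
    read_cube(l$reflectance, scale_divisor = cfg$io$scale_divisor))
  rep_un <- assess_group(cubes, bands = bands)
  write_assessment_report(rep_un,
                          file.path(out_dir, "assessment_uncorrected.csv"),
                          file.path(out_dir, "assessment_uncorrected.json"))
  corr_paths <- vapply(cfg$io$lines, function(l)
    file.path(out_dir, paste0(basename(l$reflectance), suffix)), "")
  rep_co <- NULL
  if (all(file.exists(corr_paths))) {
    rep_co <- assess_group(lapply(corr_paths, read_cube), bands = bands)
    write_assessment_report(rep_co,
                            file.path(out_dir, "assessment_corrected.csv"),
                            file.path(out_dir, "assessment_corrected.json"))
  }
  invisible(list(uncorrected = rep_un, corrected = rep_co))
}

#' Fit and apply in one step
#'
#' @inheritParams run_fit
#' @return Corrected cube paths, invisibly.
#' @export
run_correct <- function(config) {
  cfg <- if (inherits(config, "brdf_config")) config
         else read_run_config(config)
  model <- run_fit(cfg)
  run_apply(cfg, model = model)
}

#' Generate a synthetic flight box on disk
#'
#' Writes one reflectance cube and one 10-layer observation file per
#' synthetic line, a truth sidecar (JSON), and a ready-to-run config
#' (`run_config.yaml`) listing the files.
#'
#' @param spec A [synth_spec()] (or a list of its arguments).
#' @param out_dir Destination directory.
#' @return Path to the written run config, invisibly.
#' @export
run_synth <- function(spec = synth_spec(), out_dir) {
  if (!inherits(spec, "synth_spec")) spec <- do.call(synth_spec, spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grp <- generate_group(spec)
  lines_cfg <- list()
  for (i in seq_along(grp$lines)) {
    rp <- file.path(out_dir, sprintf("line%02d_refl", i))
    op <- file.path(out_dir, sprintf("line%02d_obs", i))
    write_cube(grp$lines[[i]]$cube, rp)
    write_observation(grp$lines[[i]]$obs, op)
    lines_cfg[[i]] <- list(reflectance = basename(rp),
                           observation = basename(op))
  }
  truth <- grp$truth
  jsonlite::write_json(
    list(format = "brdfcorr-truth", seed = truth$seed,
         wavelengths = truth$wavelengths,
         bin_edges = truth$bins$edges, bin_centers = truth$bins$centers,
         coefficients = as.vector(truth$coefficients),
         coefficients_dim = dim(truth$coefficients),
         offsets = truth$offsets, solar_zenith = truth$solar_zenith,
         solar_azimuth = truth$solar_azimuth,
         pooled_solar_zenith = truth$pooled_solar_zenith,
         c_truth = truth$c_truth),
    file.path(out_dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- list(io = list(lines = lines_cfg, output_dir = "out"),
              topo = list(enabled = !identical(spec$terrain, "flat")),
              bins = list(mode = "static", n = spec$bins$n_bins),
              sampling = list(per_bin = 10000, seed = spec$seed))
  cfg_path <- file.path(out_dir, "run_config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
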