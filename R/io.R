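# ThunderSTORM-dialect column mapping: internal snake_case <-> bracketed
# unit headers.
ts_dialect <- c(
  frame = "frame",
  x_nm = "x [nm]",
  y_nm = "y [nm]",
  z_nm = "z [nm]",
  sigma_x = "sigma1 [nm]",
  sigma_y = "sigma2 [nm]",
  photons = "intensity [photon]",
  background = "offset [photon]",
  uncertainty_xy = "uncertainty_xy [nm]",
  uncertainty_z = "uncertainty_z [nm]")

#' Write a localization table as CSV
#'
#' `dialect = "thunderstorm"` emits the bracketed-unit headers
#' (`"x [nm]"`, `"sigma1 [nm]"`, `"intensity [photon]"`, ...) with quoted
#' header fields; columns without a dialect equivalent (volume, plane,
#' valid, ...) keep their internal names. `dialect = "internal"` writes
#' snake_case headers unchanged.
#'
#' @param table Localization table.
#' @param path Output path.
#' @param dialect `"thunderstorm"` or `"internal"`.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path,
                                dialect = c("thunderstorm", "internal")) {
  dialect <- match.arg(dialect)
  out <- as.data.frame(table)
  if (dialect == "thunderstorm") {
    hit <- names(out) %in% names(ts_dialect)
    names(out)[hit] <- ts_dialect[names(out)[hit]]
  }
  # quote every header field (the dialect convention); data rows plain
  hdr <- paste(sprintf('"%s"', names(out)), collapse = ",")
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  readr::write_csv(out, path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' Read a localization table from CSV
#'
#' Accepts the bracketed-header dialect or internal snake_case headers and
#' maps both onto the internal schema. Unrecognized extra columns are kept
#' unchanged. The mandatory columns are `frame`, `x [nm]`/`x_nm` and
#' `y [nm]`/`y_nm`.
#'
#' @param path CSV path.
#' @param dialect `"auto"` (default), `"thunderstorm"` or `"internal"`.
#' @return Localization tibble.
#' @export
read_localizations <- function(path,
                               dialect = c("auto", "thunderstorm",
                                           "internal")) {
  dialect <- match.arg(dialect)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect %in% c("auto", "thunderstorm")) {
    rev_map <- setNames(names(ts_dialect), ts_dialect)
    hit <- names(tab) %in% names(rev_map)
    names(tab)[hit] <- rev_map[names(tab)[hit]]
  }
  for (col in c("frame", "x_nm", "y_nm")) {
    if (!col %in% names(tab)) {
      rlang::abort(sprintf("missing mandatory column `%s`", col),
                   class = "sheetloc_format_error")
    }
  }
  tab
}

# Recognized configuration schema (nested key names).
config_schema <- list(
  optics = c("wavelength_nm", "na_inner", "na_outer", "sheet_length_um",
             "scan_angle_deg"),
  camera = c("pixel_size_nm", "gain", "offset", "read_noise", "qe"),
  detection = c("filter_scale", "threshold_k", "roi_half",
                "max_uncertainty_xy", "sigma_bounds"),
  simulate = c("kind", "n_planes", "n_volumes", "scan_step_nm", "exposure_s",
               "n_x", "n_y", "background", "k_on", "k_off", "k_bleach",
               "photons_per_frame", "photon_dispersion", "sidelobe_fraction",
               "structure"),
  calibration = c("sigma0", "focus", "depth", "a3", "a4", "z_range",
                  "d_threshold"),
  drift = c("method", "link_radius", "smoothing_window", "block_frames"),
  frc = c("render_pixel", "n_splits", "threshold"),
  npc = c("enabled", "bin_pixel", "area_bounds", "roi_size", "n_top",
          "kde_grid"),
  render = c("pixel", "sigma_source", "fixed_sigma"),
  seeds = c("simulate", "frc"),
  paths = c("out_dir"))

#' Default pipeline configuration
#'
#' All the printed operating defaults in one place: 637 nm excitation
#' through a 0.42/0.50 annulus, 20 um sheet at 32.5 degrees, 102 nm camera
#' pixel, 10 nm NPC binning with the 250--300 px^2 area filter, 32 px ROI,
#' top-50 overlay, FRC threshold 1/7.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    optics = list(wavelength_nm = 637, na_inner = 0.42, na_outer = 0.50,
                  sheet_length_um = 20, scan_angle_deg = 32.5),
    camera = list(pixel_size_nm = 102, gain = 2.2, offset = 100,
                  read_noise = 3.5, qe = 1),
    detection = list(filter_scale = 1.3, threshold_k = 5, roi_half = 5,
                     max_uncertainty_xy = 50, sigma_bounds = c(40, 500)),
    simulate = list(kind = "npc_ring", n_planes = 1, n_volumes = 200,
                    scan_step_nm = 316, exposure_s = 0.02, n_x = 48,
                    n_y = 48, background = 5, k_on = 0.01256, k_off = 2.5,
                    k_bleach = 0, photons_per_frame = 1000,
                    photon_dispersion = 0, sidelobe_fraction = 0,
                    structure = list(n_pores = 12, ring_diameter = 100,
                                     sites_per_ring = 8,
                                     labeling_efficiency = 1)),
    calibration = list(sigma0 = c(150, 150), focus = c(-250, 250),
                       depth = c(400, 400), a3 = c(0, 0), a4 = c(0, 0),
                       z_range = c(-600, 600), d_threshold = 2),
    drift = list(method = "fiducial", link_radius = 500,
                 smoothing_window = 50, block_frames = 50),
    frc = list(render_pixel = 10, n_splits = 5, threshold = 1 / 7),
    npc = list(enabled = TRUE, bin_pixel = 10, area_bounds = c(250, 300),
               roi_size = 32, n_top = 50, kde_grid = 2),
    render = list(pixel = 20, sigma_source = "per_event", fixed_sigma = 20),
    seeds = list(simulate = 1, frc = 1),
    paths = list(out_dir = "sheetloc_out"))
}

#' Validate a pipeline configuration
#'
#' Checks every key (top-level and nested) against the known schema and
#' rejects unknown keys with a message naming them; fills omitted keys with
#' the defaults.
#'
#' @param config Nested list (e.g. from [read_config()]).
#' @return The merged, validated configuration.
#' @export
validate_config <- function(config) {
  if (is.null(config)) return(default_config())
  unknown_top <- setdiff(names(config), names(config_schema))
  if (length(unknown_top) > 0L) {
    rlang::abort(sprintf("unknown config section(s): %s",
                         paste(unknown_top, collapse = ", ")),
                 class = "sheetloc_config_error")
  }
  for (sec in names(config)) {
    unknown <- setdiff(names(config[[sec]]), config_schema[[sec]])
    if (length(unknown) > 0L) {
      rlang::abort(sprintf("unknown key(s) in `%s`: %s", sec,
                           paste(unknown, collapse = ", ")),
                   class = "sheetloc_config_error")
    }
  }
  utils::modifyList(default_config(), config)
}

#' Read and validate a YAML pipeline configuration
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}
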