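log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the end-to-end pipeline from a configuration
#'
#' Executes simulate -> localize -> filter -> drift correction -> deskew ->
#' render -> FRC -> NPC averaging as configured, writing every artifact
#' (tables as dialect CSV, stacks and renders as TIFF, curves as CSV, a run
#' log) into the output directory. Deterministic given the configured seeds.
#'
#' @param config Configuration list (see [default_config()]); validated
#'   before any computation.
#' @param out_dir Output directory (overrides `config$paths$out_dir`).
#' @param seed Optional override for all configured seeds.
#' @return Invisibly, a list with the principal results: `locs` (filtered
#'   localization table), `drift`, `frc` (accumulation tibble or NULL),
#'   `npc` (an `npc_average` or NULL), and `paths` of written artifacts.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) {
    cfg$seeds$simulate <- seed
    cfg$seeds$frc <- seed + 1
  }
  out_dir <- out_dir %||% cfg$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logf))

  log_line(logf, "camera pixel %g nm; sheet angle %g deg",
           cfg$camera$pixel_size_nm, cfg$optics$scan_angle_deg)
  log_line(logf,
           "npc: bin %g nm, area [%g, %g] px^2, roi %d px, top-%d; frc threshold %.4g",
           cfg$npc$bin_pixel, cfg$npc$area_bounds[1], cfg$npc$area_bounds[2],
           as.integer(cfg$npc$roi_size), as.integer(cfg$npc$n_top),
           cfg$frc$threshold)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line(logf, "stage `%s` failed: %s", name, conditionMessage(e))
      rlang::abort(sprintf("pipeline stage `%s` failed: %s", name,
                           conditionMessage(e)),
                   class = "sheetloc_pipeline_error")
    })
  }

  spec <- bessel_spec(cfg$optics$wavelength_nm, cfg$optics$na_inner,
                      cfg$optics$na_outer)
  fwhm <- sheet_thickness_fwhm(spec)
  log_line(logf, "sheet FWHM %.1f nm (NA %.2f-%.2f @ %g nm)", fwhm,
           cfg$optics$na_inner, cfg$optics$na_outer,
           cfg$optics$wavelength_nm)

  camera <- camera_model(cfg$camera$pixel_size_nm, cfg$camera$gain,
                         cfg$camera$offset, cfg$camera$read_noise,
                         cfg$camera$qe)
  calib <- astig_calibration(
    sigma0 = cfg$calibration$sigma0, focus = cfg$calibration$focus,
    depth = cfg$calibration$depth, a3 = cfg$calibration$a3,
    a4 = cfg$calibration$a4, z_range = cfg$calibration$z_range,
    d_threshold = cfg$calibration$d_threshold)

  sc <- cfg$simulate
  sim <- run_stage("simulate", {
    truth <- make_ground_truth(
      sc$kind, sc$structure,
      seed = cfg$seeds$simulate)
    fid <- make_ground_truth(
      "fiducial", list(n = 2, field = c(sc$n_x, sc$n_y) *
                         camera$pixel_size),
      seed = cfg$seeds$simulate + 1)
    fid$structure_id <- fid$structure_id + max(0, truth$structure_id)
    fid$emitter <- fid$emitter + nrow(truth)
    truth <- dplyr::bind_rows(truth, fid)
    # orient the generated (in-plane) structure into the tilted sheet:
    # generated x becomes the in-sheet tilt coordinate, generated z the
    # sheet-normal offset, so plane 0 sees the structure in focus
    th <- cfg$optics$scan_angle_deg * pi / 180
    x0 <- truth$x_nm
    truth$x_nm <- x0 * cos(th) - truth$z_nm * sin(th)
    truth$z_nm <- x0 * sin(th) + truth$z_nm * cos(th)
    geom <- acquisition_geometry(
      sheet_angle = cfg$optics$scan_angle_deg, scan_step = sc$scan_step_nm,
      n_planes = sc$n_planes, exposure = sc$exposure_s, sheet_fwhm = fwhm,
      sidelobe_fraction = sc$sidelobe_fraction, n_x = sc$n_x, n_y = sc$n_y)
    blink <- blinking_model(sc$k_on, sc$k_off, sc$k_bleach,
                            sc$photons_per_frame, sc$photon_dispersion)
    simulate_stack(truth, blink, camera, geom, calib,
                   seed = cfg$seeds$simulate, n_volumes = sc$n_volumes,
                   background = sc$background)
  })
  log_line(logf, "simulated %d volume(s), %d truth events",
           length(sim$volumes), nrow(sim$truth))
  write_stack_tiff(sim, file.path(out_dir, "stacks"))

  dp <- detection_params(cfg$detection$filter_scale, cfg$detection$threshold_k,
                         cfg$detection$roi_half,
                         cfg$detection$max_uncertainty_xy,
                         cfg$detection$sigma_bounds)
  locs <- run_stage("localize", {
    series <- transpose_to_time_series(sim$volumes)
    purrr::imap(series, function(stk, p) {
      tab <- localize_stack(stk, calib, camera, dp, mode = "timeseries",
                            plane = p - 1L)
      tab$frame <- tab$volume * sc$n_planes + (p - 1L)
      tab
    }) |> dplyr::bind_rows()
  })
  log_line(logf, "localized %d events", nrow(locs))
  write_localizations(locs, file.path(out_dir, "localizations_raw.csv"))

  locs <- filter_localizations(locs,
                               max_uncertainty_xy =
                                 cfg$detection$max_uncertainty_xy,
                               sigma_bounds = cfg$detection$sigma_bounds,
                               require_valid_z = TRUE)
  log_line(logf, "%d events after filtering", nrow(locs))

  drift <- run_stage("drift", {
    tr <- if (cfg$drift$method == "fiducial") {
      tryCatch(
        track_fiducials(locs, link_radius = cfg$drift$link_radius,
                        smoothing_window = cfg$drift$smoothing_window),
        error = function(e) NULL)
    } else {
      NULL
    }
    if (is.null(tr) && length(unique(locs$frame)) >=
          2 * cfg$drift$block_frames) {
      tr <- estimate_drift_xcorr(locs, cfg$drift$block_frames)
    }
    tr
  })
  if (!is.null(drift)) {
    locs <- apply_drift(locs, drift)
    readr::write_csv(as.data.frame(drift), file.path(out_dir, "drift.csv"))
    log_line(logf, "drift corrected (%s)", attr(drift, "method"))
  } else {
    log_line(logf, "drift correction skipped (no fiducials, too few blocks)")
  }

  locs <- deskew(locs, sheet_angle = cfg$optics$scan_angle_deg,
                 scan_step = sc$scan_step_nm)
  write_localizations(locs, file.path(out_dir, "localizations.csv"))

  dens <- render_density(locs, pixel = cfg$render$pixel,
                         sigma_source = cfg$render$sigma_source,
                         fixed_sigma = cfg$render$fixed_sigma)
  tiff::writeTIFF(dens / max(dens, 1e-12),
                  file.path(out_dir, "density.tif"), bits.per.sample = 32L)

  frc_tab <- run_stage("frc", {
    if (nrow(locs) >= 200 && length(unique(locs$volume)) >= 2) {
      nvol <- length(unique(locs$volume))
      ck <- unique(pmax(1, round(seq(nvol / 4, nvol, length.out = 4))))
      out <- frc_vs_accumulation(locs, checkpoints = ck,
                                 render_pixel = cfg$frc$render_pixel,
                                 n_splits = cfg$frc$n_splits,
                                 seed = cfg$seeds$frc)
      readr::write_csv(out, file.path(out_dir, "frc_accumulation.csv"))
      out
    } else {
      NULL
    }
  })

  npc_res <- NULL
  if (isTRUE(cfg$npc$enabled) && sc$kind == "npc_ring") {
    npc_res <- run_stage("npc", {
      np <- npc_params(bin_pixel = cfg$npc$bin_pixel,
                       area_bounds = cfg$npc$area_bounds,
                       roi_size = cfg$npc$roi_size, n_top = cfg$npc$n_top,
                       kde_grid = cfg$npc$kde_grid)
      res <- tryCatch(npc_average(locs, np), error = function(e) NULL)
      if (!is.null(res)) {
        readr::write_csv(
          dplyr::select(res$candidates, -crop),
          file.path(out_dir, "npc_candidates.csv"))
        ov <- res$overlay
        tiff::writeTIFF(ov / max(ov, 1e-12),
                        file.path(out_dir, "npc_overlay.tif"),
                        bits.per.sample = 32L)
        log_line(logf, "npc diameter %.1f nm from %d candidates",
                 res$diameter_nm, nrow(res$candidates))
      }
      res
    })
  }

  invisible(list(locs = locs, drift = drift, frc = frc_tab, npc = npc_res,
                 paths = list(out_dir = out_dir)))
}
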