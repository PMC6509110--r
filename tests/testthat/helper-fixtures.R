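# Shared fixtures, built in code.

# Reference astigmatic calibration used across simulation tests: x focus
# below, y focus above the sheet plane, fairly strong cylindrical lens
# (depth 250 nm) so widths encode z tightly, quartic corrections off.
ref_calibration <- function(d_threshold = 2) {
  astig_calibration(sigma0 = c(130, 130), focus = c(-200, 200),
                    depth = c(250, 250), z_range = c(-600, 600),
                    d_threshold = d_threshold)
}

# Calibration with the PSF symmetric at the sheet plane (focal planes only
# +-50 nm out), for photon-scaling benchmarks at w = 0.
benchmark_calibration <- function() {
  astig_calibration(sigma0 = c(130, 130), focus = c(-50, 50),
                    depth = c(250, 250), z_range = c(-600, 600))
}

# Noise-free bead observations from a known calibration.
bead_obs_from <- function(calib, z = seq(-600, 600, by = 40)) {
  s <- sigma_at_z(calib, z)
  data.frame(z = z, sigma_x = s$sigma_x, sigma_y = s$sigma_y)
}

# Event cloud for one ring-shaped pore candidate rendered with the
# blurred-ring profile (for self-consistency donut tests).
render_donut_image <- function(r0 = 50, sr = 15, size = 32L, pixel = 10,
                               amplitude = 100, offset = 0,
                               center = NULL,
                               profile = "blurred_ring") {
  center <- center %||% c(size / 2 * pixel, size / 2 * pixel)
  xg <- (seq_len(size) - 0.5) * pixel
  yg <- (seq_len(size) - 0.5) * pixel
  r <- sqrt(outer((yg - center[2])^2, (xg - center[1])^2, "+"))
  amplitude * donut_profile(r, r0, sr, profile) + offset
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force 8-connected component labeling (flood fill); the oracle for
# candidate-selection area tests.
bf_label8 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0L) {
      p <- queue[[1]]; queue <- queue[-1]
      i <- (p - 1L) %% ny + 1L
      j <- (p - 1L) %/% ny + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1L || ii > ny || jj < 1L || jj > nx) next
        q <- (jj - 1L) * ny + ii
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# One-emitter camera frame via the image simulator (noise optional).
single_emitter_frame <- function(photons = 1000, u = 2000, v = 2000, w = 0,
                                 n_px = 40, cam = camera_model(),
                                 cal = ref_calibration(), noise = TRUE,
                                 seed = 1, background = 5) {
  th <- 32.5 * pi / 180
  gt <- tibble::tibble(emitter = 1L, structure_id = 1L, kind = "fiducial",
                       always_on = TRUE,
                       x_nm = u * cos(th) - w * sin(th),
                       y_nm = v, z_nm = u * sin(th) + w * cos(th))
  geom <- acquisition_geometry(n_planes = 1, n_x = n_px, n_y = n_px)
  sim <- simulate_stack(gt, blinking_model(photons_per_frame_mean = photons),
                        cam, geom, cal, seed = seed, noise = noise,
                        background = background)
  list(img = sim$volumes[[1]][1, , ], truth = sim$truth)
}

# Monte-Carlo lateral RMSE of the localizer at photon count N.
mc_rmse <- function(N, cam, cal, bg, n_mc = 60) {
  errs <- vapply(seq_len(n_mc), function(s) {
    fr <- single_emitter_frame(photons = N, seed = s, background = bg,
                               cam = cam, cal = cal)
    locs <- localize_stack(fr$img, cal, cam, detection_params())
    if (nrow(locs) == 0) return(NA_real_)
    i <- which.min((locs$x_nm - fr$truth$x_nm)^2 +
                   (locs$y_nm - fr$truth$y_nm)^2)
    sqrt(((locs$x_nm[i] - fr$truth$x_nm)^2 +
          (locs$y_nm[i] - fr$truth$y_nm)^2) / 2)
  }, numeric(1))
  errs <- errs[!is.na(errs)]
  c(rmse = sqrt(mean(errs^2)), n = length(errs))
}

# Filament-structure event tables with given per-event precision.
filament_events <- function(n_events = 8000, precision = 20, seed = 1,
                            n_volumes = 1) {
  gt <- make_ground_truth(
    "filament",
    list(control_points = rbind(c(500, 2500, 0), c(2500, 500, 0),
                                c(4500, 2500, 0), c(2500, 4500, 0)),
         density_per_um = 400), seed = seed)
  ev <- simulate_localization_events(
    gt, events_per_emitter = ceiling(n_events / max(nrow(gt), 1)),
    precision_nm = precision, n_frames = 100 * n_volumes, seed = seed + 7)
  ev$volume <- floor(ev$frame / 100)
  ev
}

# Ring-pore field event tables; event counts sized so dilated clusters land
# in the 250-300 px^2 selection window at 10 nm binning.
npc_events <- function(n_pores = 100, diameter = 100, precision = 40,
                       events_per_site = 8, seed = 1,
                       field = c(12000, 12000)) {
  gt <- make_ground_truth(
    "npc_ring",
    list(n_pores = n_pores, ring_diameter = diameter, sites_per_ring = 8,
         labeling_efficiency = 1, field = field, min_spacing = 500),
    seed = seed)
  simulate_localization_events(gt, events_per_emitter = events_per_site,
                               precision_nm = precision, n_frames = 2000,
                               seed = seed + 1000)
}

# Fiducial-bearing localization tables at the event level.
fiducial_table <- function(n_fid = 3, n_frames = 400, precision = 10,
                           drift_per_frame = c(0, 0, 0), seed = 1) {
  gt <- make_ground_truth("fiducial", list(n = n_fid,
                                           field = c(8000, 8000)),
                          seed = seed)
  simulate_localization_events(gt, precision_nm = precision,
                               n_frames = n_frames, seed = seed + 100,
                               drift_per_frame = drift_per_frame)
}
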