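#' Blinking-fluorophore kinetic model
#'
#' Two-state (on/off) kinetics with an absorbing bleached state, describing
#' spontaneously blinking dyes that cycle between fluorescent and dark forms
#' by thermal equilibrium (no activation laser). The stationary duty cycle is
#' `k_on / (k_on + k_off)`.
#'
#' Defaults describe a low-duty-cycle spontaneous blinker: mean on-time
#' 400 ms (`k_off` = 2.5/s, long against the 20 ms frame so that frame
#' discretization of the chain is faithful), duty cycle 5e-3, 1000 detected
#' photons per on frame. Photon budgets are quoted as detected photons.
#'
#' @param k_on Off-to-on rate, 1/s.
#' @param k_off On-to-off rate, 1/s.
#' @param k_bleach On-to-bleached rate, 1/s (absorbing).
#' @param photons_per_frame_mean Mean detected photons emitted per on frame.
#' @param photon_dispersion Coefficient of variation of the per-frame photon
#'   count (0 = deterministic; gamma-distributed otherwise).
#' @return Object of class `blinking_model`.
#' @export
blinking_model <- function(k_on = 0.01256, k_off = 2.5, k_bleach = 0,
                           photons_per_frame_mean = 1000,
                           photon_dispersion = 0) {
  check_number(k_on, "k_on", min = 0)
  check_number(k_off, "k_off", min = 0)
  check_number(k_bleach, "k_bleach", min = 0)
  check_number(photons_per_frame_mean, "photons_per_frame_mean", min = 0,
               strict_min = TRUE)
  check_number(photon_dispersion, "photon_dispersion", min = 0)
  structure(
    list(k_on = k_on, k_off = k_off, k_bleach = k_bleach,
         photons_per_frame_mean = photons_per_frame_mean,
         photon_dispersion = photon_dispersion),
    class = "blinking_model")
}

#' Duty cycle of a blinking model
#' @param model A [blinking_model()].
#' @return `k_on / (k_on + k_off)`.
#' @export
duty_cycle <- function(model) {
  stopifnot(inherits(model, "blinking_model"))
  if (model$k_on + model$k_off == 0) return(0)
  model$k_on / (model$k_on + model$k_off)
}

#' sCMOS camera model
#'
#' @param pixel_size Image-plane pixel size in nm (default 102).
#' @param gain Counts per detected photon.
#' @param offset Dark offset in counts.
#' @param read_noise Read noise RMS in counts.
#' @param qe Quantum efficiency in (0, 1]. Photon inputs elsewhere in the
#'   package are quoted as detected photons, so the default is 1.
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(pixel_size = 102, gain = 2.2, offset = 100,
                         read_noise = 3.5, qe = 1) {
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  check_number(gain, "gain", min = 0, strict_min = TRUE)
  check_number(offset, "offset", min = 0)
  check_number(read_noise, "read_noise", min = 0)
  check_number(qe, "qe", min = 0, max = 1, strict_min = TRUE)
  structure(list(pixel_size = pixel_size, gain = gain, offset = offset,
                 read_noise = read_noise, qe = qe),
            class = "camera_model")
}

#' Sample-scan acquisition geometry
#'
#' The light sheet meets the coverslip at `sheet_angle` degrees; the sample
#' is scanned through the static sheet in steps of `scan_step` nm per plane.
#' `sheet_fwhm` is the optical-sectioning thickness (from
#' [sheet_thickness_fwhm()]); `sidelobe_fraction` > 0 adds Bessel side-lobe
#' excitation replicas at `+/- sidelobe_offset` nm from the sheet plane.
#'
#' @param sheet_angle Degrees in (0, 90); default 32.5.
#' @param scan_step nm per plane; default 316 (0.17 um z interval / sin 32.5).
#' @param n_planes Planes per volume.
#' @param exposure Seconds per plane (default 0.02).
#' @param sheet_fwhm Sheet thickness FWHM in nm (default 500).
#' @param sidelobe_fraction Relative peak intensity of side-lobe replicas
#'   (default 0 = pure Gaussian sheet).
#' @param sidelobe_offset Side-lobe distance from the sheet plane in nm.
#' @param n_x,n_y Camera frame size in pixels.
#' @return Object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(sheet_angle = 32.5, scan_step = 316,
                                 n_planes = 1L, exposure = 0.02,
                                 sheet_fwhm = 500, sidelobe_fraction = 0,
                                 sidelobe_offset = 850,
                                 n_x = 64L, n_y = 64L) {
  check_number(sheet_angle, "sheet_angle", min = 0, max = 90,
               strict_min = TRUE)
  check_number(scan_step, "scan_step", min = 0, strict_min = TRUE)
  check_number(n_planes, "n_planes", min = 1)
  check_number(sheet_fwhm, "sheet_fwhm", min = 0, strict_min = TRUE)
  check_number(sidelobe_fraction, "sidelobe_fraction", min = 0)
  structure(
    list(sheet_angle = sheet_angle, scan_step = scan_step,
         n_planes = as.integer(n_planes), exposure = exposure,
         sheet_fwhm = sheet_fwhm, sidelobe_fraction = sidelobe_fraction,
         sidelobe_offset = sidelobe_offset,
         n_x = as.integer(n_x), n_y = as.integer(n_y)),
    class = "acquisition_geometry")
}

#' Generate ground-truth emitter sets
#'
#' Places emitters exactly on the requested structure geometry; localization
#' noise enters only downstream (PSF fitting on noisy images).
#'
#' Structure kinds and their parameters:
#' \describe{
#'   \item{`filament`}{`control_points` (matrix with columns x, y, z in nm)
#'     and `density_per_um` (linear labeling density). The emitter count is
#'     Poisson with mean density x length; emitters are uniform along the
#'     polyline's arclength.}
#'   \item{`npc_ring`}{`n_pores`, `ring_diameter` (nm, default 100),
#'     `sites_per_ring` (default 8, the eight-fold pore symmetry),
#'     `labeling_efficiency` (per-site Bernoulli, default 1), `field`
#'     (c(x, y) extent in nm), `z` (ring plane, default 0), `min_spacing`
#'     (nm between pore centers, default 300). Sites sit on a circle of
#'     radius `ring_diameter/2` at a random phase per pore.}
#'   \item{`fiducial`}{`n`, `field`, `z_range`; emitters marked `always_on`.}
#' }
#'
#' @param kind One of `"filament"`, `"npc_ring"`, `"fiducial"`.
#' @param params Named list of structure parameters (see Details).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return Tibble (class `emitter_set`) with columns `emitter`,
#'   `structure_id`, `kind`, `always_on`, `x_nm`, `y_nm`, `z_nm`.
#' @export
make_ground_truth <- function(kind, params = list(), seed = 1L) {
  kinds <- c("filament", "npc_ring", "fiducial")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds)) {
    stop_invalid(sprintf("unknown structure kind; must be one of %s",
                         paste(kinds, collapse = ", ")))
  }
  empty <- tibble::tibble(
    emitter = integer(), structure_id = integer(),
    kind = character(), always_on = logical(),
    x_nm = numeric(), y_nm = numeric(), z_nm = numeric())
  out <- with_seed(seed, {
    switch(kind,
      filament = {
        cp <- params$control_points %||%
          rbind(c(500, 500, 0), c(5500, 5500, 0))
        cp <- as.matrix(cp)
        if (ncol(cp) == 2L) cp <- cbind(cp, 0)
        dens <- params$density_per_um %||% 50
        n_fil <- params$n_structures %||% 1L
        if (n_fil == 0L) empty else {
          segs <- diff(cp)
          seglen <- sqrt(rowSums(segs^2))
          L <- sum(seglen)
          purrr::map(seq_len(n_fil), function(s) {
            off <- if (n_fil > 1L) {
              c(runif(1, 0, params$field[1] %||% 0),
                runif(1, 0, params$field[2] %||% 0), 0)
            } else c(0, 0, 0)
            n <- rpois(1, dens * L / 1000)
            if (n == 0L) return(NULL)
            t_arc <- runif(n, 0, L)
            cum <- c(0, cumsum(seglen))
            seg <- findInterval(t_arc, cum, rightmost.closed = TRUE)
            frac <- (t_arc - cum[seg]) / seglen[seg]
            pos <- cp[seg, , drop = FALSE] + segs[seg, , drop = FALSE] * frac
            tibble::tibble(structure_id = s, x_nm = pos[, 1] + off[1],
                           y_nm = pos[, 2] + off[2], z_nm = pos[, 3] + off[3])
          }) |> dplyr::bind_rows()
        }
      },
      npc_ring = {
        n_pores <- params$n_pores %||% 0L
        if (n_pores == 0L) empty else {
          dia <- params$ring_diameter %||% 100
          k <- params$sites_per_ring %||% 8L
          eff <- params$labeling_efficiency %||% 1
          field <- params$field %||% c(4000, 4000)
          zpl <- params$z %||% 0
          minsp <- params$min_spacing %||% 300
          centers <- matrix(NA_real_, 0, 2)
          tries <- 0L
          while (nrow(centers) < n_pores && tries < 20000L) {
            cand <- c(runif(1, dia, field[1] - dia),
                      runif(1, dia, field[2] - dia))
            ok <- nrow(centers) == 0L ||
              all(sqrt((centers[, 1] - cand[1])^2 +
                       (centers[, 2] - cand[2])^2) >= minsp)
            if (ok) centers <- rbind(centers, cand)
            tries <- tries + 1L
          }
          if (nrow(centers) < n_pores) {
            rlang::warn("could not place all pores at the requested spacing")
          }
          purrr::map(seq_len(nrow(centers)), function(s) {
            phase <- runif(1, 0, 2 * pi)
            th <- phase + 2 * pi * (seq_len(k) - 1L) / k
            lab <- runif(k) <= eff
            if (!any(lab)) return(NULL)
            tibble::tibble(
              structure_id = s,
              x_nm = centers[s, 1] + dia / 2 * cos(th[lab]),
              y_nm = centers[s, 2] + dia / 2 * sin(th[lab]),
              z_nm = zpl)
          }) |> dplyr::bind_rows()
        }
      },
      fiducial = {
        n <- params$n %||% 0L
        if (n == 0L) empty else {
          field <- params$field %||% c(6000, 6000)
          zr <- params$z_range %||% c(0, 0)
          tibble::tibble(
            structure_id = seq_len(n),
            x_nm = runif(n, 0.1 * field[1], 0.9 * field[1]),
            y_nm = runif(n, 0.1 * field[2], 0.9 * field[2]),
            z_nm = runif(n, zr[1], zr[2]))
        }
      })
  })
  if (nrow(out) == 0L) return(empty)
  out <- dplyr::mutate(out,
    emitter = dplyr::row_number(),
    kind = kind,
    always_on = kind == "fiducial")
  out <- dplyr::select(out, emitter, structure_id, kind, always_on,
                       x_nm, y_nm, z_nm)
  class(out) <- c("emitter_set", class(out))
  out
}

#' Simulate blinking state traces and per-frame photon counts
#'
#' Discretizes the continuous-time on/off/bleached chain at frame resolution:
#' per-frame transition probabilities are `1 - exp(-k * exposure)`; sub-frame
#' partial on-times are ignored (frames are long compared to switching
#' transients). Initial states are drawn from the on/off stationary
#' distribution so short traces are unbiased.
#'
#' @param model A [blinking_model()].
#' @param n_emitters Number of emitters.
#' @param n_frames Number of frames (>= 1).
#' @param exposure Frame time in seconds.
#' @param seed Integer seed.
#' @param always_on Logical vector (length 1 or `n_emitters`); such emitters
#'   (fiducials) are on in every frame and never bleach.
#' @return List with integer matrix `states` (`n_emitters` x `n_frames`;
#'   0 = off, 1 = on, 2 = bleached) and numeric matrix `photons`.
#' @export
simulate_blinking_trace <- function(model, n_emitters, n_frames, exposure,
                                    seed = 1L, always_on = FALSE) {
  stopifnot(inherits(model, "blinking_model"))
  check_number(n_frames, "n_frames", min = 1)
  check_number(n_emitters, "n_emitters", min = 0)
  n_emitters <- as.integer(n_emitters)
  n_frames <- as.integer(n_frames)
  always_on <- rep_len(always_on, max(n_emitters, 1L))
  p_on <- 1 - exp(-model$k_on * exposure)
  p_off <- 1 - exp(-model$k_off * exposure)
  p_bleach <- 1 - exp(-model$k_bleach * exposure)
  dc <- duty_cycle(model)
  with_seed(seed, {
    states <- matrix(0L, n_emitters, n_frames)
    if (n_emitters > 0L) {
      s <- ifelse(always_on, 1L, ifelse(runif(n_emitters) < dc, 1L, 0L))
      for (f in seq_len(n_frames)) {
        u <- runif(n_emitters)
        on <- s == 1L & !always_on
        off <- s == 0L & !always_on
        s_new <- s
        # on-state: bleaching takes precedence over switching off
        s_new[on & u < p_bleach] <- 2L
        s_new[on & u >= p_bleach & u < p_bleach + (1 - p_bleach) * p_off] <- 0L
        s_new[off & u < p_on] <- 1L
        states[, f] <- s
        s <- s_new
      }
    }
    photons <- matrix(0, n_emitters, n_frames)
    on_idx <- states == 1L
    n_on <- sum(on_idx)
    if (n_on > 0L) {
      mu <- model$photons_per_frame_mean
      cv <- model$photon_dispersion
      photons[on_idx] <- if (cv > 0) {
        rgamma(n_on, shape = 1 / cv^2, scale = mu * cv^2)
      } else {
        mu
      }
    }
    list(states = states, photons = photons)
  })
}

# Excitation weight at sheet-normal offset w (nm): Gaussian main lobe of the
# given FWHM, plus optional side-lobe replicas.
sheet_weight <- function(w, fwhm, sidelobe_fraction = 0, sidelobe_offset = 850) {
  g <- function(d) exp(-4 * log(2) * (d / fwhm)^2)
  wt <- g(w)
  if (sidelobe_fraction > 0) {
    wt <- wt + sidelobe_fraction * (g(w - sidelobe_offset) +
                                    g(w + sidelobe_offset))
  }
  wt
}

# Render one integrated-Gaussian PSF into `img` (photons units), in place.
# x, y in nm; sx, sy in nm; a = pixel size nm. Returns modified img.
add_psf <- function(img, x, y, sx, sy, photons, a) {
  ny <- nrow(img); nx <- ncol(img)
  cx <- x / a; cy <- y / a # in pixel units, pixel j covers [j-1, j)
  rx <- ceiling(4 * sx / a) + 1L
  ry <- ceiling(4 * sy / a) + 1L
  j0 <- max(1L, floor(cx) - rx); j1 <- min(nx, floor(cx) + rx + 1L)
  i0 <- max(1L, floor(cy) - ry); i1 <- min(ny, floor(cy) + ry + 1L)
  if (j0 > j1 || i0 > i1) return(img)
  ex <- pnorm(((j0:j1) * a - x) / sx) - pnorm((((j0:j1) - 1L) * a - x) / sx)
  ey <- pnorm(((i0:i1) * a - y) / sy) - pnorm((((i0:i1) - 1L) * a - y) / sy)
  img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + photons * (ey %o% ex)
  img
}

#' Simulate a sample-scan acquisition
#'
#' Generates camera frame stacks and the matching ground-truth event table
#' for emitters in the coverslip (sample) frame. For plane `p` of each
#' volume the sample has moved `p * scan_step` nm along the scan axis; each
#' emitter's in-sheet coordinates `(u, v)` and sheet-normal offset `w` are
#' obtained from the tilted-sheet geometry, the excitation weight follows the
#' sheet profile at `w`, and on-state emitters render an elliptical Gaussian
#' whose widths come from the astigmatic calibration evaluated at `w`.
#' Pixel values follow the sCMOS model
#' `round(gain * Poisson(qe * photons + background) + Normal(0, read_noise) + offset)`.
#'
#' @param truth An `emitter_set` from [make_ground_truth()] (positions in the
#'   sample frame, nm).
#' @param blink A [blinking_model()].
#' @param camera A [camera_model()].
#' @param geom An [acquisition_geometry()].
#' @param calib An [astig_calibration()] supplying the width model.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param n_volumes Number of repeated volume sweeps (global frame index is
#'   `volume * n_planes + plane`).
#' @param background Background level, photons/pixel/frame.
#' @param noise Logical; when FALSE the stack is the noiseless expected image
#'   `gain * qe * photons + offset` (float, no rounding, no background).
#' @param drift_per_frame Length-3 nm/frame rigid drift added to the in-sheet
#'   coordinates (u, v, w) at each global frame.
#' @param min_weight Events with excitation weight below this are not
#'   rendered or listed (default 1e-3).
#' @return Object of class `sim_stack`: list with `volumes` (list of
#'   `(plane, y, x)` arrays in camera counts), `truth` (tibble: volume,
#'   plane, frame, emitter, structure_id, x_nm, y_nm, z_nm, photons,
#'   sheet_weight, side_lobe), and the model objects.
#' @export
simulate_stack <- function(truth, blink = blinking_model(),
                           camera = camera_model(), geom, calib,
                           seed = 1L, n_volumes = 1L, background = 5,
                           noise = TRUE, drift_per_frame = c(0, 0, 0),
                           min_weight = 1e-3) {
  stopifnot(inherits(geom, "acquisition_geometry"),
            inherits(calib, "astig_calibration"),
            inherits(camera, "camera_model"))
  n_volumes <- as.integer(n_volumes)
  n_frames <- n_volumes * geom$n_planes
  n_em <- nrow(truth)
  theta <- geom$sheet_angle * pi / 180
  ct <- cos(theta); st <- sin(theta)
  a <- camera$pixel_size

  trace <- simulate_blinking_trace(
    blink, n_em, n_frames, geom$exposure, seed = seed,
    always_on = if (n_em > 0L) truth$always_on else FALSE)

  volumes <- vector("list", n_volumes)
  events <- vector("list", n_frames)
  any_seen <- FALSE

  with_seed(seed + 1L, {
    for (v in seq_len(n_volumes) - 1L) {
      stack <- array(0, dim = c(geom$n_planes, geom$n_y, geom$n_x))
      for (p in seq_len(geom$n_planes) - 1L) {
        f <- v * geom$n_planes + p # global 0-based frame
        img <- matrix(0, geom$n_y, geom$n_x)
        if (n_em > 0L) {
          xs <- truth$x_nm - p * geom$scan_step
          u <- xs * ct + truth$z_nm * st + drift_per_frame[1] * f
          w <- -xs * st + truth$z_nm * ct + drift_per_frame[3] * f
          vv <- truth$y_nm + drift_per_frame[2] * f
          wt <- sheet_weight(w, geom$sheet_fwhm, geom$sidelobe_fraction,
                             geom$sidelobe_offset)
          on <- trace$states[, f + 1L] == 1L & wt >= min_weight
          if (any(on)) {
            any_seen <- TRUE
            idx <- which(on)
            sig <- sigma_at_z(calib, w[idx])
            ph <- trace$photons[idx, f + 1L] * wt[idx]
            for (j in seq_along(idx)) {
              img <- add_psf(img, u[idx[j]], vv[idx[j]],
                             sig$sigma_x[j], sig$sigma_y[j], ph[j], a)
            }
            main_wt <- exp(-4 * log(2) * (w[idx] / geom$sheet_fwhm)^2)
            events[[f + 1L]] <- tibble::tibble(
              volume = v, plane = p, frame = f,
              emitter = truth$emitter[idx],
              structure_id = truth$structure_id[idx],
              x_nm = u[idx], y_nm = vv[idx], z_nm = w[idx],
              photons = ph, sheet_weight = wt[idx],
              side_lobe = main_wt / wt[idx] < 0.5)
          }
        }
        if (noise) {
          counts <- round(
            camera$gain *
              rpois(length(img), camera$qe * img + background) +
            rnorm(length(img), 0, camera$read_noise) + camera$offset)
          stack[p + 1L, , ] <- matrix(pmin(pmax(counts, 0), 65535),
                                      geom$n_y, geom$n_x)
        } else {
          stack[p + 1L, , ] <- camera$gain * camera$qe * img + camera$offset
        }
      }
      volumes[[v + 1L]] <- stack
    }
  })

  if (n_em > 0L && !any_seen) {
    rlang::warn("no emitters were excited inside the scanned slab")
  }
  truth_tbl <- dplyr::bind_rows(events)
  if (nrow(truth_tbl) == 0L) {
    truth_tbl <- tibble::tibble(
      volume = integer(), plane = integer(), frame = integer(),
      emitter = integer(), structure_id = integer(),
      x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
      photons = numeric(), sheet_weight = numeric(), side_lobe = logical())
  }
  structure(
    list(volumes = volumes, truth = truth_tbl, geom = geom, camera = camera,
         calib = calib, blink = blink, background = background, seed = seed),
    class = "sim_stack")
}

#' @export
print.sim_stack <- function(x, ...) {
  d <- dim(x$volumes[[1]])
  cat(sprintf(
    "<sim_stack> %d volume(s) of %d plane(s) %dx%d px; %d truth events\n",
    length(x$volumes), d[1], d[2], d[3], nrow(x$truth)))
  invisible(x)
}

#' Write a simulated acquisition to 16-bit TIFF stacks + truth CSV
#'
#' One multi-page grayscale TIFF per volume (`volume_000.tif`, ...), plus
#' `truth.csv` with the ground-truth event table.
#'
#' @param sim A `sim_stack`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of TIFF paths.
#' @export
write_stack_tiff <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(sim$volumes))
  for (v in seq_along(sim$volumes)) {
    stack <- sim$volumes[[v]]
    pages <- lapply(seq_len(dim(stack)[1]),
                    function(p) stack[p, , ] / 65535)
    paths[v] <- file.path(dir, sprintf("volume_%03d.tif", v - 1L))
    tiff::writeTIFF(pages, paths[v], bits.per.sample = 16L,
                    compression = "none")
  }
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  invisible(paths)
}

#' Read a TIFF stack as a (plane, y, x) array of counts
#'
#' @param path Multi-page grayscale TIFF.
#' @return Numeric array `(plane, y, x)` in camera counts (16-bit scale).
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  stack <- array(0, dim = c(length(pages), nrow(pages[[1]]),
                            ncol(pages[[1]])))
  for (p in seq_along(pages)) stack[p, , ] <- pages[[p]] * 65535
  stack
}

#' Simulate localization events directly from ground truth
#'
#' Event-level shortcut past the image pipeline: each ground-truth emitter
#' produces a Poisson number of blinking events, each localized with
#' isotropic Gaussian error of the given precision. Useful for studying the
#' post-localization stages (drift, rendering, FRC, particle averaging)
#' under controlled precision and event counts.
#'
#' @param truth An `emitter_set` from [make_ground_truth()].
#' @param events_per_emitter Mean number of registered events per emitter.
#' @param precision_nm Per-axis localization precision (std dev, nm); also
#'   recorded in `uncertainty_xy`.
#' @param n_frames Frames over which events are spread uniformly.
#' @param seed Integer seed.
#' @param drift_per_frame Length-2 (or 3) nm/frame linear drift added at
#'   each event's frame.
#' @return Localization-table tibble: `frame`, `x_nm`, `y_nm`, `z_nm`,
#'   `structure_id`, `emitter`, `photons`, `uncertainty_xy`, `volume`
#'   (frame alias for accumulation analyses), `plane` (0).
#' @export
simulate_localization_events <- function(truth, events_per_emitter = 30,
                                         precision_nm = 20,
                                         n_frames = 1000L, seed = 1L,
                                         drift_per_frame = c(0, 0, 0)) {
  drift_per_frame <- rep_len(drift_per_frame, 3)
  with_seed(seed, {
    n_ev <- rpois(nrow(truth), events_per_emitter)
    n_ev[truth$always_on] <- n_frames
    idx <- rep(seq_len(nrow(truth)), n_ev)
    n <- length(idx)
    frame <- ifelse(rep(truth$always_on, n_ev),
                    sequence(n_ev) - 1L,
                    sample.int(n_frames, n, replace = TRUE) - 1L)
    tibble::tibble(
      frame = as.integer(frame),
      x_nm = truth$x_nm[idx] + rnorm(n, 0, precision_nm) +
        drift_per_frame[1] * frame,
      y_nm = truth$y_nm[idx] + rnorm(n, 0, precision_nm) +
        drift_per_frame[2] * frame,
      z_nm = truth$z_nm[idx] + rnorm(n, 0, 2 * precision_nm) +
        drift_per_frame[3] * frame,
      structure_id = truth$structure_id[idx],
      emitter = truth$emitter[idx],
      photons = 1000,
      uncertainty_xy = precision_nm,
      volume = as.integer(frame),
      plane = 0L)
  })
}
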