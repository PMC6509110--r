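new_drift_trace <- function(tbl, method, smoothing_window = NA_integer_,
                            precision = NULL) {
  structure(
    tbl,
    method = method, smoothing_window = smoothing_window,
    precision_nm = precision,
    class = c("drift_trace", class(tbl)))
}

#' Estimate stage drift from fiducial markers
#'
#' Fiducial beads are always-on, bright emitters adhered to the sample; their
#' apparent motion is the stage drift. Each fiducial is linked through time
#' by nearest-neighbor association within `link_radius`, its displacement is
#' taken relative to its own track mean, displacements are averaged across
#' fiducials per frame, gaps are interpolated and the trace is smoothed with
#' a centered moving average.
#'
#' When `seed_positions` is NULL, fiducials are proposed automatically as
#' positions (on a `link_radius` grid, 3x3-neighborhood pooled) that carry
#' events in at least 80% of frames.
#'
#' The per-axis standard deviation of the corrected fiducial tracks is
#' attached as `attr(trace, "precision_nm")`: this residual scatter is the
#' actual localization precision achieved after drift correction.
#'
#' @param table Localization table (needs `frame`, `x_nm`, `y_nm`; `z_nm`
#'   used when present).
#' @param seed_positions Optional matrix/data frame of fiducial seed
#'   positions (columns x, y in nm).
#' @param link_radius Linking radius in nm (default 500).
#' @param smoothing_window Moving-average window in frames (default 50).
#' @return A `drift_trace` tibble: `frame`, `dx`, `dy`, `dz` (nm), with
#'   attributes `method = "fiducial"` and `precision_nm`.
#' @export
track_fiducials <- function(table, seed_positions = NULL, link_radius = 500,
                            smoothing_window = 50L) {
  frames <- sort(unique(table$frame))
  n_frames <- length(frames)
  if (n_frames == 0L) rlang::abort("empty table", class = "sheetloc_validation")

  if (is.null(seed_positions)) {
    # histogram at link_radius bins with 3x3 neighborhood pooling, so a
    # bead drifting across bin borders still counts as persistent
    bx <- floor(table$x_nm / link_radius)
    by <- floor(table$y_nm / link_radius)
    key <- paste(bx, by)
    occupied <- unique(data.frame(bx = bx, by = by))
    ev_by_key <- split(seq_len(nrow(table)), key)
    nb_rows <- function(cx, cy) {
      keys <- paste(rep(cx + (-1:1), each = 3), rep(cy + (-1:1), times = 3))
      unlist(ev_by_key[keys], use.names = FALSE)
    }
    cand <- list()
    for (i in seq_len(nrow(occupied))) {
      rows <- nb_rows(occupied$bx[i], occupied$by[i])
      if (length(unique(table$frame[rows])) >= 0.8 * n_frames) {
        cand[[length(cand) + 1L]] <- c(
          mean(table$x_nm[rows]), mean(table$y_nm[rows]), length(rows))
      }
    }
    if (length(cand) == 0L) {
      rlang::abort("no fiducial markers found", class = "sheetloc_validation")
    }
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand[, 3]), , drop = FALSE]
    # greedy: keep the strongest seed of each neighborhood cluster
    seeds <- cand[1, 1:2, drop = FALSE]
    for (i in seq_len(nrow(cand))[-1]) {
      d2 <- (seeds[, 1] - cand[i, 1])^2 + (seeds[, 2] - cand[i, 2])^2
      if (all(d2 >= (2 * link_radius)^2)) {
        seeds <- rbind(seeds, cand[i, 1:2])
      }
    }
  } else {
    seeds <- as.matrix(seed_positions)[, 1:2, drop = FALSE]
  }
  n_fid <- nrow(seeds)
  has_z <- "z_nm" %in% names(table)

  tx <- matrix(NA_real_, n_frames, n_fid)
  ty <- matrix(NA_real_, n_frames, n_fid)
  tz <- matrix(NA_real_, n_frames, n_fid)
  split_idx <- split(seq_len(nrow(table)), factor(table$frame, levels = frames))
  cur <- seeds
  for (fi in seq_len(n_frames)) {
    rows <- split_idx[[fi]]
    if (length(rows) == 0L) next
    ex <- table$x_nm[rows]; ey <- table$y_nm[rows]
    for (k in seq_len(n_fid)) {
      d2 <- (ex - cur[k, 1])^2 + (ey - cur[k, 2])^2
      j <- which.min(d2)
      if (length(j) == 1L && d2[j] <= link_radius^2) {
        tx[fi, k] <- ex[j]; ty[fi, k] <- ey[j]
        if (has_z) tz[fi, k] <- table$z_nm[rows][j]
        cur[k, ] <- c(ex[j], ey[j])
      }
    }
  }
  lost <- colMeans(is.na(tx))
  if (any(lost > 0.2)) {
    rlang::warn(sprintf("%d fiducial(s) lost in > 20%% of frames",
                        sum(lost > 0.2)))
  }

  dev <- function(m) sweep(m, 2, colMeans(m, na.rm = TRUE))
  raw <- cbind(rowMeans(dev(tx), na.rm = TRUE),
               rowMeans(dev(ty), na.rm = TRUE),
               if (has_z) rowMeans(dev(tz), na.rm = TRUE) else 0)
  raw[is.nan(raw)] <- NA_real_
  fill <- function(v) {
    if (all(is.na(v))) return(rep(0, length(v)))
    stats::approx(frames[!is.na(v)], v[!is.na(v)], xout = frames,
                  rule = 2)$y
  }
  sm <- apply(raw, 2, function(v) moving_average(fill(v), smoothing_window))

  resid <- function(m, s) as.vector(dev(m) - s)
  prec <- c(x = sd(resid(tx, sm[, 1]), na.rm = TRUE),
            y = sd(resid(ty, sm[, 2]), na.rm = TRUE),
            z = if (has_z) sd(resid(tz, sm[, 3]), na.rm = TRUE) else NA_real_)

  new_drift_trace(
    tibble::tibble(frame = frames, dx = sm[, 1], dy = sm[, 2], dz = sm[, 3]),
    method = "fiducial", smoothing_window = as.integer(smoothing_window),
    precision = prec)
}

# 2D event histogram on a fixed grid (rows = y).
hist2_events <- function(x, y, pixel, x_range, y_range) {
  nx <- max(1L, ceiling((x_range[2] - x_range[1]) / pixel))
  ny <- max(1L, ceiling((y_range[2] - y_range[1]) / pixel))
  ix <- pmin(pmax(floor((x - x_range[1]) / pixel), 0), nx - 1L) + 1L
  iy <- pmin(pmax(floor((y - y_range[1]) / pixel), 0), ny - 1L) + 1L
  m <- matrix(0, ny, nx)
  tb <- table(factor(iy + (ix - 1L) * ny, levels = seq_len(nx * ny)))
  m[] <- as.numeric(tb)
  m
}

# Sub-pixel peak of a cross-correlation surface via 3-point parabolic fit.
parabolic_peak <- function(y1, y2, y3) {
  denom <- y1 - 2 * y2 + y3
  if (denom >= 0) return(0)
  0.5 * (y1 - y3) / denom
}

#' Estimate drift by block-wise image cross-correlation
#'
#' Splits the table into consecutive blocks of `block_frames` frames, renders
#' a 2D event histogram per block, and cross-correlates each block against
#' the first by FFT. The correlation peak is refined to sub-pixel precision
#' with a 3-point parabolic fit per axis. Lateral only (`dz = 0`).
#'
#' @param table Localization table.
#' @param block_frames Frames per block (>= 2 blocks required).
#' @param render_pixel Histogram pixel in nm (default 20).
#' @return A `drift_trace` with one node per block, indexed at the block's
#'   center frame.
#' @export
estimate_drift_xcorr <- function(table, block_frames, render_pixel = 20) {
  blocks <- floor(table$frame / block_frames)
  ub <- sort(unique(blocks))
  if (length(ub) < 2L) {
    rlang::abort("need at least 2 blocks for cross-correlation drift",
                 class = "sheetloc_validation")
  }
  xr <- range(table$x_nm) + c(-2, 2) * render_pixel
  yr <- range(table$y_nm) + c(-2, 2) * render_pixel
  ref <- NULL
  out <- purrr::map(ub, function(b) {
    sel <- blocks == b
    img <- hist2_events(table$x_nm[sel], table$y_nm[sel], render_pixel,
                        xr, yr)
    img
  })
  ref <- out[[1]]
  Fref <- fft(ref)
  ny <- nrow(ref); nx <- ncol(ref)
  shifts <- purrr::map(seq_along(out), function(i) {
    if (i == 1L) return(c(0, 0))
    img <- out[[i]]
    if (sum(img) == 0) {
      rlang::warn("featureless block; assuming zero shift")
      return(c(0, 0))
    }
    cc <- Re(fft(fft(img) * Conj(Fref), inverse = TRUE)) / (nx * ny)
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    wrap <- function(i, n) ((i - 1 + n / 2) %% n) - n / 2
    gety <- function(r, c) cc[(r - 1) %% ny + 1, (c - 1) %% nx + 1]
    dy <- parabolic_peak(gety(pk[1] - 1, pk[2]), gety(pk[1], pk[2]),
                         gety(pk[1] + 1, pk[2]))
    dx <- parabolic_peak(gety(pk[1], pk[2] - 1), gety(pk[1], pk[2]),
                         gety(pk[1], pk[2] + 1))
    c(wrap(pk[2], nx) + dx, wrap(pk[1], ny) + dy) * render_pixel
  })
  center <- (ub + 0.5) * block_frames - 0.5
  new_drift_trace(
    tibble::tibble(
      frame = center,
      dx = purrr::map_dbl(shifts, 1),
      dy = purrr::map_dbl(shifts, 2),
      dz = 0),
    method = "xcorr")
}

#' Apply (subtract) a drift trace from a localization table
#'
#' Displacements are linearly interpolated between trace nodes (constant
#' beyond the ends) and subtracted from each record's coordinates.
#'
#' @param table Localization table.
#' @param trace A `drift_trace` (or any data frame with `frame`, `dx`, `dy`,
#'   `dz`). Negate its columns to undo a previous application.
#' @return The corrected table (same row order).
#' @export
apply_drift <- function(table, trace) {
  dx <- interp_trace(trace$frame, trace$dx, table$frame)
  dy <- interp_trace(trace$frame, trace$dy, table$frame)
  dz <- interp_trace(trace$frame, trace$dz, table$frame)
  out <- table
  out$x_nm <- out$x_nm - dx
  out$y_nm <- out$y_nm - dy
  if ("z_nm" %in% names(out)) out$z_nm <- out$z_nm - dz
  out
}

#' Deskew localizations from the tilted sheet frame to sample coordinates
#'
#' In a sample-scan acquisition the camera sees the sheet plane, which meets
#' the coverslip at angle theta; plane `p` corresponds to a sample advance of
#' `p * scan_step` nm along the scan axis. With `u` the in-sheet coordinate
#' along the tilt direction (`x_nm`), `v` the in-sheet horizontal (`y_nm`),
#' and `w` the sheet-normal position from astigmatism (`z_nm`), coverslip
#' coordinates are
#' \deqn{X = p s + u\cos\theta - w\sin\theta,\quad Y = v,\quad
#'       Z = u\sin\theta + w\cos\theta.}
#'
#' @param table Localization table with `plane`, `x_nm`, `y_nm` (and
#'   optionally `z_nm`).
#' @param sheet_angle Sheet--coverslip angle in degrees, in (0, 90].
#' @param scan_step Scan step per plane in nm.
#' @param inverse Undo the transform: expects `X_nm`, `Y_nm`, `Z_nm` and
#'   restores `x_nm`, `y_nm`, `z_nm`.
#' @return Table with added `X_nm`, `Y_nm`, `Z_nm` columns (sample frame).
#' @export
deskew <- function(table, sheet_angle = 32.5, scan_step, inverse = FALSE) {
  if (!is.numeric(sheet_angle) || sheet_angle <= 0 || sheet_angle > 90) {
    stop_invalid("`sheet_angle` must be in (0, 90] degrees")
  }
  check_number(scan_step, "scan_step", min = 0, strict_min = TRUE)
  th <- sheet_angle * pi / 180
  ct <- cos(th); st <- sin(th)
  p <- table[["plane"]] %||% 0
  if (!inverse) {
    w <- table[["z_nm"]] %||% rep(0, nrow(table))
    out <- table
    out$X_nm <- p * scan_step + table$x_nm * ct - w * st
    out$Y_nm <- table$y_nm
    out$Z_nm <- table$x_nm * st + w * ct
    out
  } else {
    xs <- table$X_nm - p * scan_step
    out <- table
    out$x_nm <- xs * ct + table$Z_nm * st
    out$y_nm <- table$Y_nm
    out$z_nm <- -xs * st + table$Z_nm * ct
    out
  }
}

#' Transpose a volume series into per-plane time series
#'
#' Volumetric stacks arrive as one stack per time point (volume); drift
#' correction and localization are simpler in the time domain, so the series
#' is re-indexed into one time stack per z plane. Pure, lossless reindexing.
#'
#' @param volume_series List of `(plane, y, x)` arrays (one per volume) or a
#'   4D array `(volume, plane, y, x)`.
#' @return List over planes of `(volume, y, x)` arrays.
#' @export
transpose_to_time_series <- function(volume_series) {
  if (is.array(volume_series) && length(dim(volume_series)) == 4L) {
    d <- dim(volume_series)
    volume_series <- lapply(seq_len(d[1]), function(v) {
      array(volume_series[v, , , ], dim = d[2:4])
    })
  }
  dims <- lapply(volume_series, dim)
  if (length(unique(purrr::map_int(dims, 1))) != 1L ||
      length(unique(purrr::map_int(dims, 2))) != 1L ||
      length(unique(purrr::map_int(dims, 3))) != 1L) {
    stop_invalid("all volumes must share the same (plane, y, x) dimensions")
  }
  n_planes <- dims[[1]][1]
  n_vol <- length(volume_series)
  lapply(seq_len(n_planes), function(p) {
    out <- array(0, dim = c(n_vol, dims[[1]][2], dims[[1]][3]))
    for (v in seq_len(n_vol)) out[v, , ] <- volume_series[[v]][p, , ]
    out
  })
}

#' Render a density map from localizations
#'
#' In 2D mode every event is drawn as a unit-integral symmetric Gaussian
#' whose standard deviation is the event's own localization uncertainty
#' (`sigma_source = "per_event"`) or a fixed value. In 3D mode events are
#' histogrammed into voxels and the volume is smoothed with a Gaussian
#' kernel. Total rendered weight equals the number of events for interior
#' events (kernels are not renormalized at borders, so events near the edge
#' lose the clipped mass).
#'
#' @param table Localization table.
#' @param pixel Rendering pixel (and voxel) size in nm.
#' @param mode `"2d"` or `"3d"`.
#' @param sigma_source `"per_event"` (uses `uncertainty_xy`) or `"fixed"`.
#' @param fixed_sigma Gaussian sigma in nm for `sigma_source = "fixed"` and
#'   for the 3D smoothing kernel.
#' @param extent Optional list with `x`, `y` (and `z` for 3D) length-2
#'   ranges in nm; defaults to the data range padded by 5 sigma.
#' @param coords Column pair to render, default `c("x_nm", "y_nm")` (use
#'   `c("X_nm", "Y_nm")` for deskewed tables).
#' @return 2D: matrix (rows = y) with attributes `pixel`, `origin`.
#'   3D: array `(z, y, x)` with the same attributes.
#' @export
render_density <- function(table, pixel = 10,
                           mode = c("2d", "3d"),
                           sigma_source = c("per_event", "fixed"),
                           fixed_sigma = 20, extent = NULL,
                           coords = c("x_nm", "y_nm")) {
  mode <- match.arg(mode)
  sigma_source <- match.arg(sigma_source)
  check_number(pixel, "pixel", min = 0, strict_min = TRUE)
  x <- table[[coords[1]]]
  y <- table[[coords[2]]]
  n <- length(x)
  sig <- if (sigma_source == "per_event") {
    table[["uncertainty_xy"]] %||% rep(fixed_sigma, n)
  } else {
    rep(fixed_sigma, n)
  }
  pad <- if (n > 0) 5 * max(sig, pixel) else pixel
  xr <- extent$x %||% (range(x, finite = TRUE) + c(-pad, pad))
  yr <- extent$y %||% (range(y, finite = TRUE) + c(-pad, pad))
  if (n == 0L) {
    out <- matrix(0, 1, 1)
    attr(out, "pixel") <- pixel; attr(out, "origin") <- c(0, 0)
    return(out)
  }
  if (mode == "2d") {
    nx <- max(1L, ceiling((xr[2] - xr[1]) / pixel))
    ny <- max(1L, ceiling((yr[2] - yr[1]) / pixel))
    img <- matrix(0, ny, nx)
    for (i in seq_len(n)) {
      s <- max(sig[i], 1e-6)
      r <- ceiling(5.5 * s / pixel) + 1L
      cx <- (x[i] - xr[1]) / pixel
      cy <- (y[i] - yr[1]) / pixel
      j0 <- max(1L, floor(cx) - r); j1 <- min(nx, floor(cx) + r + 1L)
      i0 <- max(1L, floor(cy) - r); i1 <- min(ny, floor(cy) + r + 1L)
      if (j0 > j1 || i0 > i1) next
      spx <- s / pixel
      ex <- pnorm(((j0:j1) - cx) / spx) - pnorm(((j0:j1) - 1 - cx) / spx)
      ey <- pnorm(((i0:i1) - cy) / spx) - pnorm(((i0:i1) - 1 - cy) / spx)
      img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + ey %o% ex
    }
    attr(img, "pixel") <- pixel
    attr(img, "origin") <- c(xr[1], yr[1])
    img
  } else {
    z <- table[["z_nm"]] %||% rep(0, n)
    zr <- extent$z %||% (range(z, finite = TRUE) + c(-pad, pad))
    nx <- max(1L, ceiling((xr[2] - xr[1]) / pixel))
    ny <- max(1L, ceiling((yr[2] - yr[1]) / pixel))
    nz <- max(1L, ceiling((zr[2] - zr[1]) / pixel))
    ix <- pmin(pmax(floor((x - xr[1]) / pixel), 0), nx - 1L)
    iy <- pmin(pmax(floor((y - yr[1]) / pixel), 0), ny - 1L)
    iz <- pmin(pmax(floor((z - zr[1]) / pixel), 0), nz - 1L)
    vol <- array(0, dim = c(nz, ny, nx))
    lin <- iz + nz * (iy + ny * ix) + 1
    tb <- table(lin)
    vol[as.integer(names(tb))] <- as.numeric(tb)
    # separable Gaussian smoothing, kernel sum 1, zero-padded borders
    s_px <- fixed_sigma / pixel
    r <- max(1L, ceiling(4 * s_px))
    k <- dnorm(-r:r, sd = max(s_px, 1e-6)); k <- k / sum(k)
    conv_dim <- function(a, d) {
      n_d <- dim(a)[d]
      out <- array(0, dim = dim(a))
      for (o in -r:r) {
        src <- seq_len(n_d) + o
        okv <- src >= 1 & src <= n_d
        idx_to <- which(okv); idx_from <- src[okv]
        w <- k[o + r + 1L]
        if (d == 1) out[idx_to, , ] <- out[idx_to, , ] +
            w * a[idx_from, , , drop = FALSE]
        if (d == 2) out[, idx_to, ] <- out[, idx_to, ] +
            w * a[, idx_from, , drop = FALSE]
        if (d == 3) out[, , idx_to] <- out[, , idx_to] +
            w * a[, , idx_from, drop = FALSE]
      }
      out
    }
    vol <- conv_dim(conv_dim(conv_dim(vol, 1), 2), 3)
    attr(vol, "pixel") <- pixel
    attr(vol, "origin") <- c(xr[1], yr[1], zr[1])
    vol
  }
}

#' Temporal segmentation and color-coded rendering
#'
#' Assigns events to bins of `frames_per_bin` consecutive frames
#' (`floor(frame / frames_per_bin)`), renders a density map per bin on a
#' common grid, and composes them into an RGB image with one color per bin.
#' The bins partition the table, so the per-bin maps sum to the full map.
#'
#' @param table Localization table.
#' @param frames_per_bin Frames per temporal bin (>= 1). 2000 frames at
#'   20 ms exposure corresponds to 40 s segments.
#' @param pixel Rendering pixel in nm.
#' @param fixed_sigma Rendering sigma in nm (fixed mode).
#' @param palette Function `n -> colors` (default `grDevices::rainbow`).
#' @return List: `image` (ny x nx x 3 RGB array, max-normalized), `maps`
#'   (list of per-bin matrices), `bins` (list of per-bin sub-tables),
#'   `frames_per_bin`, `colors`.
#' @export
render_temporal <- function(table, frames_per_bin, pixel = 20,
                            fixed_sigma = 20,
                            palette = grDevices::rainbow) {
  check_number(frames_per_bin, "frames_per_bin", min = 1)
  bin <- floor(table$frame / frames_per_bin)
  ub <- sort(unique(bin))
  pad <- 5 * max(fixed_sigma, pixel)
  ext <- list(x = range(table$x_nm) + c(-pad, pad),
              y = range(table$y_nm) + c(-pad, pad))
  subtables <- lapply(ub, function(b) table[bin == b, , drop = FALSE])
  maps <- lapply(subtables, render_density, pixel = pixel,
                 sigma_source = "fixed", fixed_sigma = fixed_sigma,
                 extent = ext)
  cols <- palette(length(ub))
  rgbm <- grDevices::col2rgb(cols) / 255
  ny <- nrow(maps[[1]]); nx <- ncol(maps[[1]])
  img <- array(0, dim = c(ny, nx, 3))
  for (i in seq_along(maps)) {
    for (ch in 1:3) img[, , ch] <- img[, , ch] + maps[[i]] * rgbm[ch, i]
  }
  mx <- max(img)
  if (mx > 0) img <- img / mx
  list(image = img, maps = maps, bins = subtables,
       frames_per_bin = frames_per_bin, colors = cols)
}

#' Maximum-intensity projection of a 3D density volume
#' @param volume Array `(z, y, x)`.
#' @param axis Axis to project over (1 = z, default).
#' @return Matrix.
#' @export
mip <- function(volume, axis = 1L) {
  apply(volume, setdiff(1:3, axis), max)
}
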