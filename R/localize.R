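#' Detection parameters for per-frame spot finding
#'
#' @param filter_scale Band-pass scale in px: difference of Gaussians at
#'   `filter_scale` and `2 * filter_scale`.
#' @param threshold_k Detection threshold in units of the robust noise std
#'   (1.4826 x MAD of the band-passed frame).
#' @param roi_half Half-size of the fit ROI in px (>= 3; ROI is
#'   `(2*roi_half+1)^2`).
#' @param max_uncertainty_xy Lateral uncertainty filter in nm (Inf = off).
#' @param sigma_bounds Accepted fitted-width interval in nm.
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(filter_scale = 1.3, threshold_k = 5,
                             roi_half = 5L, max_uncertainty_xy = Inf,
                             sigma_bounds = c(40, 500)) {
  check_number(filter_scale, "filter_scale", min = 0, strict_min = TRUE)
  check_number(threshold_k, "threshold_k", min = 0, strict_min = TRUE)
  check_number(roi_half, "roi_half", min = 3)
  structure(
    list(filter_scale = filter_scale, threshold_k = threshold_k,
         roi_half = as.integer(roi_half),
         max_uncertainty_xy = max_uncertainty_xy,
         sigma_bounds = sigma_bounds),
    class = "detection_params")
}

# Separable Gaussian blur with replicated edges (deterministic, no FFT).
gauss_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(m) {
    n <- nrow(m)
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
                m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (i in seq_len(n)) {
      out[i, ] <- crossprod(k, mp[i:(i + 2L * r), , drop = FALSE])
    }
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

#' Detect candidate spots in one frame
#'
#' Band-pass filters the frame (difference of Gaussians), estimates the noise
#' floor robustly (1.4826 x MAD), and returns 8-neighborhood local maxima
#' above `threshold_k` x noise. Candidates closer than `roi_half` px keep
#' only the brighter one, and candidates whose ROI would cross the frame
#' border are dropped. Fully deterministic.
#'
#' @param frame_image 2D numeric matrix (rows = y, cols = x), camera counts.
#' @param params A [detection_params()].
#' @return Tibble with `px` (column), `py` (row), `value` (band-passed
#'   amplitude), sorted brightest first.
#' @export
detect_spots <- function(frame_image, params = detection_params()) {
  stopifnot(is.matrix(frame_image))
  bp <- gauss_blur(frame_image, params$filter_scale) -
    gauss_blur(frame_image, 2 * params$filter_scale)
  noise <- mad(bp)
  # the absolute floor keeps float residue on constant frames below threshold
  thr <- params$threshold_k * noise +
    1e-9 * (max(frame_image) - min(frame_image) + 1)
  ny <- nrow(bp); nx <- ncol(bp)
  h <- params$roi_half
  if (ny < 2 * h + 1 || nx < 2 * h + 1) {
    return(tibble::tibble(px = integer(), py = integer(), value = numeric()))
  }
  core <- bp[2:(ny - 1), 2:(nx - 1)]
  is_max <- core > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- bp[(2 + di):(ny - 1 + di), (2 + dj):(nx - 1 + dj)]
    is_max <- is_max & (core >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(tibble::tibble(px = integer(), py = integer(), value = numeric()))
  }
  py <- idx[, 1] + 1L
  px <- idx[, 2] + 1L
  val <- bp[cbind(py, px)]
  keep <- py > h & py <= ny - h & px > h & px <= nx - h
  py <- py[keep]; px <- px[keep]; val <- val[keep]
  ord <- order(val, decreasing = TRUE)
  py <- py[ord]; px <- px[ord]; val <- val[ord]
  # duplicate suppression: greedy, brightest first
  kept <- logical(length(val))
  for (i in seq_along(val)) {
    if (i == 1L) { kept[1L] <- TRUE; next }
    prev <- which(kept)
    d2 <- (px[prev] - px[i])^2 + (py[prev] - py[i])^2
    kept[i] <- all(d2 >= h^2)
  }
  tibble::tibble(px = px[kept], py = py[kept], value = val[kept])
}

# Integrated elliptical Gaussian on a ROI grid (pixel units; pixel j covers
# [j-1, j)). Returns expected photons/pixel.
roi_model <- function(nx, ny, x0, y0, sx, sy, N, b) {
  ex <- pnorm((seq_len(nx) - x0) / sx) - pnorm((seq_len(nx) - 1 - x0) / sx)
  ey <- pnorm((seq_len(ny) - y0) / sy) - pnorm((seq_len(ny) - 1 - y0) / sy)
  N * (ey %o% ex) + b
}

#' Fit an elliptical Gaussian to a spot ROI
#'
#' Least-squares fit of an axis-aligned, pixel-integrated elliptical Gaussian
#' plus constant background to a camera ROI (converted to photons via the
#' camera gain/offset). Axis alignment is justified by the cylindrical-lens
#' axes coinciding with the camera axes. Degenerate or non-converged fits are
#' returned with `valid = FALSE` rather than raised.
#'
#' @param roi_image Square ROI matrix in camera counts.
#' @param camera A [camera_model()].
#' @param init Optional list with `x0`, `y0` (pixel units within the ROI).
#' @return One-row tibble: `x_px`, `y_px` (sub-pixel position inside the
#'   ROI), `sigma_x_px`, `sigma_y_px`, `photons`, `background`
#'   (photons/px), `fit_rss`, `valid`.
#' @export
fit_spot <- function(roi_image, camera = camera_model(), init = NULL) {
  stopifnot(is.matrix(roi_image))
  ny <- nrow(roi_image); nx <- ncol(roi_image)
  ph <- (roi_image - camera$offset) / camera$gain
  fail <- tibble::tibble(
    x_px = NA_real_, y_px = NA_real_, sigma_x_px = NA_real_,
    sigma_y_px = NA_real_, photons = NA_real_, background = NA_real_,
    fit_rss = NA_real_, valid = FALSE)
  b0 <- max(median(ph), 0)
  sig <- ph - b0
  tot <- sum(pmax(sig, 0))
  if (tot <= 0) return(fail)
  xg <- matrix(seq_len(nx) - 0.5, ny, nx, byrow = TRUE)
  yg <- matrix(seq_len(ny) - 0.5, ny, nx)
  wpos <- pmax(sig, 0)
  x0 <- init$x0 %||% sum(wpos * xg) / tot
  y0 <- init$y0 %||% sum(wpos * yg) / tot
  df <- data.frame(v = as.vector(ph))
  starts <- list(
    list(x0 = x0, y0 = y0, sx = 1.5, sy = 1.5, N = max(tot, 1), b = b0),
    list(x0 = x0, y0 = y0, sx = 1.5, sy = 1.5, N = max(tot, 1), b = 0),
    list(x0 = nx / 2, y0 = ny / 2, sx = 2.5, sy = 2.5,
         N = max(tot, 1), b = b0))
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ as.vector(roi_model(nx, ny, x0, y0, sx, sy, N, b)),
        data = df, start = st,
        lower = c(x0 = 0, y0 = 0, sx = 0.3, sy = 0.3, N = 1e-3, b = 0),
        upper = c(x0 = nx, y0 = ny, sx = nx, sy = ny, N = Inf, b = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(fail)
  # iteratively reweighted refinement: weights from the current model
  # variance (shot noise + read noise in photon units); for Poisson data
  # this IRLS scheme converges to the maximum-likelihood estimate
  read_ph2 <- (camera$read_noise / camera$gain)^2
  for (it in 1:3) {
    w <- 1 / pmax(predict(fit) + read_ph2, 0.25)
    refit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        v ~ as.vector(roi_model(nx, ny, x0, y0, sx, sy, N, b)),
        data = df, start = as.list(coef(fit)), weights = w,
        lower = c(x0 = 0, y0 = 0, sx = 0.3, sy = 0.3, N = 1e-3, b = 0),
        upper = c(x0 = nx, y0 = ny, sx = nx, sy = ny, N = Inf, b = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 50))),
      error = function(e) NULL)
    if (is.null(refit)) break
    delta <- max(abs(coef(refit) - coef(fit)) /
                   pmax(abs(coef(fit)), 1e-6))
    fit <- refit
    if (delta < 1e-4) break
  }
  p <- coef(fit)
  if (!all(is.finite(p)) || p["N"] <= 0 ||
      p["sx"] >= 0.9 * nx || p["sy"] >= 0.9 * ny) {
    return(fail)
  }
  tibble::tibble(
    x_px = unname(p["x0"]), y_px = unname(p["y0"]),
    sigma_x_px = unname(p["sx"]), sigma_y_px = unname(p["sy"]),
    photons = unname(p["N"]), background = unname(p["b"]),
    fit_rss = sum(residuals(fit)^2), valid = TRUE)
}

#' Theoretical localization uncertainty
#'
#' Thompson--Larson--Webb form:
#' \deqn{\sigma_{loc}^2 = \frac{\sigma^2}{N} + \frac{a^2}{12N} +
#'       \frac{8\pi \sigma^4 b^2}{a^2 N^2}}
#' with PSF width `sigma`, pixel size `a`, detected photons `N` and
#' background `b` photons/pixel. Mortensen's MLE formula is available via
#' `formula = "mortensen"` (same leading terms with the excess-noise
#' correction factor).
#'
#' @param photons Detected photon count N (> 0), vectorized.
#' @param sigma PSF Gaussian width in nm.
#' @param pixel_size Camera pixel size in nm (default 102).
#' @param background Background in photons/pixel (default 0).
#' @param formula `"tlw"` (default) or `"mortensen"`.
#' @return Uncertainty in nm.
#' @export
#' @examples
#' theoretical_uncertainty(1000, 150) # ~ 4.8 nm
theoretical_uncertainty <- function(photons, sigma, pixel_size = 102,
                                    background = 0,
                                    formula = c("tlw", "mortensen")) {
  formula <- match.arg(formula)
  if (any(!is.finite(photons)) || any(photons <= 0)) {
    stop_invalid("`photons` must be positive")
  }
  sa2 <- sigma^2
  a2 <- pixel_size^2
  if (formula == "tlw") {
    sqrt(sa2 / photons + a2 / (12 * photons) +
           8 * pi * sa2^2 * background^2 / (a2 * photons^2))
  } else {
    # Mortensen: pixelation-corrected variance with background excess factor
    s2 <- sa2 + a2 / 12
    tau <- 2 * pi * s2 * background / (photons * a2)
    sqrt(s2 / photons * (16 / 9 + 4 * tau))
  }
}

# Sensitivity-based axial uncertainty: propagate a width error of
# sigma_i / sqrt(N) through the calibration slopes d sigma_i / dz at z_hat.
axial_uncertainty <- function(calib, z, sigma_x, sigma_y, photons) {
  eps <- 1
  s_lo <- sigma_at_z(calib, z - eps)
  s_hi <- sigma_at_z(calib, z + eps)
  slope_x <- (s_hi$sigma_x - s_lo$sigma_x) / (2 * eps)
  slope_y <- (s_hi$sigma_y - s_lo$sigma_y) / (2 * eps)
  dsx <- sigma_x / sqrt(photons)
  dsy <- sigma_y / sqrt(photons)
  info <- (slope_x / dsx)^2 + (slope_y / dsy)^2
  ifelse(info > 0, 1 / sqrt(info), Inf)
}

empty_localization_table <- function() {
  tibble::tibble(
    volume = integer(), plane = integer(), frame = integer(),
    x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
    sigma_x = numeric(), sigma_y = numeric(),
    photons = numeric(), background = numeric(),
    uncertainty_xy = numeric(), uncertainty_z = numeric(),
    fit_rss = numeric(), valid = logical())
}

#' Localize all events in an image stack
#'
#' Runs detection, elliptical-Gaussian fitting, axial assignment from the
#' astigmatic calibration, and uncertainty attachment on every frame of a
#' stack. Frames are processed independently, so results do not depend on
#' processing order.
#'
#' @param stack 3D array `(frame, y, x)` in camera counts, or a single
#'   matrix. In `mode = "volume"` the first index is the plane of one
#'   volumetric sweep; in `mode = "timeseries"` it is the time index of a
#'   fixed plane (after [transpose_to_time_series()]).
#' @param calib An [astig_calibration()] (required).
#' @param camera A [camera_model()].
#' @param params A [detection_params()].
#' @param mode `"volume"` or `"timeseries"`.
#' @param plane Plane index recorded in `mode = "timeseries"` (0-based).
#' @param volume Volume index recorded in `mode = "volume"` (0-based).
#' @return A localization table (tibble): volume, plane, frame, x_nm, y_nm,
#'   z_nm, sigma_x, sigma_y, photons, background, uncertainty_xy,
#'   uncertainty_z, fit_rss, valid. x/y are in-sheet camera-plane
#'   coordinates; z is the sheet-normal position from astigmatism.
#' @export
localize_stack <- function(stack, calib, camera = camera_model(),
                           params = detection_params(),
                           mode = c("volume", "timeseries"),
                           plane = 0L, volume = 0L) {
  mode <- match.arg(mode)
  if (missing(calib) || !inherits(calib, "astig_calibration")) {
    rlang::abort("an astigmatic calibration is required",
                 class = "sheetloc_config_error")
  }
  if (is.matrix(stack)) {
    stack <- array(stack, dim = c(1L, nrow(stack), ncol(stack)))
  }
  n_frames <- dim(stack)[1]
  a <- camera$pixel_size
  h <- params$roi_half
  rows <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    img <- stack[f, , ]
    cand <- detect_spots(img, params)
    if (nrow(cand) == 0L) next
    fits <- purrr::map(seq_len(nrow(cand)), function(i) {
      roi <- img[(cand$py[i] - h):(cand$py[i] + h),
                 (cand$px[i] - h):(cand$px[i] + h)]
      ft <- fit_spot(roi, camera)
      if (!ft$valid) return(NULL)
      # ROI pixel (1,1) corner sits at (px - h - 1, py - h - 1) in frame px
      dplyr::mutate(ft,
        x_nm = (cand$px[i] - h - 1 + x_px) * a,
        y_nm = (cand$py[i] - h - 1 + y_px) * a,
        sigma_x = sigma_x_px * a, sigma_y = sigma_y_px * a)
    })
    fits <- dplyr::bind_rows(fits)
    if (nrow(fits) == 0L) next
    rows[[f]] <- dplyr::mutate(fits,
      frame = if (mode == "volume") f - 1L else f - 1L,
      plane = if (mode == "volume") f - 1L else as.integer(plane),
      volume = if (mode == "volume") as.integer(volume) else f - 1L)
  }
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0L) return(empty_localization_table())
  zfit <- z_from_sigma(calib, tab$sigma_x, tab$sigma_y)
  sig_sym <- sqrt(tab$sigma_x * tab$sigma_y)
  tab <- dplyr::mutate(tab,
    z_nm = zfit$z_nm,
    valid = valid & zfit$valid,
    uncertainty_xy = theoretical_uncertainty(photons, sig_sym, a, background),
    uncertainty_z = axial_uncertainty(calib, zfit$z_nm, sigma_x, sigma_y,
                                      photons))
  dplyr::select(tab, volume, plane, frame, x_nm, y_nm, z_nm, sigma_x,
                sigma_y, photons, background, uncertainty_xy, uncertainty_z,
                fit_rss, valid)
}

#' Filter a localization table
#'
#' Keeps records meeting all requested criteria; never reorders survivors.
#' The astigmatic width gate doubles as a rejection filter for out-of-focus
#' and side-lobe-excited events, whose widths match no in-focus model value.
#'
#' @param table Localization table.
#' @param max_uncertainty_xy Keep records with `uncertainty_xy <=` this (nm).
#' @param sigma_bounds Length-2 nm interval for both fitted widths.
#' @param require_valid_z Keep only records whose `valid` flag is TRUE
#'   (successful fit and in-range astigmatic inversion).
#' @return Filtered tibble.
#' @export
filter_localizations <- function(table, max_uncertainty_xy = NULL,
                                 sigma_bounds = NULL,
                                 require_valid_z = FALSE) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(max_uncertainty_xy)) {
    keep <- keep & table$uncertainty_xy <= max_uncertainty_xy
  }
  if (!is.null(sigma_bounds)) {
    keep <- keep & table$sigma_x >= sigma_bounds[1] &
      table$sigma_x <= sigma_bounds[2] &
      table$sigma_y >= sigma_bounds[1] & table$sigma_y <= sigma_bounds[2]
  }
  if (require_valid_z) keep <- keep & table$valid
  table[keep, , drop = FALSE]
}
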