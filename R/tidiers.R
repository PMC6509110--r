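#' Tidy an astigmatic calibration into one row per axis and parameter
#'
#' @param x An [astig_calibration()].
#' @param ... Unused.
#' @return Tibble with `axis`, `term`, `estimate`.
#' @export
tidy.astig_calibration <- function(x, ...) {
  tidyr::pivot_longer(x$params, -"axis", names_to = "term",
                      values_to = "estimate")
}

#' @rdname tidy.astig_calibration
#' @export
glance.astig_calibration <- function(x, ...) {
  tibble::tibble(
    z_min = x$z_range[1], z_max = x$z_range[2],
    residual_rms_x = unname(x$residual_rms["x"]),
    residual_rms_y = unname(x$residual_rms["y"]),
    d_threshold = x$d_threshold)
}

#' Tidy a donut fit
#'
#' @param x A `donut_fit` from [fit_donut()].
#' @param ... Unused.
#' @return One-row tibble of parameters.
#' @export
tidy.donut_fit <- function(x, ...) {
  tibble::tibble(
    center_x_nm = x$center[1], center_y_nm = x$center[2],
    r0_nm = x$r0, sigma_r_nm = x$sigma_r, amplitude = x$amplitude,
    offset = x$offset, rss = x$rss, rss_norm = x$rss_norm,
    converged = x$converged)
}

#' Summaries of an NPC averaging run
#'
#' @param x An `npc_average` from [npc_average()].
#' @param ... Unused.
#' @return One-row tibble: candidate counts, overlay size, diameter.
#' @export
glance.npc_average <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$candidates),
    n_converged = sum(x$candidates$converged),
    n_overlaid = attr(x$overlay, "n_used"),
    diameter_nm = x$diameter_nm,
    ring_sigma_nm = x$overlay_fit$sigma_r)
}

#' @rdname glance.npc_average
#' @export
tidy.npc_average <- function(x, ...) {
  dplyr::select(x$candidates, -"crop")
}

#' Plot an FRC curve with its threshold crossing
#'
#' @param object An `frc_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frc_curve <- function(object, ...) {
  thr <- attr(object, "threshold") %||% (1 / 7)
  res <- frc_resolution(object)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$freq_nm_inv,
                               y = .data$correlation)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(
      x = "spatial frequency (1/nm)", y = "FRC",
      title = sprintf("FRC resolution %.0f nm%s", res$resolution_nm,
                      if (res$bound) " (bound)" else "")) +
    ggplot2::theme_minimal()
}

#' Plot a drift trace
#'
#' @param object A `drift_trace`.
#' @param ... Unused.
#' @return A ggplot with one line per axis.
#' @export
autoplot.drift_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("dx", "dy", "dz"),
                              names_to = "axis", values_to = "nm")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$nm,
                                     color = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "drift (nm)",
                  title = sprintf("drift trace (%s)",
                                  attr(object, "method") %||% "")) +
    ggplot2::theme_minimal()
}

#' Plot the calibrated width-versus-z curves
#'
#' @param object An [astig_calibration()].
#' @param ... Unused.
#' @return A ggplot of sigma_x(z) and sigma_y(z).
#' @export
autoplot.astig_calibration <- function(object, ...) {
  z <- seq(object$z_range[1], object$z_range[2], length.out = 241)
  s <- sigma_at_z(object, z)
  long <- tidyr::pivot_longer(s, c("sigma_x", "sigma_y"),
                              names_to = "axis", values_to = "sigma_nm")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z_nm, y = .data$sigma_nm,
                                     color = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)", y = "PSF width (nm)") +
    ggplot2::theme_minimal()
}

#' Display a density map (or any image matrix) as a ggplot raster
#'
#' @param img Matrix with optional `pixel`/`origin` attributes (nm).
#' @param trans Intensity transform, default sqrt for display dynamic range.
#' @return A ggplot.
#' @export
plot_density_map <- function(img, trans = sqrt) {
  pixel <- attr(img, "pixel") %||% 1
  origin <- attr(img, "origin") %||% c(0, 0)
  df <- expand.grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$value <- trans(as.vector(img))
  df$x_nm <- origin[1] + (df$x - 0.5) * pixel
  df$y_nm <- origin[2] + (df$y - 0.5) * pixel
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_nm, y = .data$y_nm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' Write an RGB array (e.g. a temporal rendering) as PNG
#'
#' @param image `ny x nx x 3` array in [0, 1].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}
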