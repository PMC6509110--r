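#' Astigmatic defocus calibration object
#'
#' Holds the per-axis defocusing model that maps axial position to PSF width:
#' \deqn{\sigma_i(z) = \sigma_{0,i}\sqrt{1 + u^2 + A_i u^3 + B_i u^4},
#'   \quad u = (z - c_i)/d_i}
#' for axes i in (x, y). A cylindrical lens in the detection path displaces
#' the x and y focal planes, so the width ratio encodes z. The quartic
#' corrections absorb the asymmetry of real PSFs away from focus; the model
#' form is the standard astigmatic-SMLM choice and is substitutable.
#'
#' @param sigma0 Named or length-2 numeric: in-focus widths (nm) for x and y.
#' @param focus Length-2 numeric: focal offsets c_i (nm).
#' @param depth Length-2 numeric: depth-of-field scales d_i (nm), > 0.
#' @param a3,a4 Length-2 numeric: cubic/quartic correction coefficients
#'   (dimensionless, default 0).
#' @param z_range Length-2 numeric: valid axial range (nm).
#' @param d_threshold Rejection threshold on the width-space distance used by
#'   [z_from_sigma()] (sqrt-nm squared units; default 2).
#' @return An object of class `astig_calibration`.
#' @export
astig_calibration <- function(sigma0, focus = c(0, 0), depth = c(400, 400),
                              a3 = c(0, 0), a4 = c(0, 0),
                              z_range = c(-600, 600), d_threshold = 2) {
  as2 <- function(v, name) {
    if (length(v) == 1L) v <- rep(v, 2)
    if (length(v) != 2L || !all(is.finite(v))) {
      stop_invalid(sprintf("`%s` must be a finite length-2 numeric", name))
    }
    v
  }
  sigma0 <- as2(sigma0, "sigma0"); focus <- as2(focus, "focus")
  depth <- as2(depth, "depth"); a3 <- as2(a3, "a3"); a4 <- as2(a4, "a4")
  if (any(sigma0 <= 0)) stop_invalid("`sigma0` must be positive")
  if (any(depth <= 0)) stop_invalid("`depth` must be positive")
  if (length(z_range) != 2L || z_range[1] >= z_range[2]) {
    stop_invalid("`z_range` must be an increasing length-2 interval")
  }
  structure(
    list(
      params = tibble::tibble(
        axis = c("x", "y"), sigma0 = sigma0, focus = focus, depth = depth,
        a3 = a3, a4 = a4),
      z_range = as.numeric(z_range),
      d_threshold = d_threshold,
      residual_rms = c(x = NA_real_, y = NA_real_)
    ),
    class = "astig_calibration"
  )
}

#' @export
print.astig_calibration <- function(x, ...) {
  cat("<astig_calibration>\n")
  print(as.data.frame(x$params), row.names = FALSE)
  cat(sprintf("z range: [%g, %g] nm; residual RMS: x %.3g, y %.3g nm\n",
              x$z_range[1], x$z_range[2],
              x$residual_rms["x"], x$residual_rms["y"]))
  invisible(x)
}

defocus_width <- function(z, sigma0, focus, depth, a3, a4) {
  u <- (z - focus) / depth
  sigma0 * sqrt(pmax(1 + u^2 + a3 * u^3 + a4 * u^4, 0))
}

#' Fit the astigmatic defocusing model to bead observations
#'
#' Least-squares fit of the per-axis defocusing model to calibration-bead
#' width measurements, typically acquired by stepping a fluorescent bead
#' through focus (40 nm z steps are the usual convention). Each axis is fit
#' independently with Levenberg--Marquardt.
#'
#' @param bead_observations Data frame with columns `z` (nm), `sigma_x`,
#'   `sigma_y` (nm). At least 15 distinct z positions are required.
#' @param z_range Valid axial interval recorded in the calibration; defaults
#'   to the observed z range.
#' @param fit_quartic Fit the cubic/quartic corrections (default TRUE); when
#'   FALSE they are pinned at zero.
#' @return An [astig_calibration()] with residual RMS per axis.
#' @export
fit_defocus_model <- function(bead_observations, z_range = NULL,
                              fit_quartic = TRUE) {
  obs <- as.data.frame(bead_observations)
  need <- c("z", "sigma_x", "sigma_y")
  if (!all(need %in% names(obs))) {
    stop_invalid("bead observations need columns z, sigma_x, sigma_y")
  }
  obs <- obs[complete.cases(obs[need]), , drop = FALSE]
  if (length(unique(obs$z)) < 15L) {
    stop_invalid("need >= 15 distinct z samples for a defocus fit")
  }
  z_range <- z_range %||% range(obs$z)

  fit_axis <- function(sig) {
    i0 <- which.min(sig)
    start <- list(sigma0 = max(min(sig), 1e-3), focus = obs$z[i0],
                  depth = diff(range(obs$z)) / 4)
    if (fit_quartic) start <- c(start, list(a3 = 0, a4 = 0))
    form <- if (fit_quartic) {
      sig ~ defocus_width(z, sigma0, focus, depth, a3, a4)
    } else {
      sig ~ defocus_width(z, sigma0, focus, depth, 0, 0)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(
        form, data = data.frame(z = obs$z, sig = sig), start = start,
        lower = c(sigma0 = 1e-3, focus = -Inf, depth = 1,
                  if (fit_quartic) c(a3 = -10, a4 = -10)),
        upper = c(sigma0 = Inf, focus = Inf, depth = Inf,
                  if (fit_quartic) c(a3 = 10, a4 = 10)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        rlang::abort(paste0("defocus fit failed: ", conditionMessage(e)),
                     class = "sheetloc_fit_error")
      })
    p <- as.list(coef(fit))
    if (!fit_quartic) p <- c(p, list(a3 = 0, a4 = 0))
    p$rms <- sqrt(mean(residuals(fit)^2))
    p
  }

  px <- fit_axis(obs$sigma_x)
  py <- fit_axis(obs$sigma_y)
  cal <- astig_calibration(
    sigma0 = c(px$sigma0, py$sigma0), focus = c(px$focus, py$focus),
    depth = c(px$depth, py$depth), a3 = c(px$a3, py$a3),
    a4 = c(px$a4, py$a4), z_range = z_range)
  cal$residual_rms <- c(x = px$rms, y = py$rms)
  cal
}

#' Evaluate the calibrated PSF widths at given axial positions
#'
#' @param calib An [astig_calibration()].
#' @param z Axial positions in nm (vectorized).
#' @return Tibble with `z_nm`, `sigma_x`, `sigma_y` and `extrapolated`
#'   (TRUE where z falls outside the calibration's valid range).
#' @export
sigma_at_z <- function(calib, z) {
  stopifnot(inherits(calib, "astig_calibration"))
  p <- calib$params
  sx <- defocus_width(z, p$sigma0[1], p$focus[1], p$depth[1], p$a3[1], p$a4[1])
  sy <- defocus_width(z, p$sigma0[2], p$focus[2], p$depth[2], p$a3[2], p$a4[2])
  tibble::tibble(
    z_nm = z, sigma_x = sx, sigma_y = sy,
    extrapolated = z < calib$z_range[1] | z > calib$z_range[2])
}

#' Invert measured PSF widths to axial position
#'
#' Assigns z by minimizing the width-space distance
#' \deqn{D(z) = (\sqrt{\sigma_x} - \sqrt{\sigma_x^{cal}(z)})^2 +
#'              (\sqrt{\sigma_y} - \sqrt{\sigma_y^{cal}(z)})^2}
#' over the calibration's z range on a 1 nm grid with parabolic refinement
#' around the grid minimum. The square-root metric down-weights the broad
#' out-of-focus tails, the standard choice for astigmatic inversion. Events
#' whose best D exceeds `d_threshold` (out-of-focus or side-lobe excitation,
#' whose widths match no in-range model value) are flagged invalid.
#'
#' @param calib An [astig_calibration()].
#' @param sigma_x,sigma_y Measured widths in nm (vectorized, equal length).
#' @param grid_step z grid spacing in nm (default 1).
#' @param d_threshold Override for the calibration's rejection threshold.
#' @return Tibble with `z_nm`, `d_min`, `valid`.
#' @export
z_from_sigma <- function(calib, sigma_x, sigma_y, grid_step = 1,
                         d_threshold = NULL) {
  stopifnot(inherits(calib, "astig_calibration"))
  if (any(sigma_x <= 0) || any(sigma_y <= 0)) {
    stop_invalid("widths must be positive")
  }
  d_threshold <- d_threshold %||% calib$d_threshold
  zg <- seq(calib$z_range[1], calib$z_range[2], by = grid_step)
  mod <- sigma_at_z(calib, zg)
  rx <- sqrt(mod$sigma_x)
  ry <- sqrt(mod$sigma_y)
  n <- length(sigma_x)
  z_hat <- numeric(n)
  d_min <- numeric(n)
  sqx <- sqrt(sigma_x)
  sqy <- sqrt(sigma_y)
  for (i in seq_len(n)) {
    d <- (sqx[i] - rx)^2 + (sqy[i] - ry)^2
    dm <- min(d)
    cand <- which(d <= dm + 1e-12)
    j <- cand[which.min(abs(zg[cand]))] # tie-break toward smaller |z|
    z0 <- zg[j]
    # parabolic refinement on the three surrounding grid points
    if (j > 1L && j < length(zg)) {
      y1 <- d[j - 1L]; y2 <- d[j]; y3 <- d[j + 1L]
      denom <- y1 - 2 * y2 + y3
      if (denom > 0) {
        z0 <- zg[j] + grid_step * 0.5 * (y1 - y3) / denom
        z0 <- min(max(z0, zg[j - 1L]), zg[j + 1L])
      }
    }
    z_hat[i] <- z0
    d_min[i] <- dm
  }
  tibble::tibble(z_nm = z_hat, d_min = d_min, valid = d_min <= d_threshold)
}

#' Write / read a calibration as YAML
#'
#' @param calib An [astig_calibration()].
#' @param path File path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the calibration object.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "astig_calibration"))
  obj <- list(
    model = "sigma0 * sqrt(1 + u^2 + a3*u^3 + a4*u^4), u = (z - focus)/depth",
    axes = lapply(seq_len(2), function(i) as.list(calib$params[i, ])),
    z_range = calib$z_range,
    d_threshold = calib$d_threshold,
    residual_rms = as.list(calib$residual_rms))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- yaml::read_yaml(path)
  ax <- obj$axes
  get2 <- function(f) c(ax[[1]][[f]], ax[[2]][[f]])
  cal <- astig_calibration(
    sigma0 = get2("sigma0"), focus = get2("focus"), depth = get2("depth"),
    a3 = get2("a3"), a4 = get2("a4"),
    z_range = unlist(obj$z_range), d_threshold = obj$d_threshold)
  cal$residual_rms <- c(x = obj$residual_rms$x, y = obj$residual_rms$y)
  cal
}
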