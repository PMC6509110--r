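#' Bessel-beam excitation specification
#'
#' Describes the annular pupil used to create the excitation Bessel beam: the
#' illumination light fills an annulus between numerical apertures `na_inner`
#' and `na_outer` at the back focal plane of the excitation objective, which
#' produces a non-diffracting Bessel beam whose central-lobe thickness sets
#' the optical sectioning of the virtual light sheet.
#'
#' @param wavelength Excitation wavelength in nm (default 637, a deep-red
#'   line matched to silicon-rhodamine dyes).
#' @param na_inner,na_outer Inner and outer numerical aperture of the annulus
#'   (dimensionless, `0 < na_inner < na_outer < medium_index`). Defaults 0.42
#'   and 0.50.
#' @param medium_index Refractive index of the immersion/sample medium
#'   (default 1.33, water).
#'
#' @return An object of class `bessel_spec`.
#' @export
#' @examples
#' spec <- bessel_spec()
#' sheet_thickness_fwhm(spec) # ~ 495 nm
bessel_spec <- function(wavelength = 637, na_inner = 0.42, na_outer = 0.50,
                        medium_index = 1.33) {
  check_number(wavelength, "wavelength", min = 0, strict_min = TRUE)
  check_number(medium_index, "medium_index", min = 0, strict_min = TRUE)
  check_number(na_inner, "na_inner", min = 0, strict_min = TRUE)
  check_number(na_outer, "na_outer", min = 0, strict_min = TRUE)
  if (!(na_inner < na_outer)) {
    stop_invalid("`na_inner` must be strictly smaller than `na_outer`")
  }
  if (!(na_outer < medium_index)) {
    stop_invalid("`na_outer` must be smaller than the medium refractive index")
  }
  structure(
    list(wavelength = wavelength, na_inner = na_inner, na_outer = na_outer,
         medium_index = medium_index),
    class = "bessel_spec"
  )
}

#' @export
print.bessel_spec <- function(x, ...) {
  cat(sprintf(
    "<bessel_spec> lambda = %g nm, NA in [%.3f, %.3f], n = %.2f\n",
    x$wavelength, x$na_inner, x$na_outer, x$medium_index))
  invisible(x)
}

# Scalar annular-pupil field integral E(r) = int_{NAin}^{NAout} J0(k NA r) NA dNA
# evaluated by the trapezoid rule over the annulus. Vectorized over r.
annular_field <- function(spec, r, n_pupil = 401L) {
  k <- 2 * pi / spec$wavelength
  na <- seq(spec$na_inner, spec$na_outer, length.out = n_pupil)
  w <- rep(1, n_pupil)
  w[c(1L, n_pupil)] <- 0.5
  dna <- na[2L] - na[1L]
  # rows: r samples, cols: pupil samples
  vapply(r, function(ri) sum(besselJ(k * na * ri, 0) * na * w) * dna,
         numeric(1))
}

#' Radial intensity profile of the Bessel excitation beam
#'
#' Evaluates the scalar annular-pupil diffraction integral
#' \eqn{E(r) = \int_{NA_{in}}^{NA_{out}} J_0(k \, NA \, r) \, NA \, dNA}
#' with \eqn{k = 2\pi/\lambda}, squares it, and normalizes so that the
#' on-axis intensity is 1. The square of this profile across the sheet is
#' what weights the excitation of emitters at a given distance from the
#' sheet plane.
#'
#' @param spec A [bessel_spec()].
#' @param r_max Largest radius to sample, in nm.
#' @param n_samples Number of radial samples (at least 64).
#' @return A tibble with columns `r_nm` and `intensity` (I(0) = 1).
#' @export
bessel_radial_profile <- function(spec, r_max = 2000, n_samples = 2001L) {
  if (!inherits(spec, "bessel_spec")) {
    stop_invalid("`spec` must be a bessel_spec object")
  }
  check_number(r_max, "r_max", min = 0, strict_min = TRUE)
  check_number(n_samples, "n_samples", min = 64)
  r <- seq(0, r_max, length.out = as.integer(n_samples))
  intensity <- annular_field(spec, r)^2
  tibble::tibble(r_nm = r, intensity = intensity / intensity[1L])
}

#' Optical-sectioning thickness of the light sheet
#'
#' Full width at half maximum of the central lobe of the Bessel beam's radial
#' intensity profile. The crossing of half maximum is located on a 1 nm grid
#' with linear interpolation between adjacent samples; the profile is
#' symmetric so the FWHM is twice the half-maximum radius.
#'
#' @param spec A [bessel_spec()].
#' @return FWHM in nm.
#' @export
sheet_thickness_fwhm <- function(spec) {
  if (!inherits(spec, "bessel_spec")) {
    stop_invalid("`spec` must be a bessel_spec object")
  }
  r_max <- 2000
  repeat {
    prof <- bessel_radial_profile(spec, r_max = r_max,
                                  n_samples = as.integer(r_max) + 1L)
    idx <- which(prof$intensity < 0.5)
    if (length(idx) > 0L) break
    r_max <- r_max * 2
    if (r_max > 1e6) stop_invalid("no half-maximum crossing found")
  }
  i <- idx[1L]
  y1 <- prof$intensity[i - 1L]
  y2 <- prof$intensity[i]
  r_half <- prof$r_nm[i - 1L] +
    (0.5 - y1) / (y2 - y1) * (prof$r_nm[i] - prof$r_nm[i - 1L])
  2 * r_half
}

#' Acquisition-plan arithmetic for a volumetric scan
#'
#' @param n_planes Number of z planes per volume (>= 0).
#' @param exposure Exposure per plane in seconds.
#' @param overhead Extra per-plane overhead in seconds (default 0).
#' @return A one-row tibble with `n_planes`, `exposure`, `overhead`,
#'   `total_time` (s) and `plane_rate` (planes/s; `NA` when the per-plane
#'   time is zero).
#' @export
#' @examples
#' acquisition_plan(151, 0.020) # 3.02 s per volume, 50 planes/s
acquisition_plan <- function(n_planes, exposure, overhead = 0) {
  check_number(n_planes, "n_planes", min = 0)
  check_number(exposure, "exposure", min = 0)
  check_number(overhead, "overhead", min = 0)
  per_plane <- exposure + overhead
  tibble::tibble(
    n_planes = n_planes,
    exposure = exposure,
    overhead = overhead,
    total_time = n_planes * per_plane,
    plane_rate = if (per_plane > 0) 1 / per_plane else NA_real_
  )
}

#' Illumination power density at the sample
#'
#' Protocol arithmetic: assumes the beam power is spread uniformly over the
#' cross-sectional area swept by the X scan (scan range times sheet length).
#'
#' @param power Laser power at the sample, in W.
#' @param scan_range X-scanning range in micrometres.
#' @param sheet_length Light-sheet (beam propagation) length in micrometres.
#' @return Power density in kW/cm^2.
#' @export
power_density <- function(power, scan_range, sheet_length) {
  check_number(power, "power", min = 0, strict_min = TRUE)
  check_number(scan_range, "scan_range", min = 0, strict_min = TRUE)
  check_number(sheet_length, "sheet_length", min = 0, strict_min = TRUE)
  area_cm2 <- scan_range * sheet_length * 1e-8 # um^2 -> cm^2
  (power / area_cm2) / 1000                    # W/cm^2 -> kW/cm^2
}

#' Is a power density inside the optimal operating band?
#'
#' The band defaults to 0.17--0.33 kW/cm^2, the regime in which
#' spontaneously blinking dyes give the best localization yield without
#' excess bleaching.
#'
#' @param density Power density in kW/cm^2.
#' @param band Length-2 numeric, inclusive bounds in kW/cm^2.
#' @return Logical.
#' @export
in_optimal_range <- function(density, band = c(0.17, 0.33)) {
  stopifnot(length(band) == 2L, band[1] <= band[2])
  density >= band[1] & density <= band[2]
}
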