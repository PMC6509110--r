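#' Fourier ring correlation curve
#'
#' Splits the localization events into two random halves (seeded), renders
#' each half as a 2D event histogram at `render_pixel`, and correlates the
#' two Fourier transforms ring by ring:
#' \deqn{FRC(q) = \frac{\mathrm{Re}\sum_{|f| \in q} F_1 \bar F_2}
#'   {\sqrt{\sum_{|f| \in q} |F_1|^2 \sum_{|f| \in q} |F_2|^2}}}
#' The curve is averaged over `n_splits` independent splits. Histogram
#' rendering (no Gaussian smoothing) is used on purpose: smoothing inflates
#' the apparent correlation. A random event split (rather than odd/even
#' frames) avoids blinking-correlation bias, at the cost that re-blinks of
#' one molecule landing in both halves can still bias the FRC optimistic.
#'
#' @param table Localization table (>= 100 events).
#' @param render_pixel Histogram pixel in nm (default 10).
#' @param n_splits Number of random half-splits to average (default 5).
#' @param seed Integer seed for the splits.
#' @param split `"random"` (default) or `"none"`; with `"none"` both halves
#'   are the full dataset (the self-correlation reference, FRC = 1).
#' @param split_assignment Optional logical vector (one per event) fixing
#'   the half-split explicitly; overrides `split`/`n_splits`.
#' @param coords Columns to render, default `c("x_nm", "y_nm")`.
#' @return A tibble of class `frc_curve` with `freq_nm_inv` (ring center
#'   spatial frequency) and `correlation`; attributes `render_pixel`,
#'   `n_splits`, `n_events`, `threshold` (1/7).
#' @export
frc_curve <- function(table, render_pixel = 10, n_splits = 5, seed = 1L,
                      split = c("random", "none"),
                      split_assignment = NULL,
                      coords = c("x_nm", "y_nm")) {
  split <- match.arg(split)
  x <- table[[coords[1]]]
  y <- table[[coords[2]]]
  n <- length(x)
  if (is.null(split_assignment) && split == "random" && n < 100L) {
    rlang::abort("need at least 100 events for an FRC estimate",
                 class = "sheetloc_validation")
  }
  xr <- range(x); yr <- range(y)
  side <- max(xr[2] - xr[1], yr[2] - yr[1]) + 2 * render_pixel
  npx <- max(16L, ceiling(side / render_pixel))
  xr <- c(xr[1] - render_pixel, xr[1] - render_pixel + npx * render_pixel)
  yr <- c(yr[1] - render_pixel, yr[1] - render_pixel + npx * render_pixel)

  # ring index per FFT pixel (integer radius in frequency-index units)
  fidx <- c(0:(npx %/% 2), -((npx - npx %/% 2 - 1):1)) # fftfreq * npx
  fr <- sqrt(outer(fidx^2, fidx^2, "+"))
  ring <- round(fr)
  max_ring <- npx %/% 2
  ring_f <- factor(ring, levels = 0:max_ring)

  one_split <- function(half1, half2) {
    h1 <- hist2_events(x[half1], y[half1], render_pixel, xr, yr)
    h2 <- hist2_events(x[half2], y[half2], render_pixel, xr, yr)
    F1 <- fft(h1); F2 <- fft(h2)
    num <- tapply(as.vector(Re(F1 * Conj(F2))), ring_f, sum)
    d1 <- tapply(as.vector(abs(F1)^2), ring_f, sum)
    d2 <- tapply(as.vector(abs(F2)^2), ring_f, sum)
    as.numeric(num / sqrt(d1 * d2))
  }

  curves <- with_seed(seed, {
    if (!is.null(split_assignment)) {
      list(one_split(which(split_assignment), which(!split_assignment)))
    } else if (split == "none") {
      list(one_split(seq_len(n), seq_len(n)))
    } else {
      lapply(seq_len(n_splits), function(s) {
        h <- sample(n, n %/% 2)
        one_split(h, setdiff(seq_len(n), h))
      })
    }
  })
  corr <- rowMeans(do.call(cbind, curves), na.rm = TRUE)
  out <- tibble::tibble(
    freq_nm_inv = (1:max_ring) / (npx * render_pixel),
    correlation = corr[2:(max_ring + 1L)]) # drop the DC ring
  out <- out[is.finite(out$correlation), , drop = FALSE]
  structure(out,
            render_pixel = render_pixel,
            n_splits = if (split == "none") 1L else n_splits,
            n_events = n, threshold = 1 / 7,
            class = c("frc_curve", class(out)))
}

#' Resolution from an FRC curve
#'
#' The resolution is `1 / q*` where `q*` is the first downward crossing of
#' the threshold (default 1/7, the standard fixed-threshold criterion),
#' linearly interpolated between rings. When the curve never drops below the
#' threshold the resolution is better than measurable at this rendering
#' pixel: the Nyquist bound `2 * render_pixel` is returned with
#' `bound = TRUE`.
#'
#' @param curve An `frc_curve`.
#' @param threshold Crossing threshold (default: the curve's, 1/7).
#' @param smooth Optional moving-average window (rings) applied before the
#'   crossing search (0 = none).
#' @return One-row tibble: `resolution_nm`, `bound`, `threshold`.
#' @export
frc_resolution <- function(curve, threshold = NULL, smooth = 0) {
  threshold <- threshold %||% attr(curve, "threshold") %||% (1 / 7)
  q <- curve$freq_nm_inv
  cc <- curve$correlation
  if (smooth > 1) cc <- moving_average(cc, smooth)
  below <- which(cc < threshold)
  if (length(below) == 0L || below[1] == 1L) {
    if (length(below) == 0L) {
      rp <- attr(curve, "render_pixel") %||% (1 / (2 * max(q)))
      return(tibble::tibble(resolution_nm = 2 * rp, bound = TRUE,
                            threshold = threshold))
    }
    return(tibble::tibble(resolution_nm = 1 / q[1], bound = TRUE,
                          threshold = threshold))
  }
  i <- below[1]
  f <- (cc[i - 1L] - threshold) / (cc[i - 1L] - cc[i])
  q_star <- q[i - 1L] + f * (q[i] - q[i - 1L])
  tibble::tibble(resolution_nm = 1 / q_star, bound = FALSE,
                 threshold = threshold)
}

#' FRC resolution versus accumulated volumes
#'
#' Pools the events of the first k volumes for increasing k and reports the
#' FRC resolution of each accumulation: the resolution-versus-imaging-volume
#' curve that shows when accumulating further volumes stops improving the
#' reconstruction.
#'
#' @param table Localization table with a `volume` column.
#' @param checkpoints Integer vector of volume counts k to evaluate
#'   (default: every volume).
#' @param render_pixel,n_splits,seed Passed to [frc_curve()].
#' @return Tibble: `n_volumes`, `resolution_nm`, `bound`.
#' @export
frc_vs_accumulation <- function(table, checkpoints = NULL, render_pixel = 10,
                                n_splits = 5, seed = 1L) {
  if (!"volume" %in% names(table)) {
    stop_invalid("table needs a `volume` column")
  }
  vols <- sort(unique(table$volume))
  checkpoints <- checkpoints %||% seq_along(vols)
  res <- purrr::map(checkpoints, function(k) {
    sub <- table[table$volume %in% vols[seq_len(k)], , drop = FALSE]
    r <- frc_resolution(frc_curve(sub, render_pixel = render_pixel,
                                  n_splits = n_splits, seed = seed))
    tibble::tibble(n_volumes = k, resolution_nm = r$resolution_nm,
                   bound = r$bound)
  })
  dplyr::bind_rows(res)
}
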