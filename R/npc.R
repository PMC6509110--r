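#' Parameters for NPC candidate selection and averaging
#'
#' Defaults follow the standard pore-averaging recipe: 10 nm binning, mask
#' hole-filling and dilation by a 3x3 square, dilated-cluster area filter of
#' 250--300 px^2 (inclusive), 32x32 px crops, top-50 overlay.
#'
#' @param bin_pixel Binning pixel in nm (default 10).
#' @param area_bounds Inclusive dilated-component area interval in px^2.
#' @param dilation_size Square structuring-element side in px (default 3).
#' @param roi_size Crop size in px (even; default 32).
#' @param n_top Number of best-ranked fits to overlay (default 50).
#' @param kde_grid KDE evaluation lattice spacing in nm (default 2).
#' @param kde_bandwidth_rule `"silverman"` or `"fixed"`.
#' @param kde_bandwidth Bandwidth in nm when the rule is `"fixed"`.
#' @param r0_starts Multi-start ring radii for the donut fit, nm.
#' @param donut_profile Radial ring profile for fits (see [donut_profile()]).
#' @return Object of class `npc_params`.
#' @export
npc_params <- function(bin_pixel = 10, area_bounds = c(250, 300),
                       dilation_size = 3L, roi_size = 32L, n_top = 50L,
                       kde_grid = 2, kde_bandwidth_rule = c("silverman",
                                                            "fixed"),
                       kde_bandwidth = 10, r0_starts = c(30, 50, 70),
                       donut_profile = c("blurred_ring", "gaussian_ring")) {
  check_number(bin_pixel, "bin_pixel", min = 0, strict_min = TRUE)
  if (length(area_bounds) != 2L || area_bounds[1] > area_bounds[2]) {
    stop_invalid("`area_bounds` must be a non-empty interval")
  }
  roi_size <- as.integer(roi_size)
  if (roi_size %% 2L != 0L) stop_invalid("`roi_size` must be even")
  structure(
    list(bin_pixel = bin_pixel, area_bounds = area_bounds,
         dilation_size = as.integer(dilation_size), roi_size = roi_size,
         n_top = as.integer(n_top), kde_grid = kde_grid,
         kde_bandwidth_rule = match.arg(kde_bandwidth_rule),
         kde_bandwidth = kde_bandwidth, r0_starts = r0_starts,
         donut_profile = match.arg(donut_profile)),
    class = "npc_params")
}

#' Bin a 2D point cloud into a count image
#'
#' Events are assigned to pixels by floor division of their coordinates;
#' the image total equals the number of points.
#'
#' @param table Data frame with `x_nm`, `y_nm` (or a 2-column matrix).
#' @param bin_pixel Pixel size in nm (default 10).
#' @param origin Length-2 nm coordinates of the (1,1) pixel corner; default
#'   snaps to the data minimum on the bin grid.
#' @param dims Optional `c(ny, nx)` image size in px.
#' @return Count matrix (rows = y) with attributes `pixel` and `origin`.
#' @export
bin_pointcloud <- function(table, bin_pixel = 10, origin = NULL,
                           dims = NULL) {
  check_number(bin_pixel, "bin_pixel", min = 0, strict_min = TRUE)
  if (is.matrix(table)) {
    x <- table[, 1]; y <- table[, 2]
  } else {
    x <- table$x_nm; y <- table$y_nm
  }
  if (length(x) == 0L) {
    out <- matrix(0, 1, 1)
    attr(out, "pixel") <- bin_pixel
    attr(out, "origin") <- origin %||% c(0, 0)
    return(out)
  }
  origin <- origin %||% (floor(c(min(x), min(y)) / bin_pixel) * bin_pixel)
  ix <- floor((x - origin[1]) / bin_pixel) + 1L
  iy <- floor((y - origin[2]) / bin_pixel) + 1L
  nx <- if (!is.null(dims)) dims[2] else max(ix)
  ny <- if (!is.null(dims)) dims[1] else max(iy)
  ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  img <- matrix(0, ny, nx)
  tb <- table(factor(iy[ok] + (ix[ok] - 1L) * ny, levels = seq_len(nx * ny)))
  img[] <- as.numeric(tb)
  attr(img, "pixel") <- bin_pixel
  attr(img, "origin") <- origin
  img
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  ny <- nrow(lab); nx <- ncol(lab)
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    di <- sh[1]; dj <- sh[2]
    i_rng <- 1:(ny - 1L)
    j_rng <- if (dj > 0) 1:(nx - 1L) else 2:nx
    a <- lab[i_rng, j_rng, drop = FALSE]
    b <- lab[i_rng + di, j_rng + dj, drop = FALSE]
    touch <- which(a > 0L & b > 0L & a != b)
    for (t in touch) {
      ra <- find(a[t]); rb <- find(b[t])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Select NPC candidates from a binned event image
#'
#' Builds a mask of pixels carrying localized events, fills holes
#' morphologically, dilates by a square structuring element, labels
#' 8-connected components, keeps components whose dilated area lies inside
#' `area_bounds` (inclusive), computes their centroids, and crops a
#' `roi_size` x `roi_size` window from the binned image centered at the
#' rounded centroid (`[c - roi/2, c + roi/2)`). Components whose crop would
#' cross the image edge are dropped. Deterministic and independent of event
#' input order.
#'
#' @param binned Count image from [bin_pointcloud()].
#' @param params An [npc_params()].
#' @return Tibble: `id`, `centroid_x_nm`, `centroid_y_nm`, `area_px`,
#'   `crop` (list of matrices), `crop_origin_x`, `crop_origin_y` (nm of the
#'   crop's (1,1) pixel corner).
#' @export
select_candidates <- function(binned, params = npc_params()) {
  pixel <- attr(binned, "pixel") %||% params$bin_pixel
  origin <- attr(binned, "origin") %||% c(0, 0)
  empty <- tibble::tibble(
    id = integer(), centroid_x_nm = numeric(), centroid_y_nm = numeric(),
    area_px = integer(), crop = list(),
    crop_origin_x = numeric(), crop_origin_y = numeric())
  if (sum(binned) == 0) return(empty)
  mask <- binned > 0
  filled <- EBImage::fillHull(mask)
  brush <- matrix(1L, params$dilation_size, params$dilation_size)
  dil <- EBImage::dilate(filled, brush)
  lab <- label_components_8(matrix(as.logical(dil), nrow(mask)))
  n <- max(lab)
  if (n == 0L) return(empty)
  half <- params$roi_size %/% 2L
  rows <- vector("list", n)
  ny <- nrow(binned); nx <- ncol(binned)
  for (cc in seq_len(n)) {
    idx <- which(lab == cc, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < params$area_bounds[1] || area > params$area_bounds[2]) next
    cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
    ry <- round(cy); rx <- round(cx)
    i0 <- ry - half; i1 <- ry + half - 1L
    j0 <- rx - half; j1 <- rx + half - 1L
    if (i0 < 1L || j0 < 1L || i1 > ny || j1 > nx) next
    crop <- binned[i0:i1, j0:j1]
    rows[[cc]] <- tibble::tibble(
      id = cc,
      centroid_x_nm = origin[1] + (cx - 0.5) * pixel,
      centroid_y_nm = origin[2] + (cy - 0.5) * pixel,
      area_px = area,
      crop = list(crop),
      crop_origin_x = origin[1] + (j0 - 1L) * pixel,
      crop_origin_y = origin[2] + (i0 - 1L) * pixel)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty)
  out$id <- seq_len(nrow(out))
  out
}

#' Radial donut profile used by the ring fit
#'
#' `"blurred_ring"` (default) is an ideal circle of radius `r0` convolved
#' with an isotropic Gaussian of width `sr` — the exact expected density of
#' localization events from ring-arranged binding sites with `sr` of
#' localization spread:
#' \deqn{S(r) = \exp\!\left(-\frac{r^2 + r_0^2}{2 s_r^2}\right)
#'   I_0\!\left(\frac{r\, r_0}{s_r^2}\right)}
#' (evaluated in its numerically stable exponentially-scaled form).
#' `"gaussian_ring"` is the simpler Gaussian-in-radius profile
#' \eqn{\exp(-(r - r_0)^2 / (2 s_r^2))}; it describes a well-resolved donut
#' but underestimates `r0` when the localization spread is comparable to
#' the ring radius, because the blur fills the ring in.
#'
#' @param r Radial distance, nm (vectorized).
#' @param r0 Ring radius, nm.
#' @param sr Ring width / blur, nm.
#' @param profile Profile name.
#' @return Profile values (peak of order 1).
#' @export
donut_profile <- function(r, r0, sr,
                          profile = c("blurred_ring", "gaussian_ring")) {
  profile <- match.arg(profile)
  if (profile == "gaussian_ring") {
    exp(-((r - r0)^2) / (2 * sr^2))
  } else {
    exp(-((r - r0)^2) / (2 * sr^2)) * bessel_i0_scaled(r * r0 / sr^2)
  }
}

# Exponentially scaled modified Bessel function I0(x) * exp(-|x|), by the
# classic rational polynomial approximations (abs. error ~ 1e-7); fully
# vectorized, much faster than besselI() inside iterative fits.
bessel_i0_scaled <- function(x) {
  x <- abs(x)
  out <- numeric(length(x))
  lo <- x <= 3.75
  if (any(lo)) {
    t2 <- (x[lo] / 3.75)^2
    p <- 1 + t2 * (3.5156229 + t2 * (3.0899424 + t2 * (1.2067492 +
           t2 * (0.2659732 + t2 * (0.0360768 + t2 * 0.0045813)))))
    out[lo] <- p * exp(-x[lo])
  }
  if (any(!lo)) {
    t <- 3.75 / x[!lo]
    p <- 0.39894228 + t * (0.01328592 + t * (0.00225319 + t * (-0.00157565 +
           t * (0.00916281 + t * (-0.02057706 + t * (0.02635537 +
           t * (-0.01647633 + t * 0.00392377)))))))
    out[!lo] <- p / sqrt(x[!lo])
  }
  out
}

#' Fit a donut (ring) model to a candidate image
#'
#' Least-squares fit of
#' \deqn{I(x, y) = A \, S(\|(x,y) - center\|;\, r_0, \sigma_r) + c}
#' to a cropped candidate image, where `S` is a [donut_profile()]. The fit
#' is multi-started over ring radii `r0_starts` with the intensity centroid
#' as the initial center; the lowest-RSS solution is kept. The
#' event-coordinate variant bins the events at `event_bin` nm first and fits
#' the same model.
#'
#' @param crop Candidate image matrix, or a data frame of events (`x_nm`,
#'   `y_nm`) when `events = TRUE`.
#' @param pixel Pixel size of `crop` in nm.
#' @param r0_starts Ring-radius starts in nm.
#' @param events Treat `crop` as an event table.
#' @param event_bin Binning for the event variant, nm.
#' @param profile Radial profile (see [donut_profile()]).
#' @return Object of class `donut_fit`: list with `center` (nm, in crop
#'   coordinates), `r0`, `sigma_r`, `amplitude`, `offset`, `rss`,
#'   `rss_norm` (RSS / total crop energy) and `converged`.
#' @export
fit_donut <- function(crop, pixel = 10, r0_starts = c(30, 50, 70),
                      events = FALSE, event_bin = 5,
                      profile = c("blurred_ring", "gaussian_ring")) {
  profile <- match.arg(profile)
  if (events) {
    img <- bin_pointcloud(crop, bin_pixel = event_bin,
                          origin = c(0, 0))
    return(fit_donut(img, pixel = event_bin, r0_starts = r0_starts,
                     profile = profile))
  }
  stopifnot(is.matrix(crop))
  failed <- structure(
    list(center = c(NA_real_, NA_real_), r0 = NA_real_, sigma_r = NA_real_,
         amplitude = NA_real_, offset = NA_real_, rss = NA_real_,
         rss_norm = NA_real_, converged = FALSE),
    class = "donut_fit")
  nz <- sum(crop != 0)
  if (nz < 20L) return(failed)
  ny <- nrow(crop); nx <- ncol(crop)
  xg <- rep((seq_len(nx) - 0.5) * pixel, each = ny)
  yg <- rep((seq_len(ny) - 0.5) * pixel, times = nx)
  v <- as.vector(crop)
  tot <- sum(v)
  cx0 <- sum(v * xg) / tot
  cy0 <- sum(v * yg) / tot
  a0 <- max(v) - min(v)
  c0 <- min(v)
  energy <- sum(v^2)
  best <- NULL
  for (r0s in r0_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ A * donut_profile(sqrt((xg - x0)^2 + (yg - y0)^2), r0, sr,
                              profile) + cc,
        data = data.frame(v = v, xg = xg, yg = yg),
        start = list(x0 = cx0, y0 = cy0, r0 = r0s, sr = 15,
                     A = max(a0, 1e-6), cc = c0),
        lower = c(x0 = 0, y0 = 0, r0 = 1, sr = 1, A = 0, cc = -Inf),
        upper = c(x0 = nx * pixel, y0 = ny * pixel,
                  r0 = sqrt((nx^2 + ny^2)) * pixel, sr = nx * pixel,
                  A = Inf, cc = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      p <- coef(fit)
      best <- list(p = p, rss = rss)
    }
  }
  if (is.null(best)) return(failed)
  p <- best$p
  # reject degenerate solutions (no ring contrast)
  if (!all(is.finite(p)) || p["A"] <= sqrt(energy) * 1e-6 || p["r0"] <= 1) {
    return(failed)
  }
  structure(
    list(center = unname(c(p["x0"], p["y0"])), r0 = unname(p["r0"]),
         sigma_r = unname(p["sr"]), amplitude = unname(p["A"]),
         offset = unname(p["cc"]), rss = best$rss,
         rss_norm = best$rss / energy, converged = TRUE),
    class = "donut_fit")
}

#' @export
print.donut_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<donut_fit> failed\n")
  } else {
    cat(sprintf(
      "<donut_fit> center (%.1f, %.1f) nm, r0 = %.1f nm, sigma_r = %.1f nm, norm. RSS %.3g\n",
      x$center[1], x$center[2], x$r0, x$sigma_r, x$rss_norm))
  }
  invisible(x)
}

# Silverman's rule-of-thumb bandwidth per axis.
silverman_bw <- function(v) {
  n <- length(v)
  s <- min(sd(v), IQR(v) / 1.349)
  if (!is.finite(s) || s <= 0) s <- sd(v)
  if (!is.finite(s) || s <= 0) return(1)
  1.06 * s * n^(-1 / 5)
}

#' Most probable center of a candidate's event cloud by 2D KDE
#'
#' Evaluates a bivariate Gaussian kernel density estimate on a regular
#' lattice over the events' bounding box (bandwidth per axis by Silverman's
#' rule, or fixed) and returns the probability-weighted centroid of the
#' density map. With fewer than 5 events the arithmetic mean is returned
#' and flagged.
#'
#' @param events Data frame with `x_nm`, `y_nm`.
#' @param params An [npc_params()] (grid spacing and bandwidth rule).
#' @return List: `center` (length-2 nm), `fallback` (TRUE when the mean was
#'   used), `bandwidth` (nm per axis).
#' @export
kde_center <- function(events, params = npc_params()) {
  x <- events$x_nm; y <- events$y_nm
  n <- length(x)
  if (n == 0L) stop_invalid("no events")
  if (n < 5L) {
    return(list(center = c(mean(x), mean(y)), fallback = TRUE,
                bandwidth = c(NA_real_, NA_real_)))
  }
  bw <- if (params$kde_bandwidth_rule == "silverman") {
    c(silverman_bw(x), silverman_bw(y))
  } else {
    rep(params$kde_bandwidth, 2)
  }
  bw <- pmax(bw, params$kde_grid / 2)
  g <- params$kde_grid
  gx <- seq(min(x) - 3 * bw[1], max(x) + 3 * bw[1], by = g)
  gy <- seq(min(y) - 3 * bw[2], max(y) + 3 * bw[2], by = g)
  # density on the lattice: sum of separable kernels as a matrix product
  ky <- outer(gy, y, function(g, yi) dnorm(g, yi, bw[2]))
  kx <- outer(x, gx, function(xi, g) dnorm(g, xi, bw[1]))
  dens <- ky %*% kx
  tot <- sum(dens)
  cx <- sum(dens %*% gx) / tot
  cy <- sum(t(dens) %*% gy) / tot
  list(center = c(cx, cy), fallback = FALSE, bandwidth = bw)
}

# Bilinear image translation: output(i, j) = input at (i + dy, j + dx),
# zero outside. dx, dy in pixels.
shift_bilinear <- function(img, dx, dy) {
  ny <- nrow(img); nx <- ncol(img)
  out <- matrix(0, ny, nx)
  j <- seq_len(nx) + dx
  i <- seq_len(ny) + dy
  j0 <- floor(j); i0 <- floor(i)
  fj <- j - j0; fi <- i - i0
  getm <- function(ii, jj) {
    ok_i <- ii >= 1L & ii <= ny
    ok_j <- jj >= 1L & jj <= nx
    m <- matrix(0, ny, nx)
    m[ok_i, ok_j] <- img[ii[ok_i], jj[ok_j]]
    m
  }
  (1 - fi) %o% (1 - fj) * getm(i0, j0) +
    (1 - fi) %o% fj * getm(i0, j0 + 1L) +
    fi %o% (1 - fj) * getm(i0 + 1L, j0) +
    fi %o% fj * getm(i0 + 1L, j0 + 1L)
}

#' Center and accumulate the best-ranked candidates
#'
#' Ranks donut fits by RSS normalized by crop energy (so bright and dim
#' pores compete fairly), keeps the `n_top` best, shifts each crop so its
#' KDE center lands on the crop center (bilinear interpolation), and sums.
#'
#' @param candidates Candidate tibble from [select_candidates()].
#' @param fits List of [fit_donut()] results, one per candidate.
#' @param centers List of [kde_center()] results (or length-2 vectors, nm in
#'   the same frame as the candidate crops).
#' @param n_top Number of fits to keep (default 50).
#' @return Accumulated image matrix with attributes `pixel`, `n_used`,
#'   `ranks` (candidate ids in overlay order).
#' @export
overlay_average <- function(candidates, fits, centers, n_top = 50L) {
  stopifnot(nrow(candidates) == length(fits),
            nrow(candidates) == length(centers))
  conv <- purrr::map_lgl(fits, ~ isTRUE(.x$converged))
  if (!any(conv)) {
    rlang::abort("no successful donut fits to overlay",
                 class = "sheetloc_fit_error")
  }
  score <- purrr::map_dbl(fits, ~ if (isTRUE(.x$converged)) .x$rss_norm
                                  else Inf)
  ord <- order(score)
  ord <- ord[conv[ord]]
  take <- utils::head(ord, n_top)
  pixel <- attr(candidates$crop[[take[1]]], "pixel") %||% NA_real_
  crop1 <- candidates$crop[[take[1]]]
  ny <- nrow(crop1); nx <- ncol(crop1)
  acc <- matrix(0, ny, nx)
  for (i in take) {
    crop <- candidates$crop[[i]]
    ctr <- centers[[i]]
    c_nm <- if (is.list(ctr)) ctr$center else ctr
    # crop-local nm coordinates of the KDE center
    cx_px <- (c_nm[1] - candidates$crop_origin_x[i]) / get_pixel(crop, pixel)
    cy_px <- (c_nm[2] - candidates$crop_origin_y[i]) / get_pixel(crop, pixel)
    acc <- acc + shift_bilinear(crop, cx_px - nx / 2, cy_px - ny / 2)
  }
  attr(acc, "pixel") <- get_pixel(crop1, pixel)
  attr(acc, "n_used") <- length(take)
  attr(acc, "ranks") <- candidates$id[take]
  acc
}

get_pixel <- function(img, fallback) {
  p <- attr(img, "pixel")
  if (!is.null(p)) p else if (is.finite(fallback)) fallback else 10
}

#' Estimate the pore diameter from an overlay image
#'
#' Fits the donut model to the accumulated overlay; the diameter is `2 r0`.
#'
#' @param overlay Overlay image from [overlay_average()].
#' @param pixel Pixel size in nm (default: the overlay's attribute).
#' @param r0_starts Multi-start radii, nm.
#' @param profile Radial profile (see [donut_profile()]).
#' @return Diameter in nm.
#' @export
estimate_diameter <- function(overlay, pixel = NULL,
                              r0_starts = c(30, 50, 70),
                              profile = c("blurred_ring", "gaussian_ring")) {
  pixel <- pixel %||% attr(overlay, "pixel") %||% 10
  fit <- fit_donut(overlay, pixel = pixel, r0_starts = r0_starts,
                   profile = profile)
  if (!fit$converged) {
    rlang::abort("donut fit on the overlay failed",
                 class = "sheetloc_fit_error")
  }
  2 * fit$r0
}

#' Full NPC particle-averaging pipeline
#'
#' Bins the localization table, selects ring candidates by the
#' fill/dilate/area-filter recipe, computes each candidate's KDE center from
#' its raw events, ranks candidates by donut-fit quality, overlays the top
#' `n_top`, and estimates the pore diameter from the overlay.
#'
#' @param table Localization table (`x_nm`, `y_nm`).
#' @param params An [npc_params()].
#' @return Object of class `npc_average`: list with `candidates` (tibble
#'   including per-candidate fit columns), `overlay`, `diameter_nm`,
#'   `overlay_fit` and `params`.
#' @export
npc_average <- function(table, params = npc_params()) {
  binned <- bin_pointcloud(table, bin_pixel = params$bin_pixel)
  cands <- select_candidates(binned, params)
  if (nrow(cands) == 0L) {
    rlang::abort("no NPC candidates survived selection",
                 class = "sheetloc_fit_error")
  }
  pixel <- params$bin_pixel
  fits <- vector("list", nrow(cands))
  centers <- vector("list", nrow(cands))
  for (i in seq_len(nrow(cands))) {
    x0 <- cands$crop_origin_x[i]; y0 <- cands$crop_origin_y[i]
    side <- params$roi_size * pixel
    ev <- table[table$x_nm >= x0 & table$x_nm < x0 + side &
                table$y_nm >= y0 & table$y_nm < y0 + side, , drop = FALSE]
    centers[[i]] <- if (nrow(ev) > 0L) {
      kc <- kde_center(ev, params)
      kc$center <- kc$center # nm, global frame (same frame as crop origins)
      kc
    } else {
      list(center = c(x0 + side / 2, y0 + side / 2), fallback = TRUE)
    }
    fits[[i]] <- fit_donut(cands$crop[[i]], pixel = pixel,
                           r0_starts = params$r0_starts,
                           profile = params$donut_profile)
  }
  for (i in seq_len(nrow(cands))) attr(cands$crop[[i]], "pixel") <- pixel
  overlay <- overlay_average(cands, fits, centers, n_top = params$n_top)
  ofit <- fit_donut(overlay, pixel = pixel, r0_starts = params$r0_starts,
                    profile = params$donut_profile)
  cands$r0_nm <- purrr::map_dbl(fits, "r0")
  cands$sigma_r_nm <- purrr::map_dbl(fits, "sigma_r")
  cands$rss_norm <- purrr::map_dbl(fits, "rss_norm")
  cands$converged <- purrr::map_lgl(fits, "converged")
  cands$rank <- rank(ifelse(cands$converged, cands$rss_norm, Inf),
                     ties.method = "first")
  structure(
    list(candidates = cands, overlay = overlay,
         diameter_nm = if (ofit$converged) 2 * ofit$r0 else NA_real_,
         overlay_fit = ofit, params = params),
    class = "npc_average")
}

#' @export
print.npc_average <- function(x, ...) {
  cat(sprintf(
    "<npc_average> %d candidate(s), %d overlaid; diameter %.1f nm\n",
    nrow(x$candidates), attr(x$overlay, "n_used"), x$diameter_nm))
  invisible(x)
}
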