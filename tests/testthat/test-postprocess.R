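test_that("a static noise-free fiducial gives a zero drift trace", {
  tab <- fiducial_table(n_fid = 2, n_frames = 100, precision = 0)
  tr <- track_fiducials(tab, link_radius = 500, smoothing_window = 10)
  expect_true(all(abs(tr$dx) < 1e-9))
  expect_true(all(abs(tr$dy) < 1e-9))
})

test_that("linear drift of 0.5 nm/frame is recovered within 5%", {
  tab <- fiducial_table(n_fid = 3, n_frames = 2000, precision = 15,
                        drift_per_frame = c(0.5, -0.5, 0), seed = 3)
  tr <- track_fiducials(tab, link_radius = 800, smoothing_window = 50)
  fit_x <- coef(lm(tr$dx ~ tr$frame))[2]
  fit_y <- coef(lm(tr$dy ~ tr$frame))[2]
  expect_lt(abs(fit_x - 0.5) / 0.5, 0.05)
  expect_lt(abs(fit_y + 0.5) / 0.5, 0.05)
})

test_that("corrected-trace scatter reports the localization precision", {
  tab <- fiducial_table(n_fid = 4, n_frames = 1500, precision = 40,
                        seed = 5)
  tr <- track_fiducials(tab, link_radius = 800, smoothing_window = 50)
  prec <- attr(tr, "precision_nm")
  expect_equal(unname(prec["x"]), 40, tolerance = 2 / 40)
  expect_equal(unname(prec["y"]), 40, tolerance = 2 / 40)
})

test_that("drift correction strictly reduces fiducial scatter", {
  improved <- vapply(1:20, function(s) {
    tab <- fiducial_table(n_fid = 2, n_frames = 600, precision = 15,
                          drift_per_frame = c(0.4, 0.2, 0), seed = s)
    tr <- track_fiducials(tab, link_radius = 800, smoothing_window = 50)
    corr <- apply_drift(tab, tr)
    sd_of <- function(t) {
      mean(tapply(t$x_nm, t$structure_id, sd) +
           tapply(t$y_nm, t$structure_id, sd))
    }
    sd_of(corr) < sd_of(tab)
  }, logical(1))
  expect_true(all(improved))
})

test_that("cross-correlation recovers an injected block shift", {
  # two blocks: identical structure, second shifted +30 nm in x
  gt <- make_ground_truth("npc_ring",
                          list(n_pores = 40, field = c(5000, 5000),
                               min_spacing = 200), seed = 2)
  ev <- simulate_localization_events(gt, events_per_emitter = 12,
                                     precision_nm = 10, n_frames = 200,
                                     seed = 3)
  ev2 <- ev
  ev2$frame <- ev2$frame + 200
  ev2$x_nm <- ev2$x_nm + 30
  both <- dplyr::bind_rows(ev, ev2)
  tr <- estimate_drift_xcorr(both, block_frames = 200, render_pixel = 20)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$dx[1], 0)
  expect_lt(abs(tr$dx[2] - 30), 10) # within render_pixel / 2
  expect_lt(abs(tr$dy[2]), 10)
  # identical blocks give zero shift
  same <- dplyr::bind_rows(ev, dplyr::mutate(ev, frame = frame + 200))
  tr0 <- estimate_drift_xcorr(same, block_frames = 200)
  expect_lt(max(abs(tr0$dx)), 1e-6)
  expect_lt(max(abs(tr0$dy)), 1e-6)
})

test_that("cross-correlation agrees with fiducial tracking within 10 nm RMS", {
  gt_struct <- make_ground_truth("npc_ring",
                                 list(n_pores = 50, field = c(6000, 6000),
                                      min_spacing = 200), seed = 4)
  gt_fid <- make_ground_truth("fiducial", list(n = 3,
                                               field = c(6000, 6000)),
                              seed = 5)
  gt_fid$structure_id <- gt_fid$structure_id + 1000
  drift <- c(0.05, -0.04, 0)
  ev <- dplyr::bind_rows(
    simulate_localization_events(gt_struct, events_per_emitter = 40,
                                 precision_nm = 12, n_frames = 1000,
                                 seed = 6, drift_per_frame = drift),
    simulate_localization_events(gt_fid, precision_nm = 12,
                                 n_frames = 1000, seed = 7,
                                 drift_per_frame = drift))
  tr_fid <- track_fiducials(ev, seed_positions = cbind(gt_fid$x_nm,
                                                       gt_fid$y_nm),
                            link_radius = 800, smoothing_window = 50)
  tr_xc <- estimate_drift_xcorr(ev, block_frames = 200, render_pixel = 15)
  # compare on the cross-correlation nodes, relative to each method's start
  dx_f <- interp_at <- approx(tr_fid$frame, tr_fid$dx, tr_xc$frame,
                              rule = 2)$y
  dy_f <- approx(tr_fid$frame, tr_fid$dy, tr_xc$frame, rule = 2)$y
  dd <- c((dx_f - dx_f[1]) - (tr_xc$dx - tr_xc$dx[1]),
          (dy_f - dy_f[1]) - (tr_xc$dy - tr_xc$dy[1]))
  expect_lt(sqrt(mean(dd^2)), 10)
})

test_that("applying a drift trace is invertible and zero is identity", {
  tab <- fiducial_table(n_fid = 2, n_frames = 50, precision = 5)
  zero <- tibble::tibble(frame = c(0, 49), dx = 0, dy = 0, dz = 0)
  expect_equal(apply_drift(tab, zero), tab)
  tr <- tibble::tibble(frame = c(0, 25, 49), dx = c(1, 5, 9),
                       dy = c(0, -2, 1), dz = c(0, 1, 2))
  neg <- dplyr::mutate(tr, dx = -dx, dy = -dy, dz = -dz)
  back <- apply_drift(apply_drift(tab, tr), neg)
  expect_equal(back$x_nm, tab$x_nm, tolerance = 1e-12)
  expect_equal(back$z_nm, tab$z_nm, tolerance = 1e-12)
})

test_that("deskew matches hand trigonometry and inverts exactly", {
  tab <- tibble::tibble(plane = 0L, x_nm = 1000, y_nm = 123, z_nm = 0)
  out <- deskew(tab, sheet_angle = 32.5, scan_step = 316)
  expect_equal(out$X_nm, 1000 * cos(32.5 * pi / 180), tolerance = 1e-9)
  expect_equal(out$Z_nm, 1000 * sin(32.5 * pi / 180), tolerance = 1e-9)
  expect_equal(round(out$X_nm, 1), 843.4)
  expect_equal(round(out$Z_nm, 1), 537.3)
  expect_equal(out$Y_nm, 123)
  # orthogonal sheet: Z = u, X = p*s - w
  t90 <- deskew(tibble::tibble(plane = 2L, x_nm = 700, y_nm = 0,
                               z_nm = 55), sheet_angle = 90,
                scan_step = 100)
  expect_equal(t90$Z_nm, 700, tolerance = 1e-9)
  expect_equal(t90$X_nm, 200 - 55, tolerance = 1e-9)
  # round trip
  set.seed(1)
  rt <- tibble::tibble(plane = sample(0:10, 50, TRUE),
                       x_nm = runif(50, 0, 5000),
                       y_nm = runif(50, 0, 5000),
                       z_nm = runif(50, -400, 400))
  fwd <- deskew(rt, sheet_angle = 32.5, scan_step = 316)
  inv <- deskew(fwd, sheet_angle = 32.5, scan_step = 316, inverse = TRUE)
  expect_equal(inv$x_nm, rt$x_nm, tolerance = 1e-9)
  expect_equal(inv$z_nm, rt$z_nm, tolerance = 1e-9)
  expect_error(deskew(rt, sheet_angle = 120, scan_step = 316),
               class = "sheetloc_validation")
})

test_that("deskew is an isometry within a plane", {
  set.seed(2)
  tab <- tibble::tibble(plane = 3L, x_nm = runif(30, 0, 4000),
                        y_nm = runif(30, 0, 4000),
                        z_nm = runif(30, -300, 300))
  out <- deskew(tab, sheet_angle = 32.5, scan_step = 316)
  d_in <- dist(cbind(tab$x_nm, tab$y_nm, tab$z_nm))
  d_out <- dist(cbind(out$X_nm, out$Y_nm, out$Z_nm))
  expect_lt(max(abs(d_in - d_out) / d_in), 1e-9)
})

test_that("volume-to-time-series transposition is exact bookkeeping", {
  set.seed(3)
  arr <- array(rnorm(3 * 4 * 5 * 6), dim = c(3, 4, 5, 6)) # (vol, plane, y, x)
  ts <- transpose_to_time_series(arr)
  expect_length(ts, 4)
  for (v in 1:3) for (p in 1:4) for (i in 1:5) for (j in 1:6) {
    expect_identical(ts[[p]][v, i, j], arr[v, p, i, j])
  }
  # single plane: content unchanged
  vols <- lapply(1:3, function(v) array(arr[v, 1, , ], dim = c(1, 5, 6)))
  one <- transpose_to_time_series(vols)
  expect_equal(dim(one[[1]]), c(3, 5, 6))
  # transpose twice = original
  back <- transpose_to_time_series(lapply(seq_len(dim(ts[[1]])[1]),
                                          function(v) {
    out <- array(0, dim = c(4, 5, 6))
    for (p in 1:4) out[p, , ] <- ts[[p]][v, , ]
    out
  }))
  for (p in 1:4) expect_equal(back[[p]], ts[[p]])
  # ragged volumes rejected
  bad <- list(array(0, c(2, 4, 4)), array(0, c(3, 4, 4)))
  expect_error(transpose_to_time_series(bad),
               class = "sheetloc_validation")
})

test_that("2D rendering conserves event weight and resolves pairs", {
  tab <- tibble::tibble(x_nm = c(1000, 1200), y_nm = c(1000, 1000),
                        frame = 0L, uncertainty_xy = c(40, 40))
  img <- render_density(tab, pixel = 10)
  expect_equal(sum(img), 2, tolerance = 1e-6)
  # two events 200 nm apart at sigma 40 give two local maxima
  mid_row <- img[which.max(apply(img, 1, max)), ]
  peaks <- sum(diff(sign(diff(mid_row))) == -2)
  expect_gte(peaks, 2)
  # per-event sigma: a 20 nm-uncertainty event renders tighter than a 60 nm
  tab2 <- tibble::tibble(x_nm = 500, y_nm = 500, frame = 0L,
                         uncertainty_xy = 20)
  tab3 <- dplyr::mutate(tab2, uncertainty_xy = 60)
  i2 <- render_density(tab2, pixel = 10)
  i3 <- render_density(tab3, pixel = 10)
  expect_gt(max(i2), max(i3))
  # fixed-sigma mode ignores the per-event column
  i4 <- render_density(tab3, pixel = 10, sigma_source = "fixed",
                       fixed_sigma = 20)
  expect_equal(max(i4), max(i2), tolerance = 1e-9)
  # conservation holds at other pixel sizes too
  expect_equal(sum(render_density(tab, pixel = 7)), 2, tolerance = 1e-6)
})

test_that("3D rendering conserves counts for interior events", {
  set.seed(4)
  tab <- tibble::tibble(x_nm = runif(40, 1000, 2000),
                        y_nm = runif(40, 1000, 2000),
                        z_nm = runif(40, -100, 100), frame = 0L)
  vol <- render_density(tab, pixel = 25, mode = "3d", fixed_sigma = 30)
  expect_equal(sum(vol), 40, tolerance = 1e-6)
})

test_that("temporal binning partitions events and sums to the full map", {
  set.seed(5)
  tab <- tibble::tibble(frame = sample(0:9999, 3000, TRUE),
                        x_nm = runif(3000, 0, 3000),
                        y_nm = runif(3000, 0, 3000))
  rt <- render_temporal(tab, frames_per_bin = 2000, pixel = 50)
  expect_length(rt$bins, 5) # 10,000 frames at 2000/bin
  expect_equal(sum(vapply(rt$bins, nrow, integer(1))), nrow(tab))
  # bins partition: no event in two bins
  expect_equal(dplyr::bind_rows(rt$bins) |> nrow(), nrow(tab))
  # sum of per-bin maps equals the full-map rendering on the same grid
  total <- Reduce(`+`, rt$maps)
  pad <- 5 * max(20, 50)
  full <- render_density(tab, pixel = 50, sigma_source = "fixed",
                         fixed_sigma = 20,
                         extent = list(x = range(tab$x_nm) + c(-pad, pad),
                                       y = range(tab$y_nm) + c(-pad, pad)))
  expect_equal(total, full, tolerance = 1e-9)
  # single bin reproduces the input
  one <- render_temporal(tab, frames_per_bin = 10000, pixel = 50)
  expect_length(one$bins, 1)
  expect_equal(nrow(one$bins[[1]]), nrow(tab))
})

test_that("autoplot methods return ggplot objects", {
  tab <- fiducial_table(n_fid = 2, n_frames = 100, precision = 10)
  tr <- track_fiducials(tab, link_radius = 500)
  expect_s3_class(autoplot(tr), "ggplot")
  expect_s3_class(autoplot(ref_calibration()), "ggplot")
  img <- render_density(tab, pixel = 50)
  expect_s3_class(plot_density_map(img), "ggplot")
})
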