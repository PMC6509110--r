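test_that("flat frames yield no candidates", {
  expect_equal(nrow(detect_spots(matrix(100, 50, 50))), 0)
})

test_that("an isolated blob yields exactly one candidate at its peak", {
  fr <- single_emitter_frame(photons = 2000, seed = 4)
  cand <- detect_spots(fr$img, detection_params())
  expect_equal(nrow(cand), 1)
  # at the brightest pixel of the noiseless image (oracle: argmax)
  clean <- single_emitter_frame(photons = 2000, noise = FALSE,
                                background = 0)$img
  peak <- which(clean == max(clean), arr.ind = TRUE)
  expect_lte(abs(cand$py[1] - peak[1]), 1)
  expect_lte(abs(cand$px[1] - peak[1]), 1)
})

test_that("nearby blobs merge; separated blobs are kept apart", {
  cam <- camera_model()
  cal <- ref_calibration()
  th <- 32.5 * pi / 180
  mk <- function(sep_px) {
    u <- c(2000, 2000 + sep_px * cam$pixel_size)
    gt <- tibble::tibble(emitter = 1:2, structure_id = 1:2,
                         kind = "fiducial", always_on = TRUE,
                         x_nm = u * cos(th), y_nm = 2000,
                         z_nm = u * sin(th))
    geom <- acquisition_geometry(n_planes = 1, n_x = 50, n_y = 50)
    sim <- simulate_stack(gt, blinking_model(photons_per_frame_mean = 2000),
                          cam, geom, cal, seed = 6, noise = FALSE,
                          background = 0)
    img <- sim$volumes[[1]][1, , ]
    # add mild synthetic noise so the MAD threshold is meaningful
    set.seed(1)
    img + matrix(rnorm(length(img), 0, 2), nrow(img))
  }
  expect_equal(nrow(detect_spots(mk(10))), 2)
  expect_equal(nrow(detect_spots(mk(2))), 1)
})

test_that("noise-free ROI fit recovers the center to < 0.01 px", {
  fr <- single_emitter_frame(photons = 1000, noise = FALSE, background = 0)
  cand <- which(fr$img == max(fr$img), arr.ind = TRUE)
  h <- 5
  roi <- fr$img[(cand[1] - h):(cand[1] + h), (cand[2] - h):(cand[2] + h)]
  ft <- fit_spot(roi, camera_model())
  expect_true(ft$valid)
  a <- camera_model()$pixel_size
  x_fit <- (cand[2] - h - 1 + ft$x_px) * a
  y_fit <- (cand[1] - h - 1 + ft$y_px) * a
  expect_lt(abs(x_fit - fr$truth$x_nm), 0.01 * a)
  expect_lt(abs(y_fit - fr$truth$y_nm), 0.01 * a)
  expect_equal(ft$photons, fr$truth$photons, tolerance = 0.01)
})

test_that("flat ROI is flagged invalid", {
  expect_false(fit_spot(matrix(100, 11, 11), camera_model())$valid)
})

test_that("theoretical uncertainty follows the closed form", {
  # hand arithmetic: sqrt((150^2 + 102^2/12) / 1000)
  expect_equal(theoretical_uncertainty(1000, 150, 102, 0),
               sqrt((150^2 + 102^2 / 12) / 1000), tolerance = 1e-12)
  expect_equal(theoretical_uncertainty(1000, 150), 4.834, tolerance = 1e-3)
  # b = 0: quadrupling N halves the uncertainty
  expect_equal(theoretical_uncertainty(4000, 150),
               theoretical_uncertainty(1000, 150) / 2, tolerance = 1e-12)
  # background term raises it
  expect_gt(theoretical_uncertainty(1000, 150, 102, 10),
            theoretical_uncertainty(1000, 150, 102, 0))
  expect_error(theoretical_uncertainty(0, 150),
               class = "sheetloc_validation")
})

test_that("positional RMSE stays within 1.3x the theoretical uncertainty", {
  cam <- camera_model()
  cal <- ref_calibration()
  bg <- 5
  sig <- sigma_at_z(cal, 0)
  s_eff <- sqrt(sig$sigma_x * sig$sigma_y)
  for (N in c(250, 1000, 4000)) {
    r <- mc_rmse(N, cam, cal, bg)
    theo <- theoretical_uncertainty(N, s_eff, cam$pixel_size, bg)
    expect_gte(r["n"], 50)
    expect_lte(r["rmse"], 1.3 * theo)
  }
})

test_that("positional RMSE scales as 1/sqrt(N) in the shot-noise limit", {
  # low background and read noise isolate the 1/sqrt(N) law; emitters sit
  # on the sheet plane where the mildly astigmatic PSF is symmetric (the
  # standard condition for benchmarking photon-limited precision). The
  # scaled error rmse * sqrt(N) must be flat across a 16-fold photon range.
  cam <- camera_model(read_noise = 1)
  cal <- benchmark_calibration()
  scaled <- vapply(c(250, 1000, 4000), function(N) {
    r <- mc_rmse(N, cam, cal, bg = 0.5, n_mc = 100)
    expect_gte(r["n"], 90)
    unname(r["rmse"] * sqrt(N))
  }, numeric(1))
  expect_lt(max(scaled) / min(scaled) - 1, 0.15)
})

test_that("localize_stack assigns z consistently with ground truth", {
  cam <- camera_model()
  cal <- ref_calibration()
  set.seed(8)
  ws <- runif(40, -300, 300)
  lat_err <- c(); z_err <- c()
  for (i in seq_along(ws)) {
    fr <- single_emitter_frame(photons = 1500, w = ws[i], seed = 100 + i)
    locs <- localize_stack(fr$img, cal, cam, detection_params())
    locs <- filter_localizations(locs, require_valid_z = TRUE)
    if (nrow(locs) == 0) next
    j <- which.min((locs$x_nm - fr$truth$x_nm)^2 +
                   (locs$y_nm - fr$truth$y_nm)^2)
    lat_err <- c(lat_err, sqrt(((locs$x_nm[j] - fr$truth$x_nm)^2 +
                                (locs$y_nm[j] - fr$truth$y_nm)^2) / 2))
    z_err <- c(z_err, abs(locs$z_nm[j] - fr$truth$z_nm))
  }
  expect_gte(length(z_err), 30)
  expect_lte(median(z_err), 2.5 * median(lat_err))
  # z round trip is exact on noise-free widths
  s <- sigma_at_z(cal, 200)
  expect_lt(abs(z_from_sigma(cal, s$sigma_x, s$sigma_y)$z_nm - 200), 1)
})

test_that("recall and precision reach 0.9 on isolated bright emitters", {
  cam <- camera_model()
  cal <- ref_calibration()
  th <- 32.5 * pi / 180
  us <- seq(1000, 4000, by = 750)
  vs <- seq(1000, 4000, by = 750)
  grid <- expand.grid(u = us, v = vs)
  gt <- tibble::tibble(
    emitter = seq_len(nrow(grid)), structure_id = seq_len(nrow(grid)),
    kind = "fiducial", always_on = TRUE,
    x_nm = grid$u * cos(th), y_nm = grid$v, z_nm = grid$u * sin(th))
  geom <- acquisition_geometry(n_planes = 1, n_x = 50, n_y = 50)
  tp <- 0; fp <- 0; fn <- 0
  for (s in 1:8) {
    sim <- simulate_stack(gt, blinking_model(photons_per_frame_mean = 1200),
                          cam, geom, cal, seed = s, background = 5)
    locs <- localize_stack(sim$volumes[[1]][1, , ], cal, cam,
                           detection_params())
    truth <- sim$truth
    used <- rep(FALSE, nrow(locs))
    for (i in seq_len(nrow(truth))) {
      if (nrow(locs) == 0) { fn <- fn + 1; next }
      d <- sqrt((locs$x_nm - truth$x_nm[i])^2 +
                (locs$y_nm - truth$y_nm[i])^2)
      j <- which.min(ifelse(used, Inf, d))
      if (d[j] <= 100 && !used[j]) {
        tp <- tp + 1; used[j] <- TRUE
      } else {
        fn <- fn + 1
      }
    }
    fp <- fp + sum(!used)
  }
  expect_gte(tp / (tp + fn), 0.9)
  expect_gte(tp / (tp + fp), 0.9)
})

test_that("localization is deterministic and order-invariant", {
  fr <- single_emitter_frame(photons = 1000, seed = 3)
  cal <- ref_calibration()
  l1 <- localize_stack(fr$img, cal)
  l2 <- localize_stack(fr$img, cal)
  expect_identical(l1, l2)
  # stack of two frames processed together equals per-frame processing
  stack <- array(0, dim = c(2, nrow(fr$img), ncol(fr$img)))
  fr2 <- single_emitter_frame(photons = 800, seed = 9)
  stack[1, , ] <- fr$img
  stack[2, , ] <- fr2$img
  both <- localize_stack(stack, cal)
  solo2 <- localize_stack(fr2$img, cal)
  expect_equal(both$x_nm[both$frame == 1], solo2$x_nm, tolerance = 1e-12)
})

test_that("empty stacks give an empty table with full schema", {
  cal <- ref_calibration()
  tab <- localize_stack(matrix(100, 30, 30), cal)
  expect_equal(nrow(tab), 0)
  expect_true(all(c("frame", "x_nm", "y_nm", "z_nm", "sigma_x", "sigma_y",
                    "photons", "uncertainty_xy", "uncertainty_z", "valid")
                  %in% names(tab)))
  expect_error(localize_stack(matrix(100, 30, 30)),
               class = "sheetloc_config_error")
})

test_that("filtering is monotone, order-preserving, and catches side lobes", {
  cal <- ref_calibration()
  cam <- camera_model()
  gt <- make_ground_truth("fiducial", list(n = 6, field = c(4500, 4500)),
                          seed = 2)
  # spread emitters in depth so side-lobe replicas excite off-sheet copies
  gt$z_nm <- gt$x_nm * tan(32.5 * pi / 180) # w = 0 plane
  geom <- acquisition_geometry(n_planes = 6, scan_step = 400, n_x = 50,
                               n_y = 50, sidelobe_fraction = 0.3,
                               sidelobe_offset = 850)
  sim <- simulate_stack(gt, blinking_model(photons_per_frame_mean = 1500),
                        cam, geom, cal, seed = 12, background = 3)
  locs <- localize_stack(
    aperm(array(unlist(sim$volumes[[1]]), dim(sim$volumes[[1]])),
          c(1, 2, 3)),
    cal, cam, detection_params())
  # identity when no criteria
  expect_identical(filter_localizations(locs), locs)
  # zero-uncertainty criterion empties the table
  expect_equal(nrow(filter_localizations(locs, max_uncertainty_xy = 0)), 0)
  # monotone non-increasing record count under stricter criteria
  n1 <- nrow(filter_localizations(locs, max_uncertainty_xy = 50))
  n2 <- nrow(filter_localizations(locs, max_uncertainty_xy = 20))
  expect_lte(n2, n1)
  # order preserved
  f <- filter_localizations(locs, max_uncertainty_xy = 50)
  expect_false(is.unsorted(match(paste(f$frame, f$x_nm),
                                 paste(locs$frame, locs$x_nm))))
})

test_that("the width gate rejects side-lobe-excited events", {
  cal <- ref_calibration()
  cam <- camera_model()
  th <- 32.5 * pi / 180
  # bright emitters on the sheet plane (main lobe) and at the side-lobe
  # offset, laterally separated in a roomy field so detections never merge
  # and the noise floor estimate stays background-dominated
  u <- seq(1500, 8500, length.out = 5)
  gt_main <- tibble::tibble(
    emitter = 1:5, structure_id = 1:5, kind = "fiducial", always_on = TRUE,
    x_nm = u * cos(th), y_nm = seq(1000, 8000, length.out = 5),
    z_nm = u * sin(th))
  w_side <- 850
  gt_side <- tibble::tibble(
    emitter = 6:10, structure_id = 6:10, kind = "fiducial",
    always_on = TRUE,
    x_nm = u * cos(th) - w_side * sin(th),
    y_nm = seq(1000, 8000, length.out = 5) + 1500,
    z_nm = u * sin(th) + w_side * cos(th))
  geom <- acquisition_geometry(n_planes = 1, n_x = 100, n_y = 100,
                               sidelobe_fraction = 0.4,
                               sidelobe_offset = 850)
  frac_kept_side <- c(); frac_raw_side <- c()
  for (s in 1:6) {
    sim <- simulate_stack(dplyr::bind_rows(gt_main, gt_side),
                          blinking_model(photons_per_frame_mean = 6000),
                          cam, geom, cal, seed = s, background = 3)
    # broad, dim side-lobe blobs need a coarser band-pass and a lower
    # threshold to register at all
    locs <- localize_stack(sim$volumes[[1]][1, , ], cal, cam,
                           detection_params(filter_scale = 2,
                                            threshold_k = 3))
    if (nrow(locs) == 0) next
    truth <- sim$truth
    # label each localization by its nearest truth event's lobe
    lobe_side <- vapply(seq_len(nrow(locs)), function(i) {
      d <- sqrt((truth$x_nm - locs$x_nm[i])^2 +
                (truth$y_nm - locs$y_nm[i])^2)
      truth$side_lobe[which.min(d)]
    }, logical(1))
    frac_raw_side <- c(frac_raw_side, mean(lobe_side))
    kept <- filter_localizations(locs, require_valid_z = TRUE,
                                 sigma_bounds = c(100, 300))
    kept_side <- vapply(seq_len(nrow(kept)), function(i) {
      d <- sqrt((truth$x_nm - kept$x_nm[i])^2 +
                (truth$y_nm - kept$y_nm[i])^2)
      truth$side_lobe[which.min(d)]
    }, logical(1))
    frac_kept_side <- c(frac_kept_side, mean(kept_side))
  }
  expect_gt(mean(frac_raw_side), 0.15)
  expect_lt(mean(frac_kept_side), 0.05)
})
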