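test_that("detection finds bright spots and rejects flat or dim frames", {
  opt <- test_optics()
  cam <- quiet_camera()
  flat <- matrix(cam$offset, 17, 17)
  expect_equal(nrow(detect_peaks(flat, opt, cam)), 0)

  # a bright spot over a constant background of 2 pe/px
  bg_pe <- 2
  es <- steady_emitter(c(8.3 * 105, 8.6 * 105), i_on = 600)
  st <- render_frames(es, opt, cam, noise = FALSE)
  frame <- st$frames[, , 1] + bg_pe * cam$em_gain
  pk <- detect_peaks(frame, opt, cam)
  expect_equal(nrow(pk), 1)
  expect_equal(unname(pk[1, ]), c(9, 9))

  # amplitude only 2x background with threshold factor 4: rejected
  dim_es <- steady_emitter(c(8.3 * 105, 8.6 * 105), i_on = 50)
  dim_st <- render_frames(dim_es, opt, cam, noise = FALSE)
  dim_frame <- dim_st$frames[, , 1] + 10 * cam$em_gain
  expect_equal(nrow(detect_peaks(dim_frame, opt, cam)), 0)
})

test_that("noiseless MLE recovers the position to sub-millipixel accuracy", {
  opt <- test_optics()
  cam <- quiet_camera()
  for (pos in list(c(8.27, 8.61), c(8.5, 8.5), c(7.9, 9.2))) {
    es <- steady_emitter(pos * 105, i_on = 400)
    st <- render_frames(es, opt, cam, noise = FALSE)
    fit <- fit_mle(st$frames[, , 1], matrix(c(9, 9), 1, 2), opt, cam)
    expect_true(fit$converged)
    expect_lt(abs(fit$x - pos[1] * 105), 1e-3 * 105)
    expect_lt(abs(fit$y - pos[2] * 105), 1e-3 * 105)
    expect_lt(abs(fit$photons - 360) / 360, 1e-3)
  }
  expect_error(fit_mle(st$frames[, , 1], matrix(c(1, 1), 1, 2), opt, cam),
               "border")
})

test_that("empirical localization spread matches the CRLB within 15%", {
  opt <- test_optics()
  cam <- test_camera()
  es <- steady_emitter(c(8.4 * 105, 8.5 * 105), i_on = 400)
  set.seed(8)
  xs <- ys <- prec <- rep(NA_real_, 250)
  for (r in seq_len(250)) {
    st <- render_frames(es, opt, cam, noise = TRUE)
    pk <- detect_peaks(st$frames[, , 1], opt, cam)
    if (nrow(pk) < 1) next
    f <- fit_mle(st$frames[, , 1], pk[1, , drop = FALSE], opt, cam)
    if (!f$converged[1]) next
    xs[r] <- f$x; ys[r] <- f$y; prec[r] <- f$precision
  }
  expect_gt(mean(!is.na(xs)), 0.95)
  emp <- sqrt((sd(xs, na.rm = TRUE)^2 + sd(ys, na.rm = TRUE)^2) / 2)
  expect_lt(abs(emp - mean(prec, na.rm = TRUE)) / emp, 0.15)
})

test_that("CRLB precision scales as 1/sqrt(N) and carries the EMCCD factor", {
  opt <- test_optics()
  cam_em <- test_camera()
  cam_cc <- test_camera(excess_noise_factor = 1)
  # negligible background: quadrupling photons halves the precision
  p1 <- crlb_precision(500, 1e-6, opt, cam_cc)
  p4 <- crlb_precision(2000, 1e-6, opt, cam_cc)
  expect_lt(abs(p4 - p1 / 2) / (p1 / 2), 0.01)
  # EM excess noise costs exactly sqrt(2)
  expect_equal(crlb_precision(500, 1, opt, cam_em),
               sqrt(2) * crlb_precision(500, 1, opt, cam_cc))
  expect_error(crlb_precision(0, 1, opt, cam_em))
})

test_that("drift correction subtracts the mean fiducial displacement", {
  tb <- localization_table(frame = c(1L, 2L, 3L), x = c(100, 101, 102),
                           y = c(50, 50, 50), photons = rep(100, 3),
                           background = rep(0, 3), precision = rep(10, 3))
  # constant fiducials: identity
  fid <- fiducial_track(frame = rep(1:3, 2), id = rep(c("a", "b"), each = 3),
                        x = rep(c(0, 500), each = 3),
                        y = rep(c(0, 500), each = 3))
  out <- correct_drift(tb, fid)
  expect_equal(out$x, tb$x)
  # linear drift of 1 nm/frame in x on both fiducials
  drift <- (0:2)
  fid2 <- fiducial_track(frame = rep(1:3, 2), id = rep(c("a", "b"), each = 3),
                         x = c(0 + drift, 500 + drift),
                         y = rep(c(0, 500), each = 3))
  tb2 <- tb
  tb2$x <- 100 + drift   # emitters carried by the same drift
  class(tb2) <- class(tb)
  out2 <- correct_drift(tb2, fid2)
  expect_equal(out2$x, rep(100, 3), tolerance = 1e-12)
  # a frame without fiducial coverage is an error
  fid3 <- fiducial_track(frame = c(1, 2), id = c("a", "a"),
                         x = c(0, 0), y = c(0, 0))
  expect_error(correct_drift(tb, fid3), "coverage")
})

test_that("second-order co-registration recovers exact transforms", {
  set.seed(6)
  x <- runif(12, 0, 5000); y <- runif(12, 0, 5000)
  tb <- localization_table(frame = rep(1L, 12), x = x, y = y,
                           photons = rep(1, 12), background = rep(0, 12),
                           precision = rep(10, 12))
  ident <- data.frame(x = x, y = y, x_ref = x, y_ref = y)
  out <- coregister(ident, tb)
  expect_equal(out$x, x, tolerance = 1e-9)
  expect_lt(max(attr(out, "residuals")), 1e-9)
  shift <- data.frame(x = x, y = y, x_ref = x + 250, y_ref = y - 80)
  out2 <- coregister(shift, tb)
  expect_equal(out2$x, x + 250, tolerance = 1e-6)
  expect_equal(out2$y, y - 80, tolerance = 1e-6)
  expect_error(coregister(ident[1:5, ], tb), "6")
})

test_that("rendering conserves localization counts and Gaussian mass", {
  fov <- 2000
  spec <- render_spec("histogram", pixel_size = 20)
  empty <- render_palm(localization_table(), spec, fov)
  expect_true(all(empty == 0))
  tb <- localization_table(frame = 1L, x = 1010, y = 515, photons = 100,
                           background = 0, precision = 20)
  h <- render_palm(tb, spec, fov)
  expect_equal(sum(h), 1)
  expect_equal(h[floor(515 / 20) + 1, floor(1010 / 20) + 1], 1)
  pm <- render_palm(tb, render_spec("probability_map", 20), fov)
  expect_lt(abs(sum(pm) - 1), 1e-3)
  # records outside the precision window are dropped
  tb2 <- localization_table(frame = 1L, x = 1010, y = 515, photons = 100,
                            background = 0, precision = 80)
  expect_equal(sum(render_palm(tb2, spec, fov)), 0)
})
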