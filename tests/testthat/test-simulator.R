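test_that("switching-free emitters emit exactly i_on every frame", {
  kin <- photokinetics(activation_rate = 0, k_off = 0, k_on = 0,
                       bleach_rate = 0, i_on = 123, p_preactivated = 1)
  tr <- simulate_traces(5, kin, 20, seed = 1)
  m <- trace_matrix(tr)
  expect_equal(dim(m), c(5, 20))
  expect_true(all(abs(m - 123) < 1e-9))
})

test_that("no activation means no photons", {
  kin <- photokinetics(activation_rate = 0, i_on = 100)
  tr <- simulate_traces(10, kin, 50, seed = 1)
  expect_equal(nrow(tr), 0)
})

test_that("stationary blinking converges to the analytic on fraction", {
  for (rho in c(0.3, 0.5)) {
    k_on <- 4
    k_off <- k_on * (1 - rho) / rho
    kin <- photokinetics(activation_rate = 0, k_off = k_off, k_on = k_on,
                         bleach_rate = 0, i_on = 100, p_preactivated = 1)
    expect_equal(on_time_ratio(kin), rho)
    tr <- simulate_traces(300, kin, 1000, seed = 7)
    frac <- mean(trace_matrix(tr)) / 100
    expect_lt(abs(frac - rho), 0.02)   # Monte-Carlo vs stationary prob.
  }
})

test_that("bleached emitters never emit again", {
  kin <- photokinetics(activation_rate = 0, k_off = 2, k_on = 2,
                       bleach_rate = 20, i_on = 100, p_preactivated = 1)
  tr <- simulate_traces(200, kin, 400, seed = 3)
  m <- trace_matrix(tr)
  active <- colSums(m > 0)
  # with no fresh activation, cumulative-max of activity is front-loaded:
  # once an emitter's last photon is emitted it stays dark
  last_active <- apply(m > 0, 1, function(z) if (any(z)) max(which(z)) else 0)
  for (e in which(last_active > 0)) {
    expect_true(all(m[e, seq(last_active[e], 400)][-1] == 0))
  }
  # the late stack is quieter than the early stack
  expect_lt(sum(active[201:400]), sum(active[1:200]))
})

test_that("seed determinism gives bitwise identical traces and stacks", {
  kin <- kinetic_preset("meos2")
  t1 <- simulate_traces(50, kin, 200, seed = 11)
  t2 <- simulate_traces(50, kin, 200, seed = 11)
  expect_identical(t1$photons, t2$photons)
  es <- make_bar_target(200, fov = 64 * 105, seed = 5)
  es$traces <- simulate_traces(nrow(es$positions), kin, 50, seed = 5)
  opt <- test_optics()
  s1 <- render_frames(es, opt, test_camera(), seed = 9)
  s2 <- render_frames(es, opt, test_camera(), seed = 9)
  expect_identical(s1$frames, s2$frames)
})

test_that("rendering with no emitters gives the offset everywhere", {
  kin <- photokinetics(activation_rate = 0, i_on = 100)
  es <- emitter_set(matrix(numeric(0), 0, 2))
  es$traces <- simulate_traces(0, kin, 3)
  attr(es, "fov") <- 16 * 105
  cam <- quiet_camera()
  st <- render_frames(es, test_optics(), cam, noise = FALSE)
  expect_true(all(st$frames == cam$offset))
})

test_that("a steady centred emitter renders a symmetric, photon-conserving spot", {
  opt <- test_optics()
  cam <- quiet_camera()
  es <- steady_emitter(c(8.5 * 105, 8.5 * 105), i_on = 500)
  st <- render_frames(es, opt, cam, noise = FALSE)
  img <- (st$frames[, , 1] - cam$offset) / cam$em_gain
  # total photo-electrons = QE * I_on within PSF truncation tolerance
  expect_lt(abs(sum(img) - 0.9 * 500) / (0.9 * 500), 1e-6)
  # symmetric about the centre pixel
  expect_equal(img, t(img), tolerance = 1e-12)
  expect_equal(img[, 9], rev(img[, 9]), tolerance = 1e-12)
  # closed-form Gaussian pixel integral at the peak
  s <- opt$psf_sigma
  mass1 <- (pnorm(9 * 105, 8.5 * 105, s) - pnorm(8 * 105, 8.5 * 105, s))^2
  expect_equal(img[9, 9], 0.9 * 500 * mass1, tolerance = 1e-9)
})

test_that("the camera noise model is unbiased", {
  opt <- test_optics()
  cam <- test_camera()
  es <- steady_emitter(c(4.5 * 105, 4.5 * 105), i_on = 300, fov_px = 9)
  clean <- render_frames(es, opt, cam, noise = FALSE)$frames[, , 1]
  set.seed(42)
  n <- 3000
  acc <- matrix(0, 9, 9)
  acc2 <- matrix(0, 9, 9)
  for (i in seq_len(n)) {
    f <- render_frames(es, opt, cam, noise = TRUE)$frames[, , 1]
    acc <- acc + f
    acc2 <- acc2 + f^2
  }
  mu <- acc / n
  se <- sqrt(pmax(acc2 / n - mu^2, 0) / n)
  # every pixel mean within 5 standard errors of the noiseless expectation
  expect_true(all(abs(mu - clean) < 5 * pmax(se, 0.5)))
})

test_that("bar targets realize the prescribed density inside the bars", {
  for (d in c(800, 1200)) {
    tgt <- make_bar_target(d, fov = 64 * 105, seed = 2)
    bars <- attr(tgt, "bars")
    area <- sum((bars$x1 - bars$x0) * (bars$y1 - bars$y0)) / 1e6
    expect_equal(nrow(tgt$positions), round(d * area))
    # every emitter lies inside some bar
    inside <- vapply(seq_len(nrow(tgt$positions)), function(i) {
      any(tgt$positions[i, 1] >= bars$x0 & tgt$positions[i, 1] <= bars$x1 &
          tgt$positions[i, 2] >= bars$y0 & tgt$positions[i, 2] <= bars$y1)
    }, logical(1))
    expect_true(all(inside))
    expect_true(all(diff(bars$width) <= 0))
  }
  expect_error(make_bar_target(800, fov = 1000), "wider than")
})

test_that("moving adhesions translate rigidly at the requested velocity", {
  base <- make_uniform_region(100, side = 1000, origin = c(500, 500),
                              seed = 4)
  f0 <- make_moving_adhesion(base, velocity = 0, frame_interval = 1)
  expect_identical(f0(1), f0(50))
  f <- make_moving_adhesion(base, velocity = 190, direction = c(1, 0),
                            frame_interval = 1)
  # one minute in: 190 nm along +x, y unchanged
  expect_equal(f(61)[, 1] - f(1)[, 1], rep(190, nrow(base$positions)))
  expect_equal(f(61)[, 2], f(1)[, 2])
  frev <- make_moving_adhesion(base, velocity = 190, direction = c(-1, 0),
                               frame_interval = 1)
  expect_equal(frev(61)[, 1] - frev(1)[, 1],
               -(f(61)[, 1] - f(1)[, 1]))
})
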