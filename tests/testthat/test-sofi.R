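test_that("subsequence splitting is exact floor division", {
  expect_length(split_subsequences(20000), 40)
  idx <- split_subsequences(1234)
  expect_length(idx, 2)
  expect_equal(idx[[2]], 501:1000)     # remainder frames dropped
  expect_error(split_subsequences(499), "shorter")
  st <- image_stack(array(1, dim = c(4, 4, 1100)), 105)
  subs <- split_subsequences(st)
  expect_length(subs, 2)
  expect_equal(n_frames(subs[[1]]), 500)
})

test_that("cumulant images match the raw-moment partition oracle", {
  opt <- test_optics()
  set.seed(10)
  ny <- 8; nx <- 8; T <- 150
  fr <- array(rpois(ny * nx * T, 40) * 1.0, dim = c(ny, nx, T))
  st <- image_stack(fr, 105)
  sig <- effective_sigma_px(opt)
  for (ord in 2:4) {
    ci <- cumulant_images(st, ord, opt)
    combos <- palmsofi:::cpp_cumulant_combinations(ord)
    for (cell in seq_along(combos)) {
      cb <- combos[[cell]]
      for (raw in list(c(3, 4), c(4, 3))) {
        i <- raw[1]; j <- raw[2]       # 0-based raw pixel
        trs <- lapply(seq_along(cb$dy), function(k)
          fr[i + 1 + cb$dy[k], j + 1 + cb$dx[k], ])
        expected <- oracle_joint_cumulant(trs) *
          exp(cb$pair_d2 / (2 * ord * sig^2))
        got <- ci[i * ord + cb$a + 1, j * ord + cb$b + 1]
        expect_lt(abs(got - expected), 1e-8 * max(1, abs(expected)))
      }
    }
  }
})

test_that("temporally constant stacks have zero cumulants", {
  opt <- test_optics()
  img <- matrix(runif(64, 10, 200), 8, 8)
  st <- image_stack(array(img, dim = c(8, 8, 50)), 105)
  for (ord in c(2, 4)) {
    expect_true(all(abs(cumulant_images(st, ord, opt)) < 1e-18))
  }
})

test_that("order-n cumulants scale with the n-th brightness power", {
  opt <- test_optics()
  set.seed(12)
  fr <- array(rpois(6 * 6 * 80, 30) * 1.0, dim = c(6, 6, 80))
  st1 <- image_stack(fr, 105)
  st3 <- image_stack(fr * 3, 105)
  for (ord in 2:5) {
    c1 <- cumulant_images(st1, ord, opt)
    c3 <- cumulant_images(st3, ord, opt)
    expect_equal(as_plain(c3), 3^ord * as_plain(c1), tolerance = 1e-12)
  }
})

test_that("cumulants of independent populations add within sampling error", {
  opt <- test_optics()
  set.seed(13)
  kin <- photokinetics(activation_rate = 0, k_off = 6, k_on = 4,
                       bleach_rate = 0, i_on = 300, p_preactivated = 1)
  mk <- function(seed) {
    es <- make_uniform_region(150, side = 700, origin = c(200, 200),
                              seed = seed)
    es$traces <- simulate_traces(nrow(es$positions), kin, 3000)
    attr(es, "fov") <- 10 * 105
    render_frames(es, test_optics(), quiet_camera(), noise = FALSE,
                  fov = 10 * 105)
  }
  a <- mk(1); b <- mk(2)
  both <- image_stack(a$frames + b$frames - quiet_camera()$offset, 105)
  c_a <- cumulant_images(a, 2, opt)
  c_b <- cumulant_images(b, 2, opt)
  c_ab <- cumulant_images(both, 2, opt)
  sum_sep <- unclass(c_a) + unclass(c_b)
  core <- function(m) m[9:12, 9:12]
  expect_lt(max(abs(core(unclass(c_ab)) - core(sum_sep))) /
              max(abs(core(sum_sep))), 0.2)
})

test_that("blinking statistics follow the Bernoulli cumulant formulas", {
  opt <- test_optics()
  # one emitter at a pixel centre, no noise: pixel trace ~ eps * duty
  kin <- photokinetics(activation_rate = 0, k_off = 5, k_on = 5,
                       bleach_rate = 0, i_on = 200, p_preactivated = 1)
  es <- steady_emitter(c(5.5 * 105, 5.5 * 105), fov_px = 11)
  es$traces <- simulate_traces(1, kin, 6000, seed = 14)
  st <- render_frames(es, opt, quiet_camera(), noise = FALSE, fov = 11 * 105)
  pe <- (st$frames - quiet_camera()$offset) / quiet_camera()$em_gain
  # continuous-time integration softens the on/off telegraph; compare the
  # third central moment, which must vanish at rho = 0.5 by symmetry
  tr <- pe[6, 6, ]
  m3 <- mean((tr - mean(tr))^3)
  m2 <- mean((tr - mean(tr))^2)
  expect_lt(abs(m3) / m2^1.5, 0.1)
})

test_that("subsequence averaging undoes brightness drift when corrected", {
  opt <- test_optics()
  set.seed(15)
  fr <- array(rpois(6 * 6 * 100, 50) * 1.0, dim = c(6, 6, 100))
  c1 <- cumulant_images(image_stack(fr, 105), 3, opt)
  c2 <- cumulant_images(image_stack(fr * 1.25, 105), 3, opt)
  same <- average_subsequence_cumulants(list(c1, c1))
  expect_equal(as_plain(same), as_plain(c1))
  # second input is the first at 1.25x intensity: cumulant x 1.25^3, mean
  # intensity x 1.25; the correction rescales it back onto the first
  avg <- average_subsequence_cumulants(list(c1, c2),
                                       bleaching_correction = TRUE)
  expect_equal(as_plain(avg), as_plain(c1), tolerance = 1e-10)
  expect_error(average_subsequence_cumulants(list()), "empty")
  expect_error(average_subsequence_cumulants(list(c1, cumulant_images(
    image_stack(fr, 105), 2, opt))), "orders")
})

test_that("linearization takes signed roots and adapts to blinking", {
  opt <- test_optics()
  z <- structure(matrix(0, 8, 8), order = 3L, pixel_size = 35,
                 n_frames = 500, mean_intensity = 1,
                 class = c("cumulant_image", "matrix", "array"))
  expect_true(all(linearize(z, "standard") == 0))
  cimg <- structure(matrix(c(4, -9), 4, 4), order = 2L, pixel_size = 52.5,
                    n_frames = 500, mean_intensity = 1,
                    class = c("cumulant_image", "matrix", "array"))
  lin <- linearize(cimg, "standard")
  expect_equal(as_plain(lin), matrix(c(2, -3), 4, 4))
  # two regions of equal density and brightness, different on-time ratio:
  # standard output differs, adaptive output matches
  rho <- matrix(rep(c(0.3, 0.5), each = 8), 4, 4)
  eps <- matrix(100, 4, 4)
  N <- 50
  f4 <- function(r) r * (1 - r) * (1 - 6 * r + 6 * r^2)
  k4 <- N * eps^4 * f4(rho)
  cum4 <- structure(k4, order = 4L, pixel_size = 26.25, n_frames = 500,
                    mean_intensity = 1,
                    class = c("cumulant_image", "matrix", "array"))
  maps <- list(on_time_ratio = rho, brightness_counts = eps)
  std <- linearize(cum4, "standard")
  adp <- linearize(cum4, "adaptive", maps = maps)
  expect_gt(abs(mean(std[, 1:2]) - mean(std[, 3:4])) / abs(mean(std)), 0.1)
  expect_lt(abs(mean(adp[, 1:2]) - mean(adp[, 3:4])) /
              abs(mean(adp)), 0.1)
})

test_that("molecular maps invert noiseless forward cumulants exactly", {
  opt <- test_optics()
  cam <- test_camera()
  p <- opt$pixel_size
  sig <- effective_sigma_px(opt) * p
  vn <- function(n) p^(2 * n) * (2 * pi * sig^2)^(1 - n) / n
  mk <- function(val, ord) structure(matrix(val, 20, 20), order = ord,
    pixel_size = p / ord, n_frames = 500, mean_intensity = 1,
    class = c("cumulant_image", "matrix", "array"))
  for (truth in list(c(0.3, 900, 50), c(0.42, 500, 200), c(0.15, 2000, 20))) {
    rho <- truth[1]; eps <- truth[2]; dens <- truth[3] * 1e-6  # per nm^2
    f2 <- rho * (1 - rho)
    f3 <- f2 * (1 - 2 * rho)
    f4 <- f2 * (1 - 6 * rho + 6 * rho^2)
    maps <- estimate_molecular_maps(mk(dens * eps^2 * f2 * vn(2), 2),
                                    mk(dens * eps^3 * f3 * vn(3), 3),
                                    mk(dens * eps^4 * f4 * vn(4), 4),
                                    opt, cam, mask_threshold = 0)
    expect_equal(maps$on_time_ratio[10, 10], rho, tolerance = 1e-6)
    expect_equal(maps$brightness_counts[10, 10], eps, tolerance = 1e-6)
    expect_equal(maps$density[10, 10], truth[3], tolerance = 1e-6)
  }
})

test_that("kappa3 vanishes at rho = 0.5 and background pixels are masked", {
  # f3 has an exact root at rho = 1/2
  rho <- 0.5
  expect_equal(rho * (1 - rho) * (1 - 2 * rho), 0)
  opt <- test_optics()
  cam <- test_camera()
  p <- opt$pixel_size
  sig <- effective_sigma_px(opt) * p
  vn <- function(n) p^(2 * n) * (2 * pi * sig^2)^(1 - n) / n
  base2 <- matrix(900^2 * 0.21 * vn(2) * 50e-6, 10, 10)
  base2[1:3, ] <- 1e-8 * base2[5, 5]   # background stripe
  mk <- function(vals, ord) structure(vals, order = ord, pixel_size = p / ord,
    n_frames = 500, mean_intensity = 1,
    class = c("cumulant_image", "matrix", "array"))
  maps <- estimate_molecular_maps(
    mk(base2, 2),
    mk(matrix(900^3 * 0.21 * 0.4 * vn(3) * 50e-6, 10, 10), 3),
    mk(matrix(900^4 * 0.21 * (1 - 1.8 + 0.54) * vn(4) * 50e-6, 10, 10), 4),
    opt, cam, mask_threshold = 0.05)
  expect_true(all(!maps$valid[1:3, ]))
  expect_true(all(is.na(maps$density[1:3, ])))
  expect_true(all(maps$valid[5:10, ]))
})

test_that("PALM density is merged count over area", {
  tb <- localization_table(frame = rep(1L, 400), x = runif(400, 0, 1000),
                           y = runif(400, 0, 1000), photons = rep(100, 400),
                           background = rep(0, 400),
                           precision = rep(10, 400))
  expect_equal(density_estimate_palm(tb, 1), 400)
  expect_equal(density_estimate_palm(localization_table(), 2), 0)
  expect_error(density_estimate_palm(tb, 0))
})
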