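test_that("half-splitting interleaves subsequences", {
  h <- split_halves(40)
  expect_equal(h$a, seq(1, 39, 2))
  expect_equal(h$b, seq(2, 40, 2))
  expect_length(h$a, 20)
  # 20,000 frames in 500-frame subsequences: each half carries 10,000
  expect_equal(length(split_halves(length(split_subsequences(20000)))$a) *
                 500, 10000)
  expect_equal(split_halves(2), list(a = 1L, b = 2L))
  expect_error(split_halves(1), "at least 2")
})

test_that("FRC is 1 for identical, -1 for negated, symmetric in arguments", {
  set.seed(20)
  img <- matrix(rnorm(64 * 64, 100, 20), 64, 64)
  same <- frc(img, img, pixel_size = 20)
  expect_true(all(abs(same$frc - 1) < 1e-12))
  anti <- frc(img, -img, pixel_size = 20)
  expect_true(all(abs(anti$frc + 1) < 1e-12))
  b <- matrix(rnorm(64 * 64, 100, 20), 64, 64)
  expect_identical(frc(img, b, 20)$frc, frc(b, img, 20)$frc)
})

test_that("independent white noise decorrelates over rings", {
  set.seed(21)
  a <- matrix(rnorm(128 * 128), 128, 128)
  b <- matrix(rnorm(128 * 128), 128, 128)
  curve <- frc(a, b, pixel_size = 20)
  # ring-averaged FRC ~ 0 +/- 1/sqrt(ring count); outer rings have >100 px
  outer <- curve$frc[curve$freq > 0.25 / 20]
  expect_lt(abs(mean(outer)), 0.02)
  expect_lt(max(abs(outer)), 5 / sqrt(100))
})

test_that("sector sums reproduce the full-ring FRC exactly", {
  set.seed(22)
  a <- matrix(rnorm(64 * 64, 50, 10), 64, 64)
  b <- a + matrix(rnorm(64 * 64, 0, 5), 64, 64)
  full <- frc(a, b, 20)
  sect <- sectorial_frc(a, b, 20)
  expect_length(sect, 12)
  num <- Reduce(`+`, lapply(sect, function(s) s$num))
  da <- Reduce(`+`, lapply(sect, function(s) s$den_a))
  db <- Reduce(`+`, lapply(sect, function(s) s$den_b))
  expect_equal(num / sqrt(pmax(da * db, .Machine$double.xmin)), full$frc,
               tolerance = 1e-12)
  # degenerate partition: one sector of extent pi equals the full FRC
  one <- sectorial_frc(a, b, 20, sector_extent = pi)
  expect_equal(one[[1]]$frc, full$frc, tolerance = 1e-12)
})

test_that("anisotropic structure yields direction-dependent sFRC", {
  set.seed(23)
  n <- 128
  # broadband structure modulated along x only (constant along y)
  stripes <- matrix(rep(rnorm(n, 0, 1), each = n), n, n)
  a <- stripes + matrix(rnorm(n * n, 0, 0.8), n, n)
  b <- stripes + matrix(rnorm(n * n, 0, 0.8), n, n)
  sect <- sectorial_frc(a, b, 20)
  angles <- vapply(sect, function(s) attr(s, "angle"), numeric(1))
  # no crossing means correlation persists to Nyquist: best possible
  res <- vapply(sect, function(s) {
    r <- attr(s, "resolution")
    if (is.na(r)) 2 * 20 else r
  }, numeric(1))
  # stripes modulate along x: the sector containing the kx axis (angle ~0
  # or ~pi) must resolve better (smaller value) than the ky sector
  along <- which.min(abs(angles - pi / 24))
  across <- which.min(abs(angles - pi / 2))
  expect_lt(res[along], res[across])
})

test_that("jackknife of additive reconstructions matches closed forms", {
  set.seed(24)
  N <- 1000
  contrib <- array(rnorm(8 * 8 * N, 10, 2), dim = c(8, 8, N))
  jk <- jackknife_snr(contrib, statistic = "mean")
  expect_equal(jk$n, N)
  expect_lt(abs(mean(jk$var) - 4 / N) / (4 / N), 0.1)
  # identical frames: zero variance, capped SNR
  same <- array(5, dim = c(4, 4, 10))
  expect_true(all(jackknife_snr(same, statistic = "sum")$snr_db == 99))
  expect_error(jackknife_snr(array(1, dim = c(2, 2, 1))), "at least 2")
})

test_that("algebraic leave-one-out equals brute force on small stacks", {
  set.seed(25)
  arr <- array(rpois(5 * 5 * 18, 30) * 1.0, dim = c(5, 5, 18))
  st <- image_stack(arr, 105)
  brute_mean <- jackknife_snr(st, reconstructor = function(a)
    rowMeans(a, dims = 2))
  alg_mean <- jackknife_snr(arr, statistic = "mean")
  expect_equal(brute_mean$var, alg_mean$var, tolerance = 1e-12)
  expect_equal(brute_mean$theta, alg_mean$theta, tolerance = 1e-12)
  brute_sum <- jackknife_snr(st, reconstructor = function(a)
    rowSums(a, dims = 2))
  alg_sum <- jackknife_snr(arr, statistic = "sum")
  expect_equal(brute_sum$var, alg_sum$var, tolerance = 1e-10)
  # order-2 SOFI: algebraic updates against brute-force recomputation
  opt <- test_optics()
  jk2 <- jackknife_snr_sofi2(st, opt, bin_to_raw = FALSE)
  recon <- function(a) {
    unclass(cumulant_images(image_stack(a, 105), 2, opt))
  }
  brute2 <- jackknife_snr(st, reconstructor = recon)
  expect_equal(jk2$var, brute2$var, tolerance = 1e-8)
})

test_that("MTF cutoff self-normalizes to the support edge", {
  opt <- test_optics()
  tgt <- make_bar_target(800, fov = 64 * 105, seed = 26)
  wf <- widefield_reference(tgt, opt, pixel_size = 105 / 2)
  thr <- mtf_threshold_widefield(wf, optics = opt)
  expect_gt(thr, 0)
  expect_lt(thr, 0.2)
  curve <- mtf_curve(wf$frames[, , 1], wf$pixel_size)
  self <- mtf_cutoff(curve, curve, thr)
  # support requires runs of >= 2 bins (smoothed peaks are never 1 bin)
  s0 <- pmax(curve$mag - 0.5, 0) > 0
  sup <- which(s0 & (c(s0[-1], FALSE) | c(FALSE, s0[-length(s0)])))
  expect_equal(self$cutoff, curve$freq[max(sup)])
  # a pure widefield image never beats the Abbe limit
  expect_lte(self$cutoff, abbe_cutoff(opt) * 1.02)
})
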