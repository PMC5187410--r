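test_that("Hellinger distance matches closed form and numeric integration", {
  expect_equal(hellinger_distance(0, 0, 10, 0, 0, 10), 0)
  expect_gt(hellinger_distance(0, 0, 10, 1e5, 0, 10), 0.999999)
  # frozen closed-form value for d = 20 nm, sigma = 10 nm both
  h <- hellinger_distance(0, 0, 10, 20, 0, 10)
  expect_equal(h^2, 1 - exp(-400 / 800), tolerance = 1e-12)
  expect_equal(h, 0.6273, tolerance = 1e-4)
  # numeric integration of the Hellinger integral for unequal sigmas
  cases <- list(c(20, 10, 10), c(35, 8, 22), c(0, 5, 25))
  for (cs in cases) {
    d <- cs[1]; sa <- cs[2]; sb <- cs[3]
    xs <- seq(-6 * sb - abs(d), 6 * sb + abs(d), length.out = 601)
    ys <- seq(-6 * sb, 6 * sb, length.out = 601)
    dx <- diff(xs)[1]; dy <- diff(ys)[1]
    fa <- outer(ys, xs, function(y, x)
      dnorm(x, 0, sa) * dnorm(y, 0, sa))
    fb <- outer(ys, xs, function(y, x)
      dnorm(x, d, sb) * dnorm(y, 0, sb))
    bc <- sum(sqrt(fa * fb)) * dx * dy
    expect_equal(hellinger_distance(0, 0, sa, d, 0, sb), sqrt(1 - bc),
                 tolerance = 1e-3)
  }
  expect_error(hellinger_distance(0, 0, -1, 0, 0, 1), "precisions")
})

make_table <- function(frame, x, y, prec = 10) {
  n <- length(frame)
  localization_table(frame = as.integer(frame), x = x, y = y,
                     photons = rep(100, n), background = rep(0, n),
                     precision = rep_len(prec, n))
}

test_that("basic merging contracts", {
  one <- make_table(1, 500, 500)
  m <- merge_blinks(one, merge_params(0.9, 20))
  expect_equal(m$n, 1)
  expect_true(is.na(m$t_off))
  two <- make_table(c(1, 2), c(500, 500), c(500, 500))
  expect_equal(merge_blinks(two, merge_params(0.9, 20))$n, 1)
  # unsorted input is rejected
  bad <- make_table(c(3, 1), c(0, 0), c(0, 0))
  expect_error(merge_blinks(bad, merge_params(0.9, 20)), "sorted")
  # threshold 0: only identical positions merge; distinct positions do not
  set.seed(30)
  tb <- make_table(1:20, runif(20, 0, 5000), runif(20, 0, 5000))
  expect_equal(merge_blinks(tb, merge_params(0, 20))$n, 20)
})

test_that("merged count is monotone non-increasing in the threshold", {
  set.seed(31)
  n <- 150
  tb <- make_table(sort(sample(1:300, n, replace = TRUE)),
                   runif(n, 0, 3000), runif(n, 0, 3000), prec = 15)
  regions <- list(all = c(0, 3000, 0, 3000))
  sweep <- merge_sweep(tb, thresholds = seq(0.1, 0.9, 0.2), regions,
                       params = merge_params(0.5, 20))
  expect_true(all(diff(sweep$n) <= 0))
  expect_equal(sweep$raw_count[1], n)
  expect_error(merge_sweep(tb, 0.5, list(empty = c(9000, 9100, 0, 10))),
               "empty region")
})

test_that("merging is stable under within-frame permutations", {
  set.seed(32)
  mols <- cbind(runif(30, 0, 4000), runif(30, 0, 4000))
  frame <- rep(1:10, each = 6)
  idx <- sample(1:30, 60, replace = TRUE)
  tb <- make_table(frame, mols[idx, 1] + rnorm(60, 0, 5),
                   mols[idx, 2] + rnorm(60, 0, 5))
  perm <- unlist(lapply(split(seq_len(60), frame), sample))
  tb2 <- tb[perm, ]
  class(tb2) <- class(tb)
  m1 <- merge_blinks(tb, merge_params(0.9, 20))
  m2 <- merge_blinks(tb2, merge_params(0.9, 20))
  expect_equal(m1$n, m2$n)
})

test_that("simulated ground truth is counted within Poisson error", {
  setup <- default_setup()
  opt <- setup$optics
  cam <- setup$camera
  set.seed(22)
  n_mol <- 50
  pos <- cbind(runif(n_mol, 500, 2800), runif(n_mol, 500, 2800))
  es <- emitter_set(pos)
  attr(es, "fov") <- 32 * 105
  kin <- photokinetics(activation_rate = 0.02, k_off = 8, k_on = 2,
                       bleach_rate = 4, i_on = 500)
  es$traces <- simulate_traces(n_mol, kin, 4000, exposure = 0.05)
  st <- render_frames(es, opt, cam, fov = 32 * 105)
  locs <- palm_localize(st, opt, cam)
  expect_gt(nrow(locs), n_mol)         # blinking overcounts before merging
  m <- merge_blinks(locs, merge_params(0.9), exposure = 0.05)
  expect_lt(abs(m$n - n_mol), sqrt(n_mol) + 1)
  # mean off-time between bursts within 15% of the simulated 1/k_on
  expect_lt(abs(m$t_off - 0.5) / 0.5, 0.15)
})

test_that("dense regions keep losing counts at high thresholds", {
  setup <- default_setup()
  opt <- setup$optics
  cam <- setup$camera
  set.seed(33)
  # two regions: sparse (40/um^2) and dense (800/um^2)
  sparse <- make_uniform_region(40, side = 1500, origin = c(300, 300))
  dense <- make_uniform_region(800, side = 1500, origin = c(1900, 1900))
  pos <- rbind(sparse$positions, dense$positions)
  es <- emitter_set(pos)
  attr(es, "fov") <- 36 * 105
  kin <- photokinetics(activation_rate = 0.004, k_off = 8, k_on = 2,
                       bleach_rate = 4, i_on = 500)
  es$traces <- simulate_traces(nrow(pos), kin, 3000, exposure = 0.05)
  st <- render_frames(es, opt, cam, fov = 36 * 105)
  locs <- palm_localize(st, opt, cam)
  regions <- list(sparse = c(300, 1800, 300, 1800),
                  dense = c(1900, 3400, 1900, 3400))
  sweep <- merge_sweep(locs, thresholds = c(0.5, 0.7, 0.9), regions,
                       params = merge_params(0.9, 30))
  sp <- sweep[sweep$region == "sparse", ]
  dn <- sweep[sweep$region == "dense", ]
  # relative count loss from threshold 0.7 to 0.9 is larger where denser
  drop_sparse <- (sp$n[2] - sp$n[3]) / sp$n[2]
  drop_dense <- (dn$n[2] - dn$n[3]) / dn$n[2]
  expect_gte(drop_dense, drop_sparse)
  # under-counting at high density: recovered N below ground truth
  expect_lt(dn$n[3], 800 * 1.5^2)
})
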