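test_that("optical configuration validates and yields the Abbe cutoff", {
  opt <- optical_config(600, 1.49)
  expect_equal(opt$psf_sigma, 0.21 * 600 / 1.49)
  expect_equal(abbe_cutoff(opt), 2 * 1.49 / 600)
  expect_equal(abbe_cutoff(optical_config(500, 1.0)), 4e-3)
  # homogeneity: doubling NA doubles the cutoff
  for (na in c(0.8, 1.2, 1.45)) {
    expect_equal(abbe_cutoff(optical_config(600, 2 * na, sigma_tolerance = 10)),
                 2 * abbe_cutoff(optical_config(600, na, sigma_tolerance = 10)))
  }
  expect_error(optical_config(-600, 1.49))
  expect_error(optical_config(600, 1.49, psf_sigma = 1000),
               "inconsistent")
})

test_that("camera configuration enforces its invariants", {
  cam <- camera_config()
  expect_equal(cam$excess_noise_factor, sqrt(2))
  expect_error(camera_config(quantum_efficiency = 0))
  expect_error(camera_config(em_gain = 0.5))
  expect_error(camera_config(read_noise_sd = -1))
})

test_that("image stacks round-trip through multi-page TIFF", {
  z <- image_stack(array(0, dim = c(4, 4, 3)), pixel_size = 105)
  path <- tempfile(fileext = ".tif")
  write_stack(z, path)
  back <- read_stack(path)
  expect_equal(dim(back$frames), c(4, 4, 3))
  expect_true(all(back$frames == 0))
  expect_equal(back$pixel_size, 105)

  set.seed(1)
  st <- image_stack(array(as.numeric(sample(0:65535, 5 * 6 * 4,
                                            replace = TRUE)),
                          dim = c(5, 6, 4)), pixel_size = 96,
                    frame_interval = 0.01)
  write_stack(st, path)
  back <- read_stack(path)
  expect_equal(back$frames, st$frames)   # integer counts preserved
  expect_equal(back$frame_interval, 0.01)
  unlink(c(path, paste0(path, ".meta.yaml")))
})

test_that("corrupt or missing stack files raise errors", {
  expect_error(read_stack(tempfile()), "not found")
  bad <- tempfile(fileext = ".tif")
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00, 0x08)), bad)  # truncated TIFF
  expect_error(read_stack(bad))
  unlink(bad)
})

test_that("localization tables round-trip through CSV", {
  path <- tempfile(fileext = ".csv")
  empty <- localization_table()
  write_localizations(empty, path)
  expect_equal(nrow(read_localizations(path)), 0)

  tb <- localization_table(frame = c(1L, 3L), x = c(105.00, 12.34),
                           y = c(0.00, 900.5), photons = c(500, 120.25),
                           background = c(0.5, 1.25),
                           precision = c(10, 25.75))
  write_localizations(tb, path)
  back <- read_localizations(path)
  expect_equal(back$x, tb$x, tolerance = 1e-9)   # 0.01 nm resolution kept
  expect_equal(back$frame, tb$frame)
  expect_equal(back$precision, tb$precision)
  unlink(path)
})

test_that("malformed localization rows are reported with their line", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("frame,x,y,photons,background,precision,channel",
               "1,10.0,20.0,100,0.5,12.0,default",
               "2,oops,20.0,100,0.5,12.0,default"), path)
  expect_error(read_localizations(path), "line 3")
  expect_error(localization_table(frame = 1L, x = 1, y = 1, photons = 1,
                                  background = 0, precision = 0))
  unlink(path)
})

test_that("yaml configs reconstruct typed objects", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(optics = list(wavelength = 600,
                                      numerical_aperture = 1.49),
                        camera = list(em_gain = 150),
                        kinetics = list(i_on = 250)), path)
  cfg <- read_config(path)
  expect_s3_class(cfg$optics, "optical_config")
  expect_equal(cfg$camera$em_gain, 150)
  expect_equal(cfg$kinetics$i_on, 250)
  unlink(path)
})
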