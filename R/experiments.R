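#' Default optics and camera used by the scripted experiments
#'
#' 1.49 NA TIRF objective, 600 nm emission, 105 nm back-projected pixels;
#' EMCCD with gain 100, sqrt(2) excess noise, 50 ms exposure.
#'
#' @return A list with elements `optics` and `camera`.
#' @export
default_setup <- function() {
  list(optics = optical_config(wavelength = 600, numerical_aperture = 1.49,
                               pixel_size = 105),
       camera = camera_config())
}

#' Cutoff-frequency sweep on the simulated bar target
#'
#' Simulates the bar test target at a given emitter density and on-state
#' brightness, reconstructs PALM localization histograms (at a pixel size
#' matching the finest SOFI order) and SOFI images of orders 2-6 for every
#' frame count of the grid, and measures the MTF cutoff frequency of every
#' reconstruction. Frame counts are nested: one sequence of
#' `max(frame_grid)` frames is simulated and smaller counts are prefixes.
#' SOFI images use 500-frame subsequences whose cumulants are computed once
#' and prefix-averaged; the MTF reference for every method is its own
#' reconstruction at the largest frame count. The SOFI cutoff of a frame
#' count is the maximum over the computed orders.
#'
#' @param density Emitter density in 1/um^2 (e.g. 800 or 1200).
#' @param i_on Photons per emitter per frame in the on state.
#' @param preset Photokinetic preset name (see [kinetic_preset()]);
#'   `"meos2"` matches the lower-density scenario, `"pscfp2"` the
#'   higher-density one.
#' @param frame_grid Increasing frame counts to evaluate.
#' @param orders SOFI cumulant orders.
#' @param fov_px Field of view in raw pixels (square).
#' @param sub_length SOFI subsequence length in frames.
#' @param palm_pixel_div PALM histogram pixel = raw pixel / this.
#' @param bg_photons Diffuse background emission (photons per pixel per
#'   frame) emulating cellular autofluorescence; part of the simulated
#'   study conditions.
#' @param setup List with `optics` and `camera` (default [default_setup()]).
#' @param seed Integer seed for target, kinetics and noise.
#' @param verbose Print progress.
#' @return A `cutoff_sweep` object: list with `table` (data frame: frames,
#'   method, cutoff), `f_widefield` (Abbe cutoff 1/nm), `sofi_best`,
#'   `palm` (named cutoff vectors by frame count), `onset_sofi`,
#'   `onset_palm` (first frame count exceeding the widefield cutoff, NA if
#'   never), `crossover` (first frame count where PALM exceeds the best
#'   SOFI cutoff, NA if never), plus the simulation parameters.
#' @export
run_cutoff_sweep <- function(density, i_on = 100,
                             preset = c("meos2", "pscfp2"),
                             frame_grid = c(500, 1000, 2000, 5000, 10000,
                                            20000),
                             orders = 2:6, fov_px = 64, sub_length = 500,
                             palm_pixel_div = 6, bg_photons = 5,
                             setup = default_setup(),
                             seed = 1, verbose = interactive()) {
  preset <- match.arg(preset)
  stopifnot(all(diff(frame_grid) > 0), frame_grid[1] >= sub_length)
  optics <- setup$optics
  camera <- setup$camera
  tmax <- max(frame_grid)
  nsub <- tmax %/% sub_length
  stopifnot(all(frame_grid %% sub_length == 0))
  set.seed(seed)
  fov <- fov_px * optics$pixel_size
  target <- make_bar_target(density, fov = fov)
  kin <- kinetic_preset(preset, i_on = i_on)
  target$traces <- simulate_traces(nrow(target$positions), kin, tmax,
                                   exposure = camera$exposure_time)
  # per-subsequence processing: PALM localizations + cumulants per order
  locs <- vector("list", nsub)
  cums <- lapply(orders, function(o) vector("list", nsub))
  names(cums) <- paste0("sofi", orders)
  for (s in seq_len(nsub)) {
    fr <- ((s - 1) * sub_length + 1):(s * sub_length)
    st <- render_frames(target, optics, camera, frames = fr, fov = fov,
                        bg_photons = bg_photons)
    locs[[s]] <- palm_localize(st, optics, camera,
                               frame_offset = (s - 1L) * sub_length)
    for (k in seq_along(orders)) {
      cums[[k]][[s]] <- cumulant_images(st, orders[k], optics)
    }
    if (verbose) message("subsequence ", s, "/", nsub, ": ",
                         nrow(locs[[s]]), " localizations")
  }
  all_locs <- do.call(rbind, lapply(locs, as.data.frame))
  all_locs <- as_localization_table(all_locs)
  # bar rows for profile averaging
  bars <- attr(target, "bars")
  rowsel <- function(px) {
    n <- round(fov / px)
    i <- seq_len(n)
    which((i - 0.5) * px >= min(bars$y0) & (i - 0.5) * px <= max(bars$y1))
  }
  # widefield threshold from a noiseless fine-grid rendering
  wf <- widefield_reference(target, optics, pixel_size = optics$pixel_size / 2,
                            fov = fov)
  wfm <- bar_modulation(wf$frames[, , 1], wf$pixel_size, bars)
  ok <- is.finite(wfm$amp)
  thr <- max(stats::approx(wfm$freq[ok], wfm$amp[ok] / max(wfm$amp[ok]),
                           xout = abbe_cutoff(optics), rule = 2)$y, 1e-6)
  # PALM curves per frame count
  palm_px <- optics$pixel_size / palm_pixel_div
  spec <- render_spec("histogram", pixel_size = palm_px)
  palm_mods <- lapply(frame_grid, function(T) {
    sub <- all_locs[all_locs$frame <= T, , drop = FALSE]
    class(sub) <- class(all_locs)
    img <- render_palm(sub, spec, fov)
    bar_modulation(img, palm_px, bars)
  })
  palm_ref <- palm_mods[[length(frame_grid)]]
  palm_cut <- vapply(palm_mods, function(mv)
    bar_cutoff(mv, palm_ref, thr)$cutoff, numeric(1))
  # SOFI curves per order and frame count
  sofi_cut <- matrix(NA_real_, length(frame_grid), length(orders),
                     dimnames = list(frame_grid, names(cums)))
  for (k in seq_along(orders)) {
    o <- orders[k]
    sig_eff <- effective_sigma_px(optics) * optics$pixel_size
    mods <- lapply(frame_grid, function(T) {
      ks <- T %/% sub_length
      avg <- average_subsequence_cumulants(cums[[k]][seq_len(ks)],
                                           bleaching_correction = TRUE,
                                           offset = camera$offset)
      img <- flatten_mosaic(linearize(avg, "standard"), o)
      bm <- bar_modulation(img, optics$pixel_size / o, bars)
      # optical-transfer bound: the order-o cumulant PSF (sigma/sqrt(o))
      # cannot carry modulation beyond its band; apparent modulation
      # there is residual processing artifact, not resolution
      otf <- exp(-2 * pi^2 * (sig_eff^2 / o) * bm$freq^2)
      bm$amp[otf < 0.01] <- NA_real_
      bm
    })
    ref <- mods[[length(frame_grid)]]
    sofi_cut[, k] <- vapply(mods, function(mv)
      bar_cutoff(mv, ref, thr)$cutoff, numeric(1))
  }
  sofi_best <- apply(sofi_cut, 1, max)
  fwf <- abbe_cutoff(optics)
  first_at <- function(cond) {
    w <- which(cond)
    if (length(w) == 0) NA_real_ else frame_grid[w[1]]
  }
  tab <- rbind(
    data.frame(frames = frame_grid, method = "palm", cutoff = palm_cut),
    do.call(rbind, lapply(seq_along(orders), function(k)
      data.frame(frames = frame_grid, method = names(cums)[k],
                 cutoff = sofi_cut[, k]))),
    data.frame(frames = frame_grid, method = "sofi_best",
               cutoff = sofi_best))
  structure(list(table = tab, f_widefield = fwf,
                 palm = stats::setNames(palm_cut, frame_grid),
                 sofi_best = stats::setNames(sofi_best, frame_grid),
                 sofi_orders = sofi_cut,
                 onset_sofi = first_at(sofi_best > fwf),
                 onset_palm = first_at(palm_cut > fwf),
                 crossover = first_at(palm_cut > sofi_best),
                 density = density, i_on = i_on, preset = preset,
                 frame_grid = frame_grid, seed = seed,
                 n_localizations = nrow(all_locs)),
            class = "cutoff_sweep")
}

#' @export
print.cutoff_sweep <- function(x, ...) {
  cat(sprintf("Cutoff sweep: density %g /um^2, I_on %g, preset %s\n",
              x$density, x$i_on, x$preset))
  cat(sprintf("  widefield cutoff: %.4g 1/nm\n", x$f_widefield))
  df <- data.frame(frames = x$frame_grid,
                   palm = signif(unname(x$palm), 3),
                   sofi_best = signif(unname(x$sofi_best), 3))
  print(df, row.names = FALSE)
  cat(sprintf("  SOFI onset %s, PALM onset %s, PALM>SOFI at %s frames\n",
              x$onset_sofi, x$onset_palm, x$crossover))
  invisible(x)
}

#' Photokinetics for the density benchmark
#'
#' mEos2-like blinking with the activation rate scaled to the planned
#' acquisition length so that ~99% of the emitters are activated by the
#' last frame (as one would tune the 405 nm activation power in a counting
#' experiment). The blink cycle (mean 6 bursts before bleaching, one-third
#' duty while active) keeps each molecule fluctuating for roughly 30
#' frames, long enough for the cumulant-based duty estimation to be
#' well-conditioned.
#'
#' @param n_frames Planned frame count.
#' @param exposure Frame time (s).
#' @param i_on Photons per frame in the on state.
#' @return A [photokinetics()].
#' @export
benchmark_kinetics <- function(n_frames, exposure = 0.05, i_on = 100) {
  photokinetics(activation_rate = 4.6 / (n_frames * exposure),
                k_off = 10, k_on = 5, bleach_rate = 2, i_on = i_on)
}

#' Molecular-density benchmark (PALM vs SOFI)
#'
#' Simulates uniform-density emitter regions, estimates the molecular
#' density with blink-merged PALM counting (Hellinger threshold 0.9) and
#' with the SOFI molecular-parameter maps (median over the region), and
#' repeats everything `reps` times.
#'
#' @param densities Ground-truth densities in 1/um^2.
#' @param frame_counts Frame counts (multiples of `sub_length`).
#' @param reps Repetitions per grid point (>= 2).
#' @param fov_px Field of view in raw pixels.
#' @param region_margin_px Margin between region and field edge, px.
#' @param sub_length Processing chunk length (frames).
#' @param map_window Cumulant window length for the molecular maps. The
#'   emitters are transient (each blinks for a few tens of frames before
#'   bleaching), so cumulants are taken over windows of comparable length
#'   and the fitted per-window density is multiplied by the number of
#'   windows: each window only sees the molecules active within it.
#' @param hellinger_threshold Merge threshold for the PALM estimate.
#' @param setup List with `optics` and `camera`.
#' @param seed Base seed; repetition r of grid point g uses
#'   `seed + 1000 * g + r`.
#' @param verbose Print progress.
#' @return A `density_benchmark`: `table` (density, frames, rep,
#'   palm_est, sofi_est) and `summary` (mean and sd over reps).
#' @export
run_density_benchmark <- function(densities = c(200, 800),
                                  frame_counts = c(2000, 5000),
                                  reps = 10, fov_px = 32,
                                  region_margin_px = 5, sub_length = 500,
                                  map_window = 50,
                                  hellinger_threshold = 0.9,
                                  setup = default_setup(), seed = 1,
                                  verbose = interactive()) {
  stopifnot(reps >= 2, all(frame_counts %% sub_length == 0))
  optics <- setup$optics
  camera <- setup$camera
  fov <- fov_px * optics$pixel_size
  side <- fov - 2 * region_margin_px * optics$pixel_size
  origin <- rep(region_margin_px * optics$pixel_size, 2)
  rows <- list()
  g <- 0L
  for (d in densities) for (T in frame_counts) {
    g <- g + 1L
    for (r in seq_len(reps)) {
      set.seed(seed + 1000L * g + r)
      region <- make_uniform_region(d, side, origin)
      kin <- benchmark_kinetics(T, camera$exposure_time)
      region$traces <- simulate_traces(nrow(region$positions), kin, T,
                                       exposure = camera$exposure_time)
      attr(region, "fov") <- fov
      # chunked processing; cumulants on short windows within each chunk
      nsub <- T %/% sub_length
      stopifnot(sub_length %% map_window == 0)
      locs <- vector("list", nsub)
      c2 <- c3 <- c4 <- list()
      for (s in seq_len(nsub)) {
        frset <- ((s - 1) * sub_length + 1):(s * sub_length)
        st <- render_frames(region, optics, camera, frames = frset,
                            fov = fov)
        locs[[s]] <- palm_localize(st, optics, camera,
                                   frame_offset = (s - 1L) * sub_length)
        for (w in seq_len(sub_length %/% map_window)) {
          wi <- ((w - 1) * map_window + 1):(w * map_window)
          sub <- image_stack(st$frames[, , wi, drop = FALSE],
                             st$pixel_size, st$frame_interval)
          c2[[length(c2) + 1]] <- cumulant_images(sub, 2, optics)
          c3[[length(c3) + 1]] <- cumulant_images(sub, 3, optics)
          c4[[length(c4) + 1]] <- cumulant_images(sub, 4, optics)
        }
      }
      all_locs <- as_localization_table(
        do.call(rbind, lapply(locs, as.data.frame)))
      # PALM: merge blinks, count inside the region
      m <- merge_blinks(all_locs,
                        merge_params(hellinger_threshold = hellinger_threshold),
                        exposure = camera$exposure_time)
      mt <- m$table
      inside <- mt$x >= origin[1] & mt$x < origin[1] + side &
        mt$y >= origin[2] & mt$y < origin[2] + side
      palm_est <- sum(inside) / (side / 1000)^2
      # SOFI: molecular maps, median density inside the region; the
      # per-window density counts only the transiently active molecules,
      # so it is scaled by the number of windows
      k2 <- average_subsequence_cumulants(c2)
      k3 <- average_subsequence_cumulants(c3)
      k4 <- average_subsequence_cumulants(c4)
      maps <- estimate_molecular_maps(k2, k3, k4, optics, camera)
      n_windows <- T %/% map_window
      px2 <- attr(k2, "pixel_size")
      n2 <- nrow(maps$density)
      ii <- which((row(maps$density) - 0.5) * px2 >= origin[2] &
                  (row(maps$density) - 0.5) * px2 < origin[2] + side &
                  (col(maps$density) - 0.5) * px2 >= origin[1] &
                  (col(maps$density) - 0.5) * px2 < origin[1] + side &
                  maps$valid)
      sofi_est <- if (length(ii) > 0) {
        n_windows * stats::median(maps$density[ii])
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        density = d, frames = T, rep = r,
        palm_est = palm_est, sofi_est = sofi_est,
        raw_locs = nrow(all_locs), merged = m$n)
      if (verbose) message(sprintf(
        "density %g, %d frames, rep %d: PALM %.0f, SOFI %.0f /um^2",
        d, T, r, palm_est, sofi_est))
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(palm_est, sofi_est) ~ density + frames,
                          tab, function(z) c(mean = mean(z), sd = stats::sd(z)))
  summary <- data.frame(density = agg$density, frames = agg$frames,
                        palm_mean = agg$palm_est[, "mean"],
                        palm_sd = agg$palm_est[, "sd"],
                        sofi_mean = agg$sofi_est[, "mean"],
                        sofi_sd = agg$sofi_est[, "sd"])
  structure(list(table = tab, summary = summary, reps = reps, seed = seed),
            class = "density_benchmark")
}

#' @export
print.density_benchmark <- function(x, ...) {
  cat("Density benchmark (mean +/- sd over", x$reps, "repetitions):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  GT %4g /um^2, %5d frames: PALM %6.0f +/- %4.0f, SOFI %6.0f +/- %4.0f\n",
                s$density[i], s$frames[i], s$palm_mean[i], s$palm_sd[i],
                s$sofi_mean[i], s$sofi_sd[i]))
  }
  invisible(x)
}
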