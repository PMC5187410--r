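#' Split data into two stochastically independent halves
#'
#' Subsequences (or the localizations belonging to them) are assigned
#' alternately (odd/even index) to two groups, so each half carries half of
#' the total frames and photobleaching affects both halves equally.
#'
#' @param n_subsequences Number of subsequences (>= 2).
#' @return A list with integer index vectors `a` and `b`.
#' @export
split_halves <- function(n_subsequences) {
  if (n_subsequences < 2) stop("need at least 2 subsequences to split")
  idx <- seq_len(n_subsequences)
  list(a = idx[idx %% 2 == 1L], b = idx[idx %% 2 == 0L])
}

ring_index <- function(n) {
  # integer radial frequency index per FFT pixel (DC at [1,1])
  k <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1))
  kx <- matrix(k, n, n, byrow = TRUE)
  ky <- matrix(k, n, n)
  list(r = round(sqrt(kx^2 + ky^2)), kx = kx, ky = ky)
}

#' Fourier ring correlation
#'
#' Correlation of the Fourier transforms of two images over rings of
#' constant spatial frequency:
#' `FRC(q) = Re sum_ring F_a conj(F_b) / sqrt(sum|F_a|^2 sum|F_b|^2)`.
#' The resolution is the inverse of the first frequency where the curve
#' falls below the threshold (fixed 1/7 by default).
#'
#' @param image_a,image_b Square numeric matrices of equal size.
#' @param pixel_size Pixel size in nm.
#' @param threshold Fixed FRC threshold.
#' @return An `frc_curve`: data frame with `freq` (1/nm) and `frc`, with
#'   attributes `resolution` (nm, `NA` if no crossing) and `threshold`.
#' @export
frc <- function(image_a, image_b, pixel_size, threshold = 1 / 7) {
  stopifnot(is.matrix(image_a), all(dim(image_a) == dim(image_b)),
            nrow(image_a) == ncol(image_a))
  n <- nrow(image_a)
  fa <- stats::fft(image_a)
  fb <- stats::fft(image_b)
  ri <- ring_index(n)
  num <- Re(fa * Conj(fb))
  da <- Mod(fa)^2
  db <- Mod(fb)^2
  rmax <- floor(n / 2)
  rings <- 1:rmax
  s_num <- tapply_ring(num, ri$r, rmax)
  s_da <- tapply_ring(da, ri$r, rmax)
  s_db <- tapply_ring(db, ri$r, rmax)
  curve <- s_num / sqrt(pmax(s_da * s_db, .Machine$double.xmin))
  freq <- rings / (n * pixel_size)
  res <- crossing_resolution(freq, curve, threshold)
  structure(data.frame(freq = freq, frc = curve),
            resolution = res, threshold = threshold,
            class = c("frc_curve", "data.frame"))
}

tapply_ring <- function(values, r, rmax, sector_mask = NULL) {
  v <- values
  if (!is.null(sector_mask)) v <- v * sector_mask
  out <- numeric(rmax)
  sel <- r >= 1 & r <= rmax
  if (!is.null(sector_mask)) sel <- sel & sector_mask
  agg <- tapply(values[sel], r[sel], sum)
  out[as.integer(names(agg))] <- agg
  out
}

crossing_resolution <- function(freq, curve, threshold) {
  below <- which(curve < threshold)
  if (length(below) == 0) return(NA_real_)
  1 / freq[below[1]]
}

#' Sectorial Fourier ring correlation
#'
#' FRC restricted to angular sectors of the frequency plane (default
#' angular extent pi/12, i.e. 12 sectors covering a half-plane, each paired
#' with its Hermitian-symmetric opposite sector). Summing the sector
#' numerators and denominators over all sectors reproduces the full-ring
#' FRC exactly.
#'
#' @inheritParams frc
#' @param sector_extent Angular sector width in radians (must divide pi).
#' @return List of `frc_curve` objects (one per sector, attribute `angle` =
#'   sector centre), with attributes `best` and `worst` (sector resolutions).
#' @export
sectorial_frc <- function(image_a, image_b, pixel_size,
                          sector_extent = pi / 12, threshold = 1 / 7) {
  stopifnot(is.matrix(image_a), all(dim(image_a) == dim(image_b)),
            nrow(image_a) == ncol(image_a))
  ns <- round(pi / sector_extent)
  if (abs(ns * sector_extent - pi) > 1e-9) {
    stop("sector_extent must divide pi")
  }
  n <- nrow(image_a)
  fa <- stats::fft(image_a)
  fb <- stats::fft(image_b)
  ri <- ring_index(n)
  num <- Re(fa * Conj(fb))
  da <- Mod(fa)^2
  db <- Mod(fb)^2
  rmax <- floor(n / 2)
  # angle folded to [0, pi): opposite sectors are Hermitian pairs
  ang <- atan2(ri$ky, ri$kx) %% pi
  sector <- pmin(floor(ang / sector_extent), ns - 1)
  freq <- (1:rmax) / (n * pixel_size)
  out <- vector("list", ns)
  for (s in seq_len(ns) - 1L) {
    mask <- sector == s
    s_num <- tapply_ring_mask(num, ri$r, rmax, mask)
    s_da <- tapply_ring_mask(da, ri$r, rmax, mask)
    s_db <- tapply_ring_mask(db, ri$r, rmax, mask)
    curve <- s_num / sqrt(pmax(s_da * s_db, .Machine$double.xmin))
    res <- crossing_resolution(freq, curve, threshold)
    out[[s + 1]] <- structure(
      data.frame(freq = freq, frc = curve,
                 num = s_num, den_a = s_da, den_b = s_db),
      resolution = res, threshold = threshold,
      angle = (s + 0.5) * sector_extent,
      class = c("frc_curve", "data.frame"))
  }
  resv <- vapply(out, function(c) attr(c, "resolution"), numeric(1))
  structure(out, best = suppressWarnings(min(resv, na.rm = TRUE)),
            worst = if (any(is.na(resv))) NA_real_ else max(resv),
            class = "sectorial_frc")
}

tapply_ring_mask <- function(values, r, rmax, mask) {
  out <- numeric(rmax)
  sel <- r >= 1 & r <= rmax & mask
  if (any(sel)) {
    agg <- tapply(values[sel], r[sel], sum)
    out[as.integer(names(agg))] <- agg
  }
  out
}

#' Jackknife SNR map
#'
#' Leave-one-frame-out resampling: the reconstruction is repeated on the N
#' data sets that each omit one camera frame, the per-pixel jackknife
#' variance is `(N-1)/N sum (theta_i - mean theta_i)^2`, and
#' `SNR_dB = 10 log10(|theta_full| / sqrt(var))`. For additive
#' reconstructors (per-frame contributions combined by sum or mean, e.g.
#' localization histograms or mean images) the leave-one-out estimates are
#' obtained algebraically; otherwise every reconstruction is recomputed via
#' `reconstructor` (brute force; small N only).
#'
#' @param x Either a 3D array of per-frame contributions `(ny, nx, N)`
#'   (additive path) or an [image_stack()] (with `reconstructor`).
#' @param statistic For the additive path: `"sum"` or `"mean"`.
#' @param reconstructor Function mapping a frames array `(ny, nx, m)` to a
#'   reconstruction matrix (brute-force path).
#' @param cap_db SNR value reported where the jackknife variance is zero.
#' @return An `snr_map`: list with `snr_db` matrix, `theta` (full
#'   reconstruction), `var` (jackknife variance), `n` frames used.
#' @export
jackknife_snr <- function(x, statistic = c("sum", "mean"),
                          reconstructor = NULL, cap_db = 99) {
  statistic <- match.arg(statistic)
  if (inherits(x, "image_stack")) {
    if (is.null(reconstructor)) stop("need a reconstructor for a raw stack")
    arr <- x$frames
    N <- dim(arr)[3]
    if (N < 2) stop("need at least 2 frames")
    theta <- reconstructor(arr)
    th_i <- array(0, dim = c(dim(theta), N))
    for (i in seq_len(N)) {
      th_i[, , i] <- reconstructor(arr[, , -i, drop = FALSE])
    }
    mbar <- apply(th_i, c(1, 2), mean)
    v <- apply(th_i, c(1, 2), function(z) sum((z - mean(z))^2)) * (N - 1) / N
  } else {
    stopifnot(is.array(x), length(dim(x)) == 3)
    N <- dim(x)[3]
    if (N < 2) stop("need at least 2 frames")
    S <- rowSums(x, dims = 2)
    S2 <- rowSums(x^2, dims = 2)
    css <- S2 - S^2 / N                 # sum (c_i - cbar)^2
    if (statistic == "sum") {
      theta <- S
      v <- (N - 1) / N * css
    } else {
      theta <- S / N
      v <- css / (N * (N - 1))
    }
  }
  snr <- ifelse(v > 0, 10 * log10(abs(theta) / sqrt(v)), cap_db)
  snr <- pmin(snr, cap_db)
  structure(list(snr_db = snr, theta = theta, var = v, n = N),
            class = "snr_map")
}

#' Jackknife SNR of an order-2 SOFI reconstruction
#'
#' Algebraic leave-one-frame-out jackknife of the order-2 cross-cumulant
#' image (the moment sums permit exact O(N) updates), optionally binned
#' back to the raw pixel grid for comparison with PALM histograms.
#'
#' @param stack An [image_stack()].
#' @param optics An [optical_config()].
#' @param bin_to_raw Bin the 2x virtual grid back to raw pixels (2x2 sums).
#' @param cap_db Cap for zero-variance pixels.
#' @return An `snr_map`.
#' @export
jackknife_snr_sofi2 <- function(stack, optics, bin_to_raw = TRUE,
                                cap_db = 99) {
  d <- dim(stack$frames)
  jk <- cpp_sofi2_jackknife(stack$frames, d[1], d[2], d[3],
                            effective_sigma_px(optics))
  theta <- jk$image
  v <- jk$var
  if (bin_to_raw) {
    theta <- bin2 (theta)
    v <- bin2(v)  # variance of the sum approximated by summed variances
  }
  snr <- ifelse(v > 0, 10 * log10(abs(theta) / sqrt(v)), cap_db)
  snr <- pmin(snr, cap_db)
  structure(list(snr_db = snr, theta = theta, var = v, n = d[3]),
            class = "snr_map")
}

bin2 <- function(m) {
  ny <- floor(nrow(m) / 2) * 2
  nx <- floor(ncol(m) / 2) * 2
  m <- m[1:ny, 1:nx]
  m[seq(1, ny, 2), seq(1, nx, 2)] + m[seq(2, ny, 2), seq(1, nx, 2)] +
    m[seq(1, ny, 2), seq(2, nx, 2)] + m[seq(2, ny, 2), seq(2, nx, 2)]
}

#' MTF curve of a bar-target reconstruction
#'
#' Average line profile across the bar rows, modulus of its discrete
#' Fourier transform, smoothed by a 3-point moving average. Bar modulation
#' produces a line spectrum, whereas the stochastic sampling floor of a
#' localization histogram (and its elevation at mid frequencies caused by
#' repeat-localization clusters) is smooth in frequency; a running-median
#' background is therefore subtracted so that only sharp modulation peaks
#' remain. The residual is rescaled so that its noise ceiling (median plus
#' three robust standard deviations) sits at 0.5; the subsequent
#' subtraction of the constant 0.5 in [mtf_cutoff()] then removes values
#' caused mostly by noise, keeping only frequencies with genuine
#' modulation.
#'
#' @param image Reconstruction of the bar target (bars along rows'
#'   direction y; profile taken along x).
#' @param pixel_size Pixel size of the image in nm.
#' @param rows Optional row range (y) over which to average the profile.
#' @param notch_period Optional period (nm): frequency bins within 2 bins
#'   of harmonics of `1/notch_period` are replaced by the local median.
#'   Cross-cumulant images carry small gain residues periodic with the raw
#'   pixel, which would otherwise masquerade as signal at harmonics of the
#'   raw-pixel frequency.
#' @return An `mtf_curve`: data frame `freq` (1/nm, excluding DC), `mag`
#'   (noise-floor-normalized magnitude).
#' @export
mtf_curve <- function(image, pixel_size, rows = NULL, notch_period = NULL) {
  stopifnot(is.matrix(image))
  if (!is.null(rows)) image <- image[rows, , drop = FALSE]
  profile <- colMeans(image)
  profile <- profile - mean(profile)
  m <- Mod(stats::fft(profile))
  nf <- length(profile)
  half <- 2:(floor(nf / 2) + 1)            # positive frequencies
  mag <- m[half]
  freq <- (half - 1) / (nf * pixel_size)
  if (!is.null(notch_period)) {
    df <- freq[1]
    harm <- seq(1 / notch_period, max(freq) + df, by = 1 / notch_period)
    bad <- which(vapply(freq, function(f)
      any(abs(f - harm) < 2.5 * df), logical(1)))
    for (b in bad) {
      nb <- setdiff(max(1, b - 5):min(length(mag), b + 5), bad)
      if (length(nb) > 0) mag[b] <- stats::median(mag[nb])
    }
  }
  # subtract the smooth spectral background (sampling floor)
  k <- min(17L, 2L * (length(mag) %/% 4L) + 1L)
  if (k >= 3) mag <- mag - stats::runmed(mag, k)
  raw <- mag
  mag <- stats::filter(mag, rep(1 / 3, 3), sides = 2)
  mag[is.na(mag)] <- raw[is.na(mag)]       # endpoints: unsmoothed
  med <- stats::median(mag)
  nu <- med + 3 * stats::median(abs(mag - med))
  if (nu > 0) mag <- mag * (0.5 / nu)
  structure(data.frame(freq = freq, mag = as.numeric(mag)),
            pixel_size = pixel_size,
            class = c("mtf_curve", "data.frame"))
}

#' Widefield MTF threshold
#'
#' The cutoff detection threshold is the value of the widefield MTF at the
#' theoretical Abbe cutoff `2NA/lambda`, relative to its maximum: a small
#' positive constant close to zero. The widefield curve is taken from a
#' noiseless diffraction-limited rendering of the same target (no noise
#' floor rescaling).
#'
#' @param wf_image Noiseless widefield image of the bar target (e.g.
#'   [widefield_reference()] on a grid finer than half the Abbe period).
#' @param pixel_size Pixel size of `wf_image` in nm.
#' @param optics An [optical_config()].
#' @return Scalar threshold.
#' @export
mtf_threshold_widefield <- function(wf_image, pixel_size, optics) {
  if (is.list(wf_image) && inherits(wf_image, "image_stack")) {
    pixel_size <- wf_image$pixel_size
    wf_image <- wf_image$frames[, , 1]
  }
  profile <- colMeans(wf_image)
  profile <- profile - mean(profile)
  m <- Mod(stats::fft(profile))
  nf <- length(profile)
  half <- 2:(floor(nf / 2) + 1)
  mag <- m[half]
  mag <- stats::filter(mag, rep(1 / 3, 3), sides = 2)
  mag[is.na(mag)] <- m[half][is.na(mag)]
  freq <- (half - 1) / (nf * pixel_size)
  fc <- abbe_cutoff(optics)
  if (fc > max(freq)) stop("widefield grid too coarse to reach the Abbe cutoff")
  val <- stats::approx(freq, mag, xout = fc)$y
  max(val / max(mag), 1e-6)
}

#' Cutoff frequency from normalized MTF curves
#'
#' Subtracts the constant 0.5 from the (noise-floor-normalized) curve,
#' clips at zero, divides by the identically processed reference curve (the
#' maximal-frame-count reconstruction of the same pipeline), and reports
#' the first frequency at which the normalized curve falls below the
#' threshold derived from the widefield MTF. Frequencies where the
#' reference itself carries no signal are skipped; if the curve never falls
#' below the threshold on the supported range, the edge of the reference
#' support is returned.
#'
#' @param curve An [mtf_curve()] of the reconstruction under test.
#' @param reference An [mtf_curve()] of the reference reconstruction.
#' @param threshold Threshold from [mtf_threshold_widefield()].
#' @return List with `cutoff` (1/nm), `freq`, `ratio` (the normalized
#'   curve, `NA` off the reference support).
#' @export
mtf_cutoff <- function(curve, reference, threshold) {
  s_t <- pmax(curve$mag - 0.5, 0)
  if (!isTRUE(all.equal(curve$freq, reference$freq))) {
    s_r0 <- pmax(reference$mag - 0.5, 0)
    s_r <- stats::approx(reference$freq, s_r0, xout = curve$freq,
                         rule = 2)$y
  } else {
    s_r <- pmax(reference$mag - 0.5, 0)
  }
  sup0 <- s_r > 0
  # isolated single-bin exceedances are noise: genuine smoothed peaks
  # span at least two adjacent bins
  nbs <- length(sup0)
  supported <- sup0 & (c(sup0[-1], FALSE) | c(FALSE, sup0[-nbs]))
  if (!any(supported)) stop("reference MTF carries no signal above the noise floor")
  # modulation peaks are a few bins wide; tolerate one-to-two-bin flank
  # misalignment between test and reference by taking a local maximum
  nb <- length(s_t)
  s_t_win <- vapply(seq_len(nb), function(b)
    max(s_t[max(1, b - 2):min(nb, b + 2)]), numeric(1))
  ratio <- ifelse(supported, s_t_win / ifelse(supported, s_r, 1), NA_real_)
  idx <- which(supported)
  below <- idx[ratio[idx] < threshold]
  cutoff <- if (length(below) > 0) curve$freq[below[1]] else
    curve$freq[max(idx)]
  list(cutoff = cutoff, freq = curve$freq, ratio = ratio,
       threshold = threshold)
}


#' Bar-group modulation amplitudes of a test-target reconstruction
#'
#' For every bar-width group of the target, the average line profile is
#' computed over the columns spanning that group (plus one bar width of
#' margin) and the rows covering the bar interiors, and the modulus of its
#' discrete Fourier component at the group frequency `1/(2 w)` is taken.
#' The rows are split into blocks and the complex component is averaged
#' over blocks, giving a standard error that reflects the stochastic
#' emitter sampling: a sparse reconstruction shows no statistically
#' significant modulation even where a mask-based contrast would.
#'
#' @param image Reconstruction of the bar target.
#' @param pixel_size Pixel size of `image` in nm.
#' @param bars Bar table from `attr(make_bar_target(...), "bars")`.
#' @param inset_y Rows this far (nm) from the bar ends are excluded.
#' @param n_blocks Row blocks for the standard error.
#' @return Data frame with `width` (nm), `freq` (1/nm), `amp` (modulation
#'   amplitude) and `se` (its standard error).
#' @export
bar_modulation <- function(image, pixel_size, bars, inset_y = 300,
                           n_blocks = 8) {
  stopifnot(is.matrix(image), nrow(bars) >= 1)
  widths <- unique(bars$width)
  ny <- nrow(image)
  yc <- (seq_len(ny) - 0.5) * pixel_size
  xc <- (seq_len(ncol(image)) - 0.5) * pixel_size
  rows <- which(yc >= min(bars$y0) + inset_y & yc <= max(bars$y1) - inset_y)
  blocks <- split(rows, cut(seq_along(rows), n_blocks, labels = FALSE))
  out <- lapply(widths, function(w) {
    g <- bars[bars$width == w, , drop = FALSE]
    cols <- which(xc >= min(g$x0) - 2 * w & xc <= max(g$x1) + 2 * w)
    f <- 1 / (2 * w)
    period_px <- max(1L, round(2 * w / pixel_size))
    if (length(cols) < period_px + 4 || 2 * pixel_size > 1 / f) {
      return(data.frame(width = w, freq = f, amp = NA_real_, se = NA_real_))
    }
    # resample the profile so that one bar period is an integer number of
    # samples: subtracting a boxcar of exactly one period then nulls the
    # smooth group envelope (whose spectral leakage would otherwise
    # register as modulation) while fully retaining the bar component
    m_per <- max(3L, as.integer(ceiling(2 * w / pixel_size)))
    dx2 <- 2 * w / m_per
    xs2 <- seq(min(xc[cols]), max(xc[cols]), by = dx2)
    phase <- exp(-2i * pi * f * xs2)
    z <- vapply(blocks, function(br) {
      prof <- colMeans(image[br, cols, drop = FALSE])
      prof2 <- stats::approx(xc[cols], prof, xout = xs2, rule = 2)$y
      env <- stats::filter(prof2, rep(1 / m_per, m_per), sides = 2)
      resid <- prof2 - env
      resid[is.na(resid)] <- 0
      sum(resid * phase) * dx2 / pixel_size
    }, complex(1))
    zm <- mean(z)
    se <- sqrt((stats::var(Re(z)) + stats::var(Im(z))) / length(z))
    data.frame(width = w, freq = f, amp = Mod(zm), se = se)
  })
  do.call(rbind, out)
}

#' Cutoff frequency from bar-group modulations
#'
#' A bar group counts as resolved when its modulation amplitude is
#' significant (at least `min_significance` standard errors) and reaches
#' the threshold fraction of the reference reconstruction's amplitude for
#' the same group. The cutoff is the frequency of the last group of the
#' initial resolved run (0 when even the widest group is unresolved).
#'
#' @param modul Bar modulations of the reconstruction under test
#'   ([bar_modulation()]).
#' @param reference Bar modulations of the maximal-frame-count reference.
#' @param threshold Threshold from the widefield modulation at the Abbe
#'   frequency (see [mtf_threshold_widefield()] for the DFT-curve analog).
#' @param min_significance Required significance of the modulation.
#' @return List with `cutoff` (1/nm), `freq`, `ratio`, `resolved`.
#' @export
bar_cutoff <- function(modul, reference, threshold, min_significance = 3) {
  o <- order(modul$freq)
  m <- modul[o, ]
  r <- reference[match(m$width, reference$width), ]
  ratio <- m$amp / pmax(r$amp, .Machine$double.xmin)
  resolved <- is.finite(m$amp) & is.finite(r$amp) & r$amp > 0 &
    m$amp >= min_significance * m$se & ratio >= threshold
  last <- if (!isTRUE(resolved[1])) 0L else max(which(cumsum(!resolved) == 0))
  list(cutoff = if (last == 0L) 0 else m$freq[last], freq = m$freq,
       ratio = ratio, resolved = resolved, threshold = threshold)
}

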