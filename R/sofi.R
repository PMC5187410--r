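#' Split a stack into fixed-length subsequences
#'
#' The cumulant analysis operates on short subsequences (default 500
#' frames) so that photobleaching within a subsequence is negligible.
#' Remainder frames beyond the last full subsequence are dropped.
#'
#' @param stack An [image_stack()] (or an integer frame count, in which
#'   case the index ranges are returned).
#' @param length Subsequence length in frames.
#' @return A list of [image_stack()] objects (or of integer index vectors
#'   when `stack` is a count).
#' @export
split_subsequences <- function(stack, length = 500) {
  stopifnot(length >= 1)
  if (is.numeric(stack) && base::length(stack) == 1L) {
    total <- as.integer(stack)
    if (total < length) stop("stack shorter than one subsequence")
    k <- floor(total / length)
    return(lapply(seq_len(k), function(s) ((s - 1) * length + 1):(s * length)))
  }
  stopifnot(inherits(stack, "image_stack"))
  total <- n_frames(stack)
  if (total < length) stop("stack shorter than one subsequence")
  k <- floor(total / length)
  lapply(seq_len(k), function(s) {
    idx <- ((s - 1) * length + 1):(s * length)
    image_stack(stack$frames[, , idx, drop = FALSE], stack$pixel_size,
                stack$frame_interval)
  })
}

#' Effective PSF sigma on the raw pixel grid
#'
#' Camera pixels integrate the PSF over their area; for cumulant amplitude
#' factors the pixel-integrated Gaussian is approximated by a Gaussian with
#' variance `sigma^2 + p^2 / 12`.
#'
#' @param optics An [optical_config()].
#' @return Effective sigma in raw pixel units.
#' @export
effective_sigma_px <- function(optics) {
  sqrt(optics$psf_sigma^2 + optics$pixel_size^2 / 12) / optics$pixel_size
}

#' Cross-cumulant image of one subsequence
#'
#' Computes the order-n joint cumulant (zero time lag) of n mean-subtracted
#' pixel traces for every virtual pixel of an n-times finer grid. For the
#' virtual pixel at sub-position (a/n, b/n) the n distinct raw pixels
#' closest together whose centroid is the virtual position are used, and
#' the result is divided by the Gaussian distance factor
#' `exp(-sum_pairs d^2 / (2 n sigma_eff^2))` that attenuates cross-cumulants
#' of separated pixels. Distinct pixels make the estimator immune to
#' pixel-wise shot and read noise, which are uncorrelated between pixels.
#'
#' @param sub An [image_stack()] (one subsequence).
#' @param order Cumulant order, 2..6.
#' @param optics An [optical_config()] (for the PSF-derived distance
#'   factor).
#' @return A `cumulant_image`: numeric matrix on the n-times finer grid
#'   (zero in a 2-raw-pixel border), with attributes `order`, `pixel_size`
#'   (virtual, nm), `n_frames`, `mean_intensity` (mean count over the
#'   subsequence).
#' @export
cumulant_images <- function(sub, order, optics) {
  stopifnot(inherits(sub, "image_stack"))
  if (!(order %in% 2:6)) stop("cumulant order must be in 2..6")
  d <- dim(sub$frames)
  img <- cpp_cumulant_image(sub$frames, d[1], d[2], d[3], as.integer(order),
                            effective_sigma_px(optics))
  structure(img, order = as.integer(order),
            pixel_size = sub$pixel_size / order,
            n_frames = d[3],
            mean_intensity = mean(sub$frames),
            class = c("cumulant_image", "matrix", "array"))
}

#' Average cumulant images over subsequences
#'
#' Pixel-wise mean over subsequence cumulant images of equal order and
#' shape. With `bleaching_correction = TRUE` each image is rescaled by
#' `(I_ref / I_k)^n` before averaging, where `I_k` is the mean background-
#' subtracted intensity of subsequence k and `I_ref` that of the first
#' subsequence: the order-n cumulant scales with the n-th power of the
#' emitter brightness, so intensity loss through photobleaching between
#' subsequences is compensated. Rescale factors are clipped to [0.2, 5] to
#' avoid amplifying noise from nearly-dark subsequences.
#'
#' @param cums List of `cumulant_image` objects (same order and shape).
#' @param bleaching_correction Apply the intensity rescaling.
#' @param offset Camera offset (counts) subtracted from the recorded mean
#'   intensities before forming rescale ratios.
#' @return A `cumulant_image` (the average).
#' @export
average_subsequence_cumulants <- function(cums, bleaching_correction = FALSE,
                                          offset = 0) {
  if (length(cums) == 0) stop("empty cumulant list")
  ords <- vapply(cums, function(c) attr(c, "order"), integer(1))
  if (length(unique(ords)) != 1) stop("mixed cumulant orders")
  dms <- vapply(cums, function(c) paste(dim(c), collapse = "x"), "")
  if (length(unique(dms)) != 1) stop("shape mismatch between cumulant images")
  n <- ords[1]
  acc <- matrix(0, nrow(cums[[1]]), ncol(cums[[1]]))
  iref <- max(attr(cums[[1]], "mean_intensity") - offset, 1e-12)
  for (c in cums) {
    w <- 1
    if (bleaching_correction) {
      ik <- max(attr(c, "mean_intensity") - offset, 1e-12)
      w <- min(max((iref / ik)^n, 0.2), 5)
    }
    acc <- acc + w * unclass(c)
  }
  out <- acc / length(cums)
  structure(out, order = n, pixel_size = attr(cums[[1]], "pixel_size"),
            n_frames = sum(vapply(cums, function(c) attr(c, "n_frames"),
                                  integer(1))),
            mean_intensity = attr(cums[[1]], "mean_intensity"),
            class = c("cumulant_image", "matrix", "array"))
}

#' Linearize a cumulant image
#'
#' The order-n cumulant responds to the n-th power of the molecular
#' brightness, which compresses the dynamic range. `standard` mode takes
#' the signed n-th root, `sign(k) |k|^(1/n)`. `adaptive` mode first
#' normalizes |k| by the local brightness-and-blinking amplitude
#' `|eps^n f_n(rho)|` estimated from the molecular-parameter maps, so that
#' structures of equal emitter density map to equal output regardless of
#' the local on-time ratio; it is monotone in |k| at fixed normalization.
#' No PSF deconvolution is applied.
#'
#' @param cum A `cumulant_image` of order n.
#' @param mode `"standard"` or `"adaptive"`.
#' @param maps A `molecular_maps` object (required for `adaptive`),
#'   resampled internally to the cumulant grid.
#' @param floor Relative floor for the adaptive normalization amplitude.
#' @return Numeric matrix (linearized image).
#' @export
linearize <- function(cum, mode = c("standard", "adaptive"), maps = NULL,
                      floor = 1e-3) {
  mode <- match.arg(mode)
  n <- attr(cum, "order")
  if (is.null(n) || n < 2) stop("need a cumulant image of order >= 2")
  k <- unclass(cum)
  if (mode == "standard") {
    return(sign(k) * abs(k)^(1 / n))
  }
  if (is.null(maps)) stop("adaptive linearization needs molecular maps")
  rho <- resample_bilinear(maps$on_time_ratio, dim(k))
  eps <- resample_bilinear(maps$brightness_counts, dim(k))
  rho[!is.finite(rho)] <- 0.5
  eps[!is.finite(eps)] <- 0
  amp <- abs(eps)^n * abs(fn_blink(rho, n))
  amp <- pmax(amp, floor * max(amp, na.rm = TRUE))
  (abs(k) / amp)^(1 / n)
}

# blinking polynomial f_n(rho): cumulant of a Bernoulli(rho) variable,
# divided by the brightness power (f2 = rho(1-rho), f3 = rho(1-rho)(1-2rho),
# f4 = rho(1-rho)(1-6rho+6rho^2), ...)
fn_blink <- function(rho, n) {
  switch(as.character(n),
         "2" = rho * (1 - rho),
         "3" = rho * (1 - rho) * (1 - 2 * rho),
         "4" = rho * (1 - rho) * (1 - 6 * rho + 6 * rho^2),
         "5" = rho * (1 - rho) * (1 - 2 * rho) * (1 - 12 * rho + 12 * rho^2),
         "6" = rho * (1 - rho) *
           (1 - 30 * rho + 150 * rho^2 - 240 * rho^3 + 120 * rho^4),
         stop("unsupported order"))
}

resample_bilinear <- function(img, dims) {
  ny <- dims[1]; nx <- dims[2]
  sy <- nrow(img); sx <- ncol(img)
  # map output pixel centres onto input pixel-centre coordinates
  yc <- (seq_len(ny) - 0.5) * sy / ny + 0.5 - 0.5
  xc <- (seq_len(nx) - 0.5) * sx / nx + 0.5 - 0.5
  y0 <- pmin(pmax(floor(yc), 1), sy - 1)
  x0 <- pmin(pmax(floor(xc), 1), sx - 1)
  wy <- pmin(pmax(yc - y0, 0), 1)
  wx <- pmin(pmax(xc - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE]
  b <- img[y0 + 1, x0, drop = FALSE]
  cc <- img[y0, x0 + 1, drop = FALSE]
  d <- img[y0 + 1, x0 + 1, drop = FALSE]
  (1 - wy) %o% (1 - wx) * a + wy %o% (1 - wx) * b +
    (1 - wy) %o% wx * cc + wy %o% wx * d
}

#' Molecular-parameter maps from cumulant orders 2-4
#'
#' For a region of emitters with on-time ratio rho, brightness eps
#' (photo-electrons per frame while on) and area density N, the order-n
#' cumulant image is `kappa_n = N eps^n f_n(rho) V_n`, with blinking
#' polynomials `f_2 = rho(1-rho)`, `f_3 = rho(1-rho)(1-2rho)`,
#' `f_4 = rho(1-rho)(1-6rho+6rho^2)` and PSF-volume factors
#' `V_n = A^n (2 pi sigma_eff^2)^(1-n) / n` (A = raw pixel area,
#' sigma_eff the pixel-integration-corrected PSF sigma). The cumulant
#' ratios `r_3 = kappa_3/kappa_2` and `r_4 = kappa_4/kappa_2` are solved
#' pixel-wise for rho (quadratic root inside (0,1), sign fixed by r_3),
#' then eps, then the density `N = kappa_2 / (eps^2 f_2(rho) V_2)`.
#'
#' Pixels whose |kappa_2| falls below `mask_threshold` times the maximum,
#' or with non-physical roots, are marked invalid.
#'
#' @param cum2,cum3,cum4 `cumulant_image` objects of orders 2, 3, 4 from
#'   the same data (any grid; all are resampled to the order-2 grid).
#' @param optics An [optical_config()].
#' @param camera A [camera_config()] (gain and QE convert count-based
#'   brightness to photons).
#' @param mask_threshold Fraction of max |kappa_2| below which pixels are
#'   background.
#' @return A `molecular_maps` object: list of matrices `on_time_ratio`,
#'   `brightness` (photons/frame), `brightness_counts` (camera counts),
#'   `density` (emitters/um^2) and logical `valid`.
#' @export
estimate_molecular_maps <- function(cum2, cum3, cum4, optics, camera,
                                    mask_threshold = 0.05) {
  stopifnot(attr(cum2, "order") == 2, attr(cum3, "order") == 3,
            attr(cum4, "order") == 4)
  dims <- dim(cum2)
  k2 <- unclass(cum2)
  k3 <- resample_bilinear(unclass(cum3), dims)
  k4 <- resample_bilinear(unclass(cum4), dims)
  p <- optics$pixel_size
  sig_eff <- effective_sigma_px(optics) * p          # nm
  beta <- p^2 / (2 * pi * sig_eff^2)                 # A / (2 pi sigma^2)
  v2 <- p^2 * beta / 2                               # V_2 in nm^2
  valid <- abs(k2) >= mask_threshold * max(abs(k2)) & k2 > 0
  r3 <- ifelse(valid, k3 / k2, NA_real_)
  r4 <- ifelse(valid, k4 / k2, NA_real_)
  # undo the PSF-volume ratios: u = eps_counts * beta
  u13 <- r3 * 3 / 2                                  # = u (1 - 2 rho)
  u24 <- r4 * 2                                      # = u^2 (1-6rho+6rho^2)
  q <- u24 / u13^2
  a <- 6 - 4 * q
  disc <- 1 - 4 * (1 - q) / a
  ok <- valid & is.finite(disc) & disc >= 0 & is.finite(a) & abs(a) > 1e-12
  root <- sqrt(pmax(disc, 0)) / 2
  rho <- ifelse(u13 >= 0, 0.5 - root, 0.5 + root)
  ok <- ok & is.finite(rho) & rho > 0 & rho < 1
  u <- ifelse(abs(1 - 2 * rho) > 1e-6, u13 / (1 - 2 * rho),
              sqrt(pmax(u24 / (1 - 6 * rho + 6 * rho^2), 0)))
  ok <- ok & is.finite(u) & u > 0
  eps_counts <- u / beta
  dens <- k2 / (eps_counts^2 * rho * (1 - rho) * v2)  # per nm^2
  ok <- ok & is.finite(dens) & dens >= 0
  rho[!ok] <- NA_real_
  eps_counts[!ok] <- NA_real_
  dens[!ok] <- NA_real_
  structure(list(on_time_ratio = rho,
                 brightness_counts = eps_counts,
                 brightness = eps_counts / (camera$em_gain *
                                            camera$quantum_efficiency),
                 density = dens * 1e6,               # per um^2
                 valid = ok,
                 pixel_size = attr(cum2, "pixel_size")),
            class = "molecular_maps")
}

#' @export
print.molecular_maps <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf("Molecular maps: %d x %d px, %d valid\n", nrow(x$valid),
              ncol(x$valid), nv))
  if (nv > 0) {
    cat(sprintf("  median rho    : %.3f\n",
                stats::median(x$on_time_ratio[x$valid])))
    cat(sprintf("  median density: %.1f /um^2\n",
                stats::median(x$density[x$valid])))
  }
  invisible(x)
}

#' SOFI pipeline: averaged cumulant image of a stack
#'
#' Splits the stack into subsequences, computes the order-n cross-cumulant
#' image of each and averages them (optionally with bleaching correction).
#'
#' @param stack An [image_stack()].
#' @param order Cumulant order 2..6.
#' @param optics An [optical_config()].
#' @param sub_length Subsequence length (default 500 frames).
#' @param bleaching_correction See [average_subsequence_cumulants()].
#' @param offset Camera offset for the bleaching correction.
#' @return A `cumulant_image`.
#' @export
sofi_analyze <- function(stack, order, optics, sub_length = 500,
                         bleaching_correction = TRUE, offset = 0) {
  subs <- split_subsequences(stack, sub_length)
  cums <- lapply(subs, cumulant_images, order = order, optics = optics)
  average_subsequence_cumulants(cums, bleaching_correction, offset)
}

#' PALM-based molecular density
#'
#' Density of molecules from a blink-merged localization table: merged
#' count divided by area.
#'
#' @param merged A [merge_blinks()] result, or a localization table already
#'   reduced to one record per molecule.
#' @param area_um2 Region area in um^2 (> 0).
#' @return Density in molecules per um^2.
#' @export
density_estimate_palm <- function(merged, area_um2) {
  if (area_um2 <= 0) stop("area must be > 0")
  n <- if (inherits(merged, "merge_result")) merged$n else nrow(merged)
  n / area_um2
}

#' Flatten the sub-offset mosaic of a cumulant image
#'
#' Cross-cumulant virtual pixels at different sub-offsets use different
#' raw-pixel combinations; imperfections of the Gaussian distance-factor
#' model and unequal estimator variance leave small multiplicative gain
#' differences with the periodicity of the raw pixel, which show up as
#' spurious spectral lines at harmonics of the raw-pixel frequency. This
#' equalizes the mean absolute amplitude of the n x n sub-offset classes
#' (computed over the interior of the image), the standard flat-fielding
#' step of cross-cumulant processing.
#'
#' @param image Numeric matrix on the n-times virtual grid (a cumulant
#'   image or its linearization).
#' @param order The cumulant order n that produced the grid.
#' @return The flattened matrix.
#' @export
flatten_mosaic <- function(image, order) {
  n <- as.integer(order)
  if (n <= 1) return(image)
  ny <- nrow(image); nx <- ncol(image)
  ri <- ((seq_len(ny) - 1L) %% n)
  ci <- ((seq_len(nx) - 1L) %% n)
  interior_r <- seq(2 * n + 1, ny - 2 * n)
  interior_c <- seq(2 * n + 1, nx - 2 * n)
  sub <- abs(image[interior_r, interior_c])
  cls_r <- ri[interior_r]
  cls_c <- ci[interior_c]
  gains <- matrix(1, n, n)
  for (a in 0:(n - 1)) for (b in 0:(n - 1)) {
    v <- sub[cls_r == a, cls_c == b]
    gains[a + 1, b + 1] <- mean(v)
  }
  gains <- gains / mean(gains)
  gains[gains <= 0 | !is.finite(gains)] <- 1
  image / gains[cbind(ri + 1L, rep(ci + 1L, each = ny))]
}
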