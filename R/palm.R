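#' Detection parameters
#'
#' @param intensity_threshold_factor Peaks must exceed this multiple of the
#'   local background estimate (default 4).
#' @param min_precision,max_precision Precision window in nm used when
#'   rendering (defaults 1 and 50).
#' @param max_iter,tol Optimizer settings of the maximum-likelihood fit
#'   (iteration cap and position convergence tolerance in pixels).
#' @param min_significance Accepted localizations must have a fitted photon
#'   count of at least this many standard deviations (from the Fisher
#'   information of the fit); rejects fits indistinguishable from
#'   background fluctuations.
#' @return A `detection_params` object.
#' @export
detection_params <- function(intensity_threshold_factor = 4,
                             min_precision = 1, max_precision = 50,
                             max_iter = 50, tol = 1e-4,
                             min_significance = 4) {
  stopifnot(intensity_threshold_factor > 0,
            min_precision < max_precision, min_precision > 0,
            min_significance >= 0)
  structure(list(intensity_threshold_factor = intensity_threshold_factor,
                 min_precision = min_precision,
                 max_precision = max_precision,
                 max_iter = as.integer(max_iter), tol = tol,
                 min_significance = min_significance),
            class = "detection_params")
}

fit_halfwin <- function(optics) {
  max(2L, as.integer(ceiling(3 * optics$psf_sigma / optics$pixel_size)))
}

#' Detect candidate peaks in one frame
#'
#' The frame is band-pass filtered with a difference of Gaussians
#' (sigma1 = PSF sigma, sigma2 = 2 sigma1); local maxima whose estimated
#' spot amplitude reaches `intensity_threshold_factor` times the local
#' background (median of the low-pass component in a 9x9 neighbourhood, or
#' the robust noise floor, whichever is larger) are kept. Duplicates within
#' one PSF radius are suppressed.
#'
#' @param frame Numeric matrix of camera counts.
#' @param optics An [optical_config()].
#' @param camera A [camera_config()].
#' @param params A [detection_params()].
#' @return Integer matrix of candidate pixel positions (row, column),
#'   1-based; zero rows when nothing is found.
#' @export
detect_peaks <- function(frame, optics, camera, params = detection_params()) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  pe <- (frame - camera$offset) / camera$em_gain
  cpp_detect_peaks(pe, optics$psf_sigma / optics$pixel_size,
                   params$intensity_threshold_factor, fit_halfwin(optics))
}

#' Maximum-likelihood fit of candidate spots
#'
#' Fits a pixel-integrated 2D Gaussian plus constant background to each
#' candidate by maximizing the Poisson likelihood (Fisher scoring with
#' analytic derivatives). Positions are returned in nm; the reported
#' precision is the Cramer-Rao lower bound of the fit, multiplied by
#' sqrt(2) when the camera uses EM amplification.
#'
#' @param frame Numeric matrix of camera counts.
#' @param candidates Integer matrix (row, column), 1-based, e.g. from
#'   [detect_peaks()]. Candidates closer to the border than the fit window
#'   raise an error.
#' @param optics,camera,params See [detect_peaks()].
#' @return Data frame with `x`, `y` (nm), `photons`, `background`,
#'   `loglik`, `precision` (nm) and `converged`.
#' @export
fit_mle <- function(frame, candidates, optics, camera,
                    params = detection_params()) {
  stopifnot(is.matrix(candidates) || is.vector(candidates))
  if (is.vector(candidates)) candidates <- matrix(candidates, ncol = 2)
  pe <- (frame - camera$offset) / camera$em_gain
  fit <- cpp_fit_candidates(pe, candidates,
                            optics$psf_sigma / optics$pixel_size,
                            fit_halfwin(optics), params$max_iter, params$tol)
  p <- optics$pixel_size
  excess <- if (camera$excess_noise_factor > 1) sqrt(2) else 1
  data.frame(x = fit$x * p, y = fit$y * p, photons = fit$photons,
             background = fit$background, loglik = fit$loglik,
             precision = fit$precision * p * excess,
             converged = fit$converged)
}

#' Localize an entire stack
#'
#' Runs detection and MLE fitting on every frame and returns a
#' [localization_table()]. Non-converged fits are dropped.
#'
#' @param stack An [image_stack()] of camera counts.
#' @param optics An [optical_config()].
#' @param camera A [camera_config()].
#' @param params A [detection_params()].
#' @param frame_offset Added to frame indices in the output (for chunked
#'   processing).
#' @return A [localization_table()] (positions in nm, precision in nm
#'   including the EMCCD sqrt(2) factor).
#' @export
palm_localize <- function(stack, optics, camera, params = detection_params(),
                          frame_offset = 0L) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  res <- cpp_localize_stack(stack$frames, d[1], d[2], d[3],
                            1L + as.integer(frame_offset),
                            optics$psf_sigma / optics$pixel_size,
                            params$intensity_threshold_factor,
                            camera$em_gain, camera$offset,
                            fit_halfwin(optics), params$max_iter, params$tol,
                            params$min_significance)
  p <- optics$pixel_size
  excess <- if (camera$excess_noise_factor > 1) sqrt(2) else 1
  localization_table(frame = res$frame, x = res$x_px * p, y = res$y_px * p,
                     photons = res$photons, background = res$background,
                     precision = res$precision_px * p * excess)
}

#' Theoretical localization precision (CRLB)
#'
#' Cramer-Rao lower bound of the position estimate for the pixel-integrated
#' Gaussian-PSF Poisson model with constant background, evaluated for an
#' emitter at a pixel centre. The bound is multiplied by sqrt(2) when the
#' camera uses EM amplification (excess noise factor > 1).
#'
#' @param photons Expected signal photo-electrons of the spot.
#' @param background Background photo-electrons per pixel.
#' @param optics An [optical_config()].
#' @param camera A [camera_config()].
#' @return Precision (standard deviation) in nm.
#' @export
crlb_precision <- function(photons, background, optics, camera) {
  stopifnot(length(photons) == 1 || length(background) == 1 ||
            length(photons) == length(background))
  if (any(photons <= 0)) stop("photons must be > 0")
  n <- max(length(photons), length(background))
  photons <- rep_len(photons, n)
  background <- rep_len(background, n)
  p <- optics$pixel_size
  s <- optics$psf_sigma / p
  w <- fit_halfwin(optics)
  px <- seq(-w, w)
  vapply(seq_len(n), function(k) {
    # pixel masses for an emitter at the centre of pixel 0 (x0 = 0.5)
    lo <- px
    ex <- stats::pnorm(lo + 1, 0.5, s) - stats::pnorm(lo, 0.5, s)
    dex <- stats::dnorm(lo, 0.5, s) - stats::dnorm(lo + 1, 0.5, s)
    E <- outer(ex, ex)
    dEx <- outer(ex, dex)        # rows: y, cols: x derivative
    dEy <- outer(dex, ex)
    mu <- background[k] + photons[k] * E
    d <- list(x = photons[k] * dEx, y = photons[k] * dEy, N = E,
              b = matrix(1, length(px), length(px)))
    FIM <- matrix(0, 4, 4)
    for (a in 1:4) for (b2 in a:4) {
      FIM[a, b2] <- sum(d[[a]] * d[[b2]] / mu)
      FIM[b2, a] <- FIM[a, b2]
    }
    V <- solve(FIM)
    sqrt(0.5 * (V[1, 1] + V[2, 2])) * p
  }, numeric(1)) * (if (camera$excess_noise_factor > 1) sqrt(2) else 1)
}

#' Drift correction from fiducial tracks
#'
#' Subtracts, per frame, the mean fiducial displacement relative to the
#' first covered frame from every localization. Every frame carrying
#' localizations must have fiducial coverage.
#'
#' @param table A [localization_table()].
#' @param fiducials A [fiducial_track()].
#' @return Drift-corrected [localization_table()] (fiducial records are not
#'   part of the table and so are not returned).
#' @export
correct_drift <- function(table, fiducials) {
  stopifnot(inherits(table, "localization_table"),
            inherits(fiducials, "fiducial_track"))
  if (nrow(table) == 0) return(table)
  mx <- tapply(fiducials$x, fiducials$frame, mean)
  my <- tapply(fiducials$y, fiducials$frame, mean)
  frames <- as.integer(names(mx))
  f0 <- min(frames)
  need <- unique(table$frame)
  missing <- setdiff(need, frames)
  if (length(missing) > 0) {
    stop("no fiducial coverage for frame(s) ", paste(utils::head(missing, 5),
         collapse = ", "))
  }
  dx <- mx[as.character(table$frame)] - mx[as.character(f0)]
  dy <- my[as.character(table$frame)] - my[as.character(f0)]
  out <- table
  out$x <- table$x - as.numeric(dx)
  out$y <- table$y - as.numeric(dy)
  out
}

#' Channel co-registration with a second-order polynomial
#'
#' Fits x' and y' as full second-order polynomials of (x, y) by least
#' squares on matched fiducial pairs (at least 6 non-degenerate pairs) and
#' applies the transform to a localization table.
#'
#' @param reference_pairs Data frame with columns `x`, `y` (source channel)
#'   and `x_ref`, `y_ref` (target channel), in nm.
#' @param table A [localization_table()] in the source channel.
#' @return The transformed table; control-point residuals (nm, per pair)
#'   are attached as attribute `residuals`.
#' @export
coregister <- function(reference_pairs, table) {
  rp <- reference_pairs
  stopifnot(all(c("x", "y", "x_ref", "y_ref") %in% names(rp)))
  if (nrow(rp) < 6) stop("need at least 6 control pairs for a second-order fit")
  basis <- function(x, y) cbind(1, x, y, x^2, x * y, y^2)
  A <- basis(rp$x, rp$y)
  if (qr(A)$rank < 6) stop("degenerate control-point geometry")
  cx <- qr.solve(A, rp$x_ref)
  cy <- qr.solve(A, rp$y_ref)
  res <- sqrt((A %*% cx - rp$x_ref)^2 + (A %*% cy - rp$y_ref)^2)
  out <- table
  B <- basis(table$x, table$y)
  out$x <- as.numeric(B %*% cx)
  out$y <- as.numeric(B %*% cy)
  attr(out, "residuals") <- as.numeric(res)
  out
}

#' Render spec
#'
#' @param mode `"histogram"` (localization counts per output pixel) or
#'   `"probability_map"` (sum of unit-mass Gaussians with the per-record
#'   localization precision as standard deviation).
#' @param pixel_size Output pixel size in nm.
#' @return A `render_spec` object.
#' @export
render_spec <- function(mode = c("histogram", "probability_map"),
                        pixel_size = 17.5) {
  mode <- match.arg(mode)
  stopifnot(pixel_size > 0)
  structure(list(mode = mode, pixel_size = pixel_size), class = "render_spec")
}

#' Render a super-resolved image from localizations
#'
#' Records with precision outside `[min_precision, max_precision]` are
#' excluded.
#'
#' @param table A [localization_table()].
#' @param spec A [render_spec()].
#' @param fov Field of view in nm (square, origin at 0).
#' @param min_precision,max_precision Precision window in nm.
#' @return Numeric matrix (the rendered image).
#' @export
render_palm <- function(table, spec, fov, min_precision = 1,
                        max_precision = 50) {
  stopifnot(inherits(spec, "render_spec"), fov > 0)
  n <- round(fov / spec$pixel_size)
  img <- matrix(0, n, n)
  if (nrow(table) == 0) return(img)
  keep <- table$precision >= min_precision & table$precision <= max_precision
  tb <- table[keep, , drop = FALSE]
  if (nrow(tb) == 0) return(img)
  p <- spec$pixel_size
  if (spec$mode == "histogram") {
    j <- floor(tb$x / p) + 1
    i <- floor(tb$y / p) + 1
    ok <- i >= 1 & i <= n & j >= 1 & j <= n
    for (k in which(ok)) img[i[k], j[k]] <- img[i[k], j[k]] + 1
  } else {
    # probability map: per-record sigma, so render one Gaussian at a time
    for (k in seq_len(nrow(tb))) {
      img <- img + cpp_render_static(matrix(c(tb$x[k], tb$y[k]), 1, 2),
                                     1, n, n, p, tb$precision[k])
    }
  }
  img
}
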