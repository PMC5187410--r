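#' Photokinetic model of a photoactivatable fluorophore
#'
#' Four-state continuous-time Markov scheme: inactive emitters activate
#' irreversibly (`activation_rate`), emitting ("on") emitters blink into a
#' reversible dark state (`k_off`, recovery `k_on`) or photobleach
#' irreversibly (`bleach_rate`, only from the on state). While on, an
#' emitter emits `i_on` photons per frame (scaled by the fraction of the
#' exposure actually spent in the on state).
#'
#' The blinking equilibrium gives the on-time ratio
#' `rho = k_on / (k_on + k_off)`, the stationary fraction of time an
#' activated, unbleached emitter spends emitting.
#'
#' @param activation_rate Activation rate (1/s), inactive to on.
#' @param k_off Blinking off-rate (1/s), on to dark.
#' @param k_on Blinking recovery rate (1/s), dark to on.
#' @param bleach_rate Photobleaching rate (1/s), on to bleached.
#' @param i_on Photons emitted per emitter per frame while on.
#' @param p_preactivated Fraction of emitters starting in the on state.
#' @return A `photokinetics` object.
#' @seealso [kinetic_preset()]
#' @export
photokinetics <- function(activation_rate = 0.0024, k_off = 10, k_on = 4,
                          bleach_rate = 5, i_on = 100, p_preactivated = 0) {
  stopifnot(activation_rate >= 0, k_off >= 0, k_on >= 0, bleach_rate >= 0,
            i_on > 0, p_preactivated >= 0, p_preactivated <= 1)
  rho <- if (k_on + k_off > 0) k_on / (k_on + k_off) else 1
  if (rho <= 0 || rho > 1) stop("implied on-time ratio outside (0, 1]")
  structure(list(activation_rate = activation_rate, k_off = k_off,
                 k_on = k_on, bleach_rate = bleach_rate, i_on = i_on,
                 p_preactivated = p_preactivated),
            class = "photokinetics")
}

#' On-time ratio of a photokinetics model
#' @param kin A [photokinetics()] object.
#' @return The stationary on fraction `k_on / (k_on + k_off)`.
#' @export
on_time_ratio <- function(kin) {
  stopifnot(inherits(kin, "photokinetics"))
  if (kin$k_on + kin$k_off == 0) return(1)
  kin$k_on / (kin$k_on + kin$k_off)
}

#' Named photokinetic presets
#'
#' Two presets emulating the photoactivatable proteins commonly used for
#' focal-adhesion imaging. Both start with a fraction of the pool already
#' activated when recording begins (heavily overlapping single-molecule
#' images during the first tens of frames) followed by a slow activation
#' trickle of the remainder: `"pscfp2"` has the stronger burst (55% of the
#' pool) and the slower trickle, `"meos2"` a weaker burst (45%) and a
#' faster trickle. `"stationary"` is a pre-activated, non-bleaching
#' blinker useful for molecular-parameter benchmarks.
#'
#' @param name One of `"meos2"`, `"pscfp2"`, `"stationary"`.
#' @param i_on Photons per emitter per frame while on.
#' @return A [photokinetics()] object.
#' @export
kinetic_preset <- function(name = c("meos2", "pscfp2", "stationary"),
                           i_on = 100) {
  name <- match.arg(name)
  switch(name,
    meos2 = photokinetics(activation_rate = 0.0032, k_off = 10, k_on = 4,
                          bleach_rate = 5, i_on = i_on,
                          p_preactivated = 0.45),
    pscfp2 = photokinetics(activation_rate = 0.0008, k_off = 12, k_on = 3,
                           bleach_rate = 6, i_on = i_on,
                           p_preactivated = 0.55),
    stationary = photokinetics(activation_rate = 0, k_off = 8, k_on = 4,
                               bleach_rate = 0, i_on = i_on,
                               p_preactivated = 1))
}

#' Simulate per-emitter photon traces
#'
#' Integrates the four-state kinetics in continuous time (exact exponential
#' waiting times) within each frame exposure, so partial-frame on-times are
#' resolved correctly at high switching rates. The expected photon count of
#' emitter e in frame t is `i_on` times the fraction of the exposure spent
#' in the on state.
#'
#' @param n_emitters Number of emitters.
#' @param kinetics A [photokinetics()] object.
#' @param n_frames Number of frames.
#' @param exposure Frame exposure time in seconds.
#' @param seed Optional integer seed (applied with [set.seed()]).
#' @return A data frame with columns `emitter`, `frame` (1-based) and
#'   `photons` (expected photons in that frame); rows only for frames with
#'   nonzero emission. Attributes `n_emitters`, `n_frames`, `exposure`.
#' @export
simulate_traces <- function(n_emitters, kinetics, n_frames, exposure = 0.05,
                            seed = NULL) {
  stopifnot(inherits(kinetics, "photokinetics"), n_frames >= 1,
            n_emitters >= 0, exposure > 0)
  if (!is.null(seed)) set.seed(seed)
  tr <- cpp_simulate_traces(as.integer(n_emitters), as.integer(n_frames),
                            exposure, kinetics$activation_rate,
                            kinetics$k_off, kinetics$k_on,
                            kinetics$bleach_rate, kinetics$i_on,
                            kinetics$p_preactivated)
  attr(tr, "n_emitters") <- as.integer(n_emitters)
  attr(tr, "n_frames") <- as.integer(n_frames)
  attr(tr, "exposure") <- exposure
  tr
}

#' Dense trace matrix
#'
#' Expands the sparse trace representation of [simulate_traces()] into a
#' dense emitters-by-frames matrix of expected photons (small cases only).
#'
#' @param traces Output of [simulate_traces()].
#' @return Numeric matrix `n_emitters x n_frames`.
#' @export
trace_matrix <- function(traces) {
  ne <- attr(traces, "n_emitters")
  nf <- attr(traces, "n_frames")
  m <- matrix(0, ne, nf)
  if (nrow(traces) > 0) m[cbind(traces$emitter, traces$frame)] <- traces$photons
  m
}

#' Emitter set
#'
#' Ground-truth emitter positions plus their photon traces.
#'
#' @param positions Two-column matrix of (x, y) positions in nm.
#' @param traces Sparse traces from [simulate_traces()] (may be `NULL` until
#'   assigned).
#' @param density Nominal emitter density in 1/um^2 (bookkeeping).
#' @param support_area Area of the support region in um^2.
#' @return An `emitter_set` object.
#' @export
emitter_set <- function(positions, traces = NULL, density = NA_real_,
                        support_area = NA_real_) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2)
  structure(list(positions = positions, traces = traces, density = density,
                 support_area = support_area),
            class = "emitter_set")
}

#' @export
print.emitter_set <- function(x, ...) {
  cat(sprintf("Emitter set: %d emitters", nrow(x$positions)))
  if (is.finite(x$density)) cat(sprintf(" (%g / um^2)", x$density))
  cat(if (is.null(x$traces)) ", no traces\n" else ", traces attached\n")
  invisible(x)
}

#' Bar test target
#'
#' A resolution test target of progressively thinner vertical bar pairs,
#' randomly filled with point emitters at a given density. Bars run along y;
#' for each width `w` two bars at pitch `2 w` are placed, groups separated
#' by `group_gap`, widths strictly decreasing left to right. The realized
#' emitter count is `round(density * total bar area)`.
#'
#' @param density Emitter density in 1/um^2.
#' @param widths Bar widths in nm, strictly decreasing.
#' @param bar_length Bar length (y extent) in nm.
#' @param n_bars Bars per width group.
#' @param group_gap Gap between width groups in nm.
#' @param fov Field of view (square side) in nm.
#' @param margin Offset of the first bar group from the left/top in nm
#'   (defaults centre the pattern).
#' @param seed Optional integer seed.
#' @return An [emitter_set()] with a `bars` attribute (data frame of bar
#'   rectangles: `x0, x1, y0, y1, width`).
#' @export
make_bar_target <- function(density,
                            widths = c(400, 280, 200, 140, 120, 80, 60, 45,
                                       35),
                            bar_length = 5500, n_bars = 2, group_gap = 150,
                            fov = 64 * 105, margin = NULL, seed = NULL) {
  stopifnot(density > 0, all(diff(widths) < 0), all(widths > 0),
            bar_length > 0, n_bars >= 1)
  if (!is.null(seed)) set.seed(seed)
  # bar rectangles
  extent <- sum(widths * (2 * n_bars - 1)) + group_gap * (length(widths) - 1)
  if (is.null(margin)) margin <- (fov - extent) / 2
  if (margin < 0) stop("bar pattern wider than the field of view")
  y0 <- (fov - bar_length) / 2
  xs <- margin
  rows <- list()
  for (w in widths) {
    for (k in seq_len(n_bars)) {
      rows[[length(rows) + 1]] <- data.frame(x0 = xs, x1 = xs + w, y0 = y0,
                                             y1 = y0 + bar_length, width = w)
      xs <- xs + w + w  # bar + gap of equal width
    }
    xs <- xs - w + group_gap  # drop trailing gap, add group separation
  }
  bars <- do.call(rbind, rows)
  area_um2 <- sum((bars$x1 - bars$x0) * (bars$y1 - bars$y0)) / 1e6
  n <- round(density * area_um2)
  # uniform placement inside bars, proportional to bar area
  bar_area <- (bars$x1 - bars$x0) * (bars$y1 - bars$y0)
  idx <- sample.int(nrow(bars), n, replace = TRUE, prob = bar_area)
  x <- bars$x0[idx] + stats::runif(n) * (bars$x1[idx] - bars$x0[idx])
  y <- bars$y0[idx] + stats::runif(n) * (bars$y1[idx] - bars$y0[idx])
  es <- emitter_set(cbind(x, y), density = density, support_area = area_um2)
  attr(es, "bars") <- bars
  attr(es, "fov") <- fov
  es
}

#' Uniform-density emitter region
#'
#' Emitters placed uniformly at random in a square region, for density
#' benchmarks. The realized count is `round(density * area)`.
#'
#' @param density Emitter density in 1/um^2.
#' @param side Side of the square region in nm.
#' @param origin Lower corner (x, y) of the region in nm.
#' @param seed Optional integer seed.
#' @return An [emitter_set()].
#' @export
make_uniform_region <- function(density, side, origin = c(0, 0), seed = NULL) {
  stopifnot(density > 0, side > 0)
  if (!is.null(seed)) set.seed(seed)
  area_um2 <- (side / 1000)^2
  n <- round(density * area_um2)
  x <- origin[1] + stats::runif(n) * side
  y <- origin[2] + stats::runif(n) * side
  es <- emitter_set(cbind(x, y), density = density, support_area = area_um2)
  attr(es, "region") <- c(x0 = origin[1], x1 = origin[1] + side,
                          y0 = origin[2], y1 = origin[2] + side)
  es
}

#' Rigidly moving emitter set
#'
#' Translates every emitter by `velocity * t` so that frame `t` sees the
#' base positions shifted rigidly; photokinetics are unaffected. Returns a
#' function of the frame index so renderers can query per-frame positions.
#'
#' @param base An [emitter_set()].
#' @param velocity Speed in nm/min.
#' @param direction Direction vector (normalised internally).
#' @param frame_interval Seconds between frames.
#' @return A function `f(frame)` returning the positions matrix (nm) at the
#'   given 1-based frame index (positions at the frame start).
#' @export
make_moving_adhesion <- function(base, velocity, direction = c(1, 0),
                                 frame_interval = 0.05) {
  stopifnot(inherits(base, "emitter_set"), velocity >= 0)
  d <- as.numeric(direction)
  nd <- sqrt(sum(d^2))
  if (velocity > 0 && nd == 0) stop("direction must be a nonzero vector")
  u <- if (nd > 0) d / nd else c(0, 0)
  v_nm_s <- velocity / 60
  function(frame) {
    t_s <- (frame - 1) * frame_interval
    sweep(base$positions, 2, u * v_nm_s * t_s, "+")
  }
}

#' Render camera frames from an emitter set
#'
#' The expected photo-electron count of a pixel integrates the Gaussian PSF
#' of every emitting fluorophore over the pixel area (error-function
#' integration), scaled by the quantum efficiency, plus dark current. The
#' recorded count is the EM-amplified Poisson photo-electron number plus
#' additive Gaussian gain noise (excess noise factor) and read-out noise,
#' plus the camera offset, clipped at zero.
#'
#' @param emitters An [emitter_set()] with traces attached, or a positions
#'   matrix together with `traces`.
#' @param optics An [optical_config()].
#' @param camera A [camera_config()].
#' @param frames Integer range of frames to render (default: all frames in
#'   the traces).
#' @param fov Field of view in nm (square); default from the emitter set or
#'   the spanned positions.
#' @param noise If `FALSE`, return the noiseless expectation
#'   `gain * (QE * photons + dark) + offset`.
#' @param bg_photons Diffuse background emission in expected photons per
#'   pixel per frame (cellular autofluorescence and out-of-focus light).
#' @param seed Optional integer seed.
#' @return An [image_stack()] of counts.
#' @export
render_frames <- function(emitters, optics, camera, frames = NULL,
                          fov = NULL, noise = TRUE, bg_photons = 0,
                          seed = NULL) {
  stopifnot(inherits(emitters, "emitter_set"), inherits(optics, "optical_config"),
            inherits(camera, "camera_config"))
  tr <- emitters$traces
  if (is.null(tr)) stop("emitter set has no traces; run simulate_traces()")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fov)) fov <- attr(emitters, "fov")
  if (is.null(fov)) fov <- max(emitters$positions) + 10 * optics$psf_sigma
  npx <- round(fov / optics$pixel_size)
  if (npx < 1) stop("field of view smaller than one pixel")
  pos <- emitters$positions
  pad <- 5 * optics$psf_sigma
  if (any(pos[, 1] < -pad | pos[, 1] > fov + pad |
          pos[, 2] < -pad | pos[, 2] > fov + pad)) {
    stop("emitters outside the field of view")
  }
  if (is.null(frames)) frames <- seq_len(attr(tr, "n_frames"))
  frames <- as.integer(frames)
  stopifnot(all(diff(frames) == 1L))
  sel <- tr$frame >= frames[1] & tr$frame <= frames[length(frames)]
  trs <- tr[sel, , drop = FALSE]
  o <- order(trs$frame)
  trs <- trs[o, , drop = FALSE]
  arr <- cpp_render_frames(pos, as.integer(trs$emitter),
                           as.integer(trs$frame), as.numeric(trs$photons),
                           frames[1], length(frames), npx, npx,
                           optics$pixel_size, optics$psf_sigma,
                           camera$quantum_efficiency, camera$em_gain,
                           camera$read_noise_sd, camera$dark_current,
                           camera$excess_noise_factor, camera$offset,
                           isTRUE(noise), bg_photons)
  image_stack(arr, pixel_size = optics$pixel_size,
              frame_interval = camera$exposure_time)
}

#' Noiseless widefield reference image
#'
#' Renders the time-integrated expected photo-electron image of an emitter
#' set on an arbitrarily fine pixel grid (no camera noise), as used for the
#' widefield MTF threshold.
#'
#' @param emitters An [emitter_set()]; if traces are attached, each emitter
#'   is weighted by its total emitted photons, otherwise by 1.
#' @param optics An [optical_config()].
#' @param pixel_size Output pixel size in nm.
#' @param fov Field of view in nm.
#' @return An [image_stack()] with one frame (photo-electron units).
#' @export
widefield_reference <- function(emitters, optics, pixel_size, fov = NULL) {
  stopifnot(inherits(emitters, "emitter_set"))
  if (is.null(fov)) fov <- attr(emitters, "fov")
  if (is.null(fov)) fov <- max(emitters$positions) + 10 * optics$psf_sigma
  npx <- round(fov / pixel_size)
  w <- if (!is.null(emitters$traces)) {
    tapply(emitters$traces$photons, factor(emitters$traces$emitter,
           levels = seq_len(nrow(emitters$positions))), sum, default = 0)
  } else rep(1, nrow(emitters$positions))
  img <- cpp_render_static(emitters$positions, as.numeric(w), npx, npx,
                           pixel_size, optics$psf_sigma)
  image_stack(array(img, dim = c(npx, npx, 1)), pixel_size = pixel_size)
}

#' Simulate a full raw image sequence
#'
#' Convenience wrapper: simulate traces for an emitter set and render all
#' frames.
#'
#' @inheritParams render_frames
#' @param kinetics A [photokinetics()].
#' @param n_frames Number of frames.
#' @param seed Optional integer seed covering both kinetics and noise.
#' @return An [image_stack()]; the emitter set with traces attached is
#'   available as attribute `emitters`.
#' @export
simulate_stack <- function(emitters, kinetics, optics, camera, n_frames,
                           fov = NULL, noise = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  emitters$traces <- simulate_traces(nrow(emitters$positions), kinetics,
                                     n_frames, exposure = camera$exposure_time)
  st <- render_frames(emitters, optics, camera, fov = fov, noise = noise)
  attr(st, "emitters") <- emitters
  st
}
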