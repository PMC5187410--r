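#' Build a kymograph along a line
#'
#' For every image of a time series, the intensity profile along the line
#' is sampled by bilinear interpolation (averaged across `width` parallel
#' offsets perpendicular to the line) and stacked into a space-time matrix.
#'
#' @param image_series List of numeric matrices (equal shape), one per time
#'   point.
#' @param line Numeric vector `c(x0, y0, x1, y1)` in nm.
#' @param pixel_size Image pixel size in nm.
#' @param width Averaging width in pixels (odd; 1 = single line).
#' @param time_step Seconds between images.
#' @param sampling Sample spacing along the line in nm (default: one
#'   pixel).
#' @return A `kymograph`: list with `matrix` (position along line x time),
#'   `positions` (nm along the line), `time_step`, `line`.
#' @export
build_kymograph <- function(image_series, line, pixel_size, width = 1,
                            time_step = 1, sampling = pixel_size) {
  stopifnot(is.list(image_series), length(image_series) >= 2,
            length(line) == 4)
  dx <- line[3] - line[1]
  dy <- line[4] - line[2]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) stop("line of zero length")
  u <- c(dx, dy) / len
  nrm <- c(-u[2], u[1])
  npos <- max(2L, floor(len / sampling) + 1L)
  s <- seq(0, len, length.out = npos)
  offs <- (seq_len(width) - (width + 1) / 2) * pixel_size
  d <- dim(image_series[[1]])
  interp <- function(img, x, y) {
    # continuous nm coordinates -> pixel-centre coordinates
    cx <- x / pixel_size + 0.5
    cy <- y / pixel_size + 0.5
    j0 <- pmin(pmax(floor(cx - 0.5) + 1, 1), d[2] - 1)
    i0 <- pmin(pmax(floor(cy - 0.5) + 1, 1), d[1] - 1)
    wx <- pmin(pmax(cx - (j0 - 0.5), 0), 1)
    wy <- pmin(pmax(cy - (i0 - 0.5), 0), 1)
    v00 <- img[cbind(i0, j0)]
    v10 <- img[cbind(i0 + 1, j0)]
    v01 <- img[cbind(i0, j0 + 1)]
    v11 <- img[cbind(i0 + 1, j0 + 1)]
    (1 - wy) * (1 - wx) * v00 + wy * (1 - wx) * v10 +
      (1 - wy) * wx * v01 + wy * wx * v11
  }
  nt <- length(image_series)
  km <- matrix(0, npos, nt)
  for (t in seq_len(nt)) {
    img <- image_series[[t]]
    if (!all(dim(img) == d)) stop("image shapes differ across time points")
    acc <- numeric(npos)
    for (o in offs) {
      px <- line[1] + s * u[1] + o * nrm[1]
      py <- line[2] + s * u[2] + o * nrm[2]
      if (any(px < 0 | px > d[2] * pixel_size |
              py < 0 | py > d[1] * pixel_size)) {
        stop("line (or its width offsets) outside the image")
      }
      acc <- acc + interp(img, px, py)
    }
    km[, t] <- acc / width
  }
  structure(list(matrix = km, positions = s, time_step = time_step,
                 line = line),
            class = "kymograph")
}

#' Centre of gravity of one kymograph column
#'
#' Intensity-weighted mean position along the line at a given time point.
#' The column median is subtracted as background and negative values are
#' clipped before weighting (a uniform offset would otherwise bias the
#' centre of gravity).
#'
#' @param kymo A [build_kymograph()] result.
#' @param time_index Column index (1-based).
#' @param background Subtract the column median before weighting.
#' @return Position in nm along the line.
#' @export
centre_of_gravity <- function(kymo, time_index, background = TRUE) {
  stopifnot(inherits(kymo, "kymograph"))
  col <- kymo$matrix[, time_index]
  if (background) col <- pmax(col - stats::median(col), 0)
  tot <- sum(col)
  if (tot <= 0) stop("kymograph column has no positive weight")
  sum(col * kymo$positions) / tot
}

#' Kymograph-based velocity estimate
#'
#' For each of `n_parallel` lines (the given line plus parallel offsets),
#' the centre of gravity of every kymograph column is fitted linearly
#' against time; the mean slope is the velocity, the standard deviation
#' over lines the error. The signed direction along x and y is obtained by
#' applying the same procedure to axis-parallel projections.
#'
#' @param image_series List of numeric matrices.
#' @param line `c(x0, y0, x1, y1)` in nm.
#' @param pixel_size Image pixel size in nm.
#' @param time_step Seconds between images.
#' @param n_parallel Number of parallel lines (spaced one pixel apart).
#' @param width Averaging width per line in pixels.
#' @return A `velocity_estimate`: list with `mean` and `sd` (nm/min),
#'   `slopes` (per line, nm/min), `direction` (unit vector).
#' @export
estimate_velocity <- function(image_series, line, pixel_size, time_step,
                              n_parallel = 5, width = 1) {
  stopifnot(n_parallel >= 1, length(image_series) >= 2)
  dx <- line[3] - line[1]
  dy <- line[4] - line[2]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) stop("line of zero length")
  u <- c(dx, dy) / len
  nrm <- c(-u[2], u[1])
  offsets <- (seq_len(n_parallel) - (n_parallel + 1) / 2) * pixel_size
  nt <- length(image_series)
  tt <- (seq_len(nt) - 1) * time_step
  slopes <- vapply(offsets, function(o) {
    l <- line + c(nrm * o, nrm * o)
    km <- build_kymograph(image_series, l, pixel_size, width = width,
                          time_step = time_step)
    r <- vapply(seq_len(nt), function(k) centre_of_gravity(km, k),
                numeric(1))
    unname(stats::coef(stats::lm(r ~ tt))[2]) * 60   # nm/s -> nm/min
  }, numeric(1))
  # direction from axis-parallel analysis: slope of weighted mean x and y
  dirsl <- vapply(1:2, function(ax) {
    r <- vapply(seq_len(nt), function(k) {
      img <- image_series[[k]]
      img <- pmax(img - stats::median(img), 0)
      w <- if (ax == 1) colSums(img) else rowSums(img)
      pos <- (seq_along(w) - 0.5) * pixel_size
      if (sum(w) <= 0) return(NA_real_)
      sum(w * pos) / sum(w)
    }, numeric(1))
    if (any(!is.finite(r))) return(0)
    unname(stats::coef(stats::lm(r ~ tt))[2])
  }, numeric(1))
  nd <- sqrt(sum(dirsl^2))
  direction <- if (nd > 0) dirsl / nd else c(NA_real_, NA_real_)
  structure(list(mean = mean(slopes), sd = if (n_parallel > 1) stats::sd(slopes)
                 else NA_real_,
                 slopes = slopes, direction = direction),
            class = "velocity_estimate")
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf("Velocity: %.1f +/- %.1f nm/min (n = %d lines)\n",
              x$mean, x$sd, length(x$slopes)))
  invisible(x)
}
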