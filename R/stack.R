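#' Image stack
#'
#' A time sequence of 2D camera frames with pixel size and frame interval
#' metadata. Frames are stored as a numeric 3D array with dimensions
#' `(y, x, time)`, in camera counts.
#'
#' @param frames 3D numeric array `(ny, nx, nt)`, or a matrix for a single
#'   frame.
#' @param pixel_size Pixel size in nm.
#' @param frame_interval Time between frame starts, in seconds.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval = 0.05) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L, dim(frames)[3] >= 1L,
            is.numeric(pixel_size), pixel_size > 0, frame_interval > 0)
  if (!all(is.finite(frames)) || any(frames < 0)) {
    stop("image stack values must be finite and non-negative")
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Image stack: %d frames of %d x %d px (%g nm/px, %g s/frame)\n",
              d[3], d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

#' Number of frames in a stack
#' @param stack An [image_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Values are rounded and clipped to the unsigned 16-bit range. Pixel size
#' and frame interval are written to a plain-text sidecar `<path>.meta.yaml`
#' so that a round trip through [read_stack()] restores the metadata.
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  nt <- n_frames(stack)
  pages <- lapply(seq_len(nt), function(t) {
    m <- pmin(pmax(round(stack$frames[, , t]), 0), 65535)
    m / 65535  # tiff package expects [0,1]; 16-bit preserves integers
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  yaml::write_yaml(list(pixel_size = stack$pixel_size,
                        frame_interval = stack$frame_interval),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' All pages must share one frame shape. Metadata is taken from the sidecar
#' written by [write_stack()] when present, else from the arguments.
#'
#' @param path Path to a multi-page TIFF.
#' @param pixel_size,frame_interval Fallback metadata when no sidecar file
#'   is found.
#' @return An [image_stack()] with integer counts.
#' @export
read_stack <- function(path, pixel_size = 105, frame_interval = 0.05) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("failed to read TIFF '", path,
                                             "': ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    stop("inconsistent frame shapes in ", path, ": ",
         paste(unique(shapes), collapse = ", "))
  }
  d <- dim(pages[[1]])
  frames <- array(0, dim = c(d[1], d[2], length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]]
  meta <- paste0(path, ".meta.yaml")
  if (file.exists(meta)) {
    m <- yaml::read_yaml(meta)
    pixel_size <- m$pixel_size
    frame_interval <- m$frame_interval
  }
  image_stack(frames, pixel_size = pixel_size, frame_interval = frame_interval)
}
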