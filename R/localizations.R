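#' Localization table
#'
#' A data frame of single-molecule localization events with one row per
#' fitted emission burst: frame index (1-based), absolute position in nm,
#' fitted photon count, background (photo-electrons per pixel) and the
#' theoretical localization precision in nm. Positions use the package's
#' coordinate convention: pixel `(i, j)` (1-based row/column) spans
#' `[(j-1) p, j p) x [(i-1) p, i p)` in nm, with the origin at the top-left
#' corner of the first pixel.
#'
#' @param frame Integer frame indices (1-based).
#' @param x,y Positions in nm.
#' @param photons Fitted photon counts.
#' @param background Fitted background in photo-electrons per pixel.
#' @param precision Localization precision (standard deviation) in nm;
#'   strictly positive.
#' @param channel Optional channel label (recycled).
#' @return A `localization_table`, a `data.frame` subclass.
#' @export
localization_table <- function(frame = integer(), x = numeric(),
                               y = numeric(), photons = numeric(),
                               background = numeric(), precision = numeric(),
                               channel = "default") {
  n <- length(frame)
  if (n == 0L) {
    df <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                     photons = numeric(), background = numeric(),
                     precision = numeric(), channel = character(),
                     stringsAsFactors = FALSE)
    class(df) <- c("localization_table", "data.frame")
    return(df)
  }
  if (length(background) == 0L) background <- rep(0, n)
  if (length(photons) == 0L) photons <- rep(NA_real_, n)
  stopifnot(length(x) == n, length(y) == n, length(precision) == n,
            length(photons) == n, length(background) == n)
  if (any(!is.finite(precision)) || any(precision <= 0)) {
    stop("localization precision must be finite and > 0")
  }
  if (any(frame < 1L)) stop("frame indices must be >= 1")
  df <- data.frame(frame = as.integer(frame), x = as.numeric(x),
                   y = as.numeric(y), photons = as.numeric(photons),
                   background = as.numeric(background),
                   precision = as.numeric(precision),
                   channel = rep_len(as.character(channel), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("localization_table", "data.frame")
  df
}

loc_columns <- c("frame", "x", "y", "photons", "background", "precision",
                 "channel")

as_localization_table <- function(df) {
  stopifnot(all(loc_columns %in% names(df)))
  df <- df[, loc_columns]
  class(df) <- c("localization_table", "data.frame")
  df
}

#' @export
print.localization_table <- function(x, ...) {
  cat(sprintf("Localization table: %d records", nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf(" (frames %d..%d, median precision %.1f nm)",
                min(x$frame), max(x$frame), stats::median(x$precision)))
  }
  cat("\n")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Write a localization table to CSV
#'
#' Plain CSV with a fixed header. Positions and precisions are written with
#' 0.01 nm resolution, photon counts and background with 0.01 resolution,
#' frames as integers.
#'
#' @param table A [localization_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  stopifnot(inherits(table, "localization_table"))
  out <- data.frame(frame = table$frame,
                    x = sprintf("%.2f", table$x),
                    y = sprintf("%.2f", table$y),
                    photons = sprintf("%.2f", table$photons),
                    background = sprintf("%.2f", table$background),
                    precision = sprintf("%.2f", table$precision),
                    channel = table$channel)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a localization table from CSV
#'
#' Malformed rows (non-numeric fields, wrong column count) raise an error
#' naming the offending line.
#'
#' @param path Path to a CSV written by [write_localizations()] (or any CSV
#'   with the same header).
#' @return A [localization_table()].
#' @export
read_localizations <- function(path) {
  if (!file.exists(path)) stop("localization file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty localization file: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!all(loc_columns %in% header)) {
    stop("missing columns in ", path, ": ",
         paste(setdiff(loc_columns, header), collapse = ", "))
  }
  if (length(lines) == 1L) return(localization_table())
  idx <- match(loc_columns, header)
  num_cols <- setdiff(loc_columns, "channel")
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  vals <- vector("list", length(loc_columns))
  names(vals) <- loc_columns
  mat <- matrix(NA_character_, nrow = length(rows), ncol = length(header))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != length(header)) {
      stop("line ", i + 1L, " of ", path, ": expected ", length(header),
           " fields, found ", length(r))
    }
    mat[i, ] <- r
  }
  for (k in seq_along(loc_columns)) {
    col <- mat[, idx[k]]
    if (loc_columns[k] == "channel") {
      vals[[k]] <- col
    } else {
      v <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(v) & !(col %in% c("NA", "NaN")))
      if (length(bad) > 0) {
        stop("line ", bad[1] + 1L, " of ", path, ": non-numeric value '",
             col[bad[1]], "' in column ", loc_columns[k])
      }
      vals[[k]] <- v
    }
  }
  localization_table(frame = vals$frame, x = vals$x, y = vals$y,
                     photons = vals$photons, background = vals$background,
                     precision = vals$precision, channel = vals$channel)
}

#' Fiducial track
#'
#' Per-frame positions of one or more stationary fiducial markers (for
#' example 100 nm gold nanospheres) used for lateral drift monitoring.
#'
#' @param frame Integer frame indices.
#' @param id Fiducial identifier (integer or character).
#' @param x,y Positions in nm (must be finite).
#' @return A `fiducial_track` data frame.
#' @export
fiducial_track <- function(frame, id, x, y) {
  stopifnot(length(frame) == length(id), length(frame) == length(x),
            length(frame) == length(y))
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("fiducial positions must be finite")
  }
  df <- data.frame(frame = as.integer(frame), id = as.character(id),
                   x = as.numeric(x), y = as.numeric(y),
                   stringsAsFactors = FALSE)
  class(df) <- c("fiducial_track", "data.frame")
  df
}
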