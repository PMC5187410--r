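#' Optical configuration
#'
#' Bundles the optical parameters of a widefield single-molecule microscope:
#' emission wavelength, numerical aperture, back-projected camera pixel size
#' and the standard deviation of the Gaussian approximation of the point
#' spread function (PSF).
#'
#' The default PSF width follows the standard Gaussian approximation of the
#' Airy pattern, `sigma = 0.21 * wavelength / NA`. A custom `psf_sigma` may
#' be supplied, but it must stay within a factor `sigma_tolerance` of the
#' Gaussian approximation so that obviously inconsistent configurations are
#' rejected early.
#'
#' @param wavelength Emission wavelength in nm.
#' @param numerical_aperture Objective numerical aperture (dimensionless).
#' @param pixel_size Back-projected camera pixel size in nm.
#' @param psf_sigma Gaussian PSF standard deviation in nm. Defaults to
#'   `0.21 * wavelength / numerical_aperture`.
#' @param sigma_tolerance Maximum allowed ratio (either way) between
#'   `psf_sigma` and the Gaussian approximation.
#' @return An object of class `optical_config`.
#' @examples
#' opt <- optical_config(wavelength = 600, numerical_aperture = 1.49)
#' opt$psf_sigma
#' @export
optical_config <- function(wavelength, numerical_aperture, pixel_size = 105,
                           psf_sigma = NULL, sigma_tolerance = 3) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1L, wavelength > 0,
            is.numeric(numerical_aperture), length(numerical_aperture) == 1L,
            numerical_aperture > 0,
            is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  sigma0 <- 0.21 * wavelength / numerical_aperture
  if (is.null(psf_sigma)) psf_sigma <- sigma0
  stopifnot(is.numeric(psf_sigma), length(psf_sigma) == 1L, psf_sigma > 0)
  ratio <- psf_sigma / sigma0
  if (ratio > sigma_tolerance || ratio < 1 / sigma_tolerance) {
    stop("psf_sigma (", signif(psf_sigma, 4), " nm) inconsistent with the ",
         "Gaussian PSF approximation 0.21*lambda/NA = ", signif(sigma0, 4),
         " nm")
  }
  structure(list(wavelength = wavelength,
                 numerical_aperture = numerical_aperture,
                 pixel_size = pixel_size,
                 psf_sigma = psf_sigma),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration\n")
  cat(sprintf("  wavelength    : %g nm\n", x$wavelength))
  cat(sprintf("  NA            : %g\n", x$numerical_aperture))
  cat(sprintf("  pixel size    : %g nm\n", x$pixel_size))
  cat(sprintf("  PSF sigma     : %g nm\n", x$psf_sigma))
  cat(sprintf("  Abbe cutoff   : %.4g 1/nm (%.0f nm)\n", abbe_cutoff(x),
              1 / abbe_cutoff(x)))
  invisible(x)
}

#' Abbe cutoff frequency
#'
#' The diffraction-limited cutoff spatial frequency of widefield imaging,
#' `2 NA / lambda`.
#'
#' @param cfg An [optical_config()].
#' @return Cutoff frequency in 1/nm.
#' @examples
#' abbe_cutoff(optical_config(600, 1.49)) # 2 * 1.49 / 600
#' @export
abbe_cutoff <- function(cfg) {
  stopifnot(inherits(cfg, "optical_config"))
  2 * cfg$numerical_aperture / cfg$wavelength
}

#' Camera model configuration
#'
#' Parameters of the (EMCCD) camera model used both by the simulator and by
#' the localization likelihood: quantum efficiency, electron-multiplying
#' gain, Gaussian read noise, dark current, excess noise factor of the EM
#' register (sqrt(2) for EMCCD), exposure time and digital offset.
#'
#' @param quantum_efficiency Detection efficiency, in (0, 1].
#' @param em_gain Electron-multiplying gain (counts per photo-electron),
#'   >= 1.
#' @param read_noise_sd Read-out noise standard deviation in counts.
#' @param dark_current Thermal photo-electrons per pixel per frame.
#' @param excess_noise_factor Multiplicative noise factor of the EM
#'   amplification; `sqrt(2)` for an EMCCD, 1 for a conventional camera.
#' @param exposure_time Frame exposure time in seconds.
#' @param offset Digital offset added to every pixel, in counts.
#' @return An object of class `camera_config`.
#' @examples
#' cam <- camera_config()
#' cam$em_gain
#' @export
camera_config <- function(quantum_efficiency = 0.9, em_gain = 100,
                          read_noise_sd = 10, dark_current = 0.2,
                          excess_noise_factor = sqrt(2),
                          exposure_time = 0.05, offset = 100) {
  stopifnot(quantum_efficiency > 0, quantum_efficiency <= 1,
            em_gain >= 1, read_noise_sd >= 0, dark_current >= 0,
            excess_noise_factor >= 1, exposure_time > 0, offset >= 0)
  structure(list(quantum_efficiency = quantum_efficiency,
                 em_gain = em_gain,
                 read_noise_sd = read_noise_sd,
                 dark_current = dark_current,
                 excess_noise_factor = excess_noise_factor,
                 exposure_time = exposure_time,
                 offset = offset),
            class = "camera_config")
}

#' @export
print.camera_config <- function(x, ...) {
  cat("Camera configuration\n")
  for (f in names(x)) cat(sprintf("  %-20s: %g\n", f, x[[f]]))
  invisible(x)
}

#' Read a combined configuration file
#'
#' Reads a YAML configuration carrying `optics`, `camera` and `kinetics`
#' sections and returns the corresponding objects. Sections not present are
#' returned as `NULL`.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `optics` ([optical_config()]), `camera`
#'   ([camera_config()]), `kinetics` ([photokinetics()]) and `params` (any
#'   remaining fields, as a list).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  out <- list(optics = NULL, camera = NULL, kinetics = NULL, params = NULL)
  if (!is.null(raw$optics)) out$optics <- do.call(optical_config, raw$optics)
  if (!is.null(raw$camera)) out$camera <- do.call(camera_config, raw$camera)
  if (!is.null(raw$kinetics)) out$kinetics <- do.call(photokinetics, raw$kinetics)
  out$params <- raw[setdiff(names(raw), c("optics", "camera", "kinetics"))]
  out
}
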