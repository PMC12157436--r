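#' Optical configuration for a widefield acquisition
#'
#' Collects the optical parameters needed by the Gaussian point-spread
#' function (PSF) emission model. The lateral PSF standard deviation is
#' derived from the emission wavelength and numerical aperture with the
#' standard Gaussian approximation \eqn{\sigma = 0.21 \lambda / \mathrm{NA}};
#' the in-focus lateral variance \eqn{v = \sigma^2} is what enters all
#' pixel-integrated likelihood computations. A z-dependent variance model can
#' be plugged in by overriding `psf_sigma_nm`.
#'
#' @param numerical_aperture Objective numerical aperture (dimensionless),
#'   must be positive and smaller than `refractive_index`.
#' @param refractive_index Immersion-medium refractive index (dimensionless).
#' @param emission_wavelength_nm Fluorophore emission wavelength in nm.
#' @param pixel_size_nm Back-projected pixel pitch in nm.
#' @param psf_sigma_nm Optional override of the lateral PSF standard
#'   deviation in nm; defaults to `0.21 * emission_wavelength_nm /
#'   numerical_aperture`.
#' @return An object of class `optics_config` with fields
#'   `numerical_aperture`, `refractive_index`, `emission_wavelength_nm`,
#'   `pixel_size_nm`, `psf_sigma_nm` and `psf_variance_nm2`.
#' @examples
#' opt <- optics_config(1.45, 1.515, 665, 133)
#' opt$psf_sigma_nm # ~96.3 nm
#' @export
optics_config <- function(numerical_aperture, refractive_index,
                          emission_wavelength_nm, pixel_size_nm,
                          psf_sigma_nm = NULL) {
  vals <- c(numerical_aperture, refractive_index, emission_wavelength_nm,
            pixel_size_nm)
  .assert(all(is.finite(vals)) && all(vals > 0),
          "invalid optics config: all parameters must be finite and positive")
  .assert(numerical_aperture < refractive_index,
          "invalid optics config: numerical_aperture must be < refractive_index")
  if (is.null(psf_sigma_nm)) {
    psf_sigma_nm <- 0.21 * emission_wavelength_nm / numerical_aperture
  }
  .assert(.is_scalar(psf_sigma_nm) && psf_sigma_nm > 0,
          "invalid optics config: psf_sigma_nm must be a positive scalar")
  structure(list(
    numerical_aperture = numerical_aperture,
    refractive_index = refractive_index,
    emission_wavelength_nm = emission_wavelength_nm,
    pixel_size_nm = pixel_size_nm,
    psf_sigma_nm = psf_sigma_nm,
    psf_variance_nm2 = psf_sigma_nm^2
  ), class = "optics_config")
}

#' Lateral PSF standard deviation
#'
#' @param optics An [optics_config()] object.
#' @return PSF sigma in nm.
#' @export
psf_sigma <- function(optics) {
  .assert(inherits(optics, "optics_config"), "expected an optics_config")
  optics$psf_sigma_nm
}

#' EMCCD camera read-out model
#'
#' Gaussian approximation to the EMCCD read-out: a pixel receiving `u`
#' expected photons reads out `w ~ Normal(offset + G u, F^2 G^2 u +
#' sigma_read^2)` in ADU, where `G` is the EM gain and `F^2` the excess noise
#' factor of the electron-multiplying register (2 for an ideal EM register).
#'
#' @param offset Camera offset in ADU.
#' @param em_gain EM gain in ADU per photoelectron; must be positive.
#' @param read_noise_sd Read noise standard deviation in ADU; must be
#'   positive so the likelihood stays proper at `u = 0`.
#' @param excess_noise_factor_sq Excess noise factor squared, `>= 1`.
#' @return Object of class `camera_emccd`.
#' @export
camera_emccd <- function(offset = 100, em_gain = 100, read_noise_sd = 2,
                         excess_noise_factor_sq = 2) {
  .assert(.is_scalar(offset), "offset must be a finite scalar")
  .assert(.is_scalar(em_gain) && em_gain > 0, "em_gain must be > 0")
  .assert(.is_scalar(read_noise_sd) && read_noise_sd >= 0,
          "read_noise_sd must be >= 0")
  .assert(.is_scalar(excess_noise_factor_sq) && excess_noise_factor_sq >= 1,
          "excess_noise_factor_sq must be >= 1")
  structure(list(offset = offset, em_gain = em_gain,
                 read_noise_sd = read_noise_sd,
                 excess_noise_factor_sq = excess_noise_factor_sq),
            class = c("camera_emccd", "camera"))
}

#' SPAD array camera model
#'
#' Binary single-photon avalanche diode detector: a pixel receiving `u`
#' expected photons fires (`w = 1`) with probability `1 - exp(-u)`.
#'
#' @return Object of class `camera_spad`.
#' @export
camera_spad <- function() {
  structure(list(), class = c("camera_spad", "camera"))
}

#' @export
print.optics_config <- function(x, ...) {
  cat(sprintf(
    "optics_config: NA=%.3g n=%.4g lambda=%.4g nm pixel=%.4g nm sigma=%.4g nm\n",
    x$numerical_aperture, x$refractive_index, x$emission_wavelength_nm,
    x$pixel_size_nm, x$psf_sigma_nm))
  invisible(x)
}
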