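#' Simulation preset
#'
#' Bundles everything needed to generate a synthetic movie: optics, camera,
#' geometry, particle count, diffusion coefficient, emission level and
#' background.
#'
#' @param optics An [optics_config()].
#' @param camera A [camera_emccd()] or [camera_spad()].
#' @param n_frames Number of frames, `>= 1`.
#' @param frame_size Frame side in pixels (scalar, square frames) or
#'   `c(I, J)`.
#' @param n_particles Number of emitting particles, `>= 1`.
#' @param diffusion_um2s Diffusion coefficient in um^2/s.
#' @param center_pixel_photons Expected signal photons at the pixel
#'   concentric with an in-focus, pixel-centered particle.
#' @param background_rate Background photons/pixel/frame.
#' @param exposure_time_s Frame exposure in seconds.
#' @param seed Seed for bit-identical regeneration.
#' @return Object of class `simulation_preset`.
#' @export
simulation_preset <- function(optics, camera, n_frames, frame_size,
                              n_particles, diffusion_um2s,
                              center_pixel_photons, background_rate,
                              exposure_time_s, seed = 1L) {
  if (length(frame_size) == 1L) frame_size <- c(frame_size, frame_size)
  .assert(.is_count(n_frames), "n_frames must be >= 1")
  .assert(all(vapply(frame_size, .is_count, logical(1L))),
          "frame_size must be positive counts")
  .assert(.is_count(n_particles), "n_particles must be >= 1")
  .assert(.is_scalar(diffusion_um2s) && diffusion_um2s >= 0,
          "diffusion_um2s must be >= 0")
  .assert(.is_scalar(center_pixel_photons) && center_pixel_photons >= 0,
          "center_pixel_photons must be >= 0")
  .assert(.is_scalar(background_rate) && background_rate >= 0,
          "background_rate must be >= 0")
  .assert(.is_scalar(exposure_time_s) && exposure_time_s > 0,
          "exposure_time_s must be > 0")
  structure(list(optics = optics, camera = camera,
                 n_frames = as.integer(n_frames),
                 frame_size = as.integer(frame_size),
                 n_particles = as.integer(n_particles),
                 diffusion_um2s = diffusion_um2s,
                 center_pixel_photons = center_pixel_photons,
                 background_rate = background_rate,
                 exposure_time_s = exposure_time_s,
                 seed = as.integer(seed)),
            class = "simulation_preset")
}

# Background series for the "fig2"-style noise sweep (photons/px/frame;
# rightmost level is 20x the leftmost, topping out around 60) and emission
# series for the "fig3"-style brightness sweep (center-pixel photons, 80 =
# reference dye brightness). Fixed package choices; see the methods vignette.
.fig2_backgrounds <- c(3, 7.5, 15, 30, 60)
.fig3_photons <- c(20, 40, 80, 160)

#' Standard synthetic-experiment presets
#'
#' Two preset families mirroring the package's reference experiments:
#' `"fig2"` sweeps the background level at fixed emission (80 center-pixel
#' photons), `"fig3"` sweeps the emission rate at fixed background
#' (60 photons/pixel/frame). Both default to ten 128x128 frames, ten
#' particles diffusing at 0.1 um^2/s, NA 1.45, refractive index 1.515,
#' 665 nm emission, 133 nm pixels, 33 ms exposure, and an EMCCD with offset
#' and EM gain of 100; a size override scales the frame down (e.g. to 32x32)
#' while preserving all densities and optics.
#'
#' @param variant `"fig2"` or `"fig3"`.
#' @param level Index into the variant's series (fig2: background levels
#'   3, 7.5, 15, 30, 60; fig3: emission levels 20, 40, 80, 160). Defaults to
#'   the first background level for fig2 and the 80-photon reference for
#'   fig3.
#' @param frame_size Optional frame-size override in pixels.
#' @param n_frames,n_particles Optional count overrides.
#' @param seed Preset seed.
#' @return A [simulation_preset()].
#' @export
make_preset <- function(variant = c("fig2", "fig3"), level = NULL,
                        frame_size = 128L, n_frames = 10L,
                        n_particles = 10L, seed = 1L) {
  variant <- match.arg(variant)
  optics <- optics_config(numerical_aperture = 1.45, refractive_index = 1.515,
                          emission_wavelength_nm = 665, pixel_size_nm = 133)
  camera <- camera_emccd(offset = 100, em_gain = 100, read_noise_sd = 2)
  if (variant == "fig2") {
    level <- level %||% 1L
    .assert(.is_count(level) && level <= length(.fig2_backgrounds),
            "unknown fig2 level")
    background <- .fig2_backgrounds[level]
    photons <- 80
  } else {
    level <- level %||% 3L
    .assert(.is_count(level) && level <= length(.fig3_photons),
            "unknown fig3 level")
    background <- 60
    photons <- .fig3_photons[level]
  }
  simulation_preset(optics = optics, camera = camera, n_frames = n_frames,
                    frame_size = frame_size, n_particles = n_particles,
                    diffusion_um2s = 0.1, center_pixel_photons = photons,
                    background_rate = background, exposure_time_s = 0.033,
                    seed = seed)
}

#' Calibrate brightness to a target concentric-pixel photon count
#'
#' Returns the brightness `h` such that an in-focus particle centered on a
#' pixel contributes exactly `target` expected signal photons to that pixel:
#' `h = target / f^2` where `f` is the Gaussian strip mass of a centered
#' pixel, `f = erf_strip_integral(0, -d/2, d/2, v)`.
#'
#' @param target Target photons at the concentric pixel, `>= 0`.
#' @param optics An [optics_config()].
#' @return Brightness `h` in photons.
#' @export
calibrate_brightness <- function(target, optics) {
  .assert(.is_scalar(target) && target >= 0, "target must be >= 0")
  d <- optics$pixel_size_nm
  f <- erf_strip_integral(0, -d / 2, d / 2, optics$psf_variance_nm2)
  .assert(f > 0, "degenerate optics: centered-pixel mass is zero")
  target / f^2
}

#' Simulate ground-truth tracks and expected photon fields
#'
#' Draws Brownian tracks from the motion model at
#' `msd_per_frame = 4 D dt` (initial positions uniform over the central 80%
#' of the field of view to limit edge truncation), calibrates the brightness
#' to the preset's concentric-pixel photon count, and renders the expected
#' photon field of every frame through the same pixel-integrated PSF model
#' the likelihood uses. Bit-identical regeneration from `(preset, seed)`.
#'
#' @param preset A [simulation_preset()].
#' @return Object of class `ground_truth`: `tracks` (`N x M x 2` nm),
#'   `h`, `background_rate`, `field` (a `photon_field`), `msd_per_frame_nm2`
#'   and the `preset`.
#' @export
simulate_ground_truth <- function(preset) {
  .assert(inherits(preset, "simulation_preset"), "expected a simulation_preset")
  set.seed(preset$seed)
  px <- preset$optics$pixel_size_nm
  nx <- preset$frame_size[1L]
  ny <- preset$frame_size[2L]
  fov <- c(0, nx * px, 0, ny * px)
  # 4 D dt, with D in um^2/s = 1e6 nm^2/s
  msd <- 4 * preset$diffusion_um2s * 1e6 * preset$exposure_time_s
  motion <- if (msd > 0) motion_params(msd) else NULL
  priors <- spt_priors(msd_shape = 2, msd_scale = max(msd, 1),
                       load_prob = 1, fov_bounds = fov)
  inner <- c(fov[2L] * 0.1, fov[2L] * 0.9, fov[4L] * 0.1, fov[4L] * 0.9)
  tracks <- if (is.null(motion)) {
    pos <- array(0, dim = c(preset$n_frames, preset$n_particles, 2L))
    for (m in seq_len(preset$n_particles)) {
      p0 <- c(stats::runif(1L, inner[1L], inner[2L]),
              stats::runif(1L, inner[3L], inner[4L]))
      pos[, m, 1L] <- p0[1L]
      pos[, m, 2L] <- p0[2L]
    }
    pos
  } else {
    sample_tracks_prior(preset$n_particles, preset$n_frames, motion, priors,
                        init_bounds = inner)
  }
  h <- calibrate_brightness(preset$center_pixel_photons, preset$optics)
  field <- expected_photons(tracks, rep(1L, preset$n_particles), h,
                            preset$background_rate, preset$optics, nx, ny)
  structure(list(tracks = tracks, h = h,
                 background_rate = preset$background_rate, field = field,
                 msd_per_frame_nm2 = msd, preset = preset),
            class = "ground_truth")
}

#' Render a recorded stack from ground truth
#'
#' Draws pixel measurements from the same detector models the likelihood
#' assumes (model-matched simulation): SPAD pixels are Bernoulli with hit
#' probability `1 - exp(-u)`; EMCCD pixels are Gaussian with mean
#' `offset + G u` and variance `F^2 G^2 u + sigma_read^2`, clipped at zero
#' and quantized to integer ADU. Uses the global RNG; seed with
#' `set.seed()` for reproducibility.
#'
#' @param truth A `ground_truth` from [simulate_ground_truth()], or any
#'   `photon_field` via the `field` argument.
#' @param camera Camera model; defaults to the preset's camera.
#' @return An [image_stack()].
#' @export
render_stack <- function(truth, camera = NULL) {
  .assert(inherits(truth, "ground_truth"), "expected a ground_truth")
  camera <- camera %||% truth$preset$camera
  stack <- render_field(truth$field, camera,
                        pixel_size_nm = truth$preset$optics$pixel_size_nm,
                        exposure_time_s = truth$preset$exposure_time_s)
  stack
}

#' Render measurements from an expected photon field
#'
#' Lower-level version of [render_stack()] taking a bare `photon_field`.
#'
#' @param field A `photon_field`.
#' @param camera Camera model.
#' @param pixel_size_nm,exposure_time_s Acquisition metadata for the
#'   returned stack.
#' @return An [image_stack()].
#' @export
render_field <- function(field, camera, pixel_size_nm, exposure_time_s) {
  u <- field$u
  n <- length(u)
  vals <- if (inherits(camera, "camera_spad")) {
    array(stats::rbinom(n, 1L, -expm1(-u)), dim = dim(u))
  } else {
    g <- camera$em_gain
    sd <- sqrt(camera$excess_noise_factor_sq * g^2 * u + camera$read_noise_sd^2)
    w <- stats::rnorm(n, camera$offset + g * u, sd)
    array(round(pmax(w, 0)), dim = dim(u))
  }
  image_stack(vals, pixel_size_nm, exposure_time_s)
}
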