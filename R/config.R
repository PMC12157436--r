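# Run configuration: one strict JSON document driving the CLI workflows.

.cfg_keys <- list(
  top = c("seed", "paths", "simulation", "optics", "camera", "priors",
          "sampler", "bench"),
  paths = c("stack", "metadata", "output_dir", "truth"),
  simulation = c("variant", "level", "frame_size", "n_frames", "n_particles",
                 "diffusion_um2s", "center_pixel_photons", "background_rate",
                 "exposure_time_s"),
  optics = c("numerical_aperture", "refractive_index",
             "emission_wavelength_nm", "pixel_size_nm", "psf_sigma_nm"),
  camera = c("type", "offset", "em_gain", "read_noise_sd",
             "excess_noise_factor_sq"),
  priors = c("msd_shape", "msd_scale", "load_prob"),
  sampler = c("n_iterations", "burn_in", "thin", "n_candidates", "brightness",
              "background_rate", "msd_init", "parametric_mode", "proposal",
              "rw_scale_nm", "infer_background", "infer_brightness",
              "checkpoint_every", "checkpoint_path", "resume_from",
              "audit_every"),
  bench = c("iterations", "warmup")
)

.check_keys <- function(x, section) {
  allowed <- .cfg_keys[[section]]
  unknown <- setdiff(names(x), allowed)
  .assert(length(unknown) == 0L,
          sprintf("unknown key(s) in config section '%s': %s", section,
                  paste(unknown, collapse = ", ")))
  invisible(x)
}

#' Read and validate a run configuration
#'
#' Single JSON document with sections `seed`, `paths`, `simulation`,
#' `optics`, `camera`, `priors`, `sampler`, `bench`. Unknown keys anywhere
#' are rejected with an error naming the key. All randomness of a CLI run
#' flows from the single `seed`.
#'
#' @param path JSON file path, or a list already in memory.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    path
  }
  .check_keys(cfg, "top")
  for (sec in intersect(names(cfg), names(.cfg_keys)[-1L])) {
    .check_keys(cfg[[sec]], sec)
  }
  .assert(!is.null(cfg$seed) && .is_count(cfg$seed, min = 0L),
          "config must contain an integer seed")
  structure(cfg, class = "run_config")
}

#' Serialize a run configuration
#'
#' @param cfg A `run_config` (or plain list).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

config_optics <- function(block) {
  .check_keys(block, "optics")
  optics_config(
    numerical_aperture = block$numerical_aperture,
    refractive_index = block$refractive_index,
    emission_wavelength_nm = block$emission_wavelength_nm,
    pixel_size_nm = block$pixel_size_nm,
    psf_sigma_nm = block$psf_sigma_nm %||% NULL
  )
}

config_camera <- function(block) {
  .check_keys(block, "camera")
  .assert(!is.null(block$type) && block$type %in% c("emccd", "spad"),
          "camera block: 'type' must be \"emccd\" or \"spad\"")
  if (block$type == "spad") {
    extra <- setdiff(names(block), "type")
    .assert(length(extra) == 0L,
            sprintf("camera block: SPAD takes no parameter(s): %s",
                    paste(extra, collapse = ", ")))
    camera_spad()
  } else {
    camera_emccd(offset = block$offset %||% 100,
                 em_gain = block$em_gain %||% 100,
                 read_noise_sd = block$read_noise_sd %||% 2,
                 excess_noise_factor_sq = block$excess_noise_factor_sq %||% 2)
  }
}

camera_to_block <- function(camera) {
  if (inherits(camera, "camera_spad")) list(type = "spad")
  else list(type = "emccd", offset = camera$offset, em_gain = camera$em_gain,
            read_noise_sd = camera$read_noise_sd,
            excess_noise_factor_sq = camera$excess_noise_factor_sq)
}

optics_to_block <- function(optics) {
  list(numerical_aperture = optics$numerical_aperture,
       refractive_index = optics$refractive_index,
       emission_wavelength_nm = optics$emission_wavelength_nm,
       pixel_size_nm = optics$pixel_size_nm,
       psf_sigma_nm = optics$psf_sigma_nm)
}

config_preset <- function(cfg) {
  sim <- cfg$simulation %||% list()
  .check_keys(sim, "simulation")
  if (!is.null(sim$variant)) {
    preset <- make_preset(sim$variant, level = sim$level %||% NULL,
                          frame_size = sim$frame_size %||% 128L,
                          n_frames = sim$n_frames %||% 10L,
                          n_particles = sim$n_particles %||% 10L,
                          seed = cfg$seed)
    # explicit fields override the preset series
    for (f in c("diffusion_um2s", "center_pixel_photons", "background_rate",
                "exposure_time_s")) {
      if (!is.null(sim[[f]])) preset[[f]] <- sim[[f]]
    }
    if (!is.null(cfg$camera)) preset$camera <- config_camera(cfg$camera)
    if (!is.null(cfg$optics)) preset$optics <- config_optics(cfg$optics)
    preset
  } else {
    .assert(!is.null(cfg$optics) && !is.null(cfg$camera),
            "config needs either simulation$variant or explicit optics + camera")
    simulation_preset(
      optics = config_optics(cfg$optics), camera = config_camera(cfg$camera),
      n_frames = sim$n_frames %||% 10L, frame_size = sim$frame_size %||% 32L,
      n_particles = sim$n_particles %||% 1L,
      diffusion_um2s = sim$diffusion_um2s %||% 0.1,
      center_pixel_photons = sim$center_pixel_photons %||% 80,
      background_rate = sim$background_rate %||% 3,
      exposure_time_s = sim$exposure_time_s %||% 0.033,
      seed = cfg$seed)
  }
}
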