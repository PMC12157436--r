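#' Geweke joint-distribution check of the Gibbs sampler
#'
#' Classic "getting it right" sampler validation: compares forward
#' simulation from the prior against a successive-conditional chain that
#' alternates (a) redrawing the data from the emission model given the
#' current parameters and (b) one full Gibbs sweep given the data. If the
#' sampler targets the correct conditionals, both procedures sample the
#' same joint distribution, so the means of any test function must agree.
#' Reported test functions: MSD, the emitter count `M`, the mean x
#' position and the mean squared x position over all candidates and frames.
#'
#' The chain side uses batch-means standard errors to account for
#' autocorrelation. Use a prior with finite second moments for the MSD
#' (shape > 2), otherwise the z-score is meaningless.
#'
#' @param optics An [optics_config()].
#' @param camera Camera model.
#' @param priors An [spt_priors()].
#' @param n_frames,frame_size Geometry of the synthetic data.
#' @param n_candidates Candidates `K`.
#' @param brightness,background_rate Emission model constants.
#' @param n_samples Iterations on each side.
#' @param exposure_time_s Nominal exposure for the rendered stacks.
#' @return List with `z` (named z-scores), `forward` and `chain` (matrices
#'   of test-function draws).
#' @export
geweke_check <- function(optics, camera, priors, n_frames, frame_size,
                         n_candidates, brightness, background_rate,
                         n_samples = 20000L, exposure_time_s = 0.033) {
  nx <- frame_size[1L]
  ny <- if (length(frame_size) > 1L) frame_size[2L] else frame_size[1L]
  k <- n_candidates
  test_fns <- function(positions, loads, msd) {
    c(msd = msd, m = sum(loads),
      mean_x = mean(positions[, , 1L]),
      mean_x2 = mean(positions[, , 1L]^2))
  }
  draw_prior <- function() {
    msd <- rinvgamma(1L, priors$msd_shape, priors$msd_scale)
    loads <- as.integer(stats::runif(k) < priors$load_prob)
    pos <- sample_tracks_prior(k, n_frames, motion_params(msd), priors)
    list(pos = pos, loads = loads, msd = msd)
  }

  # forward side: i.i.d. draws from the prior (data never needed)
  forward <- matrix(NA_real_, n_samples, 4L)
  for (i in seq_len(n_samples)) {
    d <- draw_prior()
    forward[i, ] <- test_fns(d$pos, d$loads, d$msd)
  }

  # successive-conditional side: resample data, then one Gibbs sweep
  config <- sampler_config(n_iterations = n_samples, seed = 1L,
                           n_candidates = k, brightness = brightness,
                           background_rate = background_rate)
  d <- draw_prior()
  px <- optics$pixel_size_nm
  stack0 <- image_stack(array(0, dim = c(nx, ny, n_frames)), px,
                        exposure_time_s)
  state <- chain_state(candidate_set(d$pos, d$loads), motion_params(d$msd),
                       stack0, camera, optics, brightness, background_rate)
  npx <- nx * ny
  chain <- matrix(NA_real_, n_samples, 4L)
  for (i in seq_len(n_samples)) {
    field <- structure(list(u = state$u, background_rate = background_rate,
                            h = brightness), class = "photon_field")
    stack <- render_field(field, camera, px, exposure_time_s)
    # only the cached log-likelihood depends on the data
    state$llf <- colSums(matrix(loglike_pixels(stack$values, state$u, camera),
                                nrow = npx))
    state <- gibbs_sweep(state, stack, camera, priors, config)
    chain[i, ] <- test_fns(state$positions, state$loads,
                           state$motion$msd_per_frame_nm2)
  }

  nm <- c("msd", "m", "mean_x", "mean_x2")
  colnames(forward) <- nm
  colnames(chain) <- nm
  z <- vapply(seq_len(4L), function(j) {
    se_f <- stats::sd(forward[, j]) / sqrt(n_samples)
    se_c <- batch_means_se(chain[, j])
    (mean(forward[, j]) - mean(chain[, j])) / sqrt(se_f^2 + se_c^2)
  }, numeric(1L))
  names(z) <- nm
  list(z = z, forward = forward, chain = chain)
}
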