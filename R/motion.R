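#' Brownian motion parameters
#'
#' The motion prior is an isotropic Gaussian random walk: per frame interval
#' each axis moves by `Normal(0, s)` with per-axis step variance
#' `s = msd_per_frame / 2` (2-D convention `MSD = 4 D dt`, so
#' `s = 2 D dt`).
#'
#' @param msd_per_frame_nm2 Two-dimensional mean squared displacement per
#'   frame interval, nm^2; `> 0`.
#' @return Object of class `motion_params` with fields `msd_per_frame_nm2`
#'   and `step_var_nm2` (per axis).
#' @export
motion_params <- function(msd_per_frame_nm2) {
  .assert(.is_scalar(msd_per_frame_nm2) && msd_per_frame_nm2 > 0,
          "msd_per_frame_nm2 must be > 0")
  structure(list(msd_per_frame_nm2 = msd_per_frame_nm2,
                 step_var_nm2 = msd_per_frame_nm2 / 2),
            class = "motion_params")
}

#' Prior specification for the tracking model
#'
#' @param msd_shape Inverse-gamma shape for the MSD prior; `> 0`.
#' @param msd_scale Inverse-gamma scale for the MSD prior, nm^2; `> 0`.
#' @param load_prob Prior emission probability of each candidate
#'   (i.i.d. Bernoulli loads), in `[0, 1]`.
#' @param fov_bounds Field of view as `c(xmin, xmax, ymin, ymax)` in nm;
#'   initial positions are uniform on this rectangle.
#' @return Object of class `spt_priors`.
#' @export
spt_priors <- function(msd_shape = 2, msd_scale, load_prob, fov_bounds) {
  .assert(.is_scalar(msd_shape) && msd_shape > 0, "msd_shape must be > 0")
  .assert(.is_scalar(msd_scale) && msd_scale > 0, "msd_scale must be > 0")
  .assert(.is_scalar(load_prob) && load_prob >= 0 && load_prob <= 1,
          "load_prob must be in [0, 1]")
  .assert(is.numeric(fov_bounds) && length(fov_bounds) == 4L &&
            all(is.finite(fov_bounds)) &&
            fov_bounds[2L] > fov_bounds[1L] && fov_bounds[4L] > fov_bounds[3L],
          "fov_bounds must be c(xmin, xmax, ymin, ymax) with positive extent")
  structure(list(msd_shape = msd_shape, msd_scale = msd_scale,
                 load_prob = load_prob, fov_bounds = fov_bounds),
            class = "spt_priors")
}

fov_area <- function(priors) {
  (priors$fov_bounds[2L] - priors$fov_bounds[1L]) *
    (priors$fov_bounds[4L] - priors$fov_bounds[3L])
}

in_fov <- function(xy, priors) {
  b <- priors$fov_bounds
  xy[1L] >= b[1L] && xy[1L] <= b[2L] && xy[2L] >= b[3L] && xy[2L] <= b[4L]
}

#' Candidate particle set
#'
#' `K` latent candidate tracks over `N` frames together with their binary
#' loads; only loaded (active) candidates contribute photons, the remainder
#' are invisible placeholders whose tracks still follow the motion prior.
#'
#' @param positions `N x K x 2` array of positions in nm.
#' @param loads Binary vector of length `K`.
#' @return Object of class `candidate_set` with fields `positions`, `loads`,
#'   `n_frames`, `n_candidates`, `n_active`.
#' @export
candidate_set <- function(positions, loads) {
  .assert(is.array(positions) && length(dim(positions)) == 3L &&
            dim(positions)[3L] == 2L, "positions must be N x K x 2")
  .assert(all(is.finite(positions)), "positions must be finite")
  k <- dim(positions)[2L]
  .assert(length(loads) == k && all(loads %in% c(0, 1)),
          "loads must be binary, one per candidate")
  structure(list(positions = positions, loads = as.integer(loads),
                 n_frames = dim(positions)[1L], n_candidates = k,
                 n_active = sum(loads)),
            class = "candidate_set")
}

#' Log density of the motion prior
#'
#' Sum over all candidates (active and inactive) of a uniform-FOV initial
#' term and Gaussian increment terms with per-axis variance
#' `msd_per_frame / 2`. Returns `-Inf` if any initial position falls outside
#' the field of view.
#'
#' @param candidates A [candidate_set()].
#' @param motion A [motion_params()].
#' @param priors An [spt_priors()].
#' @return Scalar log density.
#' @export
log_motion_prior <- function(candidates, motion, priors) {
  pos <- candidates$positions
  .assert(all(is.finite(pos)), "positions must be finite")
  n <- candidates$n_frames
  k <- candidates$n_candidates
  lp <- -k * log(fov_area(priors))
  for (m in seq_len(k)) {
    if (!in_fov(pos[1L, m, ], priors)) return(-Inf)
  }
  if (n >= 2L) {
    inc <- pos[-1L, , , drop = FALSE] - pos[-n, , , drop = FALSE]
    lp <- lp + sum(stats::dnorm(inc, 0, sqrt(motion$step_var_nm2), log = TRUE))
  }
  lp
}

#' Simulate candidate tracks from the motion prior
#'
#' Initial positions uniform on the FOV (or a caller-supplied sub-rectangle),
#' increments i.i.d. `Normal(0, msd_per_frame / 2)` per axis. Uses the
#' global R random number generator; seed with `set.seed()` for
#' reproducibility.
#'
#' @param n_candidates,n_frames Counts, `>= 1`.
#' @param motion A [motion_params()].
#' @param priors An [spt_priors()] (supplies the FOV).
#' @param init_bounds Optional `c(xmin, xmax, ymin, ymax)` overriding the
#'   initial-position rectangle (used by the simulator to avoid edges).
#' @return `N x K x 2` array of positions in nm.
#' @export
sample_tracks_prior <- function(n_candidates, n_frames, motion, priors,
                                init_bounds = NULL) {
  .assert(.is_count(n_candidates), "n_candidates must be a positive count")
  .assert(.is_count(n_frames), "n_frames must be a positive count")
  b <- if (is.null(init_bounds)) priors$fov_bounds else init_bounds
  pos <- array(0, dim = c(n_frames, n_candidates, 2L))
  sd_step <- sqrt(motion$step_var_nm2)
  for (m in seq_len(n_candidates)) {
    pos[1L, m, 1L] <- stats::runif(1L, b[1L], b[2L])
    pos[1L, m, 2L] <- stats::runif(1L, b[3L], b[4L])
    if (n_frames >= 2L) {
      steps <- matrix(stats::rnorm(2L * (n_frames - 1L), 0, sd_step),
                      ncol = 2L)
      pos[-1L, m, 1L] <- pos[1L, m, 1L] + cumsum(steps[, 1L])
      pos[-1L, m, 2L] <- pos[1L, m, 2L] + cumsum(steps[, 2L])
    }
  }
  pos
}

#' Gaussian bridge conditional for one frame
#'
#' Exact conditional distribution of a random-walk position given its
#' temporal neighbors: with both neighbors present the conditional is
#' `Normal((x_prev + x_next)/2, s/2)` per axis; with a single neighbor it is
#' `Normal(that neighbor, s)` (the flat initial prior is absorbed). This is
#' the proposal used by the checkerboard track update, for which the prior
#' term cancels in the Metropolis ratio.
#'
#' @param x_prev,x_next Neighbor positions (numeric length-2) or `NULL` if
#'   absent. At least one must be present.
#' @param motion A [motion_params()].
#' @return List with `mean` (length 2, nm) and `var` (scalar per-axis
#'   variance, nm^2).
#' @export
bridge_conditional <- function(x_prev, x_next, motion) {
  s <- motion$step_var_nm2
  if (!is.null(x_prev) && !is.null(x_next)) {
    list(mean = (x_prev + x_next) / 2, var = s / 2)
  } else if (!is.null(x_prev)) {
    list(mean = x_prev, var = s)
  } else if (!is.null(x_next)) {
    list(mean = x_next, var = s)
  } else {
    stop("bridge_conditional: both neighbors absent", call. = FALSE)
  }
}

#' Conjugate conditional for the mean squared displacement
#'
#' With per-axis increments `Normal(0, MSD/2)` and an
#' `InverseGamma(shape, scale)` prior on MSD, the full conditional is
#' `InverseGamma(shape + K (N-1) d / 2, scale + sum(increments^2))` where the
#' sum runs over both axes, all frame steps, and all `K` candidates (active
#' and inactive; inactive tracks also follow the motion prior). Note the
#' scale gains the plain sum of squared increments, not half of it, because
#' the per-axis variance is `MSD/2`.
#'
#' @param candidates A [candidate_set()].
#' @param priors An [spt_priors()].
#' @return List with `shape` and `scale` of the conditional inverse-gamma.
#' @export
msd_conditional_params <- function(candidates, priors) {
  n <- candidates$n_frames
  if (n < 2L) {
    return(list(shape = priors$msd_shape, scale = priors$msd_scale))
  }
  pos <- candidates$positions
  inc <- pos[-1L, , , drop = FALSE] - pos[-n, , , drop = FALSE]
  .assert(all(is.finite(inc)), "non-finite increments")
  k <- candidates$n_candidates
  list(shape = priors$msd_shape + k * (n - 1L) * 2L / 2,
       scale = priors$msd_scale + sum(inc^2))
}

# Inverse-gamma sampler: X ~ IG(shape, scale) iff 1/X ~ Gamma(shape, rate = scale).
rinvgamma <- function(n, shape, scale) {
  1 / stats::rgamma(n, shape = shape, rate = scale)
}
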