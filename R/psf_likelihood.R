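#' Gaussian mass on a strip
#'
#' Integral of a 1-D normal density with the given center and variance over
#' the interval `[lo, hi]` ("error-function strip integral"). This is the
#' basic building block of the pixel-integrated PSF model: the expected
#' photon count of one particle at one pixel is a product of an x-strip and
#' a y-strip integral.
#'
#' @param center Gaussian center (nm). Vectorized.
#' @param lo,hi Strip edges (nm), `hi > lo`.
#' @param variance Gaussian variance (nm^2), `> 0`.
#' @return Probability mass in `[0, 1]`.
#' @export
erf_strip_integral <- function(center, lo, hi, variance) {
  .assert(all(is.finite(variance)) && all(variance > 0),
          "variance must be positive")
  .assert(all(hi > lo), "hi must exceed lo")
  sd <- sqrt(variance)
  stats::pnorm(hi, center, sd) - stats::pnorm(lo, center, sd)
}

# Strip integrals of every pixel along one axis for a set of particle
# coordinates: returns an n_pixels x M matrix whose [p, m] entry is the mass
# of particle m's PSF over pixel strip p. Hot path; standardized pnorm.
axis_strip_matrix <- function(coords, n_pixels, pixel_size_nm, sigma_nm) {
  edges <- (0:n_pixels) * pixel_size_nm
  z <- outer(edges, coords, "-") / sigma_nm
  p <- stats::pnorm(z)
  p[-1L, , drop = FALSE] - p[-(n_pixels + 1L), , drop = FALSE]
}

#' Expected photon field from active candidate tracks
#'
#' Computes the expected photon count `u[i, j, n]` at every pixel of every
#' frame: a flat background plus, for each active candidate, the brightness
#' `h` times the product of pixel-integrated Gaussian PSF masses along x and
#' y. Per frame this is the rank-`M` matrix product `h U_x U_y^T` with
#' `U_x[i, m]` the x strip integral of particle `m` over pixel column `i`;
#' the frames are independent, so the whole stack is a batch of such
#' products. Candidates with load 0 do not contribute.
#'
#' @param positions `N x K x 2` array of candidate positions in nm
#'   (`positions[n, m, ]` = (x, y) of candidate `m` in frame `n`).
#' @param loads Binary vector of length `K`.
#' @param h Brightness: expected photons at a pixel concentric with an
#'   in-focus particle, divided by the squared centered-pixel strip mass
#'   (see [calibrate_brightness()]); `>= 0`.
#' @param background_rate Flat background, photons/pixel/frame; `>= 0`.
#' @param optics An [optics_config()].
#' @param n_x,n_y Frame size in pixels (I columns along x, J rows along y).
#' @return Object of class `photon_field`: list with `u` (`I x J x N`
#'   array), `background_rate`, `h`.
#' @export
expected_photons <- function(positions, loads, h, background_rate,
                             optics, n_x, n_y) {
  .assert(is.array(positions) && length(dim(positions)) == 3L &&
            dim(positions)[3L] == 2L, "positions must be N x K x 2")
  .assert(.is_scalar(h) && h >= 0, "h must be >= 0")
  .assert(.is_scalar(background_rate) && background_rate >= 0,
          "background_rate must be >= 0")
  n_frames <- dim(positions)[1L]
  k <- dim(positions)[2L]
  .assert(length(loads) == k && all(loads %in% c(0, 1)),
          "loads must be binary, one per candidate")
  sigma <- psf_sigma(optics)
  px <- optics$pixel_size_nm
  u <- array(background_rate, dim = c(n_x, n_y, n_frames))
  active <- which(loads == 1)
  if (length(active) > 0L && h > 0) {
    for (n in seq_len(n_frames)) {
      ux <- axis_strip_matrix(positions[n, active, 1L], n_x, px, sigma)
      uy <- axis_strip_matrix(positions[n, active, 2L], n_y, px, sigma)
      u[, , n] <- u[, , n] + h * tcrossprod(ux, uy)
    }
  }
  structure(list(u = u, background_rate = background_rate, h = h),
            class = "photon_field")
}

#' Serial per-pixel oracle for the expected photon field
#'
#' Same contract as [expected_photons()], evaluated with an explicit triple
#' loop over (frame, pixel column, pixel row) and per-particle calls to
#' [erf_strip_integral()]. Intentionally slow; used as an independent check
#' of the batched path on small instances.
#'
#' @inheritParams expected_photons
#' @return A `photon_field`, identical in meaning to [expected_photons()].
#' @export
expected_photons_serial <- function(positions, loads, h, background_rate,
                                    optics, n_x, n_y) {
  .assert(.is_scalar(h) && h >= 0, "h must be >= 0")
  .assert(.is_scalar(background_rate) && background_rate >= 0,
          "background_rate must be >= 0")
  n_frames <- dim(positions)[1L]
  v <- optics$psf_variance_nm2
  px <- optics$pixel_size_nm
  active <- which(loads == 1)
  u <- array(background_rate, dim = c(n_x, n_y, n_frames))
  for (n in seq_len(n_frames)) {
    for (i in seq_len(n_x)) {
      for (j in seq_len(n_y)) {
        acc <- 0
        for (m in active) {
          mx <- erf_strip_integral(positions[n, m, 1L], (i - 1) * px, i * px, v)
          my <- erf_strip_integral(positions[n, m, 2L], (j - 1) * px, j * px, v)
          acc <- acc + mx * my
        }
        u[i, j, n] <- u[i, j, n] + h * acc
      }
    }
  }
  structure(list(u = u, background_rate = background_rate, h = h),
            class = "photon_field")
}

#' SPAD per-pixel log-likelihood
#'
#' Bernoulli read-out: a pixel with expected photon count `u` fires with
#' probability `1 - exp(-u)`. `w = 0` contributes exactly `-u`; `w = 1`
#' contributes `log(1 - exp(-u))`, computed stably. `w = 1` with `u = 0`
#' yields `-Inf` (an impossible observation), never `NaN`.
#'
#' @param w Binary measurements (vectorized).
#' @param u Expected photons, `>= 0` (vectorized, recycled against `w`).
#' @return Log-probabilities.
#' @export
loglike_spad <- function(w, u) {
  .assert(all(w %in% c(0, 1)), "SPAD measurements must be binary")
  .assert(all(u >= 0), "expected photons must be >= 0")
  n <- max(length(w), length(u))
  w <- rep_len(w, n)
  u <- rep_len(u, n)
  out <- -u
  on <- w == 1
  out[on] <- log1mexp(u[on])
  out
}

#' EMCCD per-pixel log-likelihood
#'
#' Gaussian read-out model: `w ~ Normal(offset + G u, F^2 G^2 u +
#' sigma_read^2)` in ADU.
#'
#' @param w Measurements in ADU (vectorized).
#' @param u Expected photons, `>= 0`.
#' @param camera A [camera_emccd()].
#' @return Log-densities.
#' @export
loglike_emccd <- function(w, u, camera) {
  .assert(inherits(camera, "camera_emccd"), "expected a camera_emccd")
  .assert(all(u >= 0), "expected photons must be >= 0")
  g <- camera$em_gain
  v <- camera$excess_noise_factor_sq * g^2 * u + camera$read_noise_sd^2
  .assert(all(v > 0),
          "EMCCD variance must be positive (read_noise_sd > 0 required when u can be 0)")
  stats::dnorm(w, camera$offset + g * u, sqrt(v), log = TRUE)
}

# Dispatch helper used on the sampler hot path (no per-call validation).
loglike_pixels <- function(w, u, camera) {
  if (inherits(camera, "camera_spad")) {
    out <- -u
    on <- w == 1
    out[on] <- log1mexp(u[on])
    out
  } else {
    g <- camera$em_gain
    v <- camera$excess_noise_factor_sq * g^2 * u + camera$read_noise_sd^2
    stats::dnorm(w, camera$offset + g * u, sqrt(v), log = TRUE)
  }
}

#' Whole-stack log-likelihood
#'
#' Sums the per-pixel log-likelihood over every pixel and frame; pixels and
#' frames are conditionally independent given the expected photon field, so
#' the total factorizes into per-frame subtotals.
#'
#' @param stack An [image_stack()].
#' @param field A `photon_field` with matching dimensions.
#' @param camera Camera model.
#' @return List with `total` (scalar) and `per_frame` (length-N vector).
#'   `-Inf` pixels propagate to `-Inf` subtotals; `NaN` never occurs.
#' @export
stack_loglike <- function(stack, field, camera) {
  .assert(inherits(stack, "image_stack"), "expected an image_stack")
  .assert(inherits(field, "photon_field"), "expected a photon_field")
  .assert(identical(dim(stack$values), dim(field$u)),
          "stack and photon field shapes differ")
  ll <- loglike_pixels(stack$values, field$u, camera)
  .assert(!anyNA(ll), "log-likelihood produced NaN")
  per_frame <- colSums(matrix(ll, nrow = stack$height * stack$width))
  list(total = sum(per_frame), per_frame = per_frame)
}
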