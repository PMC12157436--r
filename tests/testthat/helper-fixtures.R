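# Shared fixtures and small independent oracles, built in code.

toy_optics <- function() optics_config(1.45, 1.515, 665, 133)

toy_fov <- function(n_px, px = 133) c(0, n_px * px, 0, n_px * px)

# centered tracks well inside the FOV (wiggle << distance to the edge)
centered_tracks <- function(n_frames, k, n_px, px = 133, wiggle = 30) {
  ctr <- n_px * px / 2
  pos <- array(ctr, dim = c(n_frames, k, 2L))
  pos + array(stats::rnorm(length(pos), 0, wiggle), dim = dim(pos))
}

# small simulated movie + everything needed to run a chain on it
toy_movie <- function(seed = 3, n_px = 16, n_frames = 6, n_particles = 2,
                      k = 4, load_prob = 0.5) {
  pre <- make_preset("fig2", frame_size = n_px, n_frames = n_frames,
                     n_particles = n_particles, seed = seed)
  truth <- simulate_ground_truth(pre)
  stack <- render_stack(truth)
  priors <- spt_priors(msd_scale = 13200, load_prob = load_prob,
                       fov_bounds = toy_fov(n_px))
  list(preset = pre, truth = truth, stack = stack, priors = priors,
       optics = pre$optics, camera = pre$camera)
}

# independent normal log-density (no dnorm): direct formula
ref_normal_logpdf <- function(x, mean, var) {
  -0.5 * log(2 * pi * var) - (x - mean)^2 / (2 * var)
}

# 2-D tensor-product quadrature of the Gaussian PSF over one pixel
quad_pixel_mass <- function(xc, yc, x_lo, x_hi, y_lo, y_hi, v) {
  fx <- stats::integrate(function(q) exp(-(q - xc)^2 / (2 * v)) / sqrt(2 * pi * v),
                         x_lo, x_hi, rel.tol = 1e-12)$value
  fy <- stats::integrate(function(q) exp(-(q - yc)^2 / (2 * v)) / sqrt(2 * pi * v),
                         y_lo, y_hi, rel.tol = 1e-12)$value
  fx * fy
}

# brute-force optimal one-to-one matching oracle via permutations
perm_match_oracle <- function(truth, est, radius) {
  nt <- nrow(truth)
  ne <- nrow(est)
  dmat <- sqrt(outer(truth[, 1], est[, 1], "-")^2 +
                 outer(truth[, 2], est[, 2], "-")^2)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- c(matches = -1, cost = Inf)
  n <- min(nt, ne)
  for (p in perms(seq_len(nt))) {
    # assign truth p[i] to estimate i (extra of either side unmatched)
    cnt <- 0; cost <- 0
    for (i in seq_len(n)) {
      if (dmat[p[i], i] <= radius) {
        cnt <- cnt + 1
        cost <- cost + dmat[p[i], i]
      }
    }
    if (cnt > best["matches"] ||
        (cnt == best["matches"] && cost < best["cost"])) {
      best <- c(matches = cnt, cost = cost)
    }
  }
  best
}

run_sweeps <- function(x, n_sweeps, k = 4, seed = 42, config = NULL,
                       msd0 = 13200) {
  set.seed(seed)
  config <- config %||% sampler_config(
    n_iterations = max(n_sweeps, 1L), seed = seed, n_candidates = k,
    brightness = x$truth$h, background_rate = x$truth$background_rate)
  mot <- motion_params(msd0)
  pos <- sample_tracks_prior(k, x$stack$n_frames, mot, x$priors)
  state <- chain_state(candidate_set(pos, rep(0L, k)), mot, x$stack,
                       x$camera, x$optics, x$truth$h,
                       x$truth$background_rate)
  for (i in seq_len(n_sweeps)) {
    state <- gibbs_sweep(state, x$stack, x$camera, x$priors, config)
  }
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a
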