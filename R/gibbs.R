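`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sampler configuration
#'
#' Plumbing for [run_chain()]: chain length, burn-in, thinning, seed, the
#' number of candidate particles, fixed model constants (brightness,
#' background) and mode flags. In parametric mode all `K` loads are fixed at
#' 1 (the emitter count is known); in nonparametric mode loads are sampled
#' and the emitter count `M` is inferred.
#'
#' @param n_iterations Total Gibbs sweeps.
#' @param burn_in Discarded initial sweeps; `burn_in == n_iterations` is
#'   the legal boundary yielding an empty retained-sample set.
#' @param thin Keep every `thin`-th post-burn-in sweep; `>= 1`.
#' @param seed Master seed; every random draw of the chain flows from it.
#' @param n_candidates Number of candidate particles `K`.
#' @param brightness Particle brightness `h` (photons; see
#'   [calibrate_brightness()]).
#' @param background_rate Flat background, photons/pixel/frame.
#' @param msd_init Initial MSD (nm^2/frame); default is the prior mean (or
#'   the prior scale when the prior mean is undefined).
#' @param parametric_mode If `TRUE`, loads stay fixed at 1.
#' @param proposal `"bridge"` (prior-conditional Gaussian bridge; the prior
#'   cancels in the Metropolis ratio) or `"rw"` (random walk).
#' @param rw_scale_nm Random-walk proposal scale (nm), used when
#'   `proposal = "rw"`.
#' @param infer_background,infer_brightness Optional scalar random-walk
#'   Metropolis moves on the log of the background / brightness, with Gamma
#'   priors; both off by default.
#' @param bg_prior,h_prior Gamma prior as `c(shape, rate)` for the optional
#'   background / brightness moves; defaults are set at chain start so the
#'   prior mean equals the configured initial value.
#' @param mh_scale Log-scale proposal standard deviation for the optional
#'   background/brightness moves.
#' @param checkpoint_every,checkpoint_path Write a resumable checkpoint
#'   (RDS) every so many sweeps.
#' @param audit_every If `> 0`, recompute the cached photon field and
#'   per-frame log-likelihoods from scratch every so many sweeps and stop if
#'   they drifted by more than 1e-6.
#' @return Object of class `sampler_config`.
#' @export
sampler_config <- function(n_iterations, burn_in = 0L, thin = 1L, seed = 1L,
                           n_candidates, brightness, background_rate,
                           msd_init = NULL, parametric_mode = FALSE,
                           proposal = c("bridge", "rw"), rw_scale_nm = 50,
                           infer_background = FALSE, infer_brightness = FALSE,
                           bg_prior = NULL, h_prior = NULL, mh_scale = 0.1,
                           checkpoint_every = NULL, checkpoint_path = NULL,
                           audit_every = 0L) {
  proposal <- match.arg(proposal)
  .assert(.is_count(n_iterations), "n_iterations must be a positive count")
  .assert(.is_count(burn_in, min = 0L), "burn_in must be a non-negative count")
  # burn_in == n_iterations is the legal boundary: a valid run with an
  # empty retained-sample set
  .assert(burn_in <= n_iterations, "burn_in must be <= n_iterations")
  .assert(.is_count(thin), "thin must be >= 1")
  .assert(.is_count(n_candidates), "n_candidates must be >= 1")
  .assert(.is_scalar(brightness) && brightness >= 0, "brightness must be >= 0")
  .assert(.is_scalar(background_rate) && background_rate >= 0,
          "background_rate must be >= 0")
  structure(list(
    n_iterations = as.integer(n_iterations), burn_in = as.integer(burn_in),
    thin = as.integer(thin), seed = as.integer(seed),
    n_candidates = as.integer(n_candidates), brightness = brightness,
    background_rate = background_rate, msd_init = msd_init,
    parametric_mode = isTRUE(parametric_mode), proposal = proposal,
    rw_scale_nm = rw_scale_nm,
    infer_background = isTRUE(infer_background),
    infer_brightness = isTRUE(infer_brightness),
    bg_prior = bg_prior, h_prior = h_prior, mh_scale = mh_scale,
    checkpoint_every = checkpoint_every, checkpoint_path = checkpoint_path,
    audit_every = as.integer(audit_every)
  ), class = "sampler_config")
}

#' Gibbs chain state
#'
#' One state of the sampler: candidate tracks, loads, MSD, background,
#' brightness, plus preallocated workspace caches — per-axis strip-integral
#' matrices for every candidate and frame, the expected photon field of the
#' active candidates, and per-frame log-likelihoods. The caches are
#' maintained incrementally by the update moves and are auditable against a
#' fresh recomputation (see [audit_chain_state()]).
#'
#' @param candidates A [candidate_set()].
#' @param motion A [motion_params()].
#' @param stack An [image_stack()].
#' @param camera Camera model.
#' @param optics An [optics_config()].
#' @param brightness Brightness `h` in photons.
#' @param background_rate Background photons/pixel/frame.
#' @return Object of class `chain_state`.
#' @export
chain_state <- function(candidates, motion, stack, camera, optics,
                        brightness, background_rate) {
  .assert(inherits(candidates, "candidate_set"), "expected a candidate_set")
  .assert(candidates$n_frames == stack$n_frames,
          "candidate set and stack disagree on frame count")
  state <- list(
    positions = candidates$positions, loads = candidates$loads,
    motion = motion, background = background_rate, h = brightness,
    k = candidates$n_candidates, n_frames = stack$n_frames,
    nx = stack$height, ny = stack$width,
    px = stack$pixel_size_nm, sigma = psf_sigma(optics),
    edges_x = (0:stack$height) * stack$pixel_size_nm,
    edges_y = (0:stack$width) * stack$pixel_size_nm,
    iteration = 0L,
    prop_count = numeric(candidates$n_candidates),
    acc_count = numeric(candidates$n_candidates),
    frame_touch = numeric(stack$n_frames)
  )
  class(state) <- "chain_state"
  recompute_state_caches(state, stack, camera)
}

#' Rebuild the cached photon field and log-likelihoods from scratch
#'
#' @param state A `chain_state`.
#' @param stack,camera Data and camera model.
#' @return The state with fresh `ux`, `uy`, `u` and per-frame
#'   log-likelihood caches.
#' @export
recompute_state_caches <- function(state, stack, camera) {
  nf <- state$n_frames
  state$ux <- array(0, dim = c(state$nx, state$k, nf))
  state$uy <- array(0, dim = c(state$ny, state$k, nf))
  for (n in seq_len(nf)) {
    state$ux[, , n] <- axis_strip_matrix(state$positions[n, , 1L], state$nx,
                                         state$px, state$sigma)
    state$uy[, , n] <- axis_strip_matrix(state$positions[n, , 2L], state$ny,
                                         state$px, state$sigma)
  }
  state$u <- array(state$background, dim = c(state$nx, state$ny, nf))
  active <- which(state$loads == 1L)
  if (length(active) > 0L && state$h > 0) {
    for (n in seq_len(nf)) {
      uxa <- matrix(state$ux[, active, n], ncol = length(active))
      uya <- matrix(state$uy[, active, n], ncol = length(active))
      state$u[, , n] <- state$u[, , n] + state$h * tcrossprod(uxa, uya)
    }
  }
  ll <- loglike_pixels(stack$values, state$u, camera)
  state$llf <- colSums(matrix(ll, nrow = state$nx * state$ny))
  state
}

#' Audit the incremental caches
#'
#' Recomputes the expected photon field and per-frame log-likelihoods from
#' scratch and reports the largest absolute discrepancy against the cached
#' values. Guards the incremental rank-1 updates.
#'
#' @inheritParams recompute_state_caches
#' @return Named numeric: max abs drift of `u` and of the per-frame
#'   log-likelihoods.
#' @export
audit_chain_state <- function(state, stack, camera) {
  fresh <- recompute_state_caches(state, stack, camera)
  c(u = max(abs(fresh$u - state$u)), loglike = max(abs(fresh$llf - state$llf)))
}

#' Checkerboard track update for one parity phase
#'
#' Metropolis-within-Gibbs update of all candidate positions at frames of
#' one parity, holding the opposite parity fixed. Candidates are updated
#' sequentially (the likelihood couples them through the shared photon
#' field); within a candidate, frames of one parity are conditionally
#' independent given the other parity, so they may be processed in any order
#' — per-frame random substreams are pre-assigned in canonical frame order,
#' making the result bit-identical for every `frame_order` permutation.
#'
#' With the default bridge proposal (the exact prior conditional given the
#' fixed neighbors) the motion-prior term cancels and acceptance uses only
#' the likelihood ratio of the touched frame; the flat-FOV initial prior
#' contributes an in-FOV indicator at frame 1. Inactive candidates have
#' likelihood ratio 1, so their proposals are (FOV indicator aside) always
#' accepted: an exact prior refresh.
#'
#' @param state A `chain_state`.
#' @param stack,camera Data and camera model.
#' @param priors An [spt_priors()].
#' @param phase `"odd"` or `"even"` (1-based frame parity).
#' @param frame_order Optional permutation of the phase's frames; result is
#'   independent of it.
#' @param proposal,rw_scale_nm See [sampler_config()].
#' @return Updated `chain_state`.
#' @export
update_tracks_phase <- function(state, stack, camera, priors, phase,
                                frame_order = NULL, proposal = "bridge",
                                rw_scale_nm = 50) {
  .assert(length(phase) == 1L && phase %in% c("odd", "even"),
          "phase must be 'odd' or 'even'")
  nf <- state$n_frames
  frames <- if (phase == "odd") seq(1L, nf, by = 2L) else
    seq.int(2L, length.out = max(0L, (nf %/% 2L)), by = 2L)
  if (length(frames) == 0L) return(state)
  if (is.null(frame_order)) frame_order <- frames
  .assert(length(frame_order) == length(frames) &&
            setequal(frame_order, frames),
          "frame_order must be a permutation of the phase's frames")
  ord_idx <- match(frame_order, frames)
  w <- stack$values
  b <- priors$fov_bounds
  # hot loop: work on local copies of the state fields, write back once
  nx <- state$nx; ny <- state$ny; sigma <- state$sigma; h <- state$h
  ex <- state$edges_x; ey <- state$edges_y
  pos <- state$positions; uxc <- state$ux; uyc <- state$uy
  u <- state$u; llf <- state$llf
  prop_count <- state$prop_count; acc_count <- state$acc_count
  touch <- state$frame_touch
  s <- state$motion$step_var_nm2
  sd_half <- sqrt(s / 2); sd_full <- sqrt(s)
  spad <- inherits(camera, "camera_spad")
  if (!spad) {
    g <- camera$em_gain; offset <- camera$offset
    f2g2 <- camera$excess_noise_factor_sq * g^2
    rn2 <- camera$read_noise_sd^2
  }
  nfr <- length(frames)
  for (m in seq_len(state$k)) {
    # pre-assigned substreams: one (z_x, z_y, u_accept) triple per frame,
    # drawn in canonical frame order before any frame is touched
    z <- matrix(stats::rnorm(2L * nfr), ncol = 2L)
    lua <- log(stats::runif(nfr))
    active <- state$loads[m] == 1L
    for (t in seq_len(nfr)) {
      n <- frame_order[t]
      idx <- ord_idx[t]
      if (nf == 1L) {
        # no temporal neighbors: propose from the uniform initial prior
        prop <- c(b[1L] + (b[2L] - b[1L]) * stats::pnorm(z[idx, 1L]),
                  b[3L] + (b[4L] - b[3L]) * stats::pnorm(z[idx, 2L]))
        log_alpha <- 0
      } else if (proposal == "bridge") {
        if (n == 1L) {
          mu <- pos[2L, m, ]; sdv <- sd_full
        } else if (n == nf) {
          mu <- pos[nf - 1L, m, ]; sdv <- sd_full
        } else {
          mu <- (pos[n - 1L, m, ] + pos[n + 1L, m, ]) / 2; sdv <- sd_half
        }
        prop <- mu + sdv * z[idx, ]
        log_alpha <- if (n == 1L &&
                         !(prop[1L] >= b[1L] && prop[1L] <= b[2L] &&
                           prop[2L] >= b[3L] && prop[2L] <= b[4L])) -Inf else 0
      } else {
        cur <- pos[n, m, ]
        prop <- cur + rw_scale_nm * z[idx, ]
        lp1 <- 0; lp0 <- 0
        if (n == 1L) {
          if (!(prop[1L] >= b[1L] && prop[1L] <= b[2L] &&
                prop[2L] >= b[3L] && prop[2L] <= b[4L])) lp1 <- -Inf
        } else {
          lp1 <- lp1 + sum(stats::dnorm(prop - pos[n - 1L, m, ], 0, sd_full, log = TRUE))
          lp0 <- lp0 + sum(stats::dnorm(cur - pos[n - 1L, m, ], 0, sd_full, log = TRUE))
        }
        if (n < nf) {
          lp1 <- lp1 + sum(stats::dnorm(pos[n + 1L, m, ] - prop, 0, sd_full, log = TRUE))
          lp0 <- lp0 + sum(stats::dnorm(pos[n + 1L, m, ] - cur, 0, sd_full, log = TRUE))
        }
        log_alpha <- lp1 - lp0
      }
      prop_count[m] <- prop_count[m] + 1
      touch[n] <- touch[n] + 1
      if (log_alpha == -Inf) next # rejected before likelihood
      # pixel strip integrals for both axes in one pass
      pz <- stats::pnorm(c(ex - prop[1L], ey - prop[2L]) / sigma)
      ux_new <- pz[2:(nx + 1L)] - pz[1:nx]
      uy_new <- pz[(nx + 3L):(nx + ny + 2L)] - pz[(nx + 2L):(nx + ny + 1L)]
      ll_new <- NULL
      if (active) {
        u_new <- u[, , n] +
          h * (tcrossprod(ux_new, uy_new) - tcrossprod(uxc[, m, n], uyc[, m, n]))
        u_new[u_new < 0] <- 0 # guard float cancellation at zero background
        wn <- w[, , n]
        ll_new <- if (spad) {
          lw <- -u_new
          on <- wn == 1
          lw[on] <- log1mexp(u_new[on])
          sum(lw)
        } else {
          sum(stats::dnorm(wn, offset + g * u_new,
                           sqrt(f2g2 * u_new + rn2), log = TRUE))
        }
        ll_old <- llf[n]
        log_alpha <- if (ll_new == -Inf) -Inf
          else if (ll_old == -Inf) Inf
          else log_alpha + ll_new - ll_old
      }
      if (lua[idx] < log_alpha) {
        pos[n, m, ] <- prop
        uxc[, m, n] <- ux_new
        uyc[, m, n] <- uy_new
        if (active) {
          u[, , n] <- u_new
          llf[n] <- ll_new
        }
        acc_count[m] <- acc_count[m] + 1
      }
    }
  }
  state$positions <- pos
  state$ux <- uxc
  state$uy <- uyc
  state$u <- u
  state$llf <- llf
  state$prop_count <- prop_count
  state$acc_count <- acc_count
  state$frame_touch <- touch
  state
}

#' Exact-Bernoulli load update
#'
#' For each candidate in turn, draws its load from the exact conditional
#' `p_on = gamma exp(L_on) / (gamma exp(L_on) + (1 - gamma) exp(L_off))`
#' where `L_on`/`L_off` are total stack log-likelihoods with the candidate
#' switched on/off, computed by stable log differencing. Degenerate priors
#' (`gamma` of 0 or 1) are handled exactly; a candidate that changes nothing
#' (`h = 0`) keeps exactly its prior probability.
#'
#' @inheritParams update_tracks_phase
#' @return Updated `chain_state`.
#' @export
update_loads <- function(state, stack, camera, priors) {
  gam <- priors$load_prob
  w <- stack$values
  nf <- state$n_frames
  npx <- state$nx * state$ny
  h <- state$h
  uxc <- state$ux; uyc <- state$uy
  spad <- inherits(camera, "camera_spad")
  if (!spad) {
    g <- camera$em_gain; offset <- camera$offset
    f2g2 <- camera$excess_noise_factor_sq * g^2
    rn2 <- camera$read_noise_sd^2
  }
  for (m in seq_len(state$k)) {
    ua <- stats::runif(1L)
    cur_on <- state$loads[m] == 1L
    if (h == 0) {
      # no photon contribution: conditional equals the prior exactly
      state$loads[m] <- as.integer(ua < gam)
      next
    }
    alt_u <- state$u
    sgn <- if (cur_on) -h else h
    for (n in seq_len(nf)) {
      alt_u[, , n] <- alt_u[, , n] + sgn * tcrossprod(uxc[, m, n], uyc[, m, n])
    }
    # numerical guard: subtracting a contribution can leave tiny negatives
    if (cur_on) alt_u[alt_u < 0] <- 0
    lw <- if (spad) {
      tmp <- -alt_u
      on <- w == 1
      tmp[on] <- log1mexp(alt_u[on])
      tmp
    } else {
      stats::dnorm(w, offset + g * alt_u, sqrt(f2g2 * alt_u + rn2), log = TRUE)
    }
    alt_llf <- colSums(matrix(lw, nrow = npx))
    ll_cur <- sum(state$llf)
    ll_alt <- sum(alt_llf)
    d <- if (cur_on) ll_cur - ll_alt else ll_alt - ll_cur # L_on - L_off
    if (is.nan(d)) {
      stop(sprintf("load update: candidate %d has -Inf likelihood both on and off", m),
           call. = FALSE)
    }
    p_on <- if (gam == 0) 0
      else if (gam == 1) 1
      else if (d == 0) gam
      else stats::plogis(d + log(gam) - log1p(-gam))
    new_on <- ua < p_on
    if (new_on != cur_on) {
      state$loads[m] <- as.integer(new_on)
      state$u <- alt_u
      state$llf <- alt_llf
    }
  }
  state
}

#' Conjugate MSD draw
#'
#' Draws the mean squared displacement from its inverse-gamma full
#' conditional (see [msd_conditional_params()]), over all `K` candidate
#' tracks.
#'
#' @param state A `chain_state`.
#' @param priors An [spt_priors()].
#' @return Updated `chain_state`.
#' @export
update_msd <- function(state, priors) {
  par <- msd_conditional_params(
    candidate_set(state$positions, state$loads), priors)
  state$motion <- motion_params(rinvgamma(1L, par$shape, par$scale))
  state
}

#' Redraw inactive candidate tracks from the motion prior
#'
#' The full conditional of an unloaded candidate's entire track is exactly
#' the motion prior (its positions do not enter the likelihood), so the
#' whole track can be redrawn in one block: a fresh uniform-FOV initial
#' position plus Gaussian increments at the current MSD. This move lets
#' placeholder candidates explore the field of view globally instead of by
#' a slow per-frame random walk, which is what makes emitter-count mixing
#' practical.
#'
#' @param state A `chain_state`.
#' @param priors An [spt_priors()].
#' @return Updated `chain_state`.
#' @export
refresh_inactive_tracks <- function(state, priors) {
  inact <- which(state$loads == 0L)
  if (length(inact) == 0L) return(state)
  nf <- state$n_frames
  sigma <- state$sigma
  pos_all <- state$positions
  uxc <- state$ux
  uyc <- state$uy
  for (m in inact) {
    pos <- sample_tracks_prior(1L, nf, state$motion, priors)
    pos_all[, m, ] <- pos[, 1L, ]
    px_ <- stats::pnorm(outer(state$edges_x, pos[, 1L, 1L], "-") / sigma)
    py_ <- stats::pnorm(outer(state$edges_y, pos[, 1L, 2L], "-") / sigma)
    uxc[, m, ] <- px_[-1L, , drop = FALSE] - px_[-(state$nx + 1L), , drop = FALSE]
    uyc[, m, ] <- py_[-1L, , drop = FALSE] - py_[-(state$ny + 1L), , drop = FALSE]
  }
  state$positions <- pos_all
  state$ux <- uxc
  state$uy <- uyc
  state
}

#' Track tail-swap (crossover) move
#'
#' Proposes exchanging the tails (frames `n+1 .. N`) of two candidates with
#' equal loads at a random junction frame. Because the expected photon
#' field depends only on the set of active positions per frame, swapping
#' tails between two active (or two inactive) candidates leaves the
#' likelihood invariant; the Metropolis ratio reduces to the motion-prior
#' ratio of the four junction increments. This exact move dissolves
#' "hand-off" local modes in which two candidates split one physical track
#' between them (typically near the field-of-view edge) — a configuration
#' the per-frame checkerboard moves cannot escape.
#'
#' @param state A `chain_state`.
#' @param priors An [spt_priors()].
#' @param n_props Number of proposals (default: one per candidate).
#' @return Updated `chain_state`.
#' @export
update_track_swaps <- function(state, priors, n_props = state$k) {
  if (state$k < 2L || state$n_frames < 2L) return(state)
  nf <- state$n_frames
  sd_full <- sqrt(state$motion$step_var_nm2)
  pos <- state$positions
  uxc <- state$ux
  uyc <- state$uy
  for (j in seq_len(n_props)) {
    pair <- sample.int(state$k, 2L)
    n <- sample.int(nf - 1L, 1L)
    lua <- log(stats::runif(1L))
    m1 <- pair[1L]
    m2 <- pair[2L]
    if (state$loads[m1] != state$loads[m2]) next # likelihood would change
    a_n <- pos[n, m1, ]; a_n1 <- pos[n + 1L, m1, ]
    b_n <- pos[n, m2, ]; b_n1 <- pos[n + 1L, m2, ]
    log_alpha <-
      sum(stats::dnorm(c(b_n1 - a_n, a_n1 - b_n), 0, sd_full, log = TRUE)) -
      sum(stats::dnorm(c(a_n1 - a_n, b_n1 - b_n), 0, sd_full, log = TRUE))
    if (lua < log_alpha) {
      ti <- (n + 1L):nf
      tmp <- pos[ti, m1, ]
      pos[ti, m1, ] <- pos[ti, m2, ]
      pos[ti, m2, ] <- tmp
      tmpx <- uxc[, m1, ti]
      uxc[, m1, ti] <- uxc[, m2, ti]
      uxc[, m2, ti] <- tmpx
      tmpy <- uyc[, m1, ti]
      uyc[, m1, ti] <- uyc[, m2, ti]
      uyc[, m2, ti] <- tmpy
      # u and the cached log-likelihoods are unchanged by construction
    }
  }
  state$positions <- pos
  state$ux <- uxc
  state$uy <- uyc
  state
}

# Optional scalar Metropolis move on the log of the background rate.
update_background <- function(state, stack, camera, prior, scale) {
  z <- stats::rnorm(1L)
  ua <- stats::runif(1L)
  bg_new <- state$background * exp(scale * z)
  u_new <- state$u - state$background + bg_new
  llf_new <- colSums(matrix(loglike_pixels(stack$values, u_new, camera),
                            nrow = state$nx * state$ny))
  log_alpha <- sum(llf_new) - sum(state$llf) +
    stats::dgamma(bg_new, prior[1L], prior[2L], log = TRUE) -
    stats::dgamma(state$background, prior[1L], prior[2L], log = TRUE) +
    log(bg_new) - log(state$background) # log-scale proposal Jacobian
  if (is.finite(log_alpha) && log(ua) < log_alpha) {
    state$background <- bg_new
    state$u <- u_new
    state$llf <- llf_new
  }
  state
}

# Optional scalar Metropolis move on the log of the brightness.
update_brightness <- function(state, stack, camera, prior, scale) {
  .assert(state$h > 0, "brightness inference requires h > 0")
  z <- stats::rnorm(1L)
  ua <- stats::runif(1L)
  h_new <- state$h * exp(scale * z)
  u_new <- state$background + (h_new / state$h) * (state$u - state$background)
  llf_new <- colSums(matrix(loglike_pixels(stack$values, u_new, camera),
                            nrow = state$nx * state$ny))
  log_alpha <- sum(llf_new) - sum(state$llf) +
    stats::dgamma(h_new, prior[1L], prior[2L], log = TRUE) -
    stats::dgamma(state$h, prior[1L], prior[2L], log = TRUE) +
    log(h_new) - log(state$h)
  if (is.finite(log_alpha) && log(ua) < log_alpha) {
    state$h <- h_new
    state$u <- u_new
    state$llf <- llf_new
  }
  state
}

#' One full Gibbs sweep
#'
#' Applies, in order: the prior redraw of inactive tracks (nonparametric
#' mode only), the odd- then even-parity checkerboard track phases, the
#' load update (nonparametric mode only), the optional background and
#' brightness moves, and the conjugate MSD draw. Every frame of every
#' candidate is proposed exactly once per sweep.
#'
#' @param state A `chain_state`.
#' @param stack,camera Data and camera model.
#' @param priors An [spt_priors()].
#' @param config A [sampler_config()].
#' @return Updated `chain_state` with `iteration` advanced by one.
#' @export
gibbs_sweep <- function(state, stack, camera, priors, config) {
  state$frame_touch <- numeric(state$n_frames)
  if (!config$parametric_mode) state <- refresh_inactive_tracks(state, priors)
  state <- update_tracks_phase(state, stack, camera, priors, "odd",
                               proposal = config$proposal,
                               rw_scale_nm = config$rw_scale_nm)
  state <- update_tracks_phase(state, stack, camera, priors, "even",
                               proposal = config$proposal,
                               rw_scale_nm = config$rw_scale_nm)
  state <- update_track_swaps(state, priors)
  if (!config$parametric_mode) state <- update_loads(state, stack, camera, priors)
  if (config$infer_background) {
    state <- update_background(state, stack, camera, config$bg_prior,
                               config$mh_scale)
  }
  if (config$infer_brightness) {
    state <- update_brightness(state, stack, camera, config$h_prior,
                               config$mh_scale)
  }
  state <- update_msd(state, priors)
  state$iteration <- state$iteration + 1L
  state
}

# Unnormalized log posterior of the current state (evidence term dropped).
log_posterior <- function(state, stack, camera, priors) {
  cand <- candidate_set(state$positions, state$loads)
  lp <- sum(state$llf) +
    log_motion_prior(cand, state$motion, priors) +
    sum(stats::dbinom(state$loads, 1L, priors$load_prob, log = TRUE))
  msd <- state$motion$msd_per_frame_nm2
  lp + priors$msd_shape * log(priors$msd_scale) - lgamma(priors$msd_shape) -
    (priors$msd_shape + 1) * log(msd) - priors$msd_scale / msd
}
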