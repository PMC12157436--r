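#' Run the full posterior sampler
#'
#' Orchestrates the Gibbs chain over candidate tracks, loads, and MSD for a
#' recorded (or simulated) image stack. Initialization: all loads off in
#' nonparametric mode (all on in parametric mode), candidate tracks drawn
#' from the motion prior at the initial MSD, brightness and background taken
#' from the configuration. Supports checkpoint/resume with bit-identical
#' continuation.
#'
#' @param stack An [image_stack()].
#' @param optics An [optics_config()].
#' @param camera Camera model ([camera_emccd()] or [camera_spad()]).
#' @param priors An [spt_priors()].
#' @param config A [sampler_config()].
#' @param resume_from Optional path to a checkpoint written by a previous
#'   call; the chain continues exactly as if uninterrupted.
#' @return Object of class `posterior_samples`: thinned draws of `loads`
#'   (S x K), `tracks` (S x N x K x 2), `msd`, `background`, `h`, `logpost`
#'   (all length S), `iteration` stamps, the full per-sweep `logpost_trace`,
#'   the final `state`, the `config` and acquisition `meta`.
#' @export
run_chain <- function(stack, optics, camera, priors, config,
                      resume_from = NULL) {
  validate_stack(stack, camera)
  nf <- stack$n_frames
  k <- config$n_candidates
  n_keep <- (config$n_iterations - config$burn_in) %/% config$thin

  if (!is.null(resume_from)) {
    ck <- readRDS(resume_from)
    .assert(identical(ck$config$seed, config$seed),
            "checkpoint was written with a different seed")
    state <- ck$state
    store <- ck$store
    logpost_trace <- ck$logpost_trace
    start <- ck$iteration
    assign(".Random.seed", ck$rng, envir = globalenv())
    config <- ck$config
  } else {
    set.seed(config$seed)
    msd0 <- config$msd_init %||%
      (if (priors$msd_shape > 1) priors$msd_scale / (priors$msd_shape - 1)
       else priors$msd_scale)
    motion <- motion_params(msd0)
    loads <- if (config$parametric_mode) rep(1L, k) else rep(0L, k)
    pos <- sample_tracks_prior(k, nf, motion, priors)
    state <- chain_state(candidate_set(pos, loads), motion, stack, camera,
                         optics, config$brightness, config$background_rate)
    if (config$infer_background && is.null(config$bg_prior)) {
      config$bg_prior <- c(2, 2 / max(config$background_rate, 1e-6))
    }
    if (config$infer_brightness && is.null(config$h_prior)) {
      config$h_prior <- c(2, 2 / max(config$brightness, 1e-6))
    }
    store <- list(
      loads = matrix(NA_integer_, n_keep, k),
      tracks = array(NA_real_, dim = c(n_keep, nf, k, 2L)),
      msd = rep(NA_real_, n_keep), background = rep(NA_real_, n_keep),
      h = rep(NA_real_, n_keep), logpost = rep(NA_real_, n_keep),
      iteration = rep(NA_integer_, n_keep)
    )
    logpost_trace <- rep(NA_real_, config$n_iterations)
    start <- 0L
  }

  its <- if (start < config$n_iterations)
    seq.int(start + 1L, config$n_iterations) else integer(0)
  for (it in its) {
    state <- gibbs_sweep(state, stack, camera, priors, config)
    if (config$audit_every > 0L && it %% config$audit_every == 0L) {
      drift <- audit_chain_state(state, stack, camera)
      if (max(drift) > 1e-6) {
        state <- recompute_state_caches(state, stack, camera)
        warning(sprintf("cache drift %.3g at iteration %d; caches rebuilt",
                        max(drift), it))
      }
    }
    lp <- log_posterior(state, stack, camera, priors)
    if (is.nan(lp)) {
      stop(sprintf(
        "NaN log-posterior at iteration %d (msd=%g, M=%d, background=%g, h=%g)",
        it, state$motion$msd_per_frame_nm2, sum(state$loads),
        state$background, state$h), call. = FALSE)
    }
    logpost_trace[it] <- lp
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      s <- (it - config$burn_in) %/% config$thin
      store$loads[s, ] <- state$loads
      store$tracks[s, , , ] <- state$positions
      store$msd[s] <- state$motion$msd_per_frame_nm2
      store$background[s] <- state$background
      store$h[s] <- state$h
      store$logpost[s] <- lp
      store$iteration[s] <- it
    }
    if (!is.null(config$checkpoint_every) && !is.null(config$checkpoint_path) &&
        it %% config$checkpoint_every == 0L) {
      # a "%d" in the path keeps one checkpoint per iteration instead of
      # overwriting
      ck_path <- if (grepl("%d", config$checkpoint_path, fixed = TRUE)) {
        sprintf(config$checkpoint_path, it)
      } else {
        config$checkpoint_path
      }
      saveRDS(list(state = state, store = store, iteration = it,
                   logpost_trace = logpost_trace, config = config,
                   rng = get(".Random.seed", envir = globalenv())),
              ck_path)
    }
  }

  structure(list(
    loads = store$loads, tracks = store$tracks, msd = store$msd,
    background = store$background, h = store$h, logpost = store$logpost,
    iteration = store$iteration, logpost_trace = logpost_trace,
    state = state, config = config,
    meta = list(optics = optics, camera = camera,
                pixel_size_nm = stack$pixel_size_nm,
                exposure_time_s = stack$exposure_time_s,
                n_frames = nf, priors = priors)
  ), class = "posterior_samples")
}

#' Summarize posterior samples
#'
#' Reports the marginal posterior of the emitter count `M`, the MSD (and,
#' when the exposure time is known, diffusion coefficient) posterior mean
#' and central 90% credible interval, and — conditioned on the modal `M` —
#' per-frame posterior mean tracks with central 90% intervals. Candidate
#' labels are matched across samples by greedy nearest-mean assignment
#' against a reference sample (the retained sample with the smallest
#' iteration stamp), a reporting convention rather than an inference step;
#' reference tracks are ordered by mean x (then y) so the output is
#' invariant to permutations of the sample sequence.
#'
#' @param samples A `posterior_samples` object from [run_chain()].
#' @return Object of class `spt_summary`: list with `m_counts`, `m_mode`,
#'   `msd` (mean/lower/upper, nm^2/frame), `d_coeff` (same, um^2/s),
#'   `tracks` (list of `mean`, `lower`, `upper`; `N x m_mode x 2` arrays in
#'   nm) and `n_samples_used`.
#' @export
posterior_summary <- function(samples) {
  .assert(inherits(samples, "posterior_samples"), "expected posterior_samples")
  s_total <- length(samples$msd)
  .assert(s_total > 0L, "no posterior samples to summarize")
  m_s <- rowSums(samples$loads)
  m_counts <- table(factor(m_s, levels = 0:ncol(samples$loads)))
  m_mode <- as.integer(names(m_counts)[which.max(m_counts)])

  qs <- function(x) c(mean = mean(x),
                      lower = unname(stats::quantile(x, 0.05)),
                      upper = unname(stats::quantile(x, 0.95)))
  msd_sum <- qs(samples$msd)
  dt <- samples$meta$exposure_time_s
  d_sum <- if (!is.null(dt)) msd_sum / (4 * dt * 1e6) else NULL # um^2/s

  tracks <- NULL
  sel <- which(m_s == m_mode)
  if (m_mode > 0L && length(sel) > 0L) {
    nf <- dim(samples$tracks)[2L]
    ref_s <- sel[which.min(samples$iteration[sel])]
    ref_idx <- which(samples$loads[ref_s, ] == 1L)
    ref_tracks <- samples$tracks[ref_s, , ref_idx, , drop = FALSE][1L, , , , drop = TRUE]
    ref_tracks <- array(ref_tracks, dim = c(nf, m_mode, 2L))
    ref_means <- apply(ref_tracks, c(2L, 3L), mean) # m_mode x 2
    ord <- order(ref_means[, 1L], ref_means[, 2L])
    ref_means <- ref_means[ord, , drop = FALSE]
    aligned <- array(NA_real_, dim = c(length(sel), nf, m_mode, 2L))
    for (si in seq_along(sel)) {
      s <- sel[si]
      act <- which(samples$loads[s, ] == 1L)
      tr <- array(samples$tracks[s, , act, , drop = FALSE][1L, , , , drop = TRUE],
                  dim = c(nf, m_mode, 2L))
      mu <- apply(tr, c(2L, 3L), mean)
      # greedy nearest-mean assignment to the reference labels
      dmat <- outer(seq_len(m_mode), seq_len(m_mode), Vectorize(function(a, b) {
        sqrt(sum((ref_means[a, ] - mu[b, ])^2))
      }))
      perm <- integer(m_mode)
      for (step in seq_len(m_mode)) {
        best <- which(dmat == min(dmat), arr.ind = TRUE)[1L, ]
        perm[best[1L]] <- best[2L]
        dmat[best[1L], ] <- Inf
        dmat[, best[2L]] <- Inf
      }
      aligned[si, , , ] <- tr[, perm, , drop = FALSE]
    }
    tracks <- list(
      mean = apply(aligned, c(2L, 3L, 4L), mean),
      lower = apply(aligned, c(2L, 3L, 4L), stats::quantile, 0.05),
      upper = apply(aligned, c(2L, 3L, 4L), stats::quantile, 0.95)
    )
  }

  structure(list(m_counts = m_counts, m_mode = m_mode, msd = msd_sum,
                 d_coeff = d_sum, tracks = tracks,
                 n_samples_used = length(sel)),
            class = "spt_summary")
}

#' @export
print.spt_summary <- function(x, ...) {
  cat("Posterior summary\n")
  cat(sprintf("  modal emitter count M = %d\n", x$m_mode))
  cat("  P(M) counts:", paste(names(x$m_counts), x$m_counts, sep = ":",
                              collapse = " "), "\n")
  cat(sprintf("  MSD mean %.1f nm^2/frame (90%% CI %.1f - %.1f)\n",
              x$msd["mean"], x$msd["lower"], x$msd["upper"]))
  if (!is.null(x$d_coeff)) {
    cat(sprintf("  D mean %.4f um^2/s (90%% CI %.4f - %.4f)\n",
                x$d_coeff["mean"], x$d_coeff["lower"], x$d_coeff["upper"]))
  }
  invisible(x)
}
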