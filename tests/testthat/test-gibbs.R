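test_that("inactive candidates are refreshed with acceptance exactly 1", {
  x <- toy_movie(seed = 21)
  set.seed(1)
  pos <- centered_tracks(6, 2, 16) # anchors far from the FOV edge
  mot <- motion_params(13200)
  state <- chain_state(candidate_set(pos, c(0L, 0L)), mot, x$stack,
                       x$camera, x$optics, x$truth$h, x$truth$background_rate)
  for (i in 1:20) {
    state <- update_tracks_phase(state, x$stack, x$camera, x$priors, "odd")
    state <- update_tracks_phase(state, x$stack, x$camera, x$priors, "even")
  }
  expect_equal(state$acc_count, state$prop_count)
  expect_equal(sum(state$prop_count), 2 * 6 * 20)
})

test_that("h = 0 makes every candidate behave as inactive", {
  x <- toy_movie(seed = 22)
  set.seed(2)
  pos <- centered_tracks(6, 3, 16)
  mot <- motion_params(13200)
  state <- chain_state(candidate_set(pos, c(1L, 1L, 0L)), mot, x$stack,
                       x$camera, x$optics, brightness = 0,
                       background_rate = 3)
  for (i in 1:10) {
    state <- update_tracks_phase(state, x$stack, x$camera, x$priors, "odd")
    state <- update_tracks_phase(state, x$stack, x$camera, x$priors, "even")
  }
  expect_equal(state$acc_count, state$prop_count)
})

test_that("h = 0 load conditional equals the prior; degenerate priors exact", {
  x <- toy_movie(seed = 23)
  set.seed(3)
  pos <- centered_tracks(6, 2, 16)
  mot <- motion_params(13200)
  mk_state <- function() chain_state(candidate_set(pos, c(0L, 1L)), mot,
                                     x$stack, x$camera, x$optics, 0, 3)
  gam <- 0.37
  pri <- spt_priors(msd_scale = 13200, load_prob = gam,
                    fov_bounds = toy_fov(16))
  state <- mk_state()
  draws <- replicate(4000, {
    state <<- update_loads(state, x$stack, x$camera, pri)
    state$loads
  })
  p_hat <- mean(draws)
  se <- sqrt(gam * (1 - gam) / length(draws))
  expect_lt(abs(p_hat - gam), 3 * se)
  # degenerate priors
  pri1 <- spt_priors(msd_scale = 13200, load_prob = 1, fov_bounds = toy_fov(16))
  expect_equal(update_loads(mk_state(), x$stack, x$camera, pri1)$loads,
               c(1L, 1L))
  pri0 <- spt_priors(msd_scale = 13200, load_prob = 0, fov_bounds = toy_fov(16))
  expect_equal(update_loads(mk_state(), x$stack, x$camera, pri0)$loads,
               c(0L, 0L))
})

test_that("MSD draw follows its conditional (moment checks)", {
  pri <- spt_priors(msd_shape = 6, msd_scale = 5 * 13200, load_prob = 1,
                    fov_bounds = c(0, 4000, 0, 4000))
  x <- toy_movie(seed = 24)
  # N = 1: the conditional is the prior
  stack1 <- image_stack(x$stack$values[, , 1, drop = FALSE], 133, 0.033)
  pos1 <- array(c(1000, 1000), dim = c(1, 1, 2))
  state1 <- chain_state(candidate_set(pos1, 1L), motion_params(1000), stack1,
                        x$camera, x$optics, 0, 3)
  set.seed(4)
  draws <- replicate(10000, {
    state1 <<- update_msd(state1, pri)
    state1$motion$msd_per_frame_nm2
  })
  prior_mean <- 5 * 13200 / (6 - 1)
  prior_var <- (5 * 13200)^2 / ((6 - 1)^2 * (6 - 2))
  expect_lt(abs(mean(draws) - prior_mean), 3 * sqrt(prior_var / 10000))
  # fixed increments: mean ~= scale / (shape - 1)
  set.seed(5)
  pos <- array(cumsum(c(1000, rnorm(4, 0, 90))), dim = c(5, 1, 1))
  pos <- array(c(pos, pos), dim = c(5, 1, 2))
  stateN <- chain_state(candidate_set(pos, 1L),
                        motion_params(1000),
                        image_stack(x$stack$values[, , 1:5], 133, 0.033),
                        x$camera, x$optics, 0, 3)
  par <- msd_conditional_params(candidate_set(pos, 1L), pri)
  draws2 <- replicate(10000, {
    stateN <<- update_msd(stateN, pri)
    stateN$motion$msd_per_frame_nm2
  })
  m_theory <- par$scale / (par$shape - 1)
  v_theory <- par$scale^2 / ((par$shape - 1)^2 * (par$shape - 2))
  expect_lt(abs(mean(draws2) - m_theory), 3 * sqrt(v_theory / 10000))
  # zero increments: posterior shape strictly larger than the prior's
  expect_gt(msd_conditional_params(candidate_set(pos * 0 + 500, 1L),
                                   pri)$shape, pri$msd_shape)
})

test_that("sweeps are deterministic and touch every frame exactly once", {
  x <- toy_movie(seed = 25)
  s1 <- run_sweeps(x, 15, seed = 99)
  s2 <- run_sweeps(x, 15, seed = 99)
  expect_identical(s1, s2)
  expect_equal(s1$frame_touch, rep(4, 6)) # K = 4 candidates per frame
})

test_that("frame updates within a phase are order-independent (bit-identical)", {
  x <- toy_movie(seed = 26)
  run_orders <- function(order_fun) {
    set.seed(7)
    mot <- motion_params(13200)
    pos <- sample_tracks_prior(4, 6, mot, x$priors)
    state <- chain_state(candidate_set(pos, c(1L, 1L, 0L, 0L)), mot, x$stack,
                         x$camera, x$optics, x$truth$h,
                         x$truth$background_rate)
    for (i in 1:10) {
      state <- update_tracks_phase(state, x$stack, x$camera, x$priors, "odd",
                                   frame_order = order_fun(seq(1, 6, 2)))
      state <- update_tracks_phase(state, x$stack, x$camera, x$priors, "even",
                                   frame_order = order_fun(seq(2, 6, 2)))
      state <- update_loads(state, x$stack, x$camera, x$priors)
      state <- update_msd(state, x$priors)
    }
    state
  }
  a <- run_orders(identity)
  b <- run_orders(rev)
  cset <- function(v) v[c(2, 3, 1)]
  c3 <- run_orders(cset)
  expect_identical(a, b)
  expect_identical(a, c3)
})

test_that("incremental likelihood caches match fresh recomputation", {
  x <- toy_movie(seed = 27)
  state <- run_sweeps(x, 40, seed = 11)
  drift <- audit_chain_state(state, x$stack, x$camera)
  expect_lt(drift[["u"]], 1e-6)
  expect_lt(drift[["loglike"]], 1e-6)
  expect_gt(sum(state$loads), 0) # the movie's particles were found
})

test_that("tail swaps leave the likelihood caches invariant and fix hand-offs", {
  x <- toy_movie(seed = 33)
  # two active candidates whose tracks exchange identity mid-movie: the
  # crossed configuration has tiny prior probability, so the swap move must
  # repair it with near-certain acceptance
  a <- centered_tracks(6, 1, 16, wiggle = 20)[, 1, ]
  b <- a + 900 # parallel track far away
  crossed <- array(0, dim = c(6, 2, 2))
  crossed[1:3, 1, ] <- a[1:3, ]; crossed[4:6, 1, ] <- b[4:6, ]
  crossed[1:3, 2, ] <- b[1:3, ]; crossed[4:6, 2, ] <- a[4:6, ]
  mot <- motion_params(13200)
  state <- chain_state(candidate_set(crossed, c(1L, 1L)), mot, x$stack,
                       x$camera, x$optics, x$truth$h, x$truth$background_rate)
  u_before <- state$u
  llf_before <- state$llf
  set.seed(1)
  for (i in 1:20) state <- update_track_swaps(state, x$priors)
  expect_identical(state$u, u_before)
  expect_identical(state$llf, llf_before)
  expect_lt(max(abs(audit_chain_state(state, x$stack, x$camera))), 1e-6)
  # tracks were uncrossed: each candidate is now one coherent track
  jump1 <- sqrt(sum((state$positions[4, 1, ] - state$positions[3, 1, ])^2))
  jump2 <- sqrt(sum((state$positions[4, 2, ] - state$positions[3, 2, ])^2))
  expect_lt(max(jump1, jump2), 600)
  # candidates with unequal loads are never swapped
  state2 <- chain_state(candidate_set(crossed, c(1L, 0L)), mot, x$stack,
                        x$camera, x$optics, x$truth$h, x$truth$background_rate)
  pos2 <- state2$positions
  set.seed(2)
  for (i in 1:10) state2 <- update_track_swaps(state2, x$priors)
  expect_identical(state2$positions, pos2)
})

test_that("run_chain reproduces itself and honors thinning bookkeeping", {
  x <- toy_movie(seed = 28)
  cfg <- sampler_config(n_iterations = 40, burn_in = 10, thin = 3, seed = 5,
                        n_candidates = 3, brightness = x$truth$h,
                        background_rate = x$truth$background_rate)
  a <- run_chain(x$stack, x$optics, x$camera, x$priors, cfg)
  b <- run_chain(x$stack, x$optics, x$camera, x$priors, cfg)
  expect_identical(a$loads, b$loads)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$msd, b$msd)
  expect_equal(length(a$msd), (40 - 10) %/% 3)
  expect_true(all(diff(a$iteration) == 3))
  expect_true(all(is.finite(a$logpost_trace)))
  # boundary: burn_in == n_iterations gives an empty but valid sample set
  cfg0 <- sampler_config(n_iterations = 20, burn_in = 20, seed = 5,
                         n_candidates = 3, brightness = x$truth$h,
                         background_rate = x$truth$background_rate)
  r0 <- run_chain(x$stack, x$optics, x$camera, x$priors, cfg0)
  expect_equal(length(r0$msd), 0)
  expect_true(all(is.finite(r0$logpost_trace)))
  expect_error(posterior_summary(r0), "no posterior samples")
})

test_that("checkpoint/resume continues bit-identically", {
  x <- toy_movie(seed = 29)
  tmp <- withr::local_tempdir()
  ck <- file.path(tmp, "ck_%d.rds")
  cfg <- sampler_config(n_iterations = 30, burn_in = 5, thin = 1, seed = 13,
                        n_candidates = 3, brightness = x$truth$h,
                        background_rate = x$truth$background_rate,
                        checkpoint_every = 10, checkpoint_path = ck)
  full <- run_chain(x$stack, x$optics, x$camera, x$priors, cfg)
  resumed <- run_chain(x$stack, x$optics, x$camera, x$priors, cfg,
                       resume_from = file.path(tmp, "ck_10.rds"))
  expect_identical(full$msd, resumed$msd)
  expect_identical(full$tracks, resumed$tracks)
  expect_identical(full$loads, resumed$loads)
  expect_identical(full$logpost_trace, resumed$logpost_trace)
})

test_that("parametric mode pins all loads at one", {
  x <- toy_movie(seed = 30)
  cfg <- sampler_config(n_iterations = 25, burn_in = 5, seed = 3,
                        n_candidates = 2, brightness = x$truth$h,
                        background_rate = x$truth$background_rate,
                        parametric_mode = TRUE)
  r <- run_chain(x$stack, x$optics, x$camera, x$priors, cfg)
  expect_true(all(r$loads == 1L))
})

test_that("posterior_summary: degenerate, quantile oracle, permutation invariance", {
  x <- toy_movie(seed = 31)
  cfg <- sampler_config(n_iterations = 360, burn_in = 40, thin = 1, seed = 4,
                        n_candidates = 3, brightness = x$truth$h,
                        background_rate = x$truth$background_rate)
  r <- run_chain(x$stack, x$optics, x$camera, x$priors, cfg)
  s <- posterior_summary(r)
  expect_true(s$m_mode >= 0 && s$m_mode <= 3)

  # all samples identical -> zero-width intervals
  rr <- r
  n_s <- length(rr$msd)
  for (i in seq_len(n_s)) {
    rr$loads[i, ] <- r$loads[n_s, ]
    rr$tracks[i, , , ] <- r$tracks[n_s, , , ]
    rr$msd[i] <- r$msd[n_s]
  }
  ss <- posterior_summary(rr)
  expect_equal(ss$msd[["lower"]], ss$msd[["upper"]])
  if (!is.null(ss$tracks)) {
    expect_equal(ss$tracks$lower, ss$tracks$upper, tolerance = 1e-12)
  }

  # known inverse-gamma MSD draws: CI endpoints match the quantile function
  set.seed(6)
  a <- 8; b <- 8 * 13200
  rq <- r
  rq$msd <- 1 / rgamma(n_s, a, rate = b)
  sq <- posterior_summary(rq)
  expect_equal(sq$msd[["lower"]], 1 / qgamma(0.95, a, rate = b),
               tolerance = 0.15)
  expect_equal(sq$msd[["upper"]], 1 / qgamma(0.05, a, rate = b),
               tolerance = 0.15)

  # permuting the retained-sample sequence leaves every table unchanged
  perm <- sample(n_s)
  rp <- r
  rp$loads <- r$loads[perm, , drop = FALSE]
  rp$tracks <- r$tracks[perm, , , , drop = FALSE]
  rp$msd <- r$msd[perm]
  rp$iteration <- r$iteration[perm]
  rp$logpost <- r$logpost[perm]
  sp <- posterior_summary(rp)
  expect_equal(sp$m_counts, s$m_counts)
  expect_equal(sp$msd, s$msd)
  expect_equal(sp$tracks, s$tracks)
})
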