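test_that("psf_sigma follows the 0.21 lambda / NA rule", {
  opt <- toy_optics()
  expect_equal(psf_sigma(opt), 0.21 * 665 / 1.45, tolerance = 1e-12)
  opt2 <- optics_config(1.45, 1.515, 2 * 665, 133)
  expect_equal(psf_sigma(opt2), 2 * psf_sigma(opt), tolerance = 1e-12)
  # sigma -> 0 as NA grows
  big_na <- optics_config(50, 51, 665, 133)
  expect_lt(psf_sigma(big_na), 3)
  expect_error(optics_config(-1, 1.515, 665, 133), "positive")
  expect_error(optics_config(1.45, 1.515, 0, 133), "positive")
  expect_error(optics_config(1.6, 1.515, 665, 133), "refractive")
})

test_that("erf_strip_integral matches closed forms and quadrature", {
  # total mass
  expect_equal(erf_strip_integral(0, -1e6, 1e6, 100), 1, tolerance = 1e-12)
  # symmetric interval: 2 pnorm(w / sd) - 1
  v <- 9000; w <- 150
  expect_equal(erf_strip_integral(7, 7 - w, 7 + w, v),
               2 * pnorm(w / sqrt(v)) - 1, tolerance = 1e-14)
  # randomized cases against adaptive quadrature
  set.seed(1)
  for (i in 1:25) {
    ctr <- runif(1, -500, 500)
    lo <- runif(1, -400, 100)
    hi <- lo + runif(1, 1, 500)
    vv <- runif(1, 10, 5e4)
    q <- integrate(function(x) exp(-(x - ctr)^2 / (2 * vv)) / sqrt(2 * pi * vv),
                   lo, hi, rel.tol = 1e-13)$value
    expect_equal(erf_strip_integral(ctr, lo, hi, vv), q, tolerance = 1e-10)
  }
  expect_error(erf_strip_integral(0, -1, 1, 0), "variance")
  expect_error(erf_strip_integral(0, 1, -1, 10), "hi")
})

test_that("expected photon field: empty set, mass conservation, equivariance", {
  opt <- toy_optics()
  pos <- centered_tracks(3, 2, 32)
  # all loads off -> pure background
  f0 <- expected_photons(pos, c(0, 0), 500, 1.7, opt, 32, 32)
  expect_true(all(f0$u == 1.7))
  # one centered particle, frame sums conserve h
  f1 <- expected_photons(pos, c(1, 0), 500, 1.7, opt, 32, 32)
  for (n in 1:3) {
    expect_equal(sum(f1$u[, , n] - 1.7), 500, tolerance = 1e-6 * 500)
  }
  # translation by exactly one pixel pitch shifts the contribution
  px <- opt$pixel_size_nm
  shifted <- pos
  shifted[, , 1] <- shifted[, , 1] + px
  f2 <- expected_photons(shifted, c(1, 0), 500, 0, opt, 32, 32)
  f1b <- expected_photons(pos, c(1, 0), 500, 0, opt, 32, 32)
  expect_equal(f2$u[2:32, , ], f1b$u[1:31, , ], tolerance = 1e-9)
})

test_that("batched and serial expected-photon paths agree", {
  opt <- toy_optics()
  set.seed(7)
  for (i in 1:20) {
    nf <- sample(1:4, 1)
    k <- sample(1:4, 1)
    npx <- sample(c(6, 9, 16), 1)
    pos <- array(runif(nf * k * 2, -200, npx * 133 + 200),
                 dim = c(nf, k, 2))
    loads <- rbinom(k, 1, 0.6)
    h <- runif(1, 0, 800)
    bg <- runif(1, 0, 30)
    fb <- expected_photons(pos, loads, h, bg, opt, npx, npx)
    fs <- expected_photons_serial(pos, loads, h, bg, opt, npx, npx)
    expect_equal(fb$u, fs$u, tolerance = 1e-12)
  }
})

test_that("serial oracle agrees with 2-D tensor-product quadrature", {
  opt <- toy_optics()
  px <- opt$pixel_size_nm
  v <- opt$psf_variance_nm2
  pos <- array(c(4.3 * px, 5.1 * px), dim = c(1, 1, 2))
  f <- expected_photons_serial(pos, 1L, 700, 0.5, opt, 8, 8)
  for (pix in list(c(4, 5), c(5, 5), c(1, 8), c(8, 1))) {
    i <- pix[1]; j <- pix[2]
    q <- quad_pixel_mass(pos[1, 1, 1], pos[1, 1, 2],
                         (i - 1) * px, i * px, (j - 1) * px, j * px, v)
    expect_equal(f$u[i, j, 1], 0.5 + 700 * q, tolerance = 1e-8)
  }
  # single particle at a pixel center: concentric pixel is the frame max
  ctr <- array(c(3.5 * px, 5.5 * px), dim = c(1, 1, 2))
  fc <- expected_photons_serial(ctr, 1L, 700, 0, opt, 8, 8)
  expect_equal(which(fc$u[, , 1] == max(fc$u[, , 1]), arr.ind = TRUE)[1, ],
               c(row = 4, col = 6))
})

test_that("SPAD log-likelihood is exact and stable", {
  expect_identical(loglike_spad(0, 0.7), -0.7)
  expect_equal(loglike_spad(1, log(2)), log(0.5), tolerance = 1e-14)
  expect_identical(loglike_spad(1, 0), -Inf)
  # direct pmf oracle (naive 1 - exp(-u) is itself accurate on this range)
  for (u in c(1e-3, 0.05, 0.3, 1, 3, 8)) {
    p1 <- 1 - exp(-u)
    expect_equal(loglike_spad(1, u), log(p1), tolerance = 1e-12)
    expect_equal(loglike_spad(0, u), log(1 - p1), tolerance = 1e-12)
  }
  # miss branch is exact at every scale; complement identity holds stably
  for (u in c(1e-6, 1e-3, 0.3, 3, 20)) {
    expect_identical(loglike_spad(0, u), -u)
    expect_equal(exp(loglike_spad(1, u)) + exp(loglike_spad(0, u)), 1,
                 tolerance = 1e-12)
  }
  expect_error(loglike_spad(2, 1), "binary")
  expect_error(loglike_spad(1, -1), ">= 0")
})

test_that("EMCCD log-likelihood matches the stated Gaussian model", {
  cam <- camera_emccd(offset = 100, em_gain = 100, read_noise_sd = 2)
  # mode at w = offset + G u
  u <- 0.8
  ws <- seq(0, 400, by = 10)
  ll <- loglike_emccd(ws, u, cam)
  expect_equal(ws[which.max(ll)], 100 + 100 * u, tolerance = 10)
  expect_lte(max(ll), loglike_emccd(100 + 100 * u, u, cam))
  # u = 0, unit read noise, w = offset -> standard normal at the mode
  cam1 <- camera_emccd(offset = 100, em_gain = 100, read_noise_sd = 1)
  expect_equal(loglike_emccd(100, 0, cam1), -0.5 * log(2 * pi),
               tolerance = 1e-14)
  # independent normal log-pdf oracle on random cases
  set.seed(2)
  for (i in 1:20) {
    u <- runif(1, 0, 50)
    w <- runif(1, 0, 6000)
    vtot <- 2 * 100^2 * u + 4
    expect_equal(loglike_emccd(w, u, cam),
                 ref_normal_logpdf(w, 100 + 100 * u, vtot), tolerance = 1e-12)
  }
  cam0 <- camera_emccd(read_noise_sd = 0)
  expect_error(loglike_emccd(100, 0, cam0), "variance")
})

test_that("stack log-likelihood factorizes over frames and matches a scalar loop", {
  opt <- toy_optics()
  cam <- camera_emccd()
  set.seed(4)
  pos <- centered_tracks(4, 2, 8)
  field <- expected_photons(pos, c(1, 1), 300, 3, opt, 8, 8)
  vals <- array(round(runif(8 * 8 * 4, 80, 4000)), dim = c(8, 8, 4))
  stack <- image_stack(vals, 133, 0.033)
  res <- stack_loglike(stack, field, cam)
  expect_equal(res$total, sum(res$per_frame), tolerance = 1e-9)
  # naive scalar triple loop
  tot <- 0
  for (n in 1:4) for (i in 1:8) for (j in 1:8) {
    tot <- tot + loglike_emccd(vals[i, j, n], field$u[i, j, n], cam)
  }
  expect_equal(res$total, tot, tolerance = 1e-9)
  # frame permutation leaves the total unchanged
  perm <- c(3, 1, 4, 2)
  stack_p <- image_stack(vals[, , perm], 133, 0.033)
  field_p <- field
  field_p$u <- field$u[, , perm]
  expect_equal(stack_loglike(stack_p, field_p, cam)$total, res$total,
               tolerance = 1e-9)
  # -Inf propagates (SPAD impossible pixel), never NaN
  spad_vals <- array(0L, dim = c(8, 8, 2))
  spad_vals[3, 3, 1] <- 1L
  f0 <- expected_photons(pos[1:2, , , drop = FALSE], c(0, 0), 0, 0, opt, 8, 8)
  r <- stack_loglike(image_stack(spad_vals, 133, 0.033), f0, camera_spad())
  expect_identical(r$per_frame[1], -Inf)
  expect_identical(r$total, -Inf)
  # shape mismatch errors
  bad <- image_stack(vals[, , 1:3], 133, 0.033)
  expect_error(stack_loglike(bad, field, cam), "shape")
})

test_that("EMCCD stack log-likelihood is unimodal in |w - mean|", {
  cam <- camera_emccd()
  u <- 2
  mean_w <- 100 + 100 * u
  deltas <- c(0, 50, 150, 400, 900)
  lls <- loglike_emccd(mean_w + deltas, u, cam)
  expect_true(all(diff(lls) < 0))
  lls_neg <- loglike_emccd(mean_w - deltas, u, cam)
  expect_true(all(diff(lls_neg) < 0))
})
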