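# sptgibbs

Fully Bayesian single-particle tracking (SPT) for diffraction-limited
widefield fluorescence movies, with a blocked "checkerboard"
Metropolis-within-Gibbs sampler designed around the parallelism of the
likelihood.

## Who this is for

Researchers analyzing movies of individual fluorescent emitters — membrane
proteins, labeled mRNAs, quantum dots — who want *joint* posterior
inference of how many emitters there are, where each one is in every frame,
and how fast they diffuse, directly from raw pixel counts. No
localization-then-linking heuristics, no intensity thresholds, and full
credible intervals on every quantity.

## The model

A movie is $N$ frames of $I \times J$ pixels $w_{nij}$. Each of $K$
*candidate* tracks $x_{1:N}^m$ carries a binary load
$b_m \sim \mathrm{Bernoulli}(\gamma)$; loaded candidates emit, and the
emitter count is $M = \sum_m b_m$. The expected photons at pixel $(i,j)$
of frame $n$ are

$$u_{nij} \;=\; b \;+\; h \sum_{m:\,b_m=1}
\Big[{\textstyle\int_{i\Delta}^{(i+1)\Delta}}\phi(q;x^m_n,v)\,dq\Big]
\Big[{\textstyle\int_{j\Delta}^{(j+1)\Delta}}\phi(q;y^m_n,v)\,dq\Big],$$

a pixel-integrated 2-D Gaussian PSF with variance $v = (0.21\lambda/
\mathrm{NA})^2$, evaluated per frame as the rank-$M$ product
$u_n = b + h\,U_{n,x}U_{n,y}^\top$. Detector models: EMCCD
($w \sim \mathcal N(\mathrm{offset} + Gu,\; F^2G^2u + \sigma_r^2)$) and
binary SPAD ($P(w{=}1) = 1 - e^{-u}$). Tracks follow a Gaussian random
walk with per-axis step variance $\mathrm{MSD}/2$,
$\mathrm{MSD} = 4D\Delta t$, with a conjugate inverse-gamma prior on the
MSD.

The sampler alternates: exact prior block-refresh of unloaded tracks;
odd/even checkerboard frame updates with Gaussian-bridge proposals (the
prior cancels, acceptance is one frame's likelihood ratio, and frames
within a phase carry pre-assigned random substreams so any processing order
is bit-identical); likelihood-invariant track tail-swaps; exact Bernoulli
load updates; a conjugate inverse-gamma MSD draw. See
`vignettes/tracking-model.Rmd` for the full account, including validation
by a Geweke joint-distribution test.

## Worked example

Simulate the reference experiment scaled down (ten 32×32 EMCCD frames,
three particles at $D = 0.1\,\mu m^2/s$, 80 signal photons at the
PSF-concentric pixel, 3 background photons/pixel/frame), then recover
everything:

```r
library(sptgibbs)

preset <- make_preset("fig2", frame_size = 32, n_frames = 10,
                      n_particles = 3, seed = 3)
truth  <- simulate_ground_truth(preset)
stack  <- render_stack(truth)

priors <- spt_priors(msd_shape = 2, msd_scale = 13200, load_prob = 0.5,
                     fov_bounds = c(0, 32 * 133, 0, 32 * 133))
config <- sampler_config(n_iterations = 3000, burn_in = 1000, thin = 2,
                         seed = 7, n_candidates = 6,
                         brightness = truth$h,
                         background_rate = truth$background_rate)
samples <- run_chain(stack, preset$optics, preset$camera, priors, config)
summ <- posterior_summary(samples)
summ
```

```
Posterior summary
  modal emitter count M = 3
  P(M) counts: 0:0 1:0 2:0 3:1000 4:0 5:0 6:0
  MSD mean 11720.3 nm^2/frame (90% CI 8230.2 - 16278.0)
  D mean 0.0888 um^2/s (90% CI 0.0624 - 0.1233)
```

All 1000 retained draws put the emitter count at the true value 3; the
diffusion coefficient's 90% credible interval (0.062–0.123 µm²/s) covers
the simulated 0.1 µm²/s. Score the posterior-mean tracks against the truth
with the detection-ratio metric (one-to-one matching within one
diffraction limit, $\lambda/2\mathrm{NA} \approx 229$ nm):

```r
dr <- detection_ratio(truth$tracks, summ$tracks$mean,
                      diffraction_limit(preset$optics))
cat("detection ratio:", dr$ratio, " spurious:", dr$n_spurious, "\n")
```

```
detection ratio: 1  spurious: 0
```

Every one of the 30 ground-truth positions is matched within one
diffraction limit and no spurious detections remain.

## Command line

The same workflows are scriptable through one JSON config (see
`read_run_config()` for the schema) via the installed script
`inst/cli/sptgibbs`:

```sh
sptgibbs simulate --config run.json        # stack.tif + truth.csv + metadata.json
sptgibbs track    --config run.json        # chain.rds + summaries + log.csv
sptgibbs evaluate --truth truth.csv --est tracks_mean.csv --metadata metadata.json
sptgibbs bench    --config run.json        # per-iteration wall time (no accuracy claim)
```

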