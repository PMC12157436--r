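---
title: "Bayesian single-particle tracking: model, sampler, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian single-particle tracking: model, sampler, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The inference problem

A widefield fluorescence movie records $N$ frames of $I \times J$ pixels.
Each of an unknown number $M$ of diffraction-limited emitters contributes
photons to every pixel of every frame through the microscope's point spread
function (PSF). `sptgibbs` infers, jointly and with full uncertainty:

* the emitter count $M$,
* every emitter's track $x_{1:N}^m \in \mathbb{R}^2$ (nm),
* the mean squared displacement (MSD) of the motion, hence the diffusion
  coefficient $D$,

conditioned on the raw pixel measurements $w_{1:N}^{1:I,1:J}$ — no
localization/linking pipeline, no thresholding. The posterior is

$$P(M, x, \mathrm{MSD} \mid w) \propto P(w \mid x)\, P(M, x, \mathrm{MSD}),$$

whose normalizing constant is never needed by the sampler.

# Emission model (likelihood)

Frames are conditionally independent given the tracks (fluorescence
lifetimes are orders of magnitude shorter than a frame period), and pixels
are independent given the expected photon field, so the likelihood
factorizes over frames and pixels. The expected photon count at pixel
$(i,j)$ of frame $n$ is

$$u_{nij} = b + h \sum_{m \,:\, \text{active}} \left[\int_{iA}
\phi(q_x; x_n^m, v)\,dq_x\right] \left[\int_{jA} \phi(q_y; y_n^m, v)\,
dq_y\right],$$

with $b$ a flat background (photons/pixel/frame), $h$ the brightness, and
$\phi(\cdot;\mu,v)$ a normal density: the 2-D Gaussian PSF approximation
integrated over the pixel area separates into two error-function "strip"
integrals. Per frame this is the rank-$M$ matrix product
$u_n = b + h\,U_{n,x} U_{n,y}^\top$; `expected_photons()` evaluates all
frames this way, and `expected_photons_serial()` is the deliberately slow
per-pixel oracle used to verify it.

The in-focus lateral PSF variance is $v = \sigma^2$ with
$\sigma = 0.21\,\lambda/\mathrm{NA}$ (the standard Gaussian-PSF fit to the
Airy profile). No closed form for $v$ is imposed beyond this default:
`optics_config(psf_sigma_nm=)` accepts any override, which is where a
z-dependent model would plug in.

Two detectors are modeled:

* **SPAD array** (`camera_spad()`): binary pixels,
  $P(w{=}1 \mid u) = 1 - e^{-u}$. Implemented with stable complementary
  primitives (`log(-expm1(-u))` / `log1p(-exp(-u))`); an impossible
  observation yields $-\infty$, never `NaN`.
* **EMCCD** (`camera_emccd()`): Gaussian read-out with mean
  $\mathrm{offset} + G u$ and variance $F^2 G^2 u + \sigma_\mathrm{read}^2$
  (ADU). The excess-noise factor $F^2 = 2$ is the ideal EM-register value;
  mean/variance parameterization is configurable because the Gaussian CCD
  approximation admits several conventions. $\sigma_\mathrm{read} > 0$ is
  required so the likelihood stays proper at $u = 0$ (default 2 ADU).

Background is included as a known additive scalar by default (the
simulations it emulates fix it); optional Gamma-prior Metropolis moves on
the log of background or brightness can be enabled in `sampler_config()`.

# Priors and the nonparametric device

A fixed, user-chosen number $K$ of *candidate* tracks is maintained. Each
candidate carries a binary *load* $b_m \sim \mathrm{Bernoulli}(\gamma)$;
only loaded candidates emit, and $M = \sum_m b_m$. Inference over $M$ is
thus inference over loads, capped at $K$. The default
$\gamma = \mathbb{E}[M]/K$ encodes the user's particle-count guess.

Tracks (loaded or not) follow a Gaussian random walk: initial position
uniform on the field of view, per-axis increments
$\mathcal{N}(0, s)$ with $s = \mathrm{MSD}/2$ (2-D convention
$\mathrm{MSD} = 4D\,\Delta t$). The MSD gets an
$\mathrm{InverseGamma}(\alpha, \beta)$ prior — chosen for conjugacy, since
the source framework does not state its MSD prior family — with default
$\alpha = 2$ and $\beta$ set so the prior mean matches a user guess.
Inactive candidates follow the same motion prior and enter the MSD
conditional; this keeps the load flip reversible and the Gibbs kernel
valid.

# The sampler

One sweep applies, in order:

1. **Inactive-track block refresh.** The full conditional of an unloaded
   candidate's entire track is exactly the motion prior, so the whole track
   is redrawn in one block. This move is *added* to the three standard
   blocks: without it, placeholder candidates explore the field of view
   through a per-frame random walk whose FOV-crossing time is thousands of
   sweeps, and the emitter-count mode is unreachable in practical chain
   lengths. As an exact conditional draw it leaves the posterior invariant,
   which the Geweke test exercises directly.
2. **Checkerboard track update.** Given all even-frame positions, the
   odd-frame positions are conditionally independent across frames (Markov
   boundary of a random walk), and vice versa; each parity is one phase.
   Within a phase, each candidate's frames are proposed from the exact
   Gaussian bridge conditional of their fixed neighbors — mean
   $(x_{n-1}+x_{n+1})/2$, variance $s/2$ per axis in the interior; mean of
   the single neighbor, variance $s$ at the ends — so the motion-prior term
   cancels and the Metropolis ratio is the single frame's likelihood ratio.
   The uniform initial prior contributes an in-FOV indicator at frame 1
   (for anchors more than a few step-SDs inside the FOV its rejection
   probability is below $10^{-9}$, which is why unloaded candidates are
   accepted with probability 1 for all practical purposes). A random-walk
   proposal with explicit local prior ratio is available for high-SNR
   sticking (`proposal = "rw"`).
3. **Track tail swap.** A crossover move: two candidates with equal loads
   exchange their tracks from a random junction frame onward. The expected
   photon field depends only on the *set* of active positions per frame, so
   the likelihood is exactly invariant and the Metropolis ratio reduces to
   the motion-prior ratio of the four junction increments — no pixel work
   at all. This move dissolves "hand-off" local modes in which two
   candidates split one physical track between them (typically near the
   field-of-view edge, where a candidate can park off-sensor in its "off"
   frames at no likelihood cost while the mean squared displacement
   inflates to pay for the junction jumps); the per-frame checkerboard
   moves cannot escape such modes, and without the swap move the
   emitter-count posterior can lock onto $M$ one too high.
4. **Load update.** Each $b_m$ in turn is drawn from its exact conditional
   $p_\mathrm{on} = \mathrm{logit}^{-1}(L_\mathrm{on} - L_\mathrm{off} +
   \mathrm{logit}\,\gamma)$ with $L$ the full-stack log-likelihoods with
   the candidate on/off, by stable log differencing. $\gamma \in \{0,1\}$
   and the no-contribution case $h = 0$ are handled exactly. Skipped in
   parametric mode, where all $K$ loads stay 1.
5. **Conjugate MSD draw** from
   $\mathrm{InverseGamma}(\alpha + K(N{-}1)d/2,\; \beta + \sum \Delta^2)$.
   Note the scale adds the *plain* sum of squared increments because the
   per-axis variance is $\mathrm{MSD}/2$.

Candidates are updated sequentially within a phase (the likelihood couples
them through the shared photon field); parallelism-style order freedom is
across frames only. Per-(candidate, frame) random substreams are drawn in
canonical frame order *before* any frame is touched, so processing the
frames of a phase in any order gives bit-identical chains — the testable
form of the two-phase parallel contract — and checkpoints (RDS, including
the RNG state) resume bit-identically.

The expected photon field and the per-frame log-likelihoods are cached and
maintained incrementally: a single-frame move changes `u` by the difference
of one rank-1 contribution. `audit_chain_state()` recomputes everything
from scratch and reports the drift; tests require $\le 10^{-6}$ after long
runs, and `sampler_config(audit_every=)` can enforce it during sampling.

# Synthetic data

`simulate_ground_truth()` + `render_stack()` generate movies from exactly
the model above (model-matched simulation): Brownian tracks at
$\mathrm{MSD} = 4D\Delta t$, brightness calibrated so a pixel-centered
in-focus particle contributes a stated number of photons to its concentric
pixel (`calibrate_brightness()`), and detector noise drawn from the same
SPAD/EMCCD families the likelihood assumes. EMCCD frames are clipped at
zero and quantized to integer ADU after the Gaussian draw — a slight,
deliberate model mismatch the Gaussian likelihood tolerates.

The reference presets (`make_preset()`) fix NA 1.45, refractive index
1.515, 665 nm emission, 133 nm pixels, 33 ms exposure, EMCCD offset and EM
gain 100, ten 128×128 frames, ten particles at $D = 0.1\,\mu m^2/s$, 80
signal photons at the concentric pixel. The two sweep series are package
choices stated once: background levels $\{3, 7.5, 15, 30, 60\}$
photons/px/frame (a 20× range topping out near 60) for the noise sweep, and
emission levels $\{20, 40, 80, 160\}$ photons (80 = reference dye
brightness) at fixed 60-photon background for the brightness sweep.
Initial truth positions are confined to the central 80% of the FOV to limit
edge truncation of tracks.

What the simulator does *not* emulate — and what a green test therefore
does not establish robustness against: non-Gaussian/aberrated PSFs,
sCMOS-style per-pixel noise maps or a full EM-register cascade,
photobleaching and blinking, drift, axial (z) structure, and non-Brownian
motion.

# Evaluation metric

Estimated positions (by default the posterior-mean tracks at the modal
emitter count) are matched per frame to ground truth by an *optimal
one-to-one assignment* (exact subset dynamic program): maximize the number
of pairs within one matching radius, then minimize total distance.
One-to-one matching was chosen over nearest-neighbor counting to prevent a
single estimate from claiming several truths. The radius defaults to the
Abbe limit $\lambda/(2\,\mathrm{NA})$ — "one diffraction limit" is not
otherwise pinned down — and is overridable. Estimates farther than the
radius from *every* truth are spurious; the detection ratio is correct
detections over total truth positions, reported alongside the spurious
count (the tuning convention requires zero spurious detections before the
ratio is compared).

# Sampler validation

`geweke_check()` implements the joint-distribution ("getting it right")
test: forward draws from the prior versus a successive-conditional chain
that re-renders the data and applies one sweep per iteration, compared on
MSD, $M$, mean and mean-squared position with autocorrelation-aware
(batch-means) z-scores. Two deliberate choices:

* the test model uses MSD prior shape $\alpha = 10$ (not the package
  default 2) because the z-test needs finite prior second moments;
* the test model is *low SNR* (≈1.5 signal photons, SPAD). At high SNR the
  successive-conditional chain's positions move only a localization
  precision per sweep, autocorrelation times blow up, and the z-scores
  measure standard-error misestimation rather than correctness.

# Numerical and degenerate-input policy

All probability is handled in log space; $-\infty$ is a legal value and
propagates through sums, `NaN` aborts with a diagnostic. Tiny negative
photon expectations from floating cancellation (subtracting a contribution
at zero background) are clamped to zero. `burn_in == n_iterations` is the
legal boundary yielding an empty retained-sample set. Single-frame movies
are fully supported (the even phase is empty; the track conditional is the
uniform prior times the frame likelihood). Posterior track summaries match
candidate labels across samples greedily by nearest time-mean position
against the retained sample with the smallest iteration stamp (ordered by
mean x, then y) — a reporting convention, not an inference step, and
invariant to sample-order permutations.

# Known limitations

* The emitter count is capped at the candidate budget $K$; mixing over $M$
  relies on the block refresh finding unexplained intensity, which slows
  down in very crowded or very dim scenes.
* Parallelism is expressed as order-independence contracts (pre-assigned
  substreams), not as actual multi-threading; the R implementation is
  vectorized but single-threaded.
* Wall-clock numbers from `cli_bench` are hardware-dependent and carry no
  accuracy claim.
* The EMCCD model is the Gaussian approximation; photon-counting EMCCD
  regimes (few photons, high gain) are better served by the SPAD model or
  a future full-cascade likelihood.
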