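---
title: "dcsflow: models, noise, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dcsflow: models, noise, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcsflow)
```

`dcsflow` implements the computational chain of a diffuse correlation
spectroscopy (DCS) measurement: forward models of the intensity
autocorrelation in a semi-infinite turbid medium, multi-tau correlation of
photon-count streams, an analytic photon-counting noise model, flow-index
fitting, and limiting-aperture laser-safety analysis, together with seeded
generators that stand in for the instrument. This vignette explains the
models, their assumptions, the parameters that matter, and the numerical
decisions behind the implementation.

## The forward model and its assumptions

Dynamic light scattering in a highly scattering medium is described by the
correlation diffusion equation (CDE). For a semi-infinite homogeneous
medium probed in reflection at source-detector separation $\rho$, the
unnormalized field autocorrelation is

$$G_1(\rho,\tau) \;\propto\; \frac{e^{-K(\tau) r_1}}{r_1}
  - \frac{e^{-K(\tau) r_2}}{r_2},
\qquad
K^2(\tau) = 3\mu_a\mu_s' + \mu_s'^2 k_0^2\,\alpha\langle\Delta r^2(\tau)\rangle ,$$

where $r_1=\sqrt{\rho^2+z_0^2}$ and $r_2=\sqrt{\rho^2+(z_0+2z_b)^2}$ are
the distances to the real and image (extrapolated-boundary) sources,
$z_0 = 1/(\mu_a+\mu_s')$, $z_b = 2(1+R_\mathrm{eff})/(3\mu_s'(1-R_\mathrm{eff}))$,
and $R_\mathrm{eff} = -1.44n^{-2}+0.71n^{-1}+0.668+0.064n$ accounts for
the refractive-index mismatch $n = n_0/n_\mathrm{air}$. Scatterer motion is
Brownian, $\langle\Delta r^2(\tau)\rangle = 6 D_B \tau$, with
$\alpha D_B$ the blood flow index (BFi); $\alpha$ defaults to 1, the usual
assumption for homogeneous phantoms. The measured intensity correlation
follows from the Siegert relation $g_2 = 1+\beta|g_1|^2$, valid for a
long-coherence source and ergodic speckle; $\beta \approx 1/M$ for $M$
detected speckle modes.

Assumptions worth keeping in mind: homogeneity (no layers), reflection
geometry, the diffusion approximation (valid for $\rho \gg 1/\mu_s'$;
separations below ~10 mm push it), and pure Brownian dynamics (no
random-flow $V^2\tau^2$ term).

**Units.** The internal length unit is mm — optical coefficients in
mm$^{-1}$, separations in mm — while $D_B$ is accepted and reported in
cm$^2$/s, the convention used for flow indices; the conversion
(cm$^2$/s $\times 100 \to$ mm$^2$/s) happens once, inside $K^2$. The
wavelength enters only through $k_0 = 2\pi n_0/\lambda$. Defaults
($n_0 = 1.33$ aqueous, $\lambda = 785$ nm) match a milk-phantom experiment
at the common DCS wavelength; neither is printed with the phantom recipe
this package is calibrated against, so both are explicit, configurable
arguments.

## Finite-disk illumination

The CDE is linear in the source term, so a uniform illumination disk of
radius $a$ is handled by averaging the point-source solution over the
disk,

$$G_1^{\mathrm{disk}}(\rho,\tau) = \frac{1}{\pi a^2}
  \int_{|\mathbf r_s|\le a} G_1^{\mathrm{point}}(|\boldsymbol\rho-\mathbf r_s|,\tau)\,
  \mathrm d^2 r_s ,$$

normalized by its own $\tau = 0$ value. The integrand is smooth except for
a mild peak where the disk rim approaches the detector, so the quadrature
is Gauss-Legendre in radius crossed with a uniform midpoint grid in angle
(trapezoid-exact for the periodic integrand), starting at $16\times 32$
nodes and doubling both orders until successive refinements agree to a
relative tolerance (default $10^{-6}$); non-convergence after eight
doublings is an error carrying the grid and the last change. A unit test
pins the quadrature against a brute-force $400\times 400$ Cartesian
Riemann sum.

The disk curve decays more slowly than the point curve at every lag
(dominance is tested on a lag grid), so fitting a disk-source measurement
with the point model biases $D_B$ low. With milk-phantom optics
($\mu_a = 0.0025$, $\mu_s' = 1.0$ mm$^{-1}$), a 5 mm disk and
$D_B = 2.87\times10^{-7}$ cm$^2$/s at $\rho = 10$ mm, the point-model fit
returns $\approx 2.68\times10^{-7}$ cm$^2$/s — a $\sim$6.6% underestimate
that `disk_point_bias()` shows decaying monotonically over
$\rho = 10\dots20$ mm and vanishing in the point limit. Because the
phantom's refractive index is an assumption rather than a measurement,
this bias figure shifts by a few percent with $n_0$.

## Multi-tau correlation

The correlator estimates
$g_2(\tau) = \langle I(t)I(t+\tau)\rangle / (\langle I(t)\rangle\langle I(t+\tau)\rangle)$
on a geometric lag grid: `lags_per_block` linearly spaced lags per block,
bin width multiplied by `widening_factor` at each new block (defaults:
6.145 ns base, 16 lags per block, tripling — the scheme of a hardware time
tagger). Two dialects deserve note:

- **Normalization.** The textbook estimator divides by the squared global
  mean. The default here is the *symmetric* estimator, which divides by
  the means of the leading and trailing overlap segments; it reduces
  finite-length bias and coincides with the textbook form for stationary
  streams. The plain form is available via `symmetric = FALSE`.
- **Block alignment.** With a widening factor of 3 and 16 lags per block,
  a block boundary is generally not an integer multiple of the next
  block's bin width. Each block therefore starts at the first integer
  multiple of its own bin width beyond the previous block's last lag,
  keeping lag times strictly increasing and within-block spacing equal to
  the block's bin width.

Counts entering block $b$ are produced by summing `widening_factor`
adjacent bins of block $b-1$ (photon totals conserved exactly); product
averages use full-overlap terms only, with no wrap-around. The estimator
is pinned, exactly, against an independent direct-sum implementation on
streams up to $10^4$ bins, and a requested lag with fewer than 100 product
terms is a coverage error naming the lag.

## The noise model and SNR

For a single-exponential field decay $g_1 = e^{-\Gamma\tau}$ (so
$g_2 = 1+\beta e^{-2\Gamma\tau}$), the standard deviation of $g_2$
estimated over integration time $t$ with bin width $T$ is

$$\sigma(\tau)=\sqrt{\tfrac{T}{t}}\Big[
 \beta^2\tfrac{(1+e^{-2\Gamma T})(1+e^{-2\Gamma\tau})
 +2m(1-e^{-2\Gamma T})e^{-2\Gamma\tau}}{1-e^{-2\Gamma T}}
 +2\langle n\rangle^{-1}\beta(1+e^{-2\Gamma\tau})
 +\langle n\rangle^{-2}(1+\beta e^{-\Gamma\tau})\Big]^{1/2},$$

with $m=\mathrm{round}(\tau/T)$ the delay-bin index and
$\langle n\rangle = IT$ the mean count per bin at count rate $I$. The
grouping of the $\beta^2$ terms follows the standard
correlation-spectroscopy arrangement and is pinned by a unit test against
a direct transcription. Two implementation decisions:

- **Per-block bin width.** The formula is derived for a linear correlator.
  On multi-tau grids each lag uses its own block's widened $T$ (pass
  `bin_width_T` as a per-lag vector), the conventional adaptation; the
  empirical-vs-model comparison below uses it.
- **$\Gamma T = 0$** makes the leading term singular; the implementation
  refuses it and points at the low-count simplification
  $\sigma \approx (1/I)\sqrt{(1+\beta e^{-\Gamma\tau})/(tT)}$, which is
  exactly the $\langle n\rangle^{-2}$ term of the full model.

The simplified form is the low-count *and not-too-slow* limit: the
$\beta^2$ bracket grows like $2\beta^2/( \Gamma T)\,$ as $\Gamma T\to 0$,
so for $\langle n\rangle = 10^{-3}$ and $\beta = 0.5$ the two forms agree
within 5% at $\Gamma T = 10^{-3}$ but drift to ~15% at
$\Gamma T = 10^{-6}$, where the $\beta^2$ term rivals the shot-noise term.
The agreement test therefore runs at $\Gamma T = 10^{-3}$. Both forms
scale as $1/\sqrt t$ exactly; the $1/I$ scaling is exact for the
simplified form and asymptotic (as $\langle n\rangle \to 0$) for the full
one. The measurement quality metric is $\mathrm{SNR} = (g_2-1)/\sigma$,
and `empirical_sigma()` provides the per-lag sample standard deviation
across repeated curves for model validation: 100 simulated 1 s speckle
measurements at $10^5$ counts/s agree with the model within 25% at
$\Gamma\tau < 2$.

## Fitting

`fit_g2()` minimizes
$\sum_\tau w(\tau)\,[\,1+\beta g_1^2(\tau;D_B)-g_2^{\mathrm{meas}}(\tau)]^2$
with bounded Levenberg-Marquardt, parameterized in $\log_{10} D_B$ to keep
steps well-scaled across the $[10^{-10},10^{-4}]$ cm$^2$/s bounds;
$\beta \in (0,1]$ is free by default (initialized from $g_2$ at the first
lag minus 1) or may be fixed. Weights are uniform by default — the most
transparent choice for noise-free bias studies — with optional
$1/\sigma^2$ weighting from a curve's `sigma` column. The default fit
window runs from the first lag to where $g_2-1$ first drops below 5% of
its initial amplitude, cutting the noise-dominated tail; it is
configurable. Round-trip exactness (fitting a noise-free curve generated
by the same model recovers $D_B$ and $\beta$ to at least six significant
digits) is the primary regression test. Non-convergence is flagged in the
result, never silent, and the staged pipeline turns it into a nonzero
exit.

`fit_time_course()` fits an ordered sequence of curves and normalizes BFi
by the mean over a baseline window, yielding relative-flow traces whose
baseline mean is 1 by construction.

## Synthetic data: what it emulates, and what it does not

- **Speckle streams.** Each of $M$ modes is a complex Gaussian field
  evolving as an AR(1) process with autocorrelation $e^{-\Gamma\,\delta t}$
  — exact for a single-rate exponential decay — and detection is Poisson
  at a rate proportional to the mode-averaged intensity, calibrated to the
  target count rate. The resulting stream has
  $g_2 \approx 1+(1/M)e^{-2\Gamma\tau}$, giving direct control of $\beta$
  through the integer mode count. The simulation bin must satisfy
  $\delta t \le 0.05/\Gamma$ (enforced). This single-rate field is *not*
  the multi-exponential semi-infinite kernel; where a test needs the exact
  kernel, curves are generated analytically and noise is added from the
  full $\sigma(\tau)$ model (`generate_g2_curves()`). Detector
  afterpulsing, dead time, dark counts and ambient light are not
  simulated, so tests passing on these streams say nothing about those
  artifacts.
- **Beam images.** Circular Gaussian ($1/e^2$ diameter equal to the
  nominal diameter) and flat-top (hard or raised-cosine edge) maps,
  normalized to an exact total power, with optional additive Gaussian
  noise; real conduit outputs carry speckle, asymmetry and bending
  effects that these ideal shapes do not.
- **Occlusion protocols.** Three phases (baseline / occlusion / recovery,
  default 40 s each at relative levels 1 / 0.2 / 1) with a hyperemic
  overshoot (default 1.5$\times$) decaying exponentially (default time
  constant: a quarter of the recovery phase; zero gives a step). Values
  are sampled at window midpoints and turned into per-window model curves.
  The default $D_B$ uses the phantom-scale value, so absolute BFi in this
  demo is illustrative, not physiological.

All generators are pure functions of their spec and seed (replicate $r$
of a batch uses sub-seed `seed + r`), and the generators restore the
caller's RNG state.

## Laser-safety analysis

Skin-exposure standards limit power averaged over a fixed limiting
aperture (3.5 mm diameter), not peak irradiance.
`max_aperture_averaged_irradiance()` scans the aperture centered at every
pixel — implemented as an FFT convolution of the per-pixel power map with
a disk membership kernel (pixel-center inclusion, one-pixel step;
discretization error is below 1% once the beam spans $\gtrsim 200$
pixels) — and requires dark margin of at least one aperture radius around
the beam support. `allowed_power()` scales a beam *shape* until its
hottest aperture reaches the MPE, so it is invariant under rescaling the
input's power; a beam confined inside one aperture hits the small-source
limit MPE $\times$ aperture area, and among equal-support beams the
flat-top maximizes allowed power.

The default standard implements the IEC skin CW formula
$0.2\cdot10^{0.002(\lambda-700)}$ W/cm$^2$ ($0.2958$ at 785 nm), with the
flat ANSI 0.28 W/cm$^2$ figure as a named alternative: the package's
reference power limits (28 mW point-source; 57 mW for a 5 mm flat-top via
the integer-rounded point limit times the $(5/3.5)^2$ area ratio, 58.1 mW
unrounded) follow the IEC constant. The 91.1% in-aperture fraction of a
"5 mm Gaussian" delivered by a multi-mode fiber is an empirical profile
property — no analytic Gaussian of 5 mm nominal diameter reproduces it
(an ideal $1/e^2$-diameter definition gives 62.5%) — so functions that
need it (`aperture_power_headroom()`, `theoretical_snr_gain()`) take the
fraction as an input. The $\sim$1.75$\times$ theoretical SNR gain of
flat-top conduit illumination is computed as
$2\times0.8/0.911$: twice the allowed power, 80% conduit transmission,
against a Gaussian limited to $1/0.911$ headroom, under the $1/I$ noise
scaling.

Ocular and pulsed-exposure MPE, extended-source corrections and thermal
comfort are out of scope.

## Problem sizes and determinism

The test suite and the acceptance script are sized for a laptop-class
single-core run: speckle streams of 1-10 s at a $10^{-5}$ s simulation
bin ($10^5$-$10^6$ bins), 100-replicate noise ensembles, $10^4$-replicate
Gaussian-noise ensembles, beam maps of 100-600 pixels per side, and
60-lag fits; the full suite completes in well under a minute except for
the stream ensembles (a few seconds each). Every stochastic step takes an
explicit seed, and the staged pipeline logs the resolved configuration,
seed and package version next to each output.

## Known limitations

- Homogeneous semi-infinite medium only; no layered or voxelized
  transport models, and no transmission geometry.
- Brownian dynamics only (no shear/random-flow mean-square-displacement
  terms).
- The noise model omits afterpulsing, dark counts and ambient light; at
  very low $\Gamma T$ its full and simplified forms genuinely diverge (see
  above), so regime choice matters when using the simplified form.
- Aperture membership is pixel-center based; very coarse beam maps
  (tens of pixels across) should be regenerated at finer pitch rather
  than trusted to sub-percent accuracy.
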