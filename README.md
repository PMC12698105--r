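# dcsflow

Diffuse correlation spectroscopy (DCS) measures deep-tissue blood flow from
the temporal fluctuations of multiply scattered coherent light: moving red
blood cells (or milk particles, in phantoms) decorrelate the detected
speckle field, and the decay of the normalized intensity autocorrelation
g₂(τ) encodes a blood flow index. `dcsflow` implements the complete
computational chain of such a measurement for researchers building or
evaluating DCS instruments:

- **Forward models** — the semi-infinite correlation diffusion equation
  (CDE) Green's function for point illumination, and its area-averaged
  extension for finite disk sources (e.g. a 5 mm liquid-light-guide spot),
  linked to g₂ by the Siegert relation g₂ = 1 + β|g₁|².
- **Multi-tau correlator** — g₂ estimation from photon-count streams with
  the geometric lag-widening scheme of hardware time taggers (6.145 ns base
  resolution, 16 lags per block, bin width tripling per block, by default).
- **Noise / SNR model** — the analytic photon-counting standard deviation
  σ(τ) of measured g₂ (full form and its low-count, slow-decay
  simplification σ ≈ (1/I)·√((1+βe^(−Γτ))/(tT))), and the measurement
  SNR = (g₂−1)/σ.
- **Flow-index fitting** — bounded least-squares recovery of the Brownian
  diffusion coefficient D_B (BFi = αD_B) from measured or synthetic curves,
  batch time courses, and quantification of the finite-source fitting bias
  at short source-detector separations.
- **Laser-safety analysis** — limiting-aperture maximum-permissible-exposure
  (MPE) calculations for measured or synthetic beam profiles: the maximum
  power averaged over any 3.5 mm sub-aperture, the allowed total power for
  a beam shape, in-aperture power fractions, and beam-uniformity reports.
- **Synthetic data** — seeded generators for speckle photon streams (AR(1)
  complex Gaussian fields, Poisson detection), noisy g₂ replicates, beam
  images, and cuff-occlusion flow protocols, so the whole chain runs
  without an instrument.

## The model at the core

For a semi-infinite homogeneous medium the field autocorrelation is

G₁(ρ,τ) ∝ exp(−K(τ)r₁)/r₁ − exp(−K(τ)r₂)/r₂,

with K²(τ) = 3μ_aμ_s′ + μ_s′²k₀²α⟨Δr²(τ)⟩, ⟨Δr²(τ)⟩ = 6D_Bτ for Brownian
motion, r₁, r₂ the real/image source distances built from
z₀ = 1/(μ_a+μ_s′) and the extrapolated boundary z_b(R_eff). A finite
illumination disk of radius a replaces the point source by its area
average, which decays more slowly and — if fitted with the point model —
biases D_B low at short separations.

## Worked example: finite-source fitting bias

```r
library(dcsflow)

# Milk-phantom optics at 785 nm
props <- optical_properties(mu_a = 0.0025, mu_s_prime = 1.0, n0 = 1.33)
geom  <- semi_infinite_geometry(rho = 10, props)

# Noise-free g2 curve from a 5 mm disk source at DB = 2.87e-7 cm^2/s
flow <- flow_model(DB = 2.87e-7)
tau  <- default_lag_grid(geom, props, flow)
curve <- model_g2_curve(geom, props, flow, tau, beta = 0.5,
                        model_kind = "disk", source_radius = 2.5)

# Fit it with the point-source model: the finite source biases DB down
fit_g2(curve, props, rho = 10, model_kind = "point")
#> <fit_result> point model
#>   DB = 2.67895e-07 cm^2/s, beta = 0.4993
#>   residual norm 0.00418 over 49 lags (window 1.77e-08 .. 4.87e-06 s)
```

The disk-generated curve, fitted with the point model, returns
D_B ≈ 2.68×10⁻⁷ cm²/s instead of the generating 2.87×10⁻⁷ — a ~6.6%
underestimate at ρ = 10 mm that fades rapidly at larger separations
(`disk_point_bias()` maps it over a ρ grid).

Safety side, at 785 nm under the IEC skin CW limit:

```r
std  <- safety_standard("iec", wavelength = 785)
flat <- generate_beam_image("flattop", diameter = 5, pixel_pitch = 0.05)
point_source_power_limit(std) * 1000   # 28.5 mW
allowed_power(flat, std) * 1000        # 58.1 mW
aperture_power_headroom(0.911)         # 1.10 (5 mm Gaussian headroom)
theoretical_snr_gain(2, 0.8, 0.911)    # 1.76
```

A uniform 5 mm flat-top beam may deliver about twice the total power of a
sub-aperture ("point") source at the same limiting-aperture irradiance,
while a 5 mm Gaussian with 91.1% of its power in the central 3.5 mm gains
only ~10%; folding in an 80% conduit transmission yields the ~1.75×
theoretical SNR advantage of flat-top illumination.

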