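# vegpattern

Dryland vegetation self-organizes into spotted, labyrinthine, gapped and
striped patterns through scale-dependent feedbacks: plants improve local
water infiltration, so water flows from bare ground to vegetated patches,
favouring growth at one characteristic distance and suppressing it at
others.  Classical reaction–diffusion models reproduce these patterns in
idealized *homogeneous* environments, but the result is far more regular
than anything seen in nature.  `vegpattern` treats pattern formation as a
**stochastic process**: time-constant random environmental heterogeneity
(soil properties, microtopography) enters a model coefficient as a
spatially correlated log-normal random field, and the biophysical feedbacks
act as a **linear filter** on that noise.  The package is for quantitative
ecologists and modellers who want to simulate this process, measure the
spectral structure of patterns (their own or model output), and replace a
nonlinear simulator with a calibrated linear filter.

It provides three connected layers:

1. **Nonlinear models** on periodic grids with spatially varying
   coefficients:
   * a single-species grazing model,
     `db/dt = a b (1 − b/K) − c b²/(b_n² + b²) + e ∇²b`, whose carrying
     capacity `K` can vary in space (irregular patterns), and
   * the Rietkerk scale-dependent feedback model for biomass `b`, soil
     water `w` and surface water `h`, with uptake
     `U = g_b w/(w+k_U) b`, vegetation-enhanced infiltration
     `I = a h (b + k_I w_0)/(b + k_I)`, rainfall `R`, and downslope
     advection `v_h` (regular isotropic and striped patterns).
2. **Spectral diagnostics**: periodograms and tile-averaged (Welch)
   densities, radial/directional reductions, the characteristic wavelength
   `λ_c = 2π/k_c`, the scale-invariant regularity `S_c/λ_c`, the cut-off
   wavelength of low-pass-shaped densities, spectral coherence and
   empirical transfer functions between the heterogeneity and the pattern,
   a surrogate-based periodicity test, and analytic-signal phase profiles
   of stripe trains.
3. **Parametric linear filters** fitted by minimizing the Hellinger
   distance between densities (`fit_filter()`, an S3 model object with
   `coef`/`predict`/`simulate`/`plot` methods): a higher-order low-pass
   family for irregular patterns, a two-parameter band-pass family whose
   parameters map one-to-one to `(λ_c, regularity)`, and a noisy-oscillator
   model (Lorentzian line pairs from Brownian phase noise) for striped
   patterns.  Filtered noise is thresholded to a vegetation cover fraction
   to recover the bimodal biomass distribution.

## Worked example

Simulate the Rietkerk model in a heterogeneous environment, measure the
pattern, and replace the model by a band-pass filter:

```r
library(vegpattern)

g  <- vp_grid(256, 256, dx = 1)                       # 256 m x 256 m
a  <- heterogeneity_field(mean = 0.2, cv = 0.3,       # infiltration coefficient
                          theta = 10, grid = g, seed = 21)
sim <- simulate_rietkerk(rietkerk_params(R_h = 0.7), g, a = a,
                         t_end = 3000, seed = 2)
sim
#> Rietkerk simulation: 256 x 256 grid, t = 700 d (stationary), mean biomass 6.91 g/m^2

pattern_summary(sim$b, n_surrogates = 99, seed = 12)
#> $lambda_c     52.4        # patch spacing, metres
#> $regularity   0.949       # intermediate: regular but far from periodic
#> $lambda_l     NA
#> $p_periodic   0.99        # not classified periodic

fit <- fit_filter(sim$b, "bandpass")
fit
#> bandpass filter fit (Hellinger distance)
#>   parameters: k_c = 0.0909, alpha = 1.323
#>   R^2 = 0.989
#>   lambda_c = 69.1 m, regularity = 0.617
```

`simulate(fit, grid = g, seed = 99, cover = 0.35)` then draws new patterns
with the same spatial structure from white noise — no PDE integration — and
`synthesize(fit, noise = a)` filters the *original* heterogeneity map to
predict where patches sit.  In a homogeneous environment
(`heterogeneity_field` with `cv = 0`, or `a = NULL`) the same pipeline
yields `λ_c ≈ 44` m, a much higher regularity, and a periodicity p-value
near zero: environmental noise, not water scarcity, controls how regular
the pattern is.

The numbers above are what the code prints at these settings (the run stops
at 700 d, where the spectral density is stationary by the default
tolerance); patterns and metrics vary with the seed within the sampling
spread quoted in the tests, and the Hellinger-fitted wavelength can sit
above the ring-maximum wavelength when the lobe is broad.

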