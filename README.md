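# voltaxis

Continuum modelling of spatially heterogeneous collective electrotaxis.

When an epithelial monolayer (e.g. an MDCK sheet) is stimulated with a
direct-current electric field of a few V/cm, the whole tissue migrates
along the field — but not uniformly: the bulk moves fastest while the edge
regions, which carry an endogenous cue to crawl outward, respond more
weakly and in superposition with it. `voltaxis` is an R package for
modelling, calibrating and exploiting this behaviour. It is aimed at
quantitative cell biologists and modellers who want to fit electrotaxis
recordings, predict how tissue size and geometry shape the migratory
response, and design electric fields that steer a tissue at a prescribed
velocity.

## Models

**Signal dynamics** — the field stimulus `s(t)` drives an effective signal
with perfect adaptation (excitation timescale τ<sub>e</sub> = 0.26 h,
adaptation timescale τ<sub>a</sub> = 2.04 h):

    τe ds_eff/dt = s − s_eff − I,     τa dI/dt = s − I,
    s_eff⁺ = max(s_eff, 0).

**Four-region velocity model** — force balance per unit mass for the
x-velocity of the bulk, leading, trailing and top edge regions:

    dv_bulk/dt  = −γ v + α∥ s_eff⁺
    dv_lead/dt  = −γ v + δ α∥ s_eff⁺ + α_edge
    dv_trail/dt = −γ v + δ α∥ s_eff⁺ − α_edge
    dv_top/dt   = −γ v + δ α⊥ s_eff⁺

with friction rate γ (fitted from post-stimulation exponential decay) and
edge sensitivity δ ∈ [0, 1]. Calibrated MDCK values ship as
`default_region_params()`: γ = 1.765 h⁻¹, α∥ = 171.95, α⊥ = 217.08
µm/h², δ = 0.31, α_edge = 24.93 µm/h².

**Continuum model** — the monolayer density ρ (normalised u = ρ/K) obeys a
reaction–advection–diffusion law with degenerate diffusion, density-scaled
electrotactic advection and logistic growth:

    ∂u/∂t = ∇·(D u ∇u) − ∇·(u χ(u) E) + r u (1 − u),
    χ(u) = α s_eff⁺ (δ + (1 − δ) u),      v = −D∇u + χ(u) E.

Calibrated values (`default_continuum_params()`): α = 0.837 mm/h,
D = 13.30 mm²/h, δ = 0.625, r = 0.180 h⁻¹, K = 260.29 cells/mm. The
solver is a conservative finite-volume scheme (compiled core) with
implicit nonlinear diffusion and exact logistic updates; 2D simulations
run on arbitrary tissue-shaped masked domains with no-flux boundaries.

**Inference** — Haario-style adaptive-covariance Metropolis
(`run_adaptive_mcmc()`), four chains, split-R̂ convergence diagnostics,
posterior predictive bands, with observation noise sampled as a nuisance
parameter. `fit_regions()` and `fit_continuum_1d()` wrap the two models;
results support `tidy()`, `glance()` and `autoplot()`.

**Field design** — `design_gradient_1d()` / `design_potential_1d()` invert
the velocity relation in closed form (with magnitude capping at a tolerable
field strength), and `heuristic_field()` implements the practical 2D
design: fixed magnitude, direction along the optimal gradient.

All field magnitudes are dimensionless with 1 ≡ 3 V/cm.

## Worked example

Generate synthetic region velocity traces at the calibrated truth (2 µm/h
noise, 5-minute sampling, 1 h off / 3 h on / 3 h off at 3 V/cm) and
recover the parameters by MCMC:

```r
library(voltaxis)

cfg <- synthetic_config(sigma_v = 2, seed = 1)
traces <- gen_region_traces(cfg)
fit <- fit_regions(traces, cfg$protocol, seed = 1)
tidy(fit)
#> # A tibble: 5 × 5
#>   term       estimate conf.low conf.high r_hat
#>   <chr>         <dbl>    <dbl>     <dbl> <dbl>
#> 1 alpha_par   172.     170.      175.     1.00
#> 2 alpha_perp  222.     212.      233.     1.00
#> 3 delta         0.310    0.299     0.320  1.00
#> 4 alpha_edge   24.7     24.3      25.3    1.00
#> 5 sigma         1.93     1.79      2.07   1.00
```

Every generating parameter is recovered within a few percent (truth:
α∥ = 171.95, α⊥ = 217.08, δ = 0.31, α_edge = 24.93, σ = 2), the 95%
credible intervals cover the truth, and all chains mix (R̂ ≈ 1.00). The
friction rate comes straight from the post-stimulation decay of the bulk
velocity:

```r
clean <- simulate_regions(default_region_params(), step_protocol(),
  times = seq(0, 7, 1 / 12))
estimate_gamma(clean, window = c(4.5, 7))
#> <gamma_fit> gamma = 1.765 1/h, v0 = 14.9004 um/h (n = 31, from t0 = 4.5 h)
```

— exactly the generating value, because once the signal has collapsed the
model decay is a pure exponential. On the noisy traces the same fit over a
1-hour window gives `gamma = 1.52` 1/h, illustrating the estimator's
sampling spread at 13 noisy points.

Continuum side: solve the 1D model on the −3.5…3.5 mm field of view and
sweep tissue geometries,

```r
p <- default_continuum_params()
init <- gen_density_profile_1d(synthetic_config())
kym <- solve_rad_1d(p, init, step_protocol(), output_times = 0:7)
autoplot(kym) # density kymograph

size_sweep("circle", c(0.25, 1, 2.5, 4), p, spacing = 0.05)
```

and design a field that moves a 3.5 mm circular tissue uniformly at
47 µm/h along x:

```r
tissue <- uniform_tissue(geometry_mask("circle", 3.5, spacing = 0.05),
  p$K, smooth = TRUE)
fmap <- heuristic_field(p, tissue, v_star = c(um_to_mm(47), 0), s_max = 1)
autoplot(fmap) # edge bands where the field opposes outward spreading
```

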