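---
title: "Modelling spatially heterogeneous collective electrotaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatially heterogeneous collective electrotaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(voltaxis)
```

## The biological problem

When a confluent epithelial monolayer (the canonical system is an MDCK
sheet) is exposed to a direct-current electric field of a few V/cm, its
cells polarise and migrate along the field — collective electrotaxis. The
response is strongly heterogeneous in space: the tissue bulk moves fastest,
while the edge regions, where cells already carry an endogenous cue to
crawl outward, respond more weakly. `voltaxis` implements a hierarchy of
models for this phenomenon:

1. an **adaptation–excitation signal model** for the intracellular
   representation of the field,
2. a **four-region force-balance ODE model** for the x-velocities of the
   bulk, leading, trailing and top edges,
3. **Bayesian calibration** of both models by adaptive-covariance MCMC,
4. a **density-dependent reaction–advection–diffusion continuum model** of
   the whole monolayer, and
5. **electric-field design**: closed-form 1D potentials and a
   fixed-magnitude 2D heuristic that drive a prescribed tissue velocity.

All field magnitudes are dimensionless, normalised so that the 3 V/cm
stimulus of the reference experiments equals 1 (`FIELD_UNIT_V_PER_CM`).
Velocities are in µm/h in the region model and mm/h in the continuum model
(`um_to_mm()`, `mm_to_um()`).

## Signal dynamics

The stimulus `s(t)` drives an effective signal and an inhibitor,

$$\tau_e \dot s_{\mathrm{eff}} = s - s_{\mathrm{eff}} - I, \qquad
  \tau_a \dot I = s - I,$$

with a fast excitation timescale $\tau_e = 0.26$ h and a slow adaptation
timescale $\tau_a = 2.04$ h (both fixed throughout, as they are in the
calibration this package emulates). The system adapts perfectly: under any
sustained stimulus $s_{\mathrm{eff}} \to 0$ and $I \to s$. One sign
ambiguity deserves note: the equation for $\dot s_{\mathrm{eff}}$ is only
compatible with perfect adaptation when the inhibitor is *subtracted*
(steady state $s_{\mathrm{eff}} = 0$), which is the convention implemented
here; the alternative reading (steady state $2s$) contradicts the model's
defining property and is rejected. The motility drive is the positive part
$s_{\mathrm{eff}}^+ = \max(s_{\mathrm{eff}}, 0)$, because the signal
transiently undershoots zero after stimulation ends.

Protocols are piecewise constant (`stimulus_protocol()`, `step_protocol()`)
and the linear system is propagated *exactly* on each constant interval via
the closed-form matrix exponential, so no step-size error enters downstream
inference. In two dimensions only the field magnitude drives the signal.

The stimulation timing of the reference experiments is not printed in the
source data description; the package default — 1 h rest, 3 h at magnitude
1, 3 h rest, 5-minute sampling — is an assumption, chosen to be consistent
with every timing the experiments do report, and is configurable
everywhere.

## The four-region velocity model

Each region's x-velocity obeys a force balance per unit mass: viscous
friction $-\gamma v$, an electrotactic active force
$\propto s_{\mathrm{eff}}^+$, and a constant outward edge force at the
leading/trailing edges,

$$\dot v_{\mathrm{bulk}} = -\gamma v + \alpha_\parallel s^+_{\mathrm{eff}},
 \quad
 \dot v_{\mathrm{lead/trail}} = -\gamma v +
 \delta\alpha_\parallel s^+_{\mathrm{eff}} \pm \alpha_{\mathrm{edge}},
 \quad
 \dot v_{\mathrm{top}} = -\gamma v + \delta\alpha_\perp s^+_{\mathrm{eff}}.$$

$\delta \in [0,1]$ encodes the reduced field sensitivity of the edges. The
bottom edge is omitted (identical to the top by symmetry), and the model
deliberately does not reproduce the post-stimulation velocity undershoot
seen at the top/trailing edges of real tissues — that phenomenon needs
additional signalling assumptions outside this model's scope, so passing
recovery tests here says nothing about it.

Because $\gamma$, $\tau_a$, $\tau_e$ are fixed during calibration, every
model trace is *linear* in $(\alpha_\parallel, \alpha_\perp, \delta
\alpha_\parallel, \alpha_{\mathrm{edge}})$ given two precomputable response
functions: the convolution $g(t) = \int_0^t e^{-\gamma(t-u)}
s^+_{\mathrm{eff}}(u)\,du$ and the step response $(1 -
e^{-\gamma t})/\gamma$. `simulate_regions()` exploits this with an
exponential integrator that is exact for piecewise-linear forcing (the
signal is sampled on a fine auxiliary grid, default $5\times10^{-4}$ h,
giving errors far below the $10^{-6}$ oracle tolerance used in the tests),
and `fit_regions()` reuses the same basis to make each MCMC likelihood
evaluation a handful of vector operations.

The friction rate is identified separately: after stimulation ends the
signal collapses within minutes ($\tau_e$-fast) and the bulk velocity
decays as a pure exponential, so `estimate_gamma()` fits
$v_0 e^{-\gamma(t - t_0)}$ — a log-linear least-squares fit (convex,
robust) refined by nonlinear least squares (the right estimator under
additive Gaussian noise). Fit windows must stay above the noise floor; the
function refuses windows containing zeros or sign changes rather than
returning a meaningless rate. The calibrated value for MDCK monolayers is
$\gamma = 1.765\,\mathrm{h}^{-1}$ (`default_region_params()`).

## Bayesian calibration

`run_adaptive_mcmc()` is a random-walk Metropolis sampler with
Haario-style adaptive covariance and global-scale tuning: after a
200-iteration non-adaptive phase, the running covariance, mean and a global
log-scale are updated with decaying weight $(i - 200)^{-0.6}$, targeting
the standard 0.234 acceptance rate. Four chains, independent uniform
priors, at most $2\times10^4$ iterations, convergence monitored by
split-$\widehat R$ (the classic variant, not rank-normalised) against the
usual 1.05 threshold. Burn-in discards the first half of each chain; no
thinning. The observation noise is never assumed known: it is sampled as a
nuisance parameter with a uniform prior (0–20 µm/h for velocities, 0–50
cells/mm for densities). Priors for the region model are uniforms
generously bracketing the calibrated values
($\alpha_\parallel, \alpha_\perp \in [0, 500]$ µm/h²,
$\delta \in [0,1]$, $\alpha_{\mathrm{edge}} \in [0, 100]$ µm/h²); the
continuum priors are $\alpha \in [0,2]$ mm/h, $D \in [0,20]$ mm²/h,
$\delta \in [0,1]$, $r \in [0,1]$ 1/h, $K \in [0,300]$ cells/mm.
`posterior_predictive_band()` produces middle-95% envelopes from posterior
draws.

```{r ode-fit, eval = FALSE}
cfg <- synthetic_config(sigma_v = 2, seed = 1)
traces <- gen_region_traces(cfg)
fit <- fit_regions(traces, cfg$protocol, seed = 1)
tidy(fit)
```

On synthetic traces at the calibrated truth (2 µm/h noise, 5-minute
sampling), all four sampled parameters return within a few percent with
$\widehat R \le 1.01$ in a few seconds — this is the package's core
recovery check.

## The continuum model

The monolayer density $\rho(\mathbf x, t)$ (handled internally as
$u = \rho/K$) evolves by

$$\partial_t u = \nabla\!\cdot\!\big(D\,u \nabla u\big)
 - \nabla\!\cdot\!\big(u\,\chi(u)\,\mathbf E\big) + r\,u(1-u),
 \qquad \chi(u) = \alpha\, s^+_{\mathrm{eff}} \big(\delta + (1-\delta)u\big),$$

with degenerate (porous-medium-type) diffusion, electrotactic advection
that is strongest in the bulk and reduced by $\delta$ at the low-density
edge, and logistic proliferation. The induced migration velocity is

$$\mathbf v = -D\nabla u + \chi(u)\,\mathbf E.$$

Two sign conventions had to be fixed here, and they are the most
consequential interpretations in the package: written naively, a
conservation law with flux $+D\rho\nabla\rho$ and velocity $+D\nabla\rho$
would make diffusion sharpen the tissue inward. The implemented convention
(diffusive flux down-gradient, velocity $-D\nabla u + \chi\mathbf E$) is
the unique choice under which the tissue spreads outward and electrotaxis
advects along the field, matching every qualitative statement the models
are meant to reproduce. Similarly, the printed carrying capacity
($K = 260.29$ cells/mm) and diffusion coefficient ($D = 13.30$ mm²/h) are
only dimensionally consistent if the PDE acts on the normalised density
$u$; the package therefore solves in $u$ and rescales by $K$ on output.

### Numerics

`solve_rad_1d()` / `solve_rad_2d()` use a conservative cell-centred
finite-volume scheme (compiled core) with operator splitting per step:

* **advection** — explicit first-order upwind with face speed
  $\chi(\bar u_f) E_f$, CFL safety factor 0.4;
* **diffusion** — backward-Euler with the lagged face coefficient
  $D\bar u_f$: an M-matrix tridiagonal solve per grid line, conservative
  and unconditionally stable (essential, because explicit steps at
  $D = 13.3$ mm²/h and 0.05 mm spacing would need $\sim10^{-5}$ h);
* **reaction** — the exact logistic update
  $u \mapsto u e^{r\Delta t}/(1 + u(e^{r\Delta t}-1))$, so pure logistic
  growth is reproduced to machine precision regardless of the step.

The default step bound is `dt_max = 0.01` h; the splitting is first-order
in time, and the synthetic-data generator and the fitting likelihood share
the same discretisation, so recovery studies are self-consistent. Mass is
conserved to roundoff with $r = 0$; positivity follows from upwinding under
CFL, the M-matrix property, and the logistic form (the core aborts if a
real violation ever appears). Dimensional splitting makes y-invariant 2D
problems reduce to the 1D solver row by row to ~$10^{-12}$, which the tests
assert.

In 2D the **mask is the computational domain**: faces crossing the mask
boundary carry zero flux, imposing no-flux conditions at the tissue edge.
This reading — tissue-shaped domains rather than tissues dispersing into an
open box — is what makes a uniform $\rho = K$ tissue a meaningful initial
state and designed fields nearly constant in time, and it is the setup
under which the geometry studies below are run. Velocity evaluation on
masked domains uses one-sided gradients at the boundary, and drops the
advective component in directions where a cell has no open faces (a cell
that cannot exchange flux along x cannot move along x; without this rule,
sub-grid-width corner cells report spurious bulk-speed velocities).

### Geometry and size sweeps

`size_sweep()` simulates circular or triangular tissues (`geometry_mask()`,
`uniform_tissue()`) across a range of sizes and records the maximum of
$|\mathbf v|$ over space and time during the stimulation window, over cells
holding at least 10% of the instantaneous peak density. At the calibrated
parameters the maximum velocity *rises with tissue size* for both shapes:
with no-flux boundaries, advection tilts the density against the leading
edge until the diffusive flux balances it and the net velocity decays, and
the time this equilibration takes grows as $L^2/D$ — small tissues
equilibrate almost instantly (small transient maxima), large ones are still
in transit when the signal peaks. Within 0.25–4 mm the curve has not yet
plateaued (a plateau requires the equilibration time to exceed the
stimulation window), and the two shapes behave nearly identically because
at $D = 13.3$ mm²/h diffusion globally equilibrates any corner-localised
pile-up. A strong shape contrast at these parameter values — in particular
a near-size-independent triangle curve — could not be reproduced under any
sign convention or velocity definition we examined; the sweep reports what
the stated model actually does.

### Data-processing operators

`histogram_density()` bins segmented-nuclei coordinates on the standard
150×150 grid; `strip_average()` y-averages a 2D field over a horizontal
strip a fixed margin away from the top/bottom edges, mirroring how
y-averaged 1D profiles are extracted from monolayer movies;
`gen_nuclei_points()` draws seeded spatial Poisson point clouds from an
intensity surface.

## Field design

Given a target velocity $v^*$ and a frozen density snapshot, inverting the
velocity relation gives the 1D design gradient

$$E(x) = \frac{v^* + D\,\partial_x u}
              {\alpha s_{\mathrm{eff}} (\delta + (1-\delta)u)},$$

(`design_gradient_1d()`): stronger against outward spreading at the leading
edge, weaker at the trailing edge. Because $s_{\mathrm{eff}} \to 0$ both at
start-up and under sustained stimulation, the raw expression diverges; the
gradient is clamped to a physiologically tolerable magnitude
$s_{\mathrm{max}}$ as $\mathrm{sign}(E)\min(|E|, s_{\mathrm{max}})$. (The
corresponding printed formula reads as a *floor*, $\max(\cdot,
s_{\mathrm{max}})$, which would enforce arbitrarily strong fields; given
that $s_{\mathrm{max}}$ is defined as the *maximum tolerable* strength, the
magnitude clamp is the only coherent reading.) $s_{\mathrm{max}}$ never
receives a numeric value in the source material; the package default is 1
(≡ 3 V/cm) and it is an explicit argument everywhere. The recommended
start-up policy is to stimulate at constant $s_{\mathrm{max}}$ until
$s_{\mathrm{eff}}$ exceeds a threshold (default suggestion 0.2), then
switch to the designed gradient, re-evaluated against the current density
at a configurable cadence (quasi-static design).

`design_potential_1d()` evaluates the closed-form potential (the
density-gradient part integrates exactly to a logarithm; only the $v^*$
part needs quadrature), anchored at $\phi(x_0) = 0$; its discrete gradient
matches `design_gradient_1d()` to discretisation order, and for $\delta =
1$ it falls back to direct integration. Feeding the uncapped gradient back
into the velocity relation returns $v = v^*$ identically (the tests assert
$10^{-8}$) because the same discrete gradient operator is used on both
sides.

In 2D, `design_gradient_2d()` gives the vector field $s^*$, and
`heuristic_field()` implements the practical fixed-magnitude design
$\nabla\phi = s_{\mathrm{max}} \hat s^*$: only the *direction* follows the
optimal gradient (which is independent of the unknown signal level), so the
field needs no knowledge of $s_{\mathrm{eff}}$. On circular and triangular
tissues at capacity this produces the characteristic edge bands where the
field's lateral component opposes the outward normal, visible via
`autoplot()` on the returned `field_map` or `field_transect()`.

```{r design, eval = FALSE}
p <- default_continuum_params()
tissue <- uniform_tissue(geometry_mask("circle", 3.5, spacing = 0.05),
  p$K,
  smooth = TRUE
)
fmap <- heuristic_field(p, tissue, v_star = c(um_to_mm(47), 0), s_max = 1)
autoplot(fmap)
```

## The synthetic-data generators

`synthetic_config()` bundles the study conditions the package's tests and
acceptance analyses run under; they emulate the *structure* of the
published MDCK experiments, not their raw images: step-field stimulation at
magnitude 1 (3 V/cm), region-resolved velocity traces at 5-minute sampling
with i.i.d. Gaussian noise of 2 µm/h (about 4% of the peak bulk velocity),
density profiles on the −3.5…3.5 mm field of view with a plateau at $K$ and
sigmoidal edge ramps (default width 0.2 mm), density observation noise of
10 cells/mm (the same ~4% fraction of its scale), and seeded Poisson nuclei
clouds for the histogram pipeline. All generators are pure functions of
(config, seed). What they deliberately omit: temporal autocorrelation of
PIV noise, density fluctuation textures, the post-stimulation undershoot,
and PIV itself — so green recovery tests certify the estimators under the
stated noise model, not robustness to those real-data features.

One identifiability caveat is worth stating plainly: at the calibrated
continuum parameters, density anomalies created by the $\delta$-dependent
part of the electrotactic flux relax diffusively on a timescale of minutes
— orders of magnitude faster than they accumulate — so the 1D density
likelihood is nearly flat in $\delta$ and its posterior mean is not a
reliable point estimate at realistic noise (unlike $D$, $r$, $K$ and
$\alpha$, which recover within a few percent). This is a property of the
stated parameter regime, not of the sampler; the same flatness is measured
directly in the likelihood.

## Reproducibility and scale choices

The test suite and `scripts/acceptance.R` run at desk scale, chosen as the
package's own defaults: full-length region-model MCMC (4 × 20 000
iterations; seconds, thanks to the linear-likelihood basis), 10 000
iterations for the continuum fit on a 141-cell grid with 15-minute
kymograph sampling, and two-point size sweeps at 0.05 mm spacing. Every
random quantity flows from a single integer seed. `write_run_manifest()`
drops a JSON manifest (package version, seed, config) next to any output.
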