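---
title: "Modeling magnetically controlled intraperitoneal drug targeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling magnetically controlled intraperitoneal drug targeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdtsim)
```

## The problem

Intraperitoneal (IP) chemotherapy bathes peritoneal tumors in a high drug
concentration, yet the drug rarely penetrates more than a few tens of
micrometers into the tumor: elevated interstitial fluid pressure (IFP)
drives an outward convective flow at the tumor rim, the leaky
microvasculature clears free drug back into the plasma within seconds to
minutes, and binding to the first cell layers consumes what little gets in.
Magnetically controlled drug targeting (MCDT) loads the drug onto magnetic
nanoparticle (MNP) carriers and uses an external permanent magnet to pull
them into the tissue against these barriers.

`mcdtsim` is a deterministic simulator of this system on a two-dimensional
circular tumor. It couples four stages, solved in sequence:

1. **steady interstitial flow** — Darcy's law with a Starling transvascular
   source;
2. **magnetostatics** — the analytic field of a uniformly magnetized
   rectangular magnet and the saturable force it exerts on a carrier;
3. **drug transport** — the coupled free/bound/internalized concentration
   fields with convection, diffusion, pore-model vascular exchange, and
   receptor binding/internalization kinetics;
4. **efficacy metrics** — penetration half-depth $w_{1/2}$, relative
   penetration area $PA_{rel}$, and killed-cell fractions $FK_{PA}$ and
   $FK_{eff}$ from an exponential cell-survival model.

## Interstitial flow

The interstitium is a porous medium: $v_i = -\kappa \nabla P_i$ with
$\nabla \cdot v_i = \phi_B - \phi_L$. Starling's law gives the
transvascular filtration per unit volume,
$$\phi_B = L_p \tfrac{S}{V}\left(P_B - P_i - \sigma_s(\pi_B - \pi_i)\right),$$
and the lymphatic drainage $\phi_L$ is zero (solid tumors lack functional
lymphatics). The source vanishes at the Starling equilibrium pressure
$P_e = P_B - \sigma_s(\pi_B - \pi_i) = 1470$ Pa for the default parameter
set, which is therefore the exact ceiling of the IFP (a discrete maximum
principle of the finite-volume operator). With the default tissue
parameters the dimensionless group $\alpha = R\sqrt{L_p S / (V \kappa)}
\approx 37$, so the pressure sits on a plateau at $P_e$ over almost the
whole tumor and falls to the peritoneal value across a boundary layer of
width $R/\alpha \approx 0.27$ mm; the fluid velocity is negligible inside
and peaks at $\kappa P_e \sqrt{L_p S/(V\kappa)} \approx 0.165\ \mu$m/s at
the rim, directed outward — the main convective barrier to drug entry.

A necrotic core (radius `Rn`) carries no functional vessels: the source and
all solute exchange are switched off there while pressure, flux and
concentration remain continuous across the interface. The default is
`Rn = 0`: the tumor-mean concentrations produced by deep magnetic plumes
are sensitive to a lossless core (it removes the vascular sink over up to a
quarter of the disk and inflates the means by ~30% in strong-magnet
scenarios), and the efficacy surface this package is benchmarked against
behaves like a fully perfused disk. Users modeling necrosis explicitly
should set `Rn` and re-examine the deep-penetration scenarios.

## Magnetostatics and the carrier drift

The magnet is a uniformly magnetized rectangle in plane magnetostatics
(2D, consistent with the circular tumor cross-section), centered above the
tumor with remanence pointing at it; `distance_d` separates the tumor
center from the nearest face. With zero free current the field is that of
two equivalent surface-current sheets on the magnet's side faces, with
closed-form log/arctan expressions and an analytic Jacobian. The force on a
carrier of volume $V$ is
$$F_m = \mu_0 V\, [\nabla H]^{\mathsf T} M(H), \qquad
  M(H) = \min\!\left(\tfrac{\chi}{1+\chi/3}\|H\|,\ M_{sat}\right)\hat H,$$
which reduces to $\tfrac12 \mu_0 V \chi_{eff}\nabla\|H\|^2$ below
saturation; saturation (sharp clamp at $\mu_0 M_{sat} = 0.5$ T) changes
only the magnitude, never the direction. The drift velocity balances
Stokes drag: $v_e = F_m/(6\pi a \eta)$.

Two design points deserve emphasis:

* **The mobility calibration.** The effective susceptibility is capped at 3
  by the self-demagnetization factor and the magnetization at 0.5 T, so for
  a 100 nm solid particle at 5 cm from a 1.5 T magnet the drift is bounded
  by $\approx 2\ \mu$m/s no matter how $\chi$ is chosen — whereas
  reproducing a millimeter-scale penetration half-depth against the
  vascular washout ($P\,S/V = 0.06\ \mathrm{s^{-1}}$) requires tens of
  $\mu$m/s (in the advection-dominated regime the concentration decays
  with length $\lambda = v/k$, so $v = k\, w_{1/2}/\ln 2$). The magnetic
  moment per hydrodynamic radius of real drug-coated carriers (multi-core
  clusters, chained aggregates) is poorly constrained and can exceed the
  solid-sphere value by orders of magnitude; the package therefore carries
  a single dimensionless `mobility_scale` on the drift, calibrated once
  against a penetration-depth anchor (`calibrate_mobility()`, monotone
  secant on the log scale, 1% tolerance) and recorded in provenance. The
  bounded $\chi$-calibration (`calibrate_susceptibility()`) is kept and
  reports its narrow achievable range when a target is out of reach.
* **Hindered drag.** Transport of a large carrier through the extracellular
  matrix is obstructed as its radius approaches the matrix pore scale. We
  model this as an exponential drag factor $e^{(a - a_{ref})/L}$ on the
  tissue Stokes drag, which divides *both* the diffusivity and the drift
  by $e^{-(a-a_{ref})/L}$ — one mechanism, two consequences:
  $$D(a) = D_{eff}\,\frac{a_{ref}}{a}\,e^{-(a-a_{ref})/L}, \qquad
    v_e(a) \propto a^2 e^{-(a-a_{ref})/L},$$
  with $a_{ref} = 100$ nm. A hindrance acting on $D$ alone cannot produce
  an optimal particle size: in the advection-dominated regime the
  penetration depth $\lambda = v_e/k$ does not involve $D$, so efficacy
  would grow monotonically with radius. With hindered drag the drift is
  maximal at $a^* = 2L$; the default $L = 160$ nm places the optimum near a
  300 nm radius, the calibration point of the size sweep. At the force-free
  small end (25–50 nm) the $1/a$ diffusivity dominates and the efficacy
  of the two smallest sizes is equal to within the discretization error —
  the size response is flat there rather than strictly rising.

## Drug transport

Free drug (the drug-coated carrier) obeys
$$\frac{\partial C_F}{\partial t} =
  -\nabla\cdot(v\,C_F) + D\,\nabla^2 C_F
  - \tfrac{1}{\varphi} K_{ON} C_{rec} C_F + K_{OFF} C_B + \Phi,$$
with $v = v_i + v_e$, and the bound and internalized pools follow
$\partial_t C_B = \tfrac{1}{\varphi} K_{ON} C_{rec} C_F - (K_{OFF} +
K_{INT}) C_B$ and $\partial_t C_I = K_{INT} C_B$. The transvascular
exchange uses the pore model,
$$\Phi = \phi_B (1-\sigma_f) C_p + P\tfrac{S}{V} (C_p - C_F)
  \frac{Pe}{e^{Pe}-1}, \qquad Pe = \frac{\phi_B(1-\sigma_f)}{P\,S/V},$$
evaluated by series below $|Pe| < 10^{-6}$. For IP administration the
plasma is a sink ($C_p = 0$), so the exchange is a first-order loss of
$0.06\ \mathrm{s^{-1}}$ in the plateau — the dominant barrier after the
outward convection. The rim concentration `C_outer` is a Dirichlet value
held constant over the treatment hour (continuous instillation); the whole
system is linear in it, which the boundary calibration exploits
(`calibrate_boundary_concentration()` is exact after one unit run). The
conservative form $\nabla\cdot(vC_F)$ is used so that the discrete mass
budget closes exactly; it differs from the advective form by
$C_F\,\nabla\cdot v \le \phi_B C_F \approx 6\times10^{-4}\,C_F$ per second
near the rim, one percent of the vascular loss.

**Discretization.** Finite volumes on a polar grid graded in radius: 8 μm
cells at the rim (six-plus cells across the ~60 μm conventional boundary
layer) growing geometrically (factor 1.15) to a 100 μm interior cap —
112 radial rings by 48 angular sectors at the default resolution (5376
cells), with one sector centered exactly on the penetration axis.
Convection is first-order upwind, diffusion uses two-point fluxes, and time
stepping is a θ-scheme (backward Euler by default, Crank–Nicolson
available) with the stiff binding kinetics folded in implicitly through a
per-cell Schur complement — each step is one triangular back-solve with a
constant, pre-factorized sparse matrix (Matrix's sparse LU). The operator
is an M-matrix, so concentrations remain non-negative for any step size;
$C_I$ is updated from the new $C_B$ and is non-decreasing cell-wise. The
default `dt` is 2 s (1800 steps per treatment hour, a few seconds of wall
time). Refining the grid (halved spacings) and the step (halved `dt`)
moves the conventional and magnetic half-depths by 0.3% and 1.9%
respectively; the linear solves are verified against a residual tolerance
every step, and a per-step mass audit (accumulation vs. rim influx minus
vascular loss, recomputed from the states by independent flux formulas)
closes to machine precision.

## Efficacy metrics

* $w_{1/2}$: depth at which $C_F$ first falls to half the rim value, by
  linear interpolation; the first crossing is used if the profile is
  non-monotone. Conventional runs are radially symmetric and use the
  angle-averaged profile; magnetic runs use the vertical diameter on the
  penetration side (the face away from the magnet), continued through the
  center. A profile that never crosses returns the full ray length with a
  `full_penetration` flag.
* $PA_{rel}$: the area fraction where $C_F$ exceeds a threshold fraction of
  the rim value. The threshold is an operational definition of
  "drug-reached" tissue and defaults to 0.5%: for an exponential profile
  with the conventional half-depth of ~60 μm this places the penetration
  boundary at $\ln(200)/\ln 2 \approx 7.7$ half-depths (~0.46 mm), an
  ~9% annulus of the disk. Every report carries a sensitivity table of
  $PA_{rel}$ over thresholds 0.1–5%. Note the structural coupling: for
  exponential profiles the PA depth is always $\approx 7.7\,w_{1/2}$
  whatever the scenario, so half-depth and penetration-area pairs that do
  not sit on this line (as reported magnet-assisted measurements with
  front-like profiles may not) cannot both be matched by any choice of the
  threshold — a limitation inherent to single-threshold area metrics on
  this model family, not a tunable.
* Cell kill: $SF = \exp(-10^6 \omega\, C_I)$ with $C_I$ on the molar scale
  (mol/L) of the in vitro dose–response underlying the survival constant
  $\omega = 0.4938\ \mathrm{m^3/mol}$; in the package's SI concentration
  unit this is $SF = \exp(-10^3 \omega\, C_I)$, i.e. a half-kill at
  $C_I = 1.40\times10^{-3}\ \mathrm{mol\,m^{-3}}$. Entering $C_I$ in
  mol m⁻³ with the $10^6$ prefactor would drive every reached cell to
  $FK = 1$ at realistic boundary concentrations and make the killed-cell
  fractions degenerate; the molar convention keeps them informative and on
  the observed 30–55% scale. $FK_{PA}$ is the area-weighted mean of
  $1 - SF$ over the penetration area and $FK_{eff} = FK_{PA} \cdot
  PA_{rel}/100$ exactly (an identity of the definitions).

## The reference protocol

`run_reference_protocol()` reproduces the package's benchmark study design
end to end, deterministically:

1. solve the conventional scenario with a unit rim concentration and scale
   `C_outer` so the 60-min tumor-mean free drug is 0.0013 mol/m³
   (exact by linearity; gives `C_outer` ≈ 0.088 mol/m³);
2. calibrate `mobility_scale` so the baseline magnetic case (100 nm
   carrier, 20 × 10 cm magnet, 1.5 T, 5 cm) has $w_{1/2} = 0.08$ cm
   (≈ 124 at the default resolution);
3. everything else is a prediction: the flow maxima, the conventional
   efficacy row, and sweeps over carrier radius (25–600 nm), remanence
   (0.5–2.5 T) and magnet distance (3–10 cm).

Under this protocol the magnet-assisted baseline improves on conventional
IPC by 15× in half-depth, 6× in penetration area and 5.5× in effective
kill fraction, efficacy increases monotonically with remanence and
decreases with distance, and the size sweep peaks at 300 nm.

## Known limitations

* 2D plane geometry (infinite-cylinder tumor, infinitely long magnet); a
  3D magnet of finite depth has a weaker far field.
* No poroelasticity: the interstitium is rigid, flow is steady and one-way
  coupled to transport.
* The boundary concentration is constant for one hour; no instillate
  depletion or post-infusion washout phase.
* Drug and carrier are one species — no release kinetics, no free-drug /
  carrier partitioning; the vascular permeability of the carrier is taken
  equal to the free drug's (reported size-resolved measurements, where
  available, would motivate a size-dependent $P$ and $\sigma_f$).
* The mobility scale absorbs all uncertainty about carrier composition; it
  is a calibrated effective parameter, not a measured property, and the
  absolute magnetic predictions inherit its anchor.
* Inter-particle interactions (dipole chaining, local concentration
  effects on viscosity) are ignored; the transport stays linear.

## Problem sizes

Default runs use the 112 × 48 graded polar grid with `dt` = 2 s over one
hour; the full protocol (two calibrations and 13 scenario runs) completes
in about a minute on one core. The test suite exercises the same code on
16-sector grids with `dt` = 5 s for its property checks and runs the full
protocol once for the acceptance assertions.
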