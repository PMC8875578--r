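# mcdtsim — magnetically controlled intraperitoneal drug targeting, simulated

`mcdtsim` is an R package for computational pharmacologists and drug-delivery
modelers studying **intraperitoneal (IP) chemotherapy of peritoneal tumors**
and its enhancement by **magnetic nanoparticle (MNP) drug targeting**. IP
instillation exposes a peritoneal tumor to a high drug concentration, but
elevated interstitial fluid pressure drives an outward convective flow at the
tumor rim and the leaky microvasculature clears free drug back into plasma,
confining the drug to a layer tens of micrometers thick. Placing a permanent
magnet behind the tumor pulls drug-coated MNPs into the tissue against these
barriers; this package quantifies how much that helps, as a function of
particle size, magnet strength and magnet distance.

## The model

On a circular tumor of radius *R* = 10 mm (2D cross-section), solved in four
coupled stages:

**Interstitial flow** — Darcy flow with a Starling source, solved once and
frozen:

    v_i = -κ ∇P_i,   ∇·v_i = φ_B,   φ_B = L_p (S/V) (P_B - P_i - σ_s(π_B - π_i))

The pressure plateaus at the Starling equilibrium
P_e = P_B − σ_s(π_B − π_i) = 1470 Pa and falls to the peritoneal value over a
~0.3 mm rim boundary layer, where the outward fluid velocity peaks at
~0.17 μm/s.

**Magnetostatics** — the analytic field **H** of a uniformly magnetized
rectangular magnet (equivalent surface-current sheets, log/arctan closed
forms), the saturable particle force

    F_m = ½ μ₀ V χ/(1+χ/3) ∇|H|²     (clamped at μ₀M_sat = 0.5 T, direction preserved)

and the Stokes drift v_e = F_m / (6π a η), scaled by a calibrated
magnetophoretic mobility and an exponential extracellular-matrix hindrance
factor shared with the diffusivity (hindered drag).

**Drug transport** — free (C_F), bound (C_B) and internalized (C_I)
concentrations with convection v = v_i + v_e, hindered diffusion, pore-model
transvascular loss (Peclet-corrected; plasma is a sink for IP dosing), and
receptor binding/internalization kinetics. Implicit finite volumes on a
graded polar grid; unconditionally stable and exactly mass-audited.

**Efficacy** — penetration half-depth w½ (depth where C_F falls to 50% of
the rim value), relative penetration area PA_rel (area above 0.5% of the rim
value), and killed-cell fractions from the exponential survival model
SF = exp(−10⁶ ω C_I[mol/L]), reported as FK_PA (mean kill inside the
penetration area) and FK_eff = FK_PA × PA_rel / 100 (whole tumor).

## Worked example

```r
library(mcdtsim)

# baseline magnet-assisted scenario: 100 nm carriers, 20 x 10 cm magnet,
# 1.5 T remanence, 5 cm from the tumor center; calibrated boundary
# concentration and mobility (see the config comments)
cfg <- load_config(system.file("extdata", "magnetic_baseline.cfg",
                               package = "mcdtsim"))
res <- run_scenario(cfg)
print(res)
#> <scenario_result> magnetic-baseline
#> <efficacy_report>
#>   w1/2   = 0.07969 cm (7.97% of R)
#>   PA_rel = 45.21%  (threshold 0.5% of C_outer)
#>   FK_PA  = 37.78%, FK_eff = 17.08%
#>   mean C_F/C_B/C_I = 0.007042 / 0.004374 / 0.0007545 mol m^-3
```

Reading the report: drug driven in from the tumor face away from the magnet
penetrates to a half-depth of 0.08 cm — roughly 15× the conventional-IPC
value of ~0.005 cm — and the concentration field exceeds the penetration
threshold over 45% of the tumor cross-section. After one hour, 37.8% of
cells inside that area have internalized a lethal dose, i.e. 17.1% of the
whole tumor. The tumor-mean free-drug concentration (0.0070 mol/m³) is ~5×
the conventional value (0.0013 mol/m³, the calibration anchor of the rim
concentration).

The same pipeline runs conventional IPC (`conventional_scenario()`, or any
config without a magnet block), parameter sweeps and the calibrations:

```r
base <- magnetic_baseline_scenario(
  particle = nanoparticle_spec(mobility_scale = 124.2))
base$bc$C_outer <- 0.0882
sweep(base, "B_rem", c(0.5, 1.5, 2.5))       # remanence sweep
calibrate_mobility(base, target_w_half = 8e-4) # the mobility calibration
verify_oracles()                              # independent-oracle battery
```

A command-line front end (`inst/cli/mcdtsim.R`) exposes
`simulate`, `sweep`, `calibrate` and `verify` subcommands over config files
with `--param key=value` overrides.

## Package layout

| Path | Contents |
| --- | --- |
| `R/params.R`, `R/config.R`, `R/units.R` | parameter containers, config files, SI normalization |
| `R/grid.R`, `R/flow.R` | graded polar grid; Darcy–Starling flow solver |
| `R/magnet.R` | analytic magnet field, particle force, drift |
| `R/transport.R` | implicit finite-volume transport of C_F/C_B/C_I |
| `R/metrics.R` | w½, PA_rel, FK_PA/FK_eff, survival model, calibrations |
| `R/scenario.R` | scenario runner, sweeps, reference protocol |
| `R/oracles.R` | independent 1D/quadrature oracles and the mass audit |
| `inst/extdata/` | conventional and magnetic-baseline fixture configs |
| `inst/cli/mcdtsim.R` | command-line front end |
| `scripts/acceptance.R` | end-to-end reproduction script |
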