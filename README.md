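# xtaldepot

Crystalline suspensions of therapeutic proteins are a candidate strategy for
long-acting intravitreal delivery (e.g. anti-VEGF nanobodies for wet
age-related macular degeneration): protein cleared first-order from the
vitreous gains only one elimination half-life of coverage per dose
doubling, whereas a crystal depot releases protein at a rate set by its
lattice. `xtaldepot` is an R package for the desk-side analysis behind that
idea, aimed at formulation scientists and structural biologists screening
polymorph panels:

* **Lattice density** — triclinic cell volumes
  (`V = abc√(1−cos²α−cos²β−cos²γ+2cosαcosβcosγ)`), Matthews coefficients
  `V_M = V/(Z·n_asu·M)`, solvent content `1 − (v̄/0.6022)/V_M`, and density
  ranking of crystal forms read from `CRYST1`/mmCIF headers or CSV tables.
* **Dissolution–elimination pharmacokinetics** — the two-compartment model
  `dM/dt = −A(M)·h·(Cs−Ct)`, `dCt/dt = A(M)·h·(Cs−Ct)/V − k·Ct`
  (Noyes–Whitney dissolution feeding first-order vitreous clearance), with
  lamellar/isometric area laws, zinc-suppressed lattice solubility
  `Cs·K/(K+zn)`, closed-form bolus references, time-above-threshold and
  complete-dissolution-time summaries, and `(Cs, h)` refitting.
* **Dissolution imaging** — Otsu segmentation, largest-component tracking
  of 2D projected area in time-lapse stacks, percent-remaining curves,
  dissolution times, one-way ANOVA across groups.
* **Thermal propensity** — Tm1/Tm2 peak extraction from thermograms, Tagg
  onset detection from static-light-scattering traces, and a three-way
  crystallization-propensity classification on the Tagg(266 nm) axis.
* **Synthetic data** — seeded, bit-reproducible generators for every input
  (crystal tables, dissolving-crystal image stacks, thermograms, SLS
  traces) with ground-truth sidecars.

See the methods vignette (`vignettes/crystal-depot-methods.Rmd`) for the
models, assumptions and numerical choices.

## Worked example

```r
library(xtaldepot)

# density ranking of the five-polymorph reference panel
lattice_report_table(make_crystal_table())
#>         name cell_volume_A3 matthews_A3_per_Da solvent_frac solvent_pct rank
#> 1   mutant 7        86991.4            1.57596     0.220265       22.03    1
#> 2 analogue 2        43958.5            1.58000     0.222261       22.23    2
#> 3 analogue 1        44186.2            1.59000     0.227153       22.72    3
#> 4   mutant 2        94993.5            1.73000     0.289695       28.97    4
#> 5     mNb-WT        48380.2            1.76000     0.301803       30.18    5
```

The zinc-coordinated prismatic form (`mutant 7`) ranks densest — about 22%
solvent versus 30% for the wild-type lattice — which is the packing-order
prediction that a slower-releasing depot rests on.

```r
# crystal depot vs an equal-dose solution bolus (10 mg in 4.5 mL)
params <- pk_parameters(t_half_days = 9.5, h = 0.05, V = 4.5,
                        Cs = 0.2, C_threshold = 0.02)
depot  <- crystal_depot(M0 = 10, A0 = 10, "lamellar")
t_grid <- seq(0, 240, length.out = 961)

time_above_threshold(simulate_crystal_depot(depot, params, t_grid), 0.02)
#> [1] 239.0108
time_above_threshold(simulate_bolus(10 / 4.5, params, t_grid), 0.02)
#> [1] 64.56108
interval_extension_on_dose_doubling(params, 0.2)
#> [1] 9.5
```

The lamellar depot holds the vitreous above the 0.02 mg/mL efficacy
threshold for ~239 days against ~65 days for the bolus, while doubling the
bolus dose would buy exactly one half-life (9.5 days) — the contrast that
motivates crystalline depots.

```r
classify_propensity(thermal_summary(Tm1 = 55, Tm2 = 62, Tagg266 = 47))
#> $label
#> [1] "crystallization-prone"
#> $rationale
#> [1] "Tagg(266) = 47.0 C in [36.1, 55.6); inside the favored 45-50 C band"
```

A command-line wrapper over the same functions lives at
`inst/scripts/xtaldepot` (subcommands `lattice`, `pk`, `dissolve`,
`thermo`, `synth`, `report`); `xtal_cli()` is the equivalent in-process
entry point.

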