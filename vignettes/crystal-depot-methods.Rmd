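---
title: "Crystalline protein depots: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crystalline protein depots: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtaldepot)
```

Anti-VEGF proteins injected into the vitreous are cleared first-order into
the aqueous humor, so doubling a solution dose buys only one elimination
half-life of extra coverage. A crystalline suspension behaves differently:
the depot feeds the compartment through lattice-limited dissolution, and the
lattice itself — its packing density, and any metal coordination embedded in
it — becomes a formulation variable. This package implements the desk-side
models for that idea: lattice density metrics for polymorph panels, a
dissolution–elimination pharmacokinetic model, projected-area analysis of
dissolution micrographs, thermal-property extraction with a
crystallization-propensity rule, and seeded generators that emulate each
input with known ground truth.

## Lattice density metrics

For a unit cell with edges $a, b, c$ (Å) and angles
$\alpha, \beta, \gamma$, the volume is the standard triclinic closed form

$$V = abc\sqrt{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma
      + 2\cos\alpha\cos\beta\cos\gamma},$$

which the tests cross-check against an independent metric-tensor-determinant
oracle on 1,000 random valid cells (1e-9 relative). A cell whose radicand is
non-positive is rejected as geometrically unrealizable rather than returning
`NaN`.

The Matthews coefficient $V_M = V/(Z\,n_{\mathrm{asu}}\,M)$ (Å³/Da) uses a
built-in multiplicity table for the common Sohncke space groups rather than
a full symmetry engine; unknown symbols fail loudly. Solvent content follows
the conventional closed form
$f_{\mathrm{solv}} = 1 - (\bar v/0.6022)/V_M$ with the partial specific
volume $\bar v$ defaulting to 0.74 cm³/g — the constant behind the familiar
$1.23/V_M$ protein fraction. $\bar v$ is exposed as a parameter because
reported solvent percentages in structure tables are sensitive to the
laboratory's exact choice: with $\bar v = 0.74$ the dense forms of the
reference panel compute to 21.7–22.2% where the source table prints
21.92–22.30%, a residual of ~0.2 points whose provenance (the authors'
$\bar v$ and rounding path) is unknowable from the table alone. We document
the residual rather than force agreement. Ion and ordered-solvent mass
(sulfate, zinc) is likewise excluded from the default molar mass; the
tabulated coefficients are reproducible without it.

One row of the reference panel (the prismatic zinc-coordinated mutant)
prints a cell volume ~0.4% below $abc$ computed from its own printed cell
parameters — an internal inconsistency, most plausibly a transcription
artifact. Its volume is therefore excluded from exact-volume checks; its
density *ranking* (the most compact form of the panel) is unaffected and is
asserted.

```{r lattice}
lattice_report_table(make_crystal_table())
```

Molar masses in the reference panel are back-filled by inverting
$V_M = V/(Z\,n_{\mathrm{asu}}\,M)$ on the printed volume and coefficient of
each row; the masses implied by independent rows of the same protein family
agree within 1%, which the tests assert.

## The dissolution–elimination model

Dissolved protein at concentration $C_t$ (mg/mL) in a well-mixed vitreous
volume $V$ (mL) is eliminated first-order with rate $k$ (1/day). The depot
of crystal mass $M$ feeds it through a Noyes–Whitney surface flux:

$$\frac{dM}{dt} = -A(M)\,h\,(C_s - C_t), \qquad
  \frac{dC_t}{dt} = \frac{A(M)\,h\,(C_s - C_t)}{V} - k\,C_t.$$

Here $C_s$ is the equilibrium solubility of the lattice (mg/mL) and $h$
(cm/day) is a single mass-transfer coefficient. A diffusion constant and a
boundary-layer thickness only ever enter the rate law as their ratio, so
they are merged; $h$ must be calibrated per scenario, not taken from
literature.

Design choices worth knowing:

* **Surface-area law.** The source equations leave $A$'s time dependence
  open, so the depot carries $A(M) = A_0 (M/M_0)^p$ with two modes:
  $p = 1$ for lamellae of constant thickness dissolving in-plane (area
  proportional to mass, hence exponential sink decay that never reaches
  exactly zero) and $p = 2/3$ for prismatic crystals shrinking
  self-similarly (finite-time exhaustion). A consequence that can surprise:
  at equal $M_0, A_0$ the *isometric* depot keeps the larger relative area
  as $M$ falls ($m^{2/3} > m$ for $m < 1$) and so completes *earlier* than
  the lamellar one — under sink conditions $3\tau$ versus
  $\tau\ln 10^6 \approx 13.8\,\tau$, $\tau = M_0/(A_0 h C_s)$, to the
  $10^{-6} M_0$ floor.
* **"Completely dissolved"** means $M < 10^{-6} M_0$. The floor makes the
  lamellar mode's asymptotic decay a well-posed event and is far below any
  measurable remnant.
* **Integration.** `deSolve::lsodar` with relative tolerance $10^{-8}$;
  exhaustion is handled by root detection plus an event that pins $M = 0$,
  not by clipping, because mass balance
  ($M + C_t V + \text{eliminated} = M_0 + C_0 V$, checked to $10^{-6}$
  relative) is an acceptance surface. Sink-mode complete-dissolution times
  use the exact closed forms instead of the solver.
* **Zinc.** The release medium's zinc concentration suppresses the
  solubility of the zinc-coordinated lattice. Only monotonicity is
  experimentally established, so the simplest bounded strictly-decreasing
  form is used, $C_s(\text{zn}) = C_{s0} K/(K + \text{zn})$, and only
  ordering claims are tested across the assayed gradient
  (20–300 mM); no printed dissolution time is treated as reproducible.
* **Bolus references.** The solution bolus $C_0 e^{-kt}$ is evaluated in
  closed form; the dose-doubling identity
  $\Delta t = \ln 2/k$ (one half-life, independent of dose and threshold)
  is computed from the closed-form threshold crossings. Half-life presets
  span 8–11 days with 9.5 as the midpoint default in the shipped config;
  both sink and finite-volume release modes are provided because a 10-μl
  drop assay is ambiguous between them.
* **Identifiability.** $(C_s, h)$ are refit from profiles by
  Levenberg–Marquardt on log-parameters. They are separately identifiable
  only when the profile visits both the transfer-limited and the
  saturation-shaped regime; the shipped recovery scenario (half-life 9.5 d,
  $V = 4.5$ mL, $C_s = 0.5$ mg/mL, $h = 0.03$ cm/day, 20 mg lamellar depot,
  120 d horizon) does, and recovers inputs within 1% noiseless and 10%
  under 5% multiplicative noise.

```{r pk}
params <- pk_parameters(t_half_days = 9.5, h = 0.05, V = 4.5,
                        Cs = 0.2, C_threshold = 0.02)
depot <- crystal_depot(M0 = 10, A0 = 10, "lamellar")
prof <- simulate_crystal_depot(depot, params, seq(0, 240, length.out = 961))
c(depot = time_above_threshold(prof, 0.02),
  bolus = time_above_threshold(
    simulate_bolus(10 / 4.5, params, seq(0, 240, length.out = 961)), 0.02))
```

## Dissolution imaging

The measurement mirrors the bench assay: a single crystal per 10-μl drop,
bright-field frames every 2 minutes, 2D projected area against the first
frame. Segmentation is global Otsu thresholding on the configured polarity
(dark-on-bright default), hole filling, and the largest connected component
under 8-connectivity (one crystal per field is an assumption, not a
detection). Two numerical guards matter:

* An objectless frame must segment to an *empty* mask, not to noise. After
  the Otsu split, the class-mean separation is compared with the pooled
  within-class SD; splitting pure Gaussian noise yields ≈2.7, a real
  crystal an order of magnitude more, so the default cut of 4 rejects
  noise-only frames while never rejecting a true object ≥ 500 px at ≤ 10%
  contrast noise.
* "Completely dissolved" is an area below 1% of the initial frame
  (configurable): sub-resolution remnants are indistinguishable from noise.

Group comparison of dissolution times is one-way fixed-effects ANOVA
(`stats::aov`), with unequal group sizes allowed as in the zinc-gradient
assay (n = 5, 5, 6, 5, 7, 7, 5).

## Thermal propensity

Thermograms (15–100 °C scans) are baseline-subtracted with a linear fit to
the leading and trailing 10% of the scan, Savitzky–Golay smoothed (~1 °C
window), and the two highest prominence-filtered local maxima at least 3 °C
apart are refined by a local quadratic fit. Full two-state thermodynamic
fitting is deliberately out of scope: only peak temperatures are reported
upstream, so enthalpies are not identifiable targets. Peak-maximum
estimation carries an intrinsic overlap bias when transitions crowd each
other — with the default 2.5/3 °C widths the bias passes 0.3 °C below ~8 °C
separation and the maxima merge entirely below ~6 °C — so the synthetic
panel draws separations of 8–15 °C, which is also what clearly resolved
two-event scans of this protein class look like.

Aggregation onsets from static light scattering (266 nm for small
assemblies, 473 nm for large aggregates, 15–95 °C) use a fully specified
substitute for the instrument vendor's black-box rule: first temperature
exceeding the initial-plateau median by 5 robust (MAD) SDs, sustained for 3
consecutive points; the reported onset is the *start* of the sustained run,
which keeps the persistence filter from delaying the estimate. The rule is
scale-invariant, returns "absent" (not an error) for flat traces, and on
the synthetic suite lands within ~0.3 °C of truth at 2% noise (the
threshold crossing of the generator's logistic rise sits ~0.2 °C above its
departure point at the default steepness).

Propensity classification partitions the Tagg(266 nm) axis with
closed-left/open-right boundaries: below 36.1 °C precipitation-prone, from
36.1 °C up to (but excluding) 55.6 °C crystallization-prone — with 45–50 °C
annotated as the favored sub-band, an observation rather than a fourth
class — and at or above 55.6 °C solution-stable; a missing onset is
indeterminate. The thresholds come from a nine-protein panel and are
hypothesis-level, so all are configurable; the joint Tm2 × Tagg decision
geometry is not encoded because only the axis thresholds are published.

```{r thermo}
classify_propensity(thermal_summary(Tm1 = 55, Tm2 = 62, Tagg266 = 47))
```

## Synthetic data: what it does and does not show

Every pipeline input has a seeded generator returning ground truth
alongside the data, and identical arguments plus seed give bit-identical
output (generators use a private RNG state and restore the caller's
stream).

* **Image stacks** render a convex silhouette — regular hexagon for the
  lamellar habit, 3:1 rectangle for the prismatic habit, echoing the
  published morphologies — whose area follows either a linear law or the
  depot model's lamellar sink profile $e^{-t/\tau}$. Coverage is computed
  analytically from edge half-planes with a 0.75-px soft ramp; summed
  coverage matches polygon area within 1 px per frame. The crystal is drawn
  at 17° to the pixel grid: arbitrary settling orientation is the realistic
  case, and an axis-aligned silhouette would give every edge pixel along a
  side identical coverage, a coherent quantization error of up to half the
  perimeter. Default conditions: 2-min cadence, 0.5 μm pixels, 2,000 μm²
  initial area, 5% additive Gaussian contrast noise.
* **Thermograms** are two Gaussians on a linear baseline (0.1 °C grid);
  **SLS traces** are a flat baseline with a logistic-shaped rise departing
  exactly at Tagg (0.2 °C grid, matching a 1.5 °C/min scan sampled every
  ~8 s).
* **Crystal tables** reproduce the five-polymorph reference panel verbatim
  with masses back-filled as above.

Additive Gaussian noise is the simplest parameterized model and is all the
generators claim: no photon statistics, no illumination gradients, no
debris, no focus drift, no instrument-specific baseline artifacts, no
multi-crystal fields. Passing the recovery tests therefore demonstrates
correctness of the measurement chain under controlled conditions — not
robustness to every failure mode of real micrographs or real thermograms.
Real data enter through the same readers (manifest CSVs, TIFF/PNG frames,
`T_C,signal` curves), so the validated chain applies unchanged.

Problem sizes used throughout the suite — 1,000-cell volume sweeps,
481-point/120-day PK grids, 192-px frames, 13–16-frame stacks, 100 + 100
thermal curves — were chosen as the smallest sizes at which the estimators'
asymptotic behavior is already visible.

## Known limitations

* One well-mixed compartment; no retina/aqueous sub-compartments, protein
  binding, or in vivo PK fitting (no animal data exist upstream to fit).
* Released-mass curves from the bench assay are semiquantitative; only
  curve shapes and orderings are modeled, never absolute release rates.
* The space-group table covers the common Sohncke groups only — by design,
  protein crystals cannot occupy centrosymmetric groups, and anything
  unusual should fail loudly rather than silently use a wrong multiplicity.
* The propensity rule is a univariate partition of Tagg(266 nm) given a
  measured Tm2; it is a screening heuristic, not a validated predictor.
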