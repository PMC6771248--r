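---
title: "Methods: MIRD dosimetry for mouse biodistribution studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MIRD dosimetry for mouse biodistribution studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdose)
```

## Scope and model

`mirdose` implements organ-level internal dosimetry for mouse
experiments with beta-emitting radiopharmaceuticals, in the MIRD
formalism restricted to self-irradiation:

$$D_r \;=\; \tilde A_r \cdot S(r \leftarrow r),$$

where $\tilde A_r$ is the time-integrated (cumulated) activity of region
$r$ per MBq injected and $S$ the self S-value. The restriction to
self-dose follows from the physics of the default nuclide: the mean
range of ¹⁷⁷Lu beta electrons in soft tissue is about 0.2 mm, small
against every organ dimension in the mouse, so cross-organ electron dose
is negligible. Photon (gamma) self-dose is ignored for the same reason
the electron term dominates at these geometries; this is a deliberate
simplification, not an omission.

All internal times are hours; the nuclide's half-life is converted once
inside `nuclide_properties()`. The decay constant of the packaged
¹⁷⁷Lu entry (half-life 6.65 d) is $\lambda_{phys} = \ln 2 / 159.6\,
\mathrm{h} = 4.343\times 10^{-3}\,\mathrm{h^{-1}}$.

## Quantification: %IA/g

`as_pct_ia_per_g()` reduces a counting measurement to
$100 \cdot A_{meas} e^{\lambda_{phys} t} / (A_{inj} m)$. The decay
correction references the injection time ($t = 0$) and defaults to on:
%IA/g values from animals harvested at different times are then
comparable on a common scale, which is what cross-time-point figures
assume. Whether a given published dataset applied this correction is
often unstated, so the flag is exposed and both behaviours are tested.
Counts-to-Bq calibration is a single multiplicative efficiency factor;
counter geometry, dead time and spectroscopy are out of scope. Paired
organs (kidneys) are treated as one region with combined mass, matching
the packaged S-value table's single kidneys row.

## Time–activity curves and cumulated activity

Curves hold the fraction of injected activity in a region
(`pct_ia / 100`, which requires organ masses). Two constructions are
supported and the choice is a user decision, because the underlying
experiment shapes it: with longitudinal data (`curve_by = "mouse"`)
each animal's own curve is integrated and doses are averaged; with a
cross-sectional design — each animal contributing one harvest time —
only the cohort-mean curve (`curve_by = "cohort"`) is meaningful. The
default is per-mouse; the synthetic generator emits longitudinal tables
so both routes are exercised.

`cumulated_activity()` implements two schemes:

* **trapezoid_tail** (default): linear ramp from $(0, 0)$ to the first
  point — an intraperitoneal administration implies zero activity in any
  region at injection, and no earlier samples exist — then trapezoids
  between measured points, then the analytic exponential tail
  $A_{last}/\lambda_{tail}$.
* **single_point_tail**: the one-measurement shortcut
  $\tilde A = A(t_1)\,(t_1 + 1/\lambda_{tail})$, i.e. a conservative
  plateau up to $t_1$ plus the tail.

The tail rate is a log-linear least-squares fit over the last `tail_window`
points (default 2, the exact two-point formula) and is **floored at the
physical decay constant**: a fitted rate below $\lambda_{phys}$ — or a
rising tail, which is flagged with a warning — would claim retention
outlasting physical decay, and an un-floored non-positive rate makes the
integral diverge. The floor guarantees a finite $\tilde A$ for every
curve. Numerically, a fitted slope with magnitude below $10^{-12}$/h is
snapped to zero so that exactly flat tails are recognised as such. A
measurement recorded at $t = 0$ is accepted; the ramp then contributes
nothing and the curve starts from the measured value.

Tumor clearance in the emulated study (6.29 %IA/g at 24 h falling to
3.80 at 144 h) corresponds to $\lambda_{eff} \approx 4.20\times
10^{-3}\,\mathrm{h^{-1}}$ — slightly *below* the physical constant, so
the floor is active there: decay-corrected curves can show apparent
effective rates below $\lambda_{phys}$ purely through uptake dynamics
and noise.

The integrator is verified against a dense-grid quadrature of the same
piecewise model (ramp, linear segments, exponential tail) to 0.1 % on
randomised 3–5-point curves, and is exactly invariant under inserting a
point that lies on the piecewise model.

## Self S-values: three provenances

1. **Tabulated.** The packaged table carries full-transport Monte Carlo
   self S-factors for seven regions (heart, lungs, liver, kidneys,
   spleen, brain, and a 0.016 g tumor sphere) with their reference
   masses.
2. **Local deposition.** $S = \bar E / m$ with absorbed fraction 1. For
   the tumor sphere this gives $1.335\times 10^{-9}$ Gy/Bq/s, about 1 %
   above the tabulated $1.32\times 10^{-9}$ — the difference is the
   energy that escapes the sphere. Because escape can only reduce the
   deposited energy, the local-deposition value is an upper bound for
   every organ; the test suite asserts this against all seven packaged
   rows.
3. **Straight-track Monte Carlo.** `sphere_absorbed_fraction_mc()`
   samples source points uniformly in the sphere and isotropic
   directions, and deposits energy uniformly along a straight track
   (continuous slowing down, no scattering, no bremsstrahlung). This is
   justified at these scales by the same range argument that justifies
   self-dose-only: at 0.2 mm range in a 3 mm sphere the chord geometry,
   not multiple scattering, controls escape. The estimator is checked
   against a deterministic midpoint quadrature over source radius and
   direction cosine (`sphere_absorbed_fraction_quad()`, default
   800 × 800 grid) and agrees within three standard errors; the
   absorbed fraction for the tumor sphere is ≈ 0.952, giving
   $S \approx 1.27\times 10^{-9}$ Gy/Bq/s, consistent with the
   tabulated value sitting just below the analytic bound.

   `mc_s_value()` offers a `sampled_spectrum` mode: energies drawn from
   the simplified allowed beta shape $\sqrt{E}\,(E_{max}-E)^2$ (no
   Coulomb correction) and converted to track lengths by a configurable
   energy→range map, defaulting to an $E^{1.7}$ power law anchored at
   the nuclide's mean range. The simplified shape has a higher mean
   energy than the true ¹⁷⁷Lu spectrum (the decay feeds several
   branches), so this mode is a sensitivity tool rather than a
   replacement for the tabulated values.

Geometry handling: when a nominal radius and a measured mass disagree
slightly — the emulated study quotes a 3 mm diameter alongside masses of
0.015–0.016 g — the mass wins for dose normalisation and the density is
derived, unless the caller fixes the density explicitly, in which case a
disagreement beyond 5 % is an error. The packaged table's 0.016 g is
used as the tumor reference mass.

## Cohort aggregation and therapy scaling

Per-mouse doses aggregate to mean and *sample* (n−1) standard deviation
per organ × tracer, in the fixed organ order of the packaged table, so
the output is bit-identical under permutation of mice. The sample-SD
convention matches the dosimetry table being emulated; standard error is
available in the PCI summaries where a SEM convention is plausible.
`scale_to_administration()` multiplies mean and SD by the administered
activity — dose is linear in activity, and the SD of a linearly scaled
variable scales by the same factor. Scaling the packaged per-MBq tumor
entries by 40 MBq reproduces the published therapy doses (23.692 ±
20.87 and 25.23 ± 22.38 Gy) within 0.1 %, which is a regression test.

The published per-organ Gy/MBq values themselves are *not* recomputed:
the underlying per-animal time–activity data are not printed anywhere,
so no integrator can be validated against them. The integrator is
instead validated against its own piecewise model (oracle quadrature)
and the scaling identity against the printed therapy doses.

## PCI scoring

The peritoneal carcinomatosis index sums lesion-size scores 0–3 over 13
abdominopelvic regions (nine quadrants plus four small-bowel segments),
maximum 39. Published rodent adaptations differ in region naming, so
region ids are free-form labels validated against a configurable list;
`pci_regions()` provides a default 13-label grid. The theoretical
minimum is 0 — tumor-bearing animals in practice score ≥ 1, but 0 is
allowed for generality (a treated animal can present no visible
lesion). Totals are monotone in every region score and invariant under
region permutation.

Tumor-growth summaries normalise each animal's bioluminescence flux by
its own baseline (calibration constants cancel) and average groups
geometrically, since flux is log-normally dispersed; measurements after
day 20 are excluded because the flux–burden relationship loses
linearity beyond that point.

## Synthetic cohorts: what they emulate and what they do not

The generators reproduce the *statistical structure* the analysis
assumes, with defaults pre-filled from the emulated study's printed
cohort statistics: tumor 6.29 ± 4.27 %IA/g at 24 h and 3.80 ± 2.18 at
144 h (mass 0.016 ± 10 %), blood 0.22 ± 0.02 %IA/g at 24 h, 10 MBq
injected, PCI group targets 15.5 ± 2.3 / 30.0 ± 2.3 / 30.8 ± 1.4 with
six animals per therapy group. Where the study states no value the
defaults are one-time choices a preclinical group would call realistic:
a 0.2 g blood counting aliquot, baseline flux $10^7$ photons/s with
growth rate 0.25/day and 50 % lognormal CV, treatment rate multiplier
0.5, imaging days 4/6/13/20.

* %IA/g is drawn from a **moment-matched lognormal**
  ($\sigma^2 = \ln(1 + sd^2/mean^2)$, $\mu = \ln mean - \sigma^2/2$):
  with CVs near 70 % a Gaussian would go negative. The match is exact,
  so large-cohort sample means converge to the configured means with
  standard CLT behaviour.
* Masses and PCI targets use **truncated normals** (masses > 0; PCI
  targets effectively on [0, 39], truncated to $[-0.5, 39.5)$ before
  rounding so integer rounding stays unbiased). Each PCI target is then
  distributed over the 13 regions by constrained uniform allocation
  with the per-region cap 3; the emitted map's total equals the drawn
  target exactly.
* The counting model is the **exact inverse** of the quantification
  stage — %IA/g → Bq at harvest including physical decay and counting
  efficiency — so the pipeline round-trips: in the noiseless limit the
  recovered %IA/g equals the configured means to machine precision, and
  the end-to-end cohort dose equals the hand-computed dose of the mean
  curve.

Not emulated: inter-organ correlation within a mouse (not reported;
organs are drawn independently and this is the main structural
simplification), uptake kinetics between the scheduled time points,
mouse-level covariates (weight, tumor burden heterogeneity beyond the
marginal distributions), and any imaging chain. Passing tests therefore
demonstrate correctness of the arithmetic and the statistical
machinery under the assumed distributions, not the biology of real
cohorts.

## Determinism and problem sizes

Every generator and the Monte Carlo estimator take an explicit integer
seed and are bit-reproducible under it; pipeline outputs record seed and
scheme in their header line. The test suite uses cohorts of a few
thousand animals for moment-recovery checks and $10^5$–$10^6$ Monte
Carlo histories; the acceptance script uses 10 000 animals for the
biodistribution means and 1 000 for the PCI group mean — sizes at which
the three-standard-error acceptance bands are a fraction of the
quantity being recovered while the whole suite runs in seconds.

## Known limitations

* Self-dose only; no cross-organ or voxel dosimetry, by design.
* No compartmental PK fitting: the integrator is deliberately
  non-parametric because no kinetic model is assumed.
* The straight-track transport ignores scattering and the true beta
  spectrum's branch structure; for spheres much smaller than the
  electron range it would underestimate escape asymmetries, so it is
  intended for geometries where the range is at most a fraction of the
  diameter.
* No radiobiology: absorbed dose only, no BED/TCP modelling, and group
  comparisons stop at summary statistics.
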