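---
title: "Clearance-based Transwell permeability: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clearance-based Transwell permeability: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clearperm)
```

## The measurement and its model

A Transwell-type insert separates an apical (donor) compartment from a
basolateral (receiver) compartment by a permeable membrane on which an
epithelial cell layer is grown. In the clearance variant of the assay a
compound is applied apically, and at each scheduled sampling time the
*entire* basolateral medium is collected and replaced with fresh medium.
Each basolateral sample therefore reflects a single interval's transport,
and the receiver stays close to zero concentration throughout — the sink
condition that makes flux proportional to the donor concentration.

The per-interval **clearance** is the donor-equivalent volume cleared into
the receiver:

$$\mathrm{Cl}_n = \frac{A_{\mathrm{baso},t_n} \, V_\mathrm{baso}}{A_\mathrm{stock}} \quad [\mu L],$$

where $A$ is the detector signal (RFU for carboxyfluorescein, HPLC peak
area in mAU·min for drugs) and $A_\mathrm{stock}$ the signal of the applied
stock solution; only the ratio of signals enters, so detector units cancel.
The cumulative cleared volume plotted against time is, in the sink regime,
a straight line whose slope is the permeability–surface-area product
$PS$ [µL/min] (`fit_ps()`: ordinary least squares, free intercept, with the
origin included as a data point, since zero volume has been cleared at time
zero).

A cell-covered insert is two barriers in series, so the cell-layer PS
follows from the fitted insert PS and the mean PS of matched bare-membrane
("blank") inserts:

$$\frac{1}{PS_\mathrm{cell}} = \frac{1}{PS_\mathrm{all}} - \frac{1}{PS_\mathrm{blank}},$$

and the apparent permeability coefficient is
$P_\mathrm{app} = 10 \cdot PS_\mathrm{cell} / A_\mathrm{insert}$ in µm/min
(1 µL·min⁻¹·cm⁻² = 10⁻³ cm/min = 10 µm/min; the factor 10 is pure unit
conversion).

Blanks are paired per compound × inhibitor group because different
compounds interact differently with the bare membrane; the group mean of
the blank fits is used for every cells well of that group.

## The interval-correction ambiguity

The clearance formula for later time points is sometimes quoted with a
correction term that subtracts the volume-factor-scaled clearance of
earlier time points. With full receiver replacement at every sampling this
correction has no physical basis — no transported mass is carried between
intervals — and the term as commonly printed is dimensionally ambiguous.
`interval_clearance()` therefore offers three modes:

* **`per_interval`** (default): no correction. Each interval's receiver
  starts fresh; this is the physically justified estimator.
* **`literal`**: the printed correction, read as subtracting the
  volume-factor-scaled excess of the previous intervals' clearances over
  the first interval's, $\mathrm{Cl}_n - f_V \sum_{i<n}(\mathrm{Cl}_i -
  \mathrm{Cl}_1)$, kept in µL so it remains scale-invariant. Retained for
  fidelity comparisons only.
* **`donor_corrected`**: divides by the depleted donor signal
  $A_\mathrm{stock} - f_V \sum_{i<n} A_{\mathrm{baso},i}$, a mass-balance
  correction that removes most of the depletion bias (below).

All three agree exactly at the first time point. The driver
`analysis/02_permeability_analysis.R` tabulates each mode's bias against
simulated ground truth.

## What the simulator emulates

`simulate_well()` solves the two-compartment exchange
$\dot C_a = -(PS/V_a)(C_a - C_b)$, $\dot C_b = +(PS/V_b)(C_a - C_b)$
*exactly* per interval (single-exponential relaxation towards the
equilibrium partition; the concentration difference decays with rate
$k = PS\,(V_a + V_b)/(V_a V_b)$), resetting $C_b = 0$ at every sampling
and carrying the depleted donor forward. A numerical integrator is used
only as a test oracle. Mass (donor + receiver + removed-by-sampling) is
conserved to floating-point precision, which the tests assert at 1e-9
relative.

Default study conditions follow the emulated protocol: 300 µL apical /
900 µL basolateral (volume factor 3), 0.336 cm² inserts, hourly sampling
for 4 h, 100 µM drug donor (10 µM carboxyfluorescein), cells and matched
blank inserts per group, carboxyfluorescein co-applied on every insert.
Where the protocol does not pin a value we chose once what is realistic
for plate-reader/HPLC work and kept it fixed:

* **noise**: multiplicative Gaussian with CV 3%, truncated at zero
  (detector error scales with signal); triplicate basolateral/stock and
  duplicate apical technical replicates are emitted and averaged on read;
* **blank PS**: 3× the cell-layer PS of the matched group (bare membranes
  are distinctly faster than cell layers but not transparent);
* **carrier-mediated transport**: a linear PS term with an inhibitor
  switch (`ps_active`, negative for net efflux), not Michaelis–Menten,
  since only one donor concentration is in scope;
* **ground-truth Papp** for the study-mimicking design
  (`paper_mimic_design()`): the published group means, encoded directly as
  effective cell-layer PS.

Per-well seeds are derived by hashing the master seed with the well
identity, so wells are independent and the output does not depend on
generation order.

What the simulator does **not** emulate: apical volume loss or
evaporation, unstirred water layers, pH partitioning, membrane binding
kinetics (blank PS is a constant, not adsorption), multilayer geometry,
or saturable transport. Recovery results on synthetic data therefore show
that the *estimator* is consistent under the stated noise model — not that
real HPLC error is 3% CV, which no replicate data in scope can confirm.

## Estimator bias and the sink condition

Donor depletion bends the cumulative cleared-volume curve downwards, so
the fitted `PS_all` and `PS_blank` are both biased low — but in the
series-resistance correction these biases largely cancel, which is why the
method tolerates surprisingly fast transport. The test suite quantifies
this over a grid of true Papp in {0.5, 2, 5, 12} µm/min with blank PS 2–5×
the cell PS: noise-free `per_interval` estimates are within 2% of truth
whenever total donor depletion stays below 10%, and the bias grows with
depletion beyond that. The acceptance checks run the full
study-mimicking design (noise CV 3%, n = 6, fixed seed) and require every
group mean within 5% of truth with the transport ranking reproduced.

## Numerical and degenerate-input choices

* Non-positive fitted slopes are flagged `excluded` (non-transporting or
  inverted wells); `PS_all ≥ PS_blank` is flagged `blank_dominated` (the
  correction would be non-physical). Neither enters group means; both are
  counted in the exclusion log, so reported n is auditable.
* Replicates are averaged arithmetically with no outlier rejection.
* CF normalisation defaults to the per-insert ratio (compound Papp over
  the same insert's CF Papp, then averaged), which differs from the ratio
  of group means whenever inserts vary — both modes are available.
* Zero stock signal, unsorted schedules, missing time points and absent
  blank groups are hard validation errors naming the offending well.
* The `donor_corrected` mode refuses series whose implied donor signal
  reaches zero.

## Inflammation-study readouts

TEER is blank-subtracted and area-scaled, `(R_raw − R_blank) × A`
[Ω×cm²]; inserts below 100 Ω×cm² at the start of the experiment are
excluded (boundary inclusive: exactly 100 is kept). Relative qPCR
expression is $2^{-\Delta C_t}$ against 18S rRNA, normalised per target to
the mean of the cytokine-treated group, which therefore averages exactly 1.
Group statistics use classical fixed-effects one-/two-way ANOVA
(`stats::aov`) with all pairwise comparisons on the pooled residual mean
square, adjusted by the Holm–Šidák step-down
$p_{(i)}^\mathrm{adj} = 1 - (1 - p_{(i)})^{m-i+1}$ (monotonised); the
Šidák variant is implemented in the package because `stats::p.adjust`
provides only Holm–Bonferroni. The comparison family is all pairs within
one figure panel.

## Problem sizes

The shipped analyses and tests use the design sizes of the emulated study:
14 groups × 6 cells + 3 blank inserts with carboxyfluorescein co-applied
(~240 well series), TEER n = 15 per treatment, qPCR n = 3 per group — all
generated in code at run time; no measured data ship with the package.

## Known limitations

Absolute agreement with any particular laboratory's values cannot be
checked without deposited raw data; the package therefore validates
worked-example ratios, dimensional constants, internal identities and
simulation-based recovery. The linear active-transport model cannot
express saturation or asymmetric (directional) transport, and the noise
model is a single multiplicative term — structured error such as
inter-plate drift is out of scope.
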