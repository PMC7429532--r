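---
title: "Benchmarking automatic MEG localization of the irritative zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking automatic MEG localization of the irritative zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(izbench)
```

## The problem

In pre-surgical evaluation of drug-resistant focal epilepsy, MEG is used to
localize the *irritative zone* (IZ) — the cortex generating interictal
epileptiform discharges (IEDs) — as a surrogate for the epileptogenic zone.
The clinical reference procedure is equivalent current dipole (ECD) fitting
performed by an expert, who subjectively selects a sensor subset around each
spike. `izbench` implements the machinery needed to ask, quantitatively,
whether automatic localization methods can replace that expert: a forward
model, the four localization procedures, the discrepancy metrics that compare
them to the ECD benchmark, and the lobar-concordance analysis that relates
localization to post-surgical (Engel) outcome. The package also ships, as
plain-text fixtures, the per-patient summary tables of a published 22-patient
validation study, and recomputes every downstream number of that study from
them (`reproduce_reference_results()`).

## Forward model

A current dipole with moment $\mathbf q$ (nAm) at $\mathbf r_0$ (mm) inside a
homogeneous conducting sphere produces, at an exterior point $\mathbf r$, the
closed-form magnetic field

$$\mathbf B(\mathbf r) = \frac{\mu_0}{4\pi F^2}
  \left( F\, \mathbf q \times \mathbf r_0
  - (\mathbf q \times \mathbf r_0 \cdot \mathbf r)\, \nabla F \right),
  \qquad F = a\,(ra + r^2 - \mathbf r_0 \cdot \mathbf r),$$

with $\mathbf a = \mathbf r - \mathbf r_0$. Two well-known properties follow
and are used as tests: radial moments are magnetically silent, and a dipole
at the center produces no field. The spherical conductor stands in for a
boundary-element model of the individual head: for MEG a brain-shaped
homogeneous conductor is an adequate approximation, and the sphere is
analytic, fast and exactly testable. What the sphere does *not* reproduce is
the effect of tissue inhomogeneities and realistic cortical geometry, so
synthetic results quantify method behaviour, not patient-level accuracy.

Sensors are planar gradiometers, two orthogonal ones per site, 102 sites on a
spherical cap at 110 mm covering the whole head except the face opening
(`cap_fraction = 0.8`), baseline 16.8 mm; a channel reads the finite
difference of the radial field component across the baseline in fT/cm. A
whole-head cap matters: with partial coverage, inferior sources fall outside
the array and no method (nor the expert) could localize them.

Source spaces are either a regular volumetric grid (default 5 mm spacing, as
used clinically for lesional patients) or a quasi-uniform "cortical" set on a
55–80 mm shell band. A geometric atlas splits the sphere into ten lobar
regions — frontal, temporal, central, parietal, occipital per hemisphere —
with the hemisphere given by the sign of the lateral coordinate and the five
lobes by fixed sectors of the sagittal angle `atan2(z, y)`:
F $(-45^\circ, 60^\circ]$, C $(60^\circ, 105^\circ]$,
P $(105^\circ, 150^\circ]$, O beyond $150^\circ$ (wrapping to
$-160^\circ$), T the inferior remainder. The thresholds are a surrogate for
an anatomical parcellation; they are fixed and documented rather than fitted
to anything.

## The four localization procedures

All methods share one leadfield ($L$, channels × 3 per source point).

**ECD fitting** (`ecd_fit`). The moment is profiled out by linear least
squares at each candidate location; the location minimizes the residual via a
grid scan followed by Nelder–Mead refinement from the best grid starts. The
fit reports the goodness of fit $\mathrm{GOF} = 100\,(1 - \|y - L\hat q\|^2 /
\|y\|^2)$, a 95% confidence volume from the local quadratic expansion of the
profiled chi-square (finite-difference Hessian, 1 mm step — the exact formula
used by commercial fitting software is unpublished, so this documented
definition stands in and only feeds the accept/reject rule), and the moment
magnitude; a fit is *accepted* when GOF ≥ 80%, confidence volume < 1000 mm³
and 50 ≤ |q| ≤ 500 nAm. Expert channel selection is emulated by an explicit
`channel_mask`; it is never inferred.

**Bayesian dipole probability map** (`bayes_dipole_map`,
`bayes_dipole_map_smc`). Under a single-dipole model with moment prior
$N(0, \sigma_q^2 I_3)$ and white noise $N(0, \sigma_e^2 I)$, the marginal
likelihood of the topography for a dipole at grid point $j$ is Gaussian with
covariance $\sigma_q^2 L_j L_j^\top + \sigma_e^2 I$; with a uniform location
prior, the normalized likelihoods form the posterior probability map. The
trans-dimensional samplers used in practice reduce to exactly this posterior
in their single-dipole regime, which is the regime relevant here (one
dominant generator per IED), so the exact enumeration is both the default
implementation and the oracle against which the provided sequential Monte
Carlo sampler (annealed importance sampling over grid indices, multinomial
resampling at ESS < n/2, independence Metropolis–Hastings moves, 100
particles by default) is validated: total-variation distance < 0.05 at 2000
particles on a 100-point space. Defaults: $\sigma_q$ is the ratio of the
data maximum to the leadfield maximum; $\sigma_e = 0.2 \max|y|$ for unknown
data, while the synthetic pipeline passes the generator's true noise level
(playing the role of the adaptive noise estimate of the original samplers).
The posterior is invariant under joint rescaling of $y$, $\sigma_q$,
$\sigma_e$.

**One-dipole MUSIC** (`music_scan`). The signal subspace of a single-sample
topography is its own span; the scan value at each point is the largest
canonical correlation between that subspace and the local gain column space,
and the estimate is the maximizing grid point. Recursion depth one of the
recursively-applied variant is exactly MUSIC, so no projection step is
needed.

**Depth-weighted minimum norm** (`wmne_map`). Free-orientation minimum-norm
with per-point source variance $w_j = \mathrm{tr}(L_j^\top L_j)^{-\gamma}$,
$\gamma = 0.8$ by default (the conventional "standard" exponent; the study
does not print its value, so it is configurable), Tikhonov parameter
$1/\mathrm{SNR}^2$ with SNR 3 by default, and the conventional cap on the
depth-weight dynamic range (gain power floored at $\max/10^2$) — without the
cap, near-silent deep points acquire unbounded weights and dominate every
map. The map value is the norm of the per-point moment estimate. At
$\gamma = 0$ this is classical MNE.

Grid argmax ties are always broken by the lowest point index.

## Metrics

For a map $S$ with voxel distances $d_j$ to a reference point,
$$\mathrm{MLD/SD} = \sqrt{\sum_j (d_j |S_j|)^2 \Big/ \sum_j |S_j|^2},$$
with the reference being the benchmark ECD location (MLD) or the map's own
peak (SD); both are invariant to positive rescaling of the map, and SD = MLD
whenever the ECD sits on the peak voxel. DLD is the Euclidean distance
between a point estimate and the ECD. The AUC thresholds the IED-averaged
map at every unique value (strictly-above convention, ±∞ sentinels): true
positives count ECDs whose nearest voxel is active, false positives count
active voxels containing no ECD — the asymmetric convention is deliberate
and kept exactly as published — and the ROC is integrated by the trapezoid
rule with (0,0) and (1,1) endpoints. A constant map scores 0.5 by
construction. `grid_discrepancy` quantifies the systematic error a
grid-bound estimate cannot avoid (nearest-grid-point distance of each
continuous ECD location).

Per-patient summaries use the sample (n−1) standard deviation; the source
tables do not state which convention was used, so only means are checked
against them.

## Concordance and outcome prediction

`lobar_percentages` attributes a localization to regions: share of dipoles
(ECD, MUSIC) or share of map mass (probability, intensity) per region. The
published tables apply a 10% reporting threshold; it is a *display* rule
(`filter_lobar`), while the concordance argmax always uses raw percentages.
A patient's localization is *concordant* when any region attaining the
maximal percentage is in the set of surgically treated regions — the
any-match tie rule is the only reading that reproduces the published
confusion matrices for the tied rows, and multi-lobe plans count membership.
Outcomes dichotomize as good (Engel I) vs poor (II–IV, the ambiguous "2/3"
included); non-operated patients are excluded. TP/FP/TN/FN then give
TPR, TNR, PPV, NPV and F1 (`prediction_stats`), with zero-denominator
statistics returned as `NA`.

In the bundled clinical table, the patient treated by radiofrequency
thermocoagulation only (P16) carries its SEEG target as the surgical plan;
the source does not state which lobes constitute "the plan" for that case,
and the assignment is recorded in the fixture comments as a transcription
choice (it is also the only assignment consistent with the published
confusion matrices).

## Rank statistics

`mann_whitney_u` uses the first-sample convention
$U = \#\{x_i > y_j\} + \tfrac12 \#\{x_i = y_j\}$ — the published values
include both $U = 0$ and $U = 335 > n_1 n_2 / 2$, which rules out the
min-U convention. p-values come from `stats::wilcox.test` (whose W equals
this U), exact where R allows, tie-corrected normal approximation otherwise;
the published significance threshold is 0.01. `spearman_rho` wraps
`stats::cor.test`.

## The synthetic cohort generator

`simulate_cohort` emulates the study conditions: 22 patients, 8–100 IEDs
each (the published per-patient range), one dominant dipolar generator per
IED with tangential moment magnitude uniform in 50–500 nAm (the ECD
acceptance band), white sensor noise at a configurable power SNR (default
10), and per-patient clustering: an IZ center drawn at cortical depth
(55–80 mm, the same band as the cortical source space, at least 5 mm off the
midsagittal plane where hemisphere labels are undefined), with IED generators
jittered around it (default 10 mm) and snapped to the nearest source point
*inside* the true region, so the region defines the IZ and jitter controls
spread within it. Surgical plans equal the true region for a configurable
fraction of patients and Engel outcomes are drawn conditional on that
concordance, so setting `p_plan_concordant = 1, p_good_concordant = 1,
p_good_discordant = 0` yields an *oracle cohort* on which a correct
localization chain must produce a perfect classifier (F1 = 1).

What the generator deliberately does not emulate: spike waveforms and
temporal correlation (every computation here uses single-time-sample peak
topographies), multi-source propagation, realistic cortical folding, and
inhomogeneous noise. Passing tests therefore validate the algorithmic chain,
not clinical performance on real recordings.

## Numerical choices and problem sizes

- Tie-breaks: lowest index at every grid argmax; AUC threshold rule is
  "strictly above".
- Degenerate inputs raise errors (empty grids, sensors inside the sphere,
  zero moments, all-zero maps) rather than returning empty objects.
- The ECD confidence volume folds the noise scale in as $\sigma^3$ so that
  noiseless fits do not overflow; residual-based default
  $\hat\sigma = \sqrt{\mathrm{RSS}/(m-6)}$.
- The test suite and the acceptance script run on scaled-down geometry
  chosen once for precision-per-cost: 10–20 mm grids, 30–102 sensor sites,
  22 × 10 IEDs for the end-to-end oracle run. The solver-property checks use
  the full 102-site array because an under-sampled array (≤ 50 sites)
  genuinely degrades minimum-norm peak accuracy (a finding, not a tuning
  artifact). Cohort-level study conditions (patient count, IED range,
  moment band, SNR) are never changed between tests.
- All randomness flows from a single root seed per stage; solvers themselves
  are deterministic except the Monte Carlo sampler, which takes an explicit
  seed.

The command-line surface of the package is its exported functions plus
`scripts/acceptance.R`; as an R analysis package it is driven from R rather
than a shell binary.

## Worked example

```{r example, eval = FALSE}
res <- run_ied_pipeline(
  cohort_config(n_patients = 5, ied_count_range = c(5, 10), snr = 10),
  seed = 1, spacing = 12, n_sites = 60)
res$stats          # per-method confusion counts and prediction statistics
head(res$patient_summary)

rep <- reproduce_reference_results()
rep$all_pass       # TRUE: every published downstream number recomputes
```

## Known limitations

- The sphere model cannot represent the secondary currents of a realistic
  head; absolute error magnitudes on real data will differ.
- The single-dipole Bayesian posterior is the faithful target for
  single-generator IEDs but not for multifocal activity; the
  trans-dimensional case is out of scope.
- The geometric atlas approximates lobar anatomy by angular sectors; regions
  near sector boundaries can legitimately split their mass.
- Published per-IED distributions (e.g. DLD quartiles) depend on raw patient
  recordings that are not available; only the per-patient summary tables and
  everything computable from them are reproduced.
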