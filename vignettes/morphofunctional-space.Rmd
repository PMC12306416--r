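---
title: "Morphofunctional spaces from forelimb lever mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphofunctional spaces from forelimb lever mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfspace)
```

## The problem

Inferring how an extinct mammal moved from bones alone is confounded by
many-to-one mapping of form to function: different limb architectures can
deliver the same mechanical output, and similar ratios can arise from
different anatomies. A morphofunctional space (MFS) addresses this by
ordinating many biomechanical descriptors at once and asking where a fossil
falls relative to extant species of known locomotor habit. `mfspace`
implements that workflow for the forelimb, built around the Miocene
mesotheriid *Caraguatypotherium munozi*: a taxon whose elbow leverage is
unremarkable but whose wrist leverage exceeds every extant analog in its
comparative sample, supporting a wrist-powered scratch-digging strategy.

## Measurements and functional indices

The data model is one row per specimen: ten linear measurements (cm) —
humeral length HL, humeral midshaft diameter HMLD, epicondylar breadth HEB,
ulna length UL, functional ulna length FUL = UL − OL, ulnar midshaft
diameter UMLD, olecranon length OL, radius length RL and midshaft diameter
RMLD, and the manus segment MTCIII-L (wrist joint line to the distal tip of
metacarpal III) — plus WFA, the wrist-flexor force arm (wrist joint line to
the proximal base of metacarpal III). Validation enforces positivity,
OL < UL, WFA < MTCIII-L, and FUL consistency to 1% of UL; any field may be
missing, and each operation declares what it needs and skips (with a
warning) specimens lacking it, mirroring how incomplete fossils are handled
in practice.

Seven percentage indices summarize proportions: shaft robustness of the
humerus (HRI = 100·HMLD/HL), the epicondylar index (EI = 100·HEB/HL, a
proxy for flexor/pronator attachment area), the olecranon index
(OI = 100·OL/UL), brachial indices of radius and ulna (BIR = 100·RL/HL,
BIU = 100·UL/HL), and own-bone shaft robustness of radius and ulna
(RRI = 100·RMLD/RL, URI = 100·UMLD/UL). Because denominator conventions
vary across the ecomorphological literature, the formulas live in a named
registry (`index_registry()`) and can be swapped without code changes; the
registry also carries `BIH` as an alias of `BIR`, since both names denote
the HL-denominated radial brachial index in different sources. The
own-bone denominators for RRI and URI are the package default; they are the
convention most consistent with the published holotype values we
reconstruct, but a user importing a differently-defined dataset can
override them.

## The three lever models

All three mechanical-advantage models are static osteological
approximations, MA = 100·r/R with straight-line arms from the joint axis;
no ground-reaction-force vectors, joint excursions, or sesamoid (pisiform)
moment arms are modeled.

1. **Classical elbow model** (`ma_elbow()`), the index of fossorial
   ability: force arm OL, resistance arm FUL = UL − OL, so
   MAe = 100·OL/(UL − OL). The resistance arm runs from the joint axis to
   the distal ulna tip; since the axis sits OL proximal of the olecranon
   tip, the arm is UL − OL rather than UL. This reconstruction is verified,
   not assumed: it is the only choice under which the published holotype
   OI (16.30%) and MAe (19.47%) are linked by the exact identity
   MAe = 100·OI/(100 − OI), which the test suite checks to 1e-9 on random
   inputs.
2. **Elbow + manus model** (`ma_elbow_manus()`): the resistance arm extends
   to the substrate contact point, approximated by the distal tip of
   metacarpal III. We take the forearm and manus as collinear (fully
   extended limb), giving R = FUL + MTCIII-L: collinearity is the unique
   posture-free choice, and it reproduces the published holotype chain
   (19.47% → 12.51%). A `chain_angle_deg` parameter (law of cosines on the
   two segments; default 180°) exposes flexed postures for sensitivity
   analysis. Whether the contact point should include the phalanges is
   genuinely ambiguous in the source anatomy; the landmark is a measurement
   convention here, so a user measuring to the phalangeal tips simply
   supplies that longer MTCIII-L.
3. **Wrist model** (`ma_wrist()`), a third-class lever at the carpus:
   MAw = 100·WFA/MTCIII-L, bounded in (0, 100).

Useful identities, all enforced by property tests: equal arms give 100%; a
zero-length manus collapses model 2 to model 1; model 2 is strictly below
model 1 for any positive manus; every model is invariant under uniform
scaling of the skeleton; MAe is increasing in OL, model 2 decreasing in
MTCIII-L, MAw increasing in WFA.

### Estimating a missing humerus

When the proximal humerus is missing, `estimate_humerus_length()` applies a
conspecific ulna/humerus ratio. The reference ratio is rounded to 2
decimals before division (configurable; 0 disables rounding) because
conspecific ratios are conventionally reported at that precision: for the
holotype, 23.2/19.53 → 1.19 and 16.26/1.19 → 13.66 cm. Downstream index
calculations use the estimate at its reported caliper precision (13.66),
which is what makes BIU come out at the published 119.03% rather than
119.00%; the function itself returns full precision and flags the value as
estimated. The flag propagates: any index or lever computed from an
estimated field carries `contains_estimate = TRUE`.

## Size correction and ordination

Linear measurements scale with body size, so the osteological morphospace
regresses each of the nine non-proxy variables (log10) on log10 HL by OLS
and ordinates the z-standardized residuals. Base-10 logs are a convention —
any base yields identical residuals — and variance denominators are n − 1
throughout. Nine variables, not ten, enter this block: HL is consumed as
the size regressor and cannot also be a response. The regression pools
extant and fossil specimens by default (`pool_fossils = TRUE`); the
alternative — fitting on extant only and projecting fossils — is one flag
away, because whether fossils belong in the allometric reference is a
scientific choice the package should expose rather than make silently.

The functional morphospace z-scores the ten dimensionless variables (7
indices + 3 MAs) directly; no size correction is needed or applied. Ten is
the full published variable set; a reduced variant is available by passing
`variables`.

PCA is an eigendecomposition of the covariance of the standardized matrix
(equivalently the correlation structure, since columns are z-scored).
Loadings are unit-norm eigenvectors; axis signs are fixed so each loading
column's largest-magnitude entry is positive, making outputs deterministic
across numerical libraries. The fit is cross-checked in the tests against
an independent `eigen()` oracle to 1e-8, and reconstruction
(centered data = scores × loadingsᵀ) and orthogonality are asserted as
invariants. Convex hulls are drawn per extant habit on PC1×PC2
(counterclockwise vertices; 1–2 member habits yield degenerate hulls);
fossils are projected as points only. `predict()` projects new specimens
through the stored transformations without refitting.

## Habit-level inference

For each variable, a one-way fixed-effects ANOVA compares the five extant
habits; flyers (n = 2) participate despite the tiny sample — matching the
emulated study design — with a warning logged. When the ANOVA is
significant at α = 0.05 (configurable), Tukey–Kramer HSD post hocs are
summarized as a compact letter display via an insert-and-absorb algorithm:
groups sharing a letter do not differ. The display is audited in tests to
be logically equivalent to the pairwise pattern and is cross-checked
against `multcomp::cld()`. Letters are attached only to variables with a
significant ANOVA.

Fossils are kept out of the ANOVA entirely. The focal specimen enters via
one-sample t-tests (its value as the null mean for each habit's sample);
the remaining fossil cohort enters via Welch t-tests against each habit. No
correction is applied across the ten variables, matching the emulated
analysis; consumers who want family-wise control can apply
`p.adjust` to the stored p-values.

## The radial morphofunctional space

`radial_mfs()` places the three MA models on radial axes (classical elbow
at 90°, elbow+manus at 330°, wrist at 210°), normalizes each axis by the
dataset maximum, draws rings at 20% increments of those maxima, and shades
a performance envelope for a reference habit (extant diggers by default).
The statistic behind such published envelopes is typically unstated, so
both candidates are implemented and labeled: per-axis min–max
(`envelope_stat = "range"`, the default and weakest assumption) and
mean ± SE (`"mean_se"`, comparable to standard-error bars). The tested
artifact is the plot-data structure (`radial_plot_data()`); rendering is a
thin base-graphics layer.

## The synthetic cohort generator

Real specimen tables of this kind are rarely redistributable, so the
generator produces datasets with the statistical structure the analysis
assumes. It operates in index space — the only space for which published
group-level distributions exist — and back-solves raw measurements:

- HL is drawn log-normally per habit. The log10 means (digger 0.95,
  terrestrial 1.25, climber 1.05, swimmer 1.10, flyer 0.60, mesotheriid
  1.20; SDs 0.15–0.35) are plausible humerus lengths spanning bat to horse
  scale. They are configuration, not science: every downstream index is
  size-free by construction, and only the allometric block sees HL at all.
- Each free index (HRI, EI, OI, BIR, BIU, RRI, URI, MAe+MTCIII-L, MAw) is
  drawn from a normal truncated to its feasible region, with per-habit
  means and SDs defaulting to the published group summary statistics of
  the emulated comparative sample (e.g. diggers: EI 33.9 ± 11.5,
  OI 22.9 ± 9.9). MAe is *not* free — it is determined by OI through
  MAe = 100·OI/(100 − OI).
- Raw measurements are reconstructed exactly (UL = BIU·HL/100,
  OL = OI·UL/100, MTCIII-L = 100·OL/MA₂ − FUL, WFA = MAw·MTCIII-L/100, …),
  with rejection of draws violating the lever preconditions
  (MA₂ below the OI-implied MAe; positive manus; WFA < MTCIII-L). A
  rejection budget of 1000 per specimen turns truly infeasible parameter
  sets into a typed error naming the habit.

The default configuration reproduces the emulated group sizes
(4/15/9/8/2 extant + 4 fossil mesotheriids) and appends a focal
holotype-like record whose measurements are reconstructed from published
holotype values (UL 16.26 cm, estimated HL 13.66 cm, and the printed index
column); all reconstructed fields are flagged as estimated and the record
is synthetic in every field not actually printed.

What the generator does *not* emulate: correlations among indices beyond
those induced by shared denominators (no published covariance exists to
calibrate them), phylogenetic covariance, measurement error structure, or
allometric curvature. Consequently, passing tests demonstrate that the
pipeline recovers known structure of this idealized kind — not that any
particular biological signal exists in real data, nor that real
morphospace geometries (e.g. specific variance-explained values) will be
reproduced. Reproducing published ordination percentages requires the
original specimen table, which is distributed under restricted access by
its archive; `read_measurements()` imports it directly (a configurable
column map absorbs header differences) once a user has obtained it.

Parameter recovery is verified at n = 500 per habit against the analytic
means of the truncated generating distributions — including, for OI and
MAe+MTCIII-L, numerical integration over the joint acceptance region — with
a 3·SD/√n band. Group SDs published for n = 2 and n = 4 cohorts are
unstable descriptors; the defaults use them verbatim.

## Numerical conventions and degenerate inputs

- Percentages are computed and stored at full precision; printing rounds to
  2 decimals.
- Zero-variance columns, identical specimens, degenerate levers
  (OL ≥ UL, WFA ≥ MTCIII-L), all-identical ANOVA inputs, and empty envelope
  groups raise classed errors (`mfs_domain_error`,
  `mfs_degenerate_column_error`, …) rather than propagating NaNs.
- All randomness flows from a single seed (`make_study_like_dataset(seed)`,
  `run_pipeline(seed)`); identical seeds give byte-identical outputs, which
  the tests assert on serialized files.
- Problem sizes in the test suite: study-scale datasets (43 specimens),
  recovery runs at 500 specimens per habit, and property loops of 20–200
  random cases — chosen to exercise every code path at comfortably
  interactive runtimes.

## Known limitations

- Static lever ratios ignore muscle architecture, activation, and dynamic
  effective mechanical advantage; they rank force-transmission potential,
  not performance.
- The wrist model simplifies flexor geometry to a chord; the pisiform's
  leverage contribution is absent, so absolute MAw is likely conservative
  for taxa with prominent pisiforms.
- Ordination is not phylogenetically corrected; shared ancestry can
  masquerade as functional clustering.
- The compact-letter display, like any such summary, can be non-unique
  under intransitive significance patterns; the implementation is
  deterministic (alphabetical/first-position tie-breaks) and always
  pair-faithful.
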