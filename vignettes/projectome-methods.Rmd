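---
title: "Methods: quantifying projectome organization and laminar hierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying projectome organization and laminar hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(projectome)
```

## The measurement model

Retrograde tracing labels the nuclei of neurons that project to an injected
target area. After registration to the CCFv3 atlas and automated detection,
each animal reduces to integer counts per (hemisphere, cortical area, layer).
The package treats these counts as a censored multinomial sample from the
animal's true projectome: the quantities of interest are proportions
(hemisphere shares, areal weights, laminar profiles), never absolute counts,
because tracer uptake and detection efficiency vary between animals. All
normalized quantities are therefore computed per animal first and only then
summarized across the cohort as mean ± SEM.

Hemisphere labels are injection-relative: `ipsi` is the injected side. Raw
left/right tables are relabelled with `flip_to_injection_frame()`, which
leaves counts untouched, so a right-hemisphere injection is analyzed
identically to a left one.

## Exclusion rules

Three filters clean the tables before any analysis, mirroring standard
practice for this kind of data:

1. **Injection QC** (`qc_injection()`): an animal is excluded when more than
   30% of the viral bolus lies outside the target area, or when white-matter
   transduction reaches 0.1% of the bolus volume (inclusion requires strictly
   below 0.1%). Both limits are fractions in [0, 1]
   (`max_outside_target = 0.30`, `max_whitematter = 0.001`).
2. **Minimum-cell rule** (`apply_min_cell_filter()`, `min_cells = 10`): an
   area–hemisphere with fewer than 10 cells (summed across layers) in a given
   animal is zeroed entirely. The rule operates on the area total, not per
   layer, because sparse labeling below that level is indistinguishable from
   detection noise. The filter is monotone and idempotent.
3. **Cohort inclusion** (`area_inclusion_mask()`, `min_animals = 3`): an
   (hemisphere, area) pair enters cohort-level analyses only when at least
   three animals carry ≥ 10 cells there *in the same hemisphere*. One
   threshold (≥ 10) is used for both rules 2 and 3; the package treats the
   two rules as a single consistent cell criterion.

The injected area itself is always excluded ipsilaterally — cells there are
the injection site, not a projection. Its contralateral (homotopic)
counterpart is genuinely informative and its treatment varies by analysis:
excluded from flat-map-style areal fractions and module summaries
(`exclude_homotopic_contra = TRUE`, the default of `areal_fraction()`),
retained for the homotopic-share statistic and for contralateral fILN tables,
and excluded again from the laminar-change comparison. Each public function
exposes its exclusion setting explicitly rather than hiding a global policy.

## The fILN statistic

For laminar fractions over the universe {L2/3, L5, L6},

$$\mathrm{fILN} = \frac{L5 + L6}{L2/3 + L5 + L6},$$

with ablation variants that drop L5 or L6 from numerator and denominator
alike. The statistic is scale-free (counts and fractions give the same
value), bounded in [0, 1], equals 0 iff no infragranular cells, equals 1 iff
no supragranular cells, and is undefined — propagated as `NA`, never coerced
to 0 — when the denominator layers are empty. Both ablation variants are
bounded above by the default value for every profile, which the test suite
verifies on a full simplex grid.

**L6 means L6a by default.** The imaging pipeline separates L6a and L6b;
L6b carries a tiny, noisy population, and L4 is excluded because agranular
areas lack it and granular areas contribute few L4 projection neurons. A
switch (`include_l6b = TRUE`) folds L6b into the L6 term for sensitivity
analyses. Laminar *dominance* (`dominance()`), by contrast, uses
L6 = L6a + L6b, since there the question is which anatomical layer holds the
most cells, not a hierarchy index.

Two aggregation modes are deliberately distinct:

- `pooled_filn()` sums counts over all areas in a hemisphere first
  (cell-weighted, "blind to areas") — the per-hemisphere summary;
- `filn_table()` + `rank_areas()`/`module_filn()` compute per-area fILN and
  average *unweighted* across areas and animals — the hierarchy analyses.
  Module and group means weight every area equally rather than by cell
  count; weighting by cells would let one dominant area (often the homotopic
  target) impersonate its whole module.

Rankings use NaN-aware means: an area's mean is taken over the animals in
which it is defined, the contributing n is reported, ordering is ascending,
and exact ties break by atlas index so results are deterministic. Dominance
ties break toward the deeper layer; with integer counts ties are rare, but
tests need a fixed rule.

## Statistical machinery

`compare_samples()` records the full design (test, sidedness, pairing) in its
output. With `test = "auto"`, samples are screened with the Anderson–Darling
normality test and routed to a t-type test when normal, a rank test
otherwise. Anderson–Darling requires n ≥ 8, so smaller samples are screened
with Shapiro–Wilk; figure-equivalent analyses in `run_analysis()` pin the
specific test instead of relying on routing. Wilcoxon procedures use exact
distributions up to n = 25 (cohort sizes here are 6–18) and the
continuity-corrected normal approximation above. Degenerate zero-variance
comparisons (identical paired samples) return the null result (statistic 0,
p = 1) rather than erroring, so property tests and all-equal fixtures behave
sensibly. Correlations are computed per animal and summarized as mean ± SEM
across animals, matching how cohort correlations are reported; per-area
symmetry tests are one-sample tests on the contra − ipsi difference with
Bonferroni correction over the areas actually tested (the family size is
recorded in the output, since it depends on the inclusion mask). Multiple
comparisons across the three pairwise layer tests use Bonferroni; module
dominance comparisons use one-way ANOVA with Tukey–Kramer adjustment.

The type-I calibration test draws both samples from the same normal
distribution (n = 12 per sample, 2,000 replicates, fixed seed) and requires
the rejection rate at α = 0.05 to fall in [0.035, 0.065] for the paired t,
signed-rank, and rank-sum tests. n = 12 sits inside the study's 6–18 range
and is the regime where the discrete exact Wilcoxon tests attain a size near
0.05; at n = 6 the signed-rank test's smallest achievable two-sided p is
0.031, so its size is below the band for reasons intrinsic to the exact
distribution, not to any implementation.

## The synthetic cohort generator

`ground_truth()` makes the generative model explicit: a target, an
ipsilateral share, per-hemisphere area weights (the injection site carries
weight 0 ipsilaterally), per-area laminar profiles, and a Dirichlet
concentration. `simulate_cohort()` draws, per animal, a hemisphere split,
area weights, and laminar profiles from Dirichlet distributions centered on
the truth with concentration `overdispersion × truth`, then samples
`cells_per_animal` cells categorically from the joint distribution. The
per-cell event list is emitted alongside the aggregated counts so every
downstream fraction can be verified by brute-force recounting. Infinite
overdispersion collapses to pure multinomial sampling, which the tests use
as an analytic variance anchor.

Default calibration (`default_profile()`), chosen once from the study
conditions the package emulates:

- `ipsi_share = 0.8` — roughly 80/20 ipsi/contra;
- module-structured area weights: the home module dominates (visual ≈ 0.42
  for a VISp target; somatomotor ≈ 0.62/0.83 for SSp-bfd/MOp), weights
  decline geometrically within a module, and the contralateral homotopic
  area takes ≈ 0.35 of the contralateral mass with the lateral module
  strengthened contralaterally;
- laminar profiles giving generative fILN ≈ 0.65 ipsilaterally and ≈ 0.79
  contralaterally for sensory-motor areas (L2/3 mass falls, L6a rises
  contralaterally), higher (≈ 0.85) for prefrontal/medial/lateral areas in
  both hemispheres; a deterministic per-area offset of up to ±0.10 moves
  mass between L2/3 and L6a (halved contralaterally) so that rankings are
  non-trivial and the two hemispheres stay positively correlated while the
  contralateral distribution is compressed — which also reproduces the
  negative relation between ipsilateral fILN and the interhemispheric
  difference;
- `overdispersion = 300` — per-animal SDs of a few percentage points on
  large fractions, comparable to the SEMs such cohorts show;
- `cells_per_animal = 2e5`, `n_animals = 6` — several hundred thousand cells
  per cohort, six animals per target.

The generator emulates count structure only. It does not model cell
positions, injection-bolus geometry, detection errors, registration error,
or genuinely failing animals (simulated metadata passes QC); passing tests
therefore demonstrate that the estimators recover a known truth under
realistic sampling noise, not that real data are free of those artifacts.

## Numerical conventions

- Fractions within a normalization unit sum to 1 up to floating-point error;
  `filn()` tolerates simplex dust (inputs down to −1e−9 are clamped to 0)
  and rejects genuinely negative values.
- Undefined quantities (empty hemispheres, empty layer universes, excluded
  areas) are `NA` throughout and propagate through differences and NaN-aware
  means; they are never silently replaced by 0.
- Zero-imputation happens only at ingest, where a missing (hemisphere, area,
  layer) row means "no cells detected", and respects the atlas's
  agranular flags (no L4 rows are ever created for agranular areas).
- All simulation randomness flows from the seed stored in the ground truth;
  analyses of fixed data are fully deterministic.

## Problem sizes in the test suite

Unit tests run on hand-built tables of a few rows and on a toy generator
preset (3 areas, 2 animals, 100 cells). The oracle-equivalence and recovery
tests run one full-scale default cohort (6 × 200,000 cells); the calibration
test uses 2,000 null replicates. The whole suite completes in about a
minute on a single CPU.

## Known limitations

- The packaged 45-area table and its module assignment are a reconstruction
  from the public CCFv3 ontology and the standard module grouping of the
  mouse corticocortical connectivity literature; laboratories using a
  different parcellation should supply their own CSV to `load_atlas()`.
- The area indices follow the conventional flat-map ordering only at the
  anchors that are fixed by convention; the remainder follow the packaged
  table order. Indices matter only for deterministic tie-breaking.
- fILN is an anatomical proxy for hierarchy. The package makes no claim
  about functional hierarchy and implements no comparison against
  anterograde-tracing hierarchy scores.
- `laminar_change()` assumes both hemispheres were measured for an area;
  areas defined in only one hemisphere are excluded from the tally and
  reported.
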