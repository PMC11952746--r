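# projectome

Quantitative analysis of brain-wide retrograde-tracing projectomes in R.

When a retrograde tracer is injected into one cortical area, every labeled
nucleus elsewhere in the cortex marks a neuron that projects to the injection
site. Automated cell-detection pipelines (e.g. cellfinder on serial two-photon
volumes registered to the Allen CCFv3 atlas) reduce each brain to a table of
counts per (hemisphere, cortical area, layer). `projectome` takes those tables
and answers the questions a circuit anatomist asks of them:

- How are the labeled cells split between the hemispheres, across the 45
  cortical areas, and across the six connectivity-defined cortical modules
  (prefrontal, lateral, somatomotor, visual, medial, auditory)?
- Which layer dominates each area's projection, and what does the laminar
  profile say about feedforward versus feedback organization?
- How does all of this differ between the ipsilateral and contralateral
  hemispheres?

The core statistic is the **fraction of infragranular labeled neurons**:

```
fILN = (L5 + L6) / (L2/3 + L5 + L6)
```

computed per (animal, hemisphere, area) on laminar fractions over
{L2/3, L5, L6a} (L4 and L6b are excluded; a switch folds L6b into L6).
Projections dominated by supragranular L2/3 (fILN near 0) are feedforward-like;
projections dominated by infragranular L5/L6 (fILN near 1) are feedback-like,
so ranking areas by mean fILN yields an anatomical hierarchy. Layer-ablation
variants — `excl_L5` = L6/(L2/3+L6) and `excl_L6` = L5/(L2/3+L5) — measure how
much each infragranular layer contributes to that hierarchy.

Around the statistic, the package implements the full study pipeline:

- **ingest** — cellfinder-style CSV reading, injection QC (bolus placement
  and white-matter transduction rules), the 10-cell minimum filter, the
  3-animals-per-hemisphere cohort inclusion rule, and left/right →
  ipsi/contra relabelling (`read_count_table()`, `qc_injection()`,
  `apply_min_cell_filter()`, `area_inclusion_mask()`,
  `flip_to_injection_frame()`);
- **normalization** — hemisphere shares, per-area and per-module fractional
  counts, homotopic share, laminar profiles (`hemisphere_share()`,
  `areal_fraction()`, `module_fraction()`, `homotopic_share()`,
  `laminar_fraction()`);
- **hierarchy** — fILN tables and pooled-hemisphere fILN, laminar dominance,
  rankings, interhemispheric differences, module-group comparisons, and the
  sensory-motor laminar-change analysis (`filn()`, `filn_table()`,
  `dominance()`, `rank_areas()`, `interhemispheric_delta()`,
  `module_filn()`, `laminar_change()`);
- **statistics** — normality-screened test routing (Anderson–Darling),
  exact Wilcoxon procedures, Bonferroni and Tukey–Kramer corrections,
  per-animal correlations summarized as mean ± SEM (`compare_samples()`,
  `correlate()`, `bonferroni_adjust()`, `anova_tukey()`);
- **simulation** — a Dirichlet–multinomial cohort generator with an explicit
  `ground_truth()`, calibrated defaults per target (`default_profile()`),
  per-cell event lists for brute-force verification, and parameter-recovery
  reports (`simulate_cohort()`, `recovery_report()`).

Everything is tidyverse-native: functions take and return tibbles, results
have `tidy()`/`glance()` methods, and `autoplot()`/`plot_*()` give ggplot2
figures. A thin CLI (`inst/cli/projectome.R`) wraps the simulate → analyze →
report pipeline for shell use.

The packaged 45-area parcellation (`load_atlas()`) is a reconstruction of the
CCFv3 isocortex summary structures plus entorhinal cortex with the standard
module assignment of the mouse connectivity literature; it can be overridden
with a CSV.

## Worked example

Simulate a VISp cohort (6 animals, 50,000 cells each) and run the full
analysis:

```r
library(projectome)
library(dplyr)

gt  <- default_profile("VISp", cells_per_animal = 50000L, seed = 7L)
coh <- simulate_cohort(gt, events = FALSE)
coh
#> <cohort> target: VISp | animals: 6 | cells: 300,000

res <- run_analysis(coh)
res
#> <projectome_analysis> target: VISp | animals: 6 | tables: 23

res$tables$hemisphere_share |>
  group_by(hemisphere) |> summarise(mean = mean(share))
#> 1 contra     0.191
#> 2 ipsi       0.809

head(res$tables$ranking, 5)
#>    rank area  index mean_filn     sem     n
#> 1     1 VISpm    33     0.556 0.0134      6
#> 2     2 SSp-n   19     0.564 0.00819     6
#> 3     3 SSp-m   22     0.568 0.0163      6
#> 4     4 VISl    30     0.576 0.00963     6
#> 5     5 AUDp    38     0.583 0.00836     6

res$tables$group_filn |>
  group_by(group, hemisphere) |> summarise(filn = mean(filn))
#> 1 pf-m-l contra     0.884
#> 2 pf-m-l ipsi       0.847
#> 3 v-a-sm contra     0.788
#> 4 v-a-sm ipsi       0.662

res$tables$group_tests[, c("analysis", "test_name", "sidedness", "p")]
#> 1 vasm_ipsi_vs_contra_filn   paired-t  two       0.00000106
#> 2 vasm_vs_pfml_filn_delta    paired-t  one       0.0000164
#> 3 pooled_filn_contra_gt_ipsi paired-t  one       0.0000136
```

About 80% of cells sit ipsilaterally; areas rank from low (feedforward-like)
to high fILN; the sensory-motor module group (v-a-sm) has markedly higher
fILN contralaterally (0.79 vs 0.66) while prefrontal/medial/lateral (pf-m-l)
barely moves — the interhemispheric hierarchy difference is carried by the
sensory and motor modules, and the paired tests quantify it.
`summarize_analysis(res)` renders the same headline numbers as markdown, and
`write_analysis(res, dir)` writes every table as tidy CSV with a manifest.

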