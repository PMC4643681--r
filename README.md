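# hodomap

Track-wise (hodological) lesion-deficit mapping for stroke cohorts, with
automated single-case lesion delineation, tract-disconnection
quantification against a probabilistic white-matter atlas, covariate-
adjusted per-tract regression, and a simplified voxel-wise GLM with
permutation cluster correction. It is written for researchers asking
whether a behavioural deficit — here the global/local decomposition of the
Birmingham Cognitive Screen (BCoS) complex-figure copy task — is predicted
by *disconnection of specific white-matter pathways*, over and above lesion
size and age.

Because clinical lesion data cannot ship with a package, `hodomap` includes
a first-class synthetic-cohort generator (control volumes, ellipsoidal
lesions with exact ground-truth masks, tube-shaped probabilistic tracts,
and behaviour drawn from a known disconnection→deficit model), so the whole
pipeline runs, and is tested, end-to-end out of the box.

## The statistics at the core

**Lesion delineation** — each patient voxel is tested against a control
sample with the Crawford–Howell single-case statistic

> t = (x − c̄) / (s_c · √((n+1)/n)),  df = n − 1,

and the hypointense tail of the resulting outlier t-map is thresholded into
a binary lesion map.

**Disconnection** — each tract's probability map is thresholded at 50% (its
anatomical core) and the disconnection measure is the overlap volume in cm³
between lesion and core.

**Track-wise inference** — one OLS model per tract and hemisphere,
`score ~ disconnection + lesion_volume + age` (optionally + left/right
visual-field misses), reporting the standardized coefficient
β = b·sd(x)/sd(y) and its two-sided p, Bonferroni-corrected over the
16-tract family (α = 0.05/16 = 0.003125).

**Voxel-wise GLM** — the same design fitted at every voxel of 12-mm-FWHM
smoothed lesion-density images; clusters formed at voxel p < .001, extent
threshold 800 mm³ (100 voxels at 2 mm), cluster-level family-wise error by
Freedman–Lane permutation of the maximum cluster size.

## Worked example

```r
library(hodomap)

spec   <- cohort_spec(n_patients = 60, n_controls = 20, seed = 42)
cohort <- generate_cohort(spec)

# delineate one patient against the control reference
ref <- fit_control_reference(cohort$controls)
del <- delineate(cohort$patients[["P001"]], ref, min_cluster_voxels = 2)
#> P001: delineated 3.22 cc (true 2.54 cc), Dice 0.882

# patients x tracts disconnection table (here from the ground-truth masks)
tab <- build_disconnection_table(cohort$true_lesions, cohort$atlas, cohort$behaviour)
round(percent_disconnected(tab), 1)
#>          ifof_left         ifof_right          slf3_left         slf3_right
#>               28.3               21.7                5.0               40.0
#>  long_segment_left long_segment_right           ilf_left          ilf_right
#>               15.0               40.0                6.7                3.3

# per-tract regressions, Bonferroni over the canonical 16-tract family
alpha <- bonferroni_alpha(16, 0.05)          # 0.003125, printed as .003
res <- flag_significant(run_trackwise_analysis(tab, cohort$atlas, "local_pct"), alpha)
res[res$significant & res$beta_std < 0, ]
#>       tract hemisphere  n beta_std p_value
#> 1 ifof_left       left 60   -0.626 2.4e-09
```

The delineated volume slightly exceeds the truth because the default
threshold admits ~1% of noise voxels; the `min_cluster_voxels` cleanup
removes the isolated ones. The percentage table shows the planted lesion
geography (effect tracts overlap in 28–40% of patients). The regression
recovers the planted dissociation: only the left IFOF predicts the local
score, while the same cohort's global score is predicted by the right
SLF III (β = −0.788) and right long perisylvian segment (β = −0.660) only
— negative β because more disconnection means a lower score.

The one-call version, from config to report directory
(`disconnection_table.tsv`, `trackwise_results.tsv`, cluster tables,
`report.json`, log):

```r
run_pipeline(list(seed = 42), out_dir = "demo_run")
```

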