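# tesgroup

Group-level dose optimization for transcranial electrical stimulation
(tES/tDCS) in R.

Model-driven tES planning picks electrode positions and currents so that
the induced electric field matches a target map on the cortex. The
component that matters for modulating pyramidal-cell excitability is the
field along the cortical surface normal, En (positive En points into the
cortex and depolarizes somas). Personalized planning needs a
subject-specific MRI-derived head model, which many studies cannot obtain;
`tesgroup` implements the group-level alternative: optimize one montage
against a *pool* of head models so that it works well, on average, for an
unseen subject from the same population — and quantify what is lost
relative to personalized and template-based planning.

## The objective

For weights `w`, target field `t = En_trg`, lead-field matrix `K`
(V/m per mA per electrode, fixed Cz reference) and currents `I` (mA),
the fitness is the normalized error relative to no intervention:

    NERNI(I) = ( ||w ⊙ t||² − ||w ⊙ (K I) − w ⊙ t||² ) / ||w ⊙ t||²

NERNI = 1 for a perfect fit, 0 for no stimulation, and is unbounded
below. The group objective is the arithmetic mean of NERNI over the
subject pool. The conventional target is En = 0.25 V/m with weight 10 on
the target region and 0 V/m with weight 2 elsewhere; safety constraints
are |I| ≤ 2 mA at every electrode (the implicit Cz return included), an
anodal (total injected) sum ≤ 4 mA, and at most 8 active electrodes.

The search is hybrid: for a fixed electrode subset the currents solve a
concave quadratic program exactly (dual active-set QP with an exact
orthant treatment of the anodal-sum constraint); a genetic algorithm
searches over electrode subsets. A secondary metric, the area-weighted
mean En over the target region, tracks stimulation intensity.

Because real MRI-derived cohorts cannot ship with a package, `tesgroup`
includes a synthetic cohort generator: a 4-shell concentric-sphere head
model (brain/CSF/skull/scalp, analytic Legendre-series forward solution,
idealized 10-10 electrode positions) with lognormal inter-subject
variability in shell radii and, optionally, tissue conductivities. All
statistics — montage transfer tables, paired and nonparametric protocol
comparisons, and regressions of outcomes on scalp-geodesic and
tissue-volume anatomical features — run identically on synthetic or real
lead-fields.

## Worked example

```r
library(tesgroup)

cohort <- generate_cohort(cohort_spec(n_subjects = 6, seed = 42))
cfg    <- optimization_config(ga_population = 100, seed = 1)
res    <- ga_optimize(cohort, config = cfg)   # group-mean NERNI objective
print(res)
#> <optimization_result> objective 0.869645, 8 active electrode(s), 14 generation(s)
#> <montage> 8 active electrode(s); reference current -5.551e-17 mA
#>     Fpz     CPz      P7      T8      F3      F5     FC3     AF3
#> -1.0476 -0.2932 -0.4037 -0.2892  0.2749  0.2734  0.3878  1.0975

generics::glance(res)
#> # A tibble: 1 × 5
#>   objective n_active generations_run anodal_sum_mA max_abs_current_mA
#> 1     0.870        8              14          2.03               1.10

evaluate_montage(res$montage, cohort[[1]])
#> <fit_result> sub01: NERNI 0.8874, <En> target 0.2816 V/m
```

The group montage places its anodes (F3, F5, FC3, AF3) over the
left-frontal target patch and distributes the return current; the group
objective 0.87 means the montage removes 87% of the weighted squared
error relative to no stimulation, averaged over the six heads, and the
first subject receives a target-region mean En of 0.28 V/m — close to the
0.25 V/m target level.

Higher-level entry points: `optimize_group_loo()` runs the leave-one-out
group protocol; `evaluate_transfer()` + `compare_protocols()` build the
cross-subject comparison (personalized vs group-LOO vs template vs
individual-derived montages) with paired t-tests (Bonferroni),
Kruskal-Wallis and Dunn post-hoc tests; `nerni_vs_mean_en_fit()` fits the
quadratic NERNI-vs-⟨En⟩ relationship; `geodesic_perimeters()`,
`feature_diffs()`, `fit_feature_regression()` and `loso_predict()` cover
the anatomical-feature analysis; `run_pipeline()` orchestrates everything
from a single (optionally YAML) configuration, and `inst/cli/tesgroup` is
a thin command-line front end with `simulate-cohort`, `optimize`,
`optimize-group`, `evaluate`, `features`, `regress` and `run-all`
subcommands.

See the methods vignette (`vignettes/tesgroup-methods.Rmd`) for the model
assumptions, parameter choices, and known limitations.

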