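# fmrirep

Split-half (pseudo-replicate) replicability analysis of task-fMRI
group-level statistic maps, with a synthetic multi-subject generator for
desk-scale experiments.

## The problem

How replicable is a thresholded group activation map from a task-fMRI study
with *k* participants? `fmrirep` answers this empirically with a
pseudo-replication design: a pool of *N* participants is repeatedly split
into two disjoint groups P and Q of size *k*; group z-maps are fit to each;
and their similarity is measured at three levels of analysis:

- **voxel (intensity)** — Pearson correlation *r* between the vectorized
  unthresholded z-maps;
- **voxel (thresholded)** — sign-sensitive Jaccard overlap
  *J = |same-sign intersection| / |union|* of proportion-thresholded maps,
  with the target proportion taken from a full-sample (all-*N*)
  cluster-thresholded reference;
- **cluster / peak** — Jaccard overlap of two-tailed Gaussian-random-field
  (GRF) cluster-extent-thresholded maps, and the rate at which one map's
  cluster peaks are suprathreshold (same sign) in the other, averaged over
  both directions.

Each observed curve is paired with a smoothness-matched null: 1000 (by
default) white-noise maps smoothed to the observed map smoothness and
rescaled to the observed robust (2nd/98th-percentile) intensity range; each
real map is scored by the 95th percentile of its null statistics.

A "measurables" regression relates replicability to per-participant data
properties (motion, design contrast power `1/(c (X'X)^{-1} c')`, hat-matrix
leverage outliers, within- and between-subject map similarity), expanded to
split-pair level, orthogonalized in blocks, fit per task by OLS, and
aggregated across tasks by MAP shrinkage.

Group maps use a documented stand-in for mixed-effects modeling: a
voxelwise one-sample t statistic mapped to z by cumulative matching
(`z = qnorm(pt(t, k-1))`, clamped at |z| = 38).

## Worked example

```r
library(fmrirep)

cfg <- synthetic_suite_config(seed = 1, n_sorts = 10)  # small demo run
res <- run_experiment(cfg)
sc  <- summarize_curves(res$records)
subset(sc$across_tasks, metric == "pearson")
```

With the full suite (`n_sorts = 50`, the default; ~1–2 minutes on one CPU)
this prints the across-task mean Pearson replicability by sample size,
e.g. (seed 1; signal tasks and the pure-null task averaged separately in
`sc$per_task`):

```
   k  metric threshold_label mean_of_task_means mean_within_task_sd
  16 pearson            none              0.161              0.0692
  36 pearson            none              0.292              0.0607
  64 pearson            none              0.399              0.0507
```

Replicability grows with k but remains far from 1 even at k = 64, and the
per-task curves separate by between-subject variability: at k = 64 the
task means are 0.559 (low), 0.557 (mid), 0.462 (high between-subject SD),
against null 95th-percentile curves of ~0.15. The same bundle carries the
thresholded Jaccard and peak-hit curves, the null curves
(`res$null_curves`), and the inputs for the measurables regression:

```r
ma <- measurables_analysis(res, tasks = c("lowbv", "midbv", "highbv"))
ma$aggregate
#            block   d_map delta_r2_map
#      sample_size  1.0658       0.2655   <- sample size dominates
#           motion -0.0540       0.0106
#   contrast_power  0.2381       0.0207
#     hat_outliers  0.0509       0.0252
#       within_sim  0.0619       0.0229
#      between_sim  0.1429       0.0194
```

The full-sample threshold scaling rule used for the reference maps is
exposed directly:

```r
scaled_full_sample_threshold(5.08, 200, 463)  # 7.73
```

## Command line

```sh
Rscript -e 'fmrirep::fmrirep_cli()' run --config cfg.yaml --out out/
Rscript -e 'fmrirep::fmrirep_cli()' simulate --config cfg.yaml --out data/
Rscript -e 'fmrirep::fmrirep_cli()' summarize --records out/records.csv --out curves/
```

See `?config_from_yaml` for the YAML schema. Datasets are written as
NIfTI-1 volumes with CSV sidecars and a JSON manifest.

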