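# tsfitge

Quantitative analysis of **thermal stability shift fluorescence difference
gel electrophoresis (TS-FITGE)** experiments — a label-free,
proteome-wide strategy for identifying the protein targets of bioactive
small molecules.

## The problem and the method

Drug binding changes a protein's thermal stability. In a TS-FITGE
experiment, vehicle- and drug-treated cells are heated across a
temperature series; after centrifugation the soluble (non-aggregated)
proteomes are labelled with spectrally distinct dyes — **Cy3** (vehicle),
**Cy5** (drug) — mixed with a **Cy2**-labelled *unheated* internal
standard, and separated on one 2D gel per temperature (isoelectric point
horizontally, molecular weight vertically). Most proteins denature
identically in both arms and appear yellow; a drug-stabilized protein
retains more soluble Cy5 signal at denaturing temperatures (red spot), a
destabilized one less (green spot).

`tsfitge` implements the full analysis:

* **Spot detection and quantification** — background correction by
  morphological opening, robust peak detection on the per-channel maximum,
  elliptical 2D Gaussian refinement, and integration of all three channels
  over one shared 3-sigma footprint per spot.
* **Intra-gel ratio analysis** — per-spot `log2(I_Cy5 / I_Cy3)`, box-plot
  summaries with whiskers at the 1st/99th percentiles, and candidate
  ranking (highest ratio = stabilized, lowest = destabilized).
* **Inter-gel melting curves** — affine registration and spot matching
  across the temperature series, then internal-standard normalization

  `rel_c(T) = [I_c(T) / I_Cy2(T)] / [I_c(T0) / I_Cy2(T0)]`, c in {Cy3, Cy5},

  which cancels per-gel gain exactly, followed by a 3-parameter logistic
  fit `f(T) = p + (1 - p) / (1 + exp(k (T - Tm)))` per condition.
* **Shift scoring** — the transverse melting-point shift
  `dTm = Tm(drug) - Tm(vehicle)` and the longitudinal deviation between
  the two measured curves (`y_dev_max`, `y_dev_area`), which remains
  sensitive when slopes are steep and Tm shifts are marginal.
* **Classification** — drug-induced post-translational modifications
  produce *horizontal* red/green spot pairs already present in the
  unheated gel (and vanish when treatment time is shortened); channel
  misregistration produces *vertical* red/green pairs of identical size
  and intensity. Both are recognized and separated from genuine thermal
  shifts; every track receives exactly one label.
* **Isothermal dose–response** — 4-parameter logistic EC50 fitting for
  candidate confirmation.
* **Synthetic forward model** — a seeded generator that renders
  ground-truth-annotated three-channel 16-bit TIFF gel series (log-normal
  abundances, logistic denaturation, drug-induced Tm shifts on a target
  subset, treatment-time-dependent PTM satellites, per-gel gain, affine
  warp, channel misregistration, additive + signal-proportional noise), so
  every stage of the pipeline is testable against known truth.

## Worked example

Simulate a methotrexate-style experiment (80 proteins, one target
stabilized by +8 °C, 8 temperatures from 37 to 64 °C) and analyze it:

```r
library(tsfitge)

proteome <- generate_proteome(n_species = 80, n_targets = 1, seed = 42,
                              target_delta_tm = 8, grid_px = 384)
design   <- experiment_design(image_shape = c(384, 384), seed = 42)

run_dir <- tempfile("tsfitge_demo")
simulate_run(proteome, design, run_dir)               # TIFFs + manifest + truth
run <- run_pipeline(file.path(run_dir, "manifest.tsv"),
                    file.path(run_dir, "analysis"))

table(run$calls$label)
#> stabilized  unchanged
#>          1         79

summarize_ratios(run$ratios[["T53"]])
#> log2(Cy5/Cy3) over 80 spots: median -0.012 [Q1 -0.048, Q3 0.017],
#>   1-99% whiskers [-0.279, 0.378]; 1 high / 1 low outliers

run$candidates[1, c("track_id", "label", "delta_tm", "y_dev_max", "z_score")]
#> track_id      label delta_tm y_dev_max z_score
#>   TR0001 stabilized     6.18     0.886    59.6
```

The one simulated target is the single `high` outlier beyond the
99th-percentile whisker of the 53 °C gel, and the only stabilized call:
its drug melting curve sits `y_dev_max = 0.89` soluble-fraction units
above the vehicle curve at the most discriminating temperature, with a
fitted melting-point shift of +6.2 °C. `render_report(run, "report/")`
writes red/green overlays, the per-gel box plots with flagged outliers,
and per-candidate melting-curve figures.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/tsfitge.R", package="tsfitge"))')" \
    all --out demo_run --seed 3
```

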