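# mitoscreen

Quantifying mitochondrial membrane potential (ΔΨm) dynamics of microglia in
two-channel time-lapse recordings, and screening drugs that modulate them.

Microglia respond to immune stimuli with large, structured ΔΨm changes that
can be read out with the potentiometric dye TMRE (fluorescence ∝ ΔΨm)
alongside an EGFP morphology channel. After LPS application at `t = 0` the
microglial whole-cell signal rises ~253 % in three progressive **states**
(S1–S3): steep rises separated by plateaus, with onsets near 6.06, 14.06 and
23.50 min and a slope ordering S1 > S2 > S3. The depolarization radiates
outward — soma-dominant in S1, steepest branch rise in S2, endfoot-dominant
in S3 — while neuronal somas rise only ~50 % to a plateau and slowly
decline. The TSPO inverse agonist emapunil attenuates the response in a
domain-specific way (strongly in soma and endfeet, negligibly in branches)
without affecting baseline ΔΨm. `mitoscreen` is for experimenters who want
to turn such recordings — or simulations of them — into per-compartment,
per-state statistics usable as a drug-screening readout.

The package provides:

* **Kinetics** — percent change from baseline
  `pct(t) = 100 (F(t) − F0)/F0`, rate of change (%/s, 30 s smoothed),
  slope angles (degrees of the %-per-minute slope), and a plateau-separated
  state detector (`detect_states()`: rate > 0.25 %/s for ≥ 60 s, plateaus
  ≥ 45 s).
* **Synthetic data** — a seeded generative model of every condition
  (baseline / LPS / LPS + emapunil / emapunil alone; microglia and neurons)
  as traces (`simulate_trace()`, `generate_cohort()`) or rendered
  two-channel image stacks with ground-truth manifests (`render_stack()`).
* **Segmentation** — Otsu + connected components on the morphology channel
  (`segment_cells()`), geometric soma/branch/endfoot partition via
  morphological opening and skeletonization (`partition_compartments()`),
  and mask-mean trace extraction (`extract_trace()`).
* **Statistics** — t-test / one-way ANOVA / repeated-measures ANOVA
  (`compare_groups()`) and a per-(compartment × state × metric) treatment
  screen (`screen_report()`).
* **Orchestration** — `run_pipeline()` runs simulate → kinetics → report
  from a validated (YAML) config with a deterministic layout and seed
  provenance; the numbered scripts under `analysis/` are the narrative
  drivers.

## Worked example

```r
library(mitoscreen)

p <- make_default_parameters("lps", "microglia")
trace <- simulate_trace(p, "whole_cell", noise_sd = 0)   # clean trace
pct <- percent_change(trace, baseline_window = c(-300, 0))
pct$pct[pct$time == 1800]
#> [1] 253.12

detect_states(pct)
#> <state_segmentation> 3 state(s)
#>   state onset duration pct_change pct_cumulative max_slope_angle mean_rate
#> 1     1   356      137     117.90          118.9           89.04    0.8624
#> 2     2   841      131      76.70          198.4           88.52    0.5874
#> 3     3  1421      159      46.44          249.8           86.77    0.2936
```

The clean canonical trace reaches exactly 253.12 % at the end of the
30-minute window, and the detector recovers the three states within one
smoothing window of the generative onsets (363.6, 843.6, 1410 s) and
durations, with the S1 > S3 slope ordering. A cohort screen:

```r
co <- generate_cohort(c("lps", "lps_emapunil"), n_per_group = 10, seed = 1)
rep <- screen_report(analyze_cohort(co), "lps", "lps_emapunil")
subset(rep$comparisons, state == "overall")[, c(1, 6, 7, 11, 12)]
#>    compartment mean_control mean_treatment   p_value significant
#> 1   whole_cell        240.3          130.8 5.311e-06        TRUE
#> 11        soma        258.2          102.6 5.496e-08        TRUE
#> 21    branches        204.2          172.7 7.096e-02       FALSE
#> 31     endfeet        283.3          102.9 2.048e-08        TRUE
```

Soma and endfeet attenuation are flagged at α = 0.05; branches are not —
the domain-specific emapunil signature. The `analysis/01_simulate.R` …
`analysis/04_screen.R` scripts run the full study (cohort simulation,
rendered-field segmentation scoring, canonical kinetics, screens) and
write their tables under `results/`.

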