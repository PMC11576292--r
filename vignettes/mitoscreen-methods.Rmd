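---
title: "Methods: modelling and screening microglial mitochondrial membrane potential dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling and screening microglial mitochondrial membrane potential dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscreen)
```

## The measurement and the model

Microglia respond to immune stimuli with large, temporally structured
changes in mitochondrial membrane potential (ΔΨm). In acute-slice
experiments this is read out with TMRE, a potentiometric dye whose
fluorescence is proportional to ΔΨm, alongside an EGFP morphology channel
(CX3CR1 reporter) used to delineate the cells. After bath application of
the immune stimulant LPS at `t = 0`, the microglial whole-cell TMRE signal
rises in three progressive *states* — steep rises separated by brief
plateaus — while nearby neuronal somas rise only modestly to a plateau and
then slowly decline.

`mitoscreen` packages that phenomenology as a generative model plus the
analysis chain needed to recover it from data:

* **Percent change from baseline.** `pct(t) = 100 (F(t) − F0)/F0`, with
  `F0` the mean fluorescence over a 5-minute pre-treatment window
  `[−300, 0)` s. This is scale-free, so it is invariant to illumination or
  gain changes.
* **Kinetic model.** Each state `s` contributes a linear ramp of amplitude
  `A[s, compartment]` (% of baseline) between its onset and
  onset + duration; between ramps the trace is flat. A linear ramp was
  chosen deliberately: its slope, slope angle and rate of change are known
  in closed form, which makes every downstream detector testable against
  analytic expectations. Neurons follow rise → plateau → slow decline.
* **State detection.** The percent-change trace is smoothed with a 30 s
  centred moving average and differentiated (central differences) to a
  rate-of-change trace in %/s. A state is a maximal post-treatment episode
  with rate above 0.25 %/s lasting at least 60 s; episodes separated by a
  sub-threshold gap shorter than the minimum plateau duration (45 s) are
  merged, because a dip shorter than a plateau does not constitute a
  between-state plateau. Without this merging rule a state whose true rate
  sits just above threshold would fragment under realistic measurement
  noise.

## Canonical parameter values

The packaged defaults (`make_default_parameters()`) encode the reported
LPS response of microglia: three states with onsets 363.6, 843.6 and
1410 s (6.06, 14.06 and 23.50 min) and durations 121.2, 124.2 and 180 s.
The whole-cell amplitude split across states is 120 / 80 / 53.12 %, a
calibration chosen to reproduce the reported 253.12 % total rise with the
reported slope ordering S1 > S2 > S3 given the state durations; the split
itself is a model choice, not a measured quantity. Neuron parameters are a
50 % plateau reached 540 s post-treatment, held to 960 s, then a slow
0.02 %/s decline — a rate chosen once as "steady slow decline" since only
the plateau level and its timing are constrained.

Compartment amplitudes are likewise a calibration. The whole-cell trace
must be consistent with its parts, so the model requires the whole-cell
amplitude of every state to equal the area-weighted mean of the soma,
branch and endfoot amplitudes. With area weights 0.45 / 0.40 / 0.15
(soma / branches / endfeet — plausible area fractions for a ramified
microglia) the defaults are:

| state | soma | branches | endfeet | whole cell |
|---|---|---|---|---|
| S1 | 220 | 45 | 20 | 120 |
| S2 | 40 | 140 | 40 | 80 |
| S3 | 12 | 30 | 238.13 | 53.12 |

These satisfy every qualitative constraint of the subcellular
progression: the soma's largest gain is in S1, the branches show their
steepest rise in S2, and the endfeet dominate S3. Emapunil (a TSPO
inverse agonist) is modelled as multiplicative attenuation of the state
amplitudes: 0.40 for soma S1–S2, 0.35 for endfeet S2–S3, and 0.90
everywhere else — strong domain-specific attenuation in soma and endfeet,
negligible in branches; the whole-cell attenuation is derived from the
compartment combination rather than set independently. Under `baseline`
and `emapunil_only` conditions all amplitudes are zero (emapunil alone
does not move the baseline ΔΨm).

## The synthetic-data generator

`simulate_trace()` adds i.i.d. Gaussian noise (default SD 2 a.u., i.e.
2 % of the 100 a.u. baseline) per frame to the noise-free model curve.
`generate_cohort()` simulates `n = 10` cells per condition by default,
with deterministic per-cell seeds derived from one master seed and a
shared log-normal amplitude multiplier per cell (`sdlog = 0.25`, median
1). The multiplier models the cell-to-cell variability in response
strength that underlies every between-group test: with ~25 % biological
CV at `n = 10`, a strong attenuation (soma, endfeet) is reliably
significant while the weak 10 % branch attenuation usually is not — the
pattern the screen is designed to resolve. A consequence worth noting:
cells with a weak multiplier may not resolve S3 (its rate falls below
threshold), exactly as weakly responding cells would in real recordings;
such cells contribute no S3 rows (absent, not zero).

`render_stack()` rasterizes cells into a 256 × 256 px field at 0.5 µm/px:
a soma disc (5 µm), gently curved branches (quadratic Béziers, 15 µm long,
1.5 µm wide) ending in endfoot blobs (2.5 µm), and neuron discs (6 µm).
Channel 1 is static morphology at constant brightness; channel 2 follows
each compartment's noise-free trace, plus background (10 a.u.) and
per-pixel Gaussian noise. The manifest records exact masks and traces, so
segmentation and extraction can be scored by IoU and per-frame error.

What the generator does *not* emulate: photobleaching, focal drift, slice
movement, optics (no PSF), shot-noise scaling with intensity, process
motility, or morphological activation (soma enlargement, process
retraction). Passing tests therefore demonstrate correctness of the
measurement chain under the stated noise model, not robustness to every
artefact of real slice imaging; real hand-drawn ROI masks can be supplied
directly to `extract_trace()` to bypass the automatic segmentation.

## Segmentation choices

Cells are segmented from the time-averaged EGFP frame (the morphology
channel is assumed static) by Otsu threshold and connected-component
labelling; touching cells merge (no watershed). Compartment partition is
geometric, since published recordings were hand-traced and no delineation
rule is available: the soma is the largest component surviving a 3 µm
morphological opening; the remainder is skeletonized (Zhang–Suen) and
skeleton endpoints are branch tips unless they abut the soma (cut
artefacts); leaf segments within 4 µm path length of a tip seed the
endfeet, and every non-soma pixel is assigned by nearest skeleton pixel.
Remainder components with no true tip are slivers of the soma boundary
and are returned to the soma. The partition is disjoint and exhaustive by
construction. Neurons are never auto-detected; synthetic neurons carry
class labels in the manifest and real neuron ROIs must be user-supplied.

## Statistics

`compare_groups()` wraps the standard tests (pooled-variance t,
one-way ANOVA, subject-blocked repeated-measures ANOVA) with exact df
reporting and one documented convention: groups with zero within-group
variance and identical means return statistic 0, p = 1. Raw p-values are
reported at α = 0.05 by default (no multiple-testing correction, matching
the screening convention; Benjamini–Hochberg is available via
`p_adjust = "BH"`). The screen's attenuation calls use two-sided tests
with the effect direction reported alongside. Slope angles are reported
as degrees of the arctangent of the %-per-minute slope — the unit is a
package convention (configurable to %/s) since none is standard.

## Numerical choices and problem sizes

* Trace sampling 1 s over [−300, 1800] s; rendered stacks default to 2 s
  frames but analyses here use coarser rendered sampling (19 frames at
  100 s) because segmentation accuracy is time-independent and trace
  recovery is checked per frame regardless of frame count.
* Detection tolerances: the 30 s smoothing window bounds the onset and
  duration bias of the detector (at most one window), which is the
  tolerance used throughout the tests.
* Tie-breaking when more than `max_states` candidates survive: keep the
  largest within-state percent change, then the earliest onset, and
  report chronologically.
* Per-state percent change is within-state gain (smoothed trace at state
  end minus state start); the cumulative value at state end is reported
  alongside, since either reading of "per-state change" is defensible.
* Degenerate inputs: empty masks, all-zero images, flat traces and
  missing states all return defined results (zero labels, empty
  segmentations, absent rows) rather than errors, except where the input
  violates a stated precondition (NaN pixels, non-positive baseline).

## Known limitations

The state amplitudes and attenuation factors are calibrations that
reproduce reported totals and qualitative orderings; per-state group
statistics (F and p values) of the original recordings cannot be
reproduced without the raw data and are not claimed. The detector's onset
estimate is biased early by up to half a smoothing window for steep
states (and late for shallow ones); this is inherent to
smoothing-then-thresholding and bounded by the stated tolerance. The
compartment partition is a geometric convention, not a biological
delineation.
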