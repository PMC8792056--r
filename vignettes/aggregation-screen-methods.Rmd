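---
title: "Methods: quantifying chaperone modulation of protein aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying chaperone modulation of protein aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggscreen)
```

# Overview

`aggscreen` implements the quantitative layer of a cell-based
over-expression screen that asks, for each chaperone in a panel, whether its
co-expression alleviates or aggravates the aggregation of a disease protein
— a polyglutamine-expanded Huntingtin fragment (HTT-polyQ) or an ALS-mutant
FUS — in human cells. The package covers five analysis stages (cytometry
gating, screen scoring, FRAP mobility, microscopy quantification, expression
shifts) and a synthetic-data layer that generates every input type with
known ground truth, so the full pipeline is exercised and benchmarked
without instrument data.

This vignette describes the models and procedures, the tunable parameters
and their defaults, the numerical choices, what the simulators emulate (and
what they deliberately do not), and the design decisions made where the
underlying procedures were open to interpretation.

# Pulse-shape cytometry gating

## The PulSA signal model

Pulse-shape analysis (PulSA) distinguishes cells with diffusely distributed
fluorescent protein from cells that have concentrated the protein into an
aggregate. On a flow cytometer, each cell produces a fluorescence pulse with
a height \(H\), width \(W\) and area \(A\) (total signal). A cell whose
reporter is condensed into a punctum transits the laser as a more compact
bright object: at matched total fluorescence its pulse is *narrower and
taller*. The synthetic generator expresses exactly this premise
parametrically:

* \(A \sim \mathrm{LogNormal}(\mu, \sigma)\), drawn identically for
  aggregate-bearing and diffuse cells (the two populations differ in shape,
  not amount, of signal);
* \(W \sim \mathrm{Normal}(w, s_w)\), multiplied by a contraction factor
  \(\kappa \in (0,1)\) (default 0.45) in aggregate-bearing cells;
* \(H = A/W\), with multiplicative log-normal measurement noise (default
  CV 2%) on both pulse channels.

This is a parametric stand-in, not a physical laser-sweep convolution; it is
sufficient to carry the bivariate (width down, height up) signature the
gating exploits, and it can be swapped for a convolution model without
touching the analysis side. Dead cells receive diffuse-type pulses plus a
high viability-dye (DAPI) level, so only the viability gate — not the pulse
gate — can remove them. The simulator makes no attempt to model optics,
spectral spillover or compensation.

## Gate construction

The analysis gate chain mirrors the instrument workflow:

1. viability: events with DAPI signal at or above a threshold are excluded;
2. size: events with scatter outside `[low, high]` are excluded;
3. aggregate gate: an event is AGG+ iff the scalar statistic \(R = H/W\)
   strictly exceeds a threshold.

\(R\) is the simplest monotone embodiment of "taller and narrower"; the
original screen's gate was drawn interactively on the cytometer and is not
parameterized anywhere, so a reproducible rule is substituted. The threshold
is *calibrated on a wild-type (non-aggregating) sample*: after pre-gating,
it is set to the empirical \((1-\alpha)\) quantile of \(R\) (the
\(\lceil (1-\alpha)n \rceil\)-th order statistic), so that the wild-type
sample reads back an AGG+ fraction of at most \(\alpha\). The default
\(\alpha = 0.001\) reproduces the observed wild-type behaviour of an
effective AGG+ fraction of zero. Calibration is refused below 100 gated
events. The AGG+ fraction is reported out of the events surviving the
viability and size gates; a sample in which nothing survives those gates is
flagged invalid rather than scored 0.

With the simulator defaults (log-sd 0.25 on total fluorescence, width CV
5%, \(\kappa = 0.45\)), the two populations of \(\log R\) are separated by
\(2\log(1/\kappa) \approx 1.6\) against a within-population spread of about
0.27, which puts gate sensitivity near 1 at \(\alpha = 0.001\); the
simulated screens recover planted aggregate fractions to well within
\(\pm 0.02\). Real cytometry data are messier (doublets, spillover,
instrument drift); passing these tests demonstrates correctness of the
gating machinery, not robustness to artifacts the generator does not model.

# Screen scores and empirical confidence bands

## The Aggregation Modulation Score

Each chaperone replicate is scored against the neutral-protein (DsRed)
controls of its own batch (day):

\[ S = \log_2 \frac{f_{\mathrm{AGG}}(\text{chaperone})}
                   {\overline{f_{\mathrm{AGG}}}(\text{same-day controls})} \]

so \(S = -1\) corresponds to a 50% reduction in aggregate-containing cells
and positive scores to aggravation. Replicates aggregate per chaperone as
mean ± SEM (SEM uses the \(n-1\) sample SD). A replicate with
\(f_{\mathrm{AGG}} = 0\) cannot be log-transformed; it receives the
continuity substitution \(0.5/n_{\mathrm{sized}}\) and is flagged. Scores
are invariant to any global rescaling of the fractions (log-ratio
property). Batch labels are required input — days are not inferred.

## The control-replicate null

Significance is judged against an empirical null built from the control
replicates themselves. Each control replicate is scored leave-one-out
against the mean of the *other* same-day controls; scoring a control against
a mean that includes itself would shrink the null, so leave-one-out is the
default (a pooled mode exists). The sample SD of those scores defines the
bands: the 95% band half-width is exactly \(2\cdot\mathrm{STD}\) and the
99.7% half-width exactly \(3\cdot\mathrm{STD}\). The two-sided Gaussian tail
beyond them is ≈ 4.6% and ≈ 0.27%, which is what licenses the empirical
significance labels *p* < 0.05 and *p* < 0.003. Batches contributing a
single control cannot be scored leave-one-out and are dropped with a
warning; at least three usable control replicates are required.

A chaperone is called a significant alleviator when even the conservative
edge of its score, mean + SEM, lies below \(-2\cdot\mathrm{STD}\) (p < 0.003
when below \(-3\cdot\mathrm{STD}\)); aggravators are symmetric with
mean − SEM above the positive band. Calls are refused for single-replicate
records. No multiple-testing correction is applied across chaperones — the
screen's inference is the empirical band, nothing more.

## Calibration of the bands, and a deliberate conservatism

Two facts about this construction are worth separating. First, the *band
itself* is calibrated at the replicate level: under a null screen
(no true effects), about 5% of individual replicate scores fall outside
±2·STD — the property suite verifies ≈5% ± 2 points over 1,000 simulated
screens. Second, the *call rule* is deliberately conservative: it compares a
chaperone's mean-of-\(n\) (whose spread is \(\mathrm{STD}/\sqrt{n}\)),
further pulled toward zero by one SEM, against a band derived from
single-replicate spread. For \(n = 4\) the analytic null call rate is on the
order of 0.2%, not 5%. Both properties are asserted: the per-replicate
coverage at ≈5%, and the call rule's null rate at ≤5%. This is a real
feature of the published procedure, not an artifact of the reimplementation.

For the effect-recovery property (planted multipliers
\(m \in \{0.25, 0.5, 1, 2\}\) recovered within 3·SEM of \(\log_2 m\) in
≥95% of seeds), the simulated screens use 8 replicates per chaperone. The
choice is made on t-distribution grounds: the coverage of a ±3·SEM interval
is \(P(|t_{n-1}| < 3)\), which is 0.942 at \(n = 4\) (the screen's common
replicate number) and 0.980 at \(n = 8\); a 95% success criterion is only
robustly attainable with the larger \(n\). The fraction-level screen
simulator uses a log-normal replicate noise of 0.08 log2 units, matching
the scale of the printed control STDs (0.0584 and 0.0789 in the two
screens).

## Dose-response and the reporter score

Dose series are scored per dose with the same band rule, plus a strict
monotonicity flag on the mean scores (deepening alleviation with dose, or
the reverse). The heat-shock-reporter score normalizes plate-reader
fluorescence per timepoint — baseline (empty-vector) mean subtracted, then
expressed as a percentage of the MG132 positive-control span — and averages
the 12–24 h window; timepoints where the positive control does not rise
above baseline are dropped with a warning.

# FRAP mobility analysis

Fluorescence recovery after photobleaching reports how mobile the molecules
of an aggregate are: the mobile fraction exchanges with the unbleached pool
and sets the recovery plateau. The analysis follows the published recipe
exactly and deliberately avoids curve fitting — the readout is built from
binned medians, not exponential fits to single traces.

* **Normalization**: every intensity is divided by the median of the 27
  frames immediately preceding the bleach, and time is shifted so the first
  post-bleach frame is \(t = 0\). Traces with fewer than 27 pre-bleach
  frames are rejected by name. Normalization makes all downstream output
  invariant to a rescaling of the raw trace.
* **Binning**: per aggregate, medians of consecutive 20-timepoint windows
  from \(t = 0\); a trailing partial window is kept only when it holds at
  least half a bin (≥ 10 samples) — the source procedure is silent here and
  this rule is the package's choice. The median makes each bin robust to
  single-frame outliers.
* **Recovery percent**: 100 × the median over aggregates of the final-bin
  median. With pre-bleach normalized to 1 this is the percent of original
  signal recovered at the end of acquisition. The published summary numbers
  (42% vs 29.5% recovery) are reported without an explicit formula; this
  final-bin-median reading is consistent with their normalization and is
  recorded as the package's definition.
* **Condition comparison**: per-bin two-sided two-sample t-tests across
  aggregates, Benjamini–Hochberg adjusted across bins ("FDR-corrected" is
  pinned to BH), with per-bin median ± SEM per condition. Bins with fewer
  than two aggregates on a side are skipped with a warning.

The trace simulator draws a per-trace baseline log-normally (log-sd 0.3,
emulating expression-level differences), bleaches a fraction
`bleach_depth` of the signal, and recovers exponentially:
\(I(t) = B\,[(1-d) + f_m d (1 - e^{-t/\tau})]\) with additive noise
(default 5% of baseline). Defaults — frame interval 0.93 s, ≥27 pre-bleach
frames, 302 post-bleach frames (≈280 s), bleach depth 0.95 — reproduce the
acquisition geometry of the published experiment; the stated "high
percentage of bleaching (<90%)" is taken as a typo for >90%. At the
published sample sizes (156 vs 150 aggregates) and mobile fractions 0.42 vs
0.295, the per-bin comparisons reproduce the published significance
pattern: every bin after the second separates at q < 0.01. The simulator
does not model diffusion geometry, acquisition bleaching, or focus drift;
conclusions about those failure modes cannot be drawn from these tests.

# Microscopy quantification

All imaging operators are deterministic — identical images give identical
tables — and every threshold's strictness is fixed and tested at its
boundary:

* **Cell detection** (dual-channel): the stain channel is thresholded
  (strict >) and labelled into connected components; a component counts as
  a cell iff it contains nuclear-marker signal above threshold and its area
  is at least `min_cell_area_um2` (non-strict ≥).
* **Aggregate segmentation**: threshold (strict >), watershed on the
  distance transform to split touching blobs, objects retained at
  ≥ `min_agg_area_um2`. The published pipeline used a trained
  machine-learning segmenter that is not reproducible from its description;
  the threshold + watershed chain is a deterministic operator stack with
  the same role, and the synthetic images are built so that its recovery of
  planted objects is pixel-exact.
* **Nuclear / extranuclear partition**: the nucleus mask is dilated by a
  configurable perinuclear radius (default 2 µm — the source says only "a
  fixed area around the nucleus"); an aggregate's signal inside that
  enlarged region is its nuclear share, the remainder extranuclear, so the
  two shares always sum to the object's area. (Subtracting the perinuclear
  ring from *both* shares would break that conservation; the subtraction
  convention is applied to the extranuclear side only, which is the side
  the published method corrects.)
* **Neuron z-stack pipeline**: the central 15 successive slices are
  maximum-intensity projected; cells are detected at intensity > 240
  (strict, 8-bit scale — other bit depths are rescaled first), separated by
  watershed, and size-filtered at > 50 µm² (strict); aggregate pixels are
  summed per cell and a cell is aggregate-containing iff that area is
  > 5 µm² (strict). The "> 5 µm" rule in the source is read as an area in
  µm². Watershed separation is applied to cells, as written in the source
  procedure.
* **Batch comparison**: within each experiment every image's
  aggregate-containing fraction is divided by the mean fraction over all
  images of both conditions (so each experiment's normalized fractions
  average to 1), and conditions are compared with a two-sided two-sample
  Student t-test, unadjusted — exactly the published normalization.

The image generator plants cells on a disjoint grid with discs of exactly
`round(area / pixel²)` pixels, so ground-truth areas are correct to one
pixel-area of quantization. Neuron mode plants several large aggregates
plus many small foci per positive cell (defaults 3 + 10; the source gives
no counts) and empties the nuclear region of reporter signal, emulating the
neuronal mutant-FUS phenotype. The generator is noiseless by design: it
benchmarks the operator chain, not robustness to staining variability,
uneven illumination or out-of-focus light.

# Expression-shift statistics

This layer consumes externally produced tables (TPM and LFC with adjusted
p-values); alignment and differential-expression fitting are out of scope.

* **Expressed genes**: max-over-samples TPM ≥ cutoff (non-strict; 6 or 10
  for whole experiments, 2 for the smaller dataset).
* **Differential genes**: FDR < 0.05 (strict) in at least one comparison;
  for FUS-type experiments an additional |LFC| ≥ 1 cutoff (non-strict —
  the source states "cutoff of 1" without strictness; non-strict is chosen
  and documented). Both rules are idempotent and order-invariant.
* **Gene-set shift**: "Student's t-test" is read as the pooled-variance
  two-sample test (a Welch option exists but is not the default), two-sided,
  of the set genes' LFCs against the background. The set is excluded from
  the comparison group so the two samples are disjoint; the CDF output
  still reports the full background for the standard CDF-shift plot.
* **Restoration**: for a differential set defined in a reference condition,
  each condition is summarized (median, IQR, mean |LFC|, t vs 0) and
  conditions are ranked by mean |LFC| — the closest to zero is the most
  restored toward the unperturbed state. Conditions missing more than 10%
  of the set warn and compute on the intersection.

The LFC simulator draws set genes at \(\mathrm{Normal}(\delta, \sigma)\)
and background at \(\mathrm{Normal}(0, \sigma)\), with a restored condition
multiplying each true shift by `restore_factor` before fresh noise. Under
the null (\(\delta = 0\)) the shift test's p-values are uniform
(Kolmogorov–Smirnov over 1,000 seeds); at \(\delta = 0.5\),
\(\sigma = 0.3\), set size 50 it detects the shift at p < 0.01 in ≥95% of
seeds; and the restoration ranking recovers the simulated restore-factor
ordering. Real LFC vectors are heavier-tailed and gene-gene correlated;
the Gaussian generator does not probe those violations.

# Reproducibility and problem sizes

Every generator takes one integer seed and produces bit-identical output
for a fixed seed; the pipeline runner writes a manifest (resolved config,
seed, package version) alongside its outputs, and identical configs yield
byte-identical tables. Truth labels ride along with every synthetic dataset
and are never consulted by analysis code.

The shipped test and property suites use problem sizes chosen to estimate
each property comfortably while keeping a full run in well under a minute
per module: cytometry at 10,000 events per sample (the gate-consistency
property averages 20 seeds per aggregate rate), screen properties at 100
seeds × 4 effect sizes and 1,000 simulated null screens at the fraction
level, FRAP at the published 156/150 traces with ~330 frames each,
microscopy on 256–512 px synthetic fields, and expression properties at
1,000–2,000 genes over 40–1,000 seeds.

# Known limitations

* The pulse model is parametric (H = A/W); no laser-sweep convolution,
  spillover or doublet modelling, and the published cytometer gate geometry
  is not recoverable — the quantile-calibrated \(R\) gate is a documented
  substitute with a 2-D gate left as an extension point.
* Recovery percent is a plateau readout, not a fitted mobile fraction; the
  two coincide only as \(t \gg \tau\).
* The machine-learning segmentation steps of the published imaging
  pipelines (including the nuclear-structure classifier, which is excluded
  entirely) are replaced by deterministic operators; equivalence on real
  micrographs is not claimed.
* Expression statistics treat genes as independent; the t-test inherits
  that assumption.
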