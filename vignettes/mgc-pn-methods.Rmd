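---
title: "Methods: response statistics for MGC projection neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response statistics for MGC projection neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgcpn)
```

`mgcpn` analyzes odor-evoked activity of projection neurons (PNs) from the
male-specific macroglomerular complex (MGC) of the moth antennal lobe. This
vignette documents the statistical model behind each stage, the parameters
that matter, the numerical conventions, and what the synthetic-data
generator does and does not emulate.

## Spike-train statistics

Every trial runs on a fixed 2.4 s clock: 1 s of pre-stimulation baseline,
a 0.4 s odor pulse starting at `t = 1.0` s, and 1 s post-stimulation.
Spike times are binned into 240 half-open 10 ms bins `[t, t + 10 ms)` and
converted to instantaneous rates (count / bin width).

**Z-scoring is per trial**, against the mean and SD of that trial's own 100
pre-stimulation bins (ZIFR). This makes trials with drifting excitability
comparable before averaging; the trial-averaged trace is the MZIFR. Two
conventions are fixed package-wide:

- **SD is the population SD** (`ddof = 0`). For thresholding what matters
  is a consistent scale, and the population form makes hand-checkable
  examples exact (e.g. 10 of 100 pre-stimulation bins at 1 give mean 0.1,
  SD 0.3, `T_U = 0.688`).
- **Silent baselines.** Medial-tract MGC-PNs have low spontaneous rates, so
  an all-silent pre-stimulation second is possible. When the pre-stimulation
  SD is zero, the trace falls back to the mean-subtracted raw rate scaled by
  a pooled SD (in `analyze_spike_session()`, the SD of the neuron's
  pre-stimulation rates pooled over all its trials); if that too is zero the
  trace is all zeros. This avoids division by zero without discarding quiet
  neurons.

**Response detection** uses thresholds computed from the pre-stimulation
segment of the MZIFR itself, `T_U/T_L = mean(MZIFR_PS) ± 1.96 sd(MZIFR_PS)`,
i.e. a 5% significance level under approximate normality. The SD is taken
across the 100 pre-stimulation bins of the mean trace (that is what the
formula notates), not pooled across trials. The normal 1.96 is used
literally at all trial counts rather than a t-quantile.

Two detection rules are reported:

- the **per-bin rule**: the stimulation window is excitatory (inhibitory)
  if any of its 40 bins exceeds `T_U` (falls below `T_L`). When both
  crossings occur, the temporally first crossing decides — an explicit
  tie-break, since with 40 bins tested at the 5% level both events are
  common under noise alone;
- the **sub-window rule**: the mean MZIFR of SW(i) (bins 101–110, first
  100 ms) and SW(ii) (bins 111–140) is compared to the same thresholds,
  strictly (`>`/`<`). Averaging over 10–30 bins shrinks the null variance
  roughly 3–5-fold, so this rule is far more specific; the package's
  summary `response_label` and all parameter-recovery statements use it.

**Amplitudes** (ΔMZIFR) subtract the mean pre-stimulation MZIFR from the
whole trace and average over SW(i), SW(ii), a 200 ms post-stimulation
window, or the full 400 ms stimulation window (the framework's response
value). **Onset latency** re-bins the trial at 1 ms, Z-scores against the
1,000 pre-stimulation bins, applies the `T_U` formula to the Z-scored
pre-stimulation bins, and reports the first suprathreshold stimulation bin;
with a silent baseline the fallback makes any spike suprathreshold, so a
first spike at 1.012 s gives 12 ms. Only the stimulation window is scanned
(post-stimulus spikes never create or move an onset). **Peak latency** is
the stimulation-window argmax, earliest bin on ties.

## Calcium-imaging statistics

A recording is 100 ratiometric F340/F380 frames at 10 Hz: 4 s spontaneous,
2 s stimulation, 4 s post. Baseline normalization subtracts the mean of
frames 5–25 (0.5–2.5 s); the stimulation window is frames 41–60, the
1-based frame indices of the 4–6 s stimulation period on the 10 Hz clock. The response threshold is derived from the control (hexane)
ΔF traces: per frame, mean + 1.96 × SD **across individuals**, then the
maximum over frames. The formula's axis is not self-evident; the
across-individuals reading matches "control traces across eight
individuals", and the alternative (statistics across the frames of the
pooled mean control trace) is available via `threshold_axis = "frames"`.
A stimulus evokes a response when the across-individual mean ΔF trace peaks
*strictly above* the threshold within the stimulation window. Because the
threshold is a maximum over 100 frames, the effective false-positive rate
under the null is well below the nominal 5% — the detector is conservative
by construction. The two trials per stimulus are averaged before any
statistic.

## Cross-individual consistency

Per individual × unit, the odor-response vector holds one trial-averaged
amplitude per stimulus: mean raw ratio during the stimulation window minus
the pre-stimulation mean (the shared baseline constant cancels, so raw and
baseline-normalized traces give identical vectors). Consistency is the
Pearson correlation for every unordered pair of individuals; the mean
pairwise r is tested against a chance level of 0 with a one-sample t-test.
Two caveats are deliberate, matching the original procedure: pairwise
correlations sharing an individual are not independent, so the t-test is a
descriptive index rather than an exact test; and no Fisher z-transform is
applied by default (`fisher_z = TRUE` enables it). When every pairwise
correlation is identical the t-statistic is degenerate; the package reports
`p = 0` for a nonzero common value rather than erroring.

## The descriptive framework

Neurons are grouped into every output neuropil they innervate — VLP, SLP,
SIP, LH, and the SIP column; the mushroom-body calyces are excluded because
the framework maps lateral-protocerebral outputs only. Per neuropil ×
stimulus the member MZIFR traces are averaged element-wise; the **described
value** is the ΔMZIFR of the mean trace over the full 400 ms stimulation
window. Projection-combination responses (VLP+SLP+SIP, SLP+VLP, VLP,
VLP+LH) are simulated by averaging the combination's neuropil traces and
then taking the amplitude. Averaging traces before measuring is chosen over
averaging amplitudes: for the windowed mean the two commute (both are
linear), but trace-first stays valid should a nonlinear amplitude ever be
substituted. Validation fits recorded on simulated amplitudes by least
squares, pooled over combinations × the four female-produced odors, and
reports R². Low- and high-protocol neurons are pooled.

`framework_validation_experiment()` performs the split-sample version: the
map is built from a random two-thirds of the neurons and evaluated against
the mean amplitudes of the held-out third whose projection set equals each
combination. The split is stratified by morphology class so every
combination stays populated on both sides; an unstratified split of 42
neurons would regularly leave a combination without held-out members, which
tests nothing.

## Shuffled-assembly robustness

The framework's content validity is probed by rebuilding it five times,
each time recruiting `ceiling(2/3 × n)` members of every neuropil group
uniformly without replacement (ceiling because a "two-thirds" recruitment
of a 2-member group must still recruit at least 2 only when n = 2 — a
1-member group is used whole, with a warning). Random sub-streams are keyed
by (repeat, neuropil). Each repeat's map is flattened into one
neuropil × stimulus × bin vector over the four female-produced stimuli
(control and plant odor excluded, matching the framework's panels), and
Pearson correlations between repeats are averaged over the 10 pairs. The
contrast statistic is that mean minus the mean pairwise correlation of
individual neurons' concatenated firing traces: a robust framework has
assemblies that agree with each other much more than single neurons do.

## The synthetic-data generator

The generator exists so that every stage is testable against known ground
truth; it emulates the *statistical structure* the analyses assume, not the
biophysics.

**Spike trains** are inhomogeneous Poisson processes sampled by thinning
(exact for the piecewise kernels used; expected counts equal the rate
integral). The rate is the class baseline plus a stimulus kernel, clamped
at zero:

- *phasic*: `gain × baseline × exp(−(t − onset)/τ)`, τ = 0.08 s;
- *tonic*: `gain × baseline` boxcar over the stimulus window;
- *phasic_tonic*: their sum;
- *delayed*: phasic with latency ≥ 0.15 s;
- *inhibitory*: −0.8 × baseline boxcar.

Gains are expressed as multiples of the baseline rate so "a 3× response"
means the same thing for quiet and active neurons. The default tuning table
encodes the qualitative class tuning: cumulus classes respond to the
primary pheromone and the mixture, dma/dmp (LH-projecting) classes to the
antagonist and the secondary component, mediolateral-tract neurons broadly,
lateral-tract cumulus neurons fast and strongly to PP/PM; control and plant
odor carry no kernel. The default population is 42 neurons (16 Cu-mALT, 4
dma-mALT, 4 dmp-mALT, 5 multiglomerular mALT, 3 mlALT, 10 lALT). Baseline
rates are not reported numerically in the source literature beyond
medial-tract neurons being much quieter than lateral-tract ones; the
defaults — 15 Hz for mALT/mlALT classes, 30 Hz for lALT, 20 Hz for the
generic single-trial simulator — are ordinary moth-PN spontaneous rates and
are configurable. All draws use sub-streams keyed by (neuron, stimulus,
trial), so enlarging a study never perturbs existing traces.

**Calcium traces** are an individual baseline constant (mean 1.0, SD 0.05)
plus a shared unit × stimulus amplitude (ΔF units, defaults 0–0.45) scaled
by a per-individual gain (mean 1, SD 0.25, truncated at 0.1) times a common
temporal shape — a 3-frame linear rise at stimulus onset followed by
exponential decay with τ = 1 s, the phasic transient that decays over the
stimulation period — plus i.i.d. Gaussian frame noise (SD 0.02). Shared
tuning with individual gain is exactly the structure the consistency
analysis is designed to detect.

**What the generator does not emulate:** bursting and refractoriness,
adaptation across trials, correlated (non-Poisson) spiking, photobleaching
and movement artifacts, inter-individual differences in *tuning* (only
gain and noise differ), and odor-plume dynamics. Passing tests therefore
show that the statistics recover the structure they target under their own
model assumptions — not that real recordings satisfy those assumptions.

## Problem sizes and numerical checks

The packaged experiments use desk-scale sizes chosen to give stable
statistics: threshold calibration pools 2,000 null neuron × stimulus traces
of 5 trials each (80,000 stimulation bins); parameter recovery uses 500
neurons per condition at gain 3 and 5 trials; the split-sample framework
validation reports the median R² over five seeds of the default 42-neuron
session; consistency uses the default 8-individual study. Oracle
equivalence tests compare binning, Z-scoring, windowed means, grouping
averages and correlation matrices against brute-force reimplementations at
1e-10 tolerance.

A note on the 5% calibration: with 10 ms bins and realistic rates, per-bin
spike counts are small and the MZIFR is discrete-valued, so the per-bin
exceedance of ±1.96 SD is only approximately 5% and depends on the baseline
rate; estimating the SD from the trace itself smooths, but does not remove,
this discreteness. The calibration experiment measures the pooled rate
empirically rather than assuming it.

## Known limitations

- The t-test on pairwise consistency correlations ignores their dependence
  (by design, for comparability); a permutation test would be the rigorous
  alternative.
- The framework treats every neuron's contribution to each of its target
  neuropils equally and ignores axonal conduction delays, so the timing of
  synaptic output onto the neuropils is not represented.
- Response detection thresholds assume a stationary pre-stimulation
  baseline within each trial; slow drifts inflate the pre-stimulation SD
  and make detection conservative.
- The calcium detector's max-based threshold is conservative; weak but real
  responses near the threshold are missed more often than the nominal 5%
  level suggests.
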