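---
title: "Methods: models, conventions and design choices in matcare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in matcare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matcare)
```

matcare analyzes the behavioral, acoustic, morphological,
electrophysiological and molecular readouts of maternal-immune-activation
(MIA) experiments in mouse dams. This vignette documents the quantitative
definitions the package commits to, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the choices made where
the field's conventions leave the design genuinely open.

## Behavioral scoring of pup retrieval

A retrieval assay is a time-sorted event log over a `test_duration` of
300 s (the 5-min cutoff) with four foster pups. Latency to retrieve all
pups is the time of the last retrieval, censored at 300 s; censored values
enter group tests at the cutoff value, the common practice for a fixed-end
assay, and the censoring flag is kept for sensitivity analyses.

The *relative failure index* is defined here as

$$\mathrm{RFI} = \frac{\#\{\text{approaches without retrieval}\} +
\#\{\text{drops}\}}{\#\{\text{failures}\} + \#\{\text{retrievals}\}},$$

i.e. failures normalized by all pup-directed outcomes. The label
"relative" admits several denominators (per pup, per approach, per minute);
this one bounds the index in [0, 1], preserves the ordering "more failed
approaches → higher index", and is invariant to rearing/sniffing events and
to event reordering at equal timestamps. The raw failure count is available
via `normalize = FALSE`. Drops count once per drop event even if the pup is
later retrieved.

Windowed counts (rearing in the first minute, sniffing in the first 30 s)
use half-open windows $[0, w)$: an event exactly at the boundary belongs to
the next window. The same convention applies to every interval in the
package, including firing-rate intervals and behavioral epochs.

## USV call classification

Calls are processed at the contour level — a sequence of (time, peak
frequency, amplitude) points — not at the audio level; the recorder
front-end that extracts contours from spectrograms is upstream hardware.
Call metrics are the contour span (duration), the mean linear amplitude,
and the frequency at the maximum amplitude peak, with amplitude ties
resolved to the earliest time.

The six-way classification is an ordered decision tree on the smoothed
contour with fully configurable thresholds (`usv_thresholds()`):

1. duration < `d_short` (5 ms) → **short**;
2. total modulation (max − min frequency) < `m_flat` (3 kHz) → **flat**;
3. ≥ 2 direction reversals → **complex**;
4. exactly 1 reversal with an interior frequency maximum → **chevron**;
5. net frequency change beyond ± `m_dir` (6 kHz) → **upward** /
   **downward**; anything left falls back to **flat**.

Reversals are counted on a 3-point moving-median smoothed contour with a
1-kHz hysteresis band: a reversal registers only when the contour retreats
from its running extreme by more than the band. Raw contours jitter by a
few hundred Hz point to point; without smoothing and hysteresis that jitter
inflates the complex category. Classification is invariant to uniform time
shifts and to amplitude rescaling. The exact published rule table behind
these category names is not available; the thresholds above follow the
cited classification scheme's conventions and every one is exposed.

## Dendritic morphometry

Reconstructions use SWC semantics: a single soma root, children appearing
after their parents, 3-D coordinates in micron. The reader reports
malformed lines, orphan nodes and duplicate roots with the offending line;
the writer renumbers ids contiguously and round-trips coordinates
losslessly.

Sholl profiles count, at shells $r_0, r_0 + \Delta, \dots$ with
$r_0 = \Delta = 20$ µm, the dendritic edges whose endpoint distances from
the soma straddle the shell — the standard edge-crossing reading of Sholl
analysis. An endpoint lying exactly on a shell counts as a crossing
(deterministic closed-boundary rule). An edge could in principle dip
through a shell with both endpoints outside it; the synthetic trees grow
strictly outward (each child farther from the soma than its parent, with
monotone distance along every segment), where straddle counting and true
sphere–segment intersection coincide — the equivalence the test oracle
checks. Whether a curved branch should count once or multiple times per
shell is genuinely ambiguous in the field; per-edge straddle counting is
the documented choice. Distances are 3-D even though camera-lucida material
is quasi-2-D; z may simply be zero-filled.

Cumulative length sums Euclidean inter-node distances over dendritic
edges; branch points are nodes with ≥ 2 children; soma area is
$\pi r^2$ from the soma radius, or the shoelace polygon area when an
outline is provided. For Sholl statistics the mixed ANOVA can apply
$\log_{10}(\text{count}+1)$, which stays defined at the zero counts that
occur at large radii.

Spines are typed by an ordered threshold tree on length L, head width HW
and neck width NW (µm): L > 2 → filopodia; HW > 0.6 → mushroom;
L/max(HW, NW) < 1 → stubby; L > 1 → long thin; else thin. The thresholds
default to the morphometric convention the assay delegates to and are all
configurable; any positive triple receives exactly one class at any
setting. Spine density is reported per 10 µm of dendrite, pooled as
10 · Σcounts / Σlengths so segment concatenation cannot change it.

## Single-unit analysis

**Firing rate** is spike count over a half-open interval divided by its
length; epoch rates pool all of an epoch's intervals (total spikes / total
duration) rather than averaging per-event rates — with few, short retrieval
events per session, pooling is the lower-variance choice.

**Full AP width** is measured on the mean waveform as the time between the
first and last crossings of 10 % of the peak absolute amplitude, linearly
interpolated between samples. "Full width" of the extracellular complex is
not formalized anywhere; this definition is monotone in template width,
includes the afterhyperpolarization when it exceeds the threshold, and is
exactly amplitude-invariant. The threshold fraction is configurable.

**Classification** applies the firing-rate rule first: baseline FR above
10 Hz → fast-firing. Slow units split at spike width < 1.2 ms
(narrow-spiking, putative GABAergic) and > 1.4 ms (wide-spiking, putative
dopaminergic). Units inside the 1.2–1.4 ms dead zone are assigned
wide-spiking only when the waveform shows a post-peak undershoot deeper
than 20 % of the peak lasting at least 0.3 ms — the slow-AP signature
(long duration, slow depolarization, large negative undershoot) — and are
otherwise excluded. Both undershoot parameters are configurable; the rule
never reassigns a unit against the criterion.

**Bursts** are maximal runs of spikes in which every ISI is below 80 ms
and the span (last − first spike) does not exceed 160 ms. Detection is a
greedy left-to-right scan; a spike that would push the span past the cap
closes the burst and starts the next candidate pair. This is the one
deterministic resolution of the two-constraint rule, and the test suite
proves it equal to exhaustive enumeration of maximal candidate runs.
Bursting percentage is the percentage of *spikes* inside bursts (a
per-unit scalar, as group comparisons require), not the percentage of
bursting units; with no bursts it is 0 and the spikes/burst mean is
reported as 0 with a flag.

**ΔFR.** The epoch-versus-baseline change is the symmetric contrast
$(a-b)/(a+b)$: bounded in [−1, 1], zero iff no change, antisymmetric under
swapping epoch and baseline. The emulated analyses term this a "standardized
change ratio" without an accessible definition; the contrast form is the
bounded, sign-interpretable choice, and `method = "ratio"` ($a/b$) or
`"relative"` ($(a-b)/b$) are drop-in alternatives. Both rates zero is
undefined and excluded with a flag.

## Marker fractions and expression summaries

c-Fos quantification reports the fraction of Gal⁺ cells that are c-Fos⁺
and the Gal⁺ count normalized to DAPI. Fractions are computed per image
(one per hemisphere, two sections per brain), averaged to the animal, then
to the group — unweighted means at each level, matching the acquisition
hierarchy; with balanced images this equals pooled counting, which the
tests verify.

Expression matrices are carried as `SingleCellExperiment` objects (counts
assay, cluster and sex in `colData`; clusters are taken as given labels,
e.g. the galanin-positive hypothalamic clusters i8/i16/i18, with sexes
analyzed separately). Normalization is the standard per-cell library-size
log transform $\ln(1 + 10^4 \cdot c/\text{total})$; all-zero cells are
dropped with a warning. Dot-plot summaries report, per gene and
cluster × sex group, the fraction of cells with count > 0 ("expressing",
the dot-plot convention; threshold configurable), the mean log-normalized
expression, and a z-scaled mean across each gene's groups. Neither the
normalization constant nor the expression threshold is stated for the
emulated figure; the standard conventions are adopted and exposed.

## The statistical layer

All p values are two-sided; no multiple-testing correction is applied
(none is used in the emulated analyses), which the output metadata states.

- **Mann–Whitney U**: reports $U = \min(U_x, U_y)$; exact p by full
  enumeration of all $\binom{n_x+n_y}{n_x}$ labelings for
  $n_x + n_y \le 12$ (tie-free), otherwise the normal approximation with
  tie and continuity corrections.
- **t test**: Welch by default — the fractional degrees of freedom in the
  emulated analyses indicate the Welch form — with the pooled-variance
  Student form available.
- **Spearman**: rho is Pearson on mid-ranks; exact permutation p for
  $n \le 8$ (vectorized over all $n!$ permutations), otherwise the t
  approximation with a continuity correction of half the rho-lattice step
  $12/(n^3-n)$. The plain t approximation misses the exact enumeration by
  up to ≈ 0.024 at $n = 8$; the correction keeps the disagreement below
  0.02 at the crossover size, which the suite asserts.
- **Two-way ANOVA** uses Type-II sums of squares (each main effect
  adjusted for the other, the interaction for both), appropriate for the
  unbalanced 4–6 animal groups such experiments produce.
- **Mixed (split-plot) ANOVA** tests the between factor over the subject
  error and the within factor and interaction over the subject × within
  error, requires complete profiles (no imputation), optionally applies
  $\log_{10}(y+1)$, and reports Greenhouse–Geisser corrected p values
  alongside the uncorrected ones since the emulated analyses do not state
  which was used.
- **Grubbs screen**: $G = \max_i |x_i - \bar x| / s$ against the
  closed-form critical value
  $\frac{n-1}{\sqrt n}\sqrt{t^2_{\alpha/(2n),\,n-2}/(n-2+t^2)}$ at
  α = 0.05, the rule implemented by the commonly used online outlier
  calculator; iterative removal is optional and always retains ≥ 3 points.

## What the synthetic generators emulate — and what they do not

One global seed feeds per-generator substreams, so adding or reordering
generator calls never perturbs another generator's output, and identical
seeds give bit-identical data.

- *Spike trains*: narrow and fast units are homogeneous Poisson (6 and
  15 Hz defaults); wide units (4 Hz) are a renewal process with an 85-ms
  dead time plus injected bursts (2–3 spikes at 20-ms ISIs, 0.2 bursts/s)
  kept clear of tonic spikes by more than the 80-ms ISI threshold — so
  ground-truth bursts are exactly what the detector's rule finds, making
  oracle comparison exact. Waveform templates are piecewise-linear
  triangles (with an undershoot lobe for wide units) whose base solves
  analytically for the requested width; width modes are 0.9 and 1.6 ms
  with 0.05-ms SD. Behavioral epochs (one
  approach/retrieval/post-interaction cycle per pup inside the 15-min
  session, after a 10-min baseline) rescale rates multiplicatively. Not
  emulated: refractory dynamics beyond the dead time, rate drift,
  waveform noise, spike-sorting errors.
- *Behavior*: approach attempts at exponential waiting times (1/20 s⁻¹),
  each failing with `p_fail` (split between no-retrieve and drop),
  rearing and sniffing as independent Poisson streams (8 and 12 events/min
  — chosen as typical assay counts: a handful of sniffs in the first 30 s,
  ~5–15 rearings in the first minute). Not emulated: spatial structure,
  licking/grooming, pup identity confusion.
- *USVs*: six contour archetypes with 0.3-kHz Gaussian jitter; durations
  20–60 ms (2–4 ms for short), base frequencies 60–80 kHz, ~15-kHz ramps
  and 8–10-kHz arcs. Not emulated: raw audio, call sequences, harmonics.
- *Morphology*: strictly outward-growing random binary trees (depth 4,
  ~30-µm segments) or deterministic full binary trees for hand-checkable
  geometry. Not emulated: tortuosity, tapering, non-monotone re-entrant
  branches — which is precisely what keeps straddle counting equal to the
  geometric oracle.
- *Cell tables and counts*: Bernoulli marker flags (DAPI always positive,
  Gal⁺ at 0.2, c-Fos⁺ given Gal⁺ at 0.45) over an animal × section ×
  hemisphere hierarchy; expression counts are zero-inflated negative
  binomial, `1 + NB(mean 2, size 1)` for expressing cells, so the
  expressing fraction equals the configured probability exactly.

Passing tests on these data demonstrate the *scoring* chain is correct at
known ground truth; they do not validate the generators as models of real
recordings (no sorting noise, no missed calls, no reconstruction error).

## Problem sizes and runtime choices

The verification suite uses 1000 random trains (≤ 50 spikes) for the burst
oracle, 150 units for classification recovery, 100 units for ΔFR recovery
under a doubled epoch rate, 200 random trees for the Sholl oracle, 500
random behavior logs, 500 calls per category for USV recovery, 2000 null
simulations per statistical test for type-I calibration, and 200
replicates of the two-group experiment (20 units/class and 16 dams per
group — the study's per-group sizes) for the end-to-end power property,
with 200 further zero-effect replicates for the false-positive rate.

## Known limitations

- The dead-zone undershoot rule resolves synthetic dead-zone units
  perfectly by construction; on real waveforms the 20 % / 0.3 ms defaults
  will need tuning against the recording setup.
- Bursting percentage depends on the tonic rate, so group differences in
  FR mechanically shift bursting % — visible in the worked example and
  worth keeping in mind when interpreting that metric.
- The mixed ANOVA requires complete within-subject profiles; subjects with
  missing shells must be handled upstream.
- `marker_fractions()` averages images with unequal cell counts
  unweighted, by design; weighted aggregation would need the per-image
  counts it also returns.
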