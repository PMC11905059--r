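---
title: "Cross-frequency coupling of trial-structured LFP: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-frequency coupling of trial-structured LFP: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfreq)
```

## The analysis in one paragraph

`crossfreq` asks whether the coupling between frequency bands of a cortical
LFP carries information about a visual stimulus. A session is decomposed
into seven canonical bands (δ 0.1–4, θ 4–8, α 8–12, β 12–30, γ1 30–70,
γ2 70–100, H 100–200 Hz); per trial, the analytic signal of each band gives
an instantaneous amplitude and phase; every one of the 21 band pairs yields
one phase–amplitude coupling value (PAC: low band's phase against high
band's squared amplitude) and one amplitude–amplitude coupling value (AAC:
Pearson correlation of the two envelopes); and a two-factor ANOVA over
trials screens each pair for orientation and stimulus-type effects, followed
by tuning curves, LG/CG distances and tuning-range SD ratios for the pairs
that survive.

## Preprocessing model and assumptions

**Filtering before segmentation.** The whole continuous session is filtered
first and only then cut into trials, so trial windows carry no filter edge
transients. The filter is a 3rd-order Butterworth band-pass applied forward
and backward (`filtfilt`): the net phase response is identically zero —
essential, since PAC is a statement about phase — and the magnitude response
is the square of the single-pass response. −3 dB points sit at the band
edges. The design is built in second-order sections; for the 0.1–4 Hz band
at 1.25 kHz a transfer-function form is numerically fragile (poles at radius
0.9998), while the SOS cascade is stable. Edges are handled by odd
reflection padding of at least three times the slowest pole's time constant.

**Octrode averaging.** The eight channels of a shank sit close enough that
their LFPs are near-duplicates; averaging them (after filtering — the two
linear steps commute, the order is fixed for reproducibility) trades spatial
resolution for noise reduction. One averaged signal per shank ("octrode") is
the analysis unit.

**Trial windows and normalization.** Trials are half-open sample intervals
`[onset − 0.5 s, onset + 2.5 s)` on 0-based onsets; the 2-s stimulus segment
is z-scored against the mean and SD of that trial's own 0.5-s prestimulus
segment, and only the stimulus segment is analyzed further. Per-trial
baseline normalization removes slow drifts in excitability and equates
units across bands and octrodes. Trials whose window leaves the recording
or whose prestimulus SD is zero are dropped and counted, never imputed.

## The coupling statistics

With $x̃(n)$ the discrete Hilbert transform of $x(n)$ (computed by zeroing
negative frequencies of the FFT, the periodic-boundary form of the
odd/even-lag $2/\pi(k-n)$ convolution kernel), amplitude and phase are
$A(n) = \sqrt{x^2 + x̃^2}$ and $\varphi(n) = \arg(x + i x̃) \in (-\pi,\pi]$.

$$\mathrm{PAC} = \frac{\left|\sum_n p_y(n)\, e^{i\varphi_x(n)}\right|}
{\sum_n p_y(n)}, \qquad p_y = A_y^2$$

is the modulus of the power-weighted mean phasor: 0 when high-band power is
spread evenly over low-band phase, 1 when it is concentrated at one phase.
For the envelope family $A_y = 1 + m\cos\varphi_x$ with uniform phase it has
the closed form $m/(1+m^2/2)$, which the tests exploit.

$$\mathrm{AAC} = \mathrm{corr}(A_x, A_y) \in [-1, 1]$$

is the Pearson correlation of the two instantaneous envelopes.

Both are computed per trial and octrode on the z-scored 2-s stimulus
segment. Computing the Hilbert transform per trial (rather than on the whole
session) matches the rule that all analysis happens on the stimulus window;
the edge effects of a 2500-sample analytic signal are shared by all
conditions and cancel in the comparisons. Degenerate inputs (zero power,
zero envelope variance) produce explicit `NA`s that are excluded pairwise
downstream.

**A bias worth knowing.** The PAC statistic is only unbiased when the
low-band phase completes many full cycles in the window. A 2-s window holds
less than one δ cycle, so δ-phase pairs carry a large positive bias
(≈0.4–0.5 against a θ-pair floor of ≈0.1). This is intrinsic to the
phasor-mean estimator at these window lengths, not a defect of the
implementation; δ-phase rows should be compared against their own null, not
against other pairs' values.

## Selectivity screening

Per band pair, per-trial coupling values (octrodes averaged by default; a
flag keeps them as replicates) enter a two-factor fixed-effects ANOVA with
orientation and stimulus type as crossed factors and trials as within-cell
replicates — the only reading of "orientation, stimulus and trial factors"
that yields testable per-factor p-values, since three crossed factors would
leave one observation per cell. Raw p-values are compared against α = 0.05
by default; no multiplicity correction is applied across the 21 pairs
(Bonferroni and Benjamini–Hochberg are available behind a flag) so that the
reported values are directly interpretable per pair. Pairs with an empty
design cell are flagged untestable rather than silently dropped.

Tuning curves are per-orientation trial means, normalized jointly across
both stimulus types by the curve-set maximum, so the best condition is 1 by
construction and curves are comparable across subjects. The LG/CG distance
pairs trials by within-orientation index (trimming to the common count),
takes the Euclidean distance of the two 30-trial vectors divided by the
trial count, and averages over orientations; values are computed on the
max-normalized scale so distances live on the same axis as the plotted
curves. This pairing/normalization convention is one of several defensible
readings and is therefore recorded in the function's output rather than
asserted as canonical. The SD ratio uses the per-orientation trial-mean
tuning values: SDR = SD over orientations of the LG curve divided by that of
the CG curve; SDR > 1 means the second-order stimulus spans a narrower
coupling range. Consensus across subjects is the intersection of
per-subject selectivity flags, with mean ± SD p-value summaries.

## The synthetic-session generator

The generator exists because the pipeline needs inputs with known ground
truth. Its defaults are the study conditions: 1.25 kHz sampling, 32 channels
in 4 shanks, 8 orientations (0°–315° in 45° steps) × 2 stimulus types (LG,
CG) × 30 trials in pseudorandom order, 2-s stimuli separated by a 1-s gray
screen, trials cut 0.5 s / 2 s / 0.5 s. Two conditions-count readings exist
upstream (16 = 8 × 2 vs a stated 18); the generator models the 16 that the
orientation/stimulus grid defines and makes no attempt at the two extra
conditions.

Per shank, the background is unit-SD 1/f-shaped noise (spectral exponent 1
by default — the canonical LFP slope) synthesized directly in the frequency
domain; each channel adds independent white noise (SD 0.5 by default, in
background-SD units) to its shank source, emulating sensor-level noise on
near-duplicate channels.

**PAC injection.** During each stimulus window the low band contributes a
narrowband random oscillation (a handful of random tones in the middle 80 %
of the band, so its phase wanders within a trial and decoheres across
trials), and the high band a carrier at the band center ± 15 % of bandwidth
whose envelope follows $(1 + m\cos(\varphi_{low} - \varphi_0))/(1+m)$, with
$m$ = base strength × circular-Gaussian orientation tuning × stimulus gain.
Component amplitudes default to 1.5 (low) and 1.0 (high) background-SD
units — large enough for a well-defined phase, small enough that background
dilution keeps estimated PAC realistically below its analytic value. A
wandering low-band phase is not cosmetic: with a strictly periodic carrier
the PAC magnitude is invariant to trial-shuffling (it measures spectral
overlap, not alignment), and no surrogate null could separate injected
coupling from chance.

**AAC injection.** Both carriers ride on slow log-normal envelopes
(log-SD 0.25, bandwidth 4 Hz) whose log components mix a shared process with
a private one, the shared variance fraction equal to the target correlation
ρ = base strength × tuning × gain; the envelope correlation is then ρ up to
log-normal shrinkage (≈0.69 for a target of 0.7 at this σ — inside the
tests' tolerance). The 4-Hz envelope bandwidth gives ≈16 effectively
independent envelope samples per 2-s trial, enough that per-trial
correlation estimates average close to the target.

**What the generator does not emulate** — and hence what green tests do not
establish about real recordings: spiking leakage into the H band, line
noise and movement artifacts (assumed removed upstream), non-stationary
background slope, layer-dependent phase reversal across a shank, genuinely
non-sinusoidal rhythms (whose harmonics can masquerade as PAC), and any
biophysical mechanism linking the bands. Passing tests certify that the
estimators recover known injected structure under realistic noise — not
that real cortex behaves like the model.

## Numerical and design choices

* **Hilbert transform**: frequency-domain analytic signal in production;
  the O(N²) circular parity-kernel sum serves as the independent test
  oracle. Identical results to machine precision at even lengths.
* **PAC normalization**: the bounded power-weighted-phasor form is used; an
  unnormalized variant would not be comparable across trials or bounded in
  [0, 1].
* **Filter order convention**: "3rd order" is per direction; the
  forward–backward pass doubles the effective order (6th-order magnitude).
* **Indexing**: sample indices are 0-based on disk and in event tables,
  half-open windows everywhere; R's 1-based indexing is confined to
  internals.
* **Seeds**: one global seed; stages derive sub-seeds by fixed offsets, so
  a pipeline run is bit-reproducible (manifest checksums are compared in
  the tests).
* **Missing values**: explicit `NA`s flow from degenerate trials through
  the coupling table and are excluded pairwise; a trial is never silently
  repaired.

## Problem sizes used by the test-suite

Unit tests run on reduced geometries (4–8 channels on one shank, 1–6 trials
per condition) chosen so the full suite stays fast while every code path is
exercised at the study's sampling rate and trial layout. The end-to-end
recovery experiment runs 100 independent sessions at the full behavioral
design (8 orientations × 2 stimulus types × 30 trials, 1.25 kHz) with 8
channels on one shank — probe geometry is orthogonal to the selectivity
question, and one octrode is the analysis unit either way. The acceptance
script runs the complete default geometry (32 channels, 4 shanks, 480
trials) once per coupling kind.

## Known limitations

* The PAC δ-phase bias above; comparisons involving δ-phase pairs need
  their own surrogate null.
* Filter roll-off is not a brick wall: strong band-limited injections bleed
  weak, genuinely tuned coupling into adjacent-band pairs (visible in the
  README example). The screen ranks pairs; it does not isolate a single
  causal pair.
* Per-trial analytic signals on 2500 samples have edge effects within each
  trial; they are condition-independent but inflate within-trial variance
  slightly.
* The two-factor ANOVA assumes within-cell homoscedasticity; coupling
  values near the [0, 1] bounds can violate it. With 30 trials per cell the
  F-test is robust in the simulated regime, but heavy-tailed real data may
  warrant a rank-based screen, which the package does not provide.
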