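---
title: "Decoding wearable SSVEP recordings: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding wearable SSVEP recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepkit)
```

## The problem

A steady-state visual evoked potential (SSVEP) speller presents an array of
targets, each flickering at its own frequency/phase pair. Gazing at a target
entrains occipital cortex at the flicker frequency and its harmonics; a
decoder identifies the gazed target from a short multichannel EEG segment.
`ssvepkit` implements the full decoding and evaluation chain for a
twelve-target wearable speller recorded with an 8-channel occipito-parietal
headband (POz, PO3, PO4, PO5, PO6, Oz, O1, O2) in paired wet- and
dry-electrode sessions, together with a synthetic-data generator so that the
entire pipeline is testable without any recordings.

## Stimulus model

Targets are coded by joint frequency-phase modulation: frequencies
9.25--14.75 Hz in 0.5 Hz steps and a 0.5&pi; phase increment between targets
adjacent in frequency. Frame `i` of a display refreshing at `R` frames/s has
luminance

    s(f, phi, i) = 1/2 * (1 + sin(2 pi f (i / R) + phi)),

bounded in [0, 1]. `speller_layout()` carries the twelve (frequency, phase)
pairs; `generate_stimulus_sequence()` evaluates the luminance law.

## Signal model of the generator

`simulate_epoch()` and `simulate_subject()` build epochs as

* an evoked component, from one visual latency (default 0.14 s) after
  stimulus onset: `sum_h A_h sin(2 pi h f (t - latency) + h phi)` over four
  harmonics. Default amplitudes are the group-average values at the 11.25 Hz
  target — wet 2.597, 1.262, 0.746, 0.316 uV; dry 2.444, 1.119, 0.706,
  0.305 uV. Harmonic `h` carries phase `h * phi`, the phase structure of a
  periodic nonlinear response; amplitudes decay with stimulus frequency as
  `(f / 11.25)^(-freq_decay)` (default exponent 1, a mild decay — the decay
  is known to be steep but is not quantified per frequency, so it is
  exposed as a parameter);
* a fixed occipital topography (unit gain at Oz, smaller on the
  parieto-occipital ring) mixing the component across the 8 channels;
* background noise: Gaussian `1/f` noise, independent per channel with a
  20% channel-shared component, plus a spontaneous alpha-band oscillation
  (~10.5 Hz, drifting frequency, slow amplitude envelope) projected through
  the same occipital topography;
* multiplicative trial-to-trial amplitude jitter (SD 10%).

The alpha component is the scientifically important confuser: it overlaps
the 9.25--14.75 Hz stimulus band, so it — not white noise — is what limits
single-trial decoding of real occipital EEG.

**Noise calibration.** Neither the record format nor the protocol fixes a
noise level, so the three free scales were set once so that filter-bank CCA
at a 1 s data length on synthetic subjects lands at the group-mean
accuracies reported for this paradigm (about 0.68 wet, 0.50 dry): broadband
RMS 4 uV (wet) and 6 uV (dry), alpha RMS 5 uV. These defaults are frozen;
experiments that need other regimes pass their own `subject_profile()`.

**What the generator does not emulate.** Eye blinks and movement artifacts,
electrode drift, inter-subject latency/phase variability, and
fatigue-related nonstationarity (the paradigm showed stable accuracy over
blocks). Passing tests therefore demonstrate correctness of the decoding
computations and realistic relative orderings of the methods — not
performance guarantees on any particular real dataset.

## Protocol and record layout

A session is ten blocks per electrode type; each block holds one trial per
target in random order (1 s cue, 2 s flicker, 1 s rest). Epochs span 0.5 s
before to 2.34 s after onset (0.14 s latency + 2 s stimulation + 0.2 s
post), are acquired at 1000 Hz and downsampled to 250 Hz: 710 samples. The
per-subject record is a 5-D array `[channel(8), time(710), electrode(2),
block(10), target(12)]` stored in a MAT-file under the variable `"data"`,
with electrode index 1 = wet, 2 = dry (the convention the impedance file
documents; the main array's ordering is not documented, so the impedance
convention is adopted). The impedance file is `[type(2), channel(8),
block(10), subject]` — its prose description lists the axes in a different
order than the lengths imply, and the axes are mapped by length. The
package reads and writes these layouts (`write_subject_record()`,
`load_subject_record()`, `load_impedance()`, `load_subject_info()`) with a
minimal MAT v5 codec carried in the package; loaders validate rank and axis
lengths and report expected vs. found shapes.

Indexing is 0-based with half-open windows: onset sits at sample
`round(0.5 * rate)` inside an epoch, and the decoded segment is
`[onset + 0.14 s, onset + 0.14 s + L)` — sample 160 onward at 250 Hz.
Downsampling uses a zero-phase FIR anti-alias filter (order 64, unit DC
gain, odd-reflection padding against edge transients) before taking every
4th sample.

## Decoders

**Standard CCA.** For target `k`, the first canonical correlation between
the 8-channel segment and a reference of sin/cos pairs at harmonics
`1..Nh` of `f_k` (phase 0 — the cosine row absorbs any phase offset);
`Nh = 5` by default, the point past which adding harmonics stops helping
in this paradigm. CCA is solved through explicit covariance matrices with
a trace-scaled ridge of 1e-8 — short segments (50 samples at 0.2 s)
against 8 + 10 variates are otherwise ill-conditioned — and is invariant
under invertible recombination of either signal's rows.

**FBCCA.** The segment is decomposed into `N` nested sub-bands
(`[8n, 90]` Hz, zero-phase forward-backward Chebyshev I, order 4, 0.1 dB
ripple — kept small so the doubled ripple of two passes stays well under
1 dB), and target scores are `sum_n w(n) rho_{n,k}^2` with
`w(n) = n^(-a) + b`. The weight law is printed in flattened typography in
the source material ("n-a+b"); it is implemented as the power law, the
form used by the filter-bank method it cites, under which the reported
grid optima are non-degenerate. Defaults `a = 1.25`, `b = 0.25`, `N = 5`;
the full grid `a in 0.25..2 (0.25)`, `b in 0..1 (0.25)`, `N in 1..6` — 240
cells — is searched by `grid_search()`, which computes sub-band features
once and reweights them per cell, with ties broken toward smaller `N`,
then `a`, then `b`.

**TRCA / FBTRCA.** Task-related component analysis learns, per class, the
spatial filter maximizing inter-trial reproducibility: the top generalized
eigenvector of the summed inter-trial cross-covariance against the
covariance of the concatenated trials (the standard formulation of the
method's literature; the equations are externally sourced, as the study
reporting this paradigm does not restate them). The eigenvector sign is
fixed by making its largest-magnitude entry positive. Classification
correlates the filtered test segment with the equally filtered class
template (training mean); the ensemble variant stacks all classes' filters
(the default — whether the original analysis used the ensemble is not
stated, so both are provided). Scores combine across sub-bands as
`sum_n w(n) sign(r) r^2`. Leave-one-block-out cross-validation trains on
B−1 blocks and tests on the held-out block, avoiding within-block leakage.

**Electrode transfer (ET).** Templates from the train-electrode session are
projected to one dimension per class and sub-band by AVG (channel mean),
CCA (weights against the class reference), or TRCA (the class filter). A
test trial from the other electrode type is matched to each candidate
template by an ordinary least-squares spatial filter fitted *on that trial
alone* — the calibration-free reading of the method, which exists precisely
to avoid recalibration on a new electrode type; both signals are
mean-removed and no intercept is used. The template-match correlation `r1`
and the reference correlation `r2` fuse as
`p = sign(r1) r1^2 + sign(r2) r2^2`, bounded in [−2, 2], and sub-bands
combine as `sum_n w(n) p_{n,k}` (mirroring the filter-bank structure; a
squared-fusion variant is exposed as an option).

## Evaluation

**ITR.** `itr(N, P, T) = (log2 N + P log2 P + (1-P) log2((1-P)/(N-1))) *
60 / T` bits/min, with the conventional limits at `P = 0` and `P = 1`; it
is zero exactly at chance `P = 1/N` and strictly increasing above it. `T`
defaults to the data length alone (the convention of reporting a
theoretical ITR at the stimulation time); gaze-shift time can be added by
the caller. Cohort summaries compute ITR per subject and then average —
plugging a mean accuracy into the formula gives a different (biased)
number because ITR is convex in `P`.

**Spectra and narrowband SNR.** `amplitude_spectrum()` is single-sided and
scaled so an on-bin sinusoid of amplitude A peaks at A. The narrowband SNR
is `20 log10( y(f) / sum_{k=1..5} [y(f - k df) + y(f + k df)] )` — the sum
of the ten neighbours, exactly as the formula is printed; the
accompanying prose says "mean of the neighbours", which differs by the
constant `20 log10(10) = 20` dB and is exposed as `variant = "mean"`. A
flat spectrum gives −20 dB under the sum form. One numerical subtlety: the
stimulus frequencies (x.25 / x.75 Hz) fall *between* the 0.5 Hz bins of a
2 s FFT, so `epoch_snr()` evaluates the DFT amplitude exactly at `f` and
at `f ± k/T`; offsets at integer multiples of the window resolution are
orthogonal to the stimulus component, keeping the neighbour estimates
leakage-free. `epoch_snr()` also averages the time-locked waveform across
trials *before* the spectrum (coherent averaging — the grand-average
construction used for group-level SSVEP spectra); with few trials the
alpha band dominates the neighbour sum and the SNR of a small cohort can
legitimately be negative.

**Group statistics.** `group_stats()` runs two-sided paired t-tests
(wet vs. dry) for every numeric metric, Pearson correlations (wet vs. dry
accuracy, accuracy vs. impedance per electrode, accuracy difference vs.
impedance difference), and the three-way subject split at a ±10
percentage-point accuracy difference. Raw p-values are reported without
multiplicity adjustment, matching the reporting convention of the
paradigm's literature. Degenerate inputs (zero-variance differences) yield
t = 0 / r = NA rather than errors. `block_trend()` fits the least-squares
slope of per-block accuracy — the stability-over-time check.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen as the smallest sizes at which each property is
meaningful: identity checks on noiseless 3-block sessions; chance-level
checks on 120 pure-noise trials against the 99% binomial band;
method-ordering checks on a 5-block default-noise session; the grid search
on a 3-subject, 4-5-block cohort. The acceptance script simulates 3
subjects x 5 blocks x both electrodes (180 trials per electrode) and
reports mean accuracies, ITR, SNR, the harmonic sweep, the 240-cell grid
search and the pure-noise chance level.

## A worked example

```{r example, eval = FALSE}
layout <- speller_layout()
profile <- subject_profile(subject_seed = 42)
session <- simulate_subject(layout, profile, n_blocks = 5,
                            electrodes = c("wet", "dry"))
record <- session_to_record(session)      # the 5-D study layout
wet <- record_to_epochs(record, "wet")
dry <- record_to_epochs(record, "dry")

loo_block_cv(wet, layout, "fbcca", data_length = 1)
loo_block_cv(dry, layout, "fbtrca", data_length = 1)
et_evaluate(wet, dry, layout, projection = "cca", data_length = 1)

gs <- grid_search(wet, layout, "fbcca")
glance(gs)
autoplot(gs)
```

## Known limitations

* The synthetic generator shares one latency and phase convention across
  subjects, so cross-subject coherent averages are cleaner than in real
  cohorts.
* The MAT codec covers the subset of MAT v5 needed for these records
  (numeric and character arrays, little-endian); cell/struct variables are
  out of scope.
* Grid searches over supervised methods re-use leave-one-block-out
  features across cells; this is exact for the weight parameters but means
  the filter design (order, ripple) is held fixed during the search.
* The online decoding path of the original acquisition system used
  parameters from a different experiment and is deliberately not
  reproduced.
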