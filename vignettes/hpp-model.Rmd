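---
title: "The hppsim model: from waveforms to simulated listening times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hppsim model: from waveforms to simulated listening times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hppsim)
```

`hppsim` simulates a two-phase Headturn Preference Procedure (HPP)
experiment end to end. This vignette documents the model itself — its
assumptions, its tunable parameters, the numerical choices inside each
stage, and what the synthetic stimuli do and do not emulate — so that a
user can judge which conclusions transfer from simulations to infant
studies.

## The model in one paragraph

An infant in the test phase of an HPP study is modeled as (i) an acoustic
front end that reduces speech to sequences of discrete acoustic
prototypes, (ii) an episodic memory of previously heard utterances plus
the familiarized word tokens, each stored as a fixed-dimension
co-occurrence histogram, (iii) a matching step that explains each test
sentence as a non-negative weighted mixture of everything in memory,
(iv) a familiarity score derived from the weights that land on the
familiarization entries, and (v) a behavior generator that turns the
per-sentence scores into a continuously decaying attention function from
which an experimenter-like threshold rule reads off listening times.
Crucially, the model never segments words out of the test sentences: a
sentence is matched as one "bag of acoustic events". If such a model
reproduces familiarity preferences, explicit word segmentation is not a
necessary assumption for this class of experiments.

## Acoustic front end

Waveforms (mono, 16 kHz by default) are analyzed in 20 ms windows hopped
by 10 ms — 100 frames per second, `frame_count()` gives the exact count
`floor((ms − 20)/10) + 1`. Each frame yields 13 mel-frequency cepstral
coefficients; first differences (Δ) and differences-of-differences (ΔΔ)
are appended, so a frame carries 3 × 13 = 39 numbers. Conventional
choices that the counts-and-timing specification leaves open are fixed
as: Hamming window, pre-emphasis 0.97, a 26-filter triangular mel bank up
to Nyquist, cepstra 0–12 retained (including the 0th as the energy-like
term), and a floor of 1e−10 on filterbank energies so silence produces
finite features. Δ is the plain backward difference with a zero-padded
first frame — a regression-window delta would be a stronger smoother than
the stated "difference between adjacent vectors" and was rejected for
that reason. There is deliberately no speaker normalization and no pitch
feature: generalization failures across speakers are part of what the
model is meant to exhibit.

## Prototype codebooks

Three independent codebooks (150 static, 150 Δ, 100 ΔΔ prototypes) are
learned by seeded k-means and each frame is replaced by its three
nearest-prototype labels (Euclidean distance, ties to the lowest index).
Training runs Lloyd iterations from a k-means++ initialization, capped at
50 iterations with a relative-distortion stopping tolerance of 1e−4, and
repairs empty clusters by respawning them on the worst-fit point of the
highest-distortion cluster so the inventory sizes are always exact. The
iterations are implemented in-package because the training contract
requires the per-iteration distortion trace (asserted non-increasing in
the tests), the relative-tolerance stop, and the specific repair rule;
a test cross-checks the final distortion against `stats::kmeans` on the
same data. Training material is the background utterances of the
experiment's speaker — the only pre-test acoustic experience the model
owns.

## Histograms of acoustic co-occurrences

A label stream of any length becomes a fixed-dimension count vector: for
each label class and each lag (20 ms → 2 frames, 50 ms → 5 frames), the
ordered pairs `(label_t, label_{t+L})` are counted into a `K × K` block.
Ordered (not symmetrized) pairs preserve temporal direction. Total
dimension is `2 × (150² + 150² + 100²) = 110,000`; vectors are stored
sparse (`Matrix::sparseVector`) since a ~3 s sentence fills at most a few
thousand cells. Counts are raw integers — no per-utterance length
normalization is applied by default, since the KL matching operates
naturally on counts; the dictionary-side normalization below makes the
resulting weights length-comparable, which is where comparability
actually matters.

## Episodic memory and KL-NMF matching

The memory is a list of tagged HAC vectors: 100 background utterances
(configurable 50–1000; exploratory runs showed the exact number shifts
absolute weights but hardly the familiar-vs-novel contrast), one noise
entry, and — after `familiarize()` — 5 tokens for each of 2 familiarized
words, 111 entries in all. Familiarization is full-attention and
error-free by assumption: tokens are stored verbatim. The noise entry is
an ordinary column: it participates in the decomposition and in the
weight normalization.

Matching solves `min_h D(v ‖ W h)` with `h ≥ 0`, `W` fixed, `D` the
generalized Kullback–Leibler divergence, using the standard
multiplicative updates. Three details the matching specification leaves
open are fixed as package defaults, all config-exposed:

* **Initialization** is uniform `h = 1/M` — deterministic, so repeated
  decompositions are bit-identical; randomized restarts are unnecessary
  because the objective is convex in `h` for a fixed dictionary.
* **Stopping** at a relative divergence decrease below 1e−6, capped at
  500 iterations; divisions are floored at 1e−12.
* **Dictionary columns are normalized to unit sum** before decomposition
  (`normalize_columns = TRUE`), so a weight measures "how much of this
  entry's *shape*" rather than being confounded with utterance length.

The tests pin the update rule to an independent brute-force grid search
of the weight space on tiny problems (divergence agreement within 1e−3),
and assert monotone divergence traces, non-negativity, exact-member
recovery and disjoint-support mixture recovery.

## Familiarity scores

Two definitions of recognition are computed from the same weights, both
as percentages of the total weight mass over all 111 entries: *single
episode activation* (the maximum familiarization weight — tokens as
unrelated episodes) and *cluster activation* (the summed familiarization
weights — tokens as one clustered experience). Cluster ≥ single always,
and both are invariant to rescaling of the weight vector. Scores exist
only at sentence ends: the model is sentence-based, not continuous-time.

## Behavior generation and the experimenter model

Scores (as proportions, `pct/100`) become pulses at the cumulative
sentence-end times. A trial starts with an onset pulse of amplitude
θ + ρ; ρ = 0.4 throughout, a value previously found representative and
cognitively uninteresting to vary. Attention decays exponentially at
rate α (per second) — the attention span knob; listening time is the
accumulated time attention ≥ θ, and a below-θ interval longer than 2 s
aborts the trial (the standard HPP abort rule). Choices worth spelling
out:

* **Superpose vs. reset.** The printed formula `Σ aᵢ δ(tᵢ) e^(−αt)` reads
  as an impulse train convolved with an exponential (pulses *add* to the
  decayed attention); the prose "attention is renewed" admits a
  *replacement* reading. Both are implemented (`mode = "superpose"` is
  the default, `"reset"` is first-class and tested); conclusions should
  be checked under both.
* **Amplitude scale.** Score units feeding the pulses are not pinned down
  by the source description; proportions put typical pulses at order
  0.01–0.3, commensurate with the θ grid 0.1–1.5 and with an onset level
  of 0.8 at θ = 0.4.
* **Evaluation.** Between pulses, attention is a single decaying
  exponential in either mode, so threshold crossings are solved in
  closed form per segment; a 1 ms-grid evaluator in the test suite
  serves as the independent oracle. Attention exactly equal to θ counts
  as listening (a measure-zero convention the grid oracle needs fixed).
* **Pulses during a below-θ interval take effect** and can rescue the
  trial if the 2 s have not elapsed — in a real booth the audio keeps
  playing while the head is briefly turned away.
* Listening time is non-increasing in θ and (in superpose mode) in α;
  θ → 0 yields the full passage duration and θ > 1.5 effectively zero —
  all asserted in the tests.

## Experiments, statistics and the parameter sweep

The standard design: 4 words in two familiarization pairs; all 24
sentences per word (96 per speaker) are scored twice, once under each
pair, so every sentence serves once as familiar and once as novel;
sentence scores are compared with a Mann–Whitney U test (robust to the
skewed, outlier-prone score distributions). For listening times, 30
six-sentence passages per word are sampled with replacement and each
passage is reused in both conditions — two sets of 120 passages whose
durations are identical by construction, removing length bias. Cells of
the {α ∈ 0.01–0.30 step 0.01, θ ∈ 0.10–1.50 step 0.01} grid are compared
with a Welch t-test (the safer default given unequal variances; the
pooled variant is a flag since the original flavor is unstated) at
p < 0.05 with **no multiple-comparison correction** — deliberate:
contiguous significance trajectories in the plane, not isolated cells,
are the object of interest. `plot()` on a grid draws the Hinton-style
summary.

## The synthetic stimulus generator

The generator replaces an unavailable corpus, emulating its design:
4 target words × 5 isolated tokens, 24 carrier sentences per word drawn
to 2.7–3.0 s with exactly one embedded target each, 100 background
utterances sharing a filler inventory across speakers (sentences in the
original material were identical across speakers), and one low-level
noise recording. Words are sequences of pseudo-syllable segments
(harmonic excitation shaped by two resonances plus filtered noise,
raised-cosine edges, 16 kHz); no intelligible speech is attempted because
the model only ever consumes spectral envelopes. A speaker is a rate
factor (0.5–2.0; rate is the speaker difference the lag-based HAC
encoding is most sensitive to), a spectral-envelope warp, and a seed;
token durations jitter by ±10%. Everything is a pure function of its
arguments and seeds — same seed, bit-identical output.

The *symbolic mode* (`generate_symbolic_stream()`) bypasses audio and
emits prototype-label streams directly, with a word as a deterministic
contiguous label pattern and speaker effects as label noise and
rate-scaled pattern length. It exists so the memory/matching/behavior
stages can be tested quickly and exactly; it is *not* a claim about
acoustics.

What the generator does not emulate — and hence what passing tests do
not show about real data: coarticulation between a word and its carrier
sentence, prosody and pitch contours, natural token-to-token pronunciation
variability beyond duration jitter and envelope warp, recording-channel
differences, and the acoustic similarity structure of a real lexicon.
Recovery results on synthetic stimuli demonstrate that the pipeline's
machinery is sound, not that real infant-directed speech would yield the
same grids.

## Problem sizes in the shipped tests

The test suite exercises reduced configurations chosen to keep the full
suite comfortably interactive while leaving every mechanism intact:
symbolic mode with label inventories of 10–12/10–12/8, 4–8 sentences per
word, 10–30 background utterances, 10 passages per word and coarse
α/θ grids; the end-to-end recovery check runs 20 master seeds and
requires the familiar-vs-novel sentence test at p < 0.05 plus a
familiarity-signed grid region in at least 95% of them. Full-scale runs
(150/150/100 codebooks, 24 sentences, 100 background, 4,230 grid cells)
use exactly the same code paths.

## Known limitations

* The prototype-training corpus of the original system is unknown;
  training on the speaker's background utterances is a reasoned stand-in
  and a possible source of divergence from the original behavior.
* Sentence-level scoring means attention can only be renewed at sentence
  ends; a continuous-time recognition variant would need word-like
  memory units, which the model intentionally avoids.
* α is constant within an experiment — attention span is modeled as a
  stable individual trait, which is certainly a simplification.
* The familiarization phase itself is not modeled (perfect storage);
  familiarization-by-passages designs are out of scope.
* HAC per-utterance normalization and the exact score→amplitude units
  are design decisions (defaults: off; proportions), both exposed as
  arguments rather than hidden constants.
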