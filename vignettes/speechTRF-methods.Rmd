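---
title: "Methods: encoding models, boundary decoding and the ambiguity index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encoding models, boundary decoding and the ambiguity index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

When people listen to continuous speech, non-primary auditory cortex (the
superior temporal gyrus in particular) tracks not only the acoustics but
also structure that exists only for listeners who know the language: where
words begin, how frequent and how long they are, and how predictable each
phoneme is given the word so far. `speechTRF` implements the full analysis
chain used to quantify these language-experience effects in intracranial
(ECoG) recordings — high-gamma preprocessing, temporal receptive field
(TRF) encoding models, nested unique-variance partitioning, word-boundary
decoding from acoustics and from neural activity, and an acoustic
ambiguity index (AAI) — together with a synthetic bilingual listening-study
generator that stands in for restricted patient data.

## High-gamma preprocessing

`extract_hfa()` computes the analytic amplitude of the 70–150 Hz
high-gamma range with eight Gaussian band-pass filters with log-spaced
centre frequencies. Filtering and the Hilbert transform are fused in the
frequency domain: the FFT is multiplied by the Gaussian response on
non-negative frequencies (doubled on strictly positive bins, zeroed on
negative bins), and the magnitude of the inverse transform is the band's
analytic amplitude. The eight band amplitudes are reduced per electrode to
their first principal component — the PC sign is arbitrary, so it is fixed
to correlate positively with the mean band amplitude — then downsampled to
100 Hz by block averaging and z-scored per recording block.

Two choices here are under-determined by convention and fixed as package
decisions:

* **Filter bandwidths.** We use `sigma_f = cf / 6`, i.e. bandwidth growing
  in proportion to centre frequency (constant-Q-like), which matches the
  Hilbert filter-bank literature this style of preprocessing comes from.
* **Baseline summary.** `select_speech_responsive()` compares each
  stimulus-aligned timepoint against the *per-sentence mean* of the 0.5 s
  silent baseline (one value per sentence), a two-group one-way ANOVA
  F-test per timepoint, Bonferroni-corrected over all tested timepoints in
  both the onset- and offset-aligned 0.5 s windows (100 tests at the
  defaults). An electrode is speech-responsive when at least 0.1 s (10
  frames) of contiguous significant timepoints appears in either window.

Time is kept in seconds internally; frame indices follow
`frame = floor(t * 100) + 1`, and windows are half-open `[start, end)`.

## The encoding model

The feature TRF model predicts each electrode's HFA as a lagged linear
combination of speech features:

HFA(t) = x0 + Σ_f Σ_l β(l, f) · X(f, t − l),

with 60 lags covering 0–0.6 s at 100 Hz. The full predictor set is
sentence onset, peakRate (local maxima of the positive envelope
derivative, magnitude-scaled), six consonant articulatory classes (dorsal,
coronal, labial, nasal, plosive, fricative), four vowel formants (F1–F4,
Hz at vowel onsets), word onset, log10 word frequency, word length in
phonemes, and within-word phoneme surprisal. Surprisal is defined from the
second phoneme of a word onward, so word-onset and surprisal features are
dissociated in time; word onsets are unit-height impulses (weighted
impulses would confound onset timing with the scaling of the other word
features).

Continuous features (formants, peakRate magnitude, frequency, length,
surprisal) are z-scored *at their event frames* using training-set
statistics; binary impulses stay 0/1. Scaling event values rather than
whole columns keeps the sparse impulse structure intact while absorbing
units (Hz vs bits vs log-counts).

`fit_trf()` solves the ridge problem per electrode with the penalty chosen
by inner cross-validation over 10 log-spaced values in `[1e-2, 1e6]`
(tests and examples sometimes pass a smaller grid; noiseless recovery
checks extend it downward). Folds are assigned at *sentence* granularity —
never by frame — because adjacent frames are strongly dependent and
frame-level folds would leak. All electrodes share the design matrix, so
the per-fold cross-products are computed once and solved for every
electrode and penalty jointly through one eigendecomposition; this is what
makes 300-permutation nulls affordable. Held-out performance is the
squared Pearson correlation between the concatenated predictions and the
repeat-averaged responses of the held-out sentences, clipped to 0 for
negative correlations (anticorrelated predictions should not pass R²
gates). All available repeats are averaged.

Weight profiles for cross-condition comparison take, per feature, the mean
β over the 5-sample window centred on the lag with the maximum
feature-averaged |β| (earliest lag wins ties); profiles from two
conditions are Pearson-correlated, with a shuffle null (10 shuffles per
electrode, identity permutation not excluded) summarized by its 95th
percentile.

## Unique variance

`family_schemes()` is the single source of truth for the nine nested
model pairs: the four acoustic families (sentence onset, peakRate,
consonants, formants) compare the full model against the full model minus
the family; word onset compares acoustic+word-onset against acoustic;
word frequency and word length each add their feature on top of
acoustic+word-onset; surprisal adds surprisal to acoustic; and the
combined word family compares full against acoustic. ΔR² may legitimately
be negative out of sample.

Significance uses circular temporal shifts of the family's feature
streams: per permutation, each sentence block (including its padding) is
rotated by a uniform offset at least 0.5 s away from the identity, the
full-side model is refit at the electrode's selected penalty, and ΔR² is
recomputed; `p = max(1, #{perm ≥ observed}) / 300`. Shifts are applied
*before* lag expansion (they move event times — the stronger null) and
*per sentence block* rather than across the concatenated recording, so
sentence boundaries are preserved. The reduced model never contains the
family, so its R² is constant under the null and is computed once. The
ridge penalty is not re-selected inside permutations: the observed fit's
per-electrode penalty is reused, consistent with sharing folds and grids
between the models being differenced, so that ΔR² reflects features
rather than fold or penalty luck.

The two printed gates — model R² > 0.05 with ΔR² > 0.001 for
unique-variance summaries, and R² > 0.1 for weight-profile analyses — are
applied as strict inequalities by `significance_gates()`, and all protocol
constants live in `trf_constants()`.

## Boundary decoding

Boundary events are syllable onsets, labelled *word* when they coincide
with a word onset. Word events of single-syllable words and all events of
sentence-initial words are flagged excluded (flagged, not dropped, so the
attrition is auditable). The acoustic decoder vectorizes the 0.2 s,
80-band mel-spectrogram window centred on the event (`[e-10, e+10)`
frames); the neural decoder vectorizes electrodes × the
`[-0.2 s, +0.4 s)` window (`[e-20, e+40)`). Both reduce by PCA to the
smallest number of components cumulatively explaining more than 90% of
variance — PCA and centering are fit on the training folds only — and
classify with L1-regularized logistic regression, the penalty chosen on an
inner 80/20 split over an 8-value path. Cross-validation is 20-fold and
stratified; every retained event receives exactly one held-out posterior
score. AUC is computed per fold by the rank (Mann–Whitney) formula.

Label-permutation nulls keep the fold assignment and per-fold PCA fixed
across shuffles: labels enter only the logistic stage, so permuting them
cannot change the unsupervised steps, and sharing those steps makes a
25 × 20 null run in minutes. The sliding-window variant tiles the 0.6 s
epoch with non-overlapping 0.02 s windows (step size equal to width; the
convention is a package decision) and reuses the same trials, electrodes
and folds throughout.

## The acoustic ambiguity index

`compute_aai()` scores each event as |correct label − held-out posterior|
from the *acoustic* decoder: near 0 when acoustics clearly support the
boundary type, near 1 when they point the other way. Events are split
into equal-count tertiles (ties broken by event id, so binning is
deterministic); equal-count rather than equal-width bins keep per-bin AUCs
estimable. `bin_auc_contrast()` then resamples each bin 15 times per
condition (80% of the bin's events, stratified by label, without
replacement — with/without replacement is not dictated by convention, and
the choice is recorded in the output), computes the AUC of the native and
foreign *neural* decoders' held-out scores on each resample, and forms all
15 × 15 = 225 pairwise native−foreign differences per bin; a one-way
ANOVA across the three bins (675 values, df = 2, 672) tests whether the
native advantage depends on ambiguity. Because AAI is computed from
acoustics alone, the binning cannot leak neural labels into the contrast.

## The synthetic bilingual study

The generator emulates the statistical structure the analysis assumes,
not phonetically realistic speech:

* **Languages.** Two toy languages share one phoneme inventory (14
  consonants carrying the six class features — including the liquids/glides
  *l*, *w*, which carry place but none of the nasal/plosive/fricative
  manners, so the class columns are linearly independent of a bare
  consonant indicator and TRF weights are identifiable — plus 5 vowels
  with canonical formants) but draw disjoint lexicons of 48 words built
  from language-specific syllable pools, so word prefixes are shared and
  surprisal is non-degenerate. Token counts follow a Zipf law (exponent 1,
  floored at one token so surprisal stays finite).
* **Sentences.** 5–9 words drawn proportional to counts; phone durations
  are log-normal with median 0.08 s and log-sd 0.3 (a natural-speech
  scale; no published value constrains it).
* **Acoustics.** The envelope is a chain of per-syllable rise–fall pulses
  whose local minimum falls exactly on the syllable onset; the depth of
  that pre-boundary dip is the controlled acoustic cue — deep
  (Normal(0.12, 0.05)) before word onsets, shallow (Normal(0.50, 0.08))
  within words. A configurable fraction of word boundaries has its dip
  resampled from the within-word distribution: these are the acoustically
  ambiguous boundaries. The mel-spectrogram is the envelope times a noisy
  phone-class template. The template contrast (0.08 over a 0.5 broadband
  floor, log-normal noise sd 0.8) is deliberately weak: phonotactics are
  position-dependent by construction (that is what makes surprisal
  meaningful), so strongly phone-informative spectra would let a
  classifier segment words from content alone, and fully ambiguous
  boundaries (`ambiguity_fraction = 1`) must be unclassifiable
  (AUC ≈ 0.5). The chosen contrast keeps the envelope dip as the dominant
  boundary cue while class structure remains present in the spectra.
* **Neural responses.** Ground-truth TRFs are smooth gamma-shaped lag
  kernels (random amplitude and peak latency, 0.08–0.25 s) convolved with
  the same feature streams the analysis uses, plus Gaussian noise and a
  0.5 s silent baseline per sentence. The native/foreign contract is
  exact: the foreign condition zeroes the word-level weight block and
  changes nothing else. At least two participants per condition are
  simulated so the mixed models have grouping structure; a per-participant
  proficiency scalar can scale the word block to emulate graded language
  knowledge.
* **Broadband fixture.** For testing the preprocessing,
  `simulate_raw_broadband()` amplitude-modulates sinusoidal carriers
  inside 70–150 Hz. By default two carriers are used, spaced so far apart
  that each Gaussian band is dominated by one carrier; with many carriers
  the overlapping bands share carriers and beat ripple contaminates every
  band coherently, which is realistic but makes the fixture's closed-form
  AM identity only approximate.

What passing tests on this generator show — and what they do not: the
pipeline recovers planted effects of the kind the analysis targets
(word-level unique variance, boundary decodability, ambiguity-dependent
native advantages) at desk scale, with calibrated nulls. The generator
contains no coarticulation, prosody, semantics, pitch, or anatomical
structure, so the tests say nothing about those aspects of real
recordings.

## Statistical models

Condition effects on unique variance use the mixed model
`delta_r2 ~ condition + speech stimulus language + (1|hemisphere) +
(1|participant) + (1|electrode:participant)` per feature family (foreign
is the reference level, so positive coefficients mean native > foreign).
Random terms whose grouping factor has one level are dropped with a
warning and the formula actually fitted is stored with the estimates. The
proficiency analysis fits `AUC ~ proficiency + (1|number of electrodes)`;
grouping by a numeric electrode count is unusual, but the formula is
honoured literally (each distinct count becomes a group).

## Problem sizes and runtimes

The reference checks run at desk scale, chosen so the full suite completes
in minutes on one core: 20–40 training sentences and 6–8 repeat-averaged
test sentences per TRF scenario; 300 circular-shift permutations over 10
electrodes; ~1,900 balanced boundary events for the decoder chance-level
null (25 shuffles × 20 folds); 150-sentence, 2 × 8-electrode studies for
the ambiguity-stratified contrast; 1,000 simulated null electrodes for the
responsiveness false-positive check. Sampling noise at these sizes is well
inside the stated tolerances of each check.

## Known limitations

* The synthetic acoustics carry no pitch; pitch and envelope control
  families from the same ΔR² machinery are exercised through the
  formant/peakRate families instead.
* Out-of-lexicon words are flagged (onset emitted, frequency/length
  missing) rather than silently dropped; analyses on real corpora should
  audit the flags.
* With few features, the profile shuffle null can draw the identity
  permutation; this is documented behaviour, not a bug.
* The ridge penalty grid is shared across electrodes; electrodes whose
  optimum lies outside `[1e-2, 1e6]` would saturate at the grid edge.
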