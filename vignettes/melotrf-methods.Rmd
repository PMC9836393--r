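---
title: "Models and methods behind melotrf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind melotrf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melotrf)
```

melotrf implements a complete analysis chain for studying melodic
expectation: probabilistic next-note models, note-level information
measures, and time-resolved deconvolution regression of multichannel
neural time series, with cluster-based inference on the estimated
response functions. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic-data validation
does and does not establish.

## Expectation models

All models emit a probability distribution over the 128-pitch MIDI
alphabet for the next note given a context of at most *k* preceding
notes. The first note of every composition is scored against a uniform
prior (1/128 per pitch), so its surprise and uncertainty both equal
ln 128 ≈ 4.85 nats. Contexts never cross composition boundaries. All
logarithms are natural.

### Bayesian Gestalt model

`temperley_predict()` combines three musicological principles as
probability distributions, multiplied and normalised:

1. *Central pitch tendency.* Pitches cluster around a latent central
   pitch c with x ~ N(c, v_r) and c ~ N(c0, var_c0). We marginalise c
   exactly over the discrete grid 0–127 rather than using a point
   estimate; at 128 x 24 grid points this is cheap and removes an
   approximation that would otherwise be implicit.
2. *Pitch proximity.* x_t ~ N(x_{t-1}, v_x); omitted for the first note.
3. *Key membership.* A pitch-class profile conditioned on one of 24 keys
   (12 major, prior p_maj/12 each; 12 minor, prior (1-p_maj)/12 each).
   Profiles are stored relative to the tonic, so one profile per mode
   suffices; the octave spread of key preferences is absorbed by the
   range term and the final normalisation.

The posterior over (c, key) is updated from every context note. An open
design point was whether the central-pitch belief should stay fixed per
melody or update with evidence; we update it, which makes the model
coherent as a Bayesian filter and matches how the range principle is
stated (a *latent* centre inferred from the notes).

Default parameter values (`temperley_params()`: c0 = 72, var_c0 = 34.4,
v_r = 83.2, v_x = 18.2, p_maj = 0.81) are corpus moments of a large
monophonic corpus of Western classical music, all in semitone units
(variances in semitones squared). `fit_temperley_params()` re-estimates
them from any corpus: c0/var_c0 as mean and population variance of the
compositions' mean pitches, v_r as the variance of first notes around
their melody mean, v_x from note pairs whose previous pitch equals the
melody's rounded mean (falling back to all pairs when no such notes
exist — a choice we made because the conditioning set can be empty in
short melodies). The default key profiles are *synthetic* flat
scale-membership templates (uniform over the seven scale degrees, small
residual mass elsewhere); corpus-estimated profiles are preferred
whenever key labels are available.

### Variable-order n-gram models

`ngram_train()` counts all m-grams (1 ≤ m ≤ k+1) of a corpus;
`ngram_predict()` turns counts into a distribution by interpolated
back-off. At each order the maximum-likelihood estimate
count(context, x)/N is blended with the next-lower order using escape
mass d/(N + d), where N is the context's continuation total and d its
number of distinct continuations — an escape rule in the style of
prediction by partial matching (method C). The recursion bottoms out at
uniform 1/128. The literature leaves the exact smoothing method open;
ours is documented and isolated so an alternative rule can be swapped in.
The unsmoothed relative-frequency ratio is exposed via
`ngram_raw_ratio()` for diagnostics.

The *short-term* variant (`stm_step()`) starts empty at each composition
and learns online; predictions for note t use counts from notes 1..t-1
only, which the test suite verifies by mutating future notes. The
*long-term* variant is trained once on a corpus. `combine_both()` merges
the two with entropy-derived weights, w ∝ (H/ln 128)^(-bias): the more
confident model dominates. We use a geometric (log-linear) mixture by
default — the natural choice for multiplicative combination of experts —
with an arithmetic mixture available; the mixing form is another point
the literature leaves unspecified.

Every final distribution is floored by mixing with uniform at weight
1e-6 and renormalising, so surprise is finite (capped near
ln(128/1e-6) ≈ 18.7 nats) even when finite-count models would assign an
exact zero.

Argmax accuracy breaks ties toward the lowest pitch; this only matters
for degenerate (e.g. uniform) predictions.

## Note features and impulse regressors

`build_feature_table()` produces the acoustic/adaptation baseline set:
onset flag, very-high/very-low pitch flags (strictly above the 90% /
below the 10% pooled pitch quantile, so ties are excluded), composition
onset, note repetition (pitch equal to the immediately preceding pitch),
optional sound-type flags, and three continuous acoustic measures
computed over each note span: RMS amplitude, spectral flatness (geometric
over arithmetic mean of the note window's magnitude spectrum — the
standard timbre measure; time-domain flatness is ill-defined for
zero-mean audio), and the variance of the broad-band envelope (64-band
log-spaced gammatone filterbank, 50–8000 Hz, magnitude of the analytic
signal averaged across bands). When no audio exists, acoustic columns can
be supplied from the synthetic generator's ground truth so the baseline
model remains exercisable.

`to_impulse_regressors()` places one value per note at
round(onset x srate) with half-up rounding (the rounding rule matters at
coarse rates and is therefore fixed and documented). Continuous columns
are z-scored over the note entries before placement — a stimulus-side
statistic computed once, before any train/test split; binary columns are
placed as-is. Two notes falling into one sample raise an error rather
than silently summing.

## TRF estimation and model comparison

`time_expand()` builds the lagged design matrix (column blocks ordered by
regressor, then lag; t_min = −0.2 s, t_max = 1 s by convention, giving 73
columns per regressor at 60 Hz). `fit_ols()` solves the least-squares
problem per channel via QR — never by explicitly inverting MᵀM — with an
always-included, never-penalised intercept, and refuses rank-deficient
designs naming the collinear columns (a pseudo-inverse mode exists and is
flagged in the output). `fit_ridge()` solves the penalised problem on the
centred design via SVD; alpha comes from nested cross-validation and the
candidate set must include 0 so the unpenalised solution competes.

`cv_predictive_r()` uses five *contiguous* time blocks as folds.
Interleaved samples would leak information through the 1.2 s lag window,
so block folding is the only defensible geometry; training rows whose lag
window straddles a fold boundary are dropped. Channel data are z-scored
with training-fold statistics only. The model is fit on the full lag
span; scoring restricts the held-out correlation to samples 0–0.6 s
after a note onset, where note-locked responses live. (The alternative
reading — restricting the *design* to 0–0.6 s during fitting — would
leave pre-onset and late activity unmodelled and bias the overlap
correction, so we fit the full window and restrict only the score.) The
per-fold correlation is computed on the concatenated test samples of the
fold. The summary statistic is the median across folds per channel, then
the mean across channels — optionally only the channels selected by
`select_channels()` (strictly above the 2/3 quantile of onset-model
performance; a complete tie selects nothing, in which case all channels
are kept with a warning).

`compare_models()` runs paired (or one-sample) t-tests on
per-participant summary r with Bonferroni–Holm correction and Cohen's d
from the paired differences; a zero-variance difference is reported as a
degenerate contrast (t = NA), not as ±infinity.

## Cluster statistics

`hat_t()` computes mass-univariate one-sample t values with the hat
variance adjustment t = m / sqrt((v + sigma * max(v))/n); the offset
scales with the *maximum* variance across the tested map (sigma = 1e-3 by
default), which keeps t finite where the sample variance is near zero.
`cluster_permutation()` forms clusters of suprathreshold cells over
channel adjacency x temporal contiguity (primary threshold: two-sided
alpha = 0.05 on the hat-t map — the forming threshold is configurable
since conventions differ) and compares observed cluster masses against a
sign-flip permutation null of the maximum absolute mass. P-values use the
(1 + exceedances)/(1 + permutations) correction and can never be zero.
`tfce()` integrates extent^E x height^H (E = 0.5, H = 2, ≥ 50 levels —
standard neuroimaging defaults, as they are not otherwise dictated) and
tests each sample against the null of the map maximum. For synthetic
arrays, `ring_adjacency()` supplies the channel neighbourhood; real
sensor layouts are out of scope.

## The synthetic-data module

`generate_melody()` samples a key-constrained Markov process: candidate
pitches are weighted by scale membership (out-of-key weight 0.05), a
Gaussian range constraint (centre 72, SD 8 semitones — matching the
central-pitch statistics of classical corpora), and a Gaussian proximity
bias around the previous pitch (`interval_scale`, default 2.5 semitones,
consistent with the small-interval bias of real melodies). With
`markov_order = 2` the proximity centre adds a melodic-inertia term
x_{t-1} + inertia (x_{t-1} − x_{t-2}), making the process genuinely
second order — that is what the context-length identifiability checks
exploit. Motifs of 3–6 notes are occasionally reinserted verbatim
(default probability 0.1 per step), mimicking the short motif structure
of real music. Default tempo is 4 notes/s, near the note rates of
classical monophonic repertoire.

`simulate_neural()` builds each channel as the sum over regressors of an
impulse train convolved with that regressor's ground-truth kernel, plus
white or 1/f ("pink", M/EEG-like) noise. The default kernels
(`default_truth_kernel()`) are difference-of-Gamma shapes with positive
peaks near 0.075 s and 0.2 s and a sustained negativity over 0.3–0.6 s,
the canonical auditory evoked-response morphology, with smoothly varying
signed gains across channels. The forward model is exactly linear in the
feature values, so OLS on the time-expanded design must recover the
kernels to numerical precision at zero noise — the strongest single test
of the whole deconvolution chain.

What the generator does *not* emulate: realistic sensor topographies and
field spread, non-stationary artifacts, correlated noise across channels,
performance timing variability, or polyphony. Passing tests on synthetic
data therefore validate the estimators and their calibration, not claims
about real neural recordings.

## Validation scale and calibration

The validation suite (and `scripts/acceptance.R`) uses problem sizes
chosen to be realistic yet desk-friendly: kernel-recovery runs use 1500
notes (~8 minutes of recording at 50 Hz, comparable to a few compositions
of a listening study) at amplitude SNR 0.5; calibration uses 200 null
simulations of each inference path (cluster permutation with 100 sign
flips on 10 x 6 x 15 maps; model comparison with 8 simulated listeners).
The false-positive criterion for the model comparison is directional —
claiming that a useless surprise regressor *improves* cross-validated r —
because adding an irrelevant regressor genuinely (and correctly) lowers
predictive r, which a two-sided count would misread as miscalibration.
The context-length check generates data from a known order-2 process
(eight listeners over an eight-composition corpus, with the long-term
model trained on 80 generated pieces) and
verifies that incremental neural prediction peaks at k = 2 while music
accuracy rises from k = 1 to 2: the dissociation logic between
predicting music and predicting neural data, reproduced under ground
truth.

## Known limitations

- The Gestalt model's exact-enumeration posterior is O(contexts x 24 x
  128²) per note; for very long corpora and large k it is the slowest
  predictor. The n-gram models are effectively linear in corpus size.
- `read_midi()` supports standard format 0/1 files with note events and
  tempo maps; controller data are ignored and SMPTE division is not
  supported.
- Ridge and OLS share one code path (SVD on the centred design); for
  designs with many thousands of columns a dedicated sparse solver would
  be preferable.
- The stm/ltm combination reports its entropy weights, which by
  construction sum to 1 across the two experts; other conventions exist
  and published weight pairs need not be comparable across
  implementations.
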