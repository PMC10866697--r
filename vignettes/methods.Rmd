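---
title: "Encoding and decoding articulatory features from single-neuron activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding and decoding articulatory features from single-neuron activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phonopop analyses single-unit spiking recorded while a person produces
natural speech. Its question is how the *sublexical* structure of an
upcoming word — which phonemes it contains, how they are arranged into
syllables, whether it carries a bound morpheme — is represented by
individual neurons and by the population during the ~500 ms of planning
before the word is uttered and the ~500 ms of articulation after. This
vignette explains the models the package implements, the knobs that
matter, what the synthetic-data generator does and does not emulate, and
the numerical choices made where reasonable people could have chosen
differently.

```{r setup}
library(phonopop)
```

## Word feature spaces

Words are represented compositionally rather than lexically. Each word's
phoneme sequence (ARPAbet symbols, shipped as an auditable
symbol-to-group table in `extdata/arpabet_groups.tsv`) is mapped into
articulatory group spaces:

* **Places of articulation** (the primary space, 10-dimensional): eight
  consonant constriction sites ordered front to back — bilabial,
  labiodental, dental, alveolar, postalveolar, palatal, velar, glottal —
  followed by the two vowel tongue-height classes, high and mid-low.
  The entry for a group counts how many of the word's phonemes fall in
  it. The order is fixed so vectors are comparable across sessions:
  'like' (L-AY-K, an alveolar–mid-low–velar sequence) is
  `[0 0 0 1 0 0 1 0 0 1]`.
* **Manners of articulation** (6 consonant classes: stop, fricative,
  affricate, nasal, liquid, glide). Whether vowels should join this
  space is genuinely open; `feature_space(manner_vowels = TRUE)` appends
  the two height columns, and the default leaves them out.
* **Primary cardinal vowels** (8 classes). ARPAbet vowels are assigned
  to the nearest cardinal class in the bundled table; diphthongs are
  classed by their nucleus.
* **Syllable templates**: a syllable's template is its ordered sequence
  of place groups. The inventory keeps the ten most frequent templates
  of the lexicon at hand (ties at the cut broken lexicographically so
  the inventory is reproducible), and each word gets a binary indicator
  per template. The template space is deliberately data-driven rather
  than hard-coded: a different vocabulary yields a different top ten.
* **Morphology**: two indicators (bound prefix, bound suffix) plus the
  phoneme count, which morphology models always carry as a word-length
  covariate so a morpheme effect is not a length effect in disguise.

Counts versus indicators is intentional: the phoneme space counts
repeated groups ('kick' has velar = 2), while the syllable space only
records presence.

## Per-neuron encoding models

For each neuron the spike count in a half-open analysis window — planning
`[-500, 0)` ms and production `[0, 500)` ms around word onset — is
modelled as Poisson with a log link:

$$y_w \sim \mathrm{Poisson}\!\left(\exp(\beta_0 + \beta^\top x_w)\right),$$

where $x_w$ is the word's embedding in one feature family. Words whose
planning window overlaps the previous word's articulation are excluded
(the preceding word would otherwise leak into the window), and units with
session-mean rates below 0.1 Hz are dropped; both filters are logged row
by row. Model comparison uses:

* **AIC** $= 2k - 2\ln L$;
* **D²** $= 1 - K(y, \mu_{\text{full}}) / K(y, \mu_{\text{restricted}})$
  with $K(y,\mu) = 2\,\mathrm{llf}(y;y) - 2\,\mathrm{llf}(\mu;y)$ the
  deviance — the fraction of uncertainty removed by the regressors of
  interest, in $[0,1]$ for nested maximum-likelihood fits;
* a **likelihood-ratio test** of the family's regressors at
  $\alpha = 0.01$ (the tuned/untuned call), and per-dimension two-sided
  **Wald tests**, Bonferroni-corrected across the family's categories.

The restricted model is intercept-only, except for morphology where it is
intercept plus `n_phonemes`. The full/restricted pair is the package's
definition of "the regressors of interest"; nuisance covariates can be
added through the design matrix if a dataset needs them.

A tuned neuron's **preferred composition** is the sign vector of its
family coefficients: +1 features are expected in the maximal-response
word, −1 features are expected absent, 0 (an exactly zero coefficient,
rare in practice) is unconstrained. For tuning curves each word is
encoded as signed presence (+1 contained, −1 absent) and compared to the
sign vector by Hamming distance — the number of disagreeing positions —
so that distance 0 is exactly the composition that maximizes the fitted
rate. Rates are z-scored per neuron across its included words (within
condition), binned by distance, and the monotone fall-off is summarized
by Spearman's rank correlation across words. A genuinely compositional
neuron produces a steep negative correlation; the package's tests plant
such neurons by letting the rate decay a half log-unit per position of
distance, which at a baseline of a few spikes per window yields
correlations beyond −0.8 at the single-word level. Note that per-word
correlations are noise-limited: even a noiseless neuron whose rate is
linear in feature *counts* (not presence) will not reach −1 against a
presence-based distance.

Three neuron-level population statistics round out the module: a
two-sided hypergeometric test for the overlap of two tuned
subpopulations (twice the smaller tail, capped at 1 — the convention
choice is ours), a chi-squared homogeneity test of tuned proportions
across anatomical bins (depth or rostro-caudal position, df = bins − 1),
and the preferred-syllable control comparison, which contrasts each
neuron's mean z-scored rate for words containing its preferred syllable
against words that merely contain its phonemes, contain them in a
different order, contain them across a syllable boundary, or share
nothing — with paired two-sided Wilcoxon signed-rank tests across
neurons. The five control categories are mutually exclusive and are
assigned in a fixed priority order (contains > different order >
different segmentation > shared phonemes > disjoint).

## Population decoding

Decoding asks whether the *population* predicts a word feature before the
word is spoken. Units recorded in different participants are combined
into a pseudopopulation by trial matching: words are labelled by their
binary feature pattern, and for each pattern every participant
contributes `min(count across participants)` of its own words, chosen at
random under the run's seed and never reused — no trial and no neural
data is duplicated or upsampled. Patterns absent in any participant are
dropped and logged.

One binary support-vector classifier (radial-basis kernel) is trained
per feature dimension on random 75/25 train/test splits; 50 splits by
default. The kernel coefficient defaults to 1/(number of neurons), and
the regularization constant C is chosen by cross-validation nested in
the training set over the grid {0.01, 0.1, 1, 10, 100} (five folds,
selection by mean AUC; a single-element grid disables the search, which
the test suite uses for speed). Dimensions with fewer than 10 expected
positive training trials are skipped and logged — rare categories cannot
support a classifier. Performance is the rank-based ROC-AUC with ties
counted one half; per split, a family's score is the mean AUC over its
trained dimensions, and summaries are taken over splits (dimensions are
averaged within split first; the alternative aggregation order is not
exposed). Morphology is decoded by a single any-bound-morpheme
classifier rather than per-flag classifiers.

Chance is estimated by a label-shuffle null: trial labels are permuted —
a pseudo-trial couples one word from every participant, so permuting
pseudo-trial rows permutes within participant — and the *entire*
train/test pipeline is rerun. **Model switching** evaluates decoders
trained in one epoch or condition on data from another; when the target
shares the source's trial structure the evaluation is restricted to each
split's held-out trials, so training and testing trials stay disjoint in
every case (applying the models back to their own source reproduces the
native test AUC exactly, a useful identity check).

**Time-resolved decoding** replaces window counts with instantaneous
rates (spikes binned at 5 ms, convolved with a 25 ms-s.d. Gaussian;
kernels are built on a ±4 s.d. padded grid so no spike mass is lost to
edges) and trains decoders at each time point with split assignments
shared across time. The per-split peak time is the earliest argmax of
the AUC trace (flat traces are flagged ambiguous), and each family is
summarized by the median peak ± a bootstrapped standard error of the
median (1,000 resamples), with pairwise two-sided permutation tests on
median differences (2,000 label exchanges) and a Kruskal–Wallis test
across families.

## Subspace geometry

The dynamical-systems view averages all words into one peri-event
trajectory per neuron (5 ms bins, 50 ms kernel — deliberately wider than
the decoding kernel), standardizes each neuron's trace to zero mean and
unit variance, and stacks them into a $T \times N$ matrix per epoch
(T = 100 for a 500 ms window). PCA (via SVD, component signs fixed so
the largest loading is positive) gives an orthonormal $N \times k$ basis,
k = 5 by default per the low dimensionality of such trajectories; a
90%-variance criterion can substitute for a fixed k.

The **alignment index** of a basis $D$ against another epoch's covariance
$C_B$ is $\mathrm{Tr}(D^\top C_B D)$ divided by the sum of the top-k
eigenvalues of $C_B$, the most any k-dimensional subspace could capture
— so the index attains 1 for the target's own top-k eigenvectors.
Normalizing by the *total* variance instead is available as an option;
the two differ exactly by the variance fraction outside the top-k space.
Because two random subspaces of a high-dimensional space are typically
misaligned, observed indices are referred to a Monte-Carlo null: random
subspaces $V = \mathrm{orth}(U\sqrt{S}\,v)$ with $U, S$ the
eigenvectors/values of the pooled covariance across the epochs being
compared and $v$ white noise, recomputed 1,000 times. Note a structural
property of this null worth keeping in mind: covariance-matched draws
concentrate in the target's top eigendirections, so under the top-k
normalization the null sits near the upper end of the scale — it is the
*observed* index falling below this null that indicates genuinely
distinct subspaces. Standardization is per epoch (whether to standardize
across concatenated epochs instead is exposed through the inputs, since
either could be defended).

The **Grassmannian chordal distance**
$d(A,B) = \tfrac{1}{\sqrt 2}\lVert AA^\top - BB^\top\rVert_F$ depends
only on the subspaces (it is invariant to within-subspace rotations);
dividing by $\lVert A \rVert_F = \sqrt k$ scales it to $[0, 1]$, 0 for
identical and 1 for orthogonal subspaces.

## The synthetic-session generator

Real recordings of this kind cannot be bundled, so every stage is
validated against sessions with *planted* ground truth. The generator is
the encoding model's generative twin: word window counts are drawn from
exactly the Poisson log-linear model the selectivity stage fits, which
makes parameter recovery well-posed. Its defaults emulate the recording
conditions the package targets: 5 participants, 16–115 units each,
~850 words each; baseline log-rates Normal(log 1.5, 0.3) per 500 ms
window; 20.6% of units tuned to places of articulation, 25% to syllable
templates, 11.4% to morphology; speaking- and listening-tuned
subpopulations with 7.9% of units shared; and log-normal inter-word
gaps calibrated so 10% of planning windows overlap the preceding word
(exercising the exclusion filter).

Within a window, the drawn count is laid out in time as a mixture of a
uniform component and a Gaussian bump (s.d. 50 ms) centred at the
latency of the neuron's dominant family — morpheme −400 ms, phoneme
−200 ms, syllable −80 ms before onset — creating the temporal ordering
the time-resolved decoder must recover. Spike placement never changes
the window count, so binning is conservative by construction. Background
spiking at the baseline rate fills the time between analysis windows
(and only that time). Spectral features are drawn from
place-group-specific log-normal band profiles so acoustic regressors
correlate with phoneme identity, without synthesizing audio.

What the generator does *not* emulate matters for interpreting green
tests: there is no refractoriness, no spike-sorting contamination, no
drift, no correlated trial-to-trial (state) variability, no
autocorrelated rates beyond the planted bump, and its tuning is exactly
log-linear. Passing recovery tests therefore show the *estimators* are
correct and calibrated, not that real cortex satisfies the model.

Two planted-design choices deserve explanation. First, feature families
overlap naturally (tuned sets are sampled independently, as multi-feature
neurons are common in cortex), but the temporal-ordering validation
plants *disjoint* family tuning with fuller dimension coverage (two
active dimensions per tuned neuron) and family-specific effect sizes
(place 0.8, syllable 1.6, morpheme 1.2 log-units), all spikes in the
latency bump (share 1.0, s.d. 35 ms) and a baseline of 3 spikes per
window. The reason is interdependency, not convenience: a syllable
template logically implies its constituent place groups, so
syllable-label information is partly decodable from phoneme-tuned
neurons at the *phoneme* latency. With sparse coverage that leakage
dominates the family average and the planted ordering is unrecoverable
in principle; the disjoint, well-covered design makes the planted
latency the dominant source of each family's label information, which
is the property the validation is about. Second, the tuning-curve
validation plants a neuron whose rate decays monotonically in Hamming
distance itself (0.5 log-units per position at baseline 5), the cleanest
formalization of "compositional tuning"; a count-linear neuron tops out
near ρ ≈ −0.55 against a presence-based distance no matter how strong,
which is a property of the encoding, not an estimator defect.

## Problem sizes and numerical choices

The shipped validation suite runs everything at desk scale, chosen as the
smallest sizes at which the asymptotics the statistics rely on are
comfortably valid: GLM calibration at 500 neurons × 600 words, decoding
at 400 matched trials × 30 units with 10 splits and a 40-repetition
shuffle null, temporal decoding at 300 words × 28 units × 5 splits
sampled every 40 ms, subspace nulls at 1,000 repetitions on 40–50 unit
problems, and a two-participant end-to-end pipeline. Each synthetic
condition states its seed; every random stage derives per-stage
substreams from one master seed, and identical configuration plus seed
reproduces byte-identical artefacts (JSON floats are serialized at 17
significant digits).

Degenerate inputs are handled explicitly rather than silently: empty
pronunciations, non-partitioning syllable spans, rank-deficient designs
(the offending columns are named), non-converged fits, a restricted
model that saturates (D² undefined, flagged), one-class AUC inputs,
zero-variance PETH columns (dropped with a warning), k above the
trajectory rank, and zero covariances (flagged missing). Windows are
half-open `[a, b)` so a spike at a boundary belongs to exactly one
window; argmax ties in AUC traces resolve to the earliest time;
syllable-inventory ties resolve lexicographically.

## Limitations

The symbol table covers General American English ARPAbet; other accents
or languages need a replacement table (the format is two-column-per-class
TSV). Pronunciations and syllabifications are inputs, not predictions —
there is no grapheme-to-phoneme conversion and no stress model. The
decoder wraps a standard SVM implementation; solver-level reproducibility
across BLAS builds is not guaranteed bit-for-bit, though all pipeline
randomness is seeded. Temporal decoding assumes a common trial structure
(one participant, or trial-matched tensors); and the alignment-index null
inherits the structural concentration described above, so it should be
read as a calibration reference, not as a p-value machine.
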