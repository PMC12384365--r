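---
title: "Methods: memory-augmented feedforward sleep staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: memory-augmented feedforward sleep staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Manual sleep staging assigns one of five stages — wake (W), N1, N2, N3 and
REM — to each 30-s (AASM) or 20-s (R&K) epoch of a polysomnogram. Automatic
staging from a *single* frontopolar EEG channel (the Fp1–Fp2 bipolar
derivation, attractive for wearables because the electrodes sit on the
forehead) is hard: the frontopolar site sees slow-wave and spindle activity
weakly, and individual epochs of N1, REM and light N2 are spectrally
ambiguous. `hypnomem` implements a lightweight hybrid approach: a fixed
37-feature epoch descriptor, two small feedforward networks — one that sees
only the current epoch, one that additionally receives a first-order Markov
*transition vector* summarizing the previous epoch — and a confidence-based
fusion rule that may also refuse to classify an epoch (NC).

## Why a memory feature: hypnogram persistence

Sleep stages persist. For a stage $s$, define the indicator series
$I_t = 1$ if epoch $t$ is labeled $s$. The package estimates its biased
autocovariance

$$\gamma(\tau) = \frac{1}{n}\sum_{t=1}^{n-|\tau|}
  (I_{t+|\tau|} - \bar I)(I_t - \bar I),$$

its normalization $\rho(\tau) = \gamma(\tau)/\gamma(0)$, and the
autocorrelation time

$$t_c = \Delta t \sum_{\tau = 0}^{\tau_{\max}} \rho(\tau),$$

where $\Delta t$ is the epoch duration and $\tau_{\max}$ is the last lag
before the first non-positive $\rho$ — only positive autocorrelation
reflects persistence of the same stage; summing past the first
zero-crossing would bias $t_c$ downward. The $1/n$ (rather than
$1/(n-\tau)$) normalization is deliberate and is asserted by tests against
hand-expanded values. On sticky hypnograms the deeper stages show
autocorrelation times of several minutes — many epochs of usable context —
which motivates feeding the classifier information about the previous
epoch.

Group summaries average the *autocovariance* functions across subjects
first and then normalize by the group mean's zero-lag value (not the mean
of individually normalized curves; the two differ and the tests pin the
intended one).

## The 37 features

All features are computed per epoch on the raw signal (no filtering other
than the resampler's anti-aliasing low-pass; 256 Hz recordings are
polyphase-resampled to 125 Hz):

* **Time domain (3)** — skewness and kurtosis from population moments
  (kurtosis is the Pearson, non-excess form: Gaussian 3, sine 1.5), and
  the Higuchi fractal dimension with `kmax = 10`, a conventional choice
  for 2500–3750-sample epochs.
* **Hjorth (3)** — activity (variance), mobility, complexity. Activity is
  the only amplitude-dependent feature and is z-scored within each subject
  (population SD); this pass is unsupervised and per-subject, so it is
  applied identically to training and held-out subjects without label
  leakage. In a true real-time setting the within-night mean/SD would not
  be available causally; this is a known idealization.
* **Band-power ratios (8)** — from the one-sided DFT of the full epoch
  (no taper, no detrend), band power is the sum of squared magnitudes over
  bins in $[f_{lo}, f_{hi})$ for delta 0.5–4, theta 4–8, alpha 8–13,
  sigma 11–16, beta 13–30 Hz. The eight ratios, in fixed order:
  $\delta/\alpha$, $\delta/\beta$, $\delta/\theta$, $\theta/\alpha$,
  $\theta/\beta$, $\sigma/\delta$, $\delta/(\alpha+\beta)$,
  $(\delta+\theta)/(\alpha+\beta)$. Zero denominators are guarded by
  $\varepsilon = 10^{-12}$ with a warning instead of dropping the epoch,
  keeping the pipeline total.
* **Spectral shape (3)** — over the 0.5–30 Hz full band: Shannon entropy
  of the normalized spectrum divided by $\log(\text{bins})$ so it lies in
  $[0,1]$ (the normalization makes the value independent of epoch
  length), the power-weighted centroid, and the 95% roll-off frequency.
* **Wavelet (20)** — a 5-level Daubechies-4 decomposition (periodized;
  verified coefficient-for-coefficient against an independent wavelet
  library). At 125 Hz the detail bands are approximately D1 31–62 Hz,
  D2 16–31, D3 8–16, D4 4–8, D5 0.5–4 — the conventional beta/gamma,
  beta, alpha/sigma, theta and delta scales (textbook labels quote
  32–64 Hz etc., which assume a 128 Hz rate; the dyadic edges at 125 Hz
  are treated as approximate). Per band: relative energy (denominator =
  total *detail* energy, excluding the A5 approximation, since the five
  named bands are the analysis objects; a config switch can include A5),
  Shannon entropy of the normalized squared coefficients (natural log),
  and the Hjorth mobility and complexity of the coefficient sequence.

Every feature except Hjorth activity is amplitude-scale invariant, and the
suite asserts this numerically. The implementation is checked against
independent oracles: a literal transcription of the Higuchi algorithm, a
loop-level periodogram bin sum, sine closed forms for the Hjorth
parameters ($\text{mobility} = 2\sin(\omega/2)$ for a sampled sine of
angular frequency $\omega$ rad/sample), and frozen reference values from
an independent wavelet implementation.

## Transition matrix and transition vector

From training hypnograms, the first-order transition matrix is the
row-normalized transition count
$T_{ij} = \mathrm{Count}(S_{t-1}=c_i, S_t=c_j) / \sum_j \mathrm{Count}$.
Counting never crosses subject boundaries (concatenating hypnograms would
fabricate one spurious transition per boundary). Smoothing defaults to 0;
a stage never seen as a predecessor receives a uniform row so the matrix
stays row-stochastic. The memory feature of epoch $t$ is the transition
vector $v_t = p_{t-1} T$.

Two regimes share this formula:

* **Training**: $p_{t-1}$ is the one-hot *true* previous label, so
  $v_t$ is simply the row of $T$ for the previous stage; the first epoch
  of every subject uses a wake prior ($p_0$ = one-hot W), since
  recordings begin awake. Input width is therefore 37 + 5 = 42. (The
  alternative reading — concatenating both the raw one-hot label *and*
  the transition vector, width 47 — was considered and rejected: the
  memory model's input is defined as the EEG features plus one
  K-dimensional transition vector.)
* **Testing**: strictly causal — $p_{t-1}$ is the memory model's own
  softmax output for the previous epoch. The tests assert causality by
  truncation: predictions for the first $k$ epochs are unchanged when
  later epochs are removed.

Transition vectors are *not* passed through the feature scaler: they are
already probabilities on a common $[0,1]$ scale; a config switch can
standardize them for ablations.

## Classifiers, fusion and rejection

Both networks are plain MLPs: input → 128 → 64 → 32 → softmax(5), ReLU
throughout, Adam (learning rate $10^{-3}$), sparse categorical
cross-entropy, batch size 128, early stopping with patience 10 on a
validation split of 10% of the training rows (row-wise, after a seeded
shuffle; best-epoch weights restored). Features are standardized by a
scaler fitted on the training subjects only. No class reweighting is
applied. The implementation is a compact base-R matrix version of this
standard recipe (no deep-learning framework is required at run time); it
is deterministic under a fixed seed, which the tests assert end to end.

At inference each model reports its confidence — its maximum softmax
probability. The fusion rule with threshold $\theta = 0.7$:

* if either confidence reaches $\theta$ (boundary-inclusive, so the 0.7
  default is reproducible without floating-point knife edges), predict
  with the more confident model (ties go to the memory model — a
  deterministic choice the tests pin down);
* otherwise mark the epoch NC (not classified).

Each decision is tagged with its source — memory-dominant,
no-memory-dominant, memory-only, no-memory-only, or NC — and the five
categories partition every record set. NC epochs are excluded from all
metrics; the rejected fraction is reported separately and is monotone in
the threshold, which `threshold_sweep()` exposes (per-subject-averaged by
default; pooled with `subject_ids = NULL`).

## Evaluation

Leave-one-subject-out: per fold, the scaler, transition matrix and both
networks are fitted on the training subjects only (per-fold parameter
checksums make the no-leakage property testable — perturbing the held-out
subject's data must leave them bit-identical). Metrics are accuracy,
Cohen's $\kappa$ (chance agreement from marginal products) and per-class
F1, computed over classified epochs, aggregated per subject with standard
error $\mathrm{SD}/\sqrt{n}$, and also pooled over epochs; undefined
values (all epochs rejected, single-class $\kappa$, class absent from
truth) are reported as `NA`, never as 0. Permutation importance permutes
one feature column at a time (10 repeats by default) and reports the mean
accuracy drop of the no-memory model plus normalized positive shares.

## Synthetic polysomnography

Real expert-scored PSG corpora are access-restricted, so the package
ships a generator used by all end-to-end tests:

* **Hypnograms** are first-order Markov chains started in W. The default
  transition matrix is sticky (diagonal 0.85–0.92) with the remaining
  mass on physiologically adjacent stages (W→N1, N1→N2, N2→N3/N1, N3
  back through N2, REM→N1/N2).
* **Epochs** are stage-conditioned band-structured Gaussian signals: a
  white Gaussian sequence is shaped in the frequency domain by a
  per-band gain mask whose squared gains are proportional to the stage's
  `band_weights`, then inverted to the time domain. This makes the
  *expected* band-power proportions exactly equal to the weights — the
  property the band-ranking tests assert — and is an order of magnitude
  faster than time-domain filter banks, which matters for the 60 000
  epochs the paired experiment synthesizes. Default profiles: alpha-rich
  W, theta-rich N1/REM, sigma-elevated N2 with Gaussian-windowed 13 Hz
  spindle bursts (Poisson rate 3/epoch, ~1 s long), delta-dominant N3.
  A broadband noise floor (2 µV RMS on a 30 µV RMS signal) is added.
* **Reproducibility**: per-subject seeds are the master seed plus fixed
  offsets (1000·subject index), so studies are bit-reproducible while
  subjects differ.

What the generator does *not* emulate: artifacts (blinks, EMG bursts),
nonstationarity within epochs, inter-subject spectral variability beyond
the seeded noise, and scorer disagreement. Passing tests therefore
demonstrate the correctness and internal consistency of the pipeline and
the *mechanism* of the memory benefit — not clinical-grade performance on
real recordings.

## The paired memory-benefit experiment

`memory_benefit_experiment()` makes the central claim testable at desk
scale: when stage emissions overlap heavily (`overlap = 0.8` mixes every
stage's band profile 80% toward the common mean) but the hypnogram stays
sticky, an epoch's own spectrum is weakly informative and temporal context
must carry the load. The experiment runs the full LOSO pipeline — 10
subjects × 600 epochs of 20-s epochs (R&K-style scoring; the shorter
epoch keeps 10 replicates of the full pipeline tractable on one CPU, and
the problem sizes are stated here as the package's own choice), training
capped at 40 epochs — once per master seed, and compares the combined
(confidence-fused, with rejection) accuracy against the no-memory
no-rejection baseline, paired by seed. The acceptance test requires a
positive gain in at least 8 of 10 seeds and a positive mean gain.

## Numerical choices and edge cases

* Population (1/n) variance conventions throughout (moments, Hjorth
  activity, z-scores, scaler), matching the standard ML scaler contract.
* Resampling: rational polyphase (`signal::resample`), output length
  forced to $\lfloor n f_{out}/f_{in} \rfloor$; upsampling refused.
* Epochs are 0-based half-open sample windows; trailing samples are
  discarded; concatenating epochs reproduces the consumed signal prefix
  bit-exactly.
* Subject-level QC: a subject is excluded when any per-subject feature
  summary (default: the mean of each of the 37 features) lies more than
  1.5 IQR from the global median, or when its hypnogram changes stage
  more than 40 times per scored hour. Zero-IQR summaries exclude nobody.
  Summaries are computed on raw (pre-z-scoring) activity.
* Constant epochs raise degenerate-signal errors; all-zero wavelet bands
  yield zero entropy/mobility/complexity with a warning; zero-dispersion
  scaler columns get SD 1 with a warning.
* R&K six-class hypnograms are unified by merging N4 into N3 at load
  time (`merge_n3_n4()`); 20-s epochs are supported throughout.

## Known limitations

* The within-subject activity z-score is acausal for true real-time use.
* The MLP trains on one CPU thread; very large studies would benefit from
  a compiled backend, which the architecture does not otherwise require.
* Softmax confidences are used uncalibrated; the rejection rule inherits
  any over- or under-confidence of the networks.
* EDF/EDF+ ingestion is out of scope; recordings enter either in memory
  (`eeg_recording()`) or through the plain-text study format.
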