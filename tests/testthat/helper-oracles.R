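# Independent oracles used across the suite. Each is a deliberately
# literal, loop-level transcription of the definition it checks, kept
# separate from the package's vectorized implementations.

# Higuchi fractal dimension, transcribed scale by scale and offset by
# offset from the curve-length definition.
oracle_higuchi <- function(x, kmax) {
  n <- length(x)
  Lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      nseg <- floor((n - m) / k)
      i <- seq_len(nseg)
      Lm[m] <- sum(abs(x[m + i * k] - x[m + (i - 1) * k])) *
        (n - 1) / (nseg * k) / k
    }
    Lk[k] <- mean(Lm)
  }
  unname(stats::coef(stats::lm(log(Lk) ~ log(1 / seq_len(kmax))))[2])
}

# Periodogram band power: explicit loop over one-sided DFT bins.
oracle_band_power <- function(x, fs, low, high) {
  n <- length(x)
  X <- fft(x)
  total <- 0
  for (k in 0:(n %/% 2)) {
    f <- k * fs / n
    if (f >= low && f < high) total <- total + Mod(X[k + 1])^2
  }
  total
}

# Confusion-matrix metrics computed from first principles.
oracle_confusion_metrics <- function(pred, true, stages) {
  cm <- matrix(0L, length(stages), length(stages),
               dimnames = list(pred = stages, true = stages))
  for (i in seq_along(pred)) {
    cm[pred[i], true[i]] <- cm[pred[i], true[i]] + 1L
  }
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  f1 <- sapply(stages, function(s) {
    tp <- cm[s, s]; fp <- sum(cm[s, ]) - tp; fn <- sum(cm[, s]) - tp
    if (tp + fn == 0) return(NA_real_)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  })
  list(accuracy = po, kappa = (po - pe) / (1 - pe), f1 = f1)
}

# Transition counting by brute force over consecutive pairs.
oracle_transition_counts <- function(labels, stages) {
  cm <- matrix(0L, length(stages), length(stages),
               dimnames = list(stages, stages))
  for (t in 2:length(labels)) {
    cm[labels[t - 1], labels[t]] <- cm[labels[t - 1], labels[t]] + 1L
  }
  cm
}

# Reference Daubechies-4 periodized decomposition of the fixed seeded
# signal set.seed(42); rnorm(256), computed with an independent wavelet
# library (PyWavelets 1.9.0, mode = "periodization", level = 5).
pywt_reference <- function() {
  list(
    rel = c(0.536103593386519, 0.244968974184897, 0.136242109607903,
            0.0569616059937066, 0.0257237168269739),
    cD1_head = c(0.325821537794776, -0.680462155537149, -1.39411294043991,
                 -1.35674581594904, 1.45911844814431, 0.820392782286413),
    cA5 = c(-0.3372194475857, 0.0237162797657044, 0.955899952616827,
            -1.08917055170299, 1.08633325456929, -0.349842990775492,
            -1.39121117730719, -0.11678768894151)
  )
}

# Small helper: fraction of periodogram power each named band holds.
band_fractions <- function(x, fs) {
  bp <- band_powers(x, fs)
  bp[setdiff(names(bp), "full")] / bp[["full"]]
}

# Tiny deterministic synthetic study used by several files.
tiny_study <- function(n_subjects = 3, epochs = 40, overlap = 0,
                       epoch_seconds = 30, seed = 11) {
  generate_dataset(synthetic_study_config(
    n_subjects = n_subjects, epochs_per_subject = epochs,
    epoch_seconds = epoch_seconds,
    emissions = default_emissions(overlap = overlap), seed = seed))
}
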