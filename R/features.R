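# Per-epoch feature extraction: 37 features in a fixed order —
# 3 time-domain (skewness, kurtosis, Higuchi fractal dimension),
# 3 Hjorth parameters, 8 spectral band-power ratios, 3 spectral-shape
# descriptors, and 20 Daubechies-4 wavelet sub-band features.

#' Classical EEG frequency bands
#'
#' @return Named list of `c(low, high)` band edges in Hz: delta 0.5-4,
#'   theta 4-8, alpha 8-13, sigma 11-16, beta 13-30, full 0.5-30.
#'   Band membership is half-open, `[low, high)`.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       sigma = c(11, 16), beta = c(13, 30), full = c(0.5, 30))
}

#' Feature extraction specification
#'
#' @param rolloff_fraction Spectral roll-off proportion (default 0.95).
#' @param hfd_kmax Maximum scale for the Higuchi curve-length regression
#'   (default 10).
#' @param wavelet_levels Number of DWT decomposition levels (default 5,
#'   Daubechies-4).
#' @param include_approximation If `TRUE`, the A5 approximation energy is
#'   included in the relative-energy denominator (default `FALSE`: the
#'   denominator is the total detail energy D1..D5).
#' @return An object of class `"feature_spec"`.
#' @export
feature_spec <- function(rolloff_fraction = 0.95, hfd_kmax = 10L,
                         wavelet_levels = 5L,
                         include_approximation = FALSE) {
  stopifnot(rolloff_fraction > 0, rolloff_fraction <= 1,
            hfd_kmax >= 2, wavelet_levels >= 1)
  structure(
    list(bands = eeg_bands(), rolloff_fraction = rolloff_fraction,
         hfd_kmax = as.integer(hfd_kmax),
         wavelet_levels = as.integer(wavelet_levels),
         include_approximation = include_approximation),
    class = "feature_spec"
  )
}

#' Names of the 37 features, in canonical order
#' @return Character vector of length 37.
#' @export
feature_names <- function() {
  c("skewness", "kurtosis", "hfd",
    "hjorth_activity", "hjorth_mobility", "hjorth_complexity",
    paste0("ratio_", 1:8),
    "spectral_entropy", "spectral_centroid", "spectral_rolloff",
    as.vector(t(outer(paste0("d", 1:5),
                      c("relative_energy", "wavelet_entropy",
                        "wavelet_mobility", "wavelet_complexity"),
                      function(b, f) paste0(f, "_", b)))))
}

# ---- time domain -----------------------------------------------------------

#' Time-domain features: skewness, kurtosis, Higuchi fractal dimension
#'
#' Skewness and kurtosis use the population moment definitions
#' (`m3/m2^1.5` and `m4/m2^2`); kurtosis is the non-excess (Pearson)
#' convention, so a Gaussian gives 3 and a sine 1.5. HFD follows Higuchi's
#' curve-length regression.
#'
#' @param x Numeric epoch (non-constant).
#' @param hfd_kmax Maximum Higuchi scale.
#' @return Named numeric: `skewness`, `kurtosis`, `hfd`.
#' @export
time_domain_features <- function(x, hfd_kmax = 10L) {
  if (stats::var(x) == 0) stop("degenerate (constant) epoch")
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  c(skewness = m3 / m2^1.5, kurtosis = m4 / m2^2,
    hfd = higuchi_fd(x, hfd_kmax))
}

#' Higuchi fractal dimension
#'
#' For each scale k = 1..kmax and offset m = 1..k, the normalized curve
#' length \eqn{L_m(k)} is computed from the k-strided absolute increments;
#' the fractal dimension is the negative slope of the least-squares fit of
#' \eqn{\log \bar L(k)} on \eqn{\log k}.
#'
#' @param x Numeric series, length > `kmax`.
#' @param kmax Maximum scale (default 10).
#' @return Estimated fractal dimension (about 1 for smooth curves, near 2
#'   for white noise).
#' @export
higuchi_fd <- function(x, kmax = 10L) {
  n <- length(x)
  stopifnot(n > kmax, kmax >= 2)
  Lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    d <- abs(x[(1L + k):n] - x[1L:(n - k)])   # d[i] = |x[i+k] - x[i]|
    ncol_pad <- ceiling(length(d) / k)        # pad, reshape, row-sum per offset m
    sums <- rowSums(matrix(c(d, numeric(k * ncol_pad - length(d))),
                           nrow = k))
    m <- seq_len(k)
    nseg <- floor((n - m) / k)
    Lm <- sums * (n - 1) / (nseg * k) / k
    Lk[k] <- mean(Lm)
  }
  fit <- stats::lm.fit(cbind(1, log(1 / seq_len(kmax))), log(Lk))
  unname(fit$coefficients[2L])
}

# ---- Hjorth ----------------------------------------------------------------

#' Hjorth parameters
#'
#' Activity is the (population) variance; mobility is
#' `sqrt(var(diff(x)) / var(x))`; complexity is the mobility of the first
#' difference divided by the mobility of the signal. Activity is returned
#' raw; see [zscore_activity_within_subject()] for the subject-level pass.
#'
#' @param x Numeric epoch (non-constant).
#' @return Named numeric: `activity`, `mobility`, `complexity`.
#' @export
hjorth_features <- function(x) {
  v0 <- pop_var(x)
  if (v0 == 0) stop("degenerate (constant) epoch: zero variance")
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- pop_var(d1)
  v2 <- pop_var(d2)
  mob <- sqrt(v1 / v0)
  cpx <- sqrt(v2 / v1) / mob
  c(activity = v0, mobility = mob, complexity = cpx)
}

pop_var <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

#' Within-subject z-scoring of Hjorth activity
#'
#' Standardizes the activity values of one subject's epochs to mean 0 and
#' (population) SD 1, removing absolute-amplitude differences between
#' subjects. Only activity is transformed; mobility and complexity are
#' already amplitude-invariant.
#'
#' @param activity Numeric vector of one subject's activity values (>= 2).
#' @return Standardized values; all zeros (with a warning) when the
#'   dispersion is zero.
#' @export
zscore_activity_within_subject <- function(activity) {
  stopifnot(length(activity) >= 2L)
  s <- sqrt(pop_var(activity))
  if (s == 0) {
    warning("zero dispersion in activity; returning zeros")
    return(rep(0, length(activity)))
  }
  (activity - mean(activity)) / s
}

# ---- frequency domain ------------------------------------------------------

# Internal: one-sided periodogram of an epoch.
# Returns list(freq, power) with power = squared DFT magnitudes.
one_sided_spectrum <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  k <- 0:(n %/% 2L)
  list(freq = k * fs / n, power = Mod(X[k + 1L])^2)
}

#' Band powers from the DFT
#'
#' The DFT is applied to the full epoch (no taper, no detrend); the power
#' in each band is the sum of squared one-sided DFT magnitudes over bins
#' whose frequency lies in `[low, high)`.
#'
#' @param x Numeric epoch.
#' @param fs Sampling rate in Hz.
#' @param bands Named list of band edges (default [eeg_bands()]).
#' @return Named nonnegative numeric, one entry per band.
#' @export
band_powers <- function(x, fs, bands = eeg_bands()) {
  sp <- one_sided_spectrum(x, fs)
  vapply(bands, function(lohi) {
    sum(sp$power[sp$freq >= lohi[1L] & sp$freq < lohi[2L]])
  }, numeric(1))
}

#' The eight spectral power ratios
#'
#' In fixed order: d/a, d/b, d/t, t/a, t/b, s/d, d/(a+b), (d+t)/(a+b),
#' where d, t, a, s, b are the delta, theta, alpha, sigma and beta band
#' powers. A zero denominator is replaced by `denominator + eps` with a
#' warning, keeping the pipeline total.
#'
#' @param bp Named band powers as from [band_powers()].
#' @param eps Guard added to zero denominators (default 1e-12).
#' @return Numeric vector `ratio_1` .. `ratio_8`.
#' @export
power_ratios <- function(bp, eps = 1e-12) {
  d <- bp[["delta"]]; t <- bp[["theta"]]; a <- bp[["alpha"]]
  s <- bp[["sigma"]]; b <- bp[["beta"]]
  div <- function(num, den) {
    if (den == 0) {
      warning("zero denominator in power ratio; using eps guard")
      den <- den + eps
    }
    num / den
  }
  out <- c(div(d, a), div(d, b), div(d, t), div(t, a), div(t, b),
           div(s, d), div(d, a + b), div(d + t, a + b))
  names(out) <- paste0("ratio_", 1:8)
  out
}

#' Spectral shape features
#'
#' Over the full band (0.5-30 Hz): Shannon entropy of the normalized power
#' spectrum divided by `log(n_bins)` (so in `[0, 1]`), the power-weighted
#' mean frequency (centroid), and the roll-off frequency — the smallest
#' frequency below which `rolloff_fraction` of the in-band power lies.
#'
#' @param x Numeric epoch.
#' @param fs Sampling rate in Hz.
#' @param rolloff_fraction Roll-off proportion (default 0.95).
#' @return Named numeric: `spectral_entropy`, `spectral_centroid`,
#'   `spectral_rolloff` (Hz).
#' @export
spectral_shape <- function(x, fs, rolloff_fraction = 0.95) {
  sp <- one_sided_spectrum(x, fs)
  full <- eeg_bands()$full
  idx <- sp$freq >= full[1L] & sp$freq < full[2L]
  pw <- sp$power[idx]
  fq <- sp$freq[idx]
  tot <- sum(pw)
  if (tot <= 0) stop("degenerate spectrum: zero in-band power")
  p <- pw / tot
  ent <- -sum(ifelse(p > 0, p * log(p), 0)) / log(length(p))
  centroid <- sum(fq * p)
  rolloff <- fq[which(cumsum(pw) >= rolloff_fraction * tot)[1L]]
  c(spectral_entropy = ent, spectral_centroid = centroid,
    spectral_rolloff = rolloff)
}

# ---- wavelets --------------------------------------------------------------

# Daubechies-4 (8-tap) decomposition filters.
db4_filters <- function() {
  lo <- c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651)
  hi <- rev(lo) * (-1)^seq_along(lo)
  list(lo = lo, hi = hi)
}

# Internal: one periodized DWT step. Odd-length input is extended by
# repeating its last sample; output length is ceil(n / 2).
# Convention (0-based): cA[i] = sum_j lo[j] * x[(2i + L/2 - j) mod N].
dwt_step <- function(x, lo, hi) {
  n <- length(x)
  if (n %% 2L == 1L) {
    x <- c(x, x[n])
    n <- n + 1L
  }
  L <- length(lo)
  half <- n %/% 2L
  j <- 0:(L - 1L)
  idx <- outer(2L * (seq_len(half) - 1L) + L %/% 2L, j, `-`) %% n + 1L
  seg <- matrix(x[idx], half, L)
  list(cA = as.numeric(seg %*% lo), cD = as.numeric(seg %*% hi))
}

#' Multilevel Daubechies-4 wavelet decomposition
#'
#' Periodized pyramid decomposition. With a 125 Hz epoch the detail bands
#' cover approximately D1 31-62 Hz, D2 16-31 Hz, D3 8-16 Hz, D4 4-8 Hz and
#' D5 0.5-4 Hz (the conventional beta/gamma, beta, alpha/sigma, theta and
#' delta sub-bands).
#'
#' @param x Numeric epoch, length >= `2^levels`.
#' @param levels Number of levels (default 5).
#' @return List with `details` (list `d1`..`d5` of coefficient vectors,
#'   finest first) and `approximation` (the final cA).
#' @export
dwt_db4 <- function(x, levels = 5L) {
  stopifnot(length(x) >= 2^levels)
  f <- db4_filters()
  details <- vector("list", levels)
  cur <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(cur, f$lo, f$hi)
    details[[j]] <- st$cD
    cur <- st$cA
  }
  names(details) <- paste0("d", seq_len(levels))
  list(details = details, approximation = cur)
}

#' Wavelet sub-band features
#'
#' For each detail band D1..D5 of the Daubechies-4 decomposition: the
#' relative energy (band energy over total detail energy), the Shannon
#' entropy (natural log) of the normalized squared coefficients, and the
#' Hjorth mobility and complexity of the coefficient sequence. An all-zero
#' band yields 0 for entropy, mobility and complexity with a warning.
#'
#' @param x Numeric epoch.
#' @param spec A [feature_spec()].
#' @return Named numeric vector of 20 features, grouped D1 to D5.
#' @export
wavelet_features <- function(x, spec = feature_spec()) {
  dec <- dwt_db4(x, spec$wavelet_levels)
  energies <- vapply(dec$details, function(c) sum(c^2), numeric(1))
  denom <- sum(energies)
  if (isTRUE(spec$include_approximation)) {
    denom <- denom + sum(dec$approximation^2)
  }
  out <- numeric(0)
  for (j in seq_along(dec$details)) {
    cj <- dec$details[[j]]
    Ej <- energies[j]
    rel <- if (denom > 0) Ej / denom else 0
    if (Ej > 0) {
      p <- cj^2 / Ej
      ent <- -sum(ifelse(p > 0, p * log(p), 0))
      v0 <- pop_var(cj)
      if (v0 > 0) {
        d1 <- diff(cj)
        v1 <- pop_var(d1)
        mob <- sqrt(v1 / v0)
        cpx <- if (v1 > 0) sqrt(pop_var(diff(d1)) / v1) / mob else 0
      } else {
        mob <- 0; cpx <- 0
      }
    } else {
      warning("all-zero wavelet band d", j, "; features set to 0")
      ent <- 0; mob <- 0; cpx <- 0
    }
    v <- c(rel, ent, mob, cpx)
    names(v) <- paste0(c("relative_energy", "wavelet_entropy",
                         "wavelet_mobility", "wavelet_complexity"),
                       "_d", j)
    out <- c(out, v)
  }
  out
}

# ---- assembly --------------------------------------------------------------

#' Extract the 37-feature vector of one epoch
#'
#' Fixed order: skewness, kurtosis, HFD; Hjorth activity (raw), mobility,
#' complexity; the eight band-power ratios; spectral entropy, centroid,
#' roll-off; then relative energy, wavelet entropy, wavelet mobility and
#' wavelet complexity for each detail band D1..D5. Activity is returned
#' raw here; z-scoring is a subject-level pass
#' ([zscore_activity_within_subject()]).
#'
#' @param x Numeric epoch (non-constant).
#' @param fs Sampling rate in Hz.
#' @param spec A [feature_spec()].
#' @return Named numeric vector of length 37.
#' @export
extract_features <- function(x, fs, spec = feature_spec()) {
  td <- time_domain_features(x, spec$hfd_kmax)
  hj <- hjorth_features(x)
  names(hj) <- paste0("hjorth_", names(hj))
  bp <- band_powers(x, fs, spec$bands)
  out <- c(td, hj, power_ratios(bp),
           spectral_shape(x, fs, spec$rolloff_fraction),
           wavelet_features(x, spec))
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Feature table for a whole study
#'
#' Extracts the 37 features for every epoch of every subject and (by
#' default) applies the within-subject z-scoring of Hjorth activity. This
#' pass is unsupervised and per-subject, so it is applied identically to
#' training and held-out subjects without label leakage.
#'
#' @param study An `"eeg_study"`.
#' @param spec A [feature_spec()].
#' @param zscore_activity Apply the within-subject activity z-score
#'   (default `TRUE`).
#' @return data.frame with columns `subject_id`, `epoch_index`, `label`,
#'   then the 37 feature columns.
#' @export
study_features <- function(study, spec = feature_spec(),
                           zscore_activity = TRUE) {
  stopifnot(inherits(study, "eeg_study"))
  per_subject <- lapply(study, function(s) {
    fm <- t(apply(s$epochs, 1L, extract_features, fs = s$fs, spec = spec))
    if (zscore_activity && nrow(fm) >= 2L) {
      fm[, "hjorth_activity"] <-
        zscore_activity_within_subject(fm[, "hjorth_activity"])
    }
    cbind(
      data.frame(subject_id = s$subject_id,
                 epoch_index = seq_len(nrow(fm)),
                 label = s$labels, stringsAsFactors = FALSE),
      as.data.frame(fm)
    )
  })
  do.call(rbind, c(per_subject, list(make.row.names = FALSE)))
}
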