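# Synthetic polysomnography: first-order Markov hypnograms plus
# stage-conditioned single-channel EEG epochs with stage-specific
# band-power profiles (delta-dominant N3, alpha-rich W, sigma spindle
# bursts in N2, theta-rich N1/REM).

#' Stage emission specification
#'
#' Describes how EEG epochs are synthesized for one sleep stage: the relative
#' power assigned to each classical EEG band, the sleep-spindle burst rate
#' (N2 only, bursts per epoch), and a broadband noise floor.
#'
#' @param stage Stage label, one of [sleep_stages()].
#' @param band_weights Named nonnegative numeric vector of relative band
#'   powers; names must be a subset of `c("delta","theta","alpha","sigma",
#'   "beta")` and the values must sum to a positive number.
#' @param spindle_rate Expected number of spindle bursts (11-16 Hz,
#'   Gaussian-windowed) per epoch; nonzero only for N2 by default.
#' @param noise_floor Broadband white-noise RMS in microvolts.
#' @param rms Target RMS of the band-structured component, microvolts.
#' @return An object of class `"stage_emission_spec"`.
#' @export
stage_emission_spec <- function(stage, band_weights, spindle_rate = 0,
                                noise_floor = 2, rms = 30) {
  stage <- match.arg(stage, sleep_stages())
  bands <- c("delta", "theta", "alpha", "sigma", "beta")
  if (is.null(names(band_weights)) ||
      !all(names(band_weights) %in% bands)) {
    stop("band_weights must be named with EEG band names")
  }
  if (any(band_weights < 0) || sum(band_weights) <= 0) {
    stop("band_weights must be nonnegative and sum to a positive number")
  }
  if (spindle_rate < 0) stop("spindle_rate must be >= 0")
  structure(
    list(stage = stage, band_weights = band_weights,
         spindle_rate = spindle_rate, noise_floor = noise_floor, rms = rms),
    class = "stage_emission_spec"
  )
}

#' Default stage-conditioned emission profiles
#'
#' Band-power profiles reproducing the canonical spectral signatures of each
#' stage: alpha-rich wake, theta-rich N1 and REM, sigma spindle activity in
#' N2, and delta-dominant N3. The `overlap` argument linearly mixes every
#' stage's profile toward the across-stage mean profile, making the stages
#' spectrally harder to separate (0 = fully distinct defaults, 1 = identical
#' emissions); it is the knob used to study how much classification must rely
#' on temporal structure rather than on the epoch's own spectrum.
#'
#' @param overlap Mixing proportion in `[0, 1]`.
#' @return Named list of [stage_emission_spec()] objects, one per stage.
#' @export
default_emissions <- function(overlap = 0) {
  stopifnot(overlap >= 0, overlap <= 1)
  w <- list(
    W   = c(delta = 0.15, theta = 0.15, alpha = 0.45, sigma = 0.05, beta = 0.20),
    N1  = c(delta = 0.25, theta = 0.45, alpha = 0.15, sigma = 0.05, beta = 0.10),
    N2  = c(delta = 0.40, theta = 0.25, alpha = 0.10, sigma = 0.20, beta = 0.05),
    N3  = c(delta = 0.75, theta = 0.12, alpha = 0.05, sigma = 0.04, beta = 0.04),
    REM = c(delta = 0.25, theta = 0.40, alpha = 0.12, sigma = 0.05, beta = 0.18)
  )
  wbar <- Reduce(`+`, w) / length(w)
  spindles <- c(W = 0, N1 = 0, N2 = 3, N3 = 0, REM = 0)
  out <- lapply(names(w), function(s) {
    stage_emission_spec(
      stage = s,
      band_weights = (1 - overlap) * w[[s]] + overlap * wbar,
      spindle_rate = spindles[[s]]
    )
  })
  names(out) <- names(w)
  out
}

#' Default sticky five-stage transition matrix
#'
#' A physiologically plausible first-order transition matrix: high
#' self-transition probability (0.85-0.92) with the remaining mass on
#' adjacent stages (W to N1, N1 to N2, N2 to N3/N1, N3 back through N2, REM
#' to N1/N2). Used as the ground-truth hypnogram dynamics of the synthetic
#' study.
#'
#' @return A [transition_matrix()] over [sleep_stages()].
#' @export
default_transition_matrix <- function() {
  probs <- rbind(
    W   = c(0.900, 0.080, 0.010, 0.000, 0.010),
    N1  = c(0.050, 0.850, 0.080, 0.000, 0.020),
    N2  = c(0.010, 0.030, 0.900, 0.040, 0.020),
    N3  = c(0.005, 0.005, 0.060, 0.920, 0.010),
    REM = c(0.020, 0.030, 0.040, 0.000, 0.910)
  )
  colnames(probs) <- sleep_stages()
  transition_matrix(probs, sleep_stages())
}

#' Simulate a first-order Markov hypnogram
#'
#' @param T_true A [transition_matrix()] (row-stochastic).
#' @param n_epochs Number of epochs to simulate (>= 1).
#' @param initial_stage Stage of the first epoch (default `"W"`).
#' @param seed Optional integer seed; when given, the draw is reproducible.
#' @return Character vector of stage labels of length `n_epochs`.
#' @export
#' @examples
#' simulate_hypnogram(default_transition_matrix(), 10, seed = 1)
simulate_hypnogram <- function(T_true, n_epochs, initial_stage = "W",
                               seed = NULL) {
  T_true <- as_transition_matrix(T_true)
  stages <- rownames(T_true)
  stopifnot(n_epochs >= 1)
  initial_stage <- match.arg(initial_stage, stages)
  if (!is.null(seed)) set.seed(seed)
  out <- character(n_epochs)
  out[1L] <- initial_stage
  if (n_epochs > 1L) {
    K <- length(stages)
    cur <- match(initial_stage, stages)
    u <- stats::runif(n_epochs - 1L)
    cum <- t(apply(unclass(T_true), 1L, cumsum))
    for (t in 2L:n_epochs) {
      cur <- findInterval(u[t - 1L], cum[cur, ], left.open = TRUE) + 1L
      if (cur > K) cur <- K  # guard against rounding at the top edge
      out[t] <- stages[cur]
    }
  }
  out
}

#' Synthesize one stage-conditioned EEG epoch
#'
#' Generates a band-structured Gaussian signal whose expected power
#' proportions across the classical EEG bands equal the specification's
#' `band_weights`: a white Gaussian sequence is shaped in the frequency
#' domain by a per-band gain mask and inverted back to the time domain.
#' Sleep-spindle bursts (Gaussian-windowed 13 Hz sinusoids, ~1 s long) are
#' superimposed at a Poisson rate of `spec$spindle_rate` per epoch, and a
#' broadband noise floor of RMS `spec$noise_floor` microvolts is added.
#'
#' @param stage Stage label; must equal `spec$stage`.
#' @param spec A [stage_emission_spec()].
#' @param fs Sampling rate in Hz (default 125).
#' @param epoch_seconds Epoch duration in seconds (default 30).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of length `fs * epoch_seconds` (microvolts).
#' @export
synthesize_epoch <- function(stage, spec, fs = 125, epoch_seconds = 30,
                             seed = NULL) {
  stopifnot(inherits(spec, "stage_emission_spec"))
  if (!identical(stage, spec$stage)) {
    stop("stage does not match spec$stage")
  }
  n <- fs * epoch_seconds
  if (abs(n - round(n)) > 1e-9) stop("fs * epoch_seconds must be an integer")
  n <- as.integer(round(n))
  w <- spec$band_weights
  if (sum(w) <= 0) stop("total band weight must be positive")
  w <- w / sum(w)
  if (!is.null(seed)) set.seed(seed)

  bands <- eeg_bands()
  freq <- (0:(n - 1L)) * fs / n
  freq_sym <- pmin(freq, fs - freq)  # fold to [0, fs/2]
  gain2 <- numeric(n)
  for (b in names(w)) {
    lohi <- bands[[b]]
    idx <- freq_sym >= lohi[1L] & freq_sym < lohi[2L]
    nb <- sum(idx)
    if (nb > 0L) gain2[idx] <- gain2[idx] + w[[b]] / nb
  }
  x0 <- stats::rnorm(n)
  x <- Re(stats::fft(stats::fft(x0) * sqrt(gain2), inverse = TRUE)) / n
  p <- mean(x^2)
  if (p > 0) x <- x * (spec$rms / sqrt(p))

  if (spec$spindle_rate > 0) {
    n_burst <- stats::rpois(1L, spec$spindle_rate)
    if (n_burst > 0L) {
      tt <- (0:(n - 1L)) / fs
      amp <- 1.5 * spec$rms
      for (i in seq_len(n_burst)) {
        center <- stats::runif(1L, 0, epoch_seconds)
        phase <- stats::runif(1L, 0, 2 * pi)
        x <- x + amp * exp(-(tt - center)^2 / (2 * 0.25^2)) *
          sin(2 * pi * 13 * tt + phase)
      }
    }
  }
  if (spec$noise_floor > 0) {
    x <- x + stats::rnorm(n, sd = spec$noise_floor)
  }
  x
}

#' Configuration for a synthetic study
#'
#' @param n_subjects Number of subjects.
#' @param epochs_per_subject Epochs per subject.
#' @param epoch_seconds Epoch duration, 20 or 30 s.
#' @param fs Sampling rate in Hz.
#' @param T_true Ground-truth [transition_matrix()].
#' @param emissions Named list of [stage_emission_spec()], one per stage.
#' @param seed Master integer seed.
#' @return An object of class `"synthetic_study_config"`.
#' @export
synthetic_study_config <- function(n_subjects = 10, epochs_per_subject = 600,
                                   epoch_seconds = 30, fs = 125,
                                   T_true = default_transition_matrix(),
                                   emissions = default_emissions(),
                                   seed = 1L) {
  stopifnot(n_subjects >= 1, epochs_per_subject >= 1,
            epoch_seconds %in% c(20, 30), fs > 0)
  if (abs(fs * epoch_seconds - round(fs * epoch_seconds)) > 1e-9) {
    stop("fs * epoch_seconds must be an integer sample count")
  }
  T_true <- as_transition_matrix(T_true)
  miss <- setdiff(sleep_stages(), names(emissions))
  if (length(miss) > 0L) {
    stop("emissions missing stage(s): ", paste(miss, collapse = ", "))
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         epochs_per_subject = as.integer(epochs_per_subject),
         epoch_seconds = epoch_seconds, fs = fs, T_true = T_true,
         emissions = emissions, seed = as.integer(seed)),
    class = "synthetic_study_config"
  )
}

#' Generate a synthetic polysomnography study
#'
#' Draws one hypnogram per subject from `config$T_true` (initial stage W)
#' and synthesizes a stage-conditioned EEG epoch for every label. Each
#' subject uses a seed derived from the master seed by a fixed offset, so
#' the study is fully reproducible while subjects differ.
#'
#' @param config A [synthetic_study_config()].
#' @return An object of class `"eeg_study"`: a list of subjects, each of
#'   class `"eeg_subject"` with elements `subject_id`, `epochs` (matrix,
#'   one row per epoch), `labels`, `fs`, `epoch_seconds`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_study_config"))
  n_samp <- as.integer(round(config$fs * config$epoch_seconds))
  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    subj_seed <- config$seed + 1000L * s
    set.seed(subj_seed)
    labels <- simulate_hypnogram(config$T_true, config$epochs_per_subject,
                                 initial_stage = "W")
    epochs <- matrix(NA_real_, nrow = config$epochs_per_subject, ncol = n_samp)
    for (t in seq_along(labels)) {
      epochs[t, ] <- synthesize_epoch(labels[t], config$emissions[[labels[t]]],
                                      fs = config$fs,
                                      epoch_seconds = config$epoch_seconds)
    }
    subjects[[s]] <- structure(
      list(subject_id = sprintf("S%02d", s), epochs = epochs, labels = labels,
           fs = config$fs, epoch_seconds = config$epoch_seconds),
      class = "eeg_subject"
    )
  }
  structure(subjects, class = "eeg_study")
}

#' @export
print.eeg_study <- function(x, ...) {
  cat(sprintf("<eeg_study> %d subjects\n", length(x)))
  for (s in x) {
    cat(sprintf("  %s: %d epochs x %d samples (%g s @ %g Hz)\n",
                s$subject_id, nrow(s$epochs), ncol(s$epochs),
                s$epoch_seconds, s$fs))
  }
  invisible(x)
}

#' Write a synthetic study to plain-text files
#'
#' One `<subject>_epochs.csv` (epoch matrix, no header) and one
#' `<subject>_hypnogram.txt` (one stage label per line) per subject.
#'
#' @param study An `"eeg_study"`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "eeg_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in study) {
    utils::write.table(s$epochs,
                       file.path(dir, paste0(s$subject_id, "_epochs.csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    writeLines(s$labels,
               file.path(dir, paste0(s$subject_id, "_hypnogram.txt")))
  }
  invisible(dir)
}
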