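# Epoch construction: frontopolar derivation, anti-aliased resampling,
# non-overlapping segmentation, and subject-level quality control.

#' In-memory multichannel recording
#'
#' @param samples Named list of equal-length numeric vectors (microvolts),
#'   one per channel.
#' @param fs Sampling rate in Hz.
#' @param annotations Optional data.frame with columns `onset`, `duration`
#'   (seconds) and `stage`.
#' @return An object of class `"eeg_recording"`.
#' @export
eeg_recording <- function(samples, fs, annotations = NULL) {
  stopifnot(is.list(samples), length(samples) >= 1, fs > 0)
  if (is.null(names(samples)) || any(names(samples) == "")) {
    stop("all channels must be named")
  }
  lens <- vapply(samples, length, integer(1))
  if (length(unique(lens)) != 1L) stop("all channels must have equal length")
  structure(list(samples = samples, fs = fs, annotations = annotations),
            class = "eeg_recording")
}

#' Frontopolar bipolar derivation
#'
#' Computes the Fp1-Fp2 bipolar channel as the elementwise voltage
#' difference between two referential frontopolar channels.
#'
#' @param recording An [eeg_recording()].
#' @param fp1_name,fp2_name Channel names to subtract (`fp1 - fp2`).
#' @return Numeric vector, `fp1[i] - fp2[i]`.
#' @export
derive_frontopolar <- function(recording, fp1_name = "Fp1", fp2_name = "Fp2") {
  stopifnot(inherits(recording, "eeg_recording"))
  for (nm in c(fp1_name, fp2_name)) {
    if (!nm %in% names(recording$samples)) {
      stop("channel not found: ", nm)
    }
  }
  recording$samples[[fp1_name]] - recording$samples[[fp2_name]]
}

#' Anti-aliased downsampling to a target rate
#'
#' Polyphase rational resampling (e.g. 256 Hz to 125 Hz uses the ratio
#' 125/256) with the resampler's anti-aliasing low-pass. The output length
#' is `floor(n * fs_out / fs_in)`.
#'
#' @param x Numeric signal.
#' @param fs_in,fs_out Input and output sampling rates; upsampling
#'   (`fs_out > fs_in`) is not supported.
#' @return Resampled numeric vector.
#' @export
resample_to_target <- function(x, fs_in, fs_out) {
  stopifnot(fs_in > 0, fs_out > 0)
  if (fs_out > fs_in) stop("upsampling is not supported (fs_out > fs_in)")
  if (fs_in == fs_out) return(x)
  scale <- 1e6
  a <- round(fs_out * scale); b <- round(fs_in * scale)
  g <- gcd_int(a, b)
  p <- a / g; q <- b / g
  y <- signal::resample(x, p, q)
  n_out <- floor(length(x) * fs_out / fs_in)
  length(y) <- n_out  # truncates (or NA-pads, which cannot occur for p < q)
  y
}

# Internal: integer gcd (Euclid).
gcd_int <- function(a, b) {
  while (b != 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

#' Segment a signal into labeled, non-overlapping epochs
#'
#' The first `length(labels)` contiguous windows of `fs * epoch_seconds`
#' samples are taken from the start of the signal (0-based half-open sample
#' intervals); trailing samples are discarded.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param epoch_seconds Epoch duration in seconds.
#' @param labels Stage label per epoch.
#' @param subject_id Identifier stored on the result.
#' @return An `"eeg_subject"` (epoch matrix plus aligned labels).
#' @export
segment_epochs <- function(x, fs, epoch_seconds, labels, subject_id = "S01") {
  n_ep <- length(labels)
  spe <- fs * epoch_seconds
  if (abs(spe - round(spe)) > 1e-9) stop("fs * epoch_seconds must be integer")
  spe <- as.integer(round(spe))
  if (length(x) < n_ep * spe) {
    stop("signal too short for ", n_ep, " epochs of ", spe, " samples")
  }
  epochs <- matrix(x[seq_len(n_ep * spe)], nrow = n_ep, ncol = spe,
                   byrow = TRUE)
  structure(
    list(subject_id = subject_id, epochs = epochs,
         labels = as.character(labels), fs = fs,
         epoch_seconds = epoch_seconds),
    class = "eeg_subject"
  )
}

#' Hypnogram transition rate
#'
#' Number of stage changes between consecutive epochs divided by the total
#' hours of scored epochs.
#'
#' @param labels Stage label sequence.
#' @param epoch_seconds Epoch duration in seconds.
#' @return Transitions per hour.
#' @export
transition_rate <- function(labels, epoch_seconds) {
  n <- length(labels)
  if (n < 2L) return(0)
  changes <- sum(labels[-1L] != labels[-n])
  hours <- n * epoch_seconds / 3600
  changes / hours
}

#' Subject-level quality control
#'
#' Excludes a subject when (a) any of its per-subject feature summaries lies
#' more than `iqr_mult` times the interquartile range from the global median
#' of that summary, or (b) its hypnogram transition rate exceeds
#' `max_transition_rate` per hour. Feature summaries default to the
#' per-subject mean of each of the 37 epoch features. A summary with zero
#' IQR across subjects excludes nobody.
#'
#' @param study An `"eeg_study"` (list of `"eeg_subject"`).
#' @param feature_summaries Optional numeric matrix, one row per subject;
#'   computed from [extract_features()] means when `NULL`.
#' @param iqr_mult IQR multiplier (default 1.5).
#' @param max_transition_rate Transitions/hour cut-off (default 40).
#' @param spec [feature_spec()] used when summaries are computed here.
#' @return List with `kept` (the retained `"eeg_study"`) and `report`
#'   (data.frame: `subject_id`, `excluded`, `rule`).
#' @export
qc_exclude_subjects <- function(study, feature_summaries = NULL,
                                iqr_mult = 1.5, max_transition_rate = 40,
                                spec = feature_spec()) {
  stopifnot(inherits(study, "eeg_study"), length(study) >= 3L)
  if (is.null(feature_summaries)) {
    feature_summaries <- t(vapply(study, function(s) {
      colMeans(t(apply(s$epochs, 1L, extract_features, fs = s$fs,
                       spec = spec)))
    }, numeric(37L)))
  }
  feature_summaries <- as.matrix(feature_summaries)
  stopifnot(nrow(feature_summaries) == length(study))

  med <- apply(feature_summaries, 2L, stats::median)
  iqr <- apply(feature_summaries, 2L, stats::IQR)
  rules <- character(length(study))
  for (i in seq_along(study)) {
    dev <- abs(feature_summaries[i, ] - med)
    feat_out <- any(iqr > 0 & dev > iqr_mult * iqr)
    rate <- transition_rate(study[[i]]$labels, study[[i]]$epoch_seconds)
    if (feat_out) {
      rules[i] <- "feature-outlier"
    } else if (rate > max_transition_rate) {
      rules[i] <- "transition-rate"
    } else {
      rules[i] <- ""
    }
  }
  excluded <- rules != ""
  report <- data.frame(
    subject_id = vapply(study, `[[`, character(1), "subject_id"),
    excluded = excluded,
    rule = rules,
    stringsAsFactors = FALSE
  )
  kept <- structure(study[!excluded], class = "eeg_study")
  if (length(kept) == 0L) {
    warning("all subjects excluded by QC")
  }
  list(kept = kept, report = report)
}

#' Read a study from plain-text files
#'
#' Counterpart of [write_study()]: reads `<id>_epochs.csv` /
#' `<id>_hypnogram.txt` pairs from a directory.
#'
#' @param dir Directory containing the files.
#' @param fs Sampling rate of the stored epochs.
#' @param epoch_seconds Epoch duration in seconds.
#' @return An `"eeg_study"`.
#' @export
read_study <- function(dir, fs = 125, epoch_seconds = 30) {
  files <- sort(list.files(dir, pattern = "_epochs\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop("no *_epochs.csv files in ", dir)
  subjects <- lapply(files, function(f) {
    id <- sub("_epochs\\.csv$", "", basename(f))
    epochs <- as.matrix(utils::read.table(f, sep = ",", header = FALSE))
    dimnames(epochs) <- NULL
    labels <- readLines(file.path(dir, paste0(id, "_hypnogram.txt")))
    stopifnot(length(labels) == nrow(epochs))
    structure(list(subject_id = id, epochs = epochs,
                   labels = check_stage_labels(labels), fs = fs,
                   epoch_seconds = epoch_seconds),
              class = "eeg_subject")
  })
  structure(subjects, class = "eeg_study")
}

#' Merge R&K N4 into N3
#'
#' Six-class R&K hypnograms are mapped to the unified five-class scheme by
#' relabeling N4 as N3 (used for 20-s-epoch studies scored under R&K).
#'
#' @param labels Stage label sequence possibly containing `"N4"`.
#' @return Labels with every `"N4"` replaced by `"N3"`.
#' @export
merge_n3_n4 <- function(labels) {
  labels[labels == "N4"] <- "N3"
  labels
}
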