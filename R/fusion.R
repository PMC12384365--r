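# Confidence-guided fusion of the two models' softmax outputs with a
# not-classified (NC) fallback, plus decision-source accounting and the
# confidence-threshold sweep.

decision_sources <- function() {
  c("mem_dominant", "nomem_dominant", "mem_only", "nomem_only",
    "not_classified")
}

#' Combine the two models' predictions for one or more epochs
#'
#' For each epoch let `c_m` and `c_n` be the maximum softmax probabilities
#' (confidences) of the memory and no-memory models. If the larger of the
#' two is at least the threshold, the corresponding model's argmax stage is
#' predicted ("exceeds the threshold" is boundary-inclusive, and confidence
#' ties go to the memory model); otherwise the epoch is marked NC. The
#' decision source records which models were confident: `mem_dominant` /
#' `nomem_dominant` when both reached the threshold, `mem_only` /
#' `nomem_only` when exactly one did, `not_classified` when neither did.
#'
#' @param p_mem,p_nomem Softmax probability matrices (or single
#'   distributions) from the memory and no-memory models, stage-named
#'   columns, aligned row-wise.
#' @param threshold Confidence threshold in (0, 1); default 0.7.
#' @param stage_order Stage set (defaults to the matrices' column names).
#' @return data.frame of decision records: `prediction` (stage or `"NC"`),
#'   `source`, `conf_mem`, `conf_nomem`.
#' @export
combine_models <- function(p_mem, p_nomem, threshold = 0.7,
                           stage_order = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(dim(p_mem))) p_mem <- matrix(p_mem, 1L)
  if (is.null(dim(p_nomem))) p_nomem <- matrix(p_nomem, 1L)
  stopifnot(nrow(p_mem) == nrow(p_nomem), ncol(p_mem) == ncol(p_nomem))
  if (is.null(stage_order)) stage_order <- colnames(p_mem)
  if (is.null(stage_order)) stage_order <- sleep_stages()
  apply(p_mem, 1L, check_simplex, what = "memory softmax row")
  apply(p_nomem, 1L, check_simplex, what = "no-memory softmax row")

  c_m <- apply(p_mem, 1L, max)
  c_n <- apply(p_nomem, 1L, max)
  k_m <- max.col(p_mem, ties.method = "first")
  k_n <- max.col(p_nomem, ties.method = "first")
  m_ok <- c_m >= threshold
  n_ok <- c_n >= threshold

  source <- rep("not_classified", length(c_m))
  source[m_ok & n_ok] <- ifelse(c_m[m_ok & n_ok] >= c_n[m_ok & n_ok],
                                "mem_dominant", "nomem_dominant")
  source[m_ok & !n_ok] <- "mem_only"
  source[!m_ok & n_ok] <- "nomem_only"
  use_mem <- source %in% c("mem_dominant", "mem_only")
  prediction <- rep(nc_label(), length(c_m))
  prediction[use_mem] <- stage_order[k_m[use_mem]]
  nom <- source %in% c("nomem_dominant", "nomem_only")
  prediction[nom] <- stage_order[k_n[nom]]

  data.frame(prediction = prediction,
             source = factor(source, levels = decision_sources()),
             conf_mem = c_m, conf_nomem = c_n,
             stringsAsFactors = FALSE)
}

#' Distribution of decision sources
#'
#' @param records Decision records from [combine_models()].
#' @return Named numeric vector of 5 fractions (summing to 1) over
#'   `mem_dominant`, `nomem_dominant`, `mem_only`, `nomem_only`,
#'   `not_classified`.
#' @export
decision_source_distribution <- function(records) {
  stopifnot(nrow(records) >= 1L)
  tab <- table(factor(records$source, levels = decision_sources()))
  as.numeric(tab) / nrow(records) -> out
  names(out) <- decision_sources()
  out
}

#' Ground-truth composition of NC epochs
#'
#' @param records Decision records aligned with `true_labels`.
#' @param true_labels Expert stage labels.
#' @param stages Stage set.
#' @return Named fractions of true stages among NC epochs (summing to 1),
#'   or an empty vector with attribute `flagged = TRUE` when no epoch was
#'   rejected.
#' @export
nc_composition <- function(records, true_labels, stages = sleep_stages()) {
  stopifnot(nrow(records) == length(true_labels))
  nc <- records$prediction == nc_label()
  if (!any(nc)) {
    out <- stats::setNames(numeric(0), character(0))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  tab <- table(factor(true_labels[nc], levels = stages))
  as.numeric(tab) / sum(nc) -> out
  names(out) <- stages
  out
}

#' Sweep the confidence threshold
#'
#' Recomputes the fused decisions at each threshold and reports accuracy
#' and Cohen's kappa over the classified (non-NC) epochs together with the
#' rejected fraction over all epochs. With `subject_ids` given (the
#' default reporting style), metrics are computed per subject and
#' averaged; otherwise they are pooled over epochs.
#'
#' @param p_mem,p_nomem Softmax matrices aligned with `true_labels`.
#' @param true_labels Expert stage labels.
#' @param thresholds Ascending numeric thresholds.
#' @param subject_ids Optional per-epoch subject identifiers for
#'   per-subject-then-average metrics.
#' @return data.frame with columns `threshold`, `accuracy`, `kappa`,
#'   `rejected_fraction` (`NA` metrics when every epoch is rejected).
#' @export
threshold_sweep <- function(p_mem, p_nomem, true_labels, thresholds,
                            subject_ids = NULL) {
  stopifnot(!is.unsorted(thresholds))
  rows <- lapply(thresholds, function(th) {
    rec <- combine_models(p_mem, p_nomem, threshold = th)
    rej <- mean(rec$prediction == nc_label())
    if (is.null(subject_ids)) {
      acc <- stage_accuracy(rec$prediction, true_labels)
      kap <- cohen_kappa(rec$prediction, true_labels)
    } else {
      per <- split(seq_along(true_labels), subject_ids)
      accs <- vapply(per, function(i)
        stage_accuracy(rec$prediction[i], true_labels[i]), numeric(1))
      kaps <- vapply(per, function(i)
        cohen_kappa(rec$prediction[i], true_labels[i]), numeric(1))
      acc <- mean(accs, na.rm = TRUE)
      kap <- mean(kaps, na.rm = TRUE)
      if (all(is.na(accs))) acc <- NA_real_
      if (all(is.na(kaps))) kap <- NA_real_
    }
    data.frame(threshold = th, accuracy = acc, kappa = kap,
               rejected_fraction = rej)
  })
  do.call(rbind, rows)
}
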