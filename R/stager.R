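# User-facing fitted-model surface: one call fits the transition matrix,
# the scaler and both FNNs; predict() runs the causal fused pipeline on a
# new subject.

#' Fit the hybrid sleep stager
#'
#' Trains the complete hybrid classifier on labeled epochs from one or
#' more subjects: the first-order transition matrix is estimated from the
#' hypnograms, the feature scaler from all feature rows, and two
#' feedforward networks are fitted — a no-memory model on the 37 EEG
#' features and a memory model on the features plus the transition vector
#' (computed from one-hot true previous labels at training time). At
#' prediction time the two are fused by the confidence rule with an NC
#' fallback.
#'
#' @param features Matrix or data.frame of the 37 epoch features (rows
#'   time-ordered within each subject, activity already z-scored within
#'   subject as in [study_features()]).
#' @param labels Stage labels aligned with the rows.
#' @param subjects Per-row subject identifiers (memory features never
#'   cross subject boundaries).
#' @param config An [fnn_config()].
#' @param threshold Fusion confidence threshold (default 0.7).
#' @param stage_order Ordered stage set.
#' @return Object of class `"sleep_stager"` with the fitted transition
#'   matrix, both models and the threshold.
#' @export
#' @examples
#' \donttest{
#' study <- generate_dataset(synthetic_study_config(
#'   n_subjects = 3, epochs_per_subject = 60, seed = 7))
#' feats <- study_features(study)
#' fit <- sleep_stager(feats[feature_names()], feats$label,
#'                     feats$subject_id,
#'                     config = fnn_config(max_epochs = 5))
#' print(fit)
#' }
sleep_stager <- function(features, labels, subjects,
                         config = fnn_config(), threshold = 0.7,
                         stage_order = sleep_stages()) {
  features <- as.matrix(features)
  labels <- check_stage_labels(labels, stage_order)
  subjects <- as.character(subjects)
  stopifnot(nrow(features) == length(labels),
            length(labels) == length(subjects))
  hypnograms <- split(labels, subjects)
  T_fit <- estimate_transition_matrix(hypnograms, stage_order)
  order_by_subject <- split(seq_along(labels), subjects)
  mem_inputs <- matrix(NA_real_, length(labels), length(stage_order))
  for (rows in order_by_subject) {
    mem_inputs[rows, ] <- assemble_memory_inputs_train(labels[rows], T_fit)
  }
  cfg_mem <- config; cfg_mem$seed <- config$seed + 1L
  structure(
    list(
      transition = T_fit,
      nomem = train_stage_model(features, labels, config,
                                stage_order = stage_order),
      mem = train_stage_model(features, labels, cfg_mem,
                              memory_inputs = mem_inputs,
                              stage_order = stage_order),
      threshold = threshold,
      stage_order = stage_order,
      n_train = nrow(features),
      n_subjects = length(hypnograms)
    ),
    class = "sleep_stager"
  )
}

#' @export
print.sleep_stager <- function(x, ...) {
  cat("<sleep_stager> hybrid confidence-fused stage classifier\n")
  cat(sprintf("  trained on %d epochs from %d subject(s); threshold %.2f\n",
              x$n_train, x$n_subjects, x$threshold))
  cat(sprintf("  no-memory net: best epoch %d (val loss %.4f)\n",
              x$nomem$net$best_epoch, x$nomem$net$val_loss))
  cat(sprintf("  memory net:    best epoch %d (val loss %.4f)\n",
              x$mem$net$best_epoch, x$mem$net$val_loss))
  invisible(x)
}

#' @export
summary.sleep_stager <- function(object, ...) {
  print(object)
  cat("\nFitted transition matrix:\n")
  print(object$transition)
  invisible(object)
}

#' Predict stages for one new subject
#'
#' Runs the full causal pipeline on a time-ordered feature matrix of one
#' held-out subject: no-memory probabilities, sequential memory
#' probabilities (transition vector from the previous *predicted*
#' distribution), and confidence-guided fusion with the NC fallback.
#'
#' @param object A `"sleep_stager"`.
#' @param newdata Time-ordered feature matrix (37 columns) of one subject.
#' @param threshold Optional override of the fitted threshold.
#' @param type `"decision"` (default: fused decision records) or `"prob"`
#'   (list with both probability matrices).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.sleep_stager <- function(object, newdata,
                                 threshold = object$threshold,
                                 type = c("decision", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  p_nomem <- predict(object$nomem, newdata)
  p_mem <- sequential_predict_memory(object$mem, newdata,
                                     object$transition)
  if (type == "prob") {
    return(list(p_mem = p_mem, p_nomem = p_nomem))
  }
  combine_models(p_mem, p_nomem, threshold = threshold,
                 stage_order = object$stage_order)
}

#' Simulate hypnograms from a fitted stager
#'
#' Draws stage-label sequences from the fitted first-order transition
#' matrix, starting in wake.
#'
#' @param object A `"sleep_stager"`.
#' @param nsim Number of hypnograms.
#' @param seed Optional integer seed.
#' @param n_epochs Length of each hypnogram.
#' @param ... Unused.
#' @return List of `nsim` stage-label sequences.
#' @export
simulate.sleep_stager <- function(object, nsim = 1, seed = NULL,
                                  n_epochs = 100L, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    simulate_hypnogram(object$transition, n_epochs, initial_stage = "W")
  })
}
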