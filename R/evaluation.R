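# Leave-one-subject-out evaluation: per-fold training of the paired
# models with training-subjects-only scaler and transition matrix,
# confidence-guided fusion, NC-excluded metrics, and permutation feature
# importance.

#' Leave-one-subject-out folds
#'
#' @param subject_ids Vector of unique subject identifiers (>= 2).
#' @return List of folds, each `list(train = ids, test = id)`.
#' @export
loso_split <- function(subject_ids) {
  subject_ids <- unique(as.character(subject_ids))
  if (length(subject_ids) < 2L) stop("need at least 2 subjects for LOSO")
  lapply(subject_ids, function(id) {
    list(train = setdiff(subject_ids, id), test = id)
  })
}

#' Accuracy over classified epochs
#'
#' NC predictions are excluded before scoring; `NA` when nothing remains.
#'
#' @param pred Predicted stages (possibly containing `"NC"`).
#' @param true True stages.
#' @return Fraction correct over non-NC epochs, or `NA_real_`.
#' @export
stage_accuracy <- function(pred, true) {
  stopifnot(length(pred) == length(true))
  keep <- pred != nc_label()
  if (!any(keep)) return(NA_real_)
  mean(pred[keep] == true[keep])
}

#' Cohen's kappa over classified epochs
#'
#' \deqn{\kappa = (p_o - p_e) / (1 - p_e)} with chance agreement
#' \eqn{p_e} from the product of the marginal label distributions. NC
#' epochs are excluded; `NA` when nothing remains or when \eqn{p_e = 1}
#' (a single class on both sides).
#'
#' @inheritParams stage_accuracy
#' @return Kappa, or `NA_real_` when undefined.
#' @export
cohen_kappa <- function(pred, true) {
  stopifnot(length(pred) == length(true))
  keep <- pred != nc_label()
  if (!any(keep)) return(NA_real_)
  pred <- pred[keep]; true <- true[keep]
  lev <- union(unique(pred), unique(true))
  p <- factor(pred, levels = lev); t <- factor(true, levels = lev)
  n <- length(p)
  po <- mean(pred == true)
  pe <- sum((table(p) / n) * (table(t) / n))
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Per-class F1 scores
#'
#' F1 = 2PR/(P+R) per stage over the classified epochs; a stage absent
#' from the true labels gets `NA`; a stage present but never correctly
#' predicted gets 0. The macro average is the unweighted mean over stages
#' present in the true labels.
#'
#' @inheritParams stage_accuracy
#' @param stages Stage set to report.
#' @return Named numeric of per-stage F1 plus `macro`.
#' @export
f1_per_class <- function(pred, true, stages = sleep_stages()) {
  stopifnot(length(pred) == length(true))
  keep <- pred != nc_label()
  pred <- pred[keep]; true <- true[keep]
  f1 <- vapply(stages, function(s) {
    tp <- sum(pred == s & true == s)
    fp <- sum(pred == s & true != s)
    fn <- sum(pred != s & true == s)
    if (tp + fn == 0L) return(NA_real_)  # class absent from truth
    if (tp == 0L) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  c(f1, macro = mean(f1, na.rm = TRUE))
}

# Internal: deterministic FNV-1a style checksum of numeric content,
# used for the no-leakage audit of fitted parameters.
param_checksum <- function(x) {
  s <- paste(format(unlist(x, use.names = FALSE), digits = 15),
             collapse = ",")
  h <- 0
  for (v in utf8ToInt(s)) {
    h <- (h * 31 + v) %% 2147483647  # polynomial rolling hash, 31-bit safe
  }
  sprintf("%08x", h)
}

#' Run the full LOSO evaluation
#'
#' For each fold: the feature scaler, the transition matrix and both FNN
#' models are fitted on the training subjects only; the held-out subject
#' is scored with the no-memory model and with strictly causal sequential
#' memory prediction; the two are fused at the confidence threshold; and
#' accuracy, kappa and per-class F1 are computed over the classified
#' epochs. Results are aggregated per subject (mean and standard error
#' `SD/sqrt(n)`) and also pooled over epochs.
#'
#' @param study An `"eeg_study"`.
#' @param config An [fnn_config()]; per-fold model seeds are derived from
#'   `config$seed`.
#' @param spec A [feature_spec()].
#' @param threshold Fusion confidence threshold (default 0.7).
#' @param features_df Optional precomputed [study_features()] table
#'   (with activity already z-scored); computed here when `NULL`.
#' @return Object of class `"loso_eval"`: per-fold results, aggregate
#'   means and standard errors, pooled metrics, decision-source
#'   distribution, NC composition, and per-fold scaler/T checksums.
#' @export
run_loso <- function(study, config = fnn_config(), spec = feature_spec(),
                     threshold = 0.7, features_df = NULL) {
  stopifnot(inherits(study, "eeg_study"), length(study) >= 2L)
  if (is.null(features_df)) features_df <- study_features(study, spec)
  ids <- vapply(study, `[[`, character(1), "subject_id")
  labels_by_subject <- stats::setNames(
    lapply(study, `[[`, "labels"), ids)
  fcols <- feature_names()
  folds <- loso_split(ids)
  fold_results <- vector("list", length(folds))
  pooled_records <- NULL
  pooled_true <- character(0)

  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    tr_rows <- features_df$subject_id %in% fold$train
    te_rows <- features_df$subject_id == fold$test
    Xtr <- as.matrix(features_df[tr_rows, fcols])
    ytr <- features_df$label[tr_rows]
    Xte <- as.matrix(features_df[te_rows, fcols])
    yte <- features_df$label[te_rows]
    if (length(yte) < 2L) {
      warning("fold ", fold$test, " skipped: fewer than 2 test epochs")
      next
    }
    T_fold <- estimate_transition_matrix(labels_by_subject[fold$train])
    mem_tr <- do.call(rbind, lapply(fold$train, function(id) {
      assemble_memory_inputs_train(labels_by_subject[[id]], T_fold)
    }))
    cfg_nomem <- config; cfg_nomem$seed <- config$seed + 2L * fi
    cfg_mem <- config; cfg_mem$seed <- config$seed + 2L * fi + 1L
    nomem <- train_stage_model(Xtr, ytr, cfg_nomem)
    mem <- train_stage_model(Xtr, ytr, cfg_mem, memory_inputs = mem_tr)

    p_nomem <- predict(nomem, Xte)
    p_mem <- sequential_predict_memory(mem, Xte, T_fold)
    rec <- combine_models(p_mem, p_nomem, threshold = threshold)

    fold_results[[fi]] <- list(
      test_subject = fold$test,
      decisions = rec,
      true_labels = yte,
      p_mem = p_mem,
      p_nomem = p_nomem,
      accuracy = stage_accuracy(rec$prediction, yte),
      kappa = cohen_kappa(rec$prediction, yte),
      f1 = f1_per_class(rec$prediction, yte),
      accuracy_nomem_norej =
        stage_accuracy(nomem$stage_order[max.col(p_nomem, "first")], yte),
      rejected_fraction = mean(rec$prediction == nc_label()),
      scaler_checksum = param_checksum(nomem$scaler),
      T_checksum = param_checksum(unclass(T_fold))
    )
    pooled_records <- rbind(pooled_records, rec)
    pooled_true <- c(pooled_true, yte)
  }
  fold_results <- Filter(Negate(is.null), fold_results)

  agg <- function(metric) {
    v <- vapply(fold_results, `[[`, numeric(1), metric)
    c(mean = mean(v, na.rm = TRUE),
      se = stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  }
  structure(
    list(
      folds = fold_results,
      threshold = threshold,
      accuracy = agg("accuracy"),
      kappa = agg("kappa"),
      accuracy_nomem_norej = agg("accuracy_nomem_norej"),
      rejected_fraction = agg("rejected_fraction"),
      f1 = {
        F <- do.call(rbind, lapply(fold_results, `[[`, "f1"))
        rbind(mean = colMeans(F, na.rm = TRUE),
              se = apply(F, 2L, function(c)
                stats::sd(c, na.rm = TRUE) / sqrt(sum(!is.na(c)))))
      },
      pooled = list(
        accuracy = stage_accuracy(pooled_records$prediction, pooled_true),
        kappa = cohen_kappa(pooled_records$prediction, pooled_true),
        f1 = f1_per_class(pooled_records$prediction, pooled_true)
      ),
      source_distribution = decision_source_distribution(pooled_records),
      nc_composition = nc_composition(pooled_records, pooled_true)
    ),
    class = "loso_eval"
  )
}

#' @export
print.loso_eval <- function(x, ...) {
  cat(sprintf("<loso_eval> %d folds, threshold %.2f\n",
              length(x$folds), x$threshold))
  cat(sprintf("  combined accuracy: %.3f +/- %.3f (per-subject mean +/- SE)\n",
              x$accuracy["mean"], x$accuracy["se"]))
  cat(sprintf("  combined kappa:    %.3f +/- %.3f\n",
              x$kappa["mean"], x$kappa["se"]))
  cat(sprintf("  no-memory (no rejection) accuracy: %.3f +/- %.3f\n",
              x$accuracy_nomem_norej["mean"], x$accuracy_nomem_norej["se"]))
  cat(sprintf("  rejected fraction: %.3f\n", x$rejected_fraction["mean"]))
  invisible(x)
}

#' Permutation feature importance
#'
#' Importance of feature j is the mean drop in (NC-free) accuracy of the
#' no-memory model when column j is randomly permuted, over `n_repeats`
#' seeded permutations. Normalized shares over the features with positive
#' importance are also reported.
#'
#' @param model A no-memory `"stager_fnn"`.
#' @param features Feature matrix (raw scale).
#' @param labels True stage labels.
#' @param n_repeats Permutations per feature (default 10).
#' @param seed Integer seed.
#' @return data.frame with `feature`, `importance`, `se`, `share`, sorted
#'   by decreasing importance.
#' @export
permutation_importance <- function(model, features, labels, n_repeats = 10L,
                                   seed = 1L) {
  stopifnot(inherits(model, "stager_fnn"), !model$memory_mode,
            n_repeats >= 1L)
  features <- as.matrix(features)
  labels <- check_stage_labels(labels, model$stage_order)
  base_pred <- model$stage_order[max.col(predict(model, features), "first")]
  base_acc <- mean(base_pred == labels)
  set.seed(seed)
  n <- nrow(features)
  drops <- matrix(NA_real_, ncol(features), n_repeats)
  for (j in seq_len(ncol(features))) {
    for (r in seq_len(n_repeats)) {
      xp <- features
      xp[, j] <- xp[sample.int(n), j]
      pred <- model$stage_order[max.col(predict(model, xp), "first")]
      drops[j, r] <- base_acc - mean(pred == labels)
    }
  }
  imp <- rowMeans(drops)
  se <- apply(drops, 1L, stats::sd) / sqrt(n_repeats)
  pos <- pmax(imp, 0)
  share <- if (sum(pos) > 0) pos / sum(pos) else pos
  out <- data.frame(feature = colnames(features), importance = imp,
                    se = se, share = share, stringsAsFactors = FALSE)
  out[order(-out$importance), ]
}
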