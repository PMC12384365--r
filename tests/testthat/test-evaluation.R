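# Metrics, LOSO orchestration, no-leakage audit and permutation
# importance.

test_that("LOSO folds cover every subject exactly once", {
  ids <- c("A", "B", "C")
  folds <- loso_split(ids)
  expect_length(folds, 3)
  tests <- vapply(folds, `[[`, character(1), "test")
  expect_setequal(tests, ids)
  for (f in folds) {
    expect_false(f$test %in% f$train)
    expect_setequal(c(f$train, f$test), ids)
  }
  expect_error(loso_split("A"), "2 subjects")
})

test_that("accuracy excludes NC epochs and handles the base cases", {
  expect_equal(stage_accuracy(c("W", "N1"), c("W", "N1")), 1)
  expect_equal(stage_accuracy(c("W", "N1"), c("N1", "W")), 0)
  expect_equal(stage_accuracy(c("W", "W", "W", "N1"),
                              c("W", "W", "W", "W")), 0.75)
  expect_equal(stage_accuracy(c("NC", "W"), c("N3", "W")), 1)
  expect_true(is.na(stage_accuracy(c("NC", "NC"), c("W", "N1"))))
})

test_that("kappa matches the printed 2x2 worked example", {
  # confusion counts [[40, 10], [20, 30]]: p_o = 0.7, p_e = 0.5
  pred <- c(rep("W", 40), rep("W", 10), rep("N1", 20), rep("N1", 30))
  true <- c(rep("W", 40), rep("N1", 10), rep("W", 20), rep("N1", 30))
  expect_equal(cohen_kappa(pred, true), 0.4)
})

test_that("kappa edge behavior is correct", {
  expect_equal(cohen_kappa(c("W", "N1", "N2"), c("W", "N1", "N2")), 1)
  expect_true(is.na(cohen_kappa(rep("W", 5), rep("W", 5))))  # p_e = 1
  set.seed(66)
  n <- 1e4
  pred <- sample(c("W", "N1"), n, replace = TRUE)
  true <- sample(c("W", "N1"), n, replace = TRUE)
  expect_lt(abs(cohen_kappa(pred, true)), 0.05)  # independent labels
})

test_that("per-class F1 handles perfect, missed and absent classes", {
  stages <- sleep_stages()
  f_perf <- f1_per_class(stages, stages, stages)
  expect_equal(unname(f_perf[stages]), rep(1, 5))
  f_miss <- f1_per_class(c("W", "W", "W"), c("W", "W", "N2"), stages)
  expect_equal(unname(f_miss["N2"]), 0)       # present, never predicted
  expect_true(is.na(f_miss["REM"]))           # absent from truth
})

test_that("metrics agree with confusion-matrix oracles on random instances", {
  stages <- sleep_stages()
  for (s in 1:20) {
    set.seed(s)
    n <- 100
    pred <- sample(stages, n, replace = TRUE)
    true <- sample(stages, n, replace = TRUE)
    orc <- oracle_confusion_metrics(pred, true, stages)
    expect_equal(stage_accuracy(pred, true), orc$accuracy)
    expect_equal(cohen_kappa(pred, true), orc$kappa)
    f1 <- f1_per_class(pred, true, stages)
    expect_equal(unname(f1[stages]), unname(orc$f1))
  }
})

test_that("NC epochs cannot influence the metrics", {
  pred <- c("W", "NC", "N1", "NC")
  true <- c("W", "N3", "N1", "REM")
  pred2 <- c("W", "NC", "N1", "NC")
  true2 <- c("W", "N1", "N1", "W")  # different truths under the NC slots
  expect_equal(stage_accuracy(pred, true), stage_accuracy(pred2, true2))
  expect_equal(cohen_kappa(pred, true), cohen_kappa(pred2, true2))
})

test_that("run_loso on separable emissions is accurate and deterministic", {
  study <- tiny_study(n_subjects = 4, epochs = 60, overlap = 0, seed = 17)
  cfg <- fnn_config(max_epochs = 15, seed = 9)
  ev <- suppressWarnings(run_loso(study, config = cfg))
  expect_s3_class(ev, "loso_eval")
  expect_length(ev$folds, 4)
  expect_gte(unname(ev$accuracy["mean"]), 0.95)

  ev2 <- suppressWarnings(run_loso(study, config = cfg))
  ev$folds <- lapply(ev$folds, function(f) f[setdiff(names(f), "decisions")])
  ev2$folds <- lapply(ev2$folds, function(f) f[setdiff(names(f), "decisions")])
  expect_equal(ev, ev2, tolerance = 1e-15)
})

test_that("fitted scaler and T are invariant to the held-out subject", {
  study <- tiny_study(n_subjects = 3, epochs = 40, seed = 23)
  cfg <- fnn_config(max_epochs = 3, seed = 2)
  ev <- suppressWarnings(run_loso(study, config = cfg))

  # perturb the held-out subject of fold 1 (subject S01) arbitrarily:
  # a nonlinear signal change and a different hypnogram
  perturbed <- study
  set.seed(99)
  perturbed[[1]]$epochs <- perturbed[[1]]$epochs +
    matrix(rnorm(length(perturbed[[1]]$epochs), sd = 10),
           nrow(perturbed[[1]]$epochs))
  perturbed[[1]]$labels <- sample(sleep_stages(),
                                  length(perturbed[[1]]$labels),
                                  replace = TRUE)
  ev_p <- suppressWarnings(run_loso(perturbed, config = cfg))

  f1 <- ev$folds[[1]]; f1p <- ev_p$folds[[1]]
  expect_equal(f1$test_subject, "S01")
  expect_identical(f1$scaler_checksum, f1p$scaler_checksum)
  expect_identical(f1$T_checksum, f1p$T_checksum)

  # sanity: folds that do train on S01 see different parameters
  expect_false(identical(ev$folds[[2]]$scaler_checksum,
                         ev_p$folds[[2]]$scaler_checksum))
  expect_false(identical(ev$folds[[2]]$T_checksum,
                         ev_p$folds[[2]]$T_checksum))
})

test_that("permutation importance flags informative features, not noise", {
  set.seed(31)
  n <- 400
  informative <- matrix(rnorm(n * 2), n)
  y <- ifelse(informative[, 1] + informative[, 2] > 0, "W", "N2")
  noise <- rnorm(n)
  X <- cbind(informative, noise)
  colnames(X) <- c("f1", "f2", "pure_noise")
  m <- suppressWarnings(
    train_stage_model(X, y, config = fnn_config(max_epochs = 30, seed = 6)))
  imp <- permutation_importance(m, X, y, n_repeats = 10, seed = 3)

  noise_row <- imp[imp$feature == "pure_noise", ]
  expect_lt(abs(noise_row$importance), 2 * max(noise_row$se, 1e-3))
  expect_gt(imp$importance[imp$feature == "f1"], 0.05)
  expect_gt(imp$importance[imp$feature == "f2"], 0.05)
  expect_equal(sum(imp$share), 1, tolerance = 1e-9)
  expect_true(all(imp$share >= 0))
})

test_that("sleep_stager fits, prints, predicts and simulates", {
  study <- tiny_study(n_subjects = 3, epochs = 50, seed = 41)
  feats <- study_features(study)
  fit <- suppressWarnings(
    sleep_stager(feats[feature_names()], feats$label, feats$subject_id,
                 config = fnn_config(max_epochs = 10, seed = 8)))
  expect_s3_class(fit, "sleep_stager")
  expect_output(print(fit), "hybrid confidence-fused")
  expect_output(summary(fit), "transition matrix")

  Xnew <- as.matrix(feats[feats$subject_id == "S02", feature_names()])
  dec <- predict(fit, Xnew)
  expect_equal(nrow(dec), nrow(Xnew))
  expect_true(all(dec$prediction %in% c(sleep_stages(), "NC")))
  probs <- predict(fit, Xnew, type = "prob")
  expect_equal(dim(probs$p_mem), c(nrow(Xnew), 5))

  sims <- simulate(fit, nsim = 2, seed = 5, n_epochs = 30)
  expect_length(sims, 2)
  expect_equal(sims[[1]][1], "W")
  expect_true(all(unlist(sims) %in% sleep_stages()))
})
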