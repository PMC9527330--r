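test_that("group combination maps 1 -> restricted, 2/3 -> generalized", {
  expect_equal(as.character(combine_groups(c(1, 2, 3, 1))),
               c("restricted", "generalized", "generalized", "restricted"))
  expect_true(all(combine_groups(rep(1, 5)) == "restricted"))
  g <- combine_groups(1:3)
  expect_setequal(which(g == "generalized"), 2:3)
  expect_error(combine_groups(c(1, 4)), "unknown group label")
})

test_that("feature rows count selected traces and carry age/pupil", {
  sim <- generate_cohort(4, wave = default_wave_params(n_repeats = 5L),
                         seed = 13)
  pr <- fferg:::process_traces(sim$traces)
  feats <- build_features(pr, sim$cohort)
  uni <- sum(table(sim$truth$eye$patient_id) == 1)
  ## 3 selected traces x eyes x 3 stimuli per patient
  expect_equal(nrow(feats$x), 3 * 3 * (2 * (4 - uni) + uni))
  expect_equal(ncol(feats$x), 163)
  expect_true(all(is.finite(feats$x)))
  ## missing age drops the patient with a message
  co <- sim$cohort; co$age_years[2] <- NA
  expect_message(f2 <- build_features(pr, co), "excluding 1 patient")
  expect_false(co$patient_id[2] %in% f2$meta$patient_id)
})

test_that("ensemble probability is the mean of the three calibrated base models", {
  fx <- separable_features(n_per_class = 8, seed = 2)
  m <- train_stimulus_ensemble(fx$features$x, fx$labels[fx$features$meta$patient_id])
  xs <- fferg:::apply_scaler(m$scaler, fx$features$x[1:10, ])
  p_mean <- (fferg:::lssvm_predict(m$svm, xs)[, m$classes] +
               fferg:::ada_predict(m$ada, xs)[, m$classes] +
               fferg:::lr_predict(m$lr, xs)[, m$classes]) / 3
  p <- predict_stimulus_ensemble(m, fx$features$x[1:10, ])
  expect_equal(unname(p), unname(p_mean / rowSums(p_mean)), tolerance = 1e-12)
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-9)
  expect_error(train_stimulus_ensemble(fx$features$x[1:5, ], rep(1, 5)),
               "single-class")
})

test_that("a linearly separable toy is fit to training accuracy 1", {
  withr::with_seed(4, {
    x <- rbind(matrix(rnorm(40 * 3), 40), matrix(rnorm(40 * 3, mean = 8), 40))
    y <- rep(c(1, 2), each = 40)
    m <- train_stimulus_ensemble(x, y)
    p <- predict_stimulus_ensemble(m, x)
    expect_equal(mean(m$classes[max.col(p)] == y), 1)
  })
})

test_that("probability aggregation averages within eye, then across eyes", {
  meta <- data.frame(patient_id = c("A", "A", "A", "B"),
                     eye = c("L", "L", "R", "R"),
                     stimulus = "DA10", stringsAsFactors = FALSE)
  probs <- rbind(c(1, 0, 0), c(0, 1, 0),   # A left eye -> (0.5, 0.5, 0)
                 c(0, 1, 0),               # A right eye
                 c(0.2, 0.3, 0.5))         # B single eye, no imputation
  agg <- aggregate_probs(meta, probs, patients = c("A", "B"))
  expect_equal(unname(agg$x["A", 1:3]), c(0.25, 0.75, 0))
  expect_equal(unname(agg$x["B", 1:3]), c(0.2, 0.3, 0.5))
  expect_false(any(agg$imputed[, "DA10"]))
  ## missing stimuli imputed uniform and flagged
  expect_true(all(agg$imputed[, c("LA3", "LA30Hz")]))
  expect_equal(unname(agg$x["A", 4:6]), rep(1 / 3, 3))
  ## identical eyes: patient value equals either eye
  meta2 <- data.frame(patient_id = "C", eye = c("L", "R"), stimulus = "DA10")
  p2 <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(unname(aggregate_probs(meta2, p2)$x[1, 1:3]), c(0.5, 0.5, 0))
})

test_that("nested CV is deterministic, leakage-free and learns a separable cohort", {
  fx <- separable_features(n_per_class = 12, seed = 6)
  cfg <- tiny_cv_config(seed = 3)
  rep1 <- run_nested_cv(fx$features, fx$labels, cfg, "3class")
  expect_gte(rep1$accuracy, 0.98)
  expect_equal(rowSums(rep1$confusion_normalized), rep(1, 3),
               tolerance = 1e-9, ignore_attr = TRUE)
  prob_cols <- as.matrix(rep1$predictions[, rep1$classes])
  expect_equal(rowSums(prob_cols), rep(1, nrow(prob_cols)), tolerance = 1e-9)
  ## determinism: same config and seed give an identical report
  rep2 <- run_nested_cv(fx$features, fx$labels, cfg, "3class")
  expect_identical(rep1$folds, rep2$folds)
  expect_identical(rep1$predictions, rep2$predictions)

  ## no leakage: permuting the labels of the held-out patients changes
  ## neither the fitted models nor the test predictions
  pats <- names(fx$labels)
  test_pat <- pats[1:8]; train_pat <- setdiff(pats, test_pat)
  labels <- factor(fx$labels, levels = 1:3)
  names(labels) <- pats
  f1 <- fferg:::fit_fold(fx$features, labels, train_pat, test_pat, cfg, 7L)
  lab_perm <- labels
  lab_perm[test_pat] <- withr::with_seed(1, sample(labels[test_pat]))
  f2 <- fferg:::fit_fold(fx$features, lab_perm, train_pat, test_pat, cfg, 7L)
  expect_identical(f1$final$alpha, f2$final$alpha)
  expect_identical(f1$ensembles$DA10$svm$alpha, f2$ensembles$DA10$svm$alpha)
  expect_identical(f1$test_pred, f2$test_pred)
  expect_identical(f1$test_prob, f2$test_prob)
})

test_that("permuted labels give chance-level accuracy", {
  fx <- separable_features(n_per_class = 12, seed = 9)
  labels <- withr::with_seed(2, stats::setNames(sample(fx$labels),
                                                names(fx$labels)))
  rep <- run_nested_cv(fx$features, labels, tiny_cv_config(seed = 5), "3class")
  se <- max(rep$accuracy_se, sqrt((1 / 3) * (2 / 3) / length(labels)))
  expect_lt(abs(rep$accuracy - 1 / 3), 3 * se)
})

test_that("binary mode reports sensitivity, specificity and AUC", {
  fx <- separable_features(n_per_class = 10, seed = 8)
  ## merge classes 2+3: still separable by age
  rep <- run_nested_cv(fx$features, fx$labels, tiny_cv_config(seed = 4),
                       "binary")
  expect_equal(rep$classes, c("restricted", "generalized"))
  expect_gte(rep$sensitivity, 0.9)
  expect_gte(rep$specificity, 0.9)
  expect_gte(rep$auc[["generalized"]], 0.95)
})

test_that("the soft vote is no worse than its best base model (soft check)", {
  sim <- generate_cohort(60, wave = default_wave_params(n_repeats = 3L),
                         seed = 44)
  feats <- build_features(fferg:::process_traces(sim$traces), sim$cohort)
  labels <- stats::setNames(sim$cohort$group_label, sim$cohort$patient_id)
  pats <- unique(feats$meta$patient_id)
  train_pat <- withr::with_seed(1, unlist(lapply(split(pats, labels[pats]),
                                                 function(p) sample(p, round(0.7 * length(p))))))
  test_rows <- !(feats$meta$patient_id %in% train_pat) &
    feats$meta$stimulus == "DA10"
  train_rows <- feats$meta$patient_id %in% train_pat &
    feats$meta$stimulus == "DA10"
  y_tr <- labels[feats$meta$patient_id[train_rows]]
  y_te <- labels[feats$meta$patient_id[test_rows]]
  m <- train_stimulus_ensemble(feats$x[train_rows, ], y_tr)
  xs <- fferg:::apply_scaler(m$scaler, feats$x[test_rows, ])
  acc <- function(p) mean(m$classes[max.col(p[, m$classes])] == y_te)
  base_acc <- c(acc(fferg:::lssvm_predict(m$svm, xs)),
                acc(fferg:::ada_predict(m$ada, xs)),
                acc(fferg:::lr_predict(m$lr, xs)))
  vote_acc <- acc(predict_stimulus_ensemble(m, feats$x[test_rows, ]))
  expect_gte(vote_acc, max(base_acc) - 0.02)
})

test_that("stratification failure raises a clear error", {
  fx <- separable_features(n_per_class = 3, seed = 10)
  expect_error(run_nested_cv(fx$features, fx$labels, tiny_cv_config(), "3class"),
               "patients per class")
})
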