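## Hierarchical soft-voting ensemble classification of the ERG phenotype
## groups, evaluated by repeated nested five-fold cross-validation with all
## traces of a patient kept in one fold.

#' Combine the three phenotype groups into binary labels
#'
#' Group 1 becomes `"restricted"` (disease confined to the macula); groups 2
#' and 3 become `"generalized"`.
#'
#' @param labels vector of group labels in \{1, 2, 3\}.
#' @return factor with levels `restricted`, `generalized`.
#' @export
combine_groups <- function(labels) {
  labels <- as.integer(as.character(labels))
  if (any(!labels %in% 1:3)) stopf("unknown group label")
  factor(ifelse(labels == 1, "restricted", "generalized"),
         levels = c("restricted", "generalized"))
}

#' Build single-trace classifier features
#'
#' One row per selected trace: the 161 standard-grid voltages plus patient
#' age and binary pupil class (163 features). Patients lacking age or pupil
#' metadata are excluded with a message. Standardization statistics are not
#' computed here: they are fitted on training folds only, inside the
#' cross-validation.
#'
#' @param selected processed trace structure (`measure_cohort()$selected` or
#'   the result of the internal `process_traces()`).
#' @param cohort cohort metadata table.
#' @return list with `meta` (patient, eye, stimulus, repeat per row) and `x`
#'   (numeric feature matrix).
#' @export
build_features <- function(selected, cohort) {
  idx <- selected$index
  keep_pat <- cohort$patient_id[!is.na(cohort$age_years) &
                                  !is.na(cohort$pupil_class)]
  drop <- setdiff(unique(idx$patient_id), keep_pat)
  if (length(drop))
    message(sprintf("excluding %d patient(s) with missing age/pupil: %s",
                    length(drop), paste(utils::head(drop, 5), collapse = ", ")))
  keep <- idx$patient_id %in% keep_pat
  idx <- idx[keep, , drop = FALSE]
  v <- selected$voltages[, keep, drop = FALSE]
  mi <- match(idx$patient_id, cohort$patient_id)
  x <- cbind(t(v),
             age_years = cohort$age_years[mi],
             pupil_small = as.numeric(cohort$pupil_class[mi] == "<7mm"))
  colnames(x) <- c(sprintf("v%03d", seq_len(nrow(selected$voltages))),
                   "age_years", "pupil_small")
  rownames(x) <- NULL
  list(meta = idx, x = x)
}

#' Train a per-stimulus soft-voting ensemble
#'
#' Fits the three base learners (RBF least-squares SVM, AdaBoost with
#' decision trees, logistic regression) on single-trace rows of one
#' stimulus. The ensemble probability is the arithmetic mean of the three
#' calibrated probability outputs.
#'
#' @param x feature matrix (unstandardized; a scaler is fitted internally).
#' @param y class labels (>= 2 classes required).
#' @param hp named list of hyperparameters:
#'   `svm = list(C, gamma)`, `ada = list(depth, n_estimators)`,
#'   `lr = list(C)`.
#' @param class_weights use inverse-frequency observation weights.
#' @return ensemble model object.
#' @export
train_stimulus_ensemble <- function(x, y,
                                    hp = list(svm = list(C = 1, gamma = "scale"),
                                              ada = list(depth = 1L,
                                                         n_estimators = 50L),
                                              lr = list(C = 1)),
                                    class_weights = FALSE) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stopf("single-class training set")
  scaler <- fit_scaler(x)
  xs <- apply_scaler(scaler, x)
  obs_w <- NULL
  if (isTRUE(class_weights)) {
    tab <- table(y)
    obs_w <- as.numeric(sum(tab) / (nlevels(y) * tab[y]))
  }
  structure(list(
    scaler = scaler, classes = levels(y),
    svm = lssvm_fit(xs, y, C = hp$svm$C, gamma = hp$svm$gamma, obs_w = obs_w),
    ada = ada_fit(xs, y, depth = hp$ada$depth,
                  n_estimators = hp$ada$n_estimators, obs_w = obs_w),
    lr = lr_fit(xs, y, C = hp$lr$C, obs_w = obs_w)),
    class = "fferg_ensemble")
}

#' Predict soft-vote probabilities from a stimulus ensemble
#'
#' @param model ensemble from [train_stimulus_ensemble()].
#' @param newx feature matrix.
#' @return probability matrix (rows sum to 1), the arithmetic mean of the
#'   three base-model probability outputs.
#' @export
predict_stimulus_ensemble <- function(model, newx) {
  xs <- apply_scaler(model$scaler, newx)
  p <- (lssvm_predict(model$svm, xs)[, model$classes] +
          ada_predict(model$ada, xs)[, model$classes] +
          lr_predict(model$lr, xs)[, model$classes]) / 3
  p / rowSums(p)
}

#' Aggregate per-trace probabilities into per-patient stimulus vectors
#'
#' Trace probabilities are averaged within each eye, then across available
#' eyes (single-eye patients use that eye alone, no imputation), per
#' stimulus; the per-stimulus class vectors are concatenated. A stimulus
#' with no traces for a patient is imputed with uniform probabilities and
#' flagged.
#'
#' @param meta trace metadata (patient_id, eye, stimulus rows).
#' @param probs matrix of per-trace class probabilities aligned with `meta`.
#' @param patients patient ids to produce rows for.
#' @param stimuli stimulus order (default the three standard stimuli).
#' @return list with `x` (patients x (stimuli * classes) matrix) and
#'   `imputed` (logical matrix patients x stimuli).
#' @export
aggregate_probs <- function(meta, probs, patients = unique(meta$patient_id),
                            stimuli = STIMULI) {
  K <- ncol(probs)
  out <- matrix(NA_real_, length(patients), length(stimuli) * K)
  imputed <- matrix(FALSE, length(patients), length(stimuli),
                    dimnames = list(patients, stimuli))
  for (si in seq_along(stimuli)) {
    st <- stimuli[si]
    sel <- meta$stimulus == st
    cols <- (si - 1) * K + seq_len(K)
    if (any(sel)) {
      ## mean over traces within eye
      eye_key <- paste(meta$patient_id[sel], meta$eye[sel], sep = "\r")
      eye_mean <- rowsum(probs[sel, , drop = FALSE], eye_key) /
        as.vector(table(eye_key)[sort(unique(eye_key))])
      ## mean over eyes within patient
      pat_of_eye <- sub("\r.*$", "", rownames(eye_mean))
      pat_mean <- rowsum(eye_mean, pat_of_eye) /
        as.vector(table(pat_of_eye)[sort(unique(pat_of_eye))])
      mi <- match(patients, rownames(pat_mean))
      out[, cols] <- pat_mean[mi, , drop = FALSE]
    }
    miss <- is.na(out[, cols[1]])
    if (any(miss)) {
      out[miss, cols] <- 1 / K
      imputed[miss, si] <- TRUE
    }
  }
  colnames(out) <- as.vector(outer(seq_len(K), stimuli,
                                   function(k, s) paste0(s, "_p", k)))
  rownames(out) <- patients
  list(x = out, imputed = imputed)
}

## expand a hyperparameter grid list into a list of combination lists
grid_combos <- function(grid) {
  dg <- expand.grid(grid, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(dg)), function(i) as.list(dg[i, , drop = FALSE]))
}

## parse gamma entries that may be "scale" or a numeric string
parse_gamma <- function(g) if (identical(g, "scale")) "scale" else as.numeric(g)

## Fit the hierarchy on one outer-training set (with an inner 80:20
## validation split for hyperparameter tuning) and predict the outer-test
## patients. Exposed for the leakage property test: nothing in the fit
## depends on test labels.
fit_fold <- function(features, labels, train_pat, test_pat, cfg,
                     inner_seed = 1L) {
  meta <- features$meta; x <- features$x
  classes <- levels(labels)
  K <- length(classes)
  ## inner split at patient level, stratified
  inner <- with_seed(inner_seed, {
    val <- unlist(lapply(split(train_pat, labels[train_pat]), function(p)
      sample(p, max(1, round(length(p) * cfg$cv$inner_frac)))))
    list(val = val, tr = setdiff(train_pat, val))
  })
  row_tr <- meta$patient_id %in% inner$tr
  row_val <- meta$patient_id %in% inner$val

  chosen <- list(); ens_inner <- list()
  for (st in STIMULI) {
    sel_tr <- row_tr & meta$stimulus == st
    sel_val <- row_val & meta$stimulus == st
    y_tr <- labels[meta$patient_id[sel_tr]]
    y_val <- labels[meta$patient_id[sel_val]]
    hp <- list(svm = NULL, ada = NULL, lr = NULL)
    for (learner in c("svm", "ada", "lr")) {
      combos <- grid_combos(cfg$grids[[learner]])
      if (learner == "svm")
        combos <- lapply(combos, function(cb) {
          cb$gamma <- parse_gamma(cb$gamma); cb })
      if (length(combos) == 1) { hp[[learner]] <- combos[[1]]; next }
      acc <- vapply(combos, function(cb) {
        m <- fit_one_learner(learner, x[sel_tr, , drop = FALSE], y_tr, cb,
                             cfg$class_weights)
        p <- predict_one_learner(learner, m, x[sel_val, , drop = FALSE])
        mean(colnames(p)[max.col(p, ties.method = "first")] == y_val)
      }, numeric(1))
      hp[[learner]] <- combos[[which.max(acc)]]
    }
    chosen[[st]] <- hp
    ens_inner[[st]] <- train_stimulus_ensemble(x[sel_tr, , drop = FALSE],
                                               y_tr, hp, cfg$class_weights)
  }

  ## tune final SVM C on inner-validation patient-level accuracy
  final_grid <- cfg$grids$final_svm$C
  if (length(final_grid) > 1) {
    probs_all <- ensemble_trace_probs(ens_inner, meta, x,
                                      row_tr | row_val, classes)
    agg_tr <- aggregate_probs(meta[probs_all$rows & row_tr, , drop = FALSE],
                              probs_all$p[row_tr[probs_all$rows], , drop = FALSE],
                              inner$tr)
    agg_val <- aggregate_probs(meta[probs_all$rows & row_val, , drop = FALSE],
                               probs_all$p[row_val[probs_all$rows], , drop = FALSE],
                               inner$val)
    acc <- vapply(final_grid, function(C) {
      m <- lssvm_fit(agg_tr$x, labels[inner$tr], C = C, gamma = "scale")
      p <- lssvm_predict(m, agg_val$x)
      mean(colnames(p)[max.col(p, ties.method = "first")] ==
             labels[inner$val])
    }, numeric(1))
    final_C <- final_grid[which.max(acc)]
  } else final_C <- final_grid

  ## refit on the full outer-training set with the chosen hyperparameters
  row_train <- meta$patient_id %in% train_pat
  ens <- list()
  for (st in STIMULI) {
    sel <- row_train & meta$stimulus == st
    ens[[st]] <- train_stimulus_ensemble(x[sel, , drop = FALSE],
                                         labels[meta$patient_id[sel]],
                                         chosen[[st]], cfg$class_weights)
  }
  ptr <- ensemble_trace_probs(ens, meta, x, row_train, classes)
  agg_train <- aggregate_probs(meta[ptr$rows, , drop = FALSE], ptr$p, train_pat)
  final <- lssvm_fit(agg_train$x, labels[train_pat], C = final_C,
                     gamma = "scale")

  row_test <- meta$patient_id %in% test_pat
  pte <- ensemble_trace_probs(ens, meta, x, row_test, classes)
  agg_test <- aggregate_probs(meta[pte$rows, , drop = FALSE], pte$p, test_pat)
  prob_test <- lssvm_predict(final, agg_test$x)[, classes, drop = FALSE]

  list(ensembles = ens, final = final, chosen = chosen, final_C = final_C,
       test_prob = prob_test,
       test_pred = classes[max.col(prob_test, ties.method = "first")])
}

## per-trace soft-vote probabilities for the rows selected by `rows`
ensemble_trace_probs <- function(ens, meta, x, rows, classes) {
  p <- matrix(NA_real_, sum(rows), length(classes),
              dimnames = list(NULL, classes))
  sub <- which(rows)
  for (st in STIMULI) {
    sel <- meta$stimulus[sub] == st
    if (any(sel))
      p[sel, ] <- predict_stimulus_ensemble(ens[[st]],
                                            x[sub[sel], , drop = FALSE])[, classes]
  }
  list(p = p, rows = rows)
}

#' Repeated nested cross-validated evaluation of the ensemble
#'
#' Outer stratified five-fold split at the patient level (all traces of a
#' patient stay together); an inner stratified 80:20 split of each outer
#' training set (64:16:20 overall) tunes hyperparameters on validation
#' accuracy only; stimulus ensembles and the final SVM are refitted on the
#' full outer-training set and metrics are computed on the untouched outer
#' test folds, repeated with different fold seeds.
#'
#' @param features feature set from [build_features()].
#' @param labels named vector/factor of patient labels (names = patient_id);
#'   groups 1-3, or any 2-level factor in binary mode.
#' @param cfg configuration ([default_config()]); `cfg$cv$repeats`,
#'   `cfg$cv$folds` and the hyperparameter grids apply.
#' @param mode `"3class"` or `"binary"` (groups 2 and 3 merged).
#' @return a `fferg_cv_report` list: per-(repeat, fold) accuracies, mean
#'   accuracy and its standard error, per-class accuracy, row-normalized
#'   confusion matrix, Cohen's kappa, one-vs-rest AUCs, binary
#'   sensitivity/specificity, and pooled per-patient predictions.
#' @export
run_nested_cv <- function(features, labels, cfg = default_config(),
                          mode = c("3class", "binary")) {
  mode <- match.arg(mode)
  patients <- intersect(names(labels), unique(features$meta$patient_id))
  labels <- labels[patients]
  if (mode == "binary" && !is.factor(labels)) {
    labels <- combine_groups(labels)
    names(labels) <- patients
  }
  labels <- droplevels(as.factor(labels))
  if (min(table(labels)) < cfg$cv$folds)
    stopf("need >= %d patients per class for stratified %d-fold CV",
          cfg$cv$folds, cfg$cv$folds)
  classes <- levels(labels)
  K <- length(classes)

  fold_rows <- list(); preds <- list()
  for (r in seq_len(cfg$cv$repeats)) {
    folds <- with_seed(derive_seed(cfg$seed, 100 + r),
                       stratified_folds(as.character(labels), cfg$cv$folds))
    for (f in seq_len(cfg$cv$folds)) {
      test_pat <- patients[folds == f]
      train_pat <- patients[folds != f]
      fit <- fit_fold(features, labels, train_pat, test_pat, cfg,
                      inner_seed = derive_seed(cfg$seed, 1000 * r + f))
      acc <- mean(fit$test_pred == as.character(labels[test_pat]))
      fold_rows[[length(fold_rows) + 1]] <-
        data.frame(repeat_ = r, fold = f, accuracy = acc)
      preds[[length(preds) + 1]] <- data.frame(
        patient_id = test_pat, repeat_ = r, fold = f,
        truth = as.character(labels[test_pat]), predicted = fit$test_pred,
        fit$test_prob, stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  folds_df <- do.call(rbind, fold_rows)
  pred_df <- do.call(rbind, c(preds, list(make.row.names = FALSE)))

  cm <- confusion_matrix(pred_df$truth, pred_df$predicted, classes)
  auc <- ovr_auc(pred_df$truth,
                 as.matrix(pred_df[, classes, drop = FALSE]))
  rep_list <- list(
    mode = mode, classes = classes,
    folds = folds_df,
    accuracy = mean(folds_df$accuracy),
    accuracy_se = stats::sd(folds_df$accuracy) / sqrt(nrow(folds_df)),
    confusion = cm$counts,
    confusion_normalized = cm$normalized,
    per_class_accuracy = diag(cm$normalized),
    kappa = cohen_kappa(cm$counts),
    auc = auc,
    predictions = pred_df)
  if (mode == "binary") {
    pos <- "generalized"
    tp <- sum(pred_df$truth == pos & pred_df$predicted == pos)
    fn <- sum(pred_df$truth == pos & pred_df$predicted != pos)
    tn <- sum(pred_df$truth != pos & pred_df$predicted != pos)
    fp <- sum(pred_df$truth != pos & pred_df$predicted == pos)
    rep_list$sensitivity <- tp / (tp + fn)
    rep_list$specificity <- tn / (tn + fp)
  }
  structure(rep_list, class = "fferg_cv_report")
}

#' @export
print.fferg_cv_report <- function(x, ...) {
  cat(sprintf("Nested CV report (%s): accuracy %.3f (SE %.4f), kappa %.3f\n",
              x$mode, x$accuracy, x$accuracy_se, x$kappa))
  cat("Row-normalized confusion matrix:\n")
  print(round(x$confusion_normalized, 3))
  if (!is.null(x$sensitivity))
    cat(sprintf("sensitivity %.3f, specificity %.3f\n",
                x$sensitivity, x$specificity))
  invisible(x)
}
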