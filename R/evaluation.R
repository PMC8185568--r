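#' Three-class confusion matrix
#'
#' Rows are true classes, columns predicted, both in the fixed order FOG,
#' STOP, WALK.
#'
#' @param truth,pred Vectors (factor or character) over the three classes.
#' @return 3 x 3 integer matrix of class `fog_confusion`.
#' @export
confusion_matrix3 <- function(truth, pred) {
  t_f <- factor(as.character(truth), levels = FOG_CLASSES)
  p_f <- factor(as.character(pred), levels = FOG_CLASSES)
  if (anyNA(t_f) || anyNA(p_f)) stop("labels outside {FOG, STOP, WALK}")
  cm <- table(truth = t_f, predicted = p_f)
  structure(matrix(as.integer(cm), 3, 3,
                   dimnames = list(truth = FOG_CLASSES,
                                   predicted = FOG_CLASSES)),
            class = "fog_confusion")
}

#' @export
print.fog_confusion <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

.as_cm <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (!all(dim(cm) == c(3, 3)) || any(cm < 0))
    stop("confusion matrix must be 3 x 3 with nonnegative counts")
  dimnames(cm) <- list(truth = FOG_CLASSES, predicted = FOG_CLASSES)
  cm
}

#' One-vs-rest sensitivity and specificity
#'
#' For the positive class (FoG by default): sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP), with the remaining two classes pooled as
#' negative. A zero denominator yields `NA` (reported as undefined, never
#' coerced to 0).
#'
#' @param cm A 3 x 3 confusion matrix (rows truth, columns predicted, in
#'   FOG/STOP/WALK order).
#' @param positive Positive class (default `"FOG"`).
#' @return Named numeric vector `c(sensitivity =, specificity =)`.
#' @examples
#' cm <- matrix(c(8, 2, 0, 1, 7, 0, 1, 1, 10), 3, 3)  # by column
#' sensitivity_specificity(cm)  # 0.8, 0.9
#' @export
sensitivity_specificity <- function(cm, positive = "FOG") {
  cm <- .as_cm(cm)
  i <- match(positive, FOG_CLASSES)
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' One-vs-rest F-score
#'
#' F1 = 2 * precision * recall / (precision + recall) for the positive
#' class; `macro = TRUE` returns the unweighted mean of the three
#' per-class F1 values. F1 is 0 when the class occurs but collects no
#' true positives, and `NA` (undefined, never coerced to 0) when the
#' class appears in neither the truth nor the predictions.
#'
#' @param cm A 3 x 3 confusion matrix.
#' @param positive Positive class (default `"FOG"`); ignored when
#'   `macro = TRUE`.
#' @param macro Return the macro average over all three classes.
#' @return F-score in `[0, 1]`, or `NA` when undefined.
#' @export
f_score <- function(cm, positive = "FOG", macro = FALSE) {
  cm <- .as_cm(cm)
  f1_of <- function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    if (tp + fn + fp == 0) return(NA_real_)  # class entirely absent
    if (tp == 0) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }
  if (macro) mean(vapply(seq_len(3), f1_of, numeric(1)))
  else f1_of(match(positive, FOG_CLASSES))
}

.fold_metrics <- function(cm) {
  ss <- sensitivity_specificity(cm)
  c(ss, f1_fog = f_score(cm), f1_macro = f_score(cm, macro = TRUE))
}

.make_report <- function(folds, scheme, seed, assignment) {
  pooled <- Reduce(`+`, lapply(folds, `[[`, "cm"))
  per_fold <- do.call(rbind, lapply(folds, function(f) {
    data.frame(fold = f$fold, n = sum(f$cm), t(.fold_metrics(f$cm)))
  }))
  predictions <- do.call(rbind, lapply(folds, `[[`, "predictions"))
  predictions <- predictions[order(predictions$index), ]
  rownames(predictions) <- NULL
  structure(
    list(scheme = scheme, seed = seed,
         folds = folds,
         per_fold = per_fold,
         predictions = predictions,
         pooled_cm = structure(pooled, class = "fog_confusion"),
         pooled = .fold_metrics(pooled),
         averaged = colMeans(per_fold[, -(1:2)], na.rm = TRUE),
         assignment = assignment),
    class = "fog_eval")
}

#' @export
print.fog_eval <- function(x, ...) {
  cat(sprintf("Cross-validation report (%s, %d folds, seed %d)\n",
              x$scheme, nrow(x$per_fold), x$seed))
  cat("pooled confusion matrix:\n")
  print(x$pooled_cm)
  cat(sprintf("pooled:   sensitivity %.3f  specificity %.3f  FoG F1 %.3f  macro F1 %.3f\n",
              x$pooled["sensitivity"], x$pooled["specificity"],
              x$pooled["f1_fog"], x$pooled["f1_macro"]))
  cat(sprintf("averaged: sensitivity %.3f  specificity %.3f  FoG F1 %.3f  macro F1 %.3f\n",
              x$averaged["sensitivity"], x$averaged["specificity"],
              x$averaged["f1_fog"], x$averaged["f1_macro"]))
  invisible(x)
}

# Run one train/test fold with any trainer: trainer(train_windows, seed)
# must return an object whose predict(model, test_windows) yields labels.
.run_fold <- function(windows, tr_i, te_i, trainer, seed, fold_id) {
  fit <- trainer(windows[tr_i], seed)
  pred <- stats::predict(fit, windows[te_i])
  list(fold = fold_id,
       cm = unclass(confusion_matrix3(windows$label[te_i], pred)),
       predictions = data.frame(index = te_i,
                                subject = windows$subject[te_i],
                                truth = as.character(windows$label[te_i]),
                                pred = as.character(pred)))
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the fold's test set is every window of that
#' subject, the training set everything else, so generalization to unseen
#' patients is measured. Aggregate metrics are computed from the pooled
#' confusion matrix; per-fold (= per-subject) metrics are reported
#' alongside, and fold averages as well, since small per-subject test
#' sets can make individual metrics undefined.
#'
#' @param windows A `fog_windows` dataset with at least two subjects.
#' @param trainer Function `(train_windows, seed) -> model` where the
#'   model has a `predict(model, windows)` method returning labels; see
#'   [cnn_trainer] and [baseline_trainer].
#' @param seed Integer seed forwarded to the trainer in every fold.
#' @return A `fog_eval` report.
#' @export
loso_cv <- function(windows, trainer, seed = 1L) {
  stopifnot(inherits(windows, "fog_windows"))
  subjects <- unique(windows$subject)
  if (length(subjects) < 2L) stop("LOSO needs at least two subjects")
  empty <- subjects[vapply(subjects,
                           function(s) sum(windows$subject == s) == 0L,
                           logical(1))]
  if (length(empty)) stop("subject(s) with zero windows: ",
                          paste(empty, collapse = ", "))
  folds <- vector("list", length(subjects))
  assignment <- data.frame(index = seq_along(windows$label),
                           subject = windows$subject,
                           fold = match(windows$subject, subjects))
  for (k in seq_along(subjects)) {
    te_i <- which(windows$subject == subjects[k])
    tr_i <- which(windows$subject != subjects[k])
    folds[[k]] <- .run_fold(windows, tr_i, te_i, trainer, seed,
                            subjects[k])
  }
  rep <- .make_report(folds, "loso", as.integer(seed), assignment)
  rep$per_subject <- rep$per_fold
  names(rep$per_subject)[1] <- "subject"
  rep
}

#' Shuffled k-fold cross-validation
#'
#' Windows are shuffled and split into `k` folds whose sizes differ by at
#' most one, ignoring subject identity (window-level splitting; note that
#' overlapping windows of one subject can then appear on both sides of a
#' fold). `stratify_subjects = TRUE` switches to a subject-level split:
#' whole subjects are assigned to folds, avoiding that leakage.
#'
#' @param windows A `fog_windows` dataset.
#' @param trainer As in [loso_cv].
#' @param k Number of folds (default 10).
#' @param seed Integer seed fixing the shuffle and forwarded to the
#'   trainer.
#' @param stratify_subjects Split by subject instead of by window.
#' @return A `fog_eval` report.
#' @export
kfold_cv <- function(windows, trainer, k = 10L, seed = 1L,
                     stratify_subjects = FALSE) {
  stopifnot(inherits(windows, "fog_windows"))
  n <- length(windows$label)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of windows")
  set.seed(seed)
  if (stratify_subjects) {
    subjects <- unique(windows$subject)
    if (k > length(subjects)) stop("k exceeds the number of subjects")
    sf <- rep_len(seq_len(k), length(subjects))[sample.int(length(subjects))]
    fold_of <- sf[match(windows$subject, subjects)]
  } else {
    fold_of <- rep_len(seq_len(k), n)[sample.int(n)]
  }
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    te_i <- which(fold_of == f)
    tr_i <- which(fold_of != f)
    folds[[f]] <- .run_fold(windows, tr_i, te_i, trainer, seed, f)
  }
  .make_report(folds, if (stratify_subjects) "kfold-subject" else "kfold",
               as.integer(seed),
               data.frame(index = seq_len(n), subject = windows$subject,
                          fold = fold_of))
}

#' Fold trainers for cross-validation
#'
#' Convenience factories producing the `trainer` callable expected by
#' [loso_cv] and [kfold_cv]: `cnn_trainer` wraps [fog_cnn],
#' `baseline_trainer` wraps [fog_baseline], `majority_trainer` returns a
#' dummy model that always predicts the majority training class (a floor
#' for any informative classifier).
#'
#' @param config,control Passed to [fog_cnn].
#' @param kind Passed to [fog_baseline].
#' @return A function `(windows, seed) -> fitted model`.
#' @export
cnn_trainer <- function(config = model_config(), control = train_control()) {
  force(config); force(control)
  function(windows, seed) {
    control$seed <- as.integer(seed)
    fog_cnn(windows, config = config, control = control)
  }
}

#' @rdname cnn_trainer
#' @export
baseline_trainer <- function(kind = "decision_tree") {
  force(kind)
  function(windows, seed) fog_baseline(windows, kind = kind, seed = seed)
}

#' @rdname cnn_trainer
#' @export
majority_trainer <- function() {
  function(windows, seed) {
    tab <- table(factor(windows$label, levels = FOG_CLASSES))
    structure(list(label = names(tab)[which.max(tab)]),
              class = "fog_majority")
  }
}

#' @export
predict.fog_majority <- function(object, newdata, ...) {
  n <- if (inherits(newdata, "fog_windows")) length(newdata$label)
  else dim(newdata)[1]
  factor(rep(object$label, n), levels = FOG_CLASSES)
}

#' Export a cross-validation report
#'
#' Writes the report as machine-readable JSON, a human-readable Markdown
#' table, and the fold-assignment CSV, under a common file stem.
#'
#' @param report A `fog_eval` from [loso_cv] or [kfold_cv].
#' @param stem Output path stem; `<stem>.json`, `<stem>.md` and
#'   `<stem>_folds.csv` are written.
#' @return Invisibly, the vector of written paths.
#' @export
write_eval_report <- function(report, stem) {
  stopifnot(inherits(report, "fog_eval"))
  paths <- paste0(stem, c(".json", ".md", "_folds.csv"))
  payload <- list(
    scheme = report$scheme, seed = report$seed,
    pooled_confusion = unclass(report$pooled_cm),
    pooled = as.list(report$pooled),
    averaged = as.list(report$averaged),
    per_fold = report$per_fold)
  jsonlite::write_json(payload, paths[1], auto_unbox = TRUE, digits = NA,
                       na = "null")
  md <- c(sprintf("# Cross-validation report (%s)", report$scheme), "",
          sprintf("Seed: %d. Pooled: sensitivity %.3f, specificity %.3f, FoG F1 %.3f, macro F1 %.3f.",
                  report$seed, report$pooled["sensitivity"],
                  report$pooled["specificity"], report$pooled["f1_fog"],
                  report$pooled["f1_macro"]), "",
          "| fold | n | sensitivity | specificity | FoG F1 | macro F1 |",
          "|---|---|---|---|---|---|",
          apply(report$per_fold, 1, function(r)
            sprintf("| %s | %s | %.3f | %.3f | %.3f | %.3f |",
                    r[1], r[2], as.numeric(r[3]), as.numeric(r[4]),
                    as.numeric(r[5]), as.numeric(r[6]))))
  writeLines(md, paths[2])
  utils::write.csv(report$assignment, paths[3], row.names = FALSE)
  invisible(paths)
}
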