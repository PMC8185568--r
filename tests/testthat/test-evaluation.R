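# Hand-computed reference: rows = truth (FOG, STOP, WALK).
# TP = 8, FN = 2, FP = 2, TN = 18 -> sens 0.8, spec 0.9, F1 0.8.
hand_cm <- matrix(c(8, 1, 1,
                    2, 7, 1,
                    0, 0, 10), nrow = 3, byrow = TRUE)

test_that("sensitivity and specificity match hand computation", {
  ss <- sensitivity_specificity(hand_cm)
  expect_equal(unname(ss["sensitivity"]), 0.8)
  expect_equal(unname(ss["specificity"]), 0.9)

  perfect <- diag(c(5, 5, 5))
  expect_equal(unname(sensitivity_specificity(perfect)),
               c(1, 1))

  no_fog <- matrix(c(0, 0, 0, 1, 7, 1, 0, 0, 10), 3, byrow = TRUE)
  ss2 <- sensitivity_specificity(no_fog)
  expect_true(is.na(ss2["sensitivity"]))
  expect_false(is.na(ss2["specificity"]))
})

test_that("F-scores match hand computation and degenerate cases", {
  expect_equal(f_score(hand_cm), 0.8)
  expect_equal(f_score(diag(c(3, 3, 3))), 1.0)
  expect_equal(f_score(diag(c(3, 3, 3)), macro = TRUE), 1.0)
  # every FOG window predicted STOP -> FoG F1 = 0
  all_wrong <- matrix(c(0, 10, 0, 0, 5, 0, 0, 0, 5), 3, byrow = TRUE)
  expect_equal(f_score(all_wrong), 0)
  # macro variant averages the three one-vs-rest scores
  f_each <- vapply(c("FOG", "STOP", "WALK"),
                   function(cl) f_score(hand_cm, positive = cl),
                   numeric(1))
  expect_equal(f_score(hand_cm, macro = TRUE), mean(f_each))
})

test_that("confusion matrices count all windows in fixed class order", {
  truth <- c("FOG", "FOG", "STOP", "WALK", "WALK")
  pred <- c("FOG", "STOP", "STOP", "WALK", "FOG")
  cm <- confusion_matrix3(truth, pred)
  expect_equal(sum(cm), 5)
  expect_equal(rownames(cm), c("FOG", "STOP", "WALK"))
  expect_equal(cm["FOG", "STOP"], 1L)
  expect_equal(cm["WALK", "FOG"], 1L)
  expect_error(confusion_matrix3(c("FOG", "RUN"), c("FOG", "FOG")),
               "outside")
})

test_that("LOSO folds partition windows by subject", {
  coh <- tiny_cohort(n_subjects = 3, session_s = 30, seed = 4)
  ws <- build_windows(coh$recordings, coh$tracks, verbose = FALSE)
  rep <- loso_cv(ws, majority_trainer(), seed = 1)
  expect_equal(nrow(rep$per_fold), 3)
  # each fold's test subjects are singletons and disjoint
  folds <- split(rep$assignment$subject, rep$assignment$fold)
  expect_true(all(vapply(folds, function(s) length(unique(s)) == 1,
                         logical(1))))
  expect_equal(sort(unname(vapply(folds, function(s) s[1], character(1)))),
               sort(unique(ws$subject)))
  # pooled confusion totals all windows
  expect_equal(sum(rep$pooled_cm), length(ws$label))
  # majority dummy never predicts the minority FOG class
  if (sum(ws$label == "FOG") > 0 &&
      names(which.max(table(ws$label))) != "FOG")
    expect_equal(unname(rep$pooled["sensitivity"]), 0)
  expect_error(loso_cv(ws[ws$subject == "S01"], majority_trainer()),
               "two subjects")
})

test_that("k-fold splits are balanced, seeded, and exhaustive", {
  tw <- tone_windows(n_per_class = 35, seed = 2)  # 105 windows
  ws <- structure(list(data = tw$data[1:103, , , drop = FALSE],
                       label = tw$labels[1:103],
                       subject = rep(c("A", "B"), length.out = 103),
                       start_index = 1:103,
                       config = window_config(), scales = rep(1, 6),
                       fog_rule = "overlap"),
                  class = "fog_windows")
  r1 <- kfold_cv(ws, majority_trainer(), k = 10, seed = 5)
  sizes <- table(r1$assignment$fold)
  expect_equal(sort(unique(as.integer(sizes))), c(10L, 11L))
  expect_equal(as.integer(sum(sizes)), 103L)
  expect_lte(max(sizes) - min(sizes), 1)
  r2 <- kfold_cv(ws, majority_trainer(), k = 10, seed = 5)
  expect_identical(r1$assignment, r2$assignment)
  # union of test folds is the dataset, pairwise disjoint by construction
  expect_setequal(r1$assignment$index, 1:103)
  expect_error(kfold_cv(ws, majority_trainer(), k = 1), ">= 2")
  # subject-stratified variant keeps whole subjects in one fold
  r3 <- kfold_cv(ws, majority_trainer(), k = 2, seed = 1,
                 stratify_subjects = TRUE)
  by_subj <- table(r3$assignment$subject, r3$assignment$fold)
  expect_true(all(rowSums(by_subj > 0) == 1))
})

test_that("reported metrics are recomputable from stored confusions", {
  coh <- tiny_cohort(n_subjects = 2, session_s = 30, seed = 6)
  ws <- build_windows(coh$recordings, coh$tracks, verbose = FALSE)
  rep <- loso_cv(ws, majority_trainer(), seed = 1)
  pooled <- Reduce(`+`, lapply(rep$folds, `[[`, "cm"))
  expect_equal(unclass(rep$pooled_cm), pooled)
  ss <- sensitivity_specificity(pooled)
  expect_equal(rep$pooled[["sensitivity"]], ss[["sensitivity"]])
  expect_equal(rep$pooled[["f1_fog"]], f_score(pooled))
  for (f in rep$folds) {
    row <- rep$per_fold[rep$per_fold$fold == f$fold, ]
    expect_equal(row$sensitivity,
                 sensitivity_specificity(f$cm)[["sensitivity"]])
  }
})

test_that("uniform random prediction yields chance-level sensitivity", {
  random_trainer <- function() {
    function(windows, seed) structure(list(seed = seed),
                                      class = "unif_model")
  }
  assign("predict.unif_model",
         function(object, newdata, ...) {
           n <- length(newdata$label)
           set.seed(object$seed)
           factor(sample(c("FOG", "STOP", "WALK"), n, TRUE),
                  levels = c("FOG", "STOP", "WALK"))
         }, envir = globalenv())
  on.exit(rm("predict.unif_model", envir = globalenv()))
  tw <- tone_windows(n_per_class = 60, seed = 3)
  ws <- structure(list(data = tw$data, label = tw$labels,
                       subject = rep(c("A", "B", "C"),
                                     length.out = length(tw$labels)),
                       start_index = seq_along(tw$labels),
                       config = window_config(), scales = rep(1, 6),
                       fog_rule = "overlap"),
                  class = "fog_windows")
  rep <- loso_cv(ws, random_trainer(), seed = 9)
  # 60 FoG windows, p = 1/3: 3 binomial SD ~ 0.18
  expect_lt(abs(rep$pooled[["sensitivity"]] - 1 / 3), 0.19)
})

test_that("evaluation reports export to JSON, Markdown and CSV", {
  coh <- tiny_cohort(n_subjects = 2, session_s = 30, seed = 8)
  ws <- build_windows(coh$recordings, coh$tracks, verbose = FALSE)
  rep <- loso_cv(ws, majority_trainer(), seed = 1)
  d <- withr::local_tempdir()
  paths <- write_eval_report(rep, file.path(d, "rep"))
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[1], simplifyVector = TRUE)
  expect_equal(js$scheme, "loso")
  expect_equal(js$pooled$sensitivity, rep$pooled[["sensitivity"]])
  folds_csv <- read.csv(paths[3])
  expect_equal(nrow(folds_csv), length(ws$label))
})
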