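# Evaluation protocol: subject-level 80/20 split with the study's printed
# class counts, leave-one-out cross-validation on the training partition,
# incremental best-k feature sweep over the top-ranked features, and
# table-style reports.

#' Subject-level train/test split with fixed per-class counts
#'
#' Draws the requested number of training subjects per class without
#' replacement; the remainder is the test set. With the 64/46 cohort and
#' train counts (50, 38) this reproduces the study's 14-patient / 8-control
#' test partition. Both phases of a subject inherit the subject's side.
#'
#' @param subjects data.frame with columns `subject_id` and `class`
#'   (one row per subject).
#' @param train_counts named counts, e.g. `c(case = 50, control = 38)`.
#' @param seed RNG seed; same seed, same plan.
#' @return list with `train`, `test` (subject id vectors) and `counts`
#'   (per class x side table); attribute `empty_test` flags a boundary split.
#' @export
make_split <- function(subjects, train_counts = c(case = 50, control = 38),
                       seed = 1L) {
  stopifnot(all(c("subject_id", "class") %in% names(subjects)),
            !anyDuplicated(subjects$subject_id),
            all(names(train_counts) %in% unique(subjects$class)))
  train <- character(0)
  for (cl in names(train_counts)) {
    ids <- subjects$subject_id[subjects$class == cl]
    k <- train_counts[[cl]]
    if (k > length(ids)) {
      stop(sprintf("requested %d training subjects of class '%s' but only %d exist",
                   k, cl, length(ids)), call. = FALSE)
    }
    picked <- with_seed(derive_seed(seed, match(cl, names(train_counts))),
                        sample(ids, k))
    train <- c(train, picked)
  }
  test <- setdiff(subjects$subject_id, train)
  counts <- table(class = subjects$class[match(c(train, test),
                                               subjects$subject_id)],
                  side = rep(c("train", "test"),
                             c(length(train), length(test))))
  out <- list(train = sort(train), test = sort(test), counts = counts)
  attr(out, "empty_test") <- length(test) == 0
  out
}

#' Leave-one-out cross-validated evaluation on a training set
#'
#' For each training sample, fits on the remaining n-1 and predicts the
#' held-out one; the n held-out predictions are pooled and scored once with
#' [compute_metrics()]. SVM standardisation is refit inside every fold (it is
#' part of [fit_classifier()]). Folds whose training part degenerates to a
#' single class fall back to a majority vote.
#'
#' @param x numeric matrix, samples x features.
#' @param y binary labels (1 = case).
#' @param spec a [classifier_spec()].
#' @param seed seed for stochastic learners.
#' @return metrics list from [compute_metrics()].
#' @export
loocv_eval <- function(x, y, spec, seed = 1L) {
  y <- as_binary_labels(y)
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n >= 4, sum(y == 1) >= 2, sum(y == 0) >= 2)
  pred <- integer(n)
  score <- numeric(n)
  for (i in seq_len(n)) {
    model <- fit_classifier(spec, x[-i, , drop = FALSE], y[-i],
                            seed = derive_seed(seed, i))
    p <- predict_classifier(model, x[i, , drop = FALSE])
    pred[i] <- p$class
    score[i] <- p$score
  }
  compute_metrics(y, pred, score)
}

#' Incremental best-k feature sweep
#'
#' For k = 1..k_max, evaluates each classifier on the top-k ranked features:
#' LOOCV on the training partition (optional) and train-fit/test-score on the
#' held-out partition. The best k per classifier is the one maximising test
#' accuracy (ties to the smallest k).
#'
#' @param train_x,train_y training matrix and labels.
#' @param test_x,test_y test matrix and labels.
#' @param ranked ranked features from [rank_best()] (or a character vector).
#' @param specs named list of [classifier_spec()] objects.
#' @param k_max sweep upper bound (default 10).
#' @param seed master seed for stochastic learners.
#' @param loocv compute training LOOCV metrics as well (default TRUE).
#' @return data.frame of class `sweep_curve`: one row per classifier x k with
#'   test metrics and (if requested) training LOOCV metrics.
#' @export
feature_sweep <- function(train_x, train_y, test_x, test_y, ranked,
                          specs, k_max = 10L, seed = 1L, loocv = TRUE) {
  features <- if (is.data.frame(ranked)) ranked$Feature else ranked
  stopifnot(length(features) >= 1,
            all(features %in% colnames(train_x)))
  k_max <- min(k_max, length(features))
  rows <- list()
  for (ci in seq_along(specs)) {
    spec <- specs[[ci]]
    for (k in seq_len(k_max)) {
      cols <- features[seq_len(k)]
      tr_x <- train_x[, cols, drop = FALSE]
      te_x <- test_x[, cols, drop = FALSE]
      model <- fit_classifier(spec, tr_x, train_y,
                              seed = derive_seed(seed, ci, k))
      p <- predict_classifier(model, te_x)
      test_m <- compute_metrics(test_y, p$class, p$score)
      row <- data.frame(classifier = names(specs)[ci], k = k,
                        test_sensitivity = test_m$sensitivity,
                        test_specificity = test_m$specificity,
                        test_accuracy = test_m$accuracy,
                        test_auc = test_m$auc,
                        stringsAsFactors = FALSE)
      if (loocv) {
        tr_m <- loocv_eval(tr_x, train_y, spec,
                           seed = derive_seed(seed, ci, k, 2L))
        row$train_sensitivity <- tr_m$sensitivity
        row$train_specificity <- tr_m$specificity
        row$train_accuracy <- tr_m$accuracy
        row$train_auc <- tr_m$auc
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_curve", class(out))
  out
}

#' Best (k, metrics) per classifier from a sweep curve
#'
#' @param sweep a [feature_sweep()] result.
#' @return data.frame, one row per classifier x stage at the classifier's
#'   best k (max test accuracy, smallest k on ties).
#' @export
sweep_report <- function(sweep) {
  rows <- list()
  for (cl in unique(sweep$classifier)) {
    s <- sweep[sweep$classifier == cl, ]
    best <- s[order(-s$test_accuracy, s$k)[1], ]
    if (!is.null(best$train_accuracy)) {
      rows[[length(rows) + 1]] <- data.frame(
        classifier = cl, stage = "training", k = best$k,
        sensitivity = best$train_sensitivity,
        specificity = best$train_specificity,
        accuracy = best$train_accuracy, auc = best$train_auc,
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- data.frame(
      classifier = cl, stage = "test", k = best$k,
      sensitivity = best$test_sensitivity,
      specificity = best$test_specificity,
      accuracy = best$test_accuracy, auc = best$test_auc,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Run the full per-phase evaluation protocol
#'
#' Per phase (R-wave and T-wave tables are processed separately, with one
#' shared subject-level split): screen features (t-test gate), score and rank
#' by Relief-F (top 10), split subjects with the study's per-class training
#' counts, sweep k = 1..k_max over all four classifiers, and assemble the
#' report at each classifier's best k.
#'
#' @param feature_tables named list with elements `R` and `T`, each a
#'   data.frame from [extract_cohort()] restricted to one phase (columns
#'   `subject_id`, `class`, `phase`, then features).
#' @param train_counts per-class training counts
#'   (default `c(case = 50, control = 38)`).
#' @param alpha t-test significance level for the gate (default 0.05).
#' @param k_neighbors Relief-F neighbours (default 5).
#' @param top_n ranked features fed to the classifiers (default 10).
#' @param k_max feature-sweep upper bound (default 10).
#' @param seed master seed (split + stochastic learners).
#' @param loocv compute training LOOCV metrics (default TRUE).
#' @return list of class `echo_protocol`: per phase the `screening`, `ranked`,
#'   `split`, `sweep` and `report` objects.
#' @export
run_full_protocol <- function(feature_tables,
                              train_counts = c(case = 50, control = 38),
                              alpha = 0.05, k_neighbors = 5L, top_n = 10L,
                              k_max = 10L, seed = 1L, loocv = TRUE) {
  stopifnot(all(c("R", "T") %in% names(feature_tables)))
  reg <- feature_registry()
  subjects <- unique(feature_tables$R[, c("subject_id", "class")])
  split <- make_split(subjects, train_counts, seed = derive_seed(seed, 1L))
  out <- list(split = split, seed = seed)
  for (phase in c("R", "T")) {
    tab <- feature_tables[[phase]]
    stopifnot(!anyDuplicated(tab$subject_id))
    feat_cols <- setdiff(names(tab), c("subject_id", "class", "phase"))
    x <- as.matrix(tab[, feat_cols])
    rownames(x) <- tab$subject_id
    y <- as_binary_labels(tab$class)
    # train/test subject disjointness is a protocol invariant
    stopifnot(length(intersect(split$train, split$test)) == 0)
    tr <- tab$subject_id %in% split$train
    # screening and ranking see only the training partition, so the held-out
    # test subjects cannot influence feature selection (no selection leakage)
    screening <- screen_features(x[tr, , drop = FALSE], y[tr], alpha = alpha)
    scores <- relieff_scores(x[tr, , drop = FALSE], y[tr],
                             k_neighbors = k_neighbors)
    ranked <- rank_best(scores, screening, top_n = top_n, registry = reg)
    if (nrow(ranked) == 0) {
      # global-null cohorts can leave the t-gate empty; the protocol still
      # needs features to evaluate, so fall back to the ungated ranking and
      # flag it
      ungated <- screening
      ungated$significant <- TRUE
      ranked <- rank_best(scores, ungated, top_n = top_n, registry = reg)
      attr(ranked, "ungated") <- TRUE
    }
    specs <- default_classifier_specs(phase)
    sweep <- feature_sweep(x[tr, , drop = FALSE], y[tr],
                           x[!tr, , drop = FALSE], y[!tr],
                           ranked, specs, k_max = k_max,
                           seed = derive_seed(seed, 2L, match(phase,
                                                              c("R", "T"))),
                           loocv = loocv)
    out[[phase]] <- list(screening = screening, scores = scores,
                         ranked = ranked, sweep = sweep,
                         report = sweep_report(sweep))
  }
  class(out) <- "echo_protocol"
  out
}
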