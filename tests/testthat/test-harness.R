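subjects_6446 <- data.frame(
  subject_id = sprintf("S%03d", 1:110),
  class = rep(c("case", "control"), c(64, 46)),
  stringsAsFactors = FALSE
)

test_that("the 80/20 split reproduces the published class counts", {
  sp <- make_split(subjects_6446, c(case = 50, control = 38), seed = 4)
  expect_length(sp$train, 88)
  expect_length(sp$test, 22)
  cls <- subjects_6446$class[match(sp$test, subjects_6446$subject_id)]
  expect_equal(sum(cls == "case"), 14)
  expect_equal(sum(cls == "control"), 8)
  expect_length(intersect(sp$train, sp$test), 0)

  # determinism and seed sensitivity
  expect_identical(sp, make_split(subjects_6446, seed = 4))
  expect_false(identical(sp$train,
                         make_split(subjects_6446, seed = 5)$train))
})

test_that("boundary and infeasible splits are handled", {
  full <- make_split(subjects_6446, c(case = 64, control = 46), seed = 1)
  expect_length(full$test, 0)
  expect_true(attr(full, "empty_test"))
  expect_error(make_split(subjects_6446, c(case = 65, control = 38)),
               "only")
})

separable_data <- function(n = 12, seed = 2) {
  set.seed(seed)
  y <- rep(c(1, 0), each = n / 2)
  x <- cbind(f1 = y * 10 + rnorm(n, sd = 0.1),
             f2 = y * 5 + rnorm(n, sd = 0.2))
  list(x = x, y = y)
}

test_that("LOOCV is perfect on separable data for every classifier", {
  d <- separable_data(16)
  for (kind in c("decision_tree", "svm_rbf", "random_forest", "adaboost")) {
    m <- loocv_eval(d$x, d$y, classifier_spec(kind, phase = "R"), seed = 1)
    expect_equal(m$accuracy, 100)
    expect_equal(m$auc, 1)
  }
})

test_that("LOOCV on permuted labels hovers around chance", {
  set.seed(300)
  accs <- replicate(20, {
    n <- 24
    x <- cbind(a = rnorm(n), b = rnorm(n))
    y <- sample(rep(c(1, 0), each = n / 2))
    loocv_eval(x, y, classifier_spec("decision_tree"), seed = 1)$accuracy
  })
  half_width <- 100 * 1.96 * sqrt(0.25 / 24)
  expect_lt(abs(mean(accs) - 50), half_width)
})

test_that("the feature sweep uses nested top-k subsets and reports the best k", {
  d <- separable_data(20, seed = 6)
  test_d <- separable_data(10, seed = 7)
  ranked <- data.frame(Feature = c("f1", "f2"))
  specs <- list(svm_rbf = classifier_spec("svm_rbf"))
  sw <- feature_sweep(d$x, d$y, test_d$x, test_d$y, ranked, specs,
                      k_max = 10, seed = 1)
  # curve is capped by the number of ranked features
  expect_equal(sw$k, 1:2)
  # k = 1 uses exactly the rank-1 feature: the separating f1 alone is perfect
  expect_equal(sw$test_accuracy[sw$k == 1], 100)
  rep <- sweep_report(sw)
  expect_equal(unique(rep$stage), c("training", "test"))
  best <- rep[rep$stage == "test", ]
  expect_equal(best$accuracy, max(sw$test_accuracy))
  expect_equal(best$k, min(sw$k[sw$test_accuracy == max(sw$test_accuracy)]))
})

test_that("classifier wrappers emit aligned classes and scores", {
  d <- separable_data(20, seed = 11)
  for (kind in c("decision_tree", "svm_rbf", "random_forest", "adaboost")) {
    model <- fit_classifier(classifier_spec(kind), d$x, d$y, seed = 3)
    p <- predict_classifier(model, d$x)
    expect_true(all(p$class %in% c(0L, 1L)))
    # scores must orient toward the case class
    expect_gt(auc_mann_whitney(d$y, p$score), 0.9)
  }
})

test_that("random-forest hyperparameters differ by phase as printed", {
  r <- classifier_spec("random_forest", phase = "R")
  t <- classifier_spec("random_forest", phase = "T")
  expect_equal(c(r$num_trees, r$mtry, r$max_depth), c(28, 3, 5))
  expect_equal(c(t$num_trees, t$mtry, t$max_depth), c(29, 5, 8))
})
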