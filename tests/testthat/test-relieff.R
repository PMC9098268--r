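make_relieff_fixture <- function(n_per_class = 40, seed = 1) {
  set.seed(seed)
  y <- rep(c(1, 0), each = n_per_class)
  x <- cbind(label_copy = y,
             noise = runif(2 * n_per_class),
             constant = rep(2.5, 2 * n_per_class))
  list(x = x, y = y)
}

test_that("a label-copy feature dominates and a constant feature scores 0", {
  fx <- make_relieff_fixture()
  w <- relieff_scores(fx$x, fx$y, k_neighbors = 5)
  expect_gt(w[["label_copy"]], 0.9)
  expect_lt(abs(w[["noise"]]), 0.1)
  expect_identical(w[["constant"]], 0)
  expect_true(all(w >= -1 & w <= 1))
})

test_that("scores are invariant to affine rescaling of a column", {
  fx <- make_relieff_fixture(seed = 3)
  w1 <- relieff_scores(fx$x, fx$y)
  x2 <- fx$x
  x2[, "noise"] <- 100 * x2[, "noise"] - 7
  w2 <- relieff_scores(x2, fx$y)
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("scores stay bounded on random data and are deterministic", {
  set.seed(77)
  for (rep in 1:5) {
    x <- matrix(rnorm(60 * 8), 60, 8,
                dimnames = list(NULL, paste0("f", 1:8)))
    y <- rep(c(1, 0), each = 30)
    w <- relieff_scores(x, y)
    expect_true(all(w >= -1 & w <= 1))
    expect_identical(w, relieff_scores(x, y))
  }
})

test_that("a wide-margin separating feature attains the top score", {
  set.seed(9)
  n <- 30
  y <- rep(c(1, 0), each = n)
  # margin between classes is 60% of the feature's range
  sep <- c(runif(n, 0.8, 1.0), runif(n, 0, 0.2))
  x <- cbind(sep = sep,
             n1 = runif(2 * n), n2 = rnorm(2 * n), n3 = runif(2 * n))
  w <- relieff_scores(x, y)
  expect_equal(names(which.max(w)), "sep")
})

test_that("too small a class for the neighbourhood errors helpfully", {
  x <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- c(1, 1, 1, 1, 1, 0, 0, 0)
  expect_error(relieff_scores(x, y, k_neighbors = 5), "k_neighbors")
})
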