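test_that("normality test conventions and calibration", {
  expect_equal(ks_normality(rep(4, 10)), 0)  # degenerate sample

  # size: Gaussian samples should pass at about the nominal rate
  set.seed(101)
  pass <- mean(replicate(100, ks_normality(rnorm(1000)) > 0.05))
  expect_gte(pass, 0.9)

  # power: strongly skewed samples are rejected essentially always
  set.seed(102)
  rej <- mean(replicate(100, ks_normality(rexp(1000)) < 0.05))
  expect_gte(rej, 0.99)
})

test_that("two-sample t on hand-computed cases", {
  r <- two_sample_t(1:5, 3:7)
  expect_equal(r$statistic, -2)
  expect_equal(r$df, 8)
  expect_equal(r$p.value, 0.0805, tolerance = 1e-3)
  # agrees with the standard routine
  ref <- t.test(1:5, 3:7, var.equal = TRUE)
  expect_equal(r$p.value, ref$p.value)

  # identical samples
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  # swapping flips the sign, keeps p
  s1 <- two_sample_t(1:5, 3:7)
  s2 <- two_sample_t(3:7, 1:5)
  expect_equal(s2$statistic, -s1$statistic)
  expect_equal(s2$p.value, s1$p.value)

  # degenerate perfect separation
  ps <- two_sample_t(c(1, 1), c(2, 2))
  expect_equal(ps$p.value, 0)
})

test_that("screening gates features by the t-test", {
  set.seed(201)
  n <- c(50, 38)
  y <- rep(c(1, 0), n)
  # a 3-pooled-SD shifted feature is significant in every replicate
  hits <- replicate(100, {
    f <- rnorm(sum(n)) + 3 * y
    x <- cbind(shifted = f, flat = rep(1, sum(n)))
    sc <- screen_features(x, y)
    c(sc$significant[1], sc$significant[2])
  })
  expect_true(all(hits[1, ]))
  expect_false(any(hits[2, ]))  # identical-in-both-classes feature

  # alpha = 0 shuts the gate completely
  x <- cbind(a = rnorm(20) + rep(c(5, 0), each = 10), b = rnorm(20))
  sc0 <- screen_features(x, rep(c(1, 0), each = 10), alpha = 0)
  expect_equal(sum(sc0$significant), 0)
})

test_that("ranking keeps only significant features, ordered by score", {
  scores <- c(A = 0.3, B = 0.2, C = 0.1)
  screening <- data.frame(feature = c("A", "B", "C"),
                          significant = c(TRUE, TRUE, TRUE))
  rk <- rank_best(scores, screening, top_n = 2)
  expect_equal(rk$Feature, c("A", "B"))
  expect_equal(rk$Rank, 1:2)
  expect_identical(names(rk), c("Group", "Rank", "Feature", "Score"))
  expect_false(attr(rk, "short"))

  # a gated-out feature never appears, even with the best score
  screening$significant <- c(FALSE, TRUE, TRUE)
  rk2 <- rank_best(scores, screening, top_n = 10)
  expect_false("A" %in% rk2$Feature)
  expect_true(attr(rk2, "short"))

  # registry features carry their group name
  scores3 <- c(Gab8V = 0.5, Mean = 0.2)
  scr3 <- data.frame(feature = c("Gab8V", "Mean"),
                     significant = c(TRUE, TRUE))
  rk3 <- rank_best(scores3, scr3)
  expect_equal(rk3$Group, c("Gabor", "Histogram"))
})
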