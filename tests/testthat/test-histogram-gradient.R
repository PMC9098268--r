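test_that("histogram features on hand-computed cases", {
  f <- histogram_features(matrix(7, 8, 8))
  expect_equal(unname(f[c("Mean", "Variance", "Perc50", "Skewness",
                          "Kurtosis")]), c(7, 0, 7, 0, 0))

  f2 <- histogram_features(matrix(c(0, 0, 255, 255), 2, 2))
  expect_equal(unname(f2["Mean"]), 127.5)
  expect_equal(unname(f2["Variance"]), 16256.25)  # population variance
  expect_equal(unname(f2["Skewness"]), 0)

  # nearest-rank percentiles on a 1..100 ramp
  f3 <- histogram_features(matrix(1:100, 10, 10))
  expect_equal(unname(f3[c("Perc01", "Perc10", "Perc50", "Perc90",
                           "Perc99")]), c(1, 10, 50, 90, 99))
})

test_that("intensity scaling acts on mean/percentiles linearly and on variance quadratically", {
  img <- random_image(24, seed = 11)
  f1 <- histogram_features(img)
  f3 <- histogram_features(3 * img)
  lin <- c("Mean", "Perc01", "Perc10", "Perc50", "Perc90", "Perc99")
  expect_equal(unname(f3[lin]), unname(3 * f1[lin]))
  expect_equal(unname(f3["Variance"]), unname(9 * f1["Variance"]))
  expect_equal(unname(f3[c("Skewness", "Kurtosis")]),
               unname(f1[c("Skewness", "Kurtosis")]))
})

test_that("gradient features: constant image, step edge, symmetries", {
  expect_equal(unname(gradient_features(matrix(5, 8, 8))), rep(0, 5))

  # vertical step edge in a 6x6 image: nonzero central-difference magnitudes
  # only in the two interior columns adjacent to the edge -> 50% of interior
  img <- cbind(matrix(0, 6, 3), matrix(100, 6, 3))
  f <- gradient_features(img)
  expect_equal(unname(f["GrNonZeros"]), 50)

  # magnitude is symmetric under 90-degree rotation
  r <- random_image(16, seed = 3)
  expect_equal(gradient_features(r), gradient_features(rot90(r)),
               tolerance = 1e-12)

  # constant offset leaves the gradient group unchanged
  expect_equal(gradient_features(r), gradient_features(r + 40),
               tolerance = 1e-12)
})
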