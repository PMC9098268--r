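test_that("flat input produces deterministic codes", {
  f <- lbp_features(matrix(5, 10, 10))
  # all four neighbours >= center: Oc4 code 15
  expect_equal(unname(f["Oc4n15"]), 1)
  # no sign transitions: Tr4 code 0
  expect_equal(unname(f["Tr4n0"]), 1)
  # all opposing pairs tie (>= holds): all-ones codes
  expect_equal(unname(f["Cs4n3"]), 1)
  expect_equal(unname(f["Cs8n15"]), 1)
  expect_equal(unname(f["Cs12n63"]), 1)
})

test_that("each of the five histograms sums to 1", {
  for (seed in 1:5) {
    f <- lbp_features(random_image(9, seed = seed))
    expect_equal(sum(f[paste0("Oc4n", 0:15)]), 1)
    expect_equal(sum(f[paste0("Tr4n", 0:15)]), 1)
    expect_equal(sum(f[paste0("Cs4n", 0:3)]), 1)
    expect_equal(sum(f[paste0("Cs8n", 0:15)]), 1)
    expect_equal(sum(f[paste0("Cs12n", 0:63)]), 1)
  }
})

test_that("histograms match the per-pixel code enumerator", {
  set.seed(55)
  for (rep in 1:100) {
    img <- random_image(8)
    f <- lbp_features(img)
    expect_equal(unname(f[paste0("Oc4n", 0:15)]), oracle_lbp(img, "Oc4"),
                 tolerance = 1e-12)
    expect_equal(unname(f[paste0("Tr4n", 0:15)]), oracle_lbp(img, "Tr4"),
                 tolerance = 1e-12)
    expect_equal(unname(f[paste0("Cs4n", 0:3)]), oracle_lbp(img, "Cs4"),
                 tolerance = 1e-12)
  }
  # interpolated variants on a smaller batch (the oracle is slow)
  for (rep in 1:20) {
    img <- random_image(8)
    f <- lbp_features(img)
    expect_equal(unname(f[paste0("Cs8n", 0:15)]), oracle_lbp(img, "Cs8"),
                 tolerance = 1e-12)
    expect_equal(unname(f[paste0("Cs12n", 0:63)]), oracle_lbp(img, "Cs12"),
                 tolerance = 1e-12)
  }
})

test_that("LBP ignores constant offsets and too-small images error", {
  img <- random_image(10, seed = 4)
  expect_equal(lbp_features(img), lbp_features(img + 31), tolerance = 1e-12)
  expect_error(lbp_features(matrix(1, 4, 4)), "small|5x5")
})
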