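test_that("the feature vector matches the registry exactly", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 250)
  expect_equal(unname(feature_group_sizes()),
               c(9L, 5L, 5L, 28L, 24L, 24L, 28L, 11L, 116L))

  img <- random_image(256, seed = 1)
  fv <- extract_all(img)
  expect_length(fv, 250)
  expect_identical(names(fv), reg$name)
  expect_true(all(is.finite(fv)))

  # names attested in the published ranked-feature tables
  attested <- c("Gab8V", "Gab8H", "Gab6V", "Gab6Z", "Gab6N", "Gab4H",
                "GrVariance", "Oc4n10", "Oc4n4", "Cs12n47", "Cs8n9",
                "DifVarnc", "HaarS2HL", "O16b8")
  expect_true(all(attested %in% reg$name))
})

test_that("extraction is deterministic", {
  img <- random_image(64, seed = 9)
  expect_identical(extract_all(img), extract_all(img))
})

test_that("feature groups respond to offset and 90-degree rotation as designed", {
  img <- random_image(128, seed = 30)
  f1 <- extract_all(img)
  reg <- feature_registry()

  # offset invariance of gradient, wavelet and LBP groups
  f_off <- extract_all(img + 10)
  inv_groups <- reg$name[reg$group %in% c("Gradient", "Wavelet",
                                          "Local binary patterns")]
  expect_equal(f_off[inv_groups], f1[inv_groups], tolerance = 1e-8)

  # rotation: histogram group identical; pooled GLCM identical
  f_rot <- extract_all(rot90(img))
  hist_names <- reg$name[reg$group == "Histogram"]
  glcm_names <- reg$name[reg$group == "Cooccurrence matrix"]
  expect_equal(f_rot[hist_names], f1[hist_names], tolerance = 1e-10)
  expect_equal(f_rot[glcm_names], f1[glcm_names], tolerance = 1e-10)
})

test_that("cohort extraction produces the labelled feature table", {
  co <- generate_cohort(cohort_spec(2, 2, seed = 5), speckle_params(64))
  tab <- extract_cohort(co)
  expect_equal(dim(tab), c(8, 253))
  expect_identical(names(tab)[1:3], c("subject_id", "class", "phase"))
  expect_identical(names(tab)[-(1:3)], feature_registry()$name)
})
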