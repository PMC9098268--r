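test_that("generation is bit-identical under a fixed seed", {
  p <- speckle_params(64)
  sp <- cohort_spec(2, 2, seed = 7)
  a <- generate_roi(p, sp, class = "case", seed = 123)
  b <- generate_roi(p, sp, class = "case", seed = 123)
  expect_identical(a, b)
  co1 <- generate_cohort(sp, p)
  co2 <- generate_cohort(sp, p)
  expect_identical(co1$manifest, co2$manifest)
  expect_identical(co1$images, co2$images)
})

test_that("cohort geometry matches the specification", {
  sp <- cohort_spec(64, 46, seed = 1)
  co <- generate_cohort(sp, speckle_params(64))
  expect_equal(length(unique(co$manifest$subject_id)), 110)
  expect_equal(nrow(co$manifest), 220)
  expect_equal(sum(co$manifest$class == "case"), 128)   # 64 subjects x 2
  expect_equal(sort(unique(co$manifest$phase)), c("R", "T"))

  tiny <- generate_cohort(cohort_spec(1, 1, seed = 1), speckle_params(64))
  expect_equal(nrow(tiny$manifest), 4)
  expect_setequal(tiny$manifest$class, c("case", "control"))
})

test_that("invalid ROI sizes are rejected with an explicit message", {
  expect_error(speckle_params(100), "power of two")
  expect_error(speckle_params(32), "power of two|at least 64")
})

test_that("pre-compression speckle amplitude is approximately Rayleigh", {
  set.seed(404)
  z <- echotexture:::speckle_field(128, 2)   # > 10^4 pixels
  a <- as.vector(Mod(z))
  sigma_hat <- sqrt(mean(a^2) / 2)
  ks <- suppressWarnings(
    ks.test(a, function(q) 1 - exp(-q^2 / (2 * sigma_hat^2))))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("null cohorts give calibrated two-sample KS tests on a feature", {
  # with effect_size = 0, case and control images are one distribution: a
  # two-sample KS test on the histogram mean at alpha = 0.01 should reject
  # at about the nominal rate
  p <- speckle_params(64)
  rejections <- 0
  n_runs <- 200
  for (run in seq_len(n_runs)) {
    sp <- cohort_spec(50, 50, effect_size = 0, seed = 9000 + run)
    means <- matrix(NA_real_, 50, 2)
    for (i in 1:50) {
      means[i, 1] <- mean(generate_roi(p, sp, "case",
                                       seed = derive_seed(sp$seed, i, 1L)))
      means[i, 2] <- mean(generate_roi(p, sp, "control",
                                       seed = derive_seed(sp$seed, i, 2L)))
    }
    pv <- suppressWarnings(ks.test(means[, 1], means[, 2])$p.value)
    rejections <- rejections + (pv < 0.01)
  }
  # nominal 1%; allow binomial fluctuation around it (200 runs)
  expect_lte(rejections / n_runs, 0.045)
})

test_that("a strong band effect separates the matched Gabor feature", {
  p <- speckle_params(128)
  sp <- cohort_spec(50, 50, effect_size = 1, effect_orientation = 90,
                    effect_scale = 8, seed = 77)
  co <- generate_cohort(sp, p)
  r_rows <- which(co$manifest$phase == "R")
  g8v <- vapply(co$images[r_rows],
                function(im) gabor_features(im)[["Gab8V"]], numeric(1))
  cls <- co$manifest$class[r_rows]
  pooled_sd <- sqrt(mean(c(var(g8v[cls == "case"]),
                           var(g8v[cls == "control"]))))
  shift <- abs(mean(g8v[cls == "case"]) - mean(g8v[cls == "control"]))
  expect_gt(shift / pooled_sd, 3)
})

test_that("PNG round trip preserves the raster and manifest paths", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(1, 1, seed = 3), speckle_params(64),
                        dir = dir)
  expect_true(all(file.exists(co$manifest$path)))
  back <- read_roi_png(co$manifest$path[1])
  expect_equal(back, unname(co$images[[1]]), tolerance = 1e-12)
})
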