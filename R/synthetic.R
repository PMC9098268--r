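# Synthetic speckle-image cohort generator. Images follow the fully developed
# speckle model: a smooth positive echogenicity map multiplied by the envelope
# of a spatially correlated circular complex Gaussian scatterer field, so the
# pre-compression amplitude is Rayleigh-distributed. The case class
# additionally receives an oriented sinusoidal band whose wavelength and
# orientation match one Gabor filter of the texture bank, so the class signal
# concentrates in oriented band energy.

#' Speckle image parameters
#'
#' @param roi_size side of the square ROI in pixels; a power of two, >= 64,
#'   so dyadic wavelet levels are well defined (default 256).
#' @param bg_smoothness correlation length (pixels) of the echogenicity map.
#' @param speckle_grain correlation length (pixels) of the complex scatterer
#'   field; controls speckle cell size.
#' @param log_compress apply display-style log compression (40 dB dynamic
#'   range) before rescaling; default FALSE, keeping the Rayleigh amplitude
#'   statistics in the output.
#' @param bit_depth output bit depth (default 8).
#' @return list of class `speckle_params`.
#' @export
speckle_params <- function(roi_size = 256L, bg_smoothness = 32,
                           speckle_grain = 2, log_compress = FALSE,
                           bit_depth = 8L) {
  if (roi_size < 64 || !is_power_of_two(roi_size)) {
    stop("roi_size must be a power of two and at least 64 pixels",
         call. = FALSE)
  }
  stopifnot(bg_smoothness >= 1, speckle_grain >= 1)
  structure(list(roi_size = as.integer(roi_size),
                 bg_smoothness = bg_smoothness,
                 speckle_grain = speckle_grain,
                 log_compress = isTRUE(log_compress),
                 bit_depth = as.integer(bit_depth)),
            class = "speckle_params")
}

#' Two-class cohort specification
#'
#' Defaults mirror the study cohort: 64 pacemaker patients (cases) and 46
#' healthy controls, two frames per subject. `effect_size` scales the
#' amplitude of the oriented band added to case images (0.3 x the image's
#' mean echo level per unit; 0 = identical class distributions); the band's
#' wavelength is `2 * effect_scale` at `effect_orientation` degrees, matching
#' the Gabor feature `Gab{effect_scale}{dir}`.
#'
#' @param n_cases,n_controls subjects per class (defaults 64 / 46).
#' @param effect_size non-negative band amplitude multiplier (default 1).
#' @param effect_orientation degrees, one of 0, 45, 90, 135 (default 90).
#' @param effect_scale envelope size in pixels the effect targets (default 8).
#' @param seed master seed for the cohort.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 64L, n_controls = 46L, effect_size = 1,
                        effect_orientation = 90, effect_scale = 8,
                        seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, effect_size >= 0,
            effect_orientation %in% c(0, 45, 90, 135), effect_scale >= 1)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 effect_size = effect_size,
                 effect_orientation = effect_orientation,
                 effect_scale = effect_scale,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Correlated standard complex Gaussian field and smooth positive echogenicity
# map; both via Gaussian smoothing of white noise (circular boundary).
speckle_field <- function(n, grain) {
  z <- gauss_smooth(matrix(stats::rnorm(n * n), n), grain) +
    1i * gauss_smooth(matrix(stats::rnorm(n * n), n), grain)
  z / sqrt(mean(Mod(z)^2) / 2)  # unit-variance components
}

#' Generate one speckle ROI image
#'
#' Pipeline: smooth positive echogenicity map x Rayleigh speckle envelope;
#' for `class = "case"`, an additive sinusoidal band at the cohort's effect
#' orientation and scale (wavelength `2 * effect_scale`, random phase) with
#' amplitude `0.3 * effect_size` times the image's mean level; optional log
#' compression; min-max rescale to `[0, 2^bit_depth - 1]` and rounding.
#' Bit-identical under a fixed seed.
#'
#' @param params [speckle_params()].
#' @param spec [cohort_spec()] carrying the class-effect definition.
#' @param class `"case"` or `"control"`.
#' @param seed integer seed for this image.
#' @return integer-valued numeric matrix `roi_size x roi_size`.
#' @export
generate_roi <- function(params, spec, class = c("control", "case"),
                         seed = 1L) {
  stopifnot(inherits(params, "speckle_params"), inherits(spec, "cohort_spec"))
  class <- match.arg(class)
  n <- params$roi_size
  with_seed(seed, {
    bg_raw <- gauss_smooth(matrix(stats::rnorm(n * n), n),
                           params$bg_smoothness)
    bg <- exp(0.5 * bg_raw / stats::sd(as.vector(bg_raw)))
    envelope <- Mod(speckle_field(n, params$speckle_grain))
    img <- bg * envelope
    if (class == "case" && spec$effect_size > 0) {
      th <- spec$effect_orientation * pi / 180
      lambda <- 2 * spec$effect_scale
      X <- matrix(seq_len(n), n, n, byrow = TRUE)
      Y <- matrix(seq_len(n), n, n)
      phase <- stats::runif(1, 0, 2 * pi)
      band <- sin(2 * pi * (X * cos(th) + Y * sin(th)) / lambda + phase)
      # band amplitude: 0.3 x mean echo level per unit effect_size, small
      # against the speckle so the class signal is carried by oriented band
      # energy (matched, orientation-selective filters) rather than by the
      # marginal intensity distribution
      img <- pmax(img + 0.3 * spec$effect_size * mean(img) * band, 0)
    }
    if (params$log_compress) {
      db <- 20 * log10(pmax(img, 1e-12) / max(img))
      img <- pmax(db, -40) + 40
    }
    rng <- range(img)
    if (rng[2] > rng[1]) {
      img <- (img - rng[1]) / (rng[2] - rng[1])
    } else {
      img[] <- 0
    }
    round(img * (2^params$bit_depth - 1))
  })
}

#' Generate a labelled two-phase cohort of speckle ROIs
#'
#' Every subject gets an end-diastolic (phase `"R"`) and an end-systolic
#' (phase `"T"`) frame as independent speckle realisations sharing the
#' subject-level class effect. Per-image seeds are derived from `spec$seed`,
#' the subject index and the phase, so the cohort is reproducible and
#' insensitive to generation order.
#'
#' @param spec [cohort_spec()].
#' @param params [speckle_params()].
#' @param dir optional directory; when given, images are written as 8-bit
#'   grayscale PNGs and the manifest gains their paths.
#' @return list with `manifest` (data.frame: subject_id, class, phase, path,
#'   seed) and `images` (list of matrices, manifest order).
#' @export
generate_cohort <- function(spec, params = speckle_params(), dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  classes <- c(rep("case", spec$n_cases), rep("control", spec$n_controls))
  subjects <- sprintf("S%03d", seq_along(classes))
  manifest <- expand.grid(phase = c("R", "T"), subject_id = subjects,
                          stringsAsFactors = FALSE)[, 2:1]
  manifest$class <- classes[match(manifest$subject_id, subjects)]
  manifest$seed <- mapply(function(s, p) {
    derive_seed(spec$seed, match(s, subjects), match(p, c("R", "T")))
  }, manifest$subject_id, manifest$phase)
  manifest$path <- NA_character_
  images <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    images[[i]] <- generate_roi(params, spec, class = manifest$class[i],
                                seed = manifest$seed[i])
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      p <- file.path(dir, sprintf("%s_%s.png", manifest$subject_id[i],
                                  manifest$phase[i]))
      write_roi_png(images[[i]], p, params$bit_depth)
      manifest$path[i] <- p
    }
  }
  rownames(manifest) <- NULL
  list(manifest = manifest[, c("subject_id", "class", "phase", "path",
                               "seed")],
       images = images, spec = spec, params = params)
}
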