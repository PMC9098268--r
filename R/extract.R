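#' Extract the full 250-feature texture vector from one ROI
#'
#' Runs the nine feature groups in registry order — histogram, autoregressive
#' model, gradient, histograms of oriented gradients, Gabor magnitudes, Haar
#' wavelet energies, run-length matrix, co-occurrence matrix and local binary
#' patterns — and concatenates them into one named vector of exactly 250
#' values. The matrix-based groups (GLRLM, GLCM) operate on a quantized copy
#' of the ROI (default: 64 levels over the mean +/- 3 sd window); all other
#' groups use raw intensities. Extraction is deterministic.
#'
#' @param img numeric matrix of intensities.
#' @param config list of options: `glcm_levels` (default 64),
#'   `quantization` ("mu_3sigma" or "full_range"), `bit_depth` (8),
#'   `gabor_sizes` (2,4,6,8,10,12), `wavelet_levels` (8).
#' @return named numeric vector of length 250, ordered per
#'   [feature_registry()]; attribute `degenerate_wavelet_levels` flags wavelet
#'   levels that were zero-filled on small images.
#' @export
#' @examples
#' img <- matrix(runif(256 * 256, 0, 255), 256)
#' fv <- extract_all(img)
#' length(fv)  # 250
extract_all <- function(img, config = list()) {
  check_gray_image(img, min_dim = 16L)
  cfg <- utils::modifyList(list(
    glcm_levels = 64L,
    quantization = "mu_3sigma",
    bit_depth = 8L,
    gabor_sizes = c(2, 4, 6, 8, 10, 12),
    wavelet_levels = 8L
  ), config)
  qimg <- quantize(img, levels = cfg$glcm_levels, method = cfg$quantization,
                   bit_depth = cfg$bit_depth)
  wav <- wavelet_energy_features(img, levels = cfg$wavelet_levels)
  out <- c(
    histogram_features(img),
    ar_model_features(img),
    gradient_features(img),
    hog_features(img),
    gabor_features(img, sizes = cfg$gabor_sizes),
    wav,
    glrlm_features(qimg),
    glcm_features(qimg),
    lbp_features(img)
  )
  reg <- feature_registry(gabor_sizes = cfg$gabor_sizes)
  stopifnot(identical(names(out), reg$name), all(is.finite(out)))
  attr(out, "degenerate_wavelet_levels") <- attr(wav, "degenerate_levels")
  out
}

#' Extract a feature table from a simulated or loaded cohort
#'
#' Applies [extract_all()] to every image of a cohort and assembles the
#' samples x features table with identifying columns `subject_id`, `class`
#' and `phase` followed by the 250 registry features.
#'
#' @param cohort a cohort from [generate_cohort()] (list with `manifest` and
#'   `images`), or a manifest data.frame with a `path` column of PNG files.
#' @param config extraction options, see [extract_all()].
#' @return data.frame with `n_images` rows and 253 columns.
#' @export
extract_cohort <- function(cohort, config = list()) {
  if (is.data.frame(cohort)) {
    manifest <- cohort
    images <- lapply(manifest$path, read_roi_png)
  } else {
    manifest <- cohort$manifest
    images <- cohort$images
  }
  stopifnot(nrow(manifest) == length(images))
  feats <- t(vapply(images, function(im) as.numeric(extract_all(im, config)),
                    numeric(250)))
  colnames(feats) <- feature_registry()$name
  cbind(manifest[, c("subject_id", "class", "phase")],
        as.data.frame(feats), stringsAsFactors = FALSE)
}

#' Read / write a grayscale ROI as 8-bit PNG
#'
#' @param path file path.
#' @return `read_roi_png` returns a numeric matrix of intensities in
#'   `[0, 255]`.
#' @export
read_roi_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  round(x * 255)
}

#' @rdname read_roi_png
#' @param img numeric matrix with intensities in `[0, 2^bit_depth - 1]`.
#' @param bit_depth nominal bit depth (values are rescaled by its maximum).
#' @export
write_roi_png <- function(img, path, bit_depth = 8L) {
  png::writePNG(img / (2^bit_depth - 1), path)
  invisible(path)
}
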