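#' Quantize a grayscale image for co-occurrence / run-length analysis
#'
#' Linear binning of an intensity window into `levels` gray levels
#' (0 .. levels-1), the preprocessing both matrix-based feature groups
#' require. Two windows are supported:
#' \describe{
#'   \item{`full_range`}{the full nominal range `[0, 2^bit_depth - 1]`, each
#'     bin covering `2^bit_depth / levels` input values.}
#'   \item{`mu_3sigma`}{the mean +/- 3 standard deviations of the ROI, the
#'     MaZda-style normalisation; values outside the window are clipped to the
#'     extreme bins. A constant image (sd 0) falls back to `full_range`.}
#' }
#'
#' @param img numeric matrix of intensities.
#' @param levels number of output gray levels; one of 16, 32, 64, 128.
#' @param method `"mu_3sigma"` (default) or `"full_range"`.
#' @param bit_depth nominal bit depth of the source image (default 8).
#' @return integer matrix of codes in `[0, levels - 1]`; attributes `levels`,
#'   `method`, `mu`, `sigma` record the normalisation.
#' @export
quantize <- function(img, levels = 64L,
                     method = c("mu_3sigma", "full_range"),
                     bit_depth = 8L) {
  check_gray_image(img)
  method <- match.arg(method)
  stopifnot(levels %in% c(16L, 32L, 64L, 128L))
  mu <- mean(img); sigma <- stats::sd(as.vector(img))
  used <- method
  if (method == "mu_3sigma" && sigma > 0) {
    lo <- mu - 3 * sigma
    hi <- mu + 3 * sigma
  } else {
    used <- "full_range"
    lo <- 0
    hi <- 2^bit_depth  # exclusive upper edge: 256/levels values per bin
  }
  q <- floor((img - lo) / (hi - lo) * levels)
  q <- pmin(pmax(q, 0), levels - 1)
  q <- matrix(as.integer(q), nrow(img), ncol(img))
  structure(q, levels = as.integer(levels), method = used,
            mu = mu, sigma = sigma)
}

quantized_levels <- function(qimg) {
  lv <- attr(qimg, "levels")
  if (is.null(lv)) lv <- max(qimg) + 1L
  as.integer(lv)
}
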