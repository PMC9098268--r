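# Gabor magnitude features. A bank of complex Gabor kernels with Gaussian
# envelope sigma = s pixels, carrier wavelength lambda = 2s (one cycle per
# two envelope widths), at the four texture-analysis orientations
# H = 0, Z = 45, V = 90, N = 135 degrees. The feature is the mean response
# magnitude over the image interior (pixels further than the kernel
# half-width from every edge), after subtracting the image mean to suppress
# the DC response.

# cache of kernel FFTs keyed by image size + bank spec (kernels are small but
# their padded FFTs cost one full-image FFT each; reuse across images)
.gabor_cache <- new.env(parent = emptyenv())

gabor_kernel <- function(sigma, theta_deg) {
  h <- as.integer(2 * sigma)  # truncate envelope at 2 sigma
  xs <- -h:h
  X <- matrix(xs, 2 * h + 1, 2 * h + 1, byrow = TRUE)  # column offset (x)
  Y <- matrix(xs, 2 * h + 1, 2 * h + 1)                # row offset (y)
  env <- exp(-(X^2 + Y^2) / (2 * sigma^2))
  env <- env / sum(env)
  th <- theta_deg * pi / 180
  lambda <- 2 * sigma
  carrier <- exp(2i * pi * (X * cos(th) + Y * sin(th)) / lambda)
  env * carrier
}

#' Gabor-magnitude texture features
#'
#' Mean response magnitude of a 24-filter Gabor bank: six Gaussian envelope
#' sizes crossed with four orientations, horizontal (H, 0 degrees), oblique
#' (Z, 45), vertical (V, 90) and anti-oblique (N, 135). Feature `Gab8V` is the
#' mean magnitude for envelope size 8 at 90 degrees. The image mean is
#' subtracted before filtering; responses are evaluated on the interior only
#' (a border of twice the largest envelope size is excluded), so the image
#' must be larger than the largest filter support.
#'
#' @param img numeric matrix.
#' @param sizes six Gaussian envelope sizes in pixels (default 2,4,6,8,10,12).
#' @return named numeric vector of length 24 (`Gab{size}{dir}`).
#' @export
gabor_features <- function(img, sizes = c(2, 4, 6, 8, 10, 12)) {
  check_gray_image(img)
  stopifnot(length(sizes) == 6)
  nr <- nrow(img); nc <- ncol(img)
  dirs <- c(H = 0, Z = 45, V = 90, N = 135)
  hmax <- as.integer(2 * max(sizes))
  if (nr - 2 * hmax < 1 || nc - 2 * hmax < 1) {
    stop(sprintf(
      "filter support (%d px) exceeds the %dx%d image; need > %d px per side",
      2 * hmax + 1, nr, nc, 2 * hmax), call. = FALSE)
  }
  key <- paste(nr, nc, paste(sizes, collapse = ","), sep = "x")
  bank <- .gabor_cache[[key]]
  if (is.null(bank)) {
    bank <- list()
    for (s in sizes) {
      for (d in names(dirs)) {
        k <- gabor_kernel(s, dirs[[d]])
        kr <- nrow(k); hk <- (kr - 1) / 2
        kpad <- matrix(0 + 0i, nr, nc)
        kpad[((-hk:hk) %% nr) + 1, ((-hk:hk) %% nc) + 1] <- k
        bank[[paste0("Gab", s, d)]] <- fft(kpad)
      }
    }
    .gabor_cache[[key]] <- bank
  }
  F <- fft(img - mean(img))
  iy <- (hmax + 1):(nr - hmax)
  ix <- (hmax + 1):(nc - hmax)
  out <- vapply(bank, function(kf) {
    resp <- fft(F * kf, inverse = TRUE) / (nr * nc)
    mean(Mod(resp[iy, ix]))
  }, numeric(1))
  out
}
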