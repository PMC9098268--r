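# Haar wavelet subband energies. Separable orthonormal Haar analysis: at each
# level, adjacent pairs are combined into (a+b)/sqrt(2) (low) and
# (a-b)/sqrt(2) (high), first along columns (x) then along rows (y). Channels:
# HL = high in x / low in y (vertical edge energy), LH = low in x / high in y,
# HH = high in both. The per-level feature is the mean squared detail
# coefficient of the channel.

haar_split_cols <- function(m) {
  nc <- ncol(m)
  odd <- seq(1, nc - 1, by = 2)
  list(low = (m[, odd, drop = FALSE] + m[, odd + 1, drop = FALSE]) / sqrt(2),
       high = (m[, odd, drop = FALSE] - m[, odd + 1, drop = FALSE]) / sqrt(2))
}

haar_split_rows <- function(m) {
  nr <- nrow(m)
  odd <- seq(1, nr - 1, by = 2)
  list(low = (m[odd, , drop = FALSE] + m[odd + 1, , drop = FALSE]) / sqrt(2),
       high = (m[odd, , drop = FALSE] - m[odd + 1, , drop = FALSE]) / sqrt(2))
}

#' Haar wavelet subband energy features
#'
#' Dyadic 8-level Haar decomposition; the feature `HaarS{k}{ch}` is the mean
#' of the squared detail coefficients at level `k` in channel
#' `ch` (LH, HL or HH). Levels that do not exist for the image size
#' (a level needs at least 2x2 approximation pixels) are emitted as 0 and
#' flagged via the `"degenerate_levels"` attribute, so the group always
#' occupies its 24 registry slots. Energies are invariant to a global
#' intensity offset because the Haar detail filters have zero sum.
#'
#' @param img numeric matrix.
#' @param levels number of decomposition levels (default 8).
#' @return named numeric vector of length `3 * levels`, ordered
#'   `HaarS1LH, HaarS1HL, HaarS1HH, HaarS2LH, ...`; attribute
#'   `degenerate_levels` lists zero-filled levels (integer(0) if none).
#' @export
wavelet_energy_features <- function(img, levels = 8L) {
  check_gray_image(img)
  out <- stats::setNames(
    numeric(3L * levels),
    as.vector(t(outer(seq_len(levels), c("LH", "HL", "HH"),
                      function(k, ch) paste0("HaarS", k, ch)))))
  approx <- img
  degenerate <- integer(0)
  for (k in seq_len(levels)) {
    if (nrow(approx) < 2 || ncol(approx) < 2) {
      degenerate <- c(degenerate, k:levels)
      break
    }
    # trim an odd trailing row/column so pairs are complete
    approx <- approx[seq_len(2 * (nrow(approx) %/% 2)),
                     seq_len(2 * (ncol(approx) %/% 2)), drop = FALSE]
    cx <- haar_split_cols(approx)
    ll <- haar_split_rows(cx$low)
    hh <- haar_split_rows(cx$high)
    # cx$high: high in x; rows low -> HL, rows high -> HH
    out[paste0("HaarS", k, "LH")] <- mean(ll$high^2)
    out[paste0("HaarS", k, "HL")] <- mean(hh$low^2)
    out[paste0("HaarS", k, "HH")] <- mean(hh$high^2)
    approx <- ll$low
  }
  attr(out, "degenerate_levels") <- degenerate
  out
}
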