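# Gray-level co-occurrence matrix features. One symmetric matrix at offset
# distance 1 accumulated jointly over the four directions (0, 45, 90,
# 135 degrees), normalised to sum 1; eleven Haralick statistics with log
# base 2 and the convention 0*log(0) = 0. Level indices run 1..Ng.

glcm_matrix <- function(qimg) {
  ng <- quantized_levels(qimg)
  nr <- nrow(qimg); nc <- ncol(qimg)
  counts <- matrix(0, ng, ng)
  add_pairs <- function(a, b) {
    idx <- (as.vector(b)) * ng + as.vector(a) + 1L  # 0-based codes
    tab <- tabulate(idx, nbins = ng * ng)
    counts <<- counts + matrix(tab, ng, ng)
  }
  if (nc >= 2) add_pairs(qimg[, -nc], qimg[, -1])                    # H
  if (nr >= 2) add_pairs(qimg[-nr, ], qimg[-1, ])                    # V
  if (nr >= 2 && nc >= 2) {
    add_pairs(qimg[-1, -nc], qimg[-nr, -1])                          # Z (45)
    add_pairs(qimg[-nr, -nc], qimg[-1, -1])                          # N (135)
  }
  counts <- counts + t(counts)  # symmetric pairs
  counts / sum(counts)
}

haralick_stats <- function(p) {
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu_x <- sum(seq_len(ng) * px)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  log2z <- function(x) ifelse(x > 0, log2(x), 0)

  # p_{x+y}(k), k = 2..2Ng and p_{|x-y|}(k), k = 0..Ng-1
  sums <- as.vector(tapply(as.vector(p), as.vector(i + j), sum))
  ks <- sort(unique(as.vector(i + j)))
  diffs_k <- 0:(ng - 1)
  diffs <- vapply(diffs_k,
                  function(k) sum(p[abs(i - j) == k]), numeric(1))

  sum_avg <- sum(ks * sums)
  dif_mu <- sum(diffs_k * diffs)
  correlat <- if (sd_x > 0) (sum(i * j * p) - mu_x^2) / sd_x^2 else 0

  c(AngScMom = sum(p^2),
    Contrast = sum((i - j)^2 * p),
    Correlat = correlat,
    SumOfSqs = sum((i - mu_x)^2 * p),
    InvDfMom = sum(p / (1 + (i - j)^2)),
    SumAverg = sum_avg,
    SumVarnc = sum((ks - sum_avg)^2 * sums),
    SumEntrp = -sum(sums * log2z(sums)),
    Entropy = -sum(p * log2z(p)),
    DifVarnc = sum((diffs_k - dif_mu)^2 * diffs),
    DifEntrp = -sum(diffs * log2z(diffs)))
}

#' Gray-level co-occurrence matrix features
#'
#' Eleven Haralick statistics of the direction-pooled, symmetric co-occurrence
#' matrix at offset distance 1: angular second moment, contrast, correlation,
#' sum of squares (variance), inverse difference moment, sum average, sum
#' variance, sum entropy, entropy, difference variance and difference entropy.
#' Entropies use log base 2; a degenerate correlation (zero marginal variance,
#' e.g. a constant image) is 0 by convention.
#'
#' @param qimg quantized image from [quantize()].
#' @return named numeric vector of length 11.
#' @export
glcm_features <- function(qimg) {
  check_gray_image(qimg, min_dim = 2L)
  haralick_stats(glcm_matrix(qimg))
}
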