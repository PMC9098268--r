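# Histogram, autoregressive, gradient and HOG feature groups. All moments are
# population (biased) moments; kurtosis is excess kurtosis so a Gaussian
# scores 0; percentiles use the nearest-rank method.

pop_moments <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v == 0) {
    # zero-variance convention: skewness and excess kurtosis are 0
    return(c(mean = m, variance = 0, skewness = 0, kurtosis = 0))
  }
  s <- mean((x - m)^3) / v^1.5
  k <- mean((x - m)^4) / v^2 - 3
  c(mean = m, variance = v, skewness = s, kurtosis = k)
}

# Nearest-rank percentile: the ceiling(p/100 * n)-th smallest value.
nearest_rank_percentile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  idx <- pmax(1L, as.integer(ceiling(p / 100 * n)))
  xs[idx]
}

#' Histogram features of a grayscale image
#'
#' Nine first-order statistics of the intensity distribution: mean, variance,
#' skewness, excess kurtosis (population moments) and the nearest-rank 1st,
#' 10th, 50th, 90th and 99th percentiles. A zero-variance image yields
#' skewness and kurtosis of 0 by convention.
#'
#' @param img numeric matrix of intensities.
#' @return named numeric vector of length 9.
#' @export
histogram_features <- function(img) {
  check_gray_image(img)
  x <- as.vector(img)
  mo <- pop_moments(x)
  pc <- nearest_rank_percentile(x, c(1, 10, 50, 90, 99))
  c(Mean = unname(mo["mean"]), Variance = unname(mo["variance"]),
    Skewness = unname(mo["skewness"]), Kurtosis = unname(mo["kurtosis"]),
    Perc01 = pc[1], Perc10 = pc[2], Perc50 = pc[3], Perc90 = pc[4],
    Perc99 = pc[5])
}

#' Causal autoregressive model features
#'
#' Fits the first-order causal 2-D autoregressive model
#' \deqn{f(x,y) = \theta_1 f(x-1,y) + \theta_2 f(x-1,y-1) + \theta_3 f(x,y-1)
#'   + \theta_4 f(x+1,y-1) + e}
#' by ordinary least squares over all interior pixels of the mean-subtracted
#' image. `Sigma` is the root-mean-square residual. A constant image (rank
#' deficient normal equations) returns all zeros by convention.
#'
#' @param img numeric matrix, at least 3x3.
#' @return named numeric vector `Teta1..Teta4`, `Sigma`.
#' @export
ar_model_features <- function(img) {
  check_gray_image(img, min_dim = 3L)
  f <- img - mean(img)
  nr <- nrow(f); nc <- ncol(f)
  # matrix rows are y, columns are x; interior: y in 2..nr, x in 2..(nc-1)
  y <- 2:nr; x <- 2:(nc - 1)
  target <- f[y, x]
  X <- cbind(
    as.vector(f[y, x - 1]),       # f(x-1, y)
    as.vector(f[y - 1, x - 1]),   # f(x-1, y-1)
    as.vector(f[y - 1, x]),       # f(x,   y-1)
    as.vector(f[y - 1, x + 1])    # f(x+1, y-1)
  )
  b <- as.vector(target)
  qrX <- qr(X)
  if (qrX$rank < 4L) {
    return(c(Teta1 = 0, Teta2 = 0, Teta3 = 0, Teta4 = 0, Sigma = 0))
  }
  theta <- qr.coef(qrX, b)
  res <- b - X %*% theta
  c(Teta1 = theta[1], Teta2 = theta[2], Teta3 = theta[3], Teta4 = theta[4],
    Sigma = sqrt(mean(res^2)))
}

# Central-difference gradient components over interior pixels.
# Returns list(gx, gy, magnitude); gx along columns (x), gy along rows (y).
gradient_components <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  y <- 2:(nr - 1); x <- 2:(nc - 1)
  gx <- img[y, x + 1] - img[y, x - 1]
  gy <- img[y + 1, x] - img[y - 1, x]
  list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2))
}

#' Gradient-magnitude features
#'
#' Gradient magnitude by central differences over interior pixels,
#' `sqrt((f(x+1,y)-f(x-1,y))^2 + (f(x,y+1)-f(x,y-1))^2)`, summarised by its
#' population moments plus `GrNonZeros`, the percentage of interior pixels
#' with non-zero magnitude.
#'
#' @param img numeric matrix, at least 3x3.
#' @return named numeric vector of length 5.
#' @export
gradient_features <- function(img) {
  check_gray_image(img, min_dim = 3L)
  g <- gradient_components(img)$magnitude
  mo <- pop_moments(as.vector(g))
  c(GrMean = unname(mo["mean"]), GrVariance = unname(mo["variance"]),
    GrSkewness = unname(mo["skewness"]), GrKurtosis = unname(mo["kurtosis"]),
    GrNonZeros = 100 * mean(g > 0))
}

#' Histograms of oriented gradients
#'
#' One whole-ROI orientation histogram for each of 4, 8 and 16 angular bins.
#' Orientation is `atan2(gy, gx)` mapped to [0, 360); bin `b` of a `B`-bin
#' histogram covers `[b*360/B, (b+1)*360/B)`. Each interior pixel votes with
#' weight equal to its gradient magnitude; zero-magnitude pixels do not vote.
#' Each histogram is L1-normalised to sum 1 (an all-zero histogram, e.g. from
#' a constant image, stays all-zero).
#'
#' @param img numeric matrix, at least 3x3.
#' @return named numeric vector of length 28 (`O4b*`, `O8b*`, `O16b*`).
#' @export
hog_features <- function(img) {
  check_gray_image(img, min_dim = 3L)
  g <- gradient_components(img)
  mag <- as.vector(g$magnitude)
  keep <- mag > 0
  ang <- (atan2(as.vector(g$gy)[keep], as.vector(g$gx)[keep]) * 180 / pi) %% 360
  w <- mag[keep]
  one_hist <- function(B) {
    h <- numeric(B)
    if (length(ang)) {
      bin <- pmin(floor(ang / (360 / B)), B - 1) + 1
      h <- as.vector(tapply(w, factor(bin, levels = 1:B), sum,
                            default = 0))
      tot <- sum(h)
      if (tot > 0) h <- h / tot
    }
    stats::setNames(h, paste0("O", B, "b", 0:(B - 1)))
  }
  c(one_hist(4), one_hist(8), one_hist(16))
}
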