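# Local binary pattern variants: overcomplete (Oc), transition (Tr) and
# center-symmetric (Cs) codings, each summarised as an L1-normalised code
# histogram over every pixel whose full neighbour circle lies inside the
# image. Neighbour k of N sits at angle 2*pi*k/N on a circle of radius r,
# offset (drow, dcol) = (r sin, r cos); off-grid samples are bilinearly
# interpolated. Ties (neighbour equal to the reference) count as ">=", bit 1.

# Sample img at (row + dy, col + dx) for every pixel in the valid interior
# defined by `margin`; bilinear interpolation for fractional offsets.
sample_offset <- function(img, dy, dx, margin) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- (margin + 1):(nr - margin)
  cols <- (margin + 1):(nc - margin)
  y0 <- floor(dy); x0 <- floor(dx)
  fy <- dy - y0; fx <- dx - x0
  # snap near-integer offsets to the grid to avoid spurious interpolation
  if (abs(fy) < 1e-9) fy <- 0
  if (abs(fx) < 1e-9) fx <- 0
  if (fy > 1 - 1e-9) { y0 <- y0 + 1; fy <- 0 }
  if (fx > 1 - 1e-9) { x0 <- x0 + 1; fx <- 0 }
  g <- function(ddy, ddx) img[rows + ddy, cols + ddx, drop = FALSE]
  if (fy == 0 && fx == 0) return(g(y0, x0))
  (1 - fy) * (1 - fx) * g(y0, x0) +
    (1 - fy) * fx * g(y0, x0 + 1) +
    fy * (1 - fx) * g(y0 + 1, x0) +
    fy * fx * g(y0 + 1, x0 + 1)
}

circle_offsets <- function(n_neighbors, radius) {
  k <- seq_len(n_neighbors) - 1
  th <- 2 * pi * k / n_neighbors
  list(dy = radius * sin(th), dx = radius * cos(th))
}

lbp_code_hist <- function(codes, n_codes) {
  h <- tabulate(as.vector(codes) + 1L, nbins = n_codes)
  tot <- sum(h)
  if (tot > 0) h <- h / tot
  h
}

lbp_neighbors <- function(img, n_neighbors, radius) {
  margin <- as.integer(ceiling(radius))
  if (nrow(img) <= 2 * margin || ncol(img) <= 2 * margin) {
    stop(sprintf("image too small for the %d-neighbour circle of radius %g",
                 n_neighbors, radius), call. = FALSE)
  }
  off <- circle_offsets(n_neighbors, radius)
  nb <- lapply(seq_len(n_neighbors), function(k) {
    sample_offset(img, off$dy[k], off$dx[k], margin)
  })
  center <- sample_offset(img, 0, 0, margin)
  list(neighbors = nb, center = center)
}

# classic LBP over the 4-connected neighbours: bit k set when neighbour k
# (order E, S, W, N-up) >= center
lbp_oc4 <- function(img) {
  s <- lbp_neighbors(img, 4, 1)
  code <- 0
  for (k in 1:4) code <- code + (s$neighbors[[k]] >= s$center) * 2^(k - 1)
  lbp_code_hist(code, 16L)
}

# transition coding: bit k set when consecutive neighbours (circular order)
# disagree in their >=-center sign
lbp_tr4 <- function(img) {
  s <- lbp_neighbors(img, 4, 1)
  b <- lapply(s$neighbors, function(nb) nb >= s$center)
  code <- 0
  for (k in 1:4) {
    nxt <- if (k == 4) 1 else k + 1
    code <- code + (b[[k]] != b[[nxt]]) * 2^(k - 1)
  }
  lbp_code_hist(code, 16L)
}

# center-symmetric LBP: bit p set when neighbour p >= its diametric opposite
lbp_cs <- function(img, n_neighbors, radius) {
  s <- lbp_neighbors(img, n_neighbors, radius)
  half <- n_neighbors / 2
  code <- 0
  for (p in seq_len(half)) {
    code <- code + (s$neighbors[[p]] >= s$neighbors[[p + half]]) * 2^(p - 1)
  }
  lbp_code_hist(code, as.integer(2^half))
}

#' Local binary pattern features
#'
#' Three LBP codings over raw intensities, each reported as a normalised code
#' histogram: overcomplete `Oc4` (classic 4-neighbour LBP, 16 codes),
#' transition `Tr4` (sign changes between consecutive 4-neighbours, 16 codes)
#' and center-symmetric `Cs4` / `Cs8` / `Cs12` (opposing-pair comparisons on
#' circles of radius 1, 1 and 2, giving 4, 16 and 64 codes; diagonal and
#' 30-degree samples are bilinearly interpolated). Comparisons use `>=`, so
#' ties set the bit. Each histogram sums to 1.
#'
#' @param img numeric matrix, at least 5x5 (the radius-2 circle must fit).
#' @return named numeric vector of length 116
#'   (`Oc4n0..15`, `Tr4n0..15`, `Cs4n0..3`, `Cs8n0..15`, `Cs12n0..63`).
#' @export
lbp_features <- function(img) {
  check_gray_image(img, min_dim = 5L)
  c(stats::setNames(lbp_oc4(img), paste0("Oc4n", 0:15)),
    stats::setNames(lbp_tr4(img), paste0("Tr4n", 0:15)),
    stats::setNames(lbp_cs(img, 4, 1), paste0("Cs4n", 0:3)),
    stats::setNames(lbp_cs(img, 8, 1), paste0("Cs8n", 0:15)),
    stats::setNames(lbp_cs(img, 12, 2), paste0("Cs12n", 0:63)))
}
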