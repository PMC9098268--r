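# Gray-level run-length matrix features along the four standard directions
# H (0 deg, along rows), Z (45 deg, anti-diagonals), V (90 deg, along
# columns), N (135 deg, main diagonals). A run is a maximal sequence of
# equal gray levels along the direction.

# All maximal runs of a quantized image along one direction, as a
# data.frame(level, length). Traversal order within a line does not affect
# run statistics.
glrlm_runs <- function(qimg, direction) {
  nr <- nrow(qimg); nc <- ncol(qimg)
  lines <- switch(direction,
    H = split(as.vector(t(qimg)), rep(seq_len(nr), each = nc)),
    V = split(as.vector(qimg), rep(seq_len(nc), each = nr)),
    # anti-diagonals (45 deg): constant row+col
    Z = split(as.vector(qimg),
              as.vector(row(qimg) + col(qimg))),
    # main diagonals (135 deg): constant col-row
    N = split(as.vector(qimg),
              as.vector(col(qimg) - row(qimg))),
    stop("unknown run direction: ", direction, call. = FALSE)
  )
  lens <- vector("list", length(lines))
  vals <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    r <- rle(lines[[i]])
    lens[[i]] <- r$lengths
    vals[[i]] <- r$values
  }
  data.frame(level = unlist(vals, use.names = FALSE),
             length = unlist(lens, use.names = FALSE))
}

glrlm_stats_one <- function(runs, n_pixels) {
  C <- nrow(runs)                       # total number of runs
  j <- runs$length
  r_j <- tapply(rep(1L, C), j, sum)     # runs per length
  g_i <- tapply(rep(1L, C), runs$level, sum)  # runs per gray level
  c(RLNonUni = sum(r_j^2) / C,
    GLevNonUn = sum(g_i^2) / C,
    LngREmph = sum(j^2) / C,
    ShrtREmph = sum(1 / j^2) / C,
    Fraction = C / n_pixels,
    NRLNonUni = sum(r_j^2) / C^2,
    NGLevNonUni = sum(g_i^2) / C^2)
}

#' Gray-level run-length matrix features
#'
#' Seven run-length statistics (run-length non-uniformity, gray-level
#' non-uniformity, long- and short-run emphasis, fraction of image in runs,
#' and the normalised non-uniformities) for each of the four directions
#' H, Z, V, N, named by direction prefix (e.g. `HLngREmph`). With run-length
#' matrix `p(i,j)`, total runs `C`, pixels `P`, `r_j = sum_i p(i,j)` and
#' `g_i = sum_j p(i,j)`:
#' `ShrtREmph = sum p/j^2 / C`, `LngREmph = sum p j^2 / C`,
#' `GLevNonUn = sum g_i^2 / C`, `RLNonUni = sum r_j^2 / C`,
#' `Fraction = C / P`, `NRLNonUni = sum r_j^2 / C^2`,
#' `NGLevNonUni = sum g_i^2 / C^2`.
#'
#' @param qimg quantized image from [quantize()] (any integer matrix works).
#' @return named numeric vector of length 28, directions H, Z, V, N in order.
#' @export
glrlm_features <- function(qimg) {
  check_gray_image(qimg)
  n_pixels <- length(qimg)
  out <- numeric(0)
  for (d in c("H", "Z", "V", "N")) {
    s <- glrlm_stats_one(glrlm_runs(qimg, d), n_pixels)
    names(s) <- paste0(d, names(s))
    out <- c(out, s)
  }
  out
}
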