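#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with one or more integer stage/subject identifiers so
#' that pipeline stages (simulation, splitting, forest fitting, ...) each get
#' an independent, replayable RNG stream. The mix is a simple multiplicative
#' congruential fold kept below 2^31 - 1.
#'
#' @param seed master seed (integer).
#' @param ... further integer identifiers (stage index, subject index, ...).
#' @return an integer seed in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  stopifnot(length(ids) >= 1, all(is.finite(ids)))
  m <- 2147483647
  x <- 0
  for (v in ids) {
    x <- (x * 69069 + (as.numeric(v) %% m) + 1) %% m
  }
  as.integer(x)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  expr
}

# 2-D circular convolution via FFT. `kernel` (possibly complex, odd-sized) is
# wrapped around the origin so output pixel (r, c) is the correlation-free
# convolution centred there. Pixels further than the kernel half-width from
# every edge are exact (no wrap contamination).
conv2_fft <- function(img, kernel) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1, kr <= nr, kc <= nc)
  kpad <- matrix(0 + 0i, nr, nc)
  hr <- (kr - 1) / 2; hc <- (kc - 1) / 2
  rows <- ((-hr:hr) %% nr) + 1
  cols <- ((-hc:hc) %% nc) + 1
  kpad[rows, cols] <- kernel[, , drop = FALSE]
  out <- fft(fft(img) * fft(kpad), inverse = TRUE) / (nr * nc)
  out
}

# Gaussian low-pass smoothing of a real matrix (circular boundary), used by
# the speckle simulator. sigma in pixels.
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  h <- min(h, floor((min(dim(x)) - 1) / 2))
  g <- exp(-(-h:h)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k <- k / sum(k)
  Re(conv2_fft(x, k))
}

# Validate a grayscale image matrix.
check_gray_image <- function(img, min_dim = 1L) {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0) {
    stop("image must be a non-empty numeric matrix", call. = FALSE)
  }
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    stop(sprintf("image must be at least %dx%d", min_dim, min_dim),
         call. = FALSE)
  }
  if (anyNA(img)) stop("image contains missing values", call. = FALSE)
  invisible(img)
}

is_power_of_two <- function(n) {
  n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}
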