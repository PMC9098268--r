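# Small image builders shared across tests.

ramp_image <- function(n = 16, max_val = 255) {
  matrix(rep(seq(0, max_val, length.out = n), each = n), n, n, byrow = FALSE)
}

# intensity increases with x (columns)
hramp_image <- function(n = 16) {
  matrix(rep(seq_len(n), each = n), n, n)
}

# single-pixel +1/-1 checkerboard (value a at (1,1))
checkerboard <- function(n, a = 1, b = -1) {
  m <- outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2 == 0)
  ifelse(m, a, b)
}

# checkerboard of 2x2 blocks
block_checkerboard <- function(n, a = 1, b = -1) {
  m <- outer(seq_len(n), seq_len(n),
             function(i, j) (((i - 1) %/% 2) + ((j - 1) %/% 2)) %% 2 == 0)
  ifelse(m, a, b)
}

# 90-degree counter-clockwise rotation of a matrix
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

random_image <- function(n, levels = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(levels)) {
    matrix(runif(n * n, 0, 255), n)
  } else {
    matrix(sample(0:(levels - 1), n * n, replace = TRUE), n)
  }
}
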