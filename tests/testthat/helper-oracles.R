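# Independent brute-force oracles: plain per-pixel / per-pair enumeration
# loops, coded from the statistic definitions without reusing any package
# internals.

# ---- GLCM: enumerate every neighbour pair at distance 1 in the four
# directions, build the symmetric normalised matrix, apply the definitions.
oracle_glcm <- function(q, ng) {
  nr <- nrow(q); nc <- ncol(q)
  p <- matrix(0, ng, ng)
  offs <- list(c(0, 1), c(1, 0), c(-1, 1), c(1, 1))
  for (off in offs) {
    for (r in seq_len(nr)) {
      for (c in seq_len(nc)) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
          i <- q[r, c] + 1; j <- q[r2, c2] + 1
          p[i, j] <- p[i, j] + 1
          p[j, i] <- p[j, i] + 1
        }
      }
    }
  }
  p <- p / sum(p)
  lg <- function(v) if (v > 0) log2(v) else 0
  asm <- 0; contrast <- 0; idm <- 0; entropy <- 0; sij <- 0
  for (i in 1:ng) for (j in 1:ng) {
    asm <- asm + p[i, j]^2
    contrast <- contrast + (i - j)^2 * p[i, j]
    idm <- idm + p[i, j] / (1 + (i - j)^2)
    entropy <- entropy - p[i, j] * lg(p[i, j])
    sij <- sij + i * j * p[i, j]
  }
  px <- rowSums(p)
  mu <- sum((1:ng) * px)
  sdx <- sqrt(sum(((1:ng) - mu)^2 * px))
  correlat <- if (sdx > 0) (sij - mu^2) / sdx^2 else 0
  sos <- sum(((1:ng) - mu)^2 * px)
  psum <- numeric(2 * ng)
  pdif <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  savg <- sum((1:(2 * ng)) * psum)
  svar <- sum(((1:(2 * ng)) - savg)^2 * psum)
  sent <- -sum(sapply(seq_along(psum), function(k) psum[k] * lg(psum[k])))
  dmu <- sum((0:(ng - 1)) * pdif)
  dvar <- sum(((0:(ng - 1)) - dmu)^2 * pdif)
  dent <- -sum(sapply(seq_along(pdif), function(k) pdif[k] * lg(pdif[k])))
  c(AngScMom = asm, Contrast = contrast, Correlat = correlat,
    SumOfSqs = sos, InvDfMom = idm, SumAverg = savg, SumVarnc = svar,
    SumEntrp = sent, Entropy = entropy, DifVarnc = dvar, DifEntrp = dent)
}

# ---- GLRLM: walk every line of a direction pixel by pixel, collecting
# maximal runs, then apply the definitions.
oracle_glrlm_dir <- function(q, direction) {
  nr <- nrow(q); nc <- ncol(q)
  starts_step <- switch(direction,
    H = list(starts = lapply(seq_len(nr), function(r) c(r, 1)),
             step = c(0, 1)),
    V = list(starts = lapply(seq_len(nc), function(c) c(1, c)),
             step = c(1, 0)),
    # 45 deg: up-right; start on first column and bottom row
    Z = list(starts = c(lapply(seq_len(nr), function(r) c(r, 1)),
                        lapply(2:nc, function(c) c(nr, c))),
             step = c(-1, 1)),
    # 135 deg: down-right; start on first row and first column
    N = list(starts = c(lapply(seq_len(nc), function(c) c(1, c)),
                        lapply(2:nr, function(r) c(r, 1))),
             step = c(1, 1)))
  runs <- list()
  for (s in starts_step$starts) {
    pos <- s
    line <- c()
    while (pos[1] >= 1 && pos[1] <= nr && pos[2] >= 1 && pos[2] <= nc) {
      line <- c(line, q[pos[1], pos[2]])
      pos <- pos + starts_step$step
    }
    i <- 1
    while (i <= length(line)) {
      j <- i
      while (j < length(line) && line[j + 1] == line[i]) j <- j + 1
      runs[[length(runs) + 1]] <- c(level = line[i], len = j - i + 1)
      i <- j + 1
    }
  }
  runs <- do.call(rbind, runs)
  C <- nrow(runs)
  P <- nr * nc
  r_j <- table(runs[, "len"])
  g_i <- table(runs[, "level"])
  c(RLNonUni = sum(r_j^2) / C, GLevNonUn = sum(g_i^2) / C,
    LngREmph = sum(runs[, "len"]^2) / C,
    ShrtREmph = sum(1 / runs[, "len"]^2) / C,
    Fraction = C / P, NRLNonUni = sum(r_j^2) / C^2,
    NGLevNonUni = sum(g_i^2) / C^2)
}

oracle_glrlm <- function(q) {
  out <- numeric(0)
  for (d in c("H", "Z", "V", "N")) {
    s <- oracle_glrlm_dir(q, d)
    names(s) <- paste0(d, names(s))
    out <- c(out, s)
  }
  out
}

# ---- LBP: per-pixel code enumeration with its own bilinear sampler.
oracle_bilinear <- function(img, y, x) {
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  if (abs(fy) < 1e-9 && abs(fx) < 1e-9) return(img[y0, x0])
  (1 - fy) * (1 - fx) * img[y0, x0] +
    (1 - fy) * fx * img[y0, x0 + 1] +
    fy * (1 - fx) * img[y0 + 1, x0] +
    fy * fx * img[y0 + 1, x0 + 1]
}

oracle_lbp <- function(img, variant) {
  nr <- nrow(img); nc <- ncol(img)
  setup <- switch(variant,
    Oc4 = list(n = 4, r = 1, codes = 16),
    Tr4 = list(n = 4, r = 1, codes = 16),
    Cs4 = list(n = 4, r = 1, codes = 4),
    Cs8 = list(n = 8, r = 1, codes = 16),
    Cs12 = list(n = 12, r = 2, codes = 64))
  margin <- ceiling(setup$r)
  th <- 2 * pi * (seq_len(setup$n) - 1) / setup$n
  dy <- setup$r * sin(th); dx <- setup$r * cos(th)
  hist <- numeric(setup$codes)
  for (r in (margin + 1):(nr - margin)) {
    for (c in (margin + 1):(nc - margin)) {
      nb <- sapply(seq_len(setup$n), function(k) {
        oy <- dy[k]; ox <- dx[k]
        if (abs(oy - round(oy)) < 1e-9) oy <- round(oy)
        if (abs(ox - round(ox)) < 1e-9) ox <- round(ox)
        oracle_bilinear(img, r + oy, c + ox)
      })
      code <- switch(variant,
        Oc4 = sum((nb >= img[r, c]) * 2^(0:3)),
        Tr4 = {
          b <- nb >= img[r, c]
          sum((b != b[c(2, 3, 4, 1)]) * 2^(0:3))
        },
        Cs4 = sum((nb[1:2] >= nb[3:4]) * 2^(0:1)),
        Cs8 = sum((nb[1:4] >= nb[5:8]) * 2^(0:3)),
        Cs12 = sum((nb[1:6] >= nb[7:12]) * 2^(0:5)))
      hist[code + 1] <- hist[code + 1] + 1
    }
  }
  hist / sum(hist)
}

# ---- AUC by direct pair enumeration.
oracle_auc <- function(truth, scores) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}
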