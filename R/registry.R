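#' Texture feature registry
#'
#' The fixed, ordered catalogue of the 250 texture features the extractor
#' emits, in nine groups: histogram (9), autoregressive model (5), gradient
#' (5), histogram of oriented gradients (28), Gabor magnitude (24), Haar
#' wavelet subband energy (24), gray-level run-length matrix (28), gray-level
#' co-occurrence matrix (11), and local binary patterns (116). The registry is
#' the single source of feature ordering: every [`extract_all()`] vector and
#' feature table column block follows it.
#'
#' Naming follows the MaZda-lineage conventions, e.g. `Gab8V` (Gabor, Gaussian
#' envelope size 8, vertical direction), `HaarS2HL` (wavelet level 2, HL
#' channel), `HLngREmph` (run-length long-run emphasis, horizontal),
#' `Cs12n47` (center-symmetric LBP, 12 neighbours, code 47). Gradient moments
#' carry the `Gr` prefix (`GrVariance` is the gradient-group "Variance").
#'
#' @param gabor_sizes Gaussian envelope sizes (pixels) of the Gabor bank;
#'   must have length 6 so the group keeps its 24 slots.
#' @return a data.frame with columns `name` and `group` (250 rows).
#' @export
#' @examples
#' reg <- feature_registry()
#' nrow(reg)            # 250
#' table(reg$group)
feature_registry <- function(gabor_sizes = c(2, 4, 6, 8, 10, 12)) {
  stopifnot(length(gabor_sizes) == 6, !anyDuplicated(gabor_sizes))
  dirs <- c("H", "Z", "V", "N")

  histogram <- c("Mean", "Variance", "Skewness", "Kurtosis",
                 "Perc01", "Perc10", "Perc50", "Perc90", "Perc99")
  ar <- c("Teta1", "Teta2", "Teta3", "Teta4", "Sigma")
  gradient <- c("GrMean", "GrVariance", "GrSkewness", "GrKurtosis",
                "GrNonZeros")
  hog <- c(paste0("O4b", 0:3), paste0("O8b", 0:7), paste0("O16b", 0:15))
  gabor <- as.vector(t(outer(gabor_sizes, dirs,
                             function(s, d) paste0("Gab", s, d))))
  wavelet <- as.vector(t(outer(1:8, c("LH", "HL", "HH"),
                               function(k, ch) paste0("HaarS", k, ch))))
  glrlm_stats <- c("RLNonUni", "GLevNonUn", "LngREmph", "ShrtREmph",
                   "Fraction", "NRLNonUni", "NGLevNonUni")
  glrlm <- as.vector(t(outer(dirs, glrlm_stats, paste0)))
  glcm <- c("AngScMom", "Contrast", "Correlat", "SumOfSqs", "InvDfMom",
            "SumAverg", "SumVarnc", "SumEntrp", "Entropy", "DifVarnc",
            "DifEntrp")
  lbp <- c(paste0("Oc4n", 0:15), paste0("Tr4n", 0:15), paste0("Cs4n", 0:3),
           paste0("Cs8n", 0:15), paste0("Cs12n", 0:63))

  groups <- list(
    Histogram = histogram,
    `Autoregressive model` = ar,
    Gradient = gradient,
    `Histogram of oriented gradients` = hog,
    Gabor = gabor,
    Wavelet = wavelet,
    `Run-length matrix` = glrlm,
    `Cooccurrence matrix` = glcm,
    `Local binary patterns` = lbp
  )
  out <- data.frame(
    name = unlist(groups, use.names = FALSE),
    group = rep(names(groups), lengths(groups)),
    stringsAsFactors = FALSE
  )
  stopifnot(nrow(out) == 250, !anyDuplicated(out$name))
  out
}

#' Per-group feature counts of the registry
#'
#' @return named integer vector of group sizes, in registry order
#'   (9, 5, 5, 28, 24, 24, 28, 11, 116).
#' @export
feature_group_sizes <- function() {
  reg <- feature_registry()
  tab <- table(factor(reg$group, levels = unique(reg$group)))
  stats::setNames(as.integer(tab), names(tab))
}
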