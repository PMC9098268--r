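# Statistical gating and Relief-F ranking of features: normality check,
# two-sample t-test at alpha = 0.05 (no multiplicity correction), then
# Relief-F scores on the significant features, ranked Table-style.

#' Kolmogorov-Smirnov normality test of one feature
#'
#' Lilliefors-corrected one-sample KS test against a normal with the sample's
#' mean and SD (delegated to \code{nortest::lillie.test}; samples of size 3-4
#' fall back to the uncorrected KS test with estimated parameters). A
#' zero-variance sample returns p = 0 by convention (degenerate, non-normal).
#'
#' @param values numeric sample, n >= 3.
#' @return p-value in `[0, 1]`.
#' @export
ks_normality <- function(values) {
  stopifnot(length(values) >= 3)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(0)
  if (length(values) >= 5) {
    nortest::lillie.test(values)$p.value
  } else {
    suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), s)$p.value)
  }
}

#' Independent two-sample t-test (equal-variance form)
#'
#' Classical pooled-variance t statistic with two-sided p-value. Degenerate
#' conventions: zero pooled variance with equal means gives t = 0, p = 1;
#' zero pooled variance with unequal means gives p = 0 (perfect separation).
#'
#' @param a,b numeric samples, each n >= 2.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
two_sample_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  d <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (d == 0) return(list(statistic = 0, df = df, p.value = 1))
    return(list(statistic = sign(d) * Inf, df = df, p.value = 0))
  }
  t <- d / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t, df = df,
       p.value = 2 * stats::pt(-abs(t), df))
}

#' Screen features by normality and class difference
#'
#' Per feature: Lilliefors KS normality p-value and the two-sample t-test
#' p-value between classes; a feature is flagged significant when its t-test
#' p-value is below `alpha`. No multiple-testing correction is applied
#' (raw `P < 0.05` gating).
#'
#' @param x numeric matrix, samples x features, with column names.
#' @param labels binary vector (1/"case" = patient, 0/"control").
#' @param alpha significance level (default 0.05).
#' @return data.frame: `feature`, `ks_p`, `t_stat`, `t_p`, `significant`.
#' @export
screen_features <- function(x, labels, alpha = 0.05) {
  labels <- as_binary_labels(labels)
  stopifnot(is.matrix(x), nrow(x) == length(labels),
            !is.null(colnames(x)), all(is.finite(x)),
            any(labels == 1), any(labels == 0))
  a_rows <- labels == 1
  res <- lapply(seq_len(ncol(x)), function(j) {
    tt <- two_sample_t(x[a_rows, j], x[!a_rows, j])
    data.frame(feature = colnames(x)[j],
               ks_p = ks_normality(x[, j]),
               t_stat = tt$statistic,
               t_p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$t_p < alpha
  out
}

# Accept 0/1, logical, or case/control factor-ish labels; 1 = patient/case.
as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    l <- as.character(labels)
    stopifnot(all(l %in% c("case", "control")))
    return(as.integer(l == "case"))
  }
  l <- as.integer(labels)
  stopifnot(all(l %in% c(0L, 1L)))
  l
}

#' Relief-F feature scores
#'
#' Two-class Relief-F: for each instance R (all instances are used by
#' default), find its `k` nearest hits and `k` nearest misses by Manhattan
#' distance on range-normalised features, and update each feature weight by
#' `-diff(f, R, H)/(m k)` per hit and `+diff(f, R, M)/(m k)` per miss, with
#' `diff(f, x, y) = |x_f - y_f| / (max_f - min_f)`. With two classes the
#' multiclass prior weighting reduces to 1. Constant features score exactly 0;
#' scores lie in `[-1, 1]` and are invariant to affine rescaling of any
#' feature column. Neighbour ties are broken by lowest sample index, so the
#' result is deterministic.
#'
#' @param x numeric matrix, samples x features.
#' @param labels binary labels (1 = case).
#' @param k_neighbors nearest hits/misses per instance (default 5).
#' @param sample_count number of instances to use, in index order
#'   (default all).
#' @return named numeric vector of scores.
#' @export
relieff_scores <- function(x, labels, k_neighbors = 5L, sample_count = NULL) {
  labels <- as_binary_labels(labels)
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  n <- nrow(x)
  k <- as.integer(k_neighbors)
  if (min(table(labels)) < k + 1) {
    stop("each class needs at least k_neighbors + 1 samples; ",
         "use a smaller k_neighbors", call. = FALSE)
  }
  rng <- apply(x, 2, function(col) diff(range(col)))
  active <- rng > 0
  xn <- x
  xn[, active] <- sweep(
    sweep(x[, active, drop = FALSE], 2,
          apply(x[, active, drop = FALSE], 2, min), "-"),
    2, rng[active], "/")
  xn[, !active] <- 0
  m <- if (is.null(sample_count)) n else min(as.integer(sample_count), n)
  d <- as.matrix(stats::dist(xn, method = "manhattan"))
  w <- numeric(ncol(x))
  for (r in seq_len(m)) {
    same <- which(labels == labels[r])
    same <- same[same != r]
    diffc <- which(labels != labels[r])
    hits <- same[order(d[r, same], same)][seq_len(k)]
    misses <- diffc[order(d[r, diffc], diffc)][seq_len(k)]
    dh <- abs(sweep(xn[hits, , drop = FALSE], 2, xn[r, ], "-"))
    dm <- abs(sweep(xn[misses, , drop = FALSE], 2, xn[r, ], "-"))
    w <- w - colSums(dh) / (m * k) + colSums(dm) / (m * k)
  }
  stats::setNames(w, colnames(x))
}

#' Rank the best screened features by Relief-F score
#'
#' Applies the t-test gate first (only significant features are eligible),
#' then orders by descending Relief-F score, ties broken by registry order.
#' The output mirrors the published ranked-feature tables: columns `Group`,
#' `Rank`, `Feature`, `Score`.
#'
#' @param scores named Relief-F scores (e.g. from [relieff_scores()]).
#' @param screening screening result from [screen_features()].
#' @param top_n number of features to keep (default 10).
#' @param registry feature registry supplying group names and tie order.
#' @return data.frame `Group`, `Rank`, `Feature`, `Score`; attribute
#'   `short` is TRUE when fewer than `top_n` features were significant.
#' @export
rank_best <- function(scores, screening, top_n = 10L,
                      registry = feature_registry()) {
  sig <- screening$feature[screening$significant]
  eligible <- intersect(names(scores), sig)
  reg_pos <- match(eligible, registry$name)
  reg_pos[is.na(reg_pos)] <- match(eligible[is.na(reg_pos)], names(scores)) +
    nrow(registry)
  s <- scores[eligible]
  ord <- order(-s, reg_pos)
  keep <- head(ord, top_n)
  grp <- registry$group[match(eligible[keep], registry$name)]
  out <- data.frame(Group = ifelse(is.na(grp), "", grp),
                    Rank = seq_along(keep),
                    Feature = eligible[keep],
                    Score = unname(s[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "short") <- length(eligible) < top_n
  out
}
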