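#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed as the median, over features with
#' all-positive counts, of the ratio to the feature's geometric mean,
#' then centered so their geometric mean is 1. Falls back to total-count
#' scaling (with a warning) when no feature row is positive in every
#' sample.
#'
#' @param counts Non-negative count matrix, features x samples.
#' @return Positive numeric vector of per-sample size factors.
#' @examples
#' size_factors(matrix(c(10, 30, 20, 60), 2))  # ~ (0.707, 1.414)
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warnf("no all-positive feature row; falling back to total-count scaling")
    tot <- colSums(counts)
    if (any(tot == 0)) stopf("a sample has an all-zero library")
    sf <- tot / exp(mean(log(tot)))
    return(sf)
  }
  lc <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lc)
  sf <- apply(exp(lc - geo), 2, median)
  sf / exp(mean(log(sf)))
}

#' Negative-binomial Wald test for two-group differential abundance
#'
#' Per feature: counts are scaled by size factors, group means computed on
#' the normalized scale, a moment-based NB dispersion is pooled across the
#' two groups (floored at 1e-8), and a Wald statistic on the log2 fold
#' change (group2 / group1) is formed with a delta-method standard error,
#' `Var(K) = mu + phi mu^2`. Two-sided p values use a t reference with
#' `n1 + n2 - 2` degrees of freedom to account for small-sample variance
#' estimation. Features with zero mean in either group are flagged and
#' skipped (p = NA). Significance combines the BH-adjusted p value with
#' the fold-change rule: `padj <= alpha` and linear fold change >= `fc`
#' (or <= 1/fc); a nominal-p flag is also emitted.
#'
#' @param counts Count matrix, features x samples.
#' @param groups Character/factor vector of length `ncol(counts)` with
#'   exactly two levels; the first level (by order of appearance) is the
#'   reference group.
#' @param sf Size factors; computed with [size_factors()] when NULL.
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param fc Linear fold-change threshold (default 1.5).
#' @return data.frame: feature_id, base_mean, log2fc, dispersion, stat,
#'   pvalue, padj, significant, sig_nominal, skipped.
#' @export
nb_test <- function(counts, groups, sf = NULL, alpha = 0.05, fc = 1.5) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stopf("exactly two groups are required")
  i1 <- which(groups == lv[1]); i2 <- which(groups == lv[2])
  if (length(i1) < 2L || length(i2) < 2L) stopf("each group needs n >= 2")
  if (any(colSums(counts) == 0)) stopf("a sample has an all-zero library")
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")

  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  v1 <- apply(norm[, i1, drop = FALSE], 1, var)
  v2 <- apply(norm[, i2, drop = FALSE], 1, var)
  n1 <- length(i1); n2 <- length(i2)

  ## moment estimator of the NB dispersion, pooled across groups
  phi1 <- (v1 - m1) / m1^2
  phi2 <- (v2 - m2) / m2^2
  w1 <- n1 - 1L; w2 <- n2 - 1L
  phi <- (ifelse(is.finite(phi1), phi1, 0) * w1 +
            ifelse(is.finite(phi2), phi2, 0) * w2) / (w1 + w2)
  phi <- pmax(phi, 1e-8)

  skipped <- m1 == 0 | m2 == 0
  lfc <- log2(m2 / m1)
  se1 <- sqrt((m1 + phi * m1^2) / n1)
  se2 <- sqrt((m2 + phi * m2^2) / n2)
  vlog <- (se1^2 / m1^2 + se2^2 / m2^2) / log(2)^2
  stat <- lfc / sqrt(vlog)
  pval <- 2 * pt(-abs(stat), df = n1 + n2 - 2L)
  pval[skipped] <- NA_real_
  stat[skipped] <- NA_real_
  lfc[skipped] <- ifelse(m2[skipped] > m1[skipped], Inf,
                         ifelse(m2[skipped] < m1[skipped], -Inf, 0))
  padj <- rep(NA_real_, length(pval))
  padj[!skipped] <- bh_adjust(pval[!skipped])

  fids <- rownames(counts)
  if (is.null(fids)) fids <- sprintf("f%05d", seq_len(nrow(counts)))
  fc_pass <- abs(lfc) >= log2(fc)
  data.frame(
    feature_id = fids,
    base_mean = (m1 * n1 + m2 * n2) / (n1 + n2),
    log2fc = lfc, dispersion = phi, stat = stat, pvalue = pval, padj = padj,
    significant = !skipped & !is.na(padj) & padj <= alpha & fc_pass,
    sig_nominal = !skipped & !is.na(pval) & pval <= alpha & fc_pass,
    skipped = skipped,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' PCA of a log-normalized expression matrix
#'
#' Principal components of samples computed on log2(x + 1) of
#' median-of-ratios normalized counts, features centered.
#'
#' @param counts Count matrix, features x samples.
#' @param sf Size factors; computed with [size_factors()] when NULL.
#' @param n_components Number of components to return.
#' @return list: `scores` (samples x components), `percent_var` (percent
#'   variance explained per returned component).
#' @export
pca_scores <- function(counts, sf = NULL, n_components = 2L) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 3L) stopf("need at least 3 samples")
  if (is.null(sf)) sf <- size_factors(counts)
  x <- log2(sweep(counts, 2, sf, "/") + 1)
  keep <- apply(x, 1, function(r) var(r) > 0)
  if (!any(keep)) {
    warnf("constant matrix: all features have zero variance")
    k <- min(n_components, ncol(counts))
    return(list(scores = matrix(0, ncol(counts), k,
                                dimnames = list(colnames(counts),
                                                paste0("PC", seq_len(k)))),
                percent_var = rep(0, k)))
  }
  pc <- prcomp(t(x[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       percent_var = pv[seq_len(k)])
}
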