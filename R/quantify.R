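#' Back-splice-to-linear ratio
#'
#' The circRNA expression measure relative to the host linear transcript:
#' the mean back-splice junction read count over samples divided by the
#' larger of the mean left and right linear-junction read counts of the
#' same exon(s),
#' `ratio = mean(c) / max(mean(l1), mean(l2))`.
#' The ratio is undefined (and excluded from summaries) when both linear
#' means are zero.
#'
#' @param c_counts Per-sample back-splice junction counts.
#' @param l1_counts Per-sample counts of the left linear-spliced junction;
#'   NA-free numeric of the same length as `c_counts` (use zeros when the
#'   junction does not exist).
#' @param l2_counts Same for the right linear junction.
#' @return list with avg_c, avg_l1, avg_l2, ratio, defined.
#' @examples
#' backsplice_linear_ratio(c(2, 2), c(10, 10), c(20, 20))$ratio  # 0.1
#' @export
backsplice_linear_ratio <- function(c_counts, l1_counts, l2_counts) {
  n <- length(c_counts)
  if (length(l1_counts) != n || length(l2_counts) != n) {
    stopf("c, l1 and l2 must cover the same samples (equal lengths)")
  }
  avg_c <- mean(c_counts)
  avg_l1 <- mean(l1_counts)
  avg_l2 <- mean(l2_counts)
  denom <- max(avg_l1, avg_l2)
  defined <- denom > 0
  list(avg_c = avg_c, avg_l1 = avg_l1, avg_l2 = avg_l2,
       ratio = if (defined) avg_c / denom else NA_real_,
       defined = defined)
}

#' Ratio table for called circRNAs
#'
#' For each filter-passing call, locates the back-splice junction counts
#' (c) and the linear junctions flanking the circle: l1 spans the upstream
#' exon to the first back-spliced exon, l2 the last back-spliced exon to
#' the downstream exon (transcript order). A missing flank (circle at a
#' transcript end) contributes zero counts. Averages are taken over the
#' selected samples (all samples by default).
#'
#' @param evidence Evidence table from [junction_evidence()].
#' @param calls Calls from [call_circrnas()].
#' @param samples Optional character vector of sample ids to average over.
#' @return data.frame: circ_id, gene_id, avg_c, avg_l1, avg_l2, ratio,
#'   defined.
#' @export
ratio_table <- function(evidence, calls, samples = NULL) {
  cm <- evidence_counts(evidence)
  if (is.null(samples)) samples <- colnames(cm)
  cm <- cm[, samples, drop = FALSE]
  calls <- calls[calls$passes_filter, , drop = FALSE]
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    jid <- calls$junction_id[i]
    gid <- calls$gene_id[i]
    a <- calls$tx_first[i]; b <- calls$tx_last[i]
    cc <- cm[jid, ]
    getj <- function(id) {
      if (id %in% rownames(cm)) cm[id, ] else rep(0, length(samples))
    }
    l1 <- if (a > 1) getj(linear_junction_id(gid, a - 1L)) else
      rep(0, length(samples))
    l2 <- getj(linear_junction_id(gid, b))
    r <- backsplice_linear_ratio(cc, l1, l2)
    data.frame(circ_id = calls$circ_id[i], gene_id = gid,
               avg_c = r$avg_c, avg_l1 = r$avg_l1, avg_l2 = r$avg_l2,
               ratio = r$ratio, defined = r$defined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(circ_id = character(0), gene_id = character(0),
                      avg_c = numeric(0), avg_l1 = numeric(0),
                      avg_l2 = numeric(0), ratio = numeric(0),
                      defined = logical(0))
  }
  out
}

#' Summarize back-splice-to-linear ratios per group
#'
#' Median and quartiles (linear interpolation, `quantile` type 7) of the
#' defined ratios in each group; undefined records are excluded and
#' counted.
#'
#' @param records Ratio table from [ratio_table()] (needs `ratio` and
#'   `defined` columns).
#' @param grouping Character vector of group labels (e.g. cell type), one
#'   per record; a single value is recycled.
#' @return data.frame: group, n, n_undefined, q1, median, q3. Groups with
#'   no defined record are flagged with NA summaries.
#' @export
summarize_ratios <- function(records, grouping = "all") {
  if (length(grouping) == 1L) grouping <- rep(grouping, nrow(records))
  if (length(grouping) != nrow(records)) {
    stopf("grouping must have one label per record")
  }
  out <- lapply(unique(grouping), function(g) {
    rec <- records[grouping == g, , drop = FALSE]
    ok <- rec$defined & !is.na(rec$ratio)
    r <- rec$ratio[ok]
    if (length(r) == 0L) {
      data.frame(group = g, n = 0L, n_undefined = sum(!ok),
                 q1 = NA_real_, median = NA_real_, q3 = NA_real_)
    } else {
      q <- unname(quantile(r, c(0.25, 0.5, 0.75), type = 7))
      data.frame(group = g, n = length(r), n_undefined = sum(!ok),
                 q1 = q[1], median = q[2], q3 = q[3])
    }
  })
  do.call(rbind, out)
}

#' Paired comparison of circRNA vs host linear expression
#'
#' Pairs each circRNA with its host gene's linear expression and applies a
#' classical paired Student t test to the per-pair values, by default
#' log2(x + 1) of median-of-ratios-normalized counts averaged over
#' samples. When all per-pair differences are zero the test statistic is
#' taken as 0 with p = 1 (the no-signal limit of the t test).
#'
#' @param circ_mat Numeric matrix, circRNA features x samples.
#' @param host_mat Numeric matrix of the matched host features, same
#'   dimensions and sample order (row i of `host_mat` is the host of row i
#'   of `circ_mat`).
#' @param normalize Apply median-of-ratios size factors estimated from the
#'   host (linear) matrix to both matrices.
#' @param log_transform Apply log2(x + 1) before averaging.
#' @return list with t, df, p, n_pairs, mean_diff (circ - host).
#' @export
circ_vs_linear_test <- function(circ_mat, host_mat, normalize = TRUE,
                                log_transform = TRUE) {
  if (!all(dim(circ_mat) == dim(host_mat))) {
    stopf("circ and host matrices must have identical dimensions")
  }
  if (nrow(circ_mat) < 2L) stopf("need at least 2 circ/host pairs")
  if (normalize) {
    sf <- size_factors(host_mat)
    circ_mat <- sweep(circ_mat, 2, sf, "/")
    host_mat <- sweep(host_mat, 2, sf, "/")
  }
  if (log_transform) {
    circ_mat <- log2(circ_mat + 1)
    host_mat <- log2(host_mat + 1)
  }
  x <- rowMeans(circ_mat)
  y <- rowMeans(host_mat)
  d <- x - y
  n <- length(d)
  sdd <- sd(d)
  if (sdd == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = n - 1L, p = 1, n_pairs = n, mean_diff = 0))
    }
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0, n_pairs = n,
                mean_diff = mean(d)))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_pairs = n, mean_diff = mean(d))
}

#' Expression matrices for circRNAs and their host genes
#'
#' Builds the circRNA count matrix (back-splice junction counts of
#' filter-passing calls) and the matched host linear expression matrix
#' (mean linear-junction count of the host gene, a per-junction quantity
#' commensurate with the back-splice counts).
#'
#' @param evidence Evidence table from [junction_evidence()].
#' @param calls Calls from [call_circrnas()].
#' @return list with `circ` (matrix, rows = circ_id) and `host` (matrix,
#'   same row order, rows = host gene expression).
#' @export
expression_matrices <- function(evidence, calls) {
  cm <- evidence_counts(evidence)
  calls <- calls[calls$passes_filter, , drop = FALSE]
  lin <- evidence[evidence$kind == "linear", , drop = FALSE]
  lin_cm <- evidence_counts(lin)
  circ <- cm[calls$junction_id, , drop = FALSE]
  rownames(circ) <- calls$circ_id
  host <- t(vapply(calls$gene_id, function(g) {
    rows <- lin_cm[lin$gene_id == g, , drop = FALSE]
    if (nrow(rows) == 0) rep(0, ncol(cm)) else colMeans(rows)
  }, numeric(ncol(cm))))
  rownames(host) <- calls$circ_id
  list(circ = circ, host = host)
}
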