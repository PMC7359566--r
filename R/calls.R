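#' Call circRNAs from back-splice junction evidence
#'
#' Applies the read-support filter to back-splice junction evidence. Under
#' the default per-sample interpretation a circRNA passes when at least
#' `min_samples` samples each contribute at least `min_reads` back-spliced
#' reads; the pooled interpretation requires a total of `min_reads` reads
#' across samples and detection (count > 0) in at least `min_samples`
#' samples. All candidates are returned with a `passes_filter` flag so the
#' filtered set is derivable.
#'
#' @param evidence Evidence table from [junction_evidence()] (only
#'   backsplice rows are used).
#' @param min_reads Minimum supporting back-spliced reads (default 4).
#' @param min_samples Minimum number of samples (default 2).
#' @param mode Filter interpretation: "per_sample" (default) or "pooled".
#' @return data.frame of circRNA calls: circ_id ("contig:start-end", 1-based
#'   inclusive genomic span), gene_id, contig, strand, start, end, tx_first,
#'   tx_last (member transcript-order exon indices), per-sample count
#'   columns, passes_filter.
#' @examples
#' ev <- data.frame(junction_id = "g1:B02-03", kind = "backsplice",
#'                  gene_id = "g1", contig = "ctg1", strand = "+",
#'                  start = 1000, end = 1400, span = 401,
#'                  count.s1 = 5, count.s2 = 4, count.s3 = 0)
#' call_circrnas(ev)$passes_filter
#' @export
call_circrnas <- function(evidence, min_reads = 4L, min_samples = 2L,
                          mode = c("per_sample", "pooled")) {
  mode <- match.arg(mode)
  if (!is_count(min_reads) || min_reads < 1L ||
      !is_count(min_samples) || min_samples < 1L) {
    stopf("min_reads and min_samples must be integers >= 1")
  }
  bs <- evidence[evidence$kind == "backsplice", , drop = FALSE]
  cm <- evidence_counts(bs)
  passes <- if (mode == "per_sample") {
    rowSums(cm >= min_reads) >= min_samples
  } else {
    rowSums(cm) >= min_reads & rowSums(cm > 0L) >= min_samples
  }
  idx <- regmatches(bs$junction_id,
                    regexec("B([0-9]+)-([0-9]+)$", bs$junction_id))
  out <- data.frame(
    circ_id = sprintf("%s:%d-%d", bs$contig, bs$start, bs$end),
    junction_id = bs$junction_id,
    gene_id = bs$gene_id, contig = bs$contig, strand = bs$strand,
    start = bs$start, end = bs$end,
    tx_first = vapply(idx, function(m) as.integer(m[2]), 1L),
    tx_last = vapply(idx, function(m) as.integer(m[3]), 1L),
    stringsAsFactors = FALSE
  )
  for (cc in grep("^count\\.", names(bs), value = TRUE)) out[[cc]] <- bs[[cc]]
  out$passes_filter <- unname(passes)
  rownames(out) <- NULL
  out
}

#' Parse a circRNA identifier
#'
#' @param circ_id Character vector of ids formatted "contig:start-end".
#' @return data.frame with contig, start, end.
#' @export
parse_circ_id <- function(circ_id) {
  m <- regmatches(circ_id, regexec("^(.+):([0-9]+)-([0-9]+)$", circ_id))
  bad <- lengths(m) != 4L
  if (any(bad)) stopf("malformed circ_id: %s", circ_id[bad][1])
  data.frame(
    contig = vapply(m, `[`, "", 2L),
    start = vapply(m, function(x) as.integer(x[3]), 1L),
    end = vapply(m, function(x) as.integer(x[4]), 1L),
    stringsAsFactors = FALSE
  )
}

#' Evaluate calls against the planted truth
#'
#' Matching requires exact genomic coordinates (contig, start, end); an
#' off-by-one boundary call counts as a false positive.
#'
#' @param calls Calls from [call_circrnas()]; only rows with
#'   `passes_filter` are evaluated.
#' @param truth Truth set from [plant_circs_and_rcs()], or a data.frame
#'   with a `circ_id` column.
#' @return list with precision, recall, n_called, n_truth, true_positives,
#'   false_positives, false_negatives (circ_id vectors).
#' @export
evaluate_calls <- function(calls, truth) {
  truth_ids <- if (is.data.frame(truth)) truth$circ_id else
    truth$planted_circs$circ_id
  called <- unique(calls$circ_id[calls$passes_filter])
  tp <- intersect(called, truth_ids)
  fp <- setdiff(called, truth_ids)
  fn <- setdiff(truth_ids, called)
  list(
    precision = if (length(called)) length(tp) / length(called) else NA_real_,
    recall = if (length(truth_ids)) length(tp) / length(truth_ids) else NA_real_,
    n_called = length(called), n_truth = length(truth_ids),
    true_positives = tp, false_positives = fp, false_negatives = fn
  )
}
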