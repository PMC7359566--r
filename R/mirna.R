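#' Seed sequence of a mature miRNA
#'
#' The DNA reverse complement of miRNA nucleotides 2-8 (the 7-mer seed
#' match searched for in transcript sequence).
#'
#' @param mirna Mature miRNA sequence (RNA or DNA alphabet), >= 8 nt.
#' @return 7-mer DNA string, or NA (with a warning) when the seed window
#'   contains ambiguous bases.
#' @export
mirna_seed_match <- function(mirna) {
  if (nchar(mirna) < 8L) stopf("miRNA must be at least 8 nt")
  seed <- substring(chartr("Uu", "Tt", toupper(mirna)), 2L, 8L)
  if (grepl("[^ACGT]", seed)) {
    warnf("ambiguous base in seed window of '%s'; miRNA skipped", mirna)
    return(NA_character_)
  }
  revcomp1(seed)
}

#' Count miRNA seed-complementary sites in exon sequences
#'
#' Counts exact occurrences of each miRNA's 7-mer seed match (reverse
#' complement of miRNA nt 2-8) in each exon sequence; overlapping
#' occurrences are counted. miRNAs with ambiguous seed bases are skipped
#' with a warning.
#'
#' @param exon_seqs Named character vector of exon sequences (transcript
#'   orientation).
#' @param mirnas Named character vector of mature miRNA sequences.
#' @return Integer matrix, exons x miRNAs.
#' @export
seed_sites <- function(exon_seqs, mirnas) {
  seeds <- vapply(mirnas, mirna_seed_match, "")
  keep <- !is.na(seeds)
  out <- matrix(0L, length(exon_seqs), length(mirnas),
                dimnames = list(names(exon_seqs), names(mirnas)))
  if (!length(exon_seqs) || !any(keep)) return(out)
  long_enough <- nchar(exon_seqs) >= 7L
  if (any(long_enough)) {
    cnt <- Biostrings::vcountPDict(Biostrings::DNAStringSet(seeds[keep]),
                                   Biostrings::DNAStringSet(exon_seqs[long_enough]))
    out[long_enough, keep] <- t(cnt)
  }
  out
}

#' Exons that do not circularize (control set)
#'
#' All annotated exons that are not a member of any filter-passing circRNA
#' call.
#'
#' @param exons Exon table.
#' @param calls Calls from [call_circrnas()].
#' @return Character vector of control exon ids ("gene:E<genomic index>");
#'   a warning is emitted when every exon circularizes.
#' @export
build_control_set <- function(exons, calls) {
  all_ids <- sprintf("%s:E%d", exons$gene_id, exons$exon)
  calls <- calls[calls$passes_filter, , drop = FALSE]
  member <- character(0)
  for (i in seq_len(nrow(calls))) {
    e <- gene_exons(exons, calls$gene_id[i])
    n <- nrow(e)
    g <- sort(c(tx_to_genomic_idx(n, e$strand[1], calls$tx_first[i]),
                tx_to_genomic_idx(n, e$strand[1], calls$tx_last[i])))
    member <- c(member,
                sprintf("%s:E%d", calls$gene_id[i], seq(g[1], g[2])))
  }
  ctrl <- setdiff(all_ids, member)
  if (length(ctrl) == 0L) warnf("every annotated exon circularizes; control set is empty")
  ctrl
}

#' Seed-match table for circRNA and control exons
#'
#' Per-exon miRNA seed-site counts and site densities (sites per kb) for
#' exons inside filter-passing circRNAs ("circ") versus all other exons
#' ("control").
#'
#' @param exons Exon table.
#' @param genome Named character vector of contig sequences.
#' @param calls Calls from [call_circrnas()].
#' @param mirnas Named character vector of mature miRNA sequences.
#' @return data.frame: exon_id, group ("circ"/"control"), length, total
#'   (summed sites over miRNAs), density (sites per kb), plus one column
#'   per miRNA.
#' @export
seed_match_table <- function(exons, genome, calls, mirnas) {
  ids <- sprintf("%s:E%d", exons$gene_id, exons$exon)
  seqs <- vapply(seq_len(nrow(exons)), function(i) {
    s <- substring(genome[[exons$contig[i]]], exons$start[i], exons$end[i])
    if (exons$strand[i] == "-") revcomp1(s) else s
  }, "")
  names(seqs) <- ids
  ctrl <- build_control_set(exons, calls)
  grp <- ifelse(ids %in% ctrl, "control", "circ")
  cnt <- seed_sites(seqs, mirnas)
  len <- nchar(seqs)
  out <- data.frame(exon_id = ids, group = grp, length = len,
                    total = rowSums(cnt),
                    density = rowSums(cnt) / (len / 1000),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(cnt))
}

#' Compare circRNA and control seed-site distributions by empirical CDF
#'
#' Two-sample Kolmogorov-Smirnov test on per-exon seed-site densities
#' (or raw counts): D is the supremum distance between the two empirical
#' CDFs, with the two-sided p value.
#'
#' @param circ_values Densities (or counts) for circRNA exons, n >= 5.
#' @param control_values Same for control exons, n >= 5.
#' @return list: D, p, n_circ, n_control.
#' @export
cdf_enrichment <- function(circ_values, control_values) {
  if (length(circ_values) < 5L || length(control_values) < 5L) {
    stopf("each group needs at least 5 values")
  }
  kt <- suppressWarnings(ks.test(circ_values, control_values))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_circ = length(circ_values), n_control = length(control_values))
}
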