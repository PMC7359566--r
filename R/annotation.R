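#' Gene-model exon tables
#'
#' The package's canonical gene model is a plain data.frame with one row per
#' exon and columns `gene_id`, `contig`, `strand` ("+"/"-"), `exon` (1-based
#' index in genomic, ascending order), `start`, `end` (1-based, inclusive).
#' Exons of a gene are non-overlapping; introns are the gaps between
#' consecutive exons. Transcript order equals genomic order on "+" genes and
#' reversed genomic order on "-" genes.
#'
#' @param exons Exon table as described above.
#' @return `exons`, invisibly, after validation.
#' @export
validate_exons <- function(exons) {
  need <- c("gene_id", "contig", "strand", "exon", "start", "end")
  if (!all(need %in% names(exons))) {
    stopf("exon table must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(exons$start > exons$end)) stopf("exon with start > end")
  if (!all(exons$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  for (g in unique(exons$gene_id)) {
    e <- exons[exons$gene_id == g, ]
    e <- e[order(e$exon), ]
    if (!all(diff(e$start) > 0) || any(utils::head(e$end, -1) >= e$start[-1])) {
      stopf("gene %s has overlapping or unordered exons", g)
    }
  }
  invisible(exons)
}

## exon rows of one gene, in genomic order
gene_exons <- function(exons, gene_id) {
  e <- exons[exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(e) == 0) stopf("unknown gene_id: %s", gene_id)
  e[order(e$exon), , drop = FALSE]
}

#' Intron coordinates of a gene
#'
#' Introns are derived as gaps between consecutive exons, in genomic order.
#'
#' @param exons Exon table (see [validate_exons()]).
#' @param gene_id Gene identifier.
#' @return data.frame with columns intron (index, genomic order), start, end;
#'   zero rows for single-exon genes.
#' @export
gene_introns <- function(exons, gene_id) {
  e <- gene_exons(exons, gene_id)
  n <- nrow(e)
  if (n < 2) {
    return(data.frame(intron = integer(0), start = integer(0), end = integer(0)))
  }
  data.frame(
    intron = seq_len(n - 1L),
    start = e$end[-n] + 1L,
    end = e$start[-1] - 1L
  )
}

## genomic exon index for a transcript-order index (1 = 5' exon of the mRNA)
tx_to_genomic_idx <- function(n_exons, strand, tx_idx) {
  if (strand == "+") tx_idx else n_exons - tx_idx + 1L
}

## exon sequences of a gene in transcript order and orientation
gene_exon_seqs <- function(exons, genome, gene_id) {
  e <- gene_exons(exons, gene_id)
  ctg <- genome[[e$contig[1]]]
  seqs <- substring(ctg, e$start, e$end)
  if (e$strand[1] == "-") seqs <- rev(vapply(seqs, revcomp1, ""))
  unname(seqs)
}

## full (single-isoform) transcript sequence
gene_transcript <- function(exons, genome, gene_id) {
  paste(gene_exon_seqs(exons, genome, gene_id), collapse = "")
}

#' Convert an exon table to a GRanges object
#'
#' @param exons Exon table (see [validate_exons()]).
#' @return A `GRanges` with `type`, `gene_id`, `transcript_id` and
#'   `exon_number` metadata columns, suitable for GTF export.
#' @export
exons_to_granges <- function(exons) {
  gr <- GenomicRanges::GRanges(
    seqnames = exons$contig,
    ranges = IRanges::IRanges(exons$start, exons$end),
    strand = exons$strand
  )
  S4Vectors::mcols(gr)$source <- "backsplice"
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- exons$gene_id
  S4Vectors::mcols(gr)$transcript_id <- paste0(exons$gene_id, ".t1")
  S4Vectors::mcols(gr)$exon_number <- exons$exon
  gr
}

#' Convert a GRanges of exon features to an exon table
#'
#' @param gr A `GRanges` with `gene_id` metadata (e.g. from GTF import);
#'   non-exon features are dropped if a `type` column is present.
#' @return An exon table (see [validate_exons()]).
#' @export
granges_to_exons <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% names(mc)) gr <- gr[as.character(mc$type) == "exon"]
  mc <- S4Vectors::mcols(gr)
  ex <- data.frame(
    gene_id = as.character(mc$gene_id),
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    exon = if ("exon_number" %in% names(mc)) {
      as.integer(as.character(mc$exon_number))
    } else {
      NA_integer_
    },
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  ex <- ex[order(ex$gene_id, ex$start), ]
  if (anyNA(ex$exon)) {
    ex$exon <- stats::ave(ex$start, ex$gene_id, FUN = seq_along)
  }
  rownames(ex) <- NULL
  validate_exons(ex)
  ex
}
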