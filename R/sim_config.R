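#' Simulation configuration
#'
#' Bundles every tunable of the synthetic genome, truth set and read
#' simulator. Defaults emulate a small two-group (healthy vs patient) bulk
#' RNA-seq study of exonic circRNAs: multi-exon genes with long, long-tailed
#' introns, a subset of genes carrying a planted exon-only circRNA whose
#' genomic span is at least `min_span` nucleotides, inverted Alu-like repeat
#' pairs in the flanking introns of circularizing genes, negative-binomial
#' per-gene molecule counts, and paired-end reads that span linear and
#' back-spliced junctions.
#'
#' @param seed Integer seed; the same configuration (including seed) yields
#'   byte-identical FASTA/GTF/FASTQ outputs.
#' @param n_contigs Number of contigs in the toy genome.
#' @param genes_per_contig Genes placed (without overlap) on each contig.
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene.
#' @param exon_len Range `c(min, max)` of exon lengths in nt. The minimum
#'   must exceed `read_len - 2 * anchor_min` so that a read can span at most
#'   one junction with full anchors on both sides.
#' @param intron_len Range `c(min, max)` of intron lengths in nt; lengths are
#'   drawn log-uniformly, giving the long right tail seen in real introns.
#' @param circ_gene_fraction Proportion of eligible genes (>= 3 exons) given
#'   a planted circRNA.
#' @param rcs_plant_prob Probability that a circularizing gene receives an
#'   inverted repeat (RCS) pair in its flanking introns.
#' @param circ_intron_mult Multiplier applied to intron lengths of
#'   circularizing genes, emulating the longer flanking introns of circRNA
#'   host genes; set to 1 to disable.
#' @param groups Named integer vector, group label -> number of samples,
#'   e.g. `c(healthy = 4, patient = 6)`.
#' @param depth Expected read pairs per sample.
#' @param read_len Read length in nt (each mate).
#' @param fragment_len Numeric `c(mean, sd)` of fragment length in nt;
#'   `read_len` must not exceed the mean.
#' @param circ_fraction Mean circular:total molarity at circ genes for the
#'   first (reference) group.
#' @param nb_dispersion Negative-binomial dispersion of per-gene molecule
#'   counts (0 gives Poisson).
#' @param effect_log2fc Group effect (log2 fold change) applied to the
#'   circular fraction of planted circRNAs in every non-reference group.
#' @param error_rate Per-base uniform substitution error rate (default 0).
#' @param n_mirnas Number of mature miRNA sequences emitted with the genome.
#' @param mirna_len Mature miRNA length in nt.
#' @param min_span Minimum genomic span (max - min + 1) of a planted circRNA.
#' @param anchor_min Minimum read overhang (nt) on each side of a junction
#'   for the read to count as junction-spanning, used when annotating the
#'   truth table; must match the detector setting for truth equivalence.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_contigs = 1, genes_per_contig = 4)
#' cfg$depth
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 2L,
                       genes_per_contig = 20L,
                       exons_per_gene = c(4L, 8L),
                       exon_len = c(150L, 300L),
                       intron_len = c(300L, 1500L),
                       circ_gene_fraction = 0.3,
                       rcs_plant_prob = 0.8,
                       circ_intron_mult = 3,
                       groups = c(healthy = 4L, patient = 6L),
                       depth = 20000L,
                       read_len = 126L,
                       fragment_len = c(300, 30),
                       circ_fraction = 0.1,
                       nb_dispersion = 0.1,
                       effect_log2fc = 1,
                       error_rate = 0,
                       n_mirnas = 30L,
                       mirna_len = 22L,
                       min_span = 200L,
                       anchor_min = 25L) {
  cfg <- list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    genes_per_contig = as.integer(genes_per_contig),
    exons_per_gene = as.integer(exons_per_gene),
    exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
    circ_gene_fraction = circ_gene_fraction, rcs_plant_prob = rcs_plant_prob,
    circ_intron_mult = circ_intron_mult, groups = groups,
    depth = as.integer(depth), read_len = as.integer(read_len),
    fragment_len = as.numeric(fragment_len), circ_fraction = circ_fraction,
    nb_dispersion = nb_dispersion, effect_log2fc = effect_log2fc,
    error_rate = error_rate, n_mirnas = as.integer(n_mirnas),
    mirna_len = as.integer(mirna_len), min_span = as.integer(min_span),
    anchor_min = as.integer(anchor_min)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` object (or plain list with the same fields).
#' @return `cfg`, invisibly, if valid; otherwise an error listing violations.
#' @export
validate_sim_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(is_count(cfg$seed), "seed must be a single integer")
  for (f in c("n_contigs", "genes_per_contig", "read_len", "n_mirnas",
              "mirna_len", "min_span", "anchor_min")) {
    chk(is_count(cfg[[f]]) && cfg[[f]] > 0, paste(f, "must be a positive integer"))
  }
  chk(is_count(cfg$depth) && cfg$depth >= 0, "depth must be a non-negative integer")
  for (f in c("exons_per_gene", "exon_len", "intron_len")) {
    v <- cfg[[f]]
    chk(length(v) == 2L && all(v > 0) && v[1] <= v[2],
        paste(f, "must be a positive range c(min, max)"))
  }
  for (f in c("circ_gene_fraction", "rcs_plant_prob", "circ_fraction",
              "error_rate")) {
    v <- cfg[[f]]
    chk(length(v) == 1L && is.numeric(v) && v >= 0 && v <= 1,
        paste(f, "must be a probability in [0, 1]"))
  }
  chk(is.numeric(cfg$circ_intron_mult) && cfg$circ_intron_mult >= 1,
      "circ_intron_mult must be >= 1")
  chk(is.numeric(cfg$nb_dispersion) && cfg$nb_dispersion >= 0,
      "nb_dispersion must be >= 0")
  chk(is.numeric(cfg$effect_log2fc) && length(cfg$effect_log2fc) == 1L,
      "effect_log2fc must be a single number")
  chk(length(cfg$groups) >= 1 && !is.null(names(cfg$groups)) &&
        all(nzchar(names(cfg$groups))) && all(cfg$groups >= 1),
      "groups must be a named vector of positive sample counts")
  chk(length(cfg$fragment_len) == 2L && cfg$fragment_len[1] > 0 &&
        cfg$fragment_len[2] >= 0,
      "fragment_len must be c(mean, sd) with mean > 0")
  chk(cfg$read_len <= cfg$fragment_len[1],
      "read_len must not exceed the mean fragment length")
  if (length(bad)) {
    stopf("invalid sim_config:\n  - %s", paste(bad, collapse = "\n  - "))
  }
  invisible(cfg)
}

#' Sample metadata for a configuration
#'
#' @param cfg A `sim_config`.
#' @param cell_type Cell-type label recorded for every sample.
#' @return data.frame with columns sample_id, group, cell_type.
#' @export
sample_metadata <- function(cfg, cell_type = "CD14") {
  grp <- rep(names(cfg$groups), cfg$groups)
  idx <- unlist(lapply(cfg$groups, seq_len), use.names = FALSE)
  data.frame(
    sample_id = paste0(grp, "_", idx),
    group = grp,
    cell_type = cell_type,
    stringsAsFactors = FALSE
  )
}
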