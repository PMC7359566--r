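## run-configuration schema: key -> c(type, length) with defaults taken
## from sim_config() plus detector/analysis parameters
run_config_defaults <- function() {
  cfg <- sim_config()
  list(
    seed = cfg$seed, n_contigs = cfg$n_contigs,
    genes_per_contig = cfg$genes_per_contig,
    exons_per_gene = cfg$exons_per_gene, exon_len = cfg$exon_len,
    intron_len = cfg$intron_len,
    circ_gene_fraction = cfg$circ_gene_fraction,
    rcs_plant_prob = cfg$rcs_plant_prob,
    circ_intron_mult = cfg$circ_intron_mult,
    groups = cfg$groups, depth = cfg$depth, read_len = cfg$read_len,
    fragment_len = cfg$fragment_len, circ_fraction = cfg$circ_fraction,
    nb_dispersion = cfg$nb_dispersion, effect_log2fc = cfg$effect_log2fc,
    error_rate = cfg$error_rate, n_mirnas = cfg$n_mirnas,
    mirna_len = cfg$mirna_len, min_span = cfg$min_span,
    anchor_min = cfg$anchor_min,
    anchor = 50L, max_mismatch = 0L, min_reads = 4L, min_samples = 2L,
    filter_mode = "per_sample", n_shuffles = 199L, rcs_max_len = 5000L,
    repeat_min_identity = 0.8, repeat_min_len = 50L,
    de_alpha = 0.05, de_fc = 1.5
  )
}

#' Validate a pipeline run configuration
#'
#' Checks keys and value ranges of a flat run configuration (a named list,
#' or a path to a key=value file readable by [read_run_config()]). Unknown
#' keys and out-of-range values are violations.
#'
#' @param config Named list or file path.
#' @return Character vector of violations (empty when the configuration is
#'   valid), with the parsed, defaults-filled configuration attached as
#'   attribute "config".
#' @examples
#' validate_run_config(list(min_reads = 0))  # one violation
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  defs <- run_config_defaults()
  bad <- character(0)
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown)) {
    bad <- c(bad, paste("unknown config key:", unknown))
  }
  out <- defs
  for (k in intersect(names(config), names(defs))) {
    v <- config[[k]]
    if (k == "filter_mode") {
      out[[k]] <- as.character(v)
      if (!out[[k]] %in% c("per_sample", "pooled")) {
        bad <- c(bad, "filter_mode must be per_sample or pooled")
      }
      next
    }
    if (k == "groups") {
      gv <- suppressWarnings(as.integer(v))
      names(gv) <- names(v)
      if (anyNA(gv) || is.null(names(gv)) || !all(nzchar(names(gv)))) {
        bad <- c(bad, "groups must be named sample counts (label:n)")
      } else {
        out[[k]] <- gv
      }
      next
    }
    nv <- suppressWarnings(as.numeric(v))
    if (anyNA(nv) || length(nv) != length(defs[[k]])) {
      bad <- c(bad, sprintf("config key %s: expected %d numeric value(s)",
                            k, length(defs[[k]])))
      next
    }
    out[[k]] <- if (is.integer(defs[[k]])) as.integer(nv) else nv
  }
  if (!length(bad)) {
    sim_fields <- names(formals(sim_config))
    scfg <- tryCatch(do.call(sim_config, out[intersect(names(out), sim_fields)]),
                     error = function(e) conditionMessage(e))
    if (is.character(scfg)) bad <- c(bad, scfg)
    if (out$min_reads < 1 || out$min_samples < 1) {
      bad <- c(bad, "min_reads and min_samples must be >= 1")
    }
    if (out$depth < 0) bad <- c(bad, "depth must be non-negative")
    if (out$n_shuffles < 99) bad <- c(bad, "n_shuffles must be >= 99")
  }
  attr(bad, "config") <- out
  bad
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full simulate-detect-characterize pipeline
#'
#' Orchestrates simulation, junction detection, circRNA calling,
#' back-splice-to-linear quantification, flanking-intron RCS and repeat
#' characterization, miRNA seed-site CDF comparison and differential
#' abundance testing as one reproducible run. All stage outputs are
#' written as FASTA/GTF/FASTQ/TSV files under `outdir` together with a
#' JSON manifest carrying the configuration snapshot, seed, and an MD5
#' hash of every output file. Re-running with the same configuration
#' reproduces identical output hashes.
#'
#' @param config Named list or path to a key=value configuration file; see
#'   [validate_run_config()] for keys and defaults.
#' @param outdir Output directory (created if needed).
#' @return The run manifest, invisibly (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = list(), outdir) {
  viol <- validate_run_config(config)
  if (length(viol)) {
    stopf("invalid configuration:\n  - %s", paste(viol, collapse = "\n  - "))
  }
  rc <- attr(viol, "config")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim_fields <- names(formals(sim_config))
  cfg <- do.call(sim_config, rc[intersect(names(rc), sim_fields)])

  ## ---- simulate ----
  stage_log("simulate", "building genome (seed %d)", cfg$seed)
  gb <- build_genome(cfg)
  pl <- plant_circs_and_rcs(gb, cfg)
  md <- sample_metadata(cfg)
  stage_log("simulate", "%d genes, %d planted circRNAs, %d RCS pairs",
            length(unique(gb$exons$gene_id)), nrow(pl$truth$planted_circs),
            nrow(pl$truth$planted_rcs))
  fastq_dir <- file.path(outdir, "fastq")
  rd <- simulate_reads(pl$genome, gb$exons, pl$truth, cfg, outdir = fastq_dir)
  write_fasta(pl$genome, file.path(outdir, "genome.fa"))
  write_fasta(gb$repeats, file.path(outdir, "repeats.fa"))
  write_rna_fasta(gb$mirnas, file.path(outdir, "mirnas.fa"))
  write_gtf(gb$exons, file.path(outdir, "annotation.gtf"))
  write_tsv(md, file.path(outdir, "samples.tsv"))
  write_tsv(pl$truth$planted_circs, file.path(outdir, "truth_circs.tsv"))
  write_tsv(pl$truth$planted_rcs, file.path(outdir, "truth_rcs.tsv"))
  write_tsv(rd$truth_reads, file.path(outdir, "truth_reads.tsv"))

  ## ---- detect ----
  probes <- index_junctions(gb$exons, pl$genome, anchor = rc$anchor,
                            min_span = rc$min_span)
  stage_log("detect", "%d junction probes (%d backsplice candidates)",
            nrow(probes), sum(probes$kind == "backsplice"))
  ev <- junction_evidence(rd$samples, probes, anchor_min = rc$anchor_min,
                          max_mismatch = rc$max_mismatch)
  write_tsv(ev, file.path(outdir, "junction_evidence.tsv"))
  supported <- sum(rowSums(evidence_counts(ev)) > 0 & ev$kind == "backsplice")
  stage_log("detect", "%d backsplice candidates with read support", supported)

  ## ---- call ----
  calls <- call_circrnas(ev, min_reads = rc$min_reads,
                         min_samples = rc$min_samples, mode = rc$filter_mode)
  stage_log("call", "candidates %d -> called %d",
            nrow(calls), sum(calls$passes_filter))
  write_tsv(calls, file.path(outdir, "circ_calls.tsv"))
  eval <- evaluate_calls(calls, pl$truth)
  write_tsv(data.frame(metric = c("precision", "recall", "n_called", "n_truth"),
                       value = c(eval$precision, eval$recall, eval$n_called,
                                 eval$n_truth)),
            file.path(outdir, "call_evaluation.tsv"))

  ## ---- quantify ----
  ratios <- ratio_table(ev, calls)
  write_tsv(ratios, file.path(outdir, "ratios.tsv"))
  grp_of_circ <- md$cell_type[1]
  write_tsv(summarize_ratios(ratios, grp_of_circ),
            file.path(outdir, "ratio_summary.tsv"))
  stage_log("quantify", "%d ratio records (%d defined)",
            nrow(ratios), sum(ratios$defined))

  ## ---- structure ----
  called <- calls[calls$passes_filter, , drop = FALSE]
  rcs_rows <- list()
  rep_rows <- list()
  for (i in seq_len(nrow(called))) {
    fl <- extract_flanking_introns(called[i, ], gb$exons, pl$genome)
    if (fl$up_missing || fl$down_missing) next
    al <- rcs_align(fl$upstream, fl$downstream, max_len = rc$rcs_max_len)
    sig <- rcs_significance(fl$upstream, fl$downstream,
                            n_shuffles = rc$n_shuffles,
                            seed = cfg$seed + 10L + i,
                            max_len = rc$rcs_max_len)
    cls_up <- annotate_repeats(fl$upstream, gb$repeats,
                               rc$repeat_min_identity, rc$repeat_min_len)
    cls_dn <- annotate_repeats(fl$downstream, gb$repeats,
                               rc$repeat_min_identity, rc$repeat_min_len)
    ## repeat class overlapping the aligned RCS span
    span_class <- "none"
    if (al$defined && nrow(cls_dn$intervals)) {
      ov <- cls_dn$intervals$start <= al$down_end &
        cls_dn$intervals$end >= al$down_start
      if (any(ov)) span_class <- cls_dn$intervals$class[which(ov)[1]]
    }
    rcs_rows[[i]] <- data.frame(
      circ_id = called$circ_id[i], gene_id = called$gene_id[i],
      score = al$score, identity = al$identity,
      up_start = al$up_start, up_end = al$up_end,
      down_start = al$down_start, down_end = al$down_end,
      p = sig$p, repeat_class = span_class,
      stringsAsFactors = FALSE
    )
    for (sidenm in c("upstream", "downstream")) {
      ann <- if (sidenm == "upstream") cls_up else cls_dn
      if (nrow(ann$intervals)) {
        rep_rows[[paste(i, sidenm)]] <- data.frame(
          circ_id = called$circ_id[i], side = sidenm,
          ann$intervals, stringsAsFactors = FALSE)
      }
    }
  }
  rcs_tab <- if (length(rcs_rows)) do.call(rbind, rcs_rows) else
    data.frame(circ_id = character(0), gene_id = character(0),
               score = numeric(0), identity = numeric(0),
               up_start = integer(0), up_end = integer(0),
               down_start = integer(0), down_end = integer(0),
               p = numeric(0), repeat_class = character(0))
  write_tsv(rcs_tab, file.path(outdir, "rcs.tsv"))
  rep_tab <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(circ_id = character(0), side = character(0),
               class = character(0), start = integer(0), end = integer(0))
  rownames(rep_tab) <- NULL
  write_tsv(rep_tab, file.path(outdir, "repeat_annotation.tsv"))
  stage_log("structure", "%d flanking-intron pairs scored, %d with p < 0.05",
            nrow(rcs_tab), sum(rcs_tab$p < 0.05, na.rm = TRUE))

  ## ---- mirna ----
  smt <- seed_match_table(gb$exons, pl$genome, calls, gb$mirnas)
  write_tsv(smt, file.path(outdir, "seed_matches.tsv"))
  circ_d <- smt$density[smt$group == "circ"]
  ctrl_d <- smt$density[smt$group == "control"]
  enr <- if (length(circ_d) >= 5 && length(ctrl_d) >= 5) {
    cdf_enrichment(circ_d, ctrl_d)
  } else {
    list(D = NA_real_, p = NA_real_, n_circ = length(circ_d),
         n_control = length(ctrl_d))
  }
  write_tsv(as.data.frame(enr), file.path(outdir, "mirna_cdf.tsv"))
  stage_log("mirna", "KS D = %.3f, p = %.3g", enr$D, enr$p)

  ## ---- differential abundance ----
  cm <- evidence_counts(ev)[called$junction_id, , drop = FALSE]
  rownames(cm) <- called$circ_id
  de <- NULL
  if (nrow(cm) > 0 && length(unique(md$group)) == 2 &&
      all(table(md$group) >= 2) && all(colSums(cm) > 0)) {
    ## library scaling from linear junctions: when most circRNAs carry the
    ## group effect, circ-only size factors would absorb it
    lin_cm <- evidence_counts(ev[ev$kind == "linear", , drop = FALSE])
    sf <- tryCatch(size_factors(lin_cm)[colnames(cm)],
                   error = function(e) NULL)
    de <- nb_test(cm, md$group[match(colnames(cm), md$sample_id)],
                  sf = sf, alpha = rc$de_alpha, fc = rc$de_fc)
    write_tsv(de, file.path(outdir, "de_circ.tsv"))
    stage_log("de", "%d/%d circRNAs significant (padj <= %.2g, FC >= %.2g)",
              sum(de$significant), nrow(de), rc$de_alpha, rc$de_fc)
  } else {
    stage_log("de", "skipped (needs 2 groups with n >= 2 and nonzero libraries)")
  }
  if (nrow(cm) >= 2 && ncol(cm) >= 3) {
    pca <- tryCatch(pca_scores(cm, sf = rep(1, ncol(cm))),
                    error = function(e) NULL)
    if (!is.null(pca)) {
      write_tsv(data.frame(sample_id = rownames(pca$scores), pca$scores),
                file.path(outdir, "pca_scores.tsv"))
    }
  }

  ## ---- manifest ----
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "manifest.json"))
  hashes <- as.list(tools::md5sum(file.path(outdir, files)))
  names(hashes) <- files
  manifest <- list(
    tool = paste0("backsplice ", as.character(utils::packageVersion("backsplice"))),
    seed = cfg$seed,
    config = rc[order(names(rc))],
    stages = c("simulate", "detect", "call", "quantify", "structure",
               "mirna", "de"),
    files = hashes
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
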