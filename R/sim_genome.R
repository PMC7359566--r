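#' Build a toy genome, annotation and repeat library
#'
#' Generates uniform-random DNA contigs carrying non-overlapping multi-exon
#' genes, a small repeat library (one Alu-like ~300 nt consensus and one
#' simple-repeat motif), and a set of mature miRNA sequences. Genes destined
#' to circularize (the "circ candidates", a fixed fraction of genes with at
#' least three exons) have their introns lengthened by
#' `circ_intron_mult`, emulating the long flanking introns of circRNA host
#' genes. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `genome` (named character vector of contig
#'   sequences), `exons` (exon table, see [validate_exons()]), `repeats`
#'   (named character vector, names encode the class: `Alu_like`,
#'   `simple_CA`), `mirnas` (named character vector of mature miRNA
#'   sequences, RNA alphabet) and `circ_candidates` (gene ids).
#' @examples
#' gb <- build_genome(sim_config(seed = 1, n_contigs = 1, genes_per_contig = 2,
#'                               exons_per_gene = c(4, 4)))
#' nrow(gb$exons)  # 8 exons
#' @export
build_genome <- function(cfg) {
  validate_sim_config(cfg)
  max_contig_len <- 2e7
  with_seed(cfg$seed, {
    repeats <- c(Alu_like = random_dna(300L),
                 simple_CA = strrep("CA", 25L))
    mirnas <- vapply(seq_len(cfg$n_mirnas), function(i) {
      chartr("T", "U", random_dna(cfg$mirna_len))
    }, "")
    names(mirnas) <- sprintf("mir-%03d", seq_len(cfg$n_mirnas))

    exon_rows <- list()
    genome <- character(cfg$n_contigs)
    names(genome) <- sprintf("ctg%d", seq_len(cfg$n_contigs))
    gene_counter <- 0L
    gene_meta <- list()

    rint <- function(lo, hi, n = 1L) {
      lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
    }
    for (ci in seq_len(cfg$n_contigs)) {
      contig_id <- names(genome)[ci]
      for (gi in seq_len(cfg$genes_per_contig)) {
        gene_counter <- gene_counter + 1L
        gid <- sprintf("g%04d", gene_counter)
        n_ex <- rint(cfg$exons_per_gene[1], cfg$exons_per_gene[2])
        ex_len <- rint(cfg$exon_len[1], cfg$exon_len[2], n_ex)
        ## log-uniform intron lengths: long-tailed like real introns
        in_len <- if (n_ex > 1) {
          round(exp(runif(n_ex - 1L, log(cfg$intron_len[1]),
                          log(cfg$intron_len[2]))))
        } else {
          integer(0)
        }
        strand <- if (runif(1) < 0.5) "+" else "-"
        ## circ-candidate status decided later (needs the full gene list);
        ## draw a per-gene uniform now so candidate picks are seed-stable
        gene_meta[[gid]] <- list(contig = contig_id, strand = strand,
                                 n_ex = n_ex, ex_len = ex_len, in_len = in_len,
                                 u = runif(1))
      }
    }

    ## pick circ candidates: round(fraction * n_eligible) genes with >= 3 exons
    gids <- names(gene_meta)
    eligible <- gids[vapply(gene_meta, function(m) m$n_ex >= 3L, TRUE)]
    n_circ <- round(cfg$circ_gene_fraction * length(eligible))
    circ_candidates <- if (n_circ > 0) {
      eligible[order(vapply(gene_meta[eligible], function(m) m$u, 0))][seq_len(n_circ)]
    } else {
      character(0)
    }

    ## lay out coordinates (candidate introns widened) and draw contig DNA
    per_contig <- split(gids, vapply(gene_meta, function(m) m$contig, ""))
    for (ci in seq_len(cfg$n_contigs)) {
      contig_id <- names(genome)[ci]
      cursor <- 0L
      for (gid in per_contig[[contig_id]]) {
        m <- gene_meta[[gid]]
        in_len <- m$in_len
        if (gid %in% circ_candidates) {
          in_len <- round(in_len * cfg$circ_intron_mult)
        }
        gap <- rint(200L, 800L)
        gstart <- cursor + gap + 1L
        starts <- integer(m$n_ex)
        ends <- integer(m$n_ex)
        pos <- gstart
        for (k in seq_len(m$n_ex)) {
          starts[k] <- pos
          ends[k] <- pos + m$ex_len[k] - 1L
          pos <- ends[k] + (if (k < m$n_ex) in_len[k] else 0L) + 1L
        }
        exon_rows[[gid]] <- data.frame(
          gene_id = gid, contig = contig_id, strand = m$strand,
          exon = seq_len(m$n_ex), start = starts, end = ends,
          stringsAsFactors = FALSE
        )
        cursor <- ends[m$n_ex]
        if (cursor > max_contig_len) {
          stopf("contig %s too small to host requested genes (exceeds %g nt)",
                contig_id, max_contig_len)
        }
      }
      genome[ci] <- random_dna(cursor + 200L)
    }

    exons <- do.call(rbind, exon_rows)
    rownames(exons) <- NULL
    validate_exons(exons)
    list(genome = genome, exons = exons, repeats = repeats, mirnas = mirnas,
         circ_candidates = circ_candidates)
  })
}

## write a transcript-orientation sequence into an intron, honoring strand.
## offset is 1-based from the transcript-5' end of the intron.
plant_in_intron <- function(ctg, istart, iend, strand, offset, s) {
  len <- nchar(s)
  if (strand == "+") {
    g1 <- istart + offset - 1L
    substr(ctg, g1, g1 + len - 1L) <- s
  } else {
    g2 <- iend - offset + 1L
    g1 <- g2 - len + 1L
    substr(ctg, g1, g2) <- revcomp1(s)
  }
  list(ctg = ctg, start = if (strand == "+") istart + offset - 1L else g1,
       end = if (strand == "+") istart + offset + len - 2L else g2)
}

#' Plant circRNAs and inverted repeat pairs
#'
#' For each circ-candidate gene, selects an internal run of exons whose
#' genomic span is at least `cfg$min_span` as the planted circRNA. With
#' probability `cfg$rcs_plant_prob` the flanking introns of the circle
#' receive a reverse-complementary sequence (RCS) pair: a copy of the
#' Alu-like consensus written into the downstream intron and its reverse
#' complement into the upstream intron (transcript orientation), the
#' sequence-pairing arrangement that promotes circularization. The circular
#' fraction of each planted circRNA carries the group effect
#' `cfg$effect_log2fc` in every non-reference group.
#'
#' @param gb Output of [build_genome()].
#' @param cfg The same [sim_config()] used to build the genome.
#' @return A list with `truth` (the truth set: `planted_circs` data.frame
#'   with genomic span, member exons and one `circ_fraction.<group>` column
#'   per group; `planted_rcs` data.frame with genomic insert coordinates and
#'   repeat class) and `genome` (the modified genome).
#' @export
plant_circs_and_rcs <- function(gb, cfg) {
  validate_sim_config(cfg)
  genome <- gb$genome
  exons <- gb$exons
  grp_names <- names(cfg$groups)
  cf <- setNames(pmin(0.95, cfg$circ_fraction *
                        c(1, rep(2^cfg$effect_log2fc, length(grp_names) - 1L))),
                 grp_names)

  circs <- list()
  rcs <- list()
  with_seed(cfg$seed + 1L, {
    for (gid in gb$circ_candidates) {
      e <- gene_exons(exons, gid)
      n <- nrow(e)
      if (n < 3L) next
      ## internal transcript-order runs a..b with genomic span >= min_span
      runs <- expand.grid(a = 2:(n - 1L), b = 2:(n - 1L))
      runs <- runs[runs$a <= runs$b, , drop = FALSE]
      gidx <- function(t) tx_to_genomic_idx(n, e$strand[1], t)
      span <- mapply(function(a, b) {
        gs <- sort(c(gidx(a), gidx(b)))
        e$end[gs[2]] - e$start[gs[1]] + 1L
      }, runs$a, runs$b)
      runs <- runs[span >= cfg$min_span, , drop = FALSE]
      if (nrow(runs) == 0L) next
      pick <- runs[sample.int(nrow(runs), 1L), ]
      a <- pick$a; b <- pick$b
      gs <- sort(c(gidx(a), gidx(b)))
      cstart <- e$start[gs[1]]; cend <- e$end[gs[2]]
      circ_id <- sprintf("%s:%d-%d", e$contig[1], cstart, cend)
      row <- data.frame(
        gene_id = gid, contig = e$contig[1], strand = e$strand[1],
        tx_first = a, tx_last = b, start = cstart, end = cend,
        span = cend - cstart + 1L, circ_id = circ_id,
        stringsAsFactors = FALSE
      )
      for (g in grp_names) row[[paste0("circ_fraction.", g)]] <- unname(cf[g])
      circs[[gid]] <- row

      if (runif(1) < cfg$rcs_plant_prob) {
        introns <- gene_introns(exons, gid)
        ## transcript-upstream intron precedes tx exon a; downstream follows b
        up_g <- if (e$strand[1] == "+") gidx(a) - 1L else gidx(a)
        dn_g <- if (e$strand[1] == "+") gidx(b) else gidx(b) - 1L
        up <- introns[introns$intron == up_g, ]
        dn <- introns[introns$intron == dn_g, ]
        rep_seq <- gb$repeats[["Alu_like"]]
        rl <- nchar(rep_seq)
        up_len <- up$end - up$start + 1L
        dn_len <- dn$end - dn$start + 1L
        if (up_len >= rl + 2L && dn_len >= rl + 2L) {
          off_dn <- sample.int(dn_len - rl + 1L, 1L)
          off_up <- sample.int(up_len - rl + 1L, 1L)
          ctg <- genome[[e$contig[1]]]
          pd <- plant_in_intron(ctg, dn$start, dn$end, e$strand[1], off_dn,
                                rep_seq)
          pu <- plant_in_intron(pd$ctg, up$start, up$end, e$strand[1], off_up,
                                revcomp1(rep_seq))
          genome[[e$contig[1]]] <- pu$ctg
          rcs[[gid]] <- data.frame(
            gene_id = gid, circ_id = circ_id, contig = e$contig[1],
            up_start = pu$start, up_end = pu$end,
            down_start = pd$start, down_end = pd$end,
            repeat_class = "Alu-like", stringsAsFactors = FALSE
          )
        }
      }
    }
  })

  planted_circs <- if (length(circs)) {
    do.call(rbind, unname(circs))
  } else {
    data.frame(gene_id = character(0), contig = character(0),
               strand = character(0), tx_first = integer(0),
               tx_last = integer(0), start = integer(0), end = integer(0),
               span = integer(0), circ_id = character(0))
  }
  planted_rcs <- if (length(rcs)) {
    do.call(rbind, unname(rcs))
  } else {
    data.frame(gene_id = character(0), circ_id = character(0),
               contig = character(0), up_start = integer(0),
               up_end = integer(0), down_start = integer(0),
               down_end = integer(0), repeat_class = character(0))
  }
  if (length(gb$circ_candidates) > 0 && nrow(planted_circs) == 0) {
    warnf("no eligible gene for circRNA planting; truth set is empty")
  }
  truth <- list(planted_circs = planted_circs, planted_rcs = planted_rcs,
                groups = cfg$groups)
  class(truth) <- "truth_set"
  list(truth = truth, genome = genome)
}

#' Run the full simulation (genome, truth set, reads)
#'
#' Convenience wrapper chaining [build_genome()], [plant_circs_and_rcs()]
#' and [simulate_reads()].
#'
#' @param cfg A [sim_config()].
#' @return A list with `genome`, `exons`, `repeats`, `mirnas`, `truth`,
#'   `metadata` and `reads` (see [simulate_reads()]).
#' @export
simulate_dataset <- function(cfg) {
  gb <- build_genome(cfg)
  pl <- plant_circs_and_rcs(gb, cfg)
  md <- sample_metadata(cfg)
  rd <- simulate_reads(pl$genome, gb$exons, pl$truth, cfg)
  list(genome = pl$genome, exons = gb$exons, repeats = gb$repeats,
       mirnas = gb$mirnas, truth = pl$truth, metadata = md, reads = rd)
}
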