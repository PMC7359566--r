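## junction id scheme shared by the simulator truth table and the detector
linear_junction_id <- function(gene_id, tx_idx) {
  sprintf("%s:L%02d", gene_id, tx_idx)
}
bsj_id <- function(gene_id, tx_first, tx_last) {
  sprintf("%s:B%02d-%02d", gene_id, tx_first, tx_last)
}

## transcript structure of one gene: exon lengths/cumulative ends in
## transcript order, full transcript sequence
tx_structure <- function(exons, genome, gene_id) {
  seqs <- gene_exon_seqs(exons, genome, gene_id)
  lens <- nchar(seqs)
  list(seqs = seqs, lens = lens, cum = cumsum(lens), L = sum(lens),
       tx = paste(seqs, collapse = ""))
}

## which single junction does a read interval [rs, re] span with >= anchor
## overhang on both sides? boundaries: data.frame(pos, id). NA if none or
## ambiguous (>1), mirroring the detector's tie-discard rule.
assign_junctions <- function(rs, re, boundaries, anchor) {
  out <- rep(NA_character_, length(rs))
  if (nrow(boundaries) == 0L || length(rs) == 0L) return(out)
  nhit <- integer(length(rs))
  for (k in seq_len(nrow(boundaries))) {
    q <- boundaries$pos[k]
    hit <- rs <= q - anchor + 1L & re >= q + anchor
    nhit <- nhit + hit
    out[hit] <- boundaries$id[k]
  }
  out[nhit > 1L] <- NA_character_
  out
}

#' Simulate paired-end reads with an exact truth table
#'
#' For every gene and sample, a negative-binomial molecule count is split
#' between the linear transcript and (at circ genes) the circular transcript
#' according to the group's circular fraction. Fragments are drawn along the
#' transcript -- circularly permuted for circles, so reads crossing the
#' back-splice carry last-exon-to-first-exon sequence -- and sequenced as
#' `read_len` nt mates from both fragment ends. Each read is annotated in
#' the truth table with the single junction it spans with at least
#' `cfg$anchor_min` nt overhang on both sides (NA if none; reads spanning
#' two junctions, impossible at default geometry, are marked NA to mirror
#' the detector's tie-discard rule). Deterministic given `cfg$seed`.
#'
#' @param genome Named character vector of contig sequences (after
#'   planting).
#' @param exons Exon table.
#' @param truth Truth set from [plant_circs_and_rcs()].
#' @param cfg The [sim_config()].
#' @param outdir Optional directory; when given, gzipped FASTQ pairs
#'   (`<sample>_R1.fastq.gz`, `_R2.fastq.gz`) are written there.
#' @return A list with `samples` (per sample, named character vectors `r1`,
#'   `r2`; names are read ids), `truth_reads` (data.frame: read_id,
#'   sample_id, gene_id, origin linear/circ, junction_id), `molecules`
#'   (per sample x gene linear/circular molecule counts) and `metadata`.
#' @export
simulate_reads <- function(genome, exons, truth, cfg, outdir = NULL) {
  validate_sim_config(cfg)
  md <- sample_metadata(cfg)
  rl <- cfg$read_len
  anchor <- cfg$anchor_min
  gids <- unique(exons$gene_id)
  n_genes <- length(gids)
  mu <- cfg$depth / n_genes

  ## per-gene static structures
  pc <- truth$planted_circs
  genes <- lapply(gids, function(gid) {
    st <- tx_structure(exons, genome, gid)
    n <- length(st$lens)
    lin_bnd <- if (n > 1) {
      data.frame(pos = st$cum[-n], id = linear_junction_id(gid, seq_len(n - 1L)))
    } else {
      data.frame(pos = integer(0), id = character(0))
    }
    g <- list(st = st, lin_bnd = lin_bnd, circ = NULL)
    hit <- which(pc$gene_id == gid)
    if (length(hit) == 1L) {
      a <- pc$tx_first[hit]; b <- pc$tx_last[hit]
      cl <- st$lens[a:b]
      Lc <- sum(cl)
      cum_c <- cumsum(cl)
      cb <- data.frame(pos = Lc, id = bsj_id(gid, a, b))
      if (b > a) {
        internal <- data.frame(pos = cum_c[-length(cum_c)],
                               id = linear_junction_id(gid, a:(b - 1L)))
        cb <- rbind(cb, internal,
                    data.frame(pos = internal$pos + Lc, id = internal$id))
      }
      cf <- vapply(names(cfg$groups), function(gr) {
        pc[[paste0("circ_fraction.", gr)]][hit]
      }, 0)
      circ_seq <- paste(st$seqs[a:b], collapse = "")
      g$circ <- list(a = a, b = b, Lc = Lc, doubled = paste0(circ_seq, circ_seq),
                     bnd = cb, cf = cf)
    }
    g
  })
  names(genes) <- gids

  draw_frags <- function(seq2, L, n, circular) {
    if (n == 0L) {
      return(list(r1s = integer(0), r2s = integer(0)))
    }
    f <- pmin(pmax(round(rnorm(n, cfg$fragment_len[1], cfg$fragment_len[2])),
                   rl), L)
    smax <- if (circular) L else L - f + 1L
    s <- 1L + floor(runif(n) * smax)
    list(s = as.integer(s), f = as.integer(f),
         r1s = as.integer(s), r2s = as.integer(s + f - rl))
  }

  inject_errors <- function(reads) {
    if (cfg$error_rate <= 0 || length(reads) == 0L) return(reads)
    nmut <- rbinom(length(reads), rl, cfg$error_rate)
    for (i in which(nmut > 0L)) {
      ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
      pos <- sample.int(rl, nmut[i])
      for (p in pos) {
        ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
      }
      reads[i] <- paste(ch, collapse = "")
    }
    reads
  }

  samples <- list()
  truth_rows <- list()
  mol_rows <- list()

  with_seed(cfg$seed + 2L, {
    for (si in seq_len(nrow(md))) {
      smp <- md$sample_id[si]
      grp <- md$group[si]
      N <- if (cfg$nb_dispersion > 0) {
        rnbinom(n_genes, mu = mu, size = 1 / cfg$nb_dispersion)
      } else {
        stats::rpois(n_genes, mu)
      }
      r1_all <- character(0); r2_all <- character(0)
      nm_all <- character(0)
      tr <- list()
      for (gi in seq_len(n_genes)) {
        gid <- gids[gi]
        g <- genes[[gid]]
        n_tot <- N[gi]
        if (n_tot == 0L) {
          mol_rows[[length(mol_rows) + 1L]] <- data.frame(
            sample_id = smp, gene_id = gid, n_linear = 0L, n_circ = 0L)
          next
        }
        nc <- 0L
        if (!is.null(g$circ) && g$circ$Lc >= rl) {
          nc <- rbinom(1L, n_tot, g$circ$cf[[grp]])
        }
        nl <- n_tot - nc
        mol_rows[[length(mol_rows) + 1L]] <- data.frame(
          sample_id = smp, gene_id = gid, n_linear = nl, n_circ = nc)

        emit <- function(fr, seq2, bnd, origin, n) {
          if (n == 0L) return(NULL)
          r1 <- substring(seq2, fr$r1s, fr$r1s + rl - 1L)
          r2 <- revcomp(substring(seq2, fr$r2s, fr$r2s + rl - 1L))
          j1 <- assign_junctions(fr$r1s, fr$r1s + rl - 1L, bnd, anchor)
          j2 <- assign_junctions(fr$r2s, fr$r2s + rl - 1L, bnd, anchor)
          base <- sprintf("%s:%s:%s:%06d", smp, gid, origin,
                          seq_along(r1) + length(nm_all))
          list(r1 = r1, r2 = r2, names = base, j1 = j1, j2 = j2)
        }
        if (nl > 0L) {
          fr <- draw_frags(g$st$tx, g$st$L, nl, FALSE)
          em <- emit(fr, g$st$tx, g$lin_bnd, "lin", nl)
          r1_all <- c(r1_all, em$r1); r2_all <- c(r2_all, em$r2)
          nm_all <- c(nm_all, em$names)
          tr[[length(tr) + 1L]] <- data.frame(
            name = em$names, gene_id = gid, origin = "linear",
            j1 = em$j1, j2 = em$j2, stringsAsFactors = FALSE)
        }
        if (nc > 0L) {
          fr <- draw_frags(g$circ$doubled, g$circ$Lc, nc, TRUE)
          em <- emit(fr, g$circ$doubled, g$circ$bnd, "circ", nc)
          r1_all <- c(r1_all, em$r1); r2_all <- c(r2_all, em$r2)
          nm_all <- c(nm_all, em$names)
          tr[[length(tr) + 1L]] <- data.frame(
            name = em$names, gene_id = gid, origin = "circ",
            j1 = em$j1, j2 = em$j2, stringsAsFactors = FALSE)
        }
      }
      r1_all <- inject_errors(r1_all)
      r2_all <- inject_errors(r2_all)
      names(r1_all) <- paste0(nm_all, "/1", recycle0 = TRUE)
      names(r2_all) <- paste0(nm_all, "/2", recycle0 = TRUE)
      samples[[smp]] <- list(r1 = r1_all, r2 = r2_all)
      if (length(tr)) {
        trd <- do.call(rbind, tr)
        truth_rows[[smp]] <- data.frame(
          read_id = c(paste0(trd$name, "/1"), paste0(trd$name, "/2")),
          sample_id = smp,
          gene_id = c(trd$gene_id, trd$gene_id),
          origin = c(trd$origin, trd$origin),
          junction_id = c(trd$j1, trd$j2),
          stringsAsFactors = FALSE
        )
      }
    }
  })

  truth_reads <- if (length(truth_rows)) {
    out <- do.call(rbind, unname(truth_rows))
    rownames(out) <- NULL
    out
  } else {
    data.frame(read_id = character(0), sample_id = character(0),
               gene_id = character(0), origin = character(0),
               junction_id = character(0))
  }
  molecules <- do.call(rbind, mol_rows)
  rownames(molecules) <- NULL

  res <- list(samples = samples, truth_reads = truth_reads,
              molecules = molecules, metadata = md)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (smp in names(samples)) {
      write_fastq(samples[[smp]]$r1,
                  file.path(outdir, paste0(smp, "_R1.fastq.gz")))
      write_fastq(samples[[smp]]$r2,
                  file.path(outdir, paste0(smp, "_R2.fastq.gz")))
    }
  }
  res
}

#' Truth-table junction counts
#'
#' Aggregates the read-origin truth table into per-sample counts of
#' junction-spanning reads, the oracle against which detector counts are
#' compared.
#'
#' @param truth_reads `truth_reads` data.frame from [simulate_reads()].
#' @param sample_ids Sample ids defining the column order.
#' @return Integer matrix junctions x samples.
#' @export
truth_junction_counts <- function(truth_reads,
                                  sample_ids = unique(truth_reads$sample_id)) {
  tr <- truth_reads[!is.na(truth_reads$junction_id), , drop = FALSE]
  jids <- sort(unique(tr$junction_id))
  m <- matrix(0L, length(jids), length(sample_ids),
              dimnames = list(jids, sample_ids))
  if (nrow(tr)) {
    tab <- table(tr$junction_id, factor(tr$sample_id, levels = sample_ids))
    m[rownames(tab), ] <- as.integer(tab)
    storage.mode(m) <- "integer"
  }
  m
}
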