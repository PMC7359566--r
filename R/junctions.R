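#' Index candidate junction probes
#'
#' Builds, for every gene, one linear probe per adjacent exon pair and one
#' back-splice probe per exon pair (transcript order `a <= b`) whose circle
#' genomic span is at least `min_span`. A probe joins the last `anchor` nt
#' of the donor exon to the first `anchor` nt of the acceptor exon, in
#' transcript orientation (minus-strand probes are therefore built from
#' reverse-complemented exon sequence). Back-splice probes join the end of
#' the downstream exon `b` to the start of the upstream-or-same exon `a`;
#' a single-exon back-splice (`a == b`) is allowed only when that exon alone
#' reaches `min_span`. Exons shorter than `anchor` yield truncated probes,
#' flagged in the output.
#'
#' @param exons Exon table (see [validate_exons()]).
#' @param genome Named character vector of contig sequences.
#' @param anchor Probe half-length in nt (>= 8).
#' @param min_span Minimum genomic span of a candidate circle in nt.
#' @return data.frame of probes: junction_id, kind ("linear"/"backsplice"),
#'   gene_id, contig, strand, donor_pos, acceptor_pos, start, end (genomic
#'   span), span, left_len, right_len (realized anchor lengths), probe
#'   (sequence), truncated.
#' @examples
#' gb <- build_genome(sim_config(seed = 1, n_contigs = 1, genes_per_contig = 1,
#'                               exons_per_gene = c(4, 4)))
#' probes <- index_junctions(gb$exons, gb$genome)
#' table(probes$kind)
#' @export
index_junctions <- function(exons, genome, anchor = 50L, min_span = 200L) {
  if (anchor < 8L) stopf("anchor must be >= 8")
  validate_exons(exons)
  rows <- list()
  for (gid in unique(exons$gene_id)) {
    e <- gene_exons(exons, gid)
    n <- nrow(e)
    strand <- e$strand[1]
    seqs <- gene_exon_seqs(exons, genome, gid)  # transcript order
    lens <- nchar(seqs)
    gidx <- function(t) tx_to_genomic_idx(n, strand, t)
    ## genomic coordinate of a transcript-exon 3' end (donor) / 5' start
    donor_pos <- function(t) {
      k <- gidx(t); if (strand == "+") e$end[k] else e$start[k]
    }
    acceptor_pos <- function(t) {
      k <- gidx(t); if (strand == "+") e$start[k] else e$end[k]
    }
    mk <- function(id, kind, don, acc) {
      dl <- min(anchor, lens[don]); al <- min(anchor, lens[acc])
      probe <- paste0(substring(seqs[don], lens[don] - dl + 1L, lens[don]),
                      substring(seqs[acc], 1L, al))
      gs <- sort(c(gidx(don), gidx(acc)))
      krange <- range(e$start[gs[1]:gs[2]], e$end[gs[1]:gs[2]])
      data.frame(
        junction_id = id, kind = kind, gene_id = gid, contig = e$contig[1],
        strand = strand, donor_pos = donor_pos(don),
        acceptor_pos = acceptor_pos(acc),
        start = krange[1], end = krange[2], span = krange[2] - krange[1] + 1L,
        left_len = dl, right_len = al, probe = probe,
        truncated = dl < anchor || al < anchor,
        stringsAsFactors = FALSE
      )
    }
    if (n > 1) {
      for (t in seq_len(n - 1L)) {
        rows[[length(rows) + 1L]] <-
          mk(linear_junction_id(gid, t), "linear", t, t + 1L)
      }
    }
    for (a in seq_len(n)) {
      for (b in a:n) {
        gs <- sort(c(gidx(a), gidx(b)))
        span <- e$end[gs[2]] - e$start[gs[1]] + 1L
        if (span >= min_span) {
          rows[[length(rows) + 1L]] <-
            mk(bsj_id(gid, a, b), "backsplice", b, a)
        }
      }
    }
  }
  if (!length(rows)) {
    stopf("no junction probes could be built from the annotation")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## split a probe center into max_mismatch+1 contiguous seed segments
## (pigeonhole: a match with <= mm mismatches contains one exact segment)
center_segments <- function(width, mm) {
  k <- mm + 1L
  sizes <- rep(width %/% k, k)
  extra <- width %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  offs <- cumsum(c(0L, utils::head(sizes, -1L)))
  data.frame(off = offs, size = sizes)
}

## mismatches between read and probe over their overlap given the probe's
## implied start position within the read coordinate system
overlap_mismatches <- function(read_raw, probe_raw, p_start) {
  rl <- length(read_raw); pl <- length(probe_raw)
  r1 <- max(1L, p_start); r2 <- min(rl, p_start + pl - 1L)
  if (r2 < r1) return(Inf)
  sum(read_raw[r1:r2] != probe_raw[(r1 - p_start + 1L):(r2 - p_start + 1L)])
}

#' Count junction-supporting reads for one sample
#'
#' A read supports a junction if it matches the junction probe with at most
#' `max_mismatch` substitutions over the read/probe overlap and overhangs
#' the junction by at least `anchor_min` nt on both sides. Candidates are
#' located by exact k-mer seeds over the junction midpoint (the central
#' `2 * anchor_min` nt of the probe, split into `max_mismatch + 1` exact
#' segments), in both read orientations. Each read is counted for at most
#' one junction: the best match by mismatch count wins and ties between
#' different junctions are discarded.
#'
#' @param reads Read sequences: a named character vector, a `DNAStringSet`,
#'   or a character vector of FASTQ paths (both mates).
#' @param probes Probe table from [index_junctions()], or a prebuilt index
#'   from [probe_index()] (cheaper when counting many samples).
#' @param anchor_min Minimum overhang on each side of the junction (nt).
#' @param max_mismatch Maximum substitutions tolerated over the overlap.
#' @return Named integer vector of per-junction supporting read counts
#'   (one element per probe, in probe order).
#' @export
count_junction_reads <- function(reads, probes, anchor_min = 25L,
                                 max_mismatch = 0L) {
  idx <- if (inherits(probes, "probe_index")) probes else
    probe_index(probes, anchor_min, max_mismatch)
  count_junction_reads_idx(reads, idx)
}

#' Precompute the k-mer seed index over junction probes
#'
#' Builds the exact-match seed dictionaries (over the junction midpoints)
#' used by [count_junction_reads()]; build once when counting several
#' samples against the same probes.
#'
#' @inheritParams count_junction_reads
#' @return An opaque `probe_index` object.
#' @export
probe_index <- function(probes, anchor_min = 25L, max_mismatch = 0L) {
  w <- 2L * anchor_min
  usable <- which(probes$left_len >= anchor_min &
                    probes$right_len >= anchor_min)
  centers <- substring(probes$probe[usable],
                       probes$left_len[usable] - anchor_min + 1L,
                       probes$left_len[usable] + anchor_min)
  segs <- center_segments(w, as.integer(max_mismatch))
  pdicts <- lapply(seq_len(nrow(segs)), function(si) {
    if (!length(usable)) return(NULL)
    seg <- substring(centers, segs$off[si] + 1L, segs$off[si] + segs$size[si])
    Biostrings::PDict(Biostrings::DNAStringSet(seg))
  })
  structure(list(probes = probes, usable = usable, centers = centers,
                 segs = segs, pdicts = pdicts,
                 probe_raw = lapply(probes$probe[usable], charToRaw),
                 anchor_min = as.integer(anchor_min),
                 max_mismatch = as.integer(max_mismatch), w = w),
            class = "probe_index")
}

count_junction_reads_idx <- function(reads, idx) {
  probes <- idx$probes
  anchor_min <- idx$anchor_min
  max_mismatch <- idx$max_mismatch
  if (is.character(reads) && length(reads) && all(file.exists(reads)) &&
      any(grepl("\\.(fastq|fq)(\\.gz)?$", reads))) {
    reads <- unlist(lapply(reads, function(p) {
      r <- tryCatch(read_fastq(p),
                    error = function(e) stopf("unreadable FASTQ %s: %s", p,
                                              conditionMessage(e)))
      r
    }))
  }
  reads <- as.character(reads)
  counts <- setNames(integer(nrow(probes)), probes$junction_id)
  if (length(reads) == 0L) return(counts)

  w <- idx$w
  ## probes whose realized anchors cannot give anchor_min overhang both
  ## sides can never be supported
  usable <- idx$usable
  if (!length(usable)) return(counts)
  centers <- idx$centers
  segs <- idx$segs

  rd_fwd <- reads
  rd_rev <- revcomp(reads)
  probe_raw <- idx$probe_raw

  ## candidate (read, probe) pairs per orientation via exact segment seeds
  find_candidates <- function(rd) {
    hits <- vector("list", nrow(segs))
    dss <- Biostrings::DNAStringSet(rd)
    for (si in seq_len(nrow(segs))) {
      wh <- Biostrings::vwhichPDict(idx$pdicts[[si]], dss)
      nn <- lengths(wh)
      if (sum(nn) == 0) next
      hits[[si]] <- data.frame(read = rep(seq_along(rd), nn),
                               probe = unlist(wh))
    }
    hits <- do.call(rbind, hits)
    if (is.null(hits)) return(hits)
    unique(hits)
  }

  best_mm <- rep(Inf, length(reads))
  best_j <- rep(NA_integer_, length(reads))   # index into `usable`
  tied <- rep(FALSE, length(reads))

  score_candidates <- function(cand, rd) {
    if (is.null(cand) || nrow(cand) == 0L) return(invisible())
    rd_raw_cache <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(cand))) {
      ri <- cand$read[i]; pi <- cand$probe[i]
      key <- as.character(ri)
      rraw <- get0(key, envir = rd_raw_cache)
      if (is.null(rraw)) {
        rraw <- charToRaw(rd[ri])
        assign(key, rraw, envir = rd_raw_cache)
      }
      ## candidate center start positions in the read from any exact segment
      starts <- integer(0)
      for (si in seq_len(nrow(segs))) {
        seg <- substring(centers[pi], segs$off[si] + 1L,
                         segs$off[si] + segs$size[si])
        m <- gregexpr(seg, rd[ri], fixed = TRUE)[[1]]
        if (m[1] != -1L) starts <- c(starts, as.integer(m) - segs$off[si])
      }
      starts <- unique(starts)
      starts <- starts[starts >= 1L &
                         starts + w - 1L <= length(rraw)]
      if (!length(starts)) next
      left_len <- probes$left_len[usable[pi]]
      for (s in starts) {
        p_start <- s - (left_len - anchor_min)
        mm <- overlap_mismatches(rraw, probe_raw[[pi]], p_start)
        ## center region must itself satisfy the mismatch budget; the
        ## overlap test covers it since the center lies inside the overlap
        if (mm > max_mismatch) next
        if (mm < best_mm[ri]) {
          best_mm[ri] <<- mm; best_j[ri] <<- pi; tied[ri] <<- FALSE
        } else if (mm == best_mm[ri] && !is.na(best_j[ri]) &&
                   best_j[ri] != pi) {
          tied[ri] <<- TRUE
        }
      }
    }
    invisible()
  }

  score_candidates(find_candidates(rd_fwd), rd_fwd)
  score_candidates(find_candidates(rd_rev), rd_rev)

  keep <- !is.na(best_j) & !tied & is.finite(best_mm)
  if (any(keep)) {
    tab <- table(factor(usable[best_j[keep]], levels = seq_len(nrow(probes))))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Junction evidence across samples
#'
#' Runs [count_junction_reads()] for every sample and assembles the
#' junction evidence table: probe metadata plus one count column per
#' sample (`count.<sample_id>`).
#'
#' @param sample_reads Named list; each element holds the reads of one
#'   sample in any form accepted by [count_junction_reads()] (the `samples`
#'   element of [simulate_reads()] output works directly: `r1`/`r2` are
#'   concatenated).
#' @param probes Probe table from [index_junctions()].
#' @inheritParams count_junction_reads
#' @return data.frame: junction_id, kind, gene_id, contig, strand, start,
#'   end, span plus `count.<sample>` columns.
#' @export
junction_evidence <- function(sample_reads, probes, anchor_min = 25L,
                              max_mismatch = 0L) {
  ev <- probes[, c("junction_id", "kind", "gene_id", "contig", "strand",
                   "start", "end", "span")]
  idx <- probe_index(probes, anchor_min, max_mismatch)
  for (smp in names(sample_reads)) {
    rd <- sample_reads[[smp]]
    if (is.list(rd) && !is.null(rd$r1)) rd <- c(rd$r1, rd$r2)
    ev[[paste0("count.", smp)]] <-
      unname(count_junction_reads(rd, idx, anchor_min, max_mismatch))
  }
  ev
}

#' Extract the per-sample count matrix from an evidence table
#'
#' @param evidence Evidence table from [junction_evidence()].
#' @return Integer matrix junctions x samples (rownames = junction_id).
#' @export
evidence_counts <- function(evidence) {
  cc <- grep("^count\\.", names(evidence), value = TRUE)
  m <- as.matrix(evidence[, cc, drop = FALSE])
  rownames(m) <- evidence$junction_id
  colnames(m) <- sub("^count\\.", "", cc)
  storage.mode(m) <- "integer"
  m
}
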