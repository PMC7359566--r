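#' Extract the introns flanking a circRNA
#'
#' Returns the upstream and downstream flanking intron sequences in
#' transcript orientation: "upstream" precedes the first back-spliced exon
#' along the transcript (for minus-strand genes this is the genomically
#' downstream intron, reverse-complemented), "downstream" follows the last
#' back-spliced exon. A side is flagged missing when the circle reaches a
#' transcript-terminal exon.
#'
#' @param call One row of a [call_circrnas()] table (or any list with
#'   gene_id, tx_first, tx_last, circ_id).
#' @param exons Exon table.
#' @param genome Named character vector of contig sequences.
#' @return list: circ_id, upstream, downstream (character or NA), up_len,
#'   down_len, up_missing, down_missing, and the genomic coordinates
#'   up_start/up_end/down_start/down_end (NA when missing).
#' @export
extract_flanking_introns <- function(call, exons, genome) {
  gid <- call$gene_id
  e <- gene_exons(exons, gid)
  n <- nrow(e)
  a <- call$tx_first; b <- call$tx_last
  if (a < 1 || b > n || a > b) {
    stopf("exon indices %d-%d out of range for gene %s", a, b, gid)
  }
  strand <- e$strand[1]
  introns <- gene_introns(exons, gid)
  ctg <- genome[[e$contig[1]]]

  side <- function(tx_idx, upstream) {
    ## intron adjacent to transcript exon tx_idx on its transcript-5'
    ## (upstream=TRUE) or transcript-3' side
    g <- tx_to_genomic_idx(n, strand, tx_idx)
    gi <- if (strand == "+") {
      if (upstream) g - 1L else g
    } else {
      if (upstream) g else g - 1L
    }
    if (gi < 1L || gi > n - 1L) return(NULL)
    introns[introns$intron == gi, ]
  }
  up <- side(a, upstream = TRUE)
  dn <- side(b, upstream = FALSE)
  seq_of <- function(iv) {
    if (is.null(iv) || nrow(iv) == 0L) return(NA_character_)
    s <- substring(ctg, iv$start, iv$end)
    if (strand == "-") revcomp1(s) else s
  }
  up_seq <- seq_of(up); dn_seq <- seq_of(dn)
  list(
    circ_id = call$circ_id,
    upstream = up_seq, downstream = dn_seq,
    up_len = if (is.na(up_seq)) 0L else nchar(up_seq),
    down_len = if (is.na(dn_seq)) 0L else nchar(dn_seq),
    up_missing = is.na(up_seq), down_missing = is.na(dn_seq),
    up_start = if (is.null(up)) NA_integer_ else up$start,
    up_end = if (is.null(up)) NA_integer_ else up$end,
    down_start = if (is.null(dn)) NA_integer_ else dn$start,
    down_end = if (is.null(dn)) NA_integer_ else dn$end
  )
}

#' Compare log2 length distributions with an unpaired Student t test
#'
#' Two-sided pooled-variance t test on log2-transformed lengths, used for
#' circRNA exon/intron lengths against genome-wide controls.
#'
#' @param x,y Positive length vectors (nt), each of size >= 2.
#' @return list with t, df, p, mean_log2_x, mean_log2_y.
#' @export
length_comparison <- function(x, y) {
  if (any(c(x, y) <= 0)) stopf("lengths must be positive")
  if (length(x) < 2L || length(y) < 2L) stopf("each sample needs n >= 2")
  lx <- log2(x); ly <- log2(y)
  if (sd(c(lx, ly)) == 0) {
    return(list(t = 0, df = length(lx) + length(ly) - 2L, p = 1,
                mean_log2_x = mean(lx), mean_log2_y = mean(ly)))
  }
  tt <- t.test(lx, ly, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_log2_x = mean(lx), mean_log2_y = mean(ly))
}

rcs_submat <- function(match, mismatch) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = FALSE)
}

#' Align the reverse complement of the upstream intron to the downstream
#' intron
#'
#' Optimal local (Smith-Waterman) alignment of `revcomp(upstream)` against
#' `downstream` with affine gaps (a gap of length L costs
#' `gap_open + L * gap_ext`), the screen for reverse-complementary
#' sequences (RCSs) capable of pairing across the circle. Sequences longer
#' than `max_len` are truncated to the `max_len` nt nearest the circle
#' (the transcript-3' end of the upstream intron, the 5' end of the
#' downstream intron) and flagged.
#'
#' @param upstream,downstream Flanking intron sequences in transcript
#'   orientation (see [extract_flanking_introns()]).
#' @param match,mismatch,gap_open,gap_ext Scoring parameters (defaults
#'   +1/-1/5/2; penalties positive).
#' @param max_len Intron length cap in nt.
#' @return list: score, identity (percent identity of the aligned region),
#'   up_start/up_end and down_start/down_end (aligned span, 1-based
#'   coordinates within the full input sequences; the upstream span refers
#'   to the upstream intron itself, not its reverse complement), truncated,
#'   defined (FALSE for empty input).
#' @export
rcs_align <- function(upstream, downstream, match = 1, mismatch = -1,
                      gap_open = 5, gap_ext = 2, max_len = 5000L) {
  if (is.na(upstream) || is.na(downstream) ||
      nchar(upstream) == 0L || nchar(downstream) == 0L) {
    return(list(score = NA_real_, identity = NA_real_,
                up_start = NA_integer_, up_end = NA_integer_,
                down_start = NA_integer_, down_end = NA_integer_,
                truncated = FALSE, defined = FALSE))
  }
  ul <- nchar(upstream); dl <- nchar(downstream)
  truncated <- ul > max_len || dl > max_len
  up_off <- 0L
  if (ul > max_len) {       # keep the 3' end, nearest the circle
    up_off <- ul - max_len
    upstream <- substring(upstream, up_off + 1L, ul)
  }
  if (dl > max_len) downstream <- substring(downstream, 1L, max_len)

  rc_up <- revcomp1(upstream)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(rc_up), Biostrings::DNAString(downstream),
    type = "local", substitutionMatrix = rcs_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_ext
  )
  sc <- Biostrings::score(pa)
  p <- Biostrings::pattern(pa)
  s <- Biostrings::subject(pa)
  kept_ul <- nchar(upstream)
  ## map the aligned revcomp coordinates back onto the upstream intron
  rc_s <- Biostrings::start(p); rc_e <- Biostrings::end(p)
  up_start <- up_off + (kept_ul - rc_e + 1L)
  up_end <- up_off + (kept_ul - rc_s + 1L)
  list(score = sc, identity = Biostrings::pid(pa),
       up_start = up_start, up_end = up_end,
       down_start = Biostrings::start(s), down_end = Biostrings::end(s),
       truncated = truncated, defined = TRUE)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random Eulerian-path shuffle (Altschul-Erickson): the shuffled sequence
#' has exactly the original dinucleotide counts (and therefore mononucleotide
#' counts) and the original first and last characters. Uses the current RNG
#' stream.
#'
#' @param s A character string (sequence).
#' @return A shuffled string with identical dinucleotide composition.
#' @export
shuffle_dinuc <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n <= 3L) return(s)
  letters_ <- unique(ch)
  v <- match(ch, letters_)
  nv <- length(letters_)
  if (nv == 1L) return(s)
  from <- v[-n]; to <- v[-1]
  out_edges <- split(to, factor(from, levels = seq_len(nv)))
  last_v <- v[n]
  has_out <- lengths(out_edges) > 0L

  repeat {
    ## pick a random candidate last-edge per vertex (except the final one)
    last_edge <- rep(NA_integer_, nv)
    for (x in seq_len(nv)) {
      if (x != last_v && has_out[x]) {
        ee <- out_edges[[x]]
        last_edge[x] <- ee[sample.int(length(ee), 1L)]
      }
    }
    ## accept iff following last-edges from every vertex reaches last_v
    ok <- TRUE
    for (x in seq_len(nv)) {
      if (x == last_v || !has_out[x]) next
      cur <- x; steps <- 0L
      while (cur != last_v && steps <= nv) {
        if (is.na(last_edge[cur])) break
        cur <- last_edge[cur]; steps <- steps + 1L
      }
      if (cur != last_v) { ok <- FALSE; break }
    }
    if (ok) break
  }

  edges <- vector("list", nv)
  for (x in seq_len(nv)) {
    ee <- out_edges[[x]]
    if (!length(ee)) { edges[[x]] <- integer(0); next }
    if (!is.na(last_edge[x])) {
      drop1 <- match(last_edge[x], ee)
      rest <- ee[-drop1]
      edges[[x]] <- c(if (length(rest)) rest[sample.int(length(rest))],
                      last_edge[x])
    } else {
      edges[[x]] <- ee[sample.int(length(ee))]
    }
  }

  res <- integer(n)
  res[1] <- v[1]
  ptr <- rep(1L, nv)
  cur <- v[1]
  for (i in 2:n) {
    nxt <- edges[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(letters_[res], collapse = "")
}

#' Empirical significance of an RCS alignment score
#'
#' Compares the observed local alignment score to scores obtained after
#' dinucleotide-preserving shuffles of the upstream intron:
#' `p = (1 + #\{shuffled score >= observed\}) / (n_shuffles + 1)`.
#' Deterministic given `seed`.
#'
#' @inheritParams rcs_align
#' @param n_shuffles Number of shuffles (>= 99).
#' @param seed Integer seed.
#' @return list: p, observed, shuffled (score vector), n_shuffles.
#' @export
rcs_significance <- function(upstream, downstream, n_shuffles = 199L,
                             seed = 1L, match = 1, mismatch = -1,
                             gap_open = 5, gap_ext = 2, max_len = 5000L) {
  if (n_shuffles < 99L) stopf("n_shuffles must be >= 99")
  obs <- rcs_align(upstream, downstream, match, mismatch, gap_open, gap_ext,
                   max_len)
  if (!obs$defined) {
    return(list(p = NA_real_, observed = NA_real_, shuffled = numeric(0),
                n_shuffles = n_shuffles))
  }
  ul <- nchar(upstream)
  up_kept <- if (ul > max_len) substring(upstream, ul - max_len + 1L, ul) else
    upstream
  dl <- nchar(downstream)
  dn_kept <- if (dl > max_len) substring(downstream, 1L, max_len) else
    downstream
  shuffled_scores <- with_seed(seed, {
    shufs <- vapply(seq_len(n_shuffles), function(i) {
      revcomp1(shuffle_dinuc(up_kept))
    }, "")
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(shufs), Biostrings::DNAString(dn_kept),
      type = "local", substitutionMatrix = rcs_submat(match, mismatch),
      gapOpening = gap_open, gapExtension = gap_ext, scoreOnly = TRUE
    )
    pa
  })
  p <- (1 + sum(shuffled_scores >= obs$score)) / (n_shuffles + 1)
  list(p = p, observed = obs$score, shuffled = shuffled_scores,
       n_shuffles = n_shuffles)
}

repeat_class_of <- function(name) {
  if (grepl("^Alu", name, ignore.case = TRUE)) "Alu-like"
  else if (grepl("^simple", name, ignore.case = TRUE)) "simple"
  else "none"
}

#' Annotate repeats in a sequence with a consensus library
#'
#' Gapless identity matcher: for every alignment offset of each library
#' consensus (both orientations) against the sequence, windows of
#' `min_len` nt with identity >= `min_identity` are marked; overlapping
#' marks are merged per repeat class and the covered base fraction
#' reported. Screens for interspersed (Alu-like) repeats and low-complexity
#' (simple) sequence without modeling indels.
#'
#' @param sequence Character string.
#' @param library Named character vector of consensi; names choose the
#'   class ("Alu*" -> Alu-like, "simple*" -> simple).
#' @param min_identity Minimum window identity (proportion, default 0.8).
#' @param min_len Minimum window length in nt (default 50).
#' @return list: `intervals` data.frame (class, start, end) of merged hits
#'   and `fractions`, named numeric of covered base fraction per class
#'   (classes present in the library; 0 when absent from the sequence).
#' @export
annotate_repeats <- function(sequence, library, min_identity = 0.8,
                             min_len = 50L) {
  if (length(library) == 0L) stopf("repeat library is empty")
  n <- nchar(sequence)
  seq_raw <- charToRaw(sequence)
  classes <- vapply(names(library), repeat_class_of, "")
  covered <- list()

  for (li in seq_along(library)) {
    cls <- classes[li]
    for (cons in c(library[[li]], revcomp1(library[[li]]))) {
      m <- nchar(cons)
      if (m < min_len || n < min_len) next
      cons_raw <- charToRaw(cons)
      wlen <- min_len
      thr <- ceiling(min_identity * wlen)
      for (d in (min_len - m):(n - min_len)) {
        j1 <- max(1L, 1L - d); j2 <- min(m, n - d)
        ov <- j2 - j1 + 1L
        if (ov < wlen) next
        eq <- cons_raw[j1:j2] == seq_raw[(j1 + d):(j2 + d)]
        cs <- cumsum(eq)
        wm <- cs[wlen:ov] - c(0L, cs[seq_len(ov - wlen)])
        pass <- wm >= thr
        if (!any(pass)) next
        r <- rle(pass)
        ends_run <- cumsum(r$lengths)
        starts_run <- ends_run - r$lengths + 1L
        for (k in which(r$values)) {
          w1 <- starts_run[k]; w2 <- ends_run[k]
          s1 <- (j1 + w1 - 1L) + d
          s2 <- (j1 + w2 - 1L) + d + wlen - 1L
          covered[[length(covered) + 1L]] <-
            data.frame(class = cls, start = s1, end = s2,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }

  merge_ivs <- function(df) {
    df <- df[order(df$start), , drop = FALSE]
    out <- list()
    cur <- NULL
    for (i in seq_len(nrow(df))) {
      if (is.null(cur)) {
        cur <- df[i, ]
      } else if (df$start[i] <= cur$end + 1L) {
        cur$end <- max(cur$end, df$end[i])
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- df[i, ]
      }
    }
    if (!is.null(cur)) out[[length(out) + 1L]] <- cur
    do.call(rbind, out)
  }

  all_cls <- unique(classes)
  fractions <- setNames(numeric(length(all_cls)), all_cls)
  ivs <- list()
  if (length(covered)) {
    cov <- do.call(rbind, covered)
    for (cls in unique(cov$class)) {
      mg <- merge_ivs(cov[cov$class == cls, , drop = FALSE])
      ivs[[cls]] <- mg
      fractions[cls] <- sum(mg$end - mg$start + 1L) / n
    }
  }
  intervals <- if (length(ivs)) do.call(rbind, unname(ivs)) else
    data.frame(class = character(0), start = integer(0), end = integer(0))
  rownames(intervals) <- NULL
  list(intervals = intervals, fractions = fractions)
}
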