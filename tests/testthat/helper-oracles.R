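## Independent brute-force oracles used to freeze expected values.
## These deliberately do not share code with the package implementation.

rand_dna <- function(n) {
  paste(c("A", "C", "G", "T")[sample.int(4L, n, replace = TRUE)],
        collapse = "")
}

rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

## Smith-Waterman local alignment with affine gaps, O(nm) dynamic program.
## A gap of length L costs gap_open + L * gap_ext (penalties positive).
oracle_local_align <- function(a, b, match = 1, mismatch = -1,
                               gap_open = 5, gap_ext = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in b (consume a)
  F <- matrix(NEG, n + 1, m + 1)  # gap in a (consume b)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, E[i - 1, j] - gap_ext)
      F[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, F[i, j - 1] - gap_ext)
      sub <- if (av[i - 1] == bv[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

## Benjamini-Hochberg step-up from first principles
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

## two-sample KS statistic as the exhaustive sup over pooled jump points
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), 0))
}

## sliding-window enumeration of exact 7-mer seed-complement occurrences
oracle_seed_count <- function(exon, mirna) {
  seed <- substr(chartr("U", "T", toupper(mirna)), 2, 8)
  target <- rc_oracle(seed)
  L <- nchar(exon)
  if (L < 7) return(0L)
  sum(vapply(1:(L - 6), function(i) substr(exon, i, i + 6) == target, TRUE))
}

## pooled-variance two-sample t statistic from the textbook formula
oracle_t_pooled <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

## exact per-sample circRNA-calling rule re-stated from the definition
oracle_call_rule <- function(counts, min_reads = 4, min_samples = 2) {
  sum(counts >= min_reads) >= min_samples
}

## small manual gene model: one plus-strand and one minus-strand gene on a
## random contig; exon lengths chosen per test
make_toy_annotation <- function(exon_lens, strand = "+", intron_len = 300,
                                gene_id = "gX", contig = "ctgT",
                                offset = 100L) {
  n <- length(exon_lens)
  starts <- integer(n); ends <- integer(n)
  pos <- offset
  for (k in seq_len(n)) {
    starts[k] <- pos
    ends[k] <- pos + exon_lens[k] - 1L
    pos <- ends[k] + intron_len + 1L
  }
  data.frame(gene_id = gene_id, contig = contig, strand = strand,
             exon = seq_len(n), start = starts, end = ends,
             stringsAsFactors = FALSE)
}

make_toy_genome <- function(exons, pad = 200L) {
  len <- max(exons$end) + pad
  g <- setNames(rand_dna(len), unique(exons$contig))
  g
}

## synthetic back-splice evidence table from a list of per-sample counts
mk_evidence <- function(counts, kind = "backsplice") {
  n <- length(counts[[1]])
  ev <- data.frame(
    junction_id = sprintf("g%02d:B02-03", seq_along(counts)),
    kind = kind, gene_id = sprintf("g%02d", seq_along(counts)),
    contig = "ctg1", strand = "+",
    start = 1000L + seq_along(counts), end = 2000L + seq_along(counts),
    span = 1001L, stringsAsFactors = FALSE
  )
  for (s in seq_len(n)) {
    ev[[paste0("count.s", s)]] <- vapply(counts, `[`, 0, s)
  }
  ev
}

## small simulated dataset reused across detector tests
small_sim <- function(seed = 5, depth = 4000, genes = 8,
                      groups = c(healthy = 2, patient = 2), ...) {
  cfg <- sim_config(seed = seed, n_contigs = 1, genes_per_contig = genes,
                    depth = depth, groups = groups, ...)
  simulate_dataset(cfg)
}
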