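test_that("probe enumeration matches the pair-counting oracle", {
  ## 4-exon plus-strand gene with short introns so every circle span passes
  exons <- make_toy_annotation(rep(300L, 4), intron_len = 400)
  set.seed(1)
  genome <- make_toy_genome(exons)
  probes <- index_junctions(exons, genome, anchor = 50, min_span = 200)
  expect_equal(sum(probes$kind == "linear"), 3L)
  expect_equal(sum(probes$kind == "backsplice"), choose(4, 2) + 4L)  # 10

  ## min_span larger than the gene span removes all backsplice probes
  p2 <- index_junctions(exons, genome, min_span = max(exons$end) * 2L)
  expect_equal(sum(p2$kind == "backsplice"), 0L)
  expect_equal(sum(p2$kind == "linear"), 3L)
})

test_that("back-splice probe sequence joins exon ends by definition", {
  exons <- make_toy_annotation(rep(300L, 4), intron_len = 400)
  set.seed(2)
  genome <- make_toy_genome(exons)
  probes <- index_junctions(exons, genome, anchor = 50)
  ctg <- genome[["ctgT"]]
  ex_seq <- function(i) substr(ctg, exons$start[i], exons$end[i])
  p <- probes[probes$junction_id == "gX:B02-03", ]
  expect_identical(p$probe,
                   paste0(substr(ex_seq(3), 251, 300), substr(ex_seq(2), 1, 50)))
  ## minus-strand gene: probes built from reverse-complemented exons
  exm <- make_toy_annotation(rep(300L, 4), strand = "-", intron_len = 400)
  pm <- index_junctions(exm, genome, anchor = 50)
  pmx <- pm[pm$junction_id == "gX:B02-03", ]
  ## transcript exon 2 on "-" is genomic exon 3, exon 3 is genomic exon 2
  rc2 <- rc_oracle(ex_seq(3))   # transcript exon 2
  rc3 <- rc_oracle(ex_seq(2))   # transcript exon 3
  expect_identical(pmx$probe, paste0(substr(rc3, 251, 300), substr(rc2, 1, 50)))
})

test_that("read support requires full anchors on both sides", {
  exons <- make_toy_annotation(rep(300L, 3), intron_len = 400)
  set.seed(3)
  genome <- make_toy_genome(exons)
  probes <- index_junctions(exons, genome, anchor = 50)
  p <- probes[probes$junction_id == "gX:L01", ]
  ## read equal to the probe center with anchor_min overhang both sides
  center <- substr(p$probe, 26, 75)
  expect_equal(unname(count_junction_reads(c(r = center), probes)["gX:L01"]), 1L)
  ## overhang anchor_min - 1 on one side -> no support
  short <- substr(p$probe, 27, 75)
  cnt <- count_junction_reads(c(r = short), probes)
  expect_equal(sum(cnt), 0L)
  ## reverse-complemented read still counts
  expect_equal(unname(count_junction_reads(c(r = rc_oracle(center)),
                                           probes)["gX:L01"]), 1L)
})

test_that("a read matching two junctions equally is discarded, and mismatch
          tolerance behaves as configured", {
  exons <- make_toy_annotation(rep(300L, 3), intron_len = 400)
  set.seed(4)
  genome <- make_toy_genome(exons)
  probes <- index_junctions(exons, genome, anchor = 50)
  p1 <- probes$probe[probes$junction_id == "gX:L01"]
  read <- substr(p1, 16, 85)
  ## duplicate probe row under a different id forces an exact tie
  fake <- probes[probes$junction_id == "gX:L01", ]
  fake$junction_id <- "gX:L99"
  probes2 <- rbind(probes, fake)
  cnt <- count_junction_reads(c(r = read), probes2)
  expect_equal(sum(cnt), 0L)

  ## one substitution inside the center: rejected at max_mismatch 0,
  ## accepted at max_mismatch 1
  mut <- read
  substr(mut, 35, 35) <- setdiff(c("A", "C", "G", "T"),
                                 substr(read, 35, 35))[1]
  expect_equal(sum(count_junction_reads(c(r = mut), probes)), 0L)
  cnt1 <- count_junction_reads(c(r = mut), probes, max_mismatch = 1)
  expect_equal(unname(cnt1["gX:L01"]), 1L)
})

test_that("per-junction counts equal the simulator truth table exactly at
          zero error and zero mismatch tolerance", {
  ds <- small_sim(seed = 31, depth = 3000, genes = 6)
  probes <- index_junctions(ds$exons, ds$genome)
  ev <- junction_evidence(ds$reads$samples, probes)
  cm <- evidence_counts(ev)
  tc <- truth_junction_counts(ds$reads$truth_reads, ds$metadata$sample_id)
  expect_true(all(rownames(tc) %in% rownames(cm)))
  expect_equal(cm[rownames(tc), , drop = FALSE], tc)
  ## junctions with no truth reads have zero counts
  rest <- setdiff(rownames(cm), rownames(tc))
  expect_true(all(cm[rest, ] == 0L))
  ## conservation: counted reads never exceed reads in the sample
  for (smp in colnames(cm)) {
    n_reads <- length(ds$reads$samples[[smp]]$r1) +
      length(ds$reads$samples[[smp]]$r2)
    expect_lte(sum(cm[, smp]), n_reads)
  }
})

test_that("counting reads from FASTQ files matches in-memory counting", {
  ds <- small_sim(seed = 32, depth = 1500, genes = 4,
                  groups = c(healthy = 1))
  out <- tempfile()
  simulate_reads(ds$genome, ds$exons, ds$truth,
                 sim_config(seed = 32, n_contigs = 1, genes_per_contig = 4,
                            depth = 1500, groups = c(healthy = 1)),
                 outdir = out)
  probes <- index_junctions(ds$exons, ds$genome)
  from_mem <- count_junction_reads(
    c(ds$reads$samples[[1]]$r1, ds$reads$samples[[1]]$r2), probes)
  from_file <- count_junction_reads(
    file.path(out, c("healthy_1_R1.fastq.gz", "healthy_1_R2.fastq.gz")),
    probes)
  expect_identical(from_mem, from_file)
})
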