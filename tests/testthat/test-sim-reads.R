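test_that("zero circular fraction yields no back-splice-spanning reads", {
  cfg <- sim_config(seed = 3, n_contigs = 1, genes_per_contig = 6,
                    circ_gene_fraction = 0.5, circ_fraction = 0,
                    effect_log2fc = 0, depth = 3000,
                    groups = c(healthy = 2, patient = 2))
  ds <- simulate_dataset(cfg)
  tr <- ds$reads$truth_reads
  expect_gt(nrow(tr), 0)
  expect_false(any(grepl(":B", tr$junction_id), na.rm = TRUE))
  expect_true(all(ds$reads$molecules$n_circ == 0))
})

test_that("zero depth produces empty FASTQ files that still parse", {
  cfg <- sim_config(seed = 3, n_contigs = 1, genes_per_contig = 2, depth = 0,
                    groups = c(healthy = 1, patient = 1))
  ds <- simulate_dataset(cfg)
  out <- tempfile()
  rd <- simulate_reads(ds$genome, ds$exons, ds$truth, cfg, outdir = out)
  f <- file.path(out, "healthy_1_R1.fastq.gz")
  expect_true(file.exists(f))
  expect_length(read_fastq(f), 0)
})

test_that("total emitted read pairs track the configured depth", {
  cfg <- sim_config(seed = 8, n_contigs = 1, genes_per_contig = 10,
                    depth = 5000, nb_dispersion = 0.05,
                    groups = c(healthy = 2, patient = 2))
  ds <- simulate_dataset(cfg)
  for (smp in names(ds$reads$samples)) {
    n <- length(ds$reads$samples[[smp]]$r1)
    ## NB sum over genes: sd = sqrt(sum(mu + phi mu^2))
    mu <- cfg$depth / 10
    tol <- 4 * sqrt(10 * (mu + 0.05 * mu^2))
    expect_lt(abs(n - cfg$depth), tol)
    expect_equal(length(ds$reads$samples[[smp]]$r2), n)
  }
})

test_that("read simulation is deterministic and truth ids match read names", {
  cfg <- sim_config(seed = 12, n_contigs = 1, genes_per_contig = 4,
                    depth = 1000, groups = c(healthy = 1, patient = 1))
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$reads$samples, ds2$reads$samples)
  expect_identical(ds1$reads$truth_reads, ds2$reads$truth_reads)
  all_names <- unlist(lapply(ds1$reads$samples,
                             function(s) c(names(s$r1), names(s$r2))))
  expect_setequal(ds1$reads$truth_reads$read_id, all_names)
})

test_that("junction-spanning reads split evenly between back-spliced and
          linear when the geometry makes the junction windows equal", {
  ## one gene with exons (300, 400, 299): the circle over the middle exon
  ## offers one back-splice window on Lc = 400 start positions, the linear
  ## transcript two linear-junction windows on L - fragment_mean + 1 =
  ## 999 - 200 + 1 = 800 effective start positions; with twice the windows
  ## on twice the positions the expected split is 50:50 at circ_fraction 0.5
  set.seed(42)
  exons <- make_toy_annotation(c(300L, 400L, 299L))
  genome <- make_toy_genome(exons)
  cfg <- sim_config(seed = 21, depth = 40000, circ_fraction = 0.5,
                    effect_log2fc = 0, nb_dispersion = 0,
                    groups = c(healthy = 1), read_len = 126,
                    fragment_len = c(200, 10))
  truth <- list(planted_circs = data.frame(
    gene_id = "gX", contig = "ctgT", strand = "+", tx_first = 2L,
    tx_last = 2L, start = exons$start[2], end = exons$end[2],
    span = 400L, circ_id = sprintf("ctgT:%d-%d", exons$start[2], exons$end[2]),
    circ_fraction.healthy = 0.5, stringsAsFactors = FALSE),
    planted_rcs = data.frame(), groups = cfg$groups)
  rd <- simulate_reads(genome, exons, truth, cfg)
  tr <- rd$truth_reads
  spanning <- tr$junction_id[!is.na(tr$junction_id)]
  n_bsj <- sum(grepl(":B", spanning))
  n_tot <- length(spanning)
  expect_gt(n_tot, 500)
  p_hat <- n_bsj / n_tot
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n_tot))  # 3 binomial SDs
})

test_that("back-splice reads carry last-exon-to-first-exon sequence", {
  exons <- make_toy_annotation(c(300L, 300L, 300L))
  genome <- make_toy_genome(exons)
  cfg <- sim_config(seed = 22, depth = 5000, circ_fraction = 1,
                    effect_log2fc = 0, nb_dispersion = 0,
                    groups = c(healthy = 1), fragment_len = c(250, 0),
                    read_len = 126)
  truth <- list(planted_circs = data.frame(
    gene_id = "gX", contig = "ctgT", strand = "+", tx_first = 2L,
    tx_last = 2L, start = exons$start[2], end = exons$end[2],
    span = 300L, circ_id = sprintf("ctgT:%d-%d", exons$start[2], exons$end[2]),
    circ_fraction.healthy = 1, stringsAsFactors = FALSE),
    planted_rcs = data.frame(), groups = cfg$groups)
  rd <- simulate_reads(genome, exons, truth, cfg)
  tr <- rd$truth_reads
  bsj_reads <- tr$read_id[!is.na(tr$junction_id) & grepl(":B", tr$junction_id)]
  expect_gt(length(bsj_reads), 10)
  exon2 <- substr(genome[["ctgT"]], exons$start[2], exons$end[2])
  junction_seq <- paste0(substr(exon2, 300 - 24, 300), substr(exon2, 1, 25))
  smp <- rd$samples[["healthy_1"]]
  pool <- c(smp$r1, smp$r2)
  for (rid in head(bsj_reads, 20)) {
    rv <- pool[[rid]]
    expect_true(grepl(junction_seq, rv, fixed = TRUE) ||
                  grepl(rc_oracle(junction_seq), rv, fixed = TRUE))
  }
})
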