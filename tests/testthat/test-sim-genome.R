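test_that("genome construction is forced by the configuration", {
  cfg <- sim_config(seed = 1, n_contigs = 1, genes_per_contig = 2,
                    exons_per_gene = c(4, 4))
  gb <- build_genome(cfg)
  expect_equal(nrow(gb$exons), 8L)           # 2 genes x 4 exons
  n_introns <- sum(vapply(unique(gb$exons$gene_id), function(g) {
    nrow(gene_introns(gb$exons, g))
  }, 0L))
  expect_equal(n_introns, 6L)                # 3 introns per 4-exon gene

  cfg2 <- sim_config(seed = 2, n_contigs = 1, genes_per_contig = 3,
                     exon_len = c(100, 100), read_len = 90,
                     fragment_len = c(200, 20))
  gb2 <- build_genome(cfg2)
  expect_true(all(gb2$exons$end - gb2$exons$start + 1 == 100))
})

test_that("same seed gives byte-identical outputs, different seed differs", {
  cfg <- sim_config(seed = 9, n_contigs = 1, genes_per_contig = 3)
  g1 <- build_genome(cfg)
  g2 <- build_genome(cfg)
  expect_identical(g1, g2)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(g1$genome, f1); write_fasta(g2$genome, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  g3 <- build_genome(sim_config(seed = 10, n_contigs = 1,
                                genes_per_contig = 3))
  expect_false(identical(g1$genome, g3$genome))
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(sim_config(depth = -1), "depth")
  expect_error(sim_config(circ_fraction = 1.5), "circ_fraction")
  expect_error(sim_config(read_len = 300, fragment_len = c(200, 10)),
               "fragment")
  expect_error(sim_config(exon_len = c(300, 100)), "exon_len")
})

test_that("zero circ fraction plants nothing", {
  cfg <- sim_config(seed = 4, n_contigs = 1, genes_per_contig = 4,
                    circ_gene_fraction = 0)
  gb <- build_genome(cfg)
  expect_length(gb$circ_candidates, 0)
  pl <- plant_circs_and_rcs(gb, cfg)
  expect_equal(nrow(pl$truth$planted_circs), 0L)
  expect_identical(pl$genome, gb$genome)
})

test_that("planted circles are internal-exon runs with the required span", {
  cfg <- sim_config(seed = 5, n_contigs = 1, genes_per_contig = 10,
                    circ_gene_fraction = 1, rcs_plant_prob = 1)
  gb <- build_genome(cfg)
  pl <- plant_circs_and_rcs(gb, cfg)
  pc <- pl$truth$planted_circs
  expect_gt(nrow(pc), 0)
  expect_true(all(pc$span >= cfg$min_span))
  expect_true(all(pc$end - pc$start + 1 == pc$span))
  for (i in seq_len(nrow(pc))) {
    e <- gb$exons[gb$exons$gene_id == pc$gene_id[i], ]
    expect_gt(pc$tx_first[i], 1)            # internal on both sides
    expect_lt(pc$tx_last[i], nrow(e))
  }
})

test_that("rcs_plant_prob = 1 gives every circle one recorded RCS pair and
          the planted upstream insert is the reverse complement of the
          downstream insert", {
  cfg <- sim_config(seed = 6, n_contigs = 1, genes_per_contig = 8,
                    circ_gene_fraction = 1, rcs_plant_prob = 1,
                    intron_len = c(500, 1500))
  gb <- build_genome(cfg)
  pl <- plant_circs_and_rcs(gb, cfg)
  pc <- pl$truth$planted_circs
  rcs <- pl$truth$planted_rcs
  expect_equal(sort(rcs$circ_id), sort(pc$circ_id))
  for (i in seq_len(nrow(rcs))) {
    ctg <- pl$genome[[rcs$contig[i]]]
    up <- substr(ctg, rcs$up_start[i], rcs$up_end[i])
    dn <- substr(ctg, rcs$down_start[i], rcs$down_end[i])
    expect_identical(up, rc_oracle(dn))     # base-by-base revcomp check
  }
  ## inserts fall strictly inside the flanking introns of their circle
  for (i in seq_len(nrow(rcs))) {
    g <- rcs$gene_id[i]
    iv <- gene_introns(gb$exons, g)
    inside <- function(s, e) {
      any(iv$start <= s & iv$end >= e)
    }
    expect_true(inside(rcs$up_start[i], rcs$up_end[i]))
    expect_true(inside(rcs$down_start[i], rcs$down_end[i]))
  }
})

test_that("circ-candidate genes receive longer introns when configured", {
  cfg <- sim_config(seed = 7, n_contigs = 2, genes_per_contig = 25,
                    circ_gene_fraction = 0.4, circ_intron_mult = 3)
  gb <- build_genome(cfg)
  ilens <- function(gids) {
    unlist(lapply(gids, function(g) {
      iv <- gene_introns(gb$exons, g)
      iv$end - iv$start + 1
    }))
  }
  circ_genes <- gb$circ_candidates
  other <- setdiff(unique(gb$exons$gene_id), circ_genes)
  expect_gt(mean(ilens(circ_genes)), mean(ilens(other)))
})
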