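test_that("flanking introns are extracted strand-aware", {
  exons <- make_toy_annotation(rep(300L, 4), intron_len = 400)
  set.seed(21)
  genome <- make_toy_genome(exons)
  call <- list(gene_id = "gX", tx_first = 2L, tx_last = 3L, circ_id = "c1")
  fl <- extract_flanking_introns(call, exons, genome)
  ctg <- genome[["ctgT"]]
  iv <- gene_introns(exons, "gX")
  ## plus strand: upstream = intron 1, downstream = intron 3
  expect_identical(fl$upstream, substr(ctg, iv$start[1], iv$end[1]))
  expect_identical(fl$downstream, substr(ctg, iv$start[3], iv$end[3]))
  expect_false(fl$up_missing || fl$down_missing)

  ## circle reaching transcript exon 1 has no upstream intron
  fl1 <- extract_flanking_introns(list(gene_id = "gX", tx_first = 1L,
                                       tx_last = 2L, circ_id = "c2"),
                                  exons, genome)
  expect_true(fl1$up_missing)
  expect_false(fl1$down_missing)

  ## minus strand: transcript-upstream is the genomically downstream intron,
  ## reverse-complemented
  exm <- make_toy_annotation(rep(300L, 4), strand = "-", intron_len = 400)
  flm <- extract_flanking_introns(list(gene_id = "gX", tx_first = 2L,
                                       tx_last = 3L, circ_id = "c3"),
                                  exm, genome)
  ## tx exon 2 on "-" is genomic exon 3; its transcript-5' intron is
  ## genomic intron 3 (to the right of the circle)
  expect_identical(flm$upstream, rc_oracle(substr(ctg, iv$start[3], iv$end[3])))
  expect_identical(flm$downstream, rc_oracle(substr(ctg, iv$start[1], iv$end[1])))
  expect_error(extract_flanking_introns(list(gene_id = "gX", tx_first = 0L,
                                             tx_last = 9L, circ_id = "c4"),
                                        exons, genome),
               "out of range")
})

test_that("log2 length comparison matches the closed-form pooled t", {
  same <- length_comparison(c(2, 4, 8), c(2, 4, 8))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  r <- length_comparison(c(2, 4, 8), c(8, 16, 32))
  expect_equal(r$t, oracle_t_pooled(log2(c(2, 4, 8)), log2(c(8, 16, 32))))
  expect_equal(r$p, 2 * pt(-abs(r$t), df = 4))
  expect_error(length_comparison(c(0, 2), c(1, 2)), "positive")
})

test_that("tripled intron lengths are detected as significant in nearly all
          simulated cohorts", {
  set.seed(22)
  hits <- vapply(1:50, function(i) {
    ctrl <- round(exp(runif(50, log(300), log(1500))))
    circ <- round(3 * exp(runif(50, log(300), log(1500))))
    length_comparison(circ, ctrl)$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("local alignment scores equal the brute-force DP oracle", {
  set.seed(23)
  for (i in 1:25) {
    up <- rand_dna(sample(20:60, 1))
    dn <- rand_dna(sample(20:60, 1))
    al <- rcs_align(up, dn)
    expect_equal(al$score, oracle_local_align(rc_oracle(up), dn))
  }
  ## a planted 50-nt inverted repeat scores exactly 50
  ins <- rand_dna(50)
  up2 <- paste0(rand_dna(30), rc_oracle(ins), rand_dna(25))
  dn2 <- paste0(rand_dna(40), ins, rand_dna(15))
  al2 <- rcs_align(up2, dn2)
  expect_gte(al2$score, 50)
  ## perfect palindromic pair of length L scores L
  dn3 <- rand_dna(80)
  expect_equal(rcs_align(rc_oracle(dn3), dn3)$score, 80)
})

test_that("alignment span coordinates point at the planted repeat", {
  set.seed(24)
  ins <- rand_dna(60)
  ## homopolymer flanks cannot extend the alignment: revcomp(up) flanks are
  ## T runs facing A runs in the downstream intron
  up <- paste0(strrep("A", 100), rc_oracle(ins), strrep("A", 40))
  dn <- paste0(strrep("A", 70), ins, strrep("A", 70))
  al <- rcs_align(up, dn)
  expect_equal(al$score, 60)
  expect_identical(substr(up, al$up_start, al$up_end), rc_oracle(ins))
  expect_identical(substr(dn, al$down_start, al$down_end), ins)
  ## score is symmetric under swapping sides (revcomp moved to the other)
  al_sw <- rcs_align(rc_oracle(dn), rc_oracle(up))
  expect_equal(al_sw$score, al$score)
})

test_that("long introns are truncated to the cap nearest the circle", {
  set.seed(25)
  ins <- rand_dna(40)
  ## upstream: repeat near its 3' end (kept side); downstream: near 5' end;
  ## homopolymer flanks keep the optimal alignment exactly on the repeat
  up <- paste0(strrep("A", 600), rc_oracle(ins), strrep("A", 10))
  dn <- paste0(strrep("A", 10), ins, strrep("A", 600))
  al <- rcs_align(up, dn, max_len = 200)
  expect_true(al$truncated)
  expect_equal(al$score, 40)
  expect_identical(substr(up, al$up_start, al$up_end), rc_oracle(ins))
  ## empty side -> undefined result flagged
  expect_false(rcs_align("", dn)$defined)
})

test_that("dinucleotide shuffling preserves composition and endpoints", {
  set.seed(26)
  din <- function(s) {
    v <- strsplit(s, "")[[1]]
    sort(paste0(head(v, -1), v[-1]))
  }
  for (i in 1:20) {
    s <- rand_dna(sample(50:200, 1))
    x <- shuffle_dinuc(s)
    expect_identical(din(x), din(s))
    expect_identical(substr(x, 1, 1), substr(s, 1, 1))
    n <- nchar(s)
    expect_identical(substr(x, n, n), substr(s, n, n))
  }
  ## shuffles do vary
  s <- rand_dna(100)
  expect_gt(length(unique(replicate(10, shuffle_dinuc(s)))), 1)
})

test_that("empirical RCS significance attains its lower bound on planted
          repeats and is deterministic given the seed", {
  set.seed(27)
  ins <- rand_dna(300)
  up <- paste0(rand_dna(50), rc_oracle(ins), rand_dna(50))
  dn <- paste0(rand_dna(50), ins, rand_dna(50))
  sig <- rcs_significance(up, dn, n_shuffles = 199, seed = 5)
  expect_equal(sig$p, 1 / 200)      # no shuffle can reach the planted score
  sig2 <- rcs_significance(up, dn, n_shuffles = 199, seed = 5)
  expect_identical(sig, sig2)
  expect_error(rcs_significance(up, dn, n_shuffles = 10), "99")
  ## observed score at the minimum possible -> p = 1 (every shuffle >= it)
  up0 <- strrep("A", 60)
  dn0 <- strrep("A", 60)            # revcomp(up) = T..T never matches A..A
  s0 <- rcs_significance(up0, dn0, n_shuffles = 99, seed = 1)
  expect_equal(s0$p, 1)
})

test_that("repeat annotation recovers planted consensus copies", {
  set.seed(28)
  lib <- c(Alu_like = rand_dna(300), simple_CA = strrep("CA", 25))
  ## exact copy -> full coverage
  ann <- annotate_repeats(lib[["Alu_like"]], lib)
  expect_equal(unname(ann$fractions["Alu-like"]), 1)
  ## consensus + equal-length random tail -> about half covered
  seq2 <- paste0(lib[["Alu_like"]], rand_dna(300))
  ann2 <- annotate_repeats(seq2, lib)
  expect_lt(abs(ann2$fractions[["Alu-like"]] - 0.5), 0.06)
  ## reverse-complemented copy is found too
  ann_rc <- annotate_repeats(rc_oracle(lib[["Alu_like"]]), lib)
  expect_equal(unname(ann_rc$fractions["Alu-like"]), 1)
  ## random sequence: no hit at 80 % identity over 50 nt
  ann3 <- annotate_repeats(rand_dna(1000), lib)
  expect_equal(sum(ann3$fractions), 0)
  expect_equal(nrow(ann3$intervals), 0L)
  ## simple repeat class
  ann4 <- annotate_repeats(paste0(rand_dna(200), strrep("CA", 40),
                                  rand_dna(200)), lib)
  expect_gt(ann4$fractions[["simple"]], 0.1)
  expect_error(annotate_repeats("ACGT", character(0)), "empty")
})
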