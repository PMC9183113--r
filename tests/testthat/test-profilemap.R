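test_that("profile bins conserve HSP bases and merge array regions", {
  one <- data.frame(qseqid = "m", sseqid = "chr", pident = 100,
                    length = 1000L, qstart = 1L, qend = 1000L,
                    sstart = 2001L, send = 3000L, strand = "+",
                    score = 1000, qcov = 100)
  p <- profile_hsps(one, bin_size = 10000L, monomer_len = 237,
                    chrom_lengths = c(chr = 50000L))
  expect_equal(sum(p$bins$covered), 1000)
  expect_equal(p$bins$covered[1], 1000)

  empty <- profile_hsps(one[0, ], bin_size = 10000L, monomer_len = 237,
                        chrom_lengths = c(chr = 50000L))
  expect_true(all(empty$bins$covered == 0))

  # chr6/chr8-like geometry scaled down: arrays at 350-750 bp and 30-35 kb
  m <- random_dna(237, seed = 1)
  big <- make_array(m, 21, 0.03, seed = 2)    # ~5 kb
  tiny_seq <- paste0(mutate(m, 0.03, seed = 3), mutate(m, 0.03, seed = 4))
  tiny <- substr(tiny_seq, 1, 400)            # ~1.7 copies
  chrom <- paste0(random_dna(349, seed = 5), tiny,
                  random_dna(30000 - 349 - 400, seed = 6), big$seq,
                  random_dna(40000 - 30000 - nchar(big$seq), seed = 7))
  h <- local_search(m, chrom, search_params(min_qcov_pct = 40),
                    subject_name = "chr")
  p2 <- profile_hsps(h, bin_size = 1000L, monomer_len = 237,
                     chrom_lengths = c(chr = 40000L))
  expect_equal(nrow(p2$regions), 2L)
  expect_true(abs(p2$regions$start[1] - 350L) <= 1000L)
  expect_true(abs(p2$regions$end[1] - 749L) <= 1000L)
  expect_true(abs(p2$regions$start[2] - 30001L) <= 1000L)
  expect_equal(sum(p2$bins$covered), sum(h$send - h$sstart + 1L))

  arr <- delineate_arrays(h, 237)
  expect_true(arr$short[arr$start < 1000])   # the 1.7-copy region
  expect_false(arr$short[arr$start > 1000])
})

test_that("genome_fraction is union coverage over genome size", {
  h <- data.frame(qseqid = "fam1", sseqid = "chr", pident = 95,
                  length = 5000L, qstart = 1L, qend = 5000L,
                  sstart = c(1L, 4001L), send = c(5000L, 10000L),
                  strand = "+", score = 1, qcov = 100)
  fr <- genome_fraction(list(relaxed = h), genome_size = 1e6)
  expect_equal(fr$fraction_pct, 1.0)  # union = 10 kb of 1 Mb

  fr0 <- genome_fraction(list(relaxed = h[0, ]), genome_size = 1e6)
  expect_equal(fr0$fraction_pct, 0)

  # additivity over disjoint families
  h2 <- h
  h2$qseqid <- "fam2"
  h2$sstart <- h2$sstart + 50000L
  h2$send <- h2$send + 50000L
  both <- genome_fraction(list(relaxed = rbind(h, h2)), 1e6)
  expect_equal(sum(both$fraction_pct), 2.0)

  expect_error(genome_fraction(list(relaxed = h), 0))
})

test_that("strict-preset fractions never exceed relaxed-preset fractions", {
  m <- random_dna(237, seed = 8)
  arr <- make_array(m, 15, 0.07, seed = 9)   # straddles the 90% cutoff
  g <- c(chr = paste0(random_dna(2000, seed = 10), arr$seq,
                      random_dna(2000, seed = 11)))
  hits <- list(
    relaxed = search_genome(c(fam = m), g, stringency_preset("relaxed")),
    strict = search_genome(c(fam = m), g, stringency_preset("strict")))
  fr <- genome_fraction(hits, sum(nchar(g)))
  expect_gt(fr$fraction_pct[fr$preset == "relaxed"], 0)
  expect_lte(fr$fraction_pct[fr$preset == "strict"],
             fr$fraction_pct[fr$preset == "relaxed"])
})

test_that("insilico_pcr predicts amplicons and monomer-step ladders", {
  tpl <- random_dna(500, seed = 12)
  fwd <- substr(tpl, 1, 20)
  rev <- revcomp(substr(tpl, 481, 500))
  lad <- insilico_pcr(tpl, fwd, rev)
  expect_equal(lad$lengths, 500L)

  # one site per monomer in a clean 10-copy array -> ladder step = monomer
  m <- random_dna(237, seed = 13)
  arr <- make_array(m, 10, 0, seed = 14)
  f2 <- substr(m, 20, 39)
  r2 <- revcomp(substr(m, 160, 179))
  lad2 <- insilico_pcr(arr$seq, f2, r2, max_len = 2500)
  expect_equal(lad2$step, 237)

  expect_error(insilico_pcr(tpl, "ACGTACGTAC", rev), "15 bp")
  none <- insilico_pcr(tpl, random_dna(20, seed = 15),
                       random_dna(20, seed = 16))
  expect_equal(length(none$lengths), 0L)
  expect_true(is.na(none$step))
})

test_that("an IGS-anchored ladder steps by the embedded monomer length", {
  # 2.5 embedded monomers upstream of an rRNA gene: forward sites once per
  # monomer, one fixed reverse site in the gene
  M <- random_dna(208, seed = 17)
  gene <- random_dna(600, seed = 18)
  region <- paste0(random_dna(200, seed = 19), M, M, substr(M, 1, 104),
                   random_dna(150, seed = 20), gene)
  fwd <- substr(M, 10, 29)
  rev <- revcomp(substr(gene, 301, 320))
  lad <- insilico_pcr(region, fwd, rev, max_len = 2000)
  expect_equal(length(lad$lengths), 3L)
  expect_equal(unique(diff(sort(lad$lengths))), 208L)
})

test_that("insilico_pcr is template-orientation invariant", {
  m <- random_dna(237, seed = 21)
  arr <- make_array(m, 6, 0.02, seed = 22)
  f <- substr(m, 5, 24)
  r <- revcomp(substr(m, 200, 219))
  a <- insilico_pcr(arr$seq, f, r, max_len = 2000)
  b <- insilico_pcr(revcomp(arr$seq), r, f, max_len = 2000)
  expect_equal(sort(a$lengths), sort(b$lengths))
})
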