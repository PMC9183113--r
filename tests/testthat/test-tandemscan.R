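test_that("detect_period recovers planted periods and rejects noise", {
  expect_equal(detect_period(strrep("ACG", 30), k = 4)$period[1], 3L)

  m <- random_dna(237, seed = 1)
  arr <- make_array(m, 20, 0.03, seed = 1)
  pc <- detect_period(arr$seq)
  expect_equal(pc$period[1], 237L)
  orc <- oracle_period(arr$seq)
  expect_equal(pc$period[1], orc$period)
  expect_equal(pc$support[1], orc$support, tolerance = 0.02)

  noise <- random_dna(5000, seed = 2)
  pn <- detect_period(noise)
  expect_true(nrow(pn) == 0L || all(pn$support < 0.5))
  orc_n <- oracle_period(noise)
  expect_lt(orc_n$support, 0.5)

  # strand invariance of the top period
  expect_equal(detect_period(revcomp(arr$seq))$period[1], 237L)
})

test_that("segment_monomers tiles arrays and reports terminal partials", {
  m <- random_dna(200, seed = 3)
  exact <- make_array(m, 4, 0)
  seg <- segment_monomers(exact$seq, consensus = m)
  expect_equal(seg$monomers$length, rep(200L, 4))
  expect_equal(seg$copy_number, 4)

  # 3.5 copies: last record has ~half length, fractional copy number ~3.5
  arr <- make_array(m, 3, 0.03, seed = 4)
  half <- substr(mutate(m, 0.03, seed = 5), 1, 100)
  seq35 <- paste0(arr$seq, half)
  seg35 <- segment_monomers(seq35, consensus = m)
  expect_equal(nrow(seg35$monomers), 4L)
  expect_true(seg35$monomers$partial[4])
  expect_equal(seg35$monomers$length[4], 100L, tolerance = 0)
  expect_equal(seg35$copy_number, 3.5, tolerance = 0.02)

  # segmentation tiles the region contiguously
  expect_true(all(seg35$monomers$start[-1] ==
                    seg35$monomers$end[-4] + 1L))
  expect_equal(sum(seg35$monomers$length), nchar(seq35))

  expect_error(segment_monomers(random_dna(300, seed = 6)),
               "no period detected")
})

test_that("segmentation recovers indel-bearing monomer lengths", {
  # an IGS-embedded repeat of ~2.5 monomers: 209 bp (1 bp insertion),
  # 206 bp (2 bp deletion), and a 109 bp terminal partial
  M <- random_dna(208, seed = 7)
  c1 <- mutate(M, 0.03, seed = 8)
  c1 <- paste0(substr(c1, 1, 100), "A", substr(c1, 101, 208))      # 209 bp
  c2 <- mutate(M, 0.08, seed = 9)
  c2 <- paste0(substr(c2, 1, 60), substr(c2, 63, 208))             # 206 bp
  c3 <- substr(mutate(M, 0.05, seed = 10), 1, 109)                 # 109 bp
  region <- paste0(c1, c2, c3)
  seg <- segment_monomers(region, consensus = M)
  expect_equal(nrow(seg$monomers), 3L)
  expect_equal(seg$monomers$length[1], 209L, tolerance = 3)
  expect_equal(seg$monomers$length[2], 206L, tolerance = 3)
  expect_equal(seg$monomers$length[3], 109L, tolerance = 3)
  expect_equal(seg$copy_number, 2.5, tolerance = 0.05)
})

test_that("build_consensus is a majority vote anchored on the longest copy", {
  m <- random_dna(150, seed = 11)
  expect_identical(build_consensus(rep(m, 5)), m)

  # a 2:1 split column takes the majority base
  v1 <- m
  substr(v1, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                substr(m, 50, 50))[1]
  expect_identical(build_consensus(c(m, m, v1)), m)

  # hidden-master recovery and per-column vote oracle equivalence
  master <- random_dna(200, seed = 12)
  copies <- withr::with_seed(1, replicate(10, mutate(master, 0.05)))
  cons <- build_consensus(copies)
  mism <- sum(strsplit(cons, "")[[1]] != strsplit(master, "")[[1]])
  expect_lte(mism, 1)
  expect_identical(cons, oracle_consensus(copies))

  # permutation invariance
  expect_identical(build_consensus(rev(copies)), cons)
  expect_identical(build_consensus(sample(copies)), cons)

  expect_error(build_consensus(character(0)))
})

test_that("delineate_arrays chains HSPs into arrays with gap control", {
  expect_equal(nrow(delineate_arrays(local_search(random_dna(100, seed = 1),
                                                  random_dna(5000, seed = 2)),
                                     100)), 0L)

  # 20 abutting HSPs -> one array, copy number 20, no insertions
  hsps <- data.frame(qseqid = "m", sseqid = "chr", pident = 99,
                     length = 237L,
                     qstart = 1L, qend = 237L,
                     sstart = (0:19) * 237L + 1L, send = (1:20) * 237L,
                     strand = "+", score = 200, qcov = 100)
  arr <- delineate_arrays(hsps, 237)
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$copy_number, 20)
  expect_equal(arr$insertion_proportion, 0)
  expect_false(arr$short)

  # two planted arrays separated by 10 kb stay distinct at max_gap = 2L
  m <- random_dna(150, seed = 13)
  a1 <- make_array(m, 8, 0.03, seed = 14)
  a2 <- make_array(m, 5, 0.03, seed = 15)
  subj <- paste0(random_dna(500, seed = 16), a1$seq,
                 random_dna(10000, seed = 17), a2$seq,
                 random_dna(500, seed = 18))
  found <- delineate_arrays(local_search(m, subj), monomer_len = 150)
  expect_equal(nrow(found), 2L)
  truth_starts <- c(501L, 501L + 8L * 150L + 10000L)
  truth_ends <- truth_starts + c(8L, 5L) * 150L - 1L
  expect_true(all(abs(found$start - truth_starts) <= 150))
  expect_true(all(abs(found$end - truth_ends) <= 150))
  expect_equal(found$copy_number, c(8, 5), tolerance = 0.15)
})
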