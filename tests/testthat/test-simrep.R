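test_that("mutate applies forced-change substitutions at the stated rate", {
  expect_identical(mutate("ACGT", 0, seed = 1), "ACGT")

  s <- random_dna(1000, seed = 1)
  m <- mutate(s, 0.10, seed = 1)
  expect_equal(nchar(m), 1000L)
  mism <- sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  # binomial: 100 +- 3 sd (sd ~ 9.5); identity 90% +- 2 points
  expect_gt(mism, 100 - 3 * sqrt(1000 * 0.1 * 0.9))
  expect_lt(mism, 100 + 3 * sqrt(1000 * 0.1 * 0.9))

  full <- mutate(s, 1.0, seed = 2)
  expect_equal(sum(strsplit(s, "")[[1]] == strsplit(full, "")[[1]]), 0L)

  expect_error(mutate("ACGX", 0.1), "ACGT")
  expect_identical(mutate(s, 0.05, seed = 7), mutate(s, 0.05, seed = 7))
})

test_that("make_array tiles copies with exact coordinates", {
  m <- random_dna(237, seed = 3)
  arr <- make_array(m, 4, 0)
  expect_equal(nchar(arr$seq), 948L)
  expect_equal(arr$copies$start, c(1L, 238L, 475L, 712L))
  expect_equal(arr$copies$end, c(237L, 474L, 711L, 948L))
  expect_identical(substr(arr$seq, 475, 711), m)

  arr2 <- make_array(m, 20, 0.03, seed = 1)
  expect_equal(nchar(arr2$seq), 4740L)
  for (i in seq_len(20)) {
    cp <- substr(arr2$seq, arr2$copies$start[i], arr2$copies$end[i])
    idp <- 100 * mean(strsplit(cp, "")[[1]] == strsplit(m, "")[[1]])
    expect_gte(idp, 90)
  }

  ins <- list(list(after_copy = 2, seq = random_dna(50, seed = 4)))
  arr3 <- make_array(m, 3, 0, insertions = ins)
  expect_equal(nchar(arr3$seq), 3L * 237L + 50L)
  expect_equal(arr3$copies$start[3], 2L * 237L + 50L + 1L)
  expect_equal(arr3$insertions$start, 475L)

  expect_error(make_array(m, 3, 0,
                          insertions = list(list(after_copy = 5, seq = "AC"))),
               "insertion index")
})

test_that("make_rdna_unit lays out the unit and embeds spacer copies", {
  tpl <- random_dna(3000, seed = 5)
  fam <- family_spec("delCS", c(98, 111), orientation = "reverse")

  u <- make_rdna_unit(igs_template = tpl, embedded = fam, n_copies = 2,
                      seed = 6)
  expect_equal(nrow(u$igs_copies), 2L)
  expect_true(all(u$igs_copies$start >= u$igs$start &
                    u$igs_copies$end <= u$igs$end))
  # copies sit adjacent to the IGS 3' end (next unit's 18S side)
  expect_equal(u$igs$end - max(u$igs_copies$end), 100L)
  expect_equal(u$genes$gene, c("18S", "5.8S", "26S"))
  expect_true(all(diff(u$genes$start) > 0))

  u0 <- make_rdna_unit(igs_template = tpl, n_copies = 0)
  expect_identical(substr(u0$seq, u0$igs$start, u0$igs$end), tpl)

  expect_error(make_rdna_unit(igs_template = random_dna(300, seed = 7),
                              embedded = fam, n_copies = 2, seed = 8),
               "shorter than total embedded length")
})

test_that("reverse-orientation embedding reverse-complements the monomer", {
  tpl <- random_dna(2000, seed = 9)
  mono <- random_dna(150, seed = 10)
  fwd <- make_rdna_unit(igs_template = tpl, embedded = mono, n_copies = 1)
  fs_rev <- family_spec("rev", c(75, 75), orientation = "reverse")
  emb <- sim_monomer(fs_rev, seed = 11)$seq
  rev <- make_rdna_unit(igs_template = tpl,
                        embedded = family_spec("rev", c(75, 75),
                                               orientation = "reverse"),
                        n_copies = 1, seed = 11)
  planted <- substr(rev$seq, rev$igs_copies$start, rev$igs_copies$end)
  expect_identical(planted, revcomp(emb))
  expect_equal(rev$igs_copies$orientation, "-")
  expect_identical(substr(fwd$seq, fwd$igs_copies$start,
                          fwd$igs_copies$end), mono)
})

test_that("make_genome writes a faithful, deterministic truth manifest", {
  m <- random_dna(237, seed = 12)
  spec <- sim_spec(seed = 2, chroms = list(list(
    name = "chr1", length = 100000,
    features = list(list(kind = "array", start = 40001, monomer = m,
                         copies = 20, sub_rate = 0.05)))))
  sim <- make_genome(spec)
  expect_length(sim$seqs, 1L)
  expect_equal(nchar(sim$seqs[["chr1"]]), 100000L)
  expect_equal(sum(sim$manifest$kind == "array"), 1L)
  expect_equal(sum(sim$manifest$kind == "array_copy"), 20L)

  # copy intervals tile the array interval exactly (no insertions)
  a <- sim$manifest[sim$manifest$kind == "array", ]
  cp <- sim$manifest[sim$manifest$kind == "array_copy", ]
  cp <- cp[order(cp$start), ]
  expect_equal(cp$start[1], a$start)
  expect_equal(cp$end[nrow(cp)], a$end)
  expect_true(all(cp$start[-1] == cp$end[-nrow(cp)] + 1L))

  # manifest fidelity: planted copies align to the monomer near 1 - rate
  # (substitution-only, so direct mismatch counting is the alignment);
  # per-copy bound widened to 4.5 SE because 20 copies are tested jointly,
  # mean identity held to 3 SE of the mean
  se <- sqrt(0.05 * 0.95 / 237)
  idps <- vapply(seq_len(nrow(cp)), function(i) {
    seq_i <- substr(sim$seqs[["chr1"]], cp$start[i], cp$end[i])
    mean(strsplit(seq_i, "")[[1]] == strsplit(m, "")[[1]])
  }, 0)
  expect_true(all(idps >= 1 - 0.05 - 4.5 * se))
  expect_gte(mean(idps), 1 - 0.05 - 3 * se / sqrt(length(idps)))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_genome(make_genome(spec), d1)
  write_genome(make_genome(spec), d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  bad <- sim_spec(seed = 1, chroms = list(list(
    name = "chr1", length = 5000,
    features = list(
      list(kind = "array", start = 1, monomer = m, copies = 4),
      list(kind = "array", start = 500, monomer = m, copies = 4)))))
  expect_error(make_genome(bad), "overlapping")
})

test_that("rdna cluster manifests distinguish arrays from IGS copies", {
  sim <- make_genome(chr8_like_sim(seed = 3, n_units = 3, copies = 5))
  kinds <- table(sim$manifest$kind)
  expect_equal(unname(kinds["array"]), 1L)
  expect_equal(unname(kinds["rdna_unit"]), 3L)
  expect_equal(unname(kinds["igs_copy"]), 6L)
  expect_equal(unname(kinds["igs"]), 2L)
  igs <- sim$manifest[sim$manifest$kind == "igs", ]
  expect_true(all(igs$config == "N"))
  # igs copies nest inside spacers between units; array copies do not
  ic <- sim$manifest[sim$manifest$kind == "igs_copy", ]
  overlaps_igs <- vapply(seq_len(nrow(ic)), function(i)
    any(ic$start[i] >= igs$start & ic$end[i] <= igs$end), TRUE)
  # the last unit's spacer has no downstream unit, so its copies fall outside
  expect_equal(sum(overlaps_igs), 4L)
})
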