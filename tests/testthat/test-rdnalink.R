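# One simulated chr8-like contig shared across the rDNA tests: an
# independent CS array plus a 4-unit co-oriented rDNA cluster, each spacer
# carrying two reverse-oriented delCS copies.
sim <- make_genome(chr8_like_sim(seed = 1, n_units = 4, copies = 6))
units <- annotate_rdna(sim$seqs)
igs <- delineate_igs(units)

test_that("annotate_rdna recovers planted units, orientation and absence", {
  truth <- sim$manifest[sim$manifest$kind == "rdna_unit", ]
  expect_equal(nrow(units), 4L)
  expect_true(all(units$complete))
  expect_true(all(units$orientation == "+"))
  expect_equal(units$start, truth$start)
  expect_equal(units$end, truth$end)

  # a single minus-strand unit is annotated with orientation "-"
  u <- make_rdna_unit(igs_template = random_dna(1500, seed = 2),
                      unit_orientation = "-")
  g <- c(c1 = paste0(random_dna(2000, seed = 3), u$seq,
                     random_dna(2000, seed = 4)))
  um <- annotate_rdna(g)
  expect_equal(nrow(um), 1L)
  expect_equal(um$orientation, "-")

  # no rDNA, no units
  expect_equal(nrow(annotate_rdna(c(c1 = random_dna(20000, seed = 5)))), 0L)
})

test_that("delineate_igs spans from one genic block to the next", {
  truth <- sim$manifest[sim$manifest$kind == "igs", ]
  expect_equal(nrow(igs), 3L)
  expect_true(all(igs$complete))
  expect_equal(igs$start, truth$start)
  expect_equal(igs$end, truth$end)
  expect_equal(igs$length, rep(3595L, 3))
  expect_true(all(igs$upstream_flank == "26S"))
  expect_true(all(igs$downstream_flank == "18S"))

  # a single unit at a contig end yields one partial spacer
  u <- make_rdna_unit(igs_template = random_dna(1500, seed = 6))
  g <- c(c1 = paste0(random_dna(1000, seed = 7), u$seq))
  u1 <- annotate_rdna(g)
  p <- delineate_igs(u1, chrom_lengths = c(c1 = nchar(g[["c1"]])))
  expect_equal(nrow(p), 1L)
  expect_false(p$complete)

  bad <- units
  bad$start[2] <- bad$start[1]
  bad$end[2] <- bad$end[1] + 10L
  expect_error(delineate_igs(bad[order(bad$start), ]), "overlapping")
})

test_that("classify_copies separates independent from IGS-linked copies", {
  hits <- sim$manifest[sim$manifest$kind %in% c("array_copy", "igs_copy"),
                       c("kind", "chrom", "start", "end")]
  cc <- classify_copies(hits, igs)
  expect_true(all(cc$label %in% c("independent", "igs_linked")))

  # every copy of the independent array stays independent
  expect_true(all(cc$label[cc$kind == "array_copy"] == "independent"))
  # exactly 2 x (number of complete spacers) copies are IGS-linked
  expect_equal(sum(cc$label == "igs_linked"), 2L * sum(igs$complete))

  far <- data.frame(chrom = "chr8", start = 100L, end = 300L)
  expect_equal(classify_copies(far, igs)$label, "independent")
})

test_that("pair_multiplicity reports per-spacer counts and their mode", {
  hits <- sim$manifest[sim$manifest$kind == "igs_copy",
                       c("chrom", "start", "end")]
  cc <- classify_copies(hits, igs)
  pm <- pair_multiplicity(cc, igs)
  expect_equal(pm$mode, 2L)
  expect_equal(unname(pm$histogram["2"]), 3L)

  # no embedded copies -> mode 0
  pm0 <- pair_multiplicity(classify_copies(hits[0, ], igs), igs)
  expect_equal(pm0$mode, 0L)

  # constructed histogram {1:1, 2:9} -> mode 2
  fake_igs <- data.frame(chrom = "c", start = (0:9) * 1000L + 1L,
                         end = (0:9) * 1000L + 500L, length = 500L,
                         complete = TRUE, igs_id = sprintf("igs%03d", 1:10))
  class(fake_igs) <- c("igs_regions", "data.frame")
  n_per <- c(1L, rep(2L, 9))
  cp <- do.call(rbind, lapply(1:10, function(i)
    data.frame(chrom = "c", start = (i - 1L) * 1000L + 10L * seq_len(n_per[i]),
               end = (i - 1L) * 1000L + 10L * seq_len(n_per[i]) + 5L)))
  pm19 <- pair_multiplicity(classify_copies(cp, fake_igs), fake_igs)
  expect_equal(pm19$mode, 2L)
  expect_equal(unname(pm19$histogram), c(1L, 9L))
})

test_that("spacer configuration is N between co-oriented, P between inverted", {
  cfg <- classify_config(igs)
  expect_true(all(cfg$config == "N"))

  # head-to-head cluster: inverted neighbours -> P
  spec <- sim_spec(seed = 4, chroms = list(list(
    name = "cP", length = 30000,
    features = list(list(kind = "rdna_cluster", start = 1000, n_units = 3,
                         igs_template = random_dna(1500, seed = 8),
                         orientations = c("+", "-", "-"))))))
  simp <- make_genome(spec)
  up <- annotate_rdna(simp$seqs)
  ip <- classify_config(delineate_igs(up))
  expect_equal(ip$config, c("P", "N"))
  truth <- simp$manifest[simp$manifest$kind == "igs", ]
  expect_equal(ip$config, truth$config)

  # whole-locus orientation flip preserves the N/P classes
  flipped <- c(cP = revcomp(simp$seqs[["cP"]]))
  uf <- annotate_rdna(flipped)
  ifl <- classify_config(delineate_igs(uf))
  expect_equal(sort(ifl$config), sort(ip$config))
  expect_true(all(uf$orientation == rev(ifelse(up$orientation == "+",
                                               "-", "+"))))

  # a partial spacer (single unit at a contig end) is undetermined
  u1 <- make_rdna_unit(igs_template = random_dna(1200, seed = 30))
  g1 <- c(cx = paste0(random_dna(800, seed = 31), u1$seq))
  part <- delineate_igs(annotate_rdna(g1),
                        chrom_lengths = c(cx = nchar(g1[["cx"]])))
  expect_equal(classify_config(part)$config, "undetermined")
})

test_that("compare_igs_variants infers internal deletions", {
  s <- random_dna(1000, seed = 9)
  same <- compare_igs_variants(s, s)
  expect_equal(same$deletion_length, 0L)

  # planted removal of positions 932..3542 from a 3595 bp spacer
  long <- random_dna(3595, seed = 10)
  short <- paste0(substr(long, 1, 931), substr(long, 3543, 3595))
  cmp <- compare_igs_variants(long, short)
  expect_equal(cmp$deletion_length, 2611L)
  expect_equal(cmp$breakpoint, 931L, tolerance = 5)

  # length-only single-deletion model
  lcmp <- compare_igs_variants(3595, 984)
  expect_equal(lcmp$deletion_length, 2611L)
  expect_identical(lcmp$model, "length-difference")

  # two large gaps come back as a multi-deletion report
  short2 <- paste0(substr(long, 1, 500), substr(long, 601, 2000),
                   substr(long, 2501, 3595))
  cmp2 <- compare_igs_variants(long, short2)
  expect_equal(nrow(cmp2$deletions), 2L)
  expect_equal(cmp2$deletion_length, 600L)

  # applying the inferred deletion improves identity to the short variant
  before <- global_align(long, short)$identity_pct
  cut <- paste0(substr(long, 1, cmp$breakpoint),
                substr(long, cmp$breakpoint + cmp$deletion_length + 1L, 3595))
  after <- global_align(cut, short)$identity_pct
  expect_gte(after, before)
})
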