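#' Binned HSP coverage profile and array regions
#'
#' Bins each chromosome and sums HSP bases falling in each bin (each HSP
#' contributes its clipped length, so total bin coverage equals total HSP
#' length).  HSP intervals separated by at most `2 * monomer_len` are merged
#' into array regions.
#'
#' @param hsps HSP data frame from [local_search()]/[search_genome()].
#' @param bin_size Bin size in bp (default 10 kb, suited to simulated
#'   chromosomes; 100 kb is a better fit for real assemblies).
#' @param monomer_len Monomer length used for the region merge gap; when
#'   NULL, twice the median HSP length is used.
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   missing, each chromosome extends to its last HSP.
#' @return List of class `genome_profile`: `bins` (data frame chrom,
#'   bin_start, bin_end, covered), `regions` (data frame chrom, start, end),
#'   `bin_size`.
#' @export
profile_hsps <- function(hsps, bin_size = 10000L, monomer_len = NULL,
                         chrom_lengths = NULL) {
  bin_size <- as.integer(bin_size)
  merge_gap <- if (is.null(monomer_len)) {
    if (nrow(hsps)) 2L * as.integer(stats::median(hsps$send - hsps$sstart
                                                  + 1L)) else 0L
  } else 2L * as.integer(monomer_len)
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else
    unique(hsps$sseqid)
  bins <- list(); regions <- list()
  for (chrom in chroms) {
    sub <- hsps[hsps$sseqid == chrom, , drop = FALSE]
    clen <- if (!is.null(chrom_lengths)) as.integer(chrom_lengths[[chrom]])
      else if (nrow(sub)) max(sub$send) else next
    nb <- ceiling(clen / bin_size)
    covered <- numeric(nb)
    if (nrow(sub)) {
      for (i in seq_len(nrow(sub))) {
        b1 <- (sub$sstart[i] - 1L) %/% bin_size + 1L
        b2 <- (sub$send[i] - 1L) %/% bin_size + 1L
        for (b in b1:b2) {
          lo <- (b - 1L) * bin_size + 1L
          hi <- min(b * bin_size, clen)
          covered[b] <- covered[b] +
            max(0L, min(hi, sub$send[i]) - max(lo, sub$sstart[i]) + 1L)
        }
      }
      mr <- IRanges::reduce(IRanges::IRanges(sub$sstart, sub$send),
                            min.gapwidth = merge_gap + 1L)
      regions[[chrom]] <- data.frame(
        chrom = chrom, start = IRanges::start(mr), end = IRanges::end(mr))
    }
    bins[[chrom]] <- data.frame(
      chrom = chrom,
      bin_start = (seq_len(nb) - 1L) * bin_size + 1L,
      bin_end = pmin(seq_len(nb) * bin_size, clen),
      covered = covered)
  }
  structure(list(bins = do.call(rbind, c(bins, make.row.names = FALSE)),
                 regions = do.call(rbind, c(regions,
                                            make.row.names = FALSE)),
                 bin_size = bin_size),
            class = "genome_profile")
}

#' @export
print.genome_profile <- function(x, ...) {
  nr <- if (is.null(x$regions)) 0L else nrow(x$regions)
  cat(sprintf("<genome_profile> %d bins of %d bp, %d array region(s)\n",
              nrow(x$bins), x$bin_size, nr))
  invisible(x)
}

#' Write a genome profile as bedGraph (+ regions BED)
#'
#' @param profile A `genome_profile` from [profile_hsps()].
#' @param bedgraph Path for the per-bin coverage track.
#' @param regions_bed Optional path for the merged array regions.
#' @export
write_profile <- function(profile, bedgraph, regions_bed = NULL) {
  b <- profile$bins
  utils::write.table(
    data.frame(b$chrom, b$bin_start - 1L, b$bin_end, b$covered),
    bedgraph, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  if (!is.null(regions_bed) && !is.null(profile$regions)) {
    r <- profile$regions
    utils::write.table(
      data.frame(r$chrom, r$start - 1L, r$end),
      regions_bed, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  invisible(NULL)
}

#' Genome-fraction estimates per family and stringency preset
#'
#' For each preset, the union of that preset's HSP intervals (overlaps
#' merged per chromosome) is divided by the genome size.  When the HSP
#' tables carry several query families (`qseqid`), one estimate per family
#' per preset is returned; the strict preset's fraction can never exceed the
#' relaxed one on the same hits source.
#'
#' @param hsps_by_preset Named list of HSP data frames, one per preset
#'   (e.g. `list(relaxed = ..., strict = ...)`).
#' @param genome_size Genome size in bp (> 0).  The assembly's total length
#'   is the natural default; an external flow-cytometry figure can be
#'   supplied instead.
#' @return Data frame of class `fraction_estimates`: family, preset,
#'   covered_bp, genome_size, fraction_pct.
#' @export
genome_fraction <- function(hsps_by_preset, genome_size) {
  stopifnot(is.list(hsps_by_preset), !is.null(names(hsps_by_preset)),
            genome_size > 0)
  out <- list()
  for (preset in names(hsps_by_preset)) {
    h <- hsps_by_preset[[preset]]
    fams <- if (nrow(h)) unique(h$qseqid) else character(0)
    for (fam in fams) {
      sub <- h[h$qseqid == fam, , drop = FALSE]
      covered <- 0L
      for (chrom in unique(sub$sseqid)) {
        cc <- sub[sub$sseqid == chrom, ]
        covered <- covered + sum(IRanges::width(IRanges::reduce(
          IRanges::IRanges(cc$sstart, cc$send))))
      }
      out[[length(out) + 1L]] <- data.frame(
        family = fam, preset = preset, covered_bp = covered,
        genome_size = genome_size,
        fraction_pct = 100 * covered / genome_size,
        stringsAsFactors = FALSE)
    }
    if (length(fams) == 0L)
      out[[length(out) + 1L]] <- data.frame(
        family = NA_character_, preset = preset, covered_bp = 0L,
        genome_size = genome_size, fraction_pct = 0,
        stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  class(df) <- c("fraction_estimates", "data.frame")
  df
}

# Primer binding sites on a template.  A site requires <= max_mismatch
# mismatches over the primer footprint and an exact match of the primer's
# three 3'-terminal bases.  Returns forward sites (primer on + strand,
# extension to the right; 3' end = site end) and reverse sites (primer on -
# strand, extension to the left; 3' end = site start).
.primer_sites <- function(template, primer, max_mismatch) {
  n <- nchar(primer)
  find <- function(pat) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                  Biostrings::DNAString(template),
                                  max.mismatch = max_mismatch,
                                  with.indels = FALSE)
    data.frame(start = Biostrings::start(m), end = Biostrings::end(m))
  }
  fwd <- find(primer)
  if (nrow(fwd)) {
    ok <- substring(template, fwd$end - 2L, fwd$end) ==
      substring(primer, n - 2L, n)
    fwd <- fwd[ok, , drop = FALSE]
  }
  rcp <- revcomp(primer)
  rev <- find(rcp)
  if (nrow(rev)) {
    ok <- substring(template, rev$start, rev$start + 2L) ==
      substring(rcp, 1L, 3L)
    rev <- rev[ok, , drop = FALSE]
  }
  list(fwd = fwd, rev = rev)
}

#' In-silico PCR amplicon ladder
#'
#' Predicts all amplicons a primer pair would produce from a template: every
#' plus-strand site of either primer paired with every downstream
#' minus-strand site of either primer within `max_len` yields one amplicon
#' (inclusive of both primer footprints).  Binding requires at most
#' `max_mismatch` mismatches and an exactly matching 3'-terminal base trio.
#' On a tandem array with one site per monomer the amplicon lengths form a
#' ladder whose step equals the monomer length.
#'
#' @param template Template nucleotide string.
#' @param fwd_primer,rev_primer Primer sequences, each >= 15 bp.
#' @param max_len Maximum amplicon length (default 5000 bp).
#' @param max_mismatch Mismatch allowance over the primer footprint
#'   (default 2), 3'-terminal trio always exact.
#' @return List of class `amplicon_ladder`: `amplicons` (data frame start,
#'   end, length, left_primer, right_primer), `lengths` (sorted), `step`
#'   (median of consecutive differences of the unique sorted lengths; NA
#'   when fewer than two distinct lengths).
#' @export
insilico_pcr <- function(template, fwd_primer, rev_primer, max_len = 5000L,
                         max_mismatch = 2L) {
  template <- .check_dna(template, allow_n = TRUE, arg = "template")
  fwd_primer <- .check_dna(fwd_primer, arg = "fwd_primer")
  rev_primer <- .check_dna(rev_primer, arg = "rev_primer")
  if (nchar(fwd_primer) < 15L || nchar(rev_primer) < 15L)
    stop("primers must be at least 15 bp", call. = FALSE)
  sites <- list(fwd = .primer_sites(template, fwd_primer, max_mismatch),
                rev = .primer_sites(template, rev_primer, max_mismatch))
  amps <- list()
  for (left in c("fwd", "rev")) {
    for (right in c("fwd", "rev")) {
      ls <- sites[[left]]$fwd   # + strand sites of the left primer
      rs <- sites[[right]]$rev  # - strand sites of the right primer
      if (nrow(ls) == 0L || nrow(rs) == 0L) next
      for (i in seq_len(nrow(ls)))
        for (j in seq_len(nrow(rs))) {
          if (rs$start[j] <= ls$end[i]) next
          len <- rs$end[j] - ls$start[i] + 1L
          if (len > max_len) next
          amps[[length(amps) + 1L]] <- data.frame(
            start = ls$start[i], end = rs$end[j], length = len,
            left_primer = left, right_primer = right,
            stringsAsFactors = FALSE)
        }
    }
  }
  amps <- if (length(amps)) unique(do.call(rbind, amps)) else
    data.frame(start = integer(0), end = integer(0), length = integer(0),
               left_primer = character(0), right_primer = character(0))
  amps <- amps[order(amps$length, amps$start), , drop = FALSE]
  rownames(amps) <- NULL
  lens <- sort(amps$length)
  ul <- unique(lens)
  step <- if (length(ul) >= 2L) stats::median(diff(ul)) else NA_real_
  structure(list(amplicons = amps, lengths = lens, step = step),
            class = "amplicon_ladder")
}

#' @export
print.amplicon_ladder <- function(x, ...) {
  cat(sprintf("<amplicon_ladder> %d amplicon(s)%s\n", length(x$lengths),
              if (is.na(x$step)) "" else
                sprintf(", ladder step %.0f bp", x$step)))
  if (length(x$lengths)) cat(" lengths:",
                             paste(x$lengths, collapse = ", "), "\n")
  invisible(x)
}

#' Write an amplicon ladder as TSV
#'
#' One row per amplicon (start, end, length, primer roles), preceded by no
#' header comment; the ladder step is echoed as a trailing comment line.
#'
#' @param ladder An `amplicon_ladder` from [insilico_pcr()].
#' @param path Output path.
#' @export
write_ladder <- function(ladder, path) {
  utils::write.table(ladder$amplicons, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  cat(sprintf("# ladder_step\t%s\n",
              ifelse(is.na(ladder$step), "NA", ladder$step)),
      file = path, append = TRUE)
  invisible(path)
}
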