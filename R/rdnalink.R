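#' Annotate 45S rDNA units in a genome
#'
#' The 18S, 5.8S and 26S references are searched against every chromosome
#' with [local_search()]; gene hits on the same strand are assembled into
#' units when they follow the transcription order (18S, 5.8S, 26S along the
#' strand) within `max_gene_gap` of each other.  Incomplete gene runs are
#' reported as partial units.
#'
#' @param genome Named character vector of chromosome sequences (or a FASTA
#'   path).
#' @param rrna_refs Named vector/list with `18S`, `5.8S`, `26S` sequences;
#'   defaults to the bundled surrogates from [surrogate_rdna_refs()].
#' @param params A [search_params()] object; the default relaxes query
#'   coverage to 80% so genes truncated at contig ends still anchor units.
#' @param scoring An [align_scoring()] object.
#' @param max_gene_gap Largest allowed gap between consecutive genes of one
#'   unit (bp).
#' @return Data frame of class `rdna_units`: chrom, start, end (genic span
#'   18S..26S), orientation, complete, and per-gene coordinates
#'   (`start_18S`, `end_18S`, ...; NA for genes missing from partial units).
#' @export
annotate_rdna <- function(genome, rrna_refs = NULL,
                          params = search_params(min_identity_pct = 80,
                                                 min_qcov_pct = 80),
                          scoring = align_scoring(),
                          max_gene_gap = 5000L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta_chr(genome)
  stopifnot(!is.null(names(genome)))
  if (is.null(rrna_refs)) rrna_refs <- surrogate_rdna_refs()
  rrna_refs <- as.list(rrna_refs)[c("18S", "5.8S", "26S")]
  stopifnot(!any(vapply(rrna_refs, is.null, TRUE)))
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), orientation = character(0),
                      complete = logical(0),
                      start_18S = integer(0), end_18S = integer(0),
                      start_5.8S = integer(0), end_5.8S = integer(0),
                      start_26S = integer(0), end_26S = integer(0))
  class(empty) <- c("rdna_units", "data.frame")
  hits <- list()
  for (g in names(rrna_refs))
    for (chrom in names(genome)) {
      h <- local_search(rrna_refs[[g]], genome[[chrom]], params = params,
                        scoring = scoring, query_name = g,
                        subject_name = chrom)
      if (nrow(h)) hits[[paste(g, chrom)]] <- h
    }
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  units <- list()
  for (chrom in unique(hits$sseqid)) {
    for (strand in c("+", "-")) {
      sub <- hits[hits$sseqid == chrom & hits$strand == strand, ,
                  drop = FALSE]
      if (nrow(sub) == 0L) next
      sub <- sub[order(sub$sstart), , drop = FALSE]
      # gene order along ascending coordinates
      expect <- if (strand == "+") c("18S", "5.8S", "26S") else
        c("26S", "5.8S", "18S")
      i <- 1L
      while (i <= nrow(sub)) {
        run <- i
        while (length(run) < 3L && run[length(run)] + 1L <= nrow(sub)) {
          nxt <- run[length(run)] + 1L
          ok <- sub$qseqid[nxt] == expect[length(run) + 1L] &&
            sub$qseqid[run[length(run)]] == expect[length(run)] &&
            (sub$sstart[nxt] - sub$send[run[length(run)]] - 1L) <=
              max_gene_gap
          if (!ok) break
          run <- c(run, nxt)
        }
        complete <- length(run) == 3L &&
          identical(sub$qseqid[run], expect)
        blk <- sub[run, , drop = FALSE]
        coord <- function(g, what) {
          j <- which(blk$qseqid == g)
          if (length(j) == 0L) NA_integer_ else
            as.integer(blk[[what]][j[1L]])
        }
        units[[length(units) + 1L]] <- data.frame(
          chrom = chrom, start = min(blk$sstart), end = max(blk$send),
          orientation = strand, complete = complete,
          start_18S = coord("18S", "sstart"), end_18S = coord("18S", "send"),
          start_5.8S = coord("5.8S", "sstart"),
          end_5.8S = coord("5.8S", "send"),
          start_26S = coord("26S", "sstart"), end_26S = coord("26S", "send"),
          stringsAsFactors = FALSE)
        i <- run[length(run)] + 1L
      }
    }
  }
  df <- do.call(rbind, units)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("rdna_units", "data.frame")
  df
}

#' Delineate intergenic spacers between rDNA units
#'
#' One IGS per adjacent unit pair on a chromosome, spanning from the end of
#' the upstream unit's genic block + 1 to the start of the downstream unit's
#' genic block - 1 (for co-oriented units this is the stretch between the
#' 26S 3' end and the next 18S 5' end).  When `chrom_lengths` are supplied,
#' the spacer trailing the last unit in its transcription direction is also
#' reported, flagged partial.
#'
#' @param units An `rdna_units` data frame from [annotate_rdna()].
#' @param chrom_lengths Optional named integer vector of chromosome lengths.
#' @return Data frame of class `igs_regions`: chrom, start, end, length,
#'   complete, upstream_orientation, downstream_orientation, upstream_flank,
#'   downstream_flank (which gene faces the spacer from each side).
#' @export
delineate_igs <- function(units, chrom_lengths = NULL) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      complete = logical(0),
                      upstream_orientation = character(0),
                      downstream_orientation = character(0),
                      upstream_flank = character(0),
                      downstream_flank = character(0))
  class(empty) <- c("igs_regions", "data.frame")
  if (nrow(units) == 0L) return(empty)
  flank_gene <- function(u, side) {
    # gene of unit u facing ascending (side = "right") or descending
    # ("left") coordinates
    if (side == "right") {
      if (u$orientation == "+") "26S" else "18S"
    } else {
      if (u$orientation == "+") "18S" else "26S"
    }
  }
  out <- list()
  for (chrom in unique(units$chrom)) {
    uu <- units[units$chrom == chrom, , drop = FALSE]
    uu <- uu[order(uu$start), , drop = FALSE]
    if (nrow(uu) >= 2L &&
        any(uu$start[-1L] <= uu$end[-nrow(uu)]))
      stop("overlapping rDNA units on ", chrom, call. = FALSE)
    if (nrow(uu) >= 2L)
      for (i in seq_len(nrow(uu) - 1L)) {
        a <- uu[i, ]; b <- uu[i + 1L, ]
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = a$end + 1L, end = b$start - 1L,
          length = b$start - a$end - 1L, complete = TRUE,
          upstream_orientation = a$orientation,
          downstream_orientation = b$orientation,
          upstream_flank = flank_gene(a, "right"),
          downstream_flank = flank_gene(b, "left"),
          stringsAsFactors = FALSE)
      }
    if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      last <- uu[nrow(uu), ]
      first <- uu[1L, ]
      clen <- as.integer(chrom_lengths[[chrom]])
      if (last$orientation == "+" && last$end < clen)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = last$end + 1L, end = clen,
          length = clen - last$end, complete = FALSE,
          upstream_orientation = last$orientation,
          downstream_orientation = NA_character_,
          upstream_flank = flank_gene(last, "right"),
          downstream_flank = NA_character_, stringsAsFactors = FALSE)
      if (first$orientation == "-" && first$start > 1L)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = 1L, end = first$start - 1L,
          length = first$start - 1L, complete = FALSE,
          upstream_orientation = NA_character_,
          downstream_orientation = first$orientation,
          upstream_flank = NA_character_,
          downstream_flank = flank_gene(first, "left"),
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  df <- do.call(rbind, out)
  df <- df[df$length > 0L, , drop = FALSE]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df$igs_id <- sprintf("igs%03d", seq_len(nrow(df)))
  class(df) <- c("igs_regions", "data.frame")
  df
}

#' Classify repeat copies as independent or IGS-linked
#'
#' A copy is `igs_linked` when at least `min_overlap_frac` of its length
#' lies inside one intergenic spacer; every copy receives exactly one label.
#'
#' @param copies Data frame of repeat hits/copies with columns `chrom` (or
#'   `sseqid`), `start`/`end` (or `sstart`/`send`).
#' @param igs_regions An `igs_regions` data frame from [delineate_igs()].
#' @param min_overlap_frac Containment threshold (default 0.9).
#' @return The `copies` data frame with added `label` (`"igs_linked"` or
#'   `"independent"`) and `igs_id` (NA for independent copies).
#' @export
classify_copies <- function(copies, igs_regions, min_overlap_frac = 0.9) {
  if (!"chrom" %in% names(copies) && "sseqid" %in% names(copies))
    copies$chrom <- copies$sseqid
  if (!"start" %in% names(copies) && "sstart" %in% names(copies)) {
    copies$start <- copies$sstart
    copies$end <- copies$send
  }
  copies$label <- rep("independent", nrow(copies))
  copies$igs_id <- rep(NA_character_, nrow(copies))
  if (nrow(copies) == 0L || nrow(igs_regions) == 0L) return(copies)
  for (i in seq_len(nrow(copies))) {
    ig <- igs_regions[igs_regions$chrom == copies$chrom[i], , drop = FALSE]
    if (nrow(ig) == 0L) next
    ov <- pmin(ig$end, copies$end[i]) - pmax(ig$start, copies$start[i]) + 1L
    j <- which.max(ov)
    width <- copies$end[i] - copies$start[i] + 1L
    if (ov[j] >= min_overlap_frac * width) {
      copies$label[i] <- "igs_linked"
      copies$igs_id[i] <- ig$igs_id[j]
    }
  }
  copies
}

#' Embedded-copy multiplicity per intergenic spacer
#'
#' Counts IGS-linked copies per complete IGS (spacers with no copy count as
#' zero) and reports the histogram and its mode (ties break toward the
#' smaller count).
#'
#' @param classified_copies Output of [classify_copies()].
#' @param igs_regions An `igs_regions` data frame.
#' @return List of class `pair_multiplicity`: `per_igs` (data frame igs_id,
#'   count), `histogram` (named integer vector), `mode`.
#' @export
pair_multiplicity <- function(classified_copies, igs_regions) {
  complete <- igs_regions[igs_regions$complete, , drop = FALSE]
  linked <- classified_copies[classified_copies$label == "igs_linked", ,
                              drop = FALSE]
  counts <- vapply(complete$igs_id,
                   function(id) sum(linked$igs_id == id, na.rm = TRUE), 1L)
  per_igs <- data.frame(igs_id = complete$igs_id, count = counts,
                        stringsAsFactors = FALSE)
  hist <- table(per_igs$count)
  mode <- if (length(hist) == 0L) NA_integer_ else
    as.integer(names(hist)[which.max(hist)])
  structure(list(per_igs = per_igs,
                 histogram = stats::setNames(as.integer(hist), names(hist)),
                 mode = mode),
            class = "pair_multiplicity")
}

#' @export
print.pair_multiplicity <- function(x, ...) {
  cat(sprintf("<pair_multiplicity> %d complete IGS, modal copies/IGS = %s\n",
              nrow(x$per_igs), x$mode))
  print(x$histogram)
  invisible(x)
}

#' Classify the spacer configuration between flanking rDNA units
#'
#' `N` between co-oriented units, `P` between inverted units,
#' `undetermined` for partial spacers.
#'
#' @param igs_regions An `igs_regions` data frame from [delineate_igs()].
#' @return The data frame with added `config` and `evidence` columns.
#' @export
classify_config <- function(igs_regions) {
  cfg <- character(nrow(igs_regions))
  ev <- character(nrow(igs_regions))
  for (i in seq_len(nrow(igs_regions))) {
    r <- igs_regions[i, ]
    if (!isTRUE(r$complete) || is.na(r$upstream_orientation) ||
        is.na(r$downstream_orientation)) {
      cfg[i] <- "undetermined"
      ev[i] <- "partial spacer"
    } else if (r$upstream_orientation == r$downstream_orientation) {
      cfg[i] <- "N"
      ev[i] <- sprintf("co-oriented flanking units (%s/%s)",
                       r$upstream_orientation, r$downstream_orientation)
    } else {
      cfg[i] <- "P"
      ev[i] <- sprintf("inverted flanking units (%s/%s)",
                       r$upstream_orientation, r$downstream_orientation)
    }
  }
  igs_regions$config <- cfg
  igs_regions$evidence <- ev
  igs_regions
}

#' Compare two intergenic-spacer variants
#'
#' With two sequences, the short variant is globally aligned to the long one
#' and internal gap runs of at least `min_gap` bp in the short side are
#' reported as deletions, each with its breakpoint: the last aligned long
#' -variant position before the gap.  With two numeric lengths, the stated
#' single-internal-deletion model gives deletion length = length difference
#' (breakpoint unknown).  More than one large gap yields a multi-deletion
#' report, not an error.
#'
#' @param long_igs,short_igs Sequences (character) or lengths (numeric).
#' @param scoring An [align_scoring()] object.
#' @param min_gap Minimum reported deletion length in bp (default 30).
#' @return List of class `igs_comparison`: `deletion_length` (total),
#'   `breakpoint` (of the largest deletion; NA under the length-only model),
#'   `deletions` (data frame breakpoint, length), `model`.
#' @export
compare_igs_variants <- function(long_igs, short_igs,
                                 scoring = align_scoring(), min_gap = 30L) {
  if (is.numeric(long_igs) && is.numeric(short_igs)) {
    stopifnot(long_igs >= short_igs)
    dl <- as.integer(long_igs - short_igs)
    return(structure(list(
      deletion_length = dl, breakpoint = NA_integer_,
      deletions = data.frame(breakpoint = NA_integer_, length = dl),
      model = "length-difference"), class = "igs_comparison"))
  }
  long_igs <- .check_dna(long_igs, arg = "long_igs")
  short_igs <- .check_dna(short_igs, arg = "short_igs")
  al <- global_align(short_igs, long_igs, scoring)
  q <- .chars(al$aligned_query)   # short variant
  s <- .chars(al$aligned_subject) # long variant
  core <- which(q != "-" & s != "-")
  lpos <- cumsum(s != "-")
  dels <- list()
  if (length(core)) {
    rl <- rle(q[min(core):max(core)] == "-")
    ends <- min(core) - 1L + cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (i in which(rl$values & rl$lengths >= min_gap))
      dels[[length(dels) + 1L]] <- data.frame(
        breakpoint = as.integer(lpos[starts[i] - 1L]),
        length = rl$lengths[i])
  }
  dels <- if (length(dels)) do.call(rbind, dels) else
    data.frame(breakpoint = integer(0), length = integer(0))
  structure(list(
    deletion_length = sum(dels$length),
    breakpoint = if (nrow(dels)) dels$breakpoint[which.max(dels$length)]
      else NA_integer_,
    deletions = dels, model = "alignment"), class = "igs_comparison")
}

#' @export
print.igs_comparison <- function(x, ...) {
  cat(sprintf("<igs_comparison> total deletion %d bp (%s model)",
              x$deletion_length, x$model))
  if (!is.na(x$breakpoint))
    cat(sprintf(", main breakpoint after position %d", x$breakpoint))
  cat("\n")
  invisible(x)
}
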