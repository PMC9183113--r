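#' De novo tandem period detection
#'
#' Candidate periods are collected from the recurrence-distance histogram of
#' exact k-mers (distances between consecutive occurrences of the same
#' k-mer), then each candidate lag `p` is scored by its support: the
#' fraction of positions `i` with `seq[i] == seq[i + p]`.  A fundamental
#' period and its multiples have statistically identical support (copies
#' diverge independently, so matching at lag `2p` is as likely as at lag
#' `p`), differing only by sampling noise of order `1/sqrt(n)`.  The
#' candidates whose support lies within `support_tol` of the maximum are
#' therefore treated as one tie group and ranked by ascending period, so
#' the fundamental outranks its harmonics; remaining candidates follow in
#' decreasing-support order.
#'
#' @param seq Nucleotide string.
#' @param k Word size for the recurrence histogram (default 12).
#' @param max_period Largest period considered (default 2000 bp).
#' @param min_count Minimum k-mer recurrence count for a candidate lag.
#' @param max_candidates Number of histogram candidates scored.
#' @param support_tol Absolute support tolerance within which candidates
#'   are considered tied (default 0.02, several standard errors of the
#'   support estimate on kilobase-scale arrays).
#' @return Data frame of class `period_calls` with columns `period`,
#'   `support`, `count`, `phase`, ranked best first; zero rows when no
#'   periodicity is found.
#' @export
detect_period <- function(seq, k = 12L, max_period = 2000L, min_count = 2L,
                          max_candidates = 8L, support_tol = 0.02) {
  seq <- .check_dna(seq, allow_n = TRUE)
  n <- nchar(seq)
  empty <- data.frame(period = integer(0), support = numeric(0),
                      count = integer(0), phase = integer(0))
  class(empty) <- c("period_calls", "data.frame")
  if (n < 2L * 2L) return(empty)
  km <- .kmers(seq, k)
  occ <- split(seq_along(km), km)
  occ <- occ[lengths(occ) > 1L]
  if (length(occ) == 0L) return(empty)
  d <- unlist(lapply(occ, diff), use.names = FALSE)
  d <- d[d >= 2L & d <= min(max_period, n - 1L)]
  if (length(d) == 0L) return(empty)
  tab <- sort(table(d), decreasing = TRUE)
  tab <- tab[tab >= min_count]
  if (length(tab) == 0L) return(empty)
  cand <- as.integer(names(tab))[seq_len(min(max_candidates, length(tab)))]
  counts <- as.integer(tab)[seq_len(length(cand))]
  ch <- .chars(seq)
  supp_of <- function(p) mean(ch[seq_len(n - p)] == ch[(p + 1L):n])
  # local refinement: a candidate may sit 1-2 bp off the best lag
  ref <- lapply(seq_along(cand), function(i) {
    p0 <- cand[i]
    ps <- unique(pmax(2L, pmin(n - 1L, p0 + (-2L:2L))))
    sp <- vapply(ps, supp_of, 0)
    best <- which.max(sp)
    c(period = ps[best], support = sp[best], count = counts[i])
  })
  df <- as.data.frame(do.call(rbind, ref))
  df <- df[!duplicated(df$period), , drop = FALSE]
  df$phase <- vapply(df$period, function(p) {
    pos <- unlist(lapply(occ, function(o) o[which(diff(o) == p)]),
                  use.names = FALSE)
    if (length(pos) == 0L) 0L else as.integer((min(pos) - 1L) %% p)
  }, 1L)
  lead <- df$support >= max(df$support) - support_tol
  top <- df[lead, , drop = FALSE]
  rest <- df[!lead, , drop = FALSE]
  df <- rbind(top[order(top$period), , drop = FALSE],
              rest[order(-rest$support, rest$period), , drop = FALSE])
  df$period <- as.integer(df$period)
  df$count <- as.integer(df$count)
  rownames(df) <- NULL
  class(df) <- c("period_calls", "data.frame")
  df
}

#' Segment a periodic region into monomer copies
#'
#' Tiles `seq` with copies of a monomer consensus by repeated anchored
#' alignment: the consensus is aligned (pattern-global, subject-local) to a
#' window starting at the current position; the matched window prefix
#' becomes the next copy and the walk continues at its end.  A trailing
#' stretch shorter than the consensus is reported as a terminal partial copy
#' with its true length.  When no consensus is given, the top detected
#' period seeds a provisional tiling whose majority consensus is then used.
#'
#' @param seq Nucleotide string (the array region).
#' @param consensus Optional monomer consensus.
#' @param period Optional period (used only when `consensus` is NULL).
#' @param scoring An [align_scoring()] object.
#' @param min_partial Minimum reported terminal-partial length (bp).
#' @return List of class `segmentation`: `monomers` (data frame start, end,
#'   length, identity_pct, partial), `consensus`, `copy_number` (fractional:
#'   total copy length / consensus length).
#' @export
segment_monomers <- function(seq, consensus = NULL, period = NULL,
                             scoring = align_scoring(), min_partial = 20L) {
  seq <- .check_dna(seq)
  n <- nchar(seq)
  if (is.null(consensus)) {
    if (is.null(period)) {
      pc <- detect_period(seq)
      if (nrow(pc) == 0L)
        stop("consensus absent and no period detected", call. = FALSE)
      period <- pc$period[1L]
    }
    period <- as.integer(period)
    ntile <- n %/% period
    if (ntile < 1L) stop("sequence shorter than period", call. = FALSE)
    tiles <- substring(seq, (seq_len(ntile) - 1L) * period + 1L,
                       seq_len(ntile) * period)
    consensus <- if (ntile == 1L) tiles else build_consensus(tiles,
                                                             scoring = scoring)
  }
  consensus <- .check_dna(consensus, arg = "consensus")
  L <- nchar(consensus)
  slack <- max(20L, L %/% 5L)
  recs <- list()
  pos <- 1L
  while (n - pos + 1L >= min_partial) {
    rem <- n - pos + 1L
    if (rem < L) {
      # terminal partial copy: align it inside the consensus
      part <- substr(seq, pos, n)
      pa <- .pa(part, consensus, scoring, "global-local")
      idp <- .identity_from_aligned(
        as.character(Biostrings::alignedPattern(pa)),
        as.character(Biostrings::alignedSubject(pa)))
      recs[[length(recs) + 1L]] <-
        data.frame(start = pos, end = n, length = rem,
                   identity_pct = idp, partial = TRUE)
      break
    }
    win <- substr(seq, pos, min(n, pos + L + slack - 1L))
    pa <- .pa(consensus, win, scoring, "global-local")
    send <- Biostrings::end(Biostrings::subject(pa))
    if (send < L %/% 2L) send <- min(L, nchar(win))
    idp <- .identity_from_aligned(
      as.character(Biostrings::alignedPattern(pa)),
      as.character(Biostrings::alignedSubject(pa)))
    recs[[length(recs) + 1L]] <-
      data.frame(start = pos, end = pos + send - 1L, length = send,
                 identity_pct = idp, partial = FALSE)
    pos <- pos + send
  }
  monomers <- if (length(recs)) do.call(rbind, recs) else
    data.frame(start = integer(0), end = integer(0), length = integer(0),
               identity_pct = numeric(0), partial = logical(0))
  structure(list(monomers = monomers, consensus = consensus,
                 copy_number = sum(monomers$length) / L),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d copies (copy number %.1f), consensus %d bp\n",
              nrow(x$monomers), x$copy_number, nchar(x$consensus)))
  print(x$monomers)
  invisible(x)
}

#' Majority consensus of monomer copies
#'
#' Copies are aligned pairwise (affine-gap global) against an anchor copy --
#' the lexicographically smallest among the longest copies, which makes the
#' result invariant to copy order.  Each anchor column takes the majority
#' character over all copies (insertions relative to the anchor are
#' ignored); ties are broken toward the earlier base in A < C < G < T, and a
#' gap wins a column only by strict majority (majority-gap columns are
#' dropped from the consensus).
#'
#' @param copies Character vector (or list) of copy sequences, length >= 1.
#' @param scoring An [align_scoring()] object.
#' @return Consensus string.
#' @export
build_consensus <- function(copies, scoring = align_scoring()) {
  copies <- vapply(as.list(copies), .check_dna, "", arg = "copies")
  if (length(copies) == 0L) stop("no copies given", call. = FALSE)
  if (length(copies) == 1L) return(copies[[1L]])
  lens <- nchar(copies)
  longest <- copies[lens == max(lens)]
  anchor <- sort(longest)[1L]
  counts <- matrix(0L, nrow = 5L, ncol = nchar(anchor),
                   dimnames = list(c(BASES, "-"), NULL))
  for (cp in copies) {
    if (identical(cp, anchor)) {
      a_ch <- .chars(anchor)
      idx <- cbind(match(a_ch, rownames(counts)), seq_along(a_ch))
      counts[idx] <- counts[idx] + 1L
      next
    }
    al <- global_align(cp, anchor, scoring)
    qc <- .chars(al$aligned_query)
    sc <- .chars(al$aligned_subject)
    apos <- cumsum(sc != "-")
    keep <- sc != "-"
    idx <- cbind(match(qc[keep], rownames(counts)), apos[keep])
    counts[idx] <- counts[idx] + 1L
  }
  # identical anchor copies may occur several times; each was counted once
  cons <- apply(counts, 2L, function(col) {
    base_best <- which.max(col[BASES])  # earliest base wins ties
    if (col["-"] > col[BASES][base_best]) "-" else BASES[base_best]
  })
  paste(cons[cons != "-"], collapse = "")
}

#' Chain HSPs into tandem arrays
#'
#' Same-strand HSPs on the same subject are chained into one array when
#' consecutive hits are separated by at most `max_gap` (default twice the
#' monomer length, tolerating non-repeat insertions without fusing distinct
#' loci).  Fractional copy number is total aligned copy length divided by
#' the monomer length; `insertion_proportion` is the fraction of the array
#' span not covered by HSPs.  Arrays with copy number below 2.5 are flagged
#' `short`.
#'
#' @param hsps HSP data frame from [local_search()].
#' @param monomer_len Monomer (consensus) length in bp.
#' @param max_gap Maximum gap between chained HSPs (bp).
#' @return Data frame of class `tandem_arrays`: chrom, start, end, strand,
#'   n_copies, copy_number, insertion_proportion, mean_identity, short;
#'   attribute `copies` holds the per-array HSP tables.
#' @export
delineate_arrays <- function(hsps, monomer_len,
                             max_gap = 2L * monomer_len) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_copies = integer(0), copy_number = numeric(0),
                      insertion_proportion = numeric(0),
                      mean_identity = numeric(0), short = logical(0))
  class(empty) <- c("tandem_arrays", "data.frame")
  if (is.null(hsps) || nrow(hsps) == 0L) return(empty)
  out <- list()
  copies <- list()
  for (key in unique(paste(hsps$sseqid, hsps$strand))) {
    sub <- hsps[paste(hsps$sseqid, hsps$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$sstart), , drop = FALSE]
    gap_prev <- c(Inf, sub$sstart[-1L] - sub$send[-nrow(sub)] - 1L)
    grp <- cumsum(gap_prev > max_gap)
    for (g in unique(grp)) {
      blk <- sub[grp == g, , drop = FALSE]
      span <- max(blk$send) - min(blk$sstart) + 1L
      covered <- sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(blk$sstart, blk$send))))
      cn <- sum(blk$send - blk$sstart + 1L) / monomer_len
      out[[length(out) + 1L]] <- data.frame(
        chrom = blk$sseqid[1L], start = min(blk$sstart),
        end = max(blk$send), strand = blk$strand[1L],
        n_copies = nrow(blk), copy_number = cn,
        insertion_proportion = 1 - covered / span,
        mean_identity = mean(blk$pident),
        short = cn < 2.5, stringsAsFactors = FALSE)
      copies[[length(copies) + 1L]] <- blk
    }
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  copies <- copies[order(vapply(copies, function(b) b$sstart[1L], 1L))]
  rownames(df) <- NULL
  attr(df, "copies") <- copies
  class(df) <- c("tandem_arrays", "data.frame")
  df
}

#' Export tandem arrays as GFF3 and BED
#'
#' GFF3 features of type `tandem_array` carry `copy_number` (1 decimal),
#' `insertion_proportion` and `short` attributes; BED starts are 0-based.
#'
#' @param arrays A `tandem_arrays` data frame from [delineate_arrays()].
#' @param gff3,bed Output paths (either may be NULL to skip).
#' @export
write_arrays <- function(arrays, gff3 = NULL, bed = NULL) {
  if (!is.null(gff3)) {
    gr <- GenomicRanges::GRanges(arrays$chrom,
                                 IRanges::IRanges(arrays$start, arrays$end),
                                 strand = arrays$strand)
    gr$type <- "tandem_array"
    gr$copy_number <- sprintf("%.1f", arrays$copy_number)
    gr$insertion_proportion <- sprintf("%.3f", arrays$insertion_proportion)
    gr$short <- arrays$short
    rtracklayer::export(gr, gff3, format = "gff3")
  }
  if (!is.null(bed)) {
    bed_df <- data.frame(arrays$chrom, arrays$start - 1L, arrays$end,
                         sprintf("array%03d", seq_len(nrow(arrays))),
                         0L, arrays$strand)
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}
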