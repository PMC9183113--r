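#' Alignment scoring scheme
#'
#' Default scoring is blastn-like: match +1, mismatch -2, affine gaps with
#' open 5 and extend 2 (penalties are positive numbers subtracted from the
#' score).  All alignment-based operations in the package accept a scoring
#' object so identity bands can be reproduced under other schemes.
#'
#' @param match Match reward.
#' @param mismatch Mismatch score (negative).
#' @param gap_open Gap opening penalty (positive).
#' @param gap_extend Gap extension penalty (positive).
#' @return An object of class `align_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = -2, gap_open = 5,
                          gap_extend = 2) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "align_scoring")
}

.submat <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = TRUE)
}

.pa <- function(pattern, subject, scoring, type) {
  Biostrings::pairwiseAlignment(Biostrings::DNAString(pattern),
                                Biostrings::DNAString(subject),
                                substitutionMatrix = .submat(scoring),
                                gapOpening = scoring$gap_open,
                                gapExtension = scoring$gap_extend,
                                type = type)
}

# Percent identity from two gapped aligned strings.  End-gap columns
# (leading/trailing columns where either side is a gap) are trimmed; internal
# gap columns count in the denominator.
.identity_from_aligned <- function(aq, as) {
  q <- .chars(aq)
  s <- .chars(as)
  stopifnot(length(q) == length(s))
  core <- which(q != "-" & s != "-")
  if (length(core) == 0L) return(0)
  idx <- seq(min(core), max(core))
  q <- q[idx]
  s <- s[idx]
  100 * sum(q == s & q != "-") / length(q)
}

#' Global pairwise alignment
#'
#' Optimal affine-gap global (Needleman-Wunsch) alignment of two nucleotide
#' sequences.  Identity is computed over alignment columns with terminal gap
#' runs trimmed; internal gap columns count in the denominator.
#'
#' @param a,b Nucleotide strings (ACGT).
#' @param scoring An [align_scoring()] object.
#' @return An object of class `alignment`: list with `aligned_query`,
#'   `aligned_subject`, `score`, `identity_pct`.
#' @export
#' @examples
#' global_align("ACGT", "ACGA")$identity_pct
global_align <- function(a, b, scoring = align_scoring()) {
  a <- .check_dna(a, arg = "a")
  b <- .check_dna(b, arg = "b")
  pa <- .pa(a, b, scoring, "global")
  aq <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  structure(list(aligned_query = aq,
                 aligned_subject = as_,
                 score = Biostrings::score(pa),
                 identity_pct = .identity_from_aligned(aq, as_)),
            class = "alignment")
}

#' Percent identity of an alignment
#'
#' 100 x matches / alignment columns, where internal gap columns count as
#' columns and terminal gap runs are trimmed.
#'
#' @param alignment An `alignment` object from [global_align()].
#' @return Percent identity in `[0, 100]`.
#' @export
identity_pct <- function(alignment) {
  stopifnot(inherits(alignment, "alignment"))
  .identity_from_aligned(alignment$aligned_query, alignment$aligned_subject)
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> score %.1f, identity %.1f%%\n",
              x$score, x$identity_pct))
  invisible(x)
}

#' Homology search parameters
#'
#' Thresholds for [local_search()].  Two named stringency presets are
#' provided: `"relaxed"` (85% identity, 95% query coverage) and `"strict"`
#' (90% identity, 95% query coverage).
#'
#' @param word_size Exact word size used for seeding (>= 4).
#' @param min_identity_pct Minimum HSP percent identity.
#' @param min_qcov_pct Minimum query coverage percent.
#' @param min_score Minimum raw alignment score.
#' @return An object of class `search_params`.
#' @export
search_params <- function(word_size = 10, min_identity_pct = 85,
                          min_qcov_pct = 95, min_score = 20) {
  stopifnot(word_size >= 4,
            min_identity_pct >= 0, min_identity_pct <= 100,
            min_qcov_pct >= 0, min_qcov_pct <= 100)
  structure(list(word_size = as.integer(word_size),
                 min_identity_pct = min_identity_pct,
                 min_qcov_pct = min_qcov_pct,
                 min_score = min_score),
            class = "search_params")
}

#' @rdname search_params
#' @param name Preset name, `"relaxed"` or `"strict"`.
#' @export
stringency_preset <- function(name = c("relaxed", "strict")) {
  name <- match.arg(name)
  switch(name,
         relaxed = search_params(word_size = 10, min_identity_pct = 85,
                                 min_qcov_pct = 95),
         strict  = search_params(word_size = 10, min_identity_pct = 90,
                                 min_qcov_pct = 95))
}

.empty_hsps <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0),
             qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0),
             strand = character(0), score = numeric(0),
             qcov = numeric(0), stringsAsFactors = FALSE)
}

# Seed-and-extend search of one query orientation against a subject string.
# Seeds are exact word matches grouped into diagonal bands; each band is
# extended by one banded local alignment of the full query against a subject
# window inferred from the band's diagonal range.
.search_strand <- function(q, subject, k, scoring, min_seed_cov) {
  nq <- nchar(q)
  ns <- nchar(subject)
  if (ns < k) return(NULL)
  sk <- .kmers(subject, k)
  qk <- .kmers(q, k)
  hit <- which(sk %in% qk)
  if (length(hit) == 0L) return(NULL)
  qmap <- split(seq_along(qk), qk)
  ql <- qmap[sk[hit]]
  lens <- lengths(ql)
  spos <- rep.int(hit, lens)
  qpos <- unlist(ql, use.names = FALSE)
  diag <- spos - qpos
  ord <- order(diag, spos)
  spos <- spos[ord]; qpos <- qpos[ord]; diag <- diag[ord]
  band <- max(16L, nq %/% 10L)
  grp <- cumsum(c(1L, as.integer(diff(diag) > band)))
  out <- vector("list", max(grp))
  for (g in seq_len(max(grp))) {
    sel <- grp == g
    qp <- qpos[sel]
    # seed coverage of the query: union of word footprints
    cov <- sum(pmin(diff(c(sort(unique(qp)), Inf)), k)[seq_along(unique(qp))])
    if (cov < min_seed_cov) next
    dsel <- diag[sel]
    slack <- 50L
    w_start <- max(1L, min(dsel) + 1L - slack)
    w_end <- min(ns, max(dsel) + nq + slack)
    win <- substr(subject, w_start, w_end)
    pa <- .pa(q, win, scoring, "local")
    aq <- as.character(Biostrings::alignedPattern(pa))
    as_ <- as.character(Biostrings::alignedSubject(pa))
    sr <- Biostrings::subject(pa)
    pr <- Biostrings::pattern(pa)
    qs <- Biostrings::start(pr); qe <- Biostrings::end(pr)
    out[[g]] <- data.frame(
      qstart = qs, qend = qe,
      sstart = w_start + Biostrings::start(sr) - 1L,
      send = w_start + Biostrings::end(sr) - 1L,
      pident = .identity_from_aligned(aq, as_),
      length = nchar(aq),
      score = Biostrings::score(pa),
      qcov = 100 * (qe - qs + 1L) / nq,
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

# Drop HSPs mostly contained in a better-scoring HSP on the same strand.
.dedup_hsps <- function(df) {
  if (nrow(df) < 2L) return(df)
  df <- df[order(-df$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))[-1L]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      if (df$strand[i] != df$strand[j]) next
      ov <- min(df$send[i], df$send[j]) - max(df$sstart[i], df$sstart[j]) + 1L
      if (ov <= 0L) next
      shorter <- min(df$send[i] - df$sstart[i], df$send[j] - df$sstart[j]) + 1L
      if (ov > 0.5 * shorter) { keep[i] <- FALSE; break }
    }
  }
  df[keep, , drop = FALSE]
}

#' Seed-and-extend homology search
#'
#' Finds high-scoring pairs (HSPs) of a query repeat against a subject
#' sequence on both strands: exact words of length `word_size` seed diagonal
#' bands, each band is extended by local alignment, and resulting HSPs are
#' filtered by identity, query coverage and score, deduplicated, and sorted
#' by subject position.  For minus-strand HSPs the subject coordinates refer
#' to the forward strand; the match is to the reverse complement of the
#' query.
#'
#' @param query Query nucleotide string (typically a monomer consensus).
#' @param subject Subject nucleotide string (chromosome, contig, read).
#' @param params A [search_params()] object or preset from
#'   [stringency_preset()].
#' @param scoring An [align_scoring()] object.
#' @param query_name,subject_name Labels used in the output table.
#' @return A data frame of HSPs with columns `qseqid, sseqid, pident,
#'   length, qstart, qend, sstart, send, strand, score, qcov` (1-based
#'   inclusive coordinates).
#' @export
local_search <- function(query, subject, params = search_params(),
                         scoring = align_scoring(),
                         query_name = "query", subject_name = "subject") {
  query <- .check_dna(query, arg = "query")
  subject <- .check_dna(subject, allow_n = TRUE, arg = "subject")
  k <- params$word_size
  if (nchar(query) < k) stop("query shorter than word_size", call. = FALSE)
  min_seed_cov <- max(2L * k, as.integer(0.10 * nchar(query)))
  plus <- .search_strand(query, subject, k, scoring, min_seed_cov)
  if (!is.null(plus) && nrow(plus)) plus$strand <- "+"
  minus <- .search_strand(revcomp(query), subject, k, scoring, min_seed_cov)
  if (!is.null(minus) && nrow(minus)) {
    nq <- nchar(query)
    qs <- nq - minus$qend + 1L
    qe <- nq - minus$qstart + 1L
    minus$qstart <- qs
    minus$qend <- qe
    minus$strand <- "-"
  }
  df <- rbind(plus, minus)
  if (is.null(df) || nrow(df) == 0L) return(.empty_hsps())
  df <- df[df$pident >= params$min_identity_pct &
             df$qcov >= params$min_qcov_pct &
             df$score >= params$min_score, , drop = FALSE]
  if (nrow(df) == 0L) return(.empty_hsps())
  df <- .dedup_hsps(df)
  df$qseqid <- query_name
  df$sseqid <- subject_name
  df <- df[order(df$sstart, df$send), ]
  rownames(df) <- NULL
  df[, names(.empty_hsps())]
}

#' Search a set of queries against a set of chromosomes
#'
#' Convenience wrapper running [local_search()] for every (query, subject)
#' pair and binding the HSP tables.
#'
#' @param queries,subjects Named character vectors of sequences.
#' @inheritParams local_search
#' @return A combined HSP data frame.
#' @export
search_genome <- function(queries, subjects, params = search_params(),
                          scoring = align_scoring()) {
  stopifnot(!is.null(names(queries)), !is.null(names(subjects)))
  out <- list()
  for (qn in names(queries))
    for (sn in names(subjects))
      out[[paste(qn, sn)]] <- local_search(queries[[qn]], subjects[[sn]],
                                           params = params, scoring = scoring,
                                           query_name = qn, subject_name = sn)
  res <- do.call(rbind, out)
  if (is.null(res)) return(.empty_hsps())
  rownames(res) <- NULL
  res
}

#' Write HSPs as a BLAST outfmt-6 style table
#'
#' Tab-separated, no header, columns: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send score qcov.  `mismatch` and `gapopen` are
#' derived approximations (mismatches estimated from identity and length);
#' `score` is the raw alignment score, not a bit score.
#'
#' @param hsps HSP data frame from [local_search()].
#' @param path Output file path.
#' @export
write_hsps <- function(hsps, path) {
  mism <- round((100 - hsps$pident) / 100 * hsps$length)
  out <- data.frame(hsps$qseqid, hsps$sseqid, sprintf("%.2f", hsps$pident),
                    hsps$length, mism, 0L,
                    hsps$qstart, hsps$qend,
                    ifelse(hsps$strand == "-", hsps$send, hsps$sstart),
                    ifelse(hsps$strand == "-", hsps$sstart, hsps$send),
                    hsps$score, sprintf("%.1f", hsps$qcov))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
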