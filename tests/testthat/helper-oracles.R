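# Independent oracles used to cross-check the package's own algorithms.
# These deliberately take the dumb exhaustive route.

# Base-match autocorrelation over all lags; returns the smallest lag whose
# support is within `eps` of the maximum (the fundamental period).
oracle_period <- function(seq, max_lag = 500L, eps = 0.02) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  lags <- 2:min(max_lag, n - 1L)
  supp <- vapply(lags, function(p) mean(ch[1:(n - p)] == ch[(p + 1):n]), 0)
  best <- max(supp)
  list(period = lags[supp >= best - eps][1L], support = best,
       all = data.frame(lag = lags, support = supp))
}

# Brute-force sliding-window Smith-Waterman HSP search (both strands).
oracle_hsps <- function(query, subject, min_identity = 85, min_qcov = 95,
                        scoring = align_scoring()) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  nq <- nchar(query)
  ns <- nchar(subject)
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    starts <- unique(c(seq(1L, max(1L, ns - nq), by = max(1L, nq %/% 2L)),
                       max(1L, ns - 2L * nq + 1L)))
    for (ws in starts) {
      win <- substr(subject, ws, min(ns, ws + 2L * nq - 1L))
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(q), Biostrings::DNAString(win),
        substitutionMatrix = submat, gapOpening = scoring$gap_open,
        gapExtension = scoring$gap_extend, type = "local")
      aq <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
      as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
      idp <- 100 * sum(aq == as_ & aq != "-") / length(aq)
      qlen_aln <- Biostrings::end(Biostrings::pattern(pa)) -
        Biostrings::start(Biostrings::pattern(pa)) + 1L
      if (idp < min_identity || 100 * qlen_aln / nq < min_qcov) next
      hits[[length(hits) + 1L]] <- data.frame(
        sstart = ws + Biostrings::start(Biostrings::subject(pa)) - 1L,
        send = ws + Biostrings::end(Biostrings::subject(pa)) - 1L,
        strand = strand, score = Biostrings::score(pa))
    }
  }
  if (length(hits) == 0L)
    return(data.frame(sstart = integer(0), send = integer(0),
                      strand = character(0), score = numeric(0)))
  df <- unique(do.call(rbind, hits))
  df <- df[order(-df$score), ]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))[-1L]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      if (df$strand[i] != df$strand[j]) next
      ov <- min(df$send[i], df$send[j]) - max(df$sstart[i], df$sstart[j]) + 1L
      shorter <- min(df$send[i] - df$sstart[i],
                     df$send[j] - df$sstart[j]) + 1L
      if (ov > 0.5 * shorter) { keep[i] <- FALSE; break }
    }
  }
  df <- df[keep, ]
  df[order(df$sstart), ]
}

# Per-column majority vote over equal-length, gap-free copies.
oracle_consensus <- function(copies) {
  stopifnot(length(unique(nchar(copies))) == 1L)
  mat <- do.call(rbind, strsplit(copies, ""))
  paste(apply(mat, 2L, function(col) {
    tab <- table(factor(col, levels = c("A", "C", "G", "T")))
    names(tab)[which.max(tab)]  # ties -> earlier base, as in the package
  }), collapse = "")
}

# Interval-set comparison with a positional tolerance at both ends.
intervals_match <- function(found, truth, tol = 2L) {
  if (nrow(found) != nrow(truth)) return(FALSE)
  f <- found[order(found$sstart), ]
  t <- truth[order(truth$sstart), ]
  all(abs(f$sstart - t$sstart) <= tol) && all(abs(f$send - t$send) <= tol)
}

# A small simulated chr8-like contig: one independent array plus an rDNA
# cluster whose spacers each embed two reverse-oriented derived monomers.
chr8_like_sim <- function(seed = 1L, n_units = 4L, copies = 8L) {
  cs <- family_spec("CS", c(111L, 126L))
  delcs <- family_spec("delCS", c(98L, 111L), orientation = "reverse")
  unit_len <- 1800L + 250L + 160L + 250L + 3400L + 3595L
  sim_spec(seed = seed, chroms = list(list(
    name = "chr8", length = 6000L + copies * 240L + n_units * unit_len +
      4000L,
    features = list(
      list(kind = "array", start = 1000L, monomer = cs, copies = copies,
           sub_rate = 0.03),
      list(kind = "rdna_cluster", start = 5000L + copies * 240L,
           n_units = n_units, igs_template = random_dna(3595L, seed = 77L),
           embedded = delcs, n_copies = 2L, sub_rate = 0.02)))))
}
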