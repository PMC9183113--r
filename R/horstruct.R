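#' Decompose a monomer into internally homologous subunits
#'
#' Dimeric satellite monomers (higher-order repeats) consist of two diverged
#' subunits.  The boundary is found by exhaustive search over split points:
#' for every candidate split the two halves are globally aligned and the
#' split maximizing the alignment score wins (coarse step of 3 bp refined by
#' +-2 bp; ties break toward the smaller first subunit).  When the best
#' split's inter-half identity falls below `identity_floor` the monomer is
#' reported as a single subunit: under the default scoring, random dimers
#' top out near 47-48% identity while genuinely homologous subunit pairs in
#' diverged satellite families still reach 50% and above, so the default
#' floor of 48 sits in the gap.
#'
#' @param monomer Monomer string, >= 40 bp.
#' @param scoring An [align_scoring()] object.
#' @param min_subunit Smallest admissible subunit length (bp).
#' @param identity_floor Percent identity below which no internal repeat is
#'   called.
#' @return List of class `subunit_decomposition`: `subunits` (data frame
#'   start, end, length), `inter_subunit_identity_pct` (NA for single
#'   subunit), `score`, `alignment` (the inter-half `alignment`, or NULL).
#' @export
decompose_subunits <- function(monomer, scoring = align_scoring(),
                               min_subunit = 20L, identity_floor = 48) {
  monomer <- .check_dna(monomer, arg = "monomer")
  L <- nchar(monomer)
  if (L < 40L) stop("monomer shorter than 40 bp", call. = FALSE)
  min_subunit <- max(as.integer(min_subunit), 20L)
  eval_split <- function(s) {
    al <- global_align(substr(monomer, 1L, s), substr(monomer, s + 1L, L),
                       scoring)
    list(s = s, score = al$score, alignment = al)
  }
  cand <- seq(min_subunit, L - min_subunit, by = 3L)
  coarse <- lapply(cand, eval_split)
  sc <- vapply(coarse, function(x) x$score, 0)
  s0 <- cand[which.max(sc)]
  fine_cand <- setdiff(pmax(min_subunit,
                            pmin(L - min_subunit, s0 + (-2L:2L))), cand)
  fine <- lapply(fine_cand, eval_split)
  all_splits <- c(coarse, fine)
  scores <- vapply(all_splits, function(x) x$score, 0)
  ord <- order(-scores, vapply(all_splits, function(x) x$s, 1L))
  best <- all_splits[[ord[1L]]]
  if (best$alignment$identity_pct < identity_floor) {
    return(structure(list(
      subunits = data.frame(start = 1L, end = L, length = L),
      inter_subunit_identity_pct = NA_real_,
      score = NA_real_, alignment = NULL),
      class = "subunit_decomposition"))
  }
  structure(list(
    subunits = data.frame(start = c(1L, best$s + 1L),
                          end = c(best$s, L),
                          length = c(best$s, L - best$s)),
    inter_subunit_identity_pct = best$alignment$identity_pct,
    score = best$score,
    alignment = best$alignment),
    class = "subunit_decomposition")
}

#' @export
print.subunit_decomposition <- function(x, ...) {
  if (nrow(x$subunits) == 1L) {
    cat(sprintf("<subunit_decomposition> single subunit, %d bp\n",
                x$subunits$length))
  } else {
    cat(sprintf(
      "<subunit_decomposition> subunits %s bp, inter-subunit identity %.1f%%\n",
      paste(x$subunits$length, collapse = " + "),
      x$inter_subunit_identity_pct))
  }
  invisible(x)
}

# Indel calls from two gapped aligned strings (query, reference).  Only gap
# runs inside the end-trimmed core and >= min_indel long are reported.
.call_indels <- function(aq, ar, min_indel) {
  q <- .chars(aq)
  r <- .chars(ar)
  core <- which(q != "-" & r != "-")
  if (length(core) == 0L)
    return(data.frame(position = integer(0), length = integer(0),
                      sequence = character(0), direction = character(0)))
  lo <- min(core); hi <- max(core)
  rpos <- cumsum(r != "-")  # reference coordinate per column
  calls <- list()
  scan_runs <- function(is_gap, direction) {
    rl <- rle(is_gap[lo:hi])
    ends <- lo - 1L + cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (i in which(rl$values & rl$lengths >= min_indel)) {
      cols <- starts[i]:ends[i]
      if (direction == "deletion-in-query") {
        seq_side <- paste(r[cols], collapse = "")
        pos <- rpos[starts[i]]  # first deleted reference base
      } else {
        seq_side <- paste(q[cols], collapse = "")
        pos <- rpos[starts[i] - 1L]  # reference base preceding insertion
        if (starts[i] == 1L) pos <- 0L
      }
      calls[[length(calls) + 1L]] <<- data.frame(
        position = as.integer(pos), length = length(cols),
        sequence = seq_side, direction = direction,
        stringsAsFactors = FALSE)
    }
  }
  scan_runs(q == "-", "deletion-in-query")
  scan_runs(r == "-", "insertion-in-query")
  if (length(calls) == 0L)
    return(data.frame(position = integer(0), length = integer(0),
                      sequence = character(0), direction = character(0)))
  out <- do.call(rbind, calls)
  out[order(out$position), , drop = FALSE]
}

#' Compare a query subunit against a reference subunit
#'
#' Global alignment of the two sequences; maximal runs of gap columns inside
#' the end-trimmed alignment core that reach `min_indel` bp are reported as
#' indel calls, with the indel sequence taken from the ungapped side and the
#' position given in reference coordinates (first deleted reference base for
#' a deletion-in-query; the reference base preceding the inserted block for
#' an insertion-in-query).  Shorter gaps fold into the identity figure.
#'
#' @param query_subunit,reference_subunit Nucleotide strings.
#' @param scoring An [align_scoring()] object.
#' @param min_indel Minimum reported indel length in bp (default 5).
#' @return List of class `subunit_comparison`: `identity_pct`, `indels`
#'   (data frame position, length, sequence, direction), `alignment`.
#' @export
compare_subunit_families <- function(query_subunit, reference_subunit,
                                     scoring = align_scoring(),
                                     min_indel = 5L) {
  al <- global_align(query_subunit, reference_subunit, scoring)
  indels <- .call_indels(al$aligned_query, al$aligned_subject, min_indel)
  rownames(indels) <- NULL
  structure(list(identity_pct = al$identity_pct, indels = indels,
                 alignment = al),
            class = "subunit_comparison")
}

#' @export
print.subunit_comparison <- function(x, ...) {
  cat(sprintf("<subunit_comparison> identity %.1f%%, %d indel call(s)\n",
              x$identity_pct, nrow(x$indels)))
  if (nrow(x$indels)) print(x$indels)
  invisible(x)
}

#' Classify a monomer against reference family consensuses
#'
#' The monomer is globally aligned to every reference on both strands; the
#' best-scoring (reference, strand) pair gives the family label and the
#' orientation relative to the reference.  Monomers whose best identity
#' falls below `identity_floor` (default 70%) are labeled `"unassigned"`.
#'
#' @param monomer Monomer string.
#' @param references Named character vector of family consensuses.
#' @param scoring An [align_scoring()] object.
#' @param identity_floor Minimum identity percent for an assignment.
#' @return List of class `family_call`: `family`, `orientation` (`"same"` or
#'   `"reverse"`), `identity_pct`, `score`.
#' @export
classify_family <- function(monomer, references, scoring = align_scoring(),
                            identity_floor = 70) {
  monomer <- .check_dna(monomer, arg = "monomer")
  if (length(references) == 0L || is.null(names(references)))
    stop("'references' must be a non-empty named vector", call. = FALSE)
  best <- NULL
  for (fam in names(references)) {
    for (ori in c("same", "reverse")) {
      m <- if (ori == "same") monomer else revcomp(monomer)
      al <- global_align(m, references[[fam]], scoring)
      if (is.null(best) || al$score > best$score)
        best <- list(family = fam, orientation = ori,
                     identity_pct = al$identity_pct, score = al$score)
    }
  }
  if (best$identity_pct < identity_floor) best$family <- "unassigned"
  structure(best, class = "family_call")
}

#' @export
print.family_call <- function(x, ...) {
  cat(sprintf("<family_call> %s (%s strand), identity %.1f%%\n",
              x$family, x$orientation, x$identity_pct))
  invisible(x)
}
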