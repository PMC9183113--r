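#' Monomer family specification
#'
#' Describes a satellite monomer family for the simulator: a dimeric
#' (higher-order repeat) monomer assembled from two internally homologous
#' subunits, optionally carrying a planted deletion that distinguishes a
#' derived family, and a default orientation.
#'
#' @param name Family label.
#' @param subunit_lengths Integer vector of subunit lengths in bp (the
#'   monomer length is their sum), e.g. `c(111, 126)`.
#' @param planted_indel Optional `list(position =, length =)`: a deletion of
#'   `length` bp starting at `position` (1-based, within the assembled
#'   monomer) applied after assembly, producing a shortened derived monomer.
#' @param orientation `"forward"` or `"reverse"`; reverse families are
#'   embedded as reverse complements.
#' @param subunit_identity Target identity between the two subunits
#'   (fraction), default 0.70.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(name, subunit_lengths, planted_indel = NULL,
                        orientation = c("forward", "reverse"),
                        subunit_identity = 0.70) {
  orientation <- match.arg(orientation)
  subunit_lengths <- as.integer(subunit_lengths)
  stopifnot(length(subunit_lengths) >= 1, all(subunit_lengths >= 20))
  if (!is.null(planted_indel)) {
    stopifnot(is.list(planted_indel),
              planted_indel$position >= 1,
              planted_indel$length >= 1,
              planted_indel$position + planted_indel$length - 1 <=
                sum(subunit_lengths))
  }
  structure(list(name = name, subunit_lengths = subunit_lengths,
                 planted_indel = planted_indel, orientation = orientation,
                 subunit_identity = subunit_identity),
            class = "family_spec")
}

#' Simulate a monomer from a family specification
#'
#' The first subunit is random; each further subunit is derived from the
#' first by forced-change substitution down to the target subunit identity,
#' with the length difference realized as one internal insertion (longer
#' subunit) or deletion (shorter subunit) at the subunit midpoint, so both
#' subunit ends stay homologous.  A `planted_indel` in the spec is then
#' applied to the assembled monomer.
#'
#' @param spec A [family_spec()].
#' @param seed Optional integer seed.
#' @return List with `seq` (the monomer), `subunits` (data frame start, end,
#'   length in monomer coordinates, pre-indel), `removed` (the deleted
#'   segment when a `planted_indel` was applied, else `NULL`), and `spec`.
#' @export
sim_monomer <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "family_spec"))
  .with_seed(seed, {
    lens <- spec$subunit_lengths
    l1 <- lens[1L]
    s1 <- random_dna(l1)
    subs <- list(s1)
    for (li in lens[-1L]) {
      base <- mutate(s1, 1 - spec$subunit_identity)
      d <- li - l1
      mid <- nchar(base) %/% 2L
      if (d > 0) {
        base <- paste0(substr(base, 1L, mid), random_dna(d),
                       substr(base, mid + 1L, nchar(base)))
      } else if (d < 0) {
        base <- paste0(substr(base, 1L, mid), substr(base, mid + 1L - d,
                                                     nchar(base)))
      }
      subs <- c(subs, base)
    }
    monomer <- paste(unlist(subs), collapse = "")
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    removed <- NULL
    if (!is.null(spec$planted_indel)) {
      p <- spec$planted_indel$position
      l <- spec$planted_indel$length
      removed <- substr(monomer, p, p + l - 1L)
      monomer <- paste0(substr(monomer, 1L, p - 1L),
                        substr(monomer, p + l, nchar(monomer)))
    }
    list(seq = monomer,
         subunits = data.frame(start = starts, end = ends, length = lens),
         removed = removed, spec = spec)
  })
}

#' Mutate a sequence by forced-change substitution
#'
#' Each site is substituted independently with probability `sub_rate`; a
#' substituted site is always changed to one of the three other bases, so
#' the expected identity of the mutant to the input is `1 - sub_rate`.  No
#' indels are introduced.
#'
#' @param seq Nucleotide string (ACGT).
#' @param sub_rate Per-site substitution probability in `[0, 1]`.
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @return Mutated sequence of the same length.
#' @export
#' @examples
#' mutate("ACGTACGT", 0, seed = 1)
mutate <- function(seq, sub_rate, seed = NULL) {
  seq <- .check_dna(seq)
  stopifnot(is.numeric(sub_rate), sub_rate >= 0, sub_rate <= 1)
  if (sub_rate == 0) return(seq)
  .with_seed(seed, {
    ch <- .chars(seq)
    hit <- stats::runif(length(ch)) < sub_rate
    if (any(hit))
      ch[hit] <- vapply(ch[hit],
                        function(b) sample(BASES[BASES != b], 1L), "",
                        USE.NAMES = FALSE)
    paste(ch, collapse = "")
  })
}

#' Build a tandem array of mutated monomer copies
#'
#' Concatenates `copies` independently mutated copies of `monomer`, with
#' optional non-repeat insertions after stated copies.  Per-copy coordinates
#' (1-based inclusive within the array) are exact by construction.
#'
#' @param monomer Monomer string.
#' @param copies Number of copies (>= 1).
#' @param sub_rate Per-site substitution rate applied to each copy.
#' @param insertions Optional list of `list(after_copy =, seq =)`;
#'   `after_copy = 0` inserts before the first copy.
#' @param seed Optional integer seed.
#' @return List with `seq`, `copies` (data frame copy, start, end),
#'   `insertions` (data frame after_copy, start, end or NULL).
#' @export
make_array <- function(monomer, copies, sub_rate = 0, insertions = NULL,
                       seed = NULL) {
  monomer <- .check_dna(monomer, arg = "monomer")
  copies <- as.integer(copies)
  stopifnot(copies >= 1L)
  if (!is.null(insertions)) {
    idx <- vapply(insertions, function(x) as.integer(x$after_copy), 1L)
    if (any(idx < 0L | idx > copies))
      stop("insertion index beyond copy count", call. = FALSE)
  }
  .with_seed(seed, {
    pieces <- character(0)
    cp_start <- integer(copies); cp_end <- integer(copies)
    ins_rec <- list()
    pos <- 1L
    add_ins <- function(i, pos) {
      for (x in insertions) {
        if (as.integer(x$after_copy) == i) {
          s <- .check_dna(x$seq, arg = "insertion seq")
          pieces <<- c(pieces, s)
          ins_rec[[length(ins_rec) + 1L]] <<-
            data.frame(after_copy = i, start = pos,
                       end = pos + nchar(s) - 1L)
          pos <- pos + nchar(s)
        }
      }
      pos
    }
    pos <- add_ins(0L, pos)
    for (i in seq_len(copies)) {
      cp <- mutate(monomer, sub_rate)
      pieces <- c(pieces, cp)
      cp_start[i] <- pos
      cp_end[i] <- pos + nchar(cp) - 1L
      pos <- cp_end[i] + 1L
      pos <- add_ins(i, pos)
    }
    list(seq = paste(pieces, collapse = ""),
         copies = data.frame(copy = seq_len(copies), start = cp_start,
                             end = cp_end),
         insertions = if (length(ins_rec)) do.call(rbind, ins_rec) else NULL)
  })
}

#' Bundled surrogate rRNA gene and spacer references
#'
#' Fixed random-but-reproducible surrogate sequences of realistic lengths
#' for the 45S rDNA unit parts: 18S (1.8 kb), 5.8S (160 bp), 26S (3.4 kb),
#' ITS1/ITS2 (250 bp each).  Real references can be supplied instead
#' wherever these are accepted.
#'
#' @return Named character vector with elements `18S`, `ITS1`, `5.8S`,
#'   `ITS2`, `26S`.
#' @export
surrogate_rdna_refs <- function() {
  .with_seed(20220524L, c(
    "18S" = random_dna(1800L),
    "ITS1" = random_dna(250L),
    "5.8S" = random_dna(160L),
    "ITS2" = random_dna(250L),
    "26S" = random_dna(3400L)))
}

#' Build one 45S rDNA unit with repeats embedded in its spacer
#'
#' Assembles the canonical unit layout 18S-ITS1-5.8S-ITS2-26S-IGS.  When an
#' embedded family is given, `n_copies` tandem copies of its monomer are
#' written into the IGS ending `igs_margin` bp before the IGS 3' end, i.e.
#' adjacent to the next unit's 18S side; a reverse-orientation family is
#' embedded as the reverse complement of the monomer.  A minus-orientation
#' unit is the reverse complement of the whole assembly with coordinates
#' remapped.
#'
#' @param genes Named character vector/list with `18S`, `5.8S`, `26S`
#'   (defaults to [surrogate_rdna_refs()]).
#' @param igs_template IGS backbone sequence; embedded copies replace a
#'   stretch of it, so unit length does not depend on `n_copies`.
#' @param embedded Optional [family_spec()] or a plain monomer string.
#' @param n_copies Number of embedded copies (>= 0).
#' @param unit_orientation `"+"` or `"-"`.
#' @param its Named vector/list with `ITS1`, `ITS2`; defaults to surrogates.
#' @param igs_margin Distance in bp from the embedded block's end to the IGS
#'   3' end (the next unit's 18S side).
#' @param sub_rate Substitution rate applied to each embedded copy.
#' @param seed Optional integer seed.
#' @return List with `seq` and 1-based annotation data frames in unit
#'   coordinates: `genes` (gene, start, end, strand), `igs` (start, end),
#'   `igs_copies` (family, start, end, orientation) or NULL.
#' @export
make_rdna_unit <- function(genes = NULL, igs_template, embedded = NULL,
                           n_copies = 2L, unit_orientation = c("+", "-"),
                           its = NULL, igs_margin = 100L, sub_rate = 0,
                           seed = NULL) {
  unit_orientation <- match.arg(unit_orientation)
  refs <- surrogate_rdna_refs()
  if (is.null(genes)) genes <- refs[c("18S", "5.8S", "26S")]
  if (is.null(its)) its <- refs[c("ITS1", "ITS2")]
  genes <- lapply(as.list(genes), .check_dna)
  its <- lapply(as.list(its), .check_dna)
  igs_template <- .check_dna(igs_template, arg = "igs_template")
  n_copies <- as.integer(n_copies)
  stopifnot(n_copies >= 0L)

  .with_seed(seed, {
    igs_copies <- NULL
    igs <- igs_template
    if (n_copies > 0L && !is.null(embedded)) {
      if (inherits(embedded, "family_spec")) {
        fam <- embedded$name
        mono <- sim_monomer(embedded)$seq
        rev_fam <- embedded$orientation == "reverse"
      } else if (is.list(embedded) && !is.null(embedded$seq)) {
        # a pre-rendered family (one monomer shared across units)
        fam <- embedded$name
        mono <- .check_dna(embedded$seq, arg = "embedded$seq")
        rev_fam <- identical(embedded$orientation, "reverse")
      } else {
        fam <- "embedded"
        mono <- .check_dna(embedded, arg = "embedded")
        rev_fam <- FALSE
      }
      if (rev_fam) mono <- revcomp(mono)
      arr <- make_array(mono, n_copies, sub_rate = sub_rate)
      block <- arr$seq
      ti <- nchar(igs_template)
      if (nchar(block) + igs_margin > ti)
        stop("igs_template shorter than total embedded length", call. = FALSE)
      b_end <- ti - igs_margin
      b_start <- b_end - nchar(block) + 1L
      igs <- paste0(substr(igs_template, 1L, b_start - 1L), block,
                    substr(igs_template, b_end + 1L, ti))
      igs_copies <- data.frame(
        family = fam,
        start = b_start + arr$copies$start - 1L,
        end = b_start + arr$copies$end - 1L,
        orientation = if (rev_fam) "-" else "+",
        stringsAsFactors = FALSE)
    }
    parts <- c(genes[["18S"]], its[["ITS1"]], genes[["5.8S"]],
               its[["ITS2"]], genes[["26S"]], igs)
    ends <- cumsum(nchar(parts))
    starts <- ends - nchar(parts) + 1L
    gene_df <- data.frame(
      gene = c("18S", "5.8S", "26S"),
      start = starts[c(1L, 3L, 5L)], end = ends[c(1L, 3L, 5L)],
      strand = "+", stringsAsFactors = FALSE)
    igs_df <- data.frame(start = starts[6L], end = ends[6L])
    if (!is.null(igs_copies)) {
      igs_copies$start <- igs_copies$start + starts[6L] - 1L
      igs_copies$end <- igs_copies$end + starts[6L] - 1L
    }
    seq <- paste(parts, collapse = "")
    if (unit_orientation == "-") {
      n <- nchar(seq)
      flip <- function(df) {
        s <- n - df$end + 1L
        e <- n - df$start + 1L
        df$start <- s; df$end <- e
        df[order(df$start), , drop = FALSE]
      }
      seq <- revcomp(seq)
      gene_df <- flip(gene_df); gene_df$strand <- "-"
      igs_df <- flip(igs_df)
      if (!is.null(igs_copies)) {
        igs_copies <- flip(igs_copies)
        igs_copies$orientation <- ifelse(igs_copies$orientation == "+",
                                         "-", "+")
      }
      rownames(gene_df) <- rownames(igs_df) <- NULL
      if (!is.null(igs_copies)) rownames(igs_copies) <- NULL
    }
    list(seq = seq, genes = gene_df, igs = igs_df, igs_copies = igs_copies)
  })
}

#' Simulation specification
#'
#' Declares the chromosomes and planted features of a synthetic genome.
#' Each chromosome spec is `list(name =, length =, features = list(...))`
#' where a feature is either
#' `list(kind = "array", start =, monomer = <string or family_spec>,
#'       copies =, sub_rate =, insertions = NULL)` or
#' `list(kind = "rdna_cluster", start =, n_units =, igs_template =,
#'       embedded = <family_spec or string>, n_copies =, orientations =,
#'       sub_rate =)`.
#' Feature sequences overwrite the random background in place, so planted
#' coordinates are exact.
#'
#' @param seed Integer seed (default 1); fixed seed implies byte-identical
#'   output.
#' @param chroms List of chromosome specs.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(seed = 1L, chroms = list()) {
  stopifnot(length(chroms) > 0)
  for (cs in chroms) {
    stopifnot(!is.null(cs$name), !is.null(cs$length))
  }
  structure(list(seed = as.integer(seed), chroms = chroms),
            class = "sim_spec")
}

.render_array_feature <- function(f) {
  mono <- if (inherits(f$monomer, "family_spec")) {
    sim_monomer(f$monomer)$seq
  } else .check_dna(f$monomer, arg = "monomer")
  fam <- if (inherits(f$monomer, "family_spec")) f$monomer$name else
    if (!is.null(f$family)) f$family else "monomer"
  sr <- if (is.null(f$sub_rate)) 0 else f$sub_rate
  arr <- make_array(mono, f$copies, sub_rate = sr, insertions = f$insertions)
  list(seq = arr$seq, arr = arr, family = fam, monomer = mono)
}

.render_cluster_feature <- function(f) {
  n_units <- as.integer(f$n_units)
  orientations <- if (is.null(f$orientations)) rep("+", n_units) else
    f$orientations
  stopifnot(length(orientations) == n_units)
  sr <- if (is.null(f$sub_rate)) 0 else f$sub_rate
  n_copies <- if (is.null(f$n_copies)) 2L else as.integer(f$n_copies)
  # render the embedded family once so every spacer carries copies of the
  # same monomer (per-copy divergence comes from sub_rate)
  embedded <- f$embedded
  fam <- NULL
  if (inherits(embedded, "family_spec")) {
    fam <- list(name = embedded$name, seq = sim_monomer(embedded)$seq,
                orientation = embedded$orientation)
    embedded <- fam
  } else if (is.character(embedded)) {
    fam <- list(name = if (!is.null(f$family)) f$family else "embedded",
                seq = embedded, orientation = "forward")
    embedded <- fam
  }
  units <- lapply(seq_len(n_units), function(i)
    make_rdna_unit(genes = f$genes, igs_template = f$igs_template,
                   embedded = embedded, n_copies = n_copies,
                   unit_orientation = orientations[i], sub_rate = sr))
  list(units = units, orientations = orientations, family = fam)
}

#' Generate a synthetic genome with a truth manifest
#'
#' Renders every chromosome of a [sim_spec()]: a uniform-random background
#' with each planted feature's sequence written in at its stated start.
#' The truth manifest records, with exact 1-based inclusive coordinates,
#' every planted `array` (plus its per-copy `array_copy` rows and any
#' `array_insertion` rows), `rdna_unit`, `igs` (with N/P spacer
#' configuration between adjacent planted units), and `igs_copy`.
#'
#' @param spec A [sim_spec()].
#' @return List of class `sim_genome` with `seqs` (named character vector),
#'   `manifest` (data frame: kind, chrom, start, end, strand, family,
#'   copy_count, config, parent), `families` (named vector of the rendered
#'   family monomers, forward orientation -- the truth references for
#'   rescanning), and `spec`.
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  .with_seed(spec$seed, {
    seqs <- character(0)
    families <- character(0)
    rows <- list()
    add <- function(kind, chrom, start, end, strand = "*", family = NA,
                    copy_count = NA, config = NA, parent = NA) {
      rows[[length(rows) + 1L]] <<- data.frame(
        kind = kind, chrom = chrom, start = as.integer(start),
        end = as.integer(end), strand = strand, family = family,
        copy_count = copy_count, config = config, parent = parent,
        stringsAsFactors = FALSE)
    }
    for (cs in spec$chroms) {
      bg <- .chars(random_dna(cs$length))
      feats <- if (is.null(cs$features)) list() else cs$features
      placed <- list()
      fid <- 0L
      for (f in feats) {
        fid <- fid + 1L
        start <- as.integer(f$start)
        if (identical(f$kind, "array")) {
          r <- .render_array_feature(f)
          end <- start + nchar(r$seq) - 1L
          if (end > cs$length)
            stop(sprintf("feature extends beyond chromosome '%s'", cs$name),
                 call. = FALSE)
          aid <- sprintf("%s_array_%d", cs$name, fid)
          add("array", cs$name, start, end, "+", r$family,
              copy_count = nrow(r$arr$copies), parent = aid)
          for (i in seq_len(nrow(r$arr$copies)))
            add("array_copy", cs$name,
                start + r$arr$copies$start[i] - 1L,
                start + r$arr$copies$end[i] - 1L, "+", r$family,
                parent = aid)
          if (!is.null(r$arr$insertions))
            for (i in seq_len(nrow(r$arr$insertions)))
              add("array_insertion", cs$name,
                  start + r$arr$insertions$start[i] - 1L,
                  start + r$arr$insertions$end[i] - 1L, "+", parent = aid)
          bg[start:end] <- .chars(r$seq)
          families[[r$family]] <- r$monomer
          placed[[length(placed) + 1L]] <- c(start, end, "array")
        } else if (identical(f$kind, "rdna_cluster")) {
          r <- .render_cluster_feature(f)
          if (!is.null(r$family)) families[[r$family$name]] <- r$family$seq
          pos <- start
          unit_bounds <- list()
          for (ui in seq_along(r$units)) {
            u <- r$units[[ui]]
            end <- pos + nchar(u$seq) - 1L
            if (end > cs$length)
              stop(sprintf("feature extends beyond chromosome '%s'",
                           cs$name), call. = FALSE)
            uid <- sprintf("%s_unit_%d_%d", cs$name, fid, ui)
            # genic span of the unit (18S..26S), IGS reported separately
            gspan <- range(c(u$genes$start, u$genes$end))
            add("rdna_unit", cs$name, pos + gspan[1L] - 1L,
                pos + gspan[2L] - 1L, r$orientations[ui], parent = uid)
            if (!is.null(u$igs_copies))
              for (i in seq_len(nrow(u$igs_copies)))
                add("igs_copy", cs$name,
                    pos + u$igs_copies$start[i] - 1L,
                    pos + u$igs_copies$end[i] - 1L,
                    u$igs_copies$orientation[i],
                    family = u$igs_copies$family[i], parent = uid)
            unit_bounds[[ui]] <- list(
              gstart = pos + gspan[1L] - 1L, gend = pos + gspan[2L] - 1L,
              orient = r$orientations[ui], id = uid,
              n_embedded = if (is.null(u$igs_copies)) 0L else
                nrow(u$igs_copies))
            bg[pos:end] <- .chars(u$seq)
            pos <- end + 1L
          }
          # spacers between adjacent planted units
          if (length(unit_bounds) >= 2L)
            for (ui in seq_len(length(unit_bounds) - 1L)) {
              a <- unit_bounds[[ui]]; b <- unit_bounds[[ui + 1L]]
              add("igs", cs$name, a$gend + 1L, b$gstart - 1L, "*",
                  copy_count = a$n_embedded,
                  config = if (a$orient == b$orient) "N" else "P",
                  parent = a$id)
            }
          placed[[length(placed) + 1L]] <- c(start, pos - 1L, "rdna_cluster")
        } else stop("unknown feature kind: ", f$kind, call. = FALSE)
      }
      if (length(placed) >= 2L) {
        iv <- do.call(rbind, lapply(placed, function(p)
          data.frame(start = as.integer(p[1]), end = as.integer(p[2]),
                     kind = p[3])))
        iv <- iv[order(iv$start), ]
        if (any(iv$start[-1L] <= iv$end[-nrow(iv)]))
          stop("overlapping planted features", call. = FALSE)
      }
      seqs[[cs$name]] <- paste(bg, collapse = "")
    }
    manifest <- do.call(rbind, rows)
    rownames(manifest) <- NULL
    structure(list(seqs = seqs, manifest = manifest, families = families,
                   spec = spec),
              class = "sim_genome")
  })
}

#' Write a simulated genome and its truth manifest to disk
#'
#' Produces `genome.fa` (60-column FASTA), `manifest.json` (records plus the
#' generating seed), `manifest.gff3` and `manifest.bed` (0-based half-open
#' starts, as BED requires).
#'
#' @param sim A `sim_genome` from [make_genome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_genome <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_genome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             json = file.path(dir, "manifest.json"),
             gff3 = file.path(dir, "manifest.gff3"),
             bed = file.path(dir, "manifest.bed"))
  write_fasta_chr(sim$seqs, paths["fasta"])
  jsonlite::write_json(list(seed = sim$spec$seed, features = sim$manifest),
                       paths["json"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  m <- sim$manifest
  gr <- GenomicRanges::GRanges(
    seqnames = m$chrom,
    ranges = IRanges::IRanges(m$start, m$end),
    strand = ifelse(m$strand %in% c("+", "-"), m$strand, "*"))
  gr$type <- ifelse(m$kind == "array", "tandem_array", m$kind)
  gr$ID <- sprintf("feat%04d", seq_len(nrow(m)))
  gr$family <- m$family
  gr$copy_count <- m$copy_count
  gr$config <- m$config
  gr$Parent_feature <- m$parent
  rtracklayer::export(gr, paths[["gff3"]], format = "gff3")
  bed <- data.frame(m$chrom, m$start - 1L, m$end,
                    paste0(m$kind, ":", seq_len(nrow(m))), 0L,
                    ifelse(m$strand %in% c("+", "-"), m$strand, "."))
  utils::write.table(bed, paths["bed"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
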