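#' Read and validate a run configuration
#'
#' Configurations are YAML (or an equivalent R list) with optional sections
#' `simulate`, `scan`, `pcr`; see the package vignette for the schema.  The
#' stringency preset name must be `"relaxed"` or `"strict"`; referenced
#' input paths must exist.
#'
#' @param config A YAML file path or a list.
#' @return The validated configuration list, class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  preset <- config$preset %||% "relaxed"
  if (!preset %in% c("relaxed", "strict"))
    stop("preset must be 'relaxed' or 'strict', got '", preset, "'",
         call. = FALSE)
  config$preset <- preset
  for (p in c(config$scan$genome, config$scan$monomers,
              config$scan$rrna_refs, config$pcr$template)) {
    if (is.character(p) && length(p) == 1L && grepl("[./]", p) &&
        !file.exists(p))
      stop("input path does not exist: ", p, call. = FALSE)
  }
  class(config) <- c("run_config", "list")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Simulate a genome from a configuration
#'
#' Builds the [sim_spec()] declared under `config$simulate`, renders it with
#' [make_genome()], and writes FASTA plus manifest files to `out_dir`.
#'
#' @param config A `run_config` (or list/YAML path accepted by
#'   [read_run_config()]) whose `simulate` section holds `seed` and
#'   `chroms`.
#' @param out_dir Output directory.
#' @return A run report list: stage, parameter echo, output paths, feature
#'   counts.
#' @export
run_simulate <- function(config, out_dir) {
  config <- read_run_config(config)
  sc <- config$simulate
  if (is.null(sc) || is.null(sc$chroms))
    stop("validation error: config$simulate$chroms is missing",
         call. = FALSE)
  spec <- sim_spec(seed = sc$seed %||% 1L, chroms = sc$chroms)
  .log_stage("simulate", "rendering %d chromosome(s), seed %d",
             length(spec$chroms), spec$seed)
  sim <- make_genome(spec)
  paths <- write_genome(sim, out_dir)
  .log_stage("simulate", "wrote %s", paths[["fasta"]])
  list(stage = "simulate", seed = spec$seed, outputs = as.list(paths),
       n_features = nrow(sim$manifest),
       counts = as.list(table(sim$manifest$kind)))
}

#' Run the full repeat-characterization scan
#'
#' Executes the stage chain on a genome and monomer references: homology
#' search at the configured preset, array delineation, monomer segmentation
#' and consensus per array, subunit decomposition of each monomer reference,
#' family/orientation classification of array consensuses, then (when rRNA
#' references are available) rDNA unit annotation, IGS delineation, copy
#' classification, per-IGS multiplicity and N/P configuration, and finally
#' the binned profile and genome-fraction estimates at both stringency
#' presets.
#'
#' @param genome Named character vector of chromosomes, or FASTA path.
#' @param monomers Named character vector of monomer references, or FASTA
#'   path.
#' @param rrna_refs Optional named vector/list with `18S`, `5.8S`, `26S` (or
#'   FASTA path); `NULL` skips the rDNA stages with a warning.
#' @param preset Stringency preset name (`"relaxed"` or `"strict"`).
#' @param scoring An [align_scoring()] object.
#' @param bin_size Profile bin size in bp.
#' @param genome_size Genome size for fraction estimates; defaults to the
#'   total assembly length.
#' @param out_dir Optional output directory for the standard file set
#'   (HSP table, array GFF3/BED, consensus FASTA, rDNA/IGS tables, profile
#'   bedGraph, fraction TSV, report JSON).
#' @return A run report list with one entry per executed stage and the
#'   result objects (`hsps`, `arrays`, `segmentations`, `decompositions`,
#'   `family_calls`, `units`, `igs`, `copies`, `multiplicity`, `profile`,
#'   `fractions`).
#' @export
run_scan <- function(genome, monomers, rrna_refs = NULL,
                     preset = "relaxed", scoring = align_scoring(),
                     bin_size = 10000L, genome_size = NULL,
                     out_dir = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta_chr(genome)
  if (is.character(monomers) && length(monomers) == 1L &&
      file.exists(monomers))
    monomers <- read_fasta_chr(monomers)
  if (is.character(rrna_refs) && length(rrna_refs) == 1L &&
      file.exists(rrna_refs))
    rrna_refs <- as.list(read_fasta_chr(rrna_refs))
  stopifnot(!is.null(names(genome)), !is.null(names(monomers)))
  params <- stringency_preset(preset)
  genome_size <- genome_size %||% sum(nchar(genome))
  report <- list(parameters = list(preset = preset, bin_size = bin_size,
                                   genome_size = genome_size),
                 stages = character(0), warnings = character(0))
  push <- function(stage) report$stages <<- c(report$stages, stage)

  .log_stage("search", "preset '%s': %d monomer(s) vs %d sequence(s)",
             preset, length(monomers), length(genome))
  hsps <- search_genome(monomers, genome, params = params, scoring = scoring)
  push("local_search")

  arrays <- list()
  segmentations <- list()
  consensuses <- character(0)
  for (fam in names(monomers)) {
    sub <- hsps[hsps$qseqid == fam, , drop = FALSE]
    arr <- delineate_arrays(sub, monomer_len = nchar(monomers[[fam]]))
    arr$family <- if (nrow(arr)) fam else character(0)
    arrays[[fam]] <- arr
    for (i in seq_len(nrow(arr))) {
      region <- substr(genome[[arr$chrom[i]]], arr$start[i], arr$end[i])
      seg <- segment_monomers(region, consensus = monomers[[fam]],
                              scoring = scoring)
      segmentations[[paste0(fam, ":", arr$chrom[i], ":", arr$start[i])]] <-
        seg
      full <- seg$monomers[!seg$monomers$partial, , drop = FALSE]
      if (nrow(full) >= 1L) {
        cps <- substring(region, full$start, full$end)
        consensuses[paste0(fam, ":", arr$chrom[i], ":", arr$start[i])] <-
          build_consensus(cps, scoring = scoring)
      }
    }
  }
  arrays <- do.call(rbind, c(arrays, make.row.names = FALSE))
  push("delineate_arrays"); push("segment_monomers"); push("build_consensus")
  .log_stage("arrays", "%d array(s) across %d famil(ies)",
             if (is.null(arrays)) 0L else nrow(arrays), length(monomers))

  decompositions <- lapply(monomers, decompose_subunits, scoring = scoring)
  push("decompose_subunits")
  family_calls <- lapply(consensuses, classify_family,
                         references = monomers, scoring = scoring)
  push("classify_family")

  units <- igs <- copies <- multiplicity <- NULL
  if (!is.null(rrna_refs)) {
    units <- annotate_rdna(genome, rrna_refs, scoring = scoring)
    igs <- delineate_igs(units)
    igs <- classify_config(igs)
    copies <- classify_copies(hsps, igs)
    multiplicity <- pair_multiplicity(copies, igs)
    push("annotate_rdna"); push("delineate_igs"); push("classify_copies")
    push("pair_multiplicity"); push("classify_config")
    .log_stage("rdna", "%d unit(s), %d spacer(s), modal copies/IGS %s",
               nrow(units), nrow(igs),
               multiplicity$mode %||% NA)
  } else {
    report$warnings <- c(report$warnings,
                         "no rRNA references: rDNA stages skipped")
    .log_stage("rdna", "skipped (no rRNA references)")
  }

  prof <- profile_hsps(hsps, bin_size = bin_size,
                       monomer_len = stats::median(nchar(monomers)),
                       chrom_lengths = stats::setNames(nchar(genome),
                                                       names(genome)))
  push("profile")
  both <- list(
    relaxed = search_genome(monomers, genome,
                            params = stringency_preset("relaxed"),
                            scoring = scoring),
    strict = search_genome(monomers, genome,
                           params = stringency_preset("strict"),
                           scoring = scoring))
  fractions <- genome_fraction(both, genome_size)
  push("genome_fraction")

  result <- list(report = report, hsps = hsps, arrays = arrays,
                 segmentations = segmentations,
                 consensuses = consensuses,
                 decompositions = decompositions,
                 family_calls = family_calls,
                 units = units, igs = igs, copies = copies,
                 multiplicity = multiplicity,
                 profile = prof, fractions = fractions)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_hsps(hsps, file.path(out_dir, "hsps.tsv"))
    if (!is.null(arrays) && nrow(arrays))
      write_arrays(arrays, gff3 = file.path(out_dir, "arrays.gff3"),
                   bed = file.path(out_dir, "arrays.bed"))
    if (length(consensuses))
      write_fasta_chr(as.list(consensuses),
                      file.path(out_dir, "consensus.fa"))
    if (!is.null(units))
      utils::write.table(units, file.path(out_dir, "rdna_units.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(igs))
      utils::write.table(igs, file.path(out_dir, "igs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_profile(prof, file.path(out_dir, "profile.bedGraph"),
                  file.path(out_dir, "array_regions.bed"))
    utils::write.table(fractions, file.path(out_dir, "fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    .log_stage("scan", "outputs written to %s", out_dir)
  }
  result
}

#' Predict a PCR ladder from a configuration
#'
#' @param template Template sequence or FASTA path (first record used).
#' @param fwd_primer,rev_primer Primer sequences (>= 15 bp).
#' @param out Optional TSV output path.
#' @param ... Passed to [insilico_pcr()].
#' @return The `amplicon_ladder`.
#' @export
run_pcr <- function(template, fwd_primer, rev_primer, out = NULL, ...) {
  if (is.character(template) && length(template) == 1L &&
      file.exists(template))
    template <- read_fasta_chr(template)[[1L]]
  ladder <- insilico_pcr(template, fwd_primer, rev_primer, ...)
  if (length(ladder$lengths) == 0L)
    .log_stage("pcr", "warning: no amplicons predicted")
  else
    .log_stage("pcr", "%d amplicon(s), step %s", length(ladder$lengths),
               ifelse(is.na(ladder$step), "NA", ladder$step))
  if (!is.null(out)) write_ladder(ladder, out)
  ladder
}
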