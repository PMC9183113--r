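---
title: "satscout: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{satscout: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satscout)
```

# Scope

`satscout` characterizes satellite-DNA families of the kind exemplified by
the ~237 bp *Cannabis sativa* tandem repeat and its ~208 bp
deletion-derivative: long arrays of near-identical monomers, monomers that
are themselves higher-order repeats (HORs) built from diverged internal
subunits, and a subpopulation of copies embedded in the intergenic spacers
(IGS) of the 45S rDNA cluster. The package covers the full desk-scale
workflow: simulating genomes with planted truth, finding repeat copies by
seed-and-extend alignment, detecting tandem periodicity de novo,
segmenting arrays into monomers and building consensuses, decomposing
monomers into HOR subunits and calling the indels that separate family
variants, annotating rDNA units and classifying spacer-linked copies, and
summarizing everything as binned profiles, genome fractions, and in-silico
PCR ladders.

# Alignment model

All pairwise alignment uses an affine-gap model with match +1,
mismatch −2, gap open 5, gap extend 2 (penalties positive, subtracted).
This is a conventional nucleotide scoring with a gap regime that keeps a
large deletion as one gap rather than splintering it — important because
indel inference reads deletion lengths directly off gap runs. Dynamic
programming is delegated to `Biostrings::pairwiseAlignment()`; the
package's own contribution is everything around it: seeding, clustering,
extension, filtering, and the repeat-specific analyses.

Percent identity is computed on alignment columns after trimming end
gaps: terminal overhangs (which reflect incomplete copies, not
divergence) do not count, while internal gaps do. One consequence worth
knowing: identity between a sequence and a variant with a large internal
deletion is dominated by the deletion's gap columns.

# Homology search

`local_search()` is a seed-and-extend scanner in the blastn idiom:

* exact word seeding, word size 10 by default;
* seeds grouped by diagonal with a band of `max(16, query_length/10)`;
* clusters must reach a minimum seeded coverage of
  `max(2 * word_size, 0.10 * query_length)` before extension — this is
  what keeps random word hits on megabase subjects from triggering
  alignments;
* local alignment within a window around the cluster, then
  reciprocal-overlap (>50%) deduplication keeping the best score.

Hits are filtered by identity and query coverage. Two stringencies are
exposed as presets: *relaxed* (identity ≥ 85%, coverage ≥ 95%) for
inclusive copy inventories, and *strict* (identity ≥ 90%) for
high-confidence sets. Genome fractions are reported once per preset so the
two can bracket the repeat content; strict is necessarily ≤ relaxed, and
the test suite asserts that monotonicity.

# Period detection

`detect_period()` collects candidate lags from the recurrence-distance
histogram of exact 12-mers, refines each candidate ±2 bp, and scores it
by support: the fraction of positions matching their image one lag away.
A fundamental period *p* and its multiples 2*p*, 3*p* have statistically
identical support — copies diverge independently, so a base matches at
lag 2*p* as often as at lag *p* — and differ only by sampling noise of
order 1/√n (about 0.005 on a 4.7 kb array). Candidates within
`support_tol = 0.02` (several standard errors) of the maximum are
therefore treated as tied and ranked by ascending period, which makes the
fundamental outrank its harmonics without depending on which side of a
rounding boundary the noise falls.

# Segmentation and consensus

`segment_monomers()` walks an array by repeated anchored alignment: the
consensus is aligned pattern-globally into a local window at the current
position, the matched prefix becomes the next copy, and the walk resumes
at its end. Trailing stretches shorter than the consensus are emitted as
terminal partial copies, and fractional copy number is total copy length
divided by consensus length — so "about 2.5 monomers" is a legitimate
answer for a two-and-a-half-copy region. Regions under 2.5 copies are
flagged `short` by the array delineator rather than suppressed.

`build_consensus()` anchors its columns on the lexicographically smallest
of the longest copies, making the result invariant to copy order, then
takes per-column majorities (ties resolved A<C<G<T; a gap wins a column
only on strict majority).

# HOR decomposition and the 48% identity floor

`decompose_subunits()` finds the internal duplication structure of a
monomer by exhaustive split-point search: every split (coarse step 3,
then ±2 refinement) is scored by the affine-gap global alignment of the
two halves, and the best split is reported with the inter-subunit
identity. Because the search is exhaustive, it is its own brute-force
oracle; tests therefore validate it against planted truth.

A decomposition is only accepted when the inter-half identity clears a
floor. The floor must sit below the weakest genuine subunit homology in
the target family (the short-variant subunit pairs align at roughly
50–55%) yet above random background. Calibration under the default
scoring shows unrelated 237 bp sequences reach at most ≈47.6%
max-over-splits end-trimmed identity, so the floor is set to 48%:
every real homology observed (≥50%) is retained and random sequence is
rejected. This number is an empirical property of the scoring scheme and
should be recalibrated if the scoring changes.

Variant comparison (`compare_subunit_families()`) reads indels off gap
runs in the end-trimmed alignment core, reporting reference-coordinate
positions (first deleted base for deletions, preceding base for
insertions) and the deleted sequence, with a 5 bp minimum so alignment
jitter is not reported as structure.

# rDNA annotation and spacer analysis

`annotate_rdna()` locates 18S, 5.8S and 26S gene hits per strand and
assembles them greedily into units in transcription order, tolerating up
to 5 kb between consecutive genes. `delineate_igs()` then defines each
spacer as the gap between adjacent genic blocks; terminal spacers
truncated by a contig end are emitted as partial only when contig lengths
are supplied, and partial spacers are excluded from per-spacer counting.
`classify_copies()` labels a repeat copy IGS-linked when ≥90% of it lies
inside a spacer; `pair_multiplicity()` histograms linked copies per
complete spacer and reports the mode (ties toward the smaller count);
`classify_config()` calls a spacer N between co-oriented units and P
between inverted ones. `compare_igs_variants()` accepts either two spacer
sequences (gap runs ≥30 bp become deletions, breakpoint = last aligned
position before the gap) or two lengths, in which case it applies single-deletion
arithmetic (deletion length = long minus short) and labels the result
`"length-difference"`.

# The simulator and its scope

`simrep` builds genomes bottom-up from explicit specifications:
`family_spec()` describes a monomer as subunits (the second derived from
the first at a stated identity, default 70%, with the length difference
realized as a single internal indel so both ends stay homologous, plus an
optional planted indel such as a 27 bp deletion); `make_array()` tiles
mutated copies with optional insertions; `make_rdna_unit()` lays out
18S–ITS1–5.8S–ITS2–26S–IGS with embedded spacer copies ending 100 bp
before the spacer's 3′ end; `make_genome()` stamps features onto random
background and records every array, copy, unit, spacer (with N/P
configuration) and embedded copy in a truth manifest exported as JSON,
GFF3 and BED.

Mutation is substitution-only and forced-change: a site drawn at rate *r*
always changes, so expected identity is exactly 1 − *r* and test bounds
are simple binomial bounds. The simulator does not model indel drift
within arrays, gene-sequence realism (rRNA genes are fixed random
surrogates of realistic lengths: 1800/250/160/250/3400 bp), GC bias,
nested insertions of one family into another, or chromosome-scale array
sizes. It is a geometry-and-divergence simulator for validating the
scanner, not a population-genetic model.

Default per-spacer copy counts and array copy numbers in examples are
desk-scale choices (tens of copies, 3–6 rDNA units, 20–100 kb contigs):
large enough for stable statistics, small enough that the full test suite
runs in well under its time budget on one CPU. They are the package's own
choices, not biological estimates.

# In-silico PCR

`insilico_pcr()` finds primer sites with up to 2 mismatches but requires
the three 3′-terminal bases to match exactly (extension-blocking
mismatches), tries both primers in both roles on both strands, and keeps
amplicons up to 5 kb. On a tandem array this produces a ladder; the
reported step is the median difference between consecutive distinct
amplicon lengths, which on an IGS-embedded pair of ~208 bp monomers comes
out at the monomer length.

# Conventions and limitations

Coordinates are 1-based and inclusive everywhere in R; BED and bedGraph
exports convert to 0-based half-open, GFF3 stays 1-based. Known
limitations: breakpoint positions from alignment are ambiguous within a
few bases when the deleted segment's ends resemble its flanks (tests and
reported values treat ±5 bp as equivalent); segmentation assumes a single
dominant period per array; rDNA assembly assumes units are not nested or
overlapping; and the scanner's seed-coverage filter can miss copies
diverged far beyond the relaxed preset (by design — they are no longer
family members at the stated thresholds).
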