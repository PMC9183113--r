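# satscout

Characterization of satellite-DNA tandem repeats and their linkage to the
45S rDNA intergenic spacer, in R.

## The problem

Plant genomes carry satellite DNA: families of near-identical monomers
repeated head-to-tail in long arrays. Some families have internal
structure — the monomer is itself a higher-order repeat (HOR) built from
two diverged subunits — and some families live a double life, occurring
both as independent arrays and as copies embedded inside the intergenic
spacer (IGS) between 45S rDNA units. The motivating family is a ~237 bp
monomer whose two subunits (111 bp and 126 bp) align at roughly 60–70%
identity, together with a shorter variant created by a 27 bp deletion in
the longer subunit; pairs of the short variant sit inside each rDNA
spacer, and spacer length variants differ by a single large internal
deletion (3595 vs 984 bp, i.e. 2611 bp).

`satscout` implements the full desk-scale analysis for repeats of this
kind, plus a simulator that plants such structures into synthetic genomes
with a machine-readable truth manifest, so every stage is testable
offline:

| Stage | Functions |
|---|---|
| Simulation with truth manifests | `family_spec`, `make_array`, `make_rdna_unit`, `sim_spec`, `make_genome`, `write_genome` |
| Alignment and homology search | `global_align`, `identity_pct`, `local_search`, `search_genome`, `stringency_preset` |
| Tandem structure | `detect_period`, `segment_monomers`, `build_consensus`, `delineate_arrays` |
| HOR / variant structure | `decompose_subunits`, `compare_subunit_families`, `classify_family` |
| rDNA linkage | `annotate_rdna`, `delineate_igs`, `classify_copies`, `pair_multiplicity`, `classify_config`, `compare_igs_variants` |
| Summaries | `profile_hsps`, `genome_fraction`, `insilico_pcr` |
| Pipeline | `run_simulate`, `run_scan`, `run_pcr` (CLI: `inst/scripts/satscout`) |

Methods, parameter defaults and their rationale are documented in the
vignette source at `vignettes/satscout-methods.Rmd`.

## Worked example

Simulate a 40 kb contig carrying a 12-copy HOR array (subunits 111+126 bp)
and a 3-unit co-oriented rDNA cluster whose spacers each embed a
reverse-oriented pair of the deletion-variant monomer (subunits 98+111 bp):

```r
library(satscout)
cs    <- family_spec("CS",    c(111L, 126L))
delcs <- family_spec("delCS", c(98L, 111L), orientation = "reverse")
spec <- sim_spec(seed = 11, chroms = list(list(
  name = "chr8", length = 40000,
  features = list(
    list(kind = "array", start = 2000, monomer = cs, copies = 12,
         sub_rate = 0.03),
    list(kind = "rdna_cluster", start = 8000, n_units = 3,
         igs_template = random_dna(3595, seed = 77),
         embedded = delcs, n_copies = 2, sub_rate = 0.02)))))
sim <- make_genome(spec)   # sim$families: CS (237 bp), delCS (209 bp)
```

De novo period detection on the array region ranks the monomer length
first, with its harmonics behind it:

```r
arr <- sim$manifest[sim$manifest$kind == "array", ]
region <- substr(sim$seqs[["chr8"]], arr$start, arr$end)
head(detect_period(region), 3)
#>   period   support count phase
#> 1    237 0.9305715  1121     0
#> 2    474 0.9291139   357    48
#> 3    711 0.9268636   131   217
```

Segmentation recovers 12 copies (copy number 12.0) and a 237 bp
consensus, whose HOR decomposition returns the planted subunits:

```r
segs <- segment_monomers(region, period = 237)
nrow(segs$monomers); segs$copy_number   # 12; 12
decompose_subunits(segs$consensus)
#> <subunit_decomposition> subunits 111 + 126 bp, inter-subunit identity 63.5%
```

Scanning the whole contig with both family monomers, then running the
rDNA chain, identifies the cluster and the spacer-embedded pairs:

```r
hits  <- search_genome(sim$families, sim$seqs,
                       params = stringency_preset("relaxed"))  # 18 HSPs
units <- annotate_rdna(sim$seqs)          # 3 units, all "+"
igs   <- delineate_igs(units)             # 2 complete spacers
pm    <- pair_multiplicity(classify_copies(hits, igs), igs)
pm$mode                                   # 2 copies per IGS
classify_config(igs)$config               # "N" "N"  (co-oriented)
compare_igs_variants(3595, 984)$deletion_length   # 2611
```

Genome fractions at both stringencies and an in-silico PCR ladder off the
delCS monomer complete the picture:

```r
genome_fraction(list(relaxed = hits,
                     strict = search_genome(sim$families, sim$seqs,
                              params = stringency_preset("strict"))),
                genome_size = 40000)
#>   family  preset covered_bp genome_size fraction_pct
#> 1     CS relaxed       2836       40000         7.09
#> 2  delCS relaxed       1252       40000         3.13
#> 3     CS  strict       2836       40000         7.09
#> 4  delCS  strict       1252       40000         3.13

mono <- sim$families[["delCS"]]
lad <- insilico_pcr(sim$seqs[["chr8"]], substr(mono, 10, 29),
                    revcomp(substr(mono, 170, 189)))
length(lad$lengths); lad$step             # 9 amplicons; 209 bp step
```

The same chain is available end-to-end as `run_scan(genome, monomers,
rrna_refs = ...)`, which also writes GFF3/BED/bedGraph/TSV/JSON outputs,
and from the shell via the installed `satscout` script.

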