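# estssr — EST-SSR mining, genic annotation and marker design

`estssr` is an R toolkit for scientists developing microsatellite (SSR)
markers from assembled transcriptomes of non-model organisms — the setting
where no reference genome exists and expressed sequence tags are the only
tractable sequence resource. It covers the full chain from contig FASTA to
validated marker candidates:

* **Mining** — perfect di- to hexanucleotide tandem repeats of primitive
  units under MISA-style minimum repeat counts (6/5/4/3/3), with compound
  records for runs separated by at most a configurable interruption, and
  MISA-compatible TSV / GFF3 output.
* **Motif classification** — canonical motif classes under cyclic rotation
  and reverse complementation (4 di, 10 tri, 33/102/350 tetra/penta/hexa
  classes), plus the traditional printed labels for the handful of
  trinucleotide classes that surveys name non-minimally.
* **Genic location** — each locus placed as 5'UTR / coding / 3'UTR /
  undetermined from per-contig CDS coordinates (user-supplied TSV/GFF3 or
  a declared six-frame longest-ORF stand-in).
* **CMiB marker design** — greedy sequence clustering (CD-HIT-EST style),
  SSR-flanking primer enumeration under declared thermodynamic and
  geometric constraints, ipcress-style in-silico PCR with a 3'-anchor rule,
  triage to single unique products, single-linkage amplicon clustering with
  shortest-product selection, and known-marker exclusion by local-alignment
  score — with a full provenance table for every candidate.
* **Statistics** — motif × location summary tables with survey-style
  percentages, SSR frequency (% of sequences with an SSR) and density
  (SSRs / 10 kbp), GC composition with masked intervals, binomial and
  Poisson GLMs with Wald z tests, Fisher/Benjamini-Hochberg GO enrichment,
  Welch t, Spearman/Pearson correlation, marker diversity (Na, Ho, He,
  PIC) and calibrated polymorphism forecasts by repeat count.
* **Synthetic data** — seeded generators for contig sets with planted SSRs,
  CDS intervals, designable flanks and a full planting manifest, plus
  simulated marker-outcome panels for the GLMs.

## Core definitions

For a repeat unit *u* of length *k* ∈ {2..6}, a locus is a maximal run
*u*ⁿ with *n* at least the per-*k* minimum; its class is
min over rotations of *u* and of revcomp(*u*). Frequency and density of a
contig set C with locus set L:

    frequency = 100 · |{c ∈ C : c has ≥ 1 locus}| / |C|
    density   = |L| / (Σ length(c) / 10,000)

Diversity at a marker locus with allele frequencies *pᵢ*:

    He  = 1 − Σ pᵢ²        PIC = 1 − Σ pᵢ² − Σ_{i<j} 2 pᵢ² pⱼ²

## Worked example

```r
library(estssr)

gen <- generate_contigs(6, c(450, 550), 0.42,
                        ssr_spec = data.frame(contig = 1:3,
                                              unit = c("AT", "AAG", "AC"),
                                              repeats = c(8, 6, 9)),
                        seed = 42, cfg = mining_config(max_interruption = 100),
                        ensure_design = design_constraints())
detect_ssrs(gen$seqs, mining_config(max_interruption = 100))
#>   contig_id ssr_type  motif start end
#> 1  synth001       p2  (AT)8   163 178
#> 2  synth002       p3 (AAG)6   255 272
#> 3  synth003       p2  (AC)9   241 258

res <- run_cmib(gen$seqs)
res$selected[, c("candidate_id", "motif", "forward_seq", "expected_product_bp")]
#>    candidate_id  motif             forward_seq expected_product_bp
#> 1 synth001.ssr1  (AT)8    CCAGCGGCCTCAGGAATGGC                 250
#> 2 synth002.ssr1 (AAG)6 CTCAAGTGACCAGTCCTGTAGGG                 251
#> 3 synth003.ssr1  (AC)9   GCACGCAGGGTAGAGTTCGGG                 209
```

Each planted locus yields exactly one selected marker: a primer pair whose
in-silico product is unique across the whole contig set and shortest within
its amplicon cluster. The packaged survey count fixture reproduces the
published shares:

```r
tab <- summarize_by_location(table2_fixture())
summary_percent(tab, "AT")             # 46.3  (% of di-SSRs that are AT)
summary_percent(tab, "tri", "coding")  # 72.8  (% of tri-SSRs in coding regions)
round_half_up(ssr_frequency_from_counts(3694, 81284), 2)  # 4.54 (% contigs with SSRs)

diversity_stats(c("152","152","156","158"), c("156","152","158","152"))
#> $N 4   $Na 3   $Ho 0.75   $He 0.625   $PIC 0.555
```

(152/156/158 are fragment lengths of a genotyped marker; Ho is the
fraction of heterozygous individuals, He and PIC follow the formulas
above.)

## Command line

A subcommand launcher ships in `inst/cli/estssr`:

```sh
Rscript inst/cli/estssr mine contigs.fasta --out ssr        # MISA TSV + GFF3
Rscript inst/cli/estssr classify contigs.fasta ann.tsv ssr.misa.tsv
Rscript inst/cli/estssr design contigs.fasta ssr.misa.tsv --out primers.tsv
Rscript inst/cli/estssr cmib contigs.fasta --known known.fasta --outdir out/
Rscript inst/cli/estssr stats table2
Rscript inst/cli/estssr synth --n 10 --n-planted 5 --seed 1 --out synth
```

Every run writes a `run_manifest.json` (input checksums + effective
configuration) beside its outputs; exit code 2 signals a validation error.

## Layout

```
R/                  implementation (sequence IO, miner, ORF/location,
                    clustering, primer design, in-silico PCR + CMiB,
                    statistics, synthetic data, CLI)
inst/extdata/       packaged motif-by-location count fixture (TSV)
inst/cli/estssr     command-line launcher
tests/testthat/     unit, property and acceptance suites + oracles
scripts/acceptance.R
vignettes/est-ssr-methods.Rmd   the methods notes
```
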