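---
title: "Mining, annotating and designing EST-SSR markers with estssr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining, annotating and designing EST-SSR markers with estssr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estssr)
```

## The problem

Microsatellites (simple sequence repeats, SSRs) in expressed sequence tags
are a cheap source of codominant, transferable markers for species without
a reference genome — conifers being the classic case, with genomes of tens
of gigabases but transcriptomes of ordinary size. Turning an assembled
transcriptome into a panel of usable EST-SSR markers requires a chain of
decisions: which tandem repeats count as SSRs, how repeat motifs are named
so that counts are comparable across studies, where each repeat sits within
the transcript (5'UTR, coding, 3'UTR), which repeat-bearing sequences are
redundant, which primer pairs will amplify a single unique product, and
which candidate markers duplicate loci that already exist. `estssr`
implements that chain end to end, together with the summary and inferential
statistics such surveys report.

## Detection model

A locus is a maximal perfect tandem run of a *primitive* unit of 2-6 bp
(a unit is primitive when it is not a power of a shorter string; mining
starts at dinucleotides, since mononucleotide runs are dominated by
sequencing artifacts in EST data). Per-unit-length minimum repeat counts
follow the MISA convention used by most plant EST-SSR surveys:

| unit length | 2 | 3 | 4 | 5 | 6 |
|---|---|---|---|---|---|
| minimum repeats | 6 | 5 | 4 | 3 | 3 |

Runs cannot span a non-ACGT base. When two qualifying runs lie within
`max_interruption` bp of each other (including overlapping runs of
different unit lengths) they are merged into a single *compound* record;
the constituent runs are retained as children so repeat-count spectra and
polymorphism thresholds can still see them. Two conventions are in use:
`max_interruption = 0` for frequency surveys and `100` for marker design,
both exposed through the single `mining_config()` knob.

One corner case deserves a declared rule rather than silence: two maximal
runs of the same unit length can overlap by up to unit-length − 1 bases
(e.g. `...ATATAT` followed by `TCTCTC...` sharing one T). We accept
candidates in ascending start order and skip any that overlaps an accepted
locus of the same unit length. The brute-force enumerator used as the
testing oracle implements the same rule by a different algorithm (explicit
per-start extension versus the vectorized shift-match used in
`detect_ssrs()`), so the equivalence tests are meaningful.

Motif classes are canonicalized as the lexicographically smallest string
over all cyclic rotations of the unit and of its reverse complement —
4 classes for di-, 10 for tri-, 33/102/350 for tetra-/penta-/hexa-
nucleotides by exhaustive enumeration. Published tables traditionally label
three trinucleotide classes by non-minimal representatives (ATG for ATC,
GGC for CCG, AGT for ACT); `motif_label()` carries that fixed alias so
packaged count fixtures join cleanly without giving up a deterministic
canonical form.

Two corpus descriptors recur downstream: *frequency*, the percentage of
sequences containing at least one SSR, and *density*, SSR records per
10 kbp of sequence.

## Genic location

Coding-region coordinates are an *input contract*: one CDS interval per
contig, from a 4-column TSV or GFF3 CDS lines. The package deliberately
does not reproduce peptide-prediction pipelines; a six-frame longest-ORF
stand-in (`find_longest_orf()`, default minimum 30 codons) exists only so
the toolchain runs end to end without external predictions, and every
annotation records its `source` (`user` or `orf_standin`). A locus entirely
upstream of the CDS is `five_prime_utr`, entirely inside (boundary bases
inclusive) `coding`, entirely downstream `three_prime_utr`; a locus
straddling either boundary is `undetermined`, and loci on unannotated
contigs are `no_annotation`. These five values partition any locus set —
a property the tests assert directly.

## Clustering

Two flavors, both defined by dynamic-programming alignment rather than by a
k-mer heuristic, so results are reproducible and order-independent:

* `greedy_cluster()` (input deduplication, CD-HIT-EST style): sequences in
  descending length order, ties by id; each joins the first cluster whose
  representative reaches the identity threshold (default 0.80) *over the
  shorter sequence's length* (global alignment of the shorter against the
  best window of the longer), else founds a cluster. Representatives are
  therefore the longest member, and the longest-per-cluster recovery step
  is implicit.
* `single_linkage_cluster()` (amplicon grouping, BlastCLUST style): an
  edge exists when a local alignment reaches the identity threshold
  (default 0.90) and covers at least half of *either* sequence (the
  coverage-either reading of BlastCLUST's `-b F`); clusters are connected
  components labeled by their smallest member id.

Alignment scoring is the classic nucleotide +1/−3 with gap open 5 and
extend 2 throughout, including the known-marker exclusion score. The
`word_size` k-mer prefilter is an optimization only; a test asserts it
never changes the clustering.

## Primer design

`design_primers()` is a transparent stand-in for a full thermodynamic
designer: it enumerates *every* pair satisfying the declared constraints —
primer length 18-24 (optimum 20), Tm 57-63 °C (optimum 60), GC 30-70%,
homopolymer runs ≤ 4, product 100-400 bp, no perfect self- or cross-dimer
of ≥ 8 bp — and ranks by

    |Tm_f − 60| + |Tm_r − 60| + |len_f − 20| + |len_r − 20|
      + 0.01 |product − midpoint|

with ties broken by forward start then product size, making the ranking a
total order. Tm is Wallace's 2(A+T)+4(G+C) under 14 bases and
64.9 + 41(GC − 16.4)/len at or above. The true production settings of any
Primer3-era pipeline are site-specific; these defaults are conventional
values, declared in `design_constraints()` so users can mirror whatever
setting they know. Products longer than 600 bp are flagged `oversize` —
they survive design but cannot be sized on a capillary sequencer.

## In-silico PCR and the CMiB selection core

`find_amplicons()` predicts products ipcress-style: a primer binds where it
matches with at most `max_mismatch` substitutions (default 0, the
"default options" reading) *and* its 3'-terminal base matches exactly;
footprints of a productive pair may not overlap; products are capped at
5 kb; both strands are searched. `run_cmib()` chains the stages:

1. keep SSR-containing sequences (mining at interruption 100);
2. greedy-cluster at identity 0.80, keep the longest per cluster;
3. design primers per SSR locus, keep the best-ranked pair;
4. in-silico PCR of every pair against **all** retained sequences, then
   triage: 0 products → `no_product`, ≥ 2 anywhere (also within one
   template — repetitive domains inside one contig disqualify just as
   cross-template repeats do) → `multi_product`, single product →
   `unique`, unique but > 600 bp → `oversize`;
5. single-linkage clustering of unique amplicons (identity 0.90, coverage
   0.5) and selection of the shortest expected product per cluster;
6. exclusion of candidates whose *source sequence* (not the primer) reaches
   a local-alignment score above 50 against any known marker sequence.

Every candidate ends in exactly one terminal status and the full provenance
table is emitted, so any selected marker is auditable back to its locus.

## Statistics

* `summarize_by_location()` builds the motif × location count matrix (di
  and tri classes individually; tetra/penta/hexa/compound as groups) with
  percentages against three explicit denominators (unit-length subtotal,
  grand total, pure-SSR total); printed percentages round half away from
  zero at one decimal, matching survey-table style.
* `fit_glm()` wraps IRLS maximum likelihood (binomial-logit for PCR
  success, Poisson-log for allele counts) with per-term Wald z and
  two-sided normal p. Separation is detected both from the fitting warnings
  and from boundary fitted values, and flagged rather than hidden.
* `diversity_stats()` returns Na, observed heterozygosity, expected
  heterozygosity He = 1 − Σp² and Botstein's PIC = He − Σ_{i<j} 2p²ᵢp²ⱼ.
  He is uncorrected by default — the sample-size corrected (2n/(2n−1))
  variant sits behind `unbiased = TRUE`, since survey reports rarely state
  which was used.
* `enrich_go()` runs per-term one-sided Fisher exact tests of
  overrepresentation (two-sided behind a flag) with Benjamini-Hochberg
  q-values; the background is the annotated universe outside the subset.
* `welch_t()` and `rank_and_linear_correlation()` cover the GC-composition
  comparisons; `polymorphism_forecast()` encodes the calibrated repeat-count
  thresholds (di ≥ 9 / tri ≥ 10 always polymorphic in the calibration
  panel; di ≥ 6 / tri ≥ 4 sometimes; other unit lengths are explicitly
  uncalibrated).

## The synthetic world

`generate_contigs()` emulates a cleaned EST contig set: background bases
drawn i.i.d. at a target GC of 0.40 (the composition typical of conifer
transcriptome assemblies), lengths 400-800 bp (typical assembled contig
lengths), planted SSRs at recorded positions, optional central CDS
intervals, and — when `ensure_design` is supplied — flanks on which at
least one primer pair is feasible ("clean flanks"). Acceptance is by
rejection: a contig is regenerated (up to 1000 attempts) until mining it
back recovers exactly the planted loci, which simultaneously guarantees no
accidental qualifying repeat and no chance extension of a planted run.
Generators save and restore the caller's RNG state, so they are pure
functions of their parameters and seed.

What the generator does **not** emulate: sequencing error, chimeras,
assembly collapse of paralogs, length-dependent GC structure, and linkage
between loci. A green end-to-end test therefore establishes that the
pipeline logic is correct on an idealized input, not that real conifer
contigs will yield the same marker counts.

`generate_marker_outcomes()` draws a marker-validation panel (pipeline
label, genic location, product size uniform on 100-400 bp, Tm sum normal
around 120 °C, repeat count 4-15, unit length 2-6) with PCR success
binomial-logit and allele count Poisson-log under a declared coefficient
truth. The default truth sets the two effects the field reproducibly
observes — success declining in product size (−0.004 per bp) and allele
count growing in repeat number (+0.13 per repeat) — and leaves the other
coefficients at zero.

## Numerical choices and edge cases

* Coordinates are 1-based inclusive everywhere (the MISA and GFF3
  convention, and the natural one in R).
* Masking dialect: lowercase and N are both "masked" for trimming; only
  non-ACGT letters are excluded from GC composition, so soft-masked bases
  outside the trimming context are not double-penalized.
* Equal-length unmasked runs: leftmost wins (the convention is arbitrary
  but must be fixed; it is asserted by test).
* ORF ties across strands are broken toward stop-terminated ORFs, then the
  plus strand, then the smallest start, which makes the stand-in symmetric
  under reverse complementation.
* `gc_percent()` with no countable base, correlations of constant vectors,
  and diversity with all calls missing return NA or error loudly rather
  than inventing a number.

## Known limitations

* The alignment-defined clustering is quadratic in the number of
  sequences; it is meant for the post-mining scale (thousands of
  SSR-containing sequences), not for raw read sets.
* Primer thermodynamics are the two classical closed forms, not
  nearest-neighbor ΔG; hairpins are not modeled.
* One CDS interval per contig; spliced or dual-ORF contigs are rejected
  rather than guessed at.
* In-silico PCR counts substitution mismatches only (no indel bubbles),
  matching the exact-matching spirit of the 3'-anchor rule.
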