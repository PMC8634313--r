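---
title: "Methods: TE expression and virus-borne insertions with virtex"
author: "virtex authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE expression and virus-borne insertions with virtex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtex)
```

## The problem

Transposable elements (TEs) are mostly silent in healthy tissue; a biotic
stress such as infection by a large dsDNA virus (a baculovirus, in the
motivating system) can modulate their expression. Two questions drive the
design of this package:

1. **Which TE families change expression during infection?** This requires
   aggregating fragmented repeat annotations into TE copies, counting reads
   per family, normalising jointly with host genes, and calling
   differential expression (DE) under explicit thresholds.
2. **Are host TEs transcribed from within viral genomes?** A TE copy
   integrated in the virus and co-transcribed with a viral gene produces
   *chimeric reads*: one read portion aligns only to a TE consensus, the
   other only to the viral genome. Pairs of junctions flanked by a
   duplicated target-site motif (TSD) are the signature of genuine
   transposition into the virus.

Everything runs on synthetic data with planted ground truth, so each stage
is verifiable end to end without downloads.

## TE copy aggregation and filtering

Repeat annotators emit fragments. `aggregate_hits()` merges fragments of
the same family, contig and strand whose gap is at most `max_gap` bp
(default **150 bp**). The merging tool used in the original analyses does
not document its internal gap penalty, so the value is an explicit,
exposed parameter here; 150 bp is small enough not to bridge independent
copies of high-copy families at typical genomic densities, and large
enough to heal deletion- or nesting-induced splits. Nested and overlapping
fragments are merged by interval union so masked base pairs are never
double-counted, and copy divergence is the length-weighted mean of its
fragments.

`filter_copies()` applies the classic *strict* rule: keep copies **greater
than 80 bp** long with **more than 80% identity** to the consensus. Both
inequalities are strict by deliberate reading of the rule's wording: a
copy of exactly 80 bp, or at exactly 80% identity, is removed.
`filter_library()` applies the analogous library-level rule: consensus
sequences longer than 300 bp, supported over at least half of a TE
protein, and not labelled SINE/tRNA/rRNA/Unknown.

All internal coordinates are 0-based half-open; the 1-based inclusive
conventions of RepeatMasker `.out` tables and 12-column tabular alignments
are converted at parse time and restored at write time.

## Expression quantification

`count_reads_per_family()` implements single-assignment counting: each
read keeps exactly one alignment (multi-mappers are not spread), and a
read that still ties across families is assigned to the alphabetically
first one so results are reproducible.

`compute_tpm()` normalises genes and TE families **jointly**: counts are
divided by feature length in kb (RPK), the per-replicate RPK total divided
by 10^6 gives the scaling factor, and every column of the result sums to
10^6 exactly. Categories follow two cutoffs: below **4 TPM** a family is
treated as not expressed (a standard cutoff for non-expressed genes), at
or above **50 TPM** as highly expressed (about 100 RPKM in short-read
libraries). Published analyses alternate between "TPM > 4" and
"TPM >= 4"; this package standardises on **>= 4 counts as expressed**
everywhere. Condition-mean TPM (not per-replicate TPM) feeds the
categories, again a choice the source material leaves open. For plots a
square-root axis is recommended over log: most families sit near zero and
a log axis visually inflates their spread.

## Differential expression

The DE layer deliberately does **not** reimplement a full shrinkage
estimator such as DESeq2's. The scientific content of the analysis is the
thresholding and classification layer, so `call_de()` offers two engines:

* **Built-in NB Wald.** Size factors by median-of-ratios over genes and TE
  families together; per-entity dispersion by method of moments
  (`(var - mean)/mean^2`, averaged across conditions, floored at 0);
  log2 fold change from normalised condition means with a **0.5
  pseudocount** so zero counts yield finite, bounded fold changes; a Wald
  z on the log scale with the delta-method standard error
  `sqrt((1/mu1 + a)/n1 + (1/mu2 + a)/n2)`; Benjamini–Hochberg adjustment
  at FDR 0.05 after genes are dropped (genes enter normalisation only).
* **External import.** A table of externally computed `(log2fc, padj)` —
  e.g. from DESeq2 on real data — to which only the decision rule is
  applied.

The decision rule is exact: a family is differentially expressed iff
**padj < 0.05 and |log2FC| >= 2**; `up`/`down` follow the sign. *Induced*
means mock TPM < 4 (all mock time points under a matched design, the
baseline mock otherwise), infected TPM >= 4 at at least one time point,
and an `up` call; *repressed* is the mirror image with a `down` call.

Two contrast designs are supported: `"matched"` (each infected time point
against its own mock, as in a midgut time course) and `"baseline"` (every
infected time point against the earliest mock, appropriate when
late-passage mock cultures drift for reasons unrelated to infection). A
time point without mock replicates is skipped with a warning rather than
silently contrasted against the wrong mock.

With n = 3 replicates the method-of-moments plug-in makes raw p-values
mildly anticonservative; the package's own null simulations (see the test
suite) show the *post-BH, post-threshold* false-call proportion stays well
inside the nominal FDR band, which is the operating point of the decision
rule. Users wanting calibrated per-gene inference on real data should use
the external-import path.

## Chimera detection

The primary input is per-read local alignments (12-column tabular format)
computed by any external aligner. For synthetic, error-free reads the
package ships `align_reads_exact()`: the terminal k-mers (k = 20,
mirroring the shortest exact substring a sensitive short-read mapper
accepts) of each read and of its reverse complement are matched exactly
and extended without gaps or mismatches. Both portions of a chimeric read
are end-anchored, so this recovers exactly the segments needed.

`detect_chimeras()` calls a read chimeric when it has a TE segment and a
virus segment, each at least **28 bp** (the shortest alignment a default
megablast reports on 51-bp reads), with read-interval overlap at most
**10 bp** and uncovered gap at most **10 bp**. One call per read is kept
(largest combined aligned length; ties by lowest virus coordinate), so a
read can never inflate family tables more than once.

**Micro-homology convention.** When the integration site happens to share
its first bases with the TE extremity, the virus-side alignment
over-extends into the TE by exactly that homology length, making the raw
junction coordinate ambiguous. The detector resolves this deterministically:
overlapping bases are attributed to the **TE side** (whose boundary is
pinned by the consensus extremity) and the virus junction coordinate is
shifted by the overlap. Every read spanning a given junction therefore
reports the same coordinate, and on error-free synthetic data the reported
coordinate equals the planted one exactly.

`classify_junction_side()` maps the junction-adjacent end of the TE
segment onto the consensus: within **tip_tol = 5 bp** of position 0 it is
`five_prime`, within 5 bp of the consensus end `three_prime`, otherwise
`internal` (the exact offset is reported). "At the extremity" is not
quantified in the source analyses; 5 bp tolerates alignment-end fraying
and is configurable. Tip chimeras are the expected product of bona fide
transposition; internal ones indicate fragmented or rearranged copies and
are excluded from transposition-evidence tables.

`tabulate_chimeras()` counts tip chimeras per family, time point,
replicate and side, lumping families with fewer than 10 chimeric reads
over all data sets into an `Others` row. `bin_hotspots()` bins junction
coordinates into half-open 50-bp windows along the viral genome.
`junction_rpkm()` measures virus-borne TE expression from junction-spanning
reads only, because reads internal to the TE cannot be attributed to
host-borne versus virus-borne copies.

## TSD pairing

`pair_junctions()` pairs 5'-side and 3'-side junctions of the same family
and concordant orientation whose viral coordinates differ by at most
**5 bp, inclusive** ("more or less 5 bp" is read as <= 5). *Concordant
orientation* is operationalised as: the TE strand implied by the 5'
chimera equals the strand implied by the 3' chimera — the source criterion
names the requirement without defining it. Pairing is **greedy
one-to-one** by descending read support (ties by coordinate): each
junction, and hence each read, supports at most one insertion call, which
prevents the combinatorial inflation an all-versus-all pairing would
produce at hotspots. Internal chimeras never pair.

The TSD motif is simply the reference substring between the two junction
coordinates (`extract_tsd_motif()`); a coordinate difference of 0 is a
blunt insertion with an empty motif. `count_distinct_insertions()` treats
exact coordinate pairs as distinct (`merge_tol = 0` by default; the
source analyses state no collapsing tolerance), with an optional tolerance
for noisy data.

## The synthetic-data generator

The generator *defines* the conditions under which the pipeline's
guarantees are stated:

* a linear i.i.d. viral genome of 100 kb at GC 0.41 (alphabaculovirus-like;
  reads never span the circular origin, matching linear coordinate plots);
* TE consensus libraries of 0.4–2 kb with superfamily labels (one default
  length is 831 bp, the length of the motivating non-autonomous piggyBac
  element);
* insertions planted at genuine motif occurrences (TTAA, ATAA, TTA, or
  blunt), with the motif explicitly duplicated on both flanks;
* single-end reads of 101 bp (cell-line-like; 51 bp is the midgut-like
  setting) with uniform starts, Poisson read counts per template, and a
  substitution-only error model — no indels, so junction arithmetic tests
  the pipeline rather than an aligner's gap handling;
* reads drawn from both strands at half depth each, emulating an
  unstranded library;
* negative-binomial count tables with planted log2 fold changes
  (`variance = mu + dispersion * mu^2`; dispersion 0.05 is typical of a
  well-replicated bulk experiment, and three replicates per condition
  match the replication level of the motivating data sets).

The generator does not emulate: sequencing-quality variation, PCR
duplicates, splicing, paired ends, indels, or the time-dependent mixture
of viral and host transcripts (the mixture is left as free template
composition rather than fitted to any profile). Consequently, passing
tests demonstrate the *logic* of the pipeline — coordinate arithmetic,
filters, thresholds, pairing, conservation laws — not robustness to real
alignment noise, which the external-alignment path inherits from the
chosen aligner.

## Numerical choices and degenerate inputs

* Strict versus inclusive thresholds are fixed as stated above (strict
  80/80 copy filter; inclusive >= 4 TPM, >= 0.5 protein coverage,
  <= 5 bp TSD window).
* All generators and simulations are bit-reproducible under a seed, and
  restore the caller's RNG state.
* Empty inputs return typed empty results (aggregation, chimera
  detection, pairing, counting); an all-zero replicate yields `NaN` TPM
  with a warning; an empty gene set yields `NA` distances with a warning;
  zero-variance vectors make correlations `NA` with a warning rather than
  an error.
* Ties are always broken deterministically (alphabetical family for
  multi-family reads, lowest virus coordinate for equal-scoring chimera
  pairs, coordinate order in greedy TSD pairing).

## Problem sizes

The shipped tests and the acceptance script use: a 100-kb genome with 6
families and 20 planted insertions at ~30x junction coverage for the
recovery guarantees (plus a 20-kb / 6-insertion fixture for unit tests); a
5,000-entity table for the DE null; 200 simulated tables of 100 entities
for DE power; 1,000 random tables for TPM conservation; and a 500-row
random hit table for the filter oracle. These sizes were chosen so each
property is measured with comfortable statistical resolution while the
whole suite runs in well under a minute per stage on one CPU.

## Known limitations

* The built-in DE engine is intentionally simple; it is validated for the
  thresholded decision rule, not for calibrated per-entity inference.
* Copy-count replication of any specific genome annotation is not
  promised: external aggregation tools apply undocumented merge
  heuristics, and `max_gap` only approximates them.
* The exact-seed aligner requires error-free reads by design; erroneous
  or real reads must come through the external-alignment path.
* Reads internal to a TE cannot be split between host-borne and
  virus-borne copies; virus-borne expression is therefore a junction-based
  underestimate.
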