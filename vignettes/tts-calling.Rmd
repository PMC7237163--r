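---
title: "Calling transcription termination sites by internal enrichment and peak calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling transcription termination sites by internal enrichment and peak calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termini)
library(dplyr)
```

## The problem

Dense prokaryotic and archaeal genomes leave little room between genes, so
knowing where RNA polymerase actually releases a transcript — the
transcription termination site (TTS) — matters for understanding 3'
untranslated regions, antisense transcription and the regulation of genes
inside operons. Annotation-anchored approaches scan a fixed window downstream
of each annotated gene end; they cannot see termination events elsewhere, and
their window heuristics fail when true 3' UTRs are longer than expected.

`termini` calls RNA 3' ends genome-wide, with no reference to annotation,
from strand-specific paired-end RNA-seq libraries that preserve native 3'
termini (3'-adapter ligation before fragmentation). Annotation enters only
afterwards, to characterize the calls.

## The library model

During library preparation an adapter is ligated to each RNA 3' end, the
first-strand cDNA is then fragmented at random positions, and the resulting
inserts are sequenced as mate pairs. Each reconstructed insert ("fragment")
therefore has one biologically meaningful edge — the RNA 3' end, shared by
every clone of that transcript — and one arbitrary edge, the fragmentation
break point, which is very unlikely to recur across independent clones. A
genuine terminus shows up as many fragments ending at a single position while
starting at many; a PCR duplicate family shows up as many fragments sharing
*both* edges.

Which mate carries the 3' end is a property of the sequencing chemistry, not
of the data, so `read_fragments()` requires an explicit `geometry`:
`"reverse"` (default) when mate 1 maps antisense to the transcript with its
5' alignment edge at the RNA 3' end, `"forward"` for the mirror convention
where mate 2 is the antisense mate. Making this explicit prevents silent
strand flips; the simulator writes SAM under either convention and ingesting
its output with the matching flag recovers the exact fragment set, which the
test suite asserts.

## Internal enrichment (IE)

For a candidate end position $i$, let $C_i$ be the number of fragment ends at
$i$, $J(i)$ the set of start positions linked to $i$ by at least one mate
pair, and $C_j$ the number of fragment starts at $j$. The score is

$$ S_i = \frac{C_i}{\left(\prod_{j \in J(i)} C_j\right)^{1/n}}, \qquad n = |J(i)|. $$

A recurrent natural end linked to scattered break points gives $C_i \gg C_j$
and a large score; a PCR duplicate family gives $C_i = C_j$ and $S_i = 1$
regardless of its depth, which is why duplicates are *not* collapsed by
default (`dedup = FALSE`) — the score itself neutralizes them, and collapsing
would discard the depth information at true termini.

Because only ends, not starts, are biologically enriched, the reciprocally
defined start scores $S_j$ form a realistic null distribution. Each observed
$S_i$ receives an empirical p-value
$p = (\#\{S_j \ge S_i\} + 1)/(N + 1)$; the add-one keeps $p$ strictly
positive at the top score. A site is retained only if it appears in **every**
replicate with $p \le 0.05$ (`alpha`), and the geometric mean of the matched
p-values becomes its combined score.

Choices the source material leaves open, resolved here as defaults:

* the background is pooled across replicons per strand, maximizing background
  size on small genomes (`ie_score_replicate()`);
* replicate matching is exact by position (`match_dist = 0`), the plainest
  reading of "present in all replicates"; a tolerance up to the 10-nt
  intersection distance is available;
* the count floor (`min_reads`, default 1) applies to both end and start
  counts;
* ties in the reported position go to the transcript 5'-most position, for
  deterministic output.

## Peak calling (PC)

Independently of IE, `call_peaks()` tiles each replicon strand with 150-nt
windows advanced in 100-nt steps (50-nt overlap) and z-scores every
position's end count against its window's mean and standard deviation. A
position is reported when, in at least one covering window,

* $z \ge 2$,
* at least 5 fragment ends stop there, and
* those ends are at least 10% of the span coverage at the
  transcript-upstream neighbour (genomic $i-1$ on `+`, $i+1$ on `-`).

Numerical details: the window statistic uses the population standard
deviation (at window size 150 the sample/population difference is
immaterial); windows with zero deviation contribute no calls; trailing
partial windows are evaluated as-is; all threshold comparisons are
inclusive; positions at the replicon edge with no upstream neighbour pass
the 10% rule vacuously. The upstream coverage is insert-span coverage (the
whole fragment, not only read-covered bases); replicates are pooled for PC
by default since the IE stage already enforces replicate consistency.

## From evidence to TTS

`call_tts()` intersects the two evidence sets: an IE site and a PC peak on
the same strand within 10 nt support one TTS, paired greedily by increasing
distance so each evidence site backs at most one call, and the involved
position with the higher pooled end count is reported. Surviving calls
closer than 10 nt are merged to the highest-coverage one (strictly less than
10: calls 10 nt apart are distinct), so reported TTS are always at least
10 nt apart per strand.

With an annotation, each TTS is then:

* **ranked** — walking each strand in transcript orientation, the first TTS
  after a gene 3' end is that gene's `first` TTS and subsequent TTS with no
  intervening feature (gene 3' end, or TSS if a TSS table is supplied) are
  `secondary`, chained to the same gene. The search range is unbounded up to
  the next feature: bounding it would re-introduce exactly the fixed-window
  bias this method avoids. TTS with no upstream same-strand gene keep rank
  `NA` rather than being dropped;
* **classified** — `coding` when inside any annotated gene on either strand,
  else `intergenic`; `antisense` when inside an opposite-strand gene;
* **measured** — `utr_length` is the transcript-orientation distance from
  the upstream gene's 3' end, computed for first and secondary TTS alike;
* optionally **validated** — given a span-coverage track from an independent
  whole-transcriptome library, `utr_continuous` requires coverage of at
  least 1 at every position from the gene start through the TTS.

## The annotation-anchored baseline

`dsm_call()` reimplements the classical downstream-region method for
comparison: per gene, collect same-strand inserts overlapping the gene
(excluding inserts over 500 nt), let the rounded (half-up) mean insert
length define a downstream target region, and report the position with the
highest end count among region positions with at least 4 ends (ties resolve
toward the gene end, mirroring the method's short-UTR bias). Two failure
modes follow directly from the construction and are reproduced
deterministically in the test suite: a true end beyond the mean-insert
region is missed in favour of an internal pile-up, and a gene with two
genuine closely spaced ends yields only one call. `compare_dsm_iepc()`
tabulates overlap (within 10 nt, greedy 1:1) restricted to the regions the
baseline actually examined.

## What the simulator emulates — and what it does not

`simulate_genome()` / `simulate_fragments()` generate the study conditions
used throughout the tests: a single 100-kb replicon at GC 0.65 (a GC-rich
archaeal-like composition), 40 non-overlapping genes on both strands, two
TTS per gene used at fractions 0.7/0.3, first-TTS UTR lengths log-normal
with median 100 nt, 500 fragments per gene per replicate in 3 replicates,
fragment lengths geometric with mean ~60 nt truncated at 100 nt, 75-nt
reads, 2% spurious uniform 3' ends (degradation noise) and 10% PCR
duplicates. A T-stretch terminator (`TTTTT` ending at a `C`) is planted at
each TTS by default; an `AGATC` downstream motif is available. These sizes
keep a full pipeline run around ten seconds on one core while every
statistic (background size, window occupancy, replicate intersection) is
exercised at realistic per-gene depth.

The generator deliberately omits: base-level sequencing errors and mapping
ambiguity (alignment is bypassed — fragments are written as perfect
mate-pair alignments), transcription start heterogeneity, overlapping genes
and operon structure, replicon circularity, and condition-dependent TTS
usage. Passing recovery tests therefore demonstrates the statistics work as
specified under the stated noise channels, not that real libraries are free
of mapping artefacts; on real data the mapping pipeline upstream of this
package owns those effects.

`evaluate_recovery()` matches calls to truth greedily (1:1, nearest first,
±5 nt) and reports recall, precision and median positional error, optionally
stratified by usage fraction or motif class. Precision over an empty call
set is reported as 1 with an explicit `precision_defined = FALSE` flag.

## Degenerate inputs and numeric conventions

* Coordinates are 0-based half-open on the forward strand throughout; the 3'
  gene end is `end - 1` (`+`) or `start` (`-`). Replicon circularity is
  ignored; windows truncate at replicon edges.
* Geometric means are computed in log space; empirical-p tie comparison
  carries a $10^{-9}$ relative tolerance so that mathematically equal scores
  tie regardless of the floating-point path that produced them.
* Positions with no fragment ends are never scored; an empty fragment set is
  an error for the background (there is no null to compare against).
* All output tables are sorted deterministically, and every tie-break is
  documented at the function that applies it; identical inputs and seeds
  yield byte-identical outputs.

## Known limitations

IE requires libraries whose chemistry pins one fragment edge to the RNA 3'
end; it is meaningless on randomly primed libraries. Replicon-edge termini
are scored against truncated windows. The empirical p-values are not
multiplicity-corrected (none is applied by design: the replicate
intersection is the error control). The baseline comparison implements the
published description of the downstream-region method, not any particular
historical implementation of it.
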