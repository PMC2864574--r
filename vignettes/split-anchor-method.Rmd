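---
title: "Split-anchor detection of splice junctions and small indels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-anchor detection of splice junctions and small indels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorsplice)
```

## The method

`anchorsplice` finds splice junctions, small insertions and deletions in
single-end short-read RNA-seq data without using any gene annotation. The
procedure has two stages with a file boundary between them, mirroring the
division between a platform-specific alignment front-end and a general
analysis back-end.

**Stage 1 — split-anchor alignment and candidate detection.** Each read of
length $L$ is split into two anchors of length $a$: its first and its last
$a$ bases. The central $L - 2a$ bases belong to neither anchor. Both
anchors are aligned to the genome independently, on both strands, allowing
at most $m$ substitutions in the seed (defaults $L = 50$, $a = 22$,
$m = 2$). An anchor is *unique* when exactly one locus attains the minimum
mismatch count achieved by that anchor; extra loci at strictly higher
mismatch counts do not break uniqueness (the most permissive reading of
"aligns uniquely"; assessed on the seed, before extension). Each retained
half is then extended base by base toward the read interior while read and
reference agree exactly. If both halves are retained, extension stops at
the boundary of the other anchor's seed; a lone half extends to the read
end — the latter is what makes the rescue rule (below) able to recognise
breakpoints that fall inside the failed anchor.

A read whose two uniquely aligned halves together explain the read but
land on non-contiguous loci becomes a *candidate junction read*, an
oriented breakpoint pair written as one BEDPE record:

* genomic gap $> 0$, no unexplained read bases — junction/deletion type;
* genomic gap $= 0$ with $1 \le k \le L - 2a$ unexplained central bases —
  insertion of length $k$ (the inter-anchor gap geometrically caps
  detectable insertions at $L - 2a$, i.e. 6 nt for the defaults);
* unexplained bases over a nonzero genomic gap — dropped (counted);
* different chromosomes or strands — kept, flagged non-colinear, and
  eventually classified "other rearrangement".

**Rescue (the 5-base rule).** Reads in which only one anchor aligned are
scanned against the candidates: if the lone half's extension ends exactly
at a known candidate breakpoint and the read's next five bases equal the
reference on the far side of the partner breakpoint with no mismatch, the
read confirms that junction. Exactly five bases are compared even when
more are available; ambiguous rescues (more than one matching partner) are
dropped and counted. Rescue can only confirm breakpoint pairs already
present in the gap-split candidate set, never create new ones.

**Stage 2 — grouping, thresholds, classification, FDR.** Candidates are
sorted by (chromosome, left breakpoint, chromosome, right breakpoint) and
traversed once; a candidate joins the open group when both its breakpoints
lie within $d$ bp of the group's first member, on the same chromosomes.
Groups pass when they contain at least `min_reads` reads with at least
`min_unique_starts` distinct read starting points (distinct start
coordinates guard against amplification duplicates). The representative
breakpoint pair is the modal pair among members, ties broken leftmost-left
then leftmost-right. Classification: insertion if the genomic gap is zero
and the modal unexplained-base count is within the insertion cap; deletion
if the gap is positive and either both breakpoints fall inside one
annotated exon (when an exon annotation is supplied — a gap within a
single exon is unlikely to be true splicing) or, annotation-free, the gap
is at most `max_deletion_len`; junction for any other colinear gap; other
for interchromosomal, strand-discordant or inverted groups. Events whose
span exceeds `max_span` (or interchromosomal ones) are withheld from the
junction output but written to a long-range side file rather than
discarded, since they may represent real long-range splicing or fusions.

**FDR under a uniform-placement null.** For the $N$ predicted junctions,
assume a false call places its two breakpoints independently and uniformly
on the pooled genome of length $G$. Given the first breakpoint, the second
must land in a $\pm w$ window of size $2w$, so $p_w = 2w/G$; the expected
number of false calls within $w$ is $N \cdot p_w$ and
$\mathrm{FDR}_w = N p_w / \mathrm{observed}_w$. Edge effects,
per-chromosome geometry and cross-chromosome placement are deliberately
ignored, which is accurate for $w$ much smaller than a chromosome.
Computation uses the unrounded ratio; the print method rounds expected
counts to one decimal and FDR to two significant figures. With
$w = 10^6$ and $G = 2.7\times10^9$, $p_w \approx 7.4\times10^{-4}$.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `read_length` $L$ | 50 | bp | fragment-library short reads |
| `anchor_length` $a$ | 22 | bp | shorter anchors stop mapping uniquely, longer ones shrink the detectable gap; 22 maximises uniquely mapped split reads for 50-bp reads |
| `max_mismatches` $m$ | 2 | subst./anchor seed | tolerates sequencing error without losing the seed |
| `min_reads`, `min_unique_starts` | 2, 2 | reads | "at least two uniquely positioned reads" per junction |
| `max_join_distance` $d$ | 5 | bp | matches the 5-bp tolerance used for junction identity; absorbs overextension scatter |
| `max_span` | unset (e.g. 100 000) | bp | junctions beyond it go to the long-range side channel |
| `max_insertion_len` | 6 | nt | the geometric bound $L-2a$ for the defaults |
| `max_deletion_len` | 20 | nt | annotation-free deletion/junction boundary; annotation mode replaces it |
| FDR windows $w$ | $10^6$, $10^5$ | bp | the distance strata reported |

Extension is strictly exact (zero mismatches): the loosest consequence is
that a junction read with an error in its extended region is lost, never
misplaced. Uniqueness is assessed on the seed because the seed is the
anchor's identity; extension afterwards cannot change where it mapped.

## The simulator

`simulate_dataset()` generates (i) i.i.d.-base chromosomes at a target GC
fraction (default 0.42); (ii) non-overlapping single-isoform gene models
with uniform exon counts (2–5) and lengths (150–300 bp) and log-uniform
intron lengths (200 bp – 150 kb, so short introns dominate but the
long-range path past 100 kb is exercised); (iii) per-transcript
Poisson-distributed insertions (≤ 6 nt, random content) and deletions
(≤ 6 nt) planted inside exons, each recorded as a truth event with genomic
breakpoints and transcript coordinates; (iv) uniformly positioned 50-bp
reads at a chosen depth, half reverse-complemented (the library is not
strand-specific), with independent substitution errors. The default
scenario — 10 genes on a 4-Mb three-chromosome genome, one insertion and
one deletion expected per transcript (about 20 indels in total), 30×
error-free reads — is the configuration used by the recovery tests.

What the simulator does *not* emulate: platform-specific error profiles
(no quality-by-cycle decay, no colour space), read-level indel errors
(substitutions only, matching the substitution-only seed contract),
repetitive or low-complexity genome sequence, overlapping gene loci,
isoform mixtures, and realistic expression-level distributions (depth is
uniform per transcript; a log-normal multiplier is available). Passing
recovery tests therefore demonstrate correctness of the breakpoint
geometry, clustering and classification logic on mappable sequence — not
robustness to mappability artefacts in real genomes, where anchor
non-uniqueness, paralogy and chimeric artefacts dominate the error budget.

## Numerical choices and degenerate cases

* **Coordinates** are 0-based half-open everywhere, including BED/BEDPE
  output.
* **Canonical breakpoint cut.** When the first bases of an intron equal
  the first bases of the next exon (or symmetrically at the acceptor
  side), the two extended halves overlap on the read and the breakpoint
  may sit anywhere in the overlap. The cut is placed at the genomically
  leftmost consistent position, on both strands, so that reads from
  either strand of the same junction produce identical breakpoint pairs.
  The predicted position can therefore be shifted from the annotated
  boundary by up to the shared-sequence length ("overextension"); the
  per-cluster ambiguity width is reported.
* **Ties** in the modal breakpoint pair break to the leftmost pair and
  are flagged.
* **Distance strata are inclusive** (≤ 1 Mb, ≤ 100 kb, span cap
  inclusive).
* **Thresholds use ≥** ("at least two reads").
* Breakpoints within 5 bp of a chromosome end are skipped by the rescue
  index (counted); lone halves with fewer than 5 read bases beyond the
  breakpoint are not rescuable (counted); observed = 0 makes the FDR
  not-applicable rather than infinite; an empty candidate set flows
  through every stage and yields empty, well-formed outputs.
* The chromosome-name map (`chrmap`), when supplied, is applied to all
  outputs at write time only; internal coordinates keep internal names.

## Known limitations

* A junction whose shared-sequence ambiguity exceeds `max_join_distance`
  can be reported as a main call plus a low-support satellite a few bases
  away (both within the ambiguity of the true boundary). Raising `d`
  merges them at the cost of resolution.
* Rescue requires the lone half's maximal extension to stop exactly at
  the candidate breakpoint. At junctions with shared boundary sequence
  this holds for the acceptor-side half but not always for the donor-side
  half, so rescue support is asymmetric there.
* The anchor index is a dictionary scan over the genome per batch —
  adequate for desk-scale genomes (tens of Mb), not engineered for
  mammalian-scale indexes.
* No splice-motif (GT–AG) filtering is applied, by design: the method is
  meant to be unbiased with respect to splicing chemistry, which also
  means artefactual non-canonical breakpoint pairs are not suppressed.
* The uniform null calibrates only distance-stratified junction classes;
  it says nothing about insertions/deletions, for which clean-data
  precision is established by simulation instead.

## Problem sizes used by the test suite

The brute-force oracle comparison runs every 22-mer anchor of 500
simulated reads against a 20-kb two-chromosome genome at 0, 1 and 2
mismatches. The recovery test uses the default simulator scenario above
(≈ 5 000 reads, 4-Mb genome, fixed seed). Smaller fixtures (single
constructed junctions on 4-kb genomes) pin down the exact-stop, rescue and
overextension semantics base by base.
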