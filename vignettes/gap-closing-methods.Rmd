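---
title: "Closing assembly gaps with long-read tag tiling paths: methods and design"
author: "GapTiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closing assembly gaps with long-read tag tiling paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GapTiler)
```

# The problem

Draft genome assemblies built from short reads are delivered as
*scaffolds*: contigs ordered and oriented by mate-pair or linked-read
information, joined by runs of `N` that stand for sequence the assembler
could not resolve. Long reads (PacBio/Nanopore) usually span these gaps,
but their high raw error rate makes direct base-level alignment of whole
reads unreliable. GapTiler closes gaps with long reads using only
coarse-grained anchoring — no consensus calling and no local reassembly —
which makes it fast, memory-light and robust to read error.

# The procedure

## Tag tiling paths

Every read of length $L_A$ is cut into $\lfloor L_A / t \rfloor$
consecutive, non-overlapping *tags* of exactly $t$ bases (default
$t = 300$), starting at its first base; the sub-tag remainder is dropped
so that all tags share one length. The ordered tags form the read's
tiling path, and each aligned tag contributes an anchor point $(p, O)$:
its offset $p$ in the read and the position $O$ of its alignment on a
scaffold.

## Alignment coverage

Tags are aligned to the scaffolds by a pluggable aligner (see below).
Each alignment is scored by

$$\mathrm{Coverage} = \frac{\text{match bases} + \text{insert bases}}{t},$$

where match bases are the identical bases between tag and scaffold and
insert bases are read bases inserted relative to the scaffold (the SAM
definitions; from a SAM record the mismatch count is derived as
`NM - inserted - deleted`, or by counting substitution letters in the
`MD` string when `NM` is absent). Alignments with coverage of at least
0.80 (inclusive) are retained. Insertion-rich alignments can score above
1; the value is deliberately not clamped and the filter is one-sided.

## Three filtration rounds

1. **Orientation vote.** Tags with a single surviving locus ("type 1")
   are grouped per (read, scaffold). If one orientation has strictly more
   unique anchors it wins and the minority is removed; an exact tie
   removes the whole group as error-prone.
2. **Order consistency.** Within a single-orientation group the tag at
   the median read position (lower median for even counts) is the
   reference; every other anchor is kept only if its order relative to
   the reference is the same on the read and on the scaffold. Reverse
   groups compare negated scaffold positions, so consistency means
   anti-collinearity. A two-anchor group is kept or removed as a whole.
   After this round the surviving anchors are strictly monotone.
3. **Rescue of multi-mapped tags.** A tag with two or more candidate loci
   ("type 2") is adopted only if exactly one candidate lies on the same
   scaffold and orientation as its nearest retained unique neighbours on
   the read (one side suffices at read ends), in the right relative
   order, with the read/scaffold distance ratio to each neighbour
   strictly inside $(1-c,\, 1+c)$. Ambiguity leaves the tag unused, and
   rescued tags do not themselves rescue others.

## Gap classification and closure

A gap is a maximal `N` run of length $L_C$. A read *supports* a gap flank
when it has at least 5 retained anchors on that side of the gap and its
anchor nearest the gap lies within the boundary window $W$ (default
1000 bases) of the gap edge. Three cases, attempted in this order:

* **Type 1 — one read spans the gap.** Anchors on the two flanks form
  cross-boundary pairs; a pair $(a, b)$ is retained iff
  $1 - c < \frac{p(b)-p(a)}{O(b)-O(a)} < 1 + c$ (strict; default
  $c = 0.2$). The read with the most retained pairs wins (ties: longer
  read, then smaller id). The read sequence between the two anchor tags
  nearest the boundaries replaces the scaffold interval between those
  anchors' alignments. The gap closes completely with zero inserted `N`.
* **Type 2 — different reads anchor the two flanks.** Per side the read
  covering the largest proportion of the gap wins (ties: more anchors,
  then smaller id; one read may serve only one side). Each read
  contributes its sequence from the nearest anchor to its end, and the
  two pieces are joined over a spacer of
  $N = L_C - (\mathrm{ext}_L + \mathrm{ext}_R)$ `N` characters, where the
  extensions count read bases protruding past the anchors into the gap.
  If the extensions jointly span the gap, exactly 100 `N` are left as a
  sentinel marking a junction that a later iteration may confirm.
* **Type 3 — one flank only.** The best-covering read fills from its
  side; $L_C - \mathrm{ext}$ `N` remain. An extension reaching beyond the
  gap is truncated so that a 100-`N` sentinel remains, mirroring the
  type-2 sentinel rather than fabricating an unverified junction from a
  single side.

Reverse-orientation reads are canonicalised by reverse complement with
$p' = L_A - p - t$ (0-based form) before any interval arithmetic, so a
single forward-frame formula set applies throughout.

The whole cascade iterates (default 3 rounds, stopping early on zero
progress): a partial fill leaves a residual `N` run that is rediscovered
as a smaller gap, and reads can now anchor on the newly filled sequence,
so type-2/3 gaps are routinely finished as type 1 in the next round.

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| `tagLength` | 300 | bases | tag size; anchor granularity |
| `minCoverage` | 0.80 | fraction | alignment retention (inclusive) |
| `minTagCount` | 5 | tags | flank support threshold (inclusive) |
| `maxDeviation` c | 0.2 | fraction | distance-ratio tolerance (open interval) |
| `boundaryWindow` W | 1000 | bases | max distance of the nearest anchor from a gap edge |
| `minGapLength` | 1 | bases | smallest N run treated as a gap |
| `iterations` | 3 | — | maximum closure rounds (early stop on zero progress) |

# Design decisions

* **Boundary support counting.** "Tags at a boundary" are all retained
  anchors of a read strictly on that side of the gap; the window $W$
  constrains only the anchor nearest the gap. A purely windowed count
  would be bounded by $\lfloor W/t \rfloor \approx 3$ anchors and could
  never reach the threshold of 5, so the window gates proximity while the
  count measures evidence.
* **Anchors are excluded from fills.** "The sequence between the two
  tags" starts at the left anchor's end and stops at the right anchor's
  start; the replaced scaffold interval runs between the corresponding
  alignment coordinates. This may rewrite a little flank slack between
  anchor and gap edge — the anchors are the trusted correspondence
  points, and the read represents everything between them better than a
  gapped draft does.
* **Progress guard.** A partial result is emitted only when it strictly
  reduces the gap's `N` count; in particular the 100-`N` sentinel is
  suppressed for gaps of 100 bases or fewer, which keeps the total
  assembly `N` count non-increasing across iterations.
* **Coordinates.** All intervals are 1-based and closed
  (`GRanges`/`substr`/SAM conventions); all formulas are differences, so
  the published arithmetic is unchanged.
* **Ties.** Every argmax has a spelled-out deterministic tie-break
  (pair count, read length, lexicographic id; proportion, anchor count,
  id), so two runs with identical inputs produce byte-identical outputs.
* **Threads.** The `threads` field is forwarded to the external aligner;
  the R-side filtering and closure are serial, making output trivially
  independent of thread count.
* **Precomputed SAM.** A static SAM cannot track assembly edits, so that
  aligner mode performs exactly one iteration (with a warning).

# The aligner contract

The contribution of the method is the filtering and closure logic, not
the aligner, so alignment is pluggable: an aligner is any function
`f(tags, assembly, param)` returning the tag-alignment table.
`bwaAligner()` (default of the command-line driver) shells out to
`bwa mem -a -x pacbio`, reporting all loci so multiplicity
classification sees every candidate. `builtinAligner()` matches tags
exactly with `matchPDict`; it tolerates no errors and exists for
error-free fixtures and tests. `commandAligner()` accepts an arbitrary
command template with `{tags.fasta}`/`{assembly.fasta}` placeholders, and
`samAligner()` consumes a precomputed SAM.

# The synthetic-data generator

`simulateGenome()` draws i.i.d. uniform bases and can plant exact copies
of one repeat unit at non-overlapping loci. `introduceGaps()` derives a
gapped assembly either from random non-overlapping intervals (lengths
uniform in 200–2000 bases by default, echoing the floor at which repeat
regions are typically declared gaps) or by replacing every planted
repeat with an equal-length `N` run — the standard construction for
repeat-derived gaps. Random gaps are placed at least 5000 bases apart
and away from sequence ends, emulating the sparse gap spacing of real
scaffolds and keeping evaluation flanks unambiguous. `simulateReads()`
draws log-normal read lengths (mean 10 kb, log-sd 0.3, clamped at 1 kb),
uniform starts, equiprobable strands, and applies independent per-base
substitution/insertion/deletion errors.

What the generator does *not* emulate: homopolymer-biased indels,
quality-correlated error bursts, chimeric reads, coverage biases and
real repeat families. Passing tests on these fixtures therefore
demonstrate the correctness of the anchoring arithmetic and closure
logic, not performance on any particular instrument's error profile.

# Evaluation against truth

`evaluateClosure()` locates every original gap locus in the closed
assembly by exact match of truth flanks taken just outside the maximal
edit radius ($W + t$), so length changes from complete closures do not
matter. A locus is `closed_exact` when byte-identical to truth;
`closed_diff` otherwise N-free, with an identity percentage from global
pairwise alignment (unit scores) restricted to alignment columns inside
the original gap span — flank context is excluded so the metric measures
the fill itself. Contig N50 is computed over maximal N-free runs, and a
lightweight misassembly proxy (closed loci under 90 % identity, divided
by contig N50) echoes the field's normalised misassembly ratio.

Because a type-1 fill is a verbatim segment of a single read, its
identity to truth is bounded by the read accuracy: with raw reads at
10 % total error the filled loci sit near 90 % identity by construction.
Higher fill accuracy requires error-corrected input reads — the method
itself never polishes.

# Problem sizes

The shipped tests and the acceptance script use a 200 kb genome with 20
random gaps (or 10 planted 500 bp repeats) at 20× coverage — small
enough to run comfortably on a laptop core, large enough that every gap
type, the rescue path and the iteration logic are all exercised. A full
error-free study runs in a few seconds; with bwa on raw-error reads, in
well under a minute.

# Known limitations

* Fills inherit the error of the read they come from (no consensus).
* Scaffolds are never joined or split; terminal gaps can only shrink.
* A gap whose flank contig is shorter than `minTagCount` tags can never
  gain support from that side until an adjacent gap closure extends the
  contig; two such gaps separated by a sliver contig can dead-lock at a
  100-`N` sentinel.
* Placeholder gaps whose `N` count does not reflect true gap size make
  $L_C$ (and hence spacer arithmetic) only an estimate.

```{r session}
sessionInfo()
```
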