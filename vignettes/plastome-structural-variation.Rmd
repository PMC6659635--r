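---
title: "Comparative plastome structural variation: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome structural variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastovar)
```

## The analysis in one paragraph

Chloroplast genomes (plastomes) of closely related plant species are nearly
collinear ~130-160 kb circles with the canonical quadripartite layout: a
large and a small single-copy region (LSC, SSC) separated by two identical
inverted repeats (IRa, IRb). Given a set of such genomes, a multiple sequence
alignment of them, and a time-calibrated phylogeny, `plastovar` (i) detects
the quadripartite partition and the gene-to-junction distances, (ii) extracts
single-nucleotide variants and insertion/deletion *events* from the
alignment, polarized against an outgroup, (iii) places each event on the
timetree by binary-character parsimony and converts per-branch and
root-to-tip counts into occurrence rates in events per million years, (iv)
detects tandem (Rt), palindromic (Rp) and dispersed (Rd) repeats and perfect
microsatellites (SSRs) by exact matching at field-standard minimum sizes, and
(v) tests whether variants are enriched in repeats and their flanks by a
permutation test. A fully logged simulator of plastome evolution generates
genomes, the true alignment and a ground-truth event log, so every stage is
verifiable end to end without external data.

## Coordinates and containers

All coordinates are 1-based closed intervals on the linearized plus strand,
the convention of every container the package uses (IRanges, Biostrings,
R strings); conversion happens only at file boundaries, and GFF3 and GenBank
already use 1-based closed coordinates, so no shifting occurs anywhere. A
single convention throughout is what keeps interval arithmetic safe; adding a
second internal convention would create the very off-by-one risk it is meant
to avoid. Circular genomes are stored linearized at the deposited origin;
features spanning the origin are split into two exon intervals.

## Quadripartite detection

`detect_quadripartite()` seeds on exact 25-mer matches between the sequence
and its reverse complement, merges seed hits along diagonals into maximal
exact runs, and keeps the longest inverted pair of at least `min_ir_len`
(default 1000 bp) whose removal leaves two single-copy arcs. The search runs
on the doubled sequence so an IR spanning the deposited origin is found, and
the result is reported in a canonical rotation (LSC first, then IRb, SSC,
IRa) with an `offset` mapping back to deposit coordinates. Exact matching is
the right model for plastid IRs, which are kept identical by copy
correction; a genome whose IR has decayed below the threshold raises a
`NoIRStructure` error, which the pipeline treats as "IR-lacking" and
continues without region annotation. The default `min_ir_len` of 1000 bp is
a deliberate choice: plastid IRs are 15-30 kb, and no other inverted
repeat in these genomes approaches 1 kb, so the threshold separates the two
populations by more than an order of magnitude.

## Event extraction and its granularity

SNVs are read per alignment column: every column with two or more of A/C/G/T
among non-gap rows yields one event per derived state, with the outgroup
residue as the ancestral state. N is never a state. If the outgroup is gap or
N, the event is flagged `unpolarized` and the majority state stands in as a
provisional ancestral state (ties break alphabetically).

Indels are counted as *events*, not per-taxon differences: one event per
maximal run of consecutive columns sharing an identical gap pattern. Taxa
gapped where the outgroup has residues carry a deletion; taxa with residues
where the outgroup is gapped carry an insertion. Overlapping indels from
different branches therefore stay distinct (they have different gap
patterns), matching the philosophy of phylogeny-aware aligners that keep
events from different branches apart even when they overlap.

Two refinements to the raw run definition matter quantitatively, and both
were adopted after measuring estimator bias on simulations at realistic
event densities:

1. **Carrier-contiguity merge.** Runs with an identical gap pattern separated
   only by columns in which every carrier taxon is also gapped are one
   event: in the carrier genomes that gap is contiguous, and the
   interrupting columns belong to other lineages' events. Without this
   merge, deletions fragment over interleaved foreign columns and deletion
   rates inflate by a few percent.
2. **Dollo resolution of nested insertion fragments.** An inserted sequence
   originates once. When an insertion run is interrupted by a younger
   insertion in a nested subclade (`[big][small][big]`), the outer fragments
   are merged into one insertion. When a nested fragment pair abuts a
   deletion event carried by exactly the taxa missing the small fragment -
   the overhang signature of a real deletion cutting from root sequence into
   the insertion - the fragments merge and the flanking deletion absorbs the
   interior columns. A nested pair with neither corroboration stays two
   independent insertions, because the alignment genuinely cannot
   distinguish an interior deletion from an edge insertion in a subclade.

With both rules, simulated genome-wide insertion and deletion rates are
recovered within the Monte-Carlo error of the simulation (see the acceptance
suite); the residual few-percent discrepancy is the identifiability limit of
deletions strictly interior to older insertions, which no alignment-only
method can see.

Events inside the IRs appear twice by construction; the IRb copy is kept and
the IRa mirror flagged (`ira_mirror`), so one mutation is one event in all
densities and spectra. Whether the per-kb tables pool the two IR copies into
one region is a reporting choice; pooling is the default and the
alternative is a flag.

## Placement and rates

`place_events()` reconstructs each event's presence vector on the rooted
timetree with Fitch small parsimony, the outgroup fixing the ancestral
state. Among minimum-change reconstructions the DELTRAN (delayed
transformation) resolution is used, which pushes ambiguous changes tip-ward
and so prefers recent independent origins over ancient gain plus loss; this
is the conservative choice for events observed in scattered taxa, and the
exhaustive-enumeration property test guarantees the change count is always
the true minimum.

Rates come in two conventions. Per-branch rates divide origin counts by
branch durations. Lineage rates are measured from the ingroup *crown* node
to each tip, divided by the crown age, and the genus-wide figure is their
unweighted mean. The crown (not the root) is the right anchor because events
on the outgroup branch are unpolarizable by construction - an outgroup-branch
deletion is indistinguishable from an ingroup-stem insertion - and mirror
onto the stem with their type swapped. The stem lies outside every
crown-to-tip path, so lineage rates are immune to this artifact; stem-branch
rates are still reported but should be read as conflated. A branch-sum
convention (total origins over summed branch time) is available via
`convention = "branch_sum"`.

## Repeat detection

All finders use exact matching; N never matches anything, including another
N. Minimum copy sizes default to the field-standard 15 bp (tandem), 20 bp
(palindromic) and 30 bp (dispersed); SSRs are perfect arrays of primitive
2-5 bp units with class thresholds of 8/9/12/15 bp total span. Exact
matching is reproducible and oracle-checkable, which approximate tools with
unstated scoring are not; a mismatch tolerance would be a config extension,
not a default. Redundancy rules are codified rather than manual: pairs fully
contained in a longer reported pair are dropped; a tandem array is reported
once at the smallest unit length it supports; adjacent copies are tandem,
not dispersed, and pairs wholly inside a reported tandem array are not
re-reported (precedence Rt over Rp over Rd). SSR motifs are canonicalized by
rotation only, never by complementation, so counts are strand-specific. When
scanning a whole plastome, the IRa copy is masked first - otherwise the
genome-scale IR dominates all palindromic output.

Shared repeats group occurrences of one category whose start positions fall
within 50 alignment columns and whose spans differ by at most 20% (both
configurable); groups carry flags for internal length variation and SNVs.
Group membership vectors feed the same parsimony placement as variants,
giving repeat gain and loss counts per category.

## Enrichment testing

The observed statistic is variants per site over the union of the class
intervals (each site counted once, so overlapping copies cannot
double-count). Each permutation redraws an interval set of identical lengths
uniformly at random without overlap, avoiding the masked IRa so observed and
null share one searchable space, and the one-sided empirical p-value uses +1
smoothing: `p = (1 + #{null >= obs}) / (1 + n)`, never exactly zero. Flank
classes are the 50 bp on each side of every copy with repeat interiors
excluded, so repeat and flank contrasts are disjoint. Defaults of 1000
permutations and a one-sided test are choices; under a uniform null the
p-values are uniform (checked by a Kolmogorov-Smirnov calibration test).

## The simulator

`simulate_plastomes()` draws events per branch as Poisson counts
(rate x duration), applied in drawn order with positions uniform over the
current genome: substitutions under a symmetric single-nucleotide model,
insertions of random sequence, deletions, and tandem duplications that copy
a segment in place. Every residue ever simulated has a unique site id
threaded through a master column order, which yields the true alignment and
a complete, replayable log (`replay()` reproduces every tip bit-exactly).

Defaults describe the study conditions the package targets: 134 kb root
genomes at 39% GC with a 20.8 kb planted IR, a 24-lineage ultrametric tree
with a 15.3 Myr crown and an outgroup at 18 Myr, 7 insertions and 15
deletions per genome per Myr, and an indel length law that is a
two-component geometric mixture (85% short with mean 3 bp, 15% long with
mean 40 bp). The mixture is a calibration, not ground truth: it reproduces
the strongly short-skewed spectra reported for real plastomes (roughly 82%
of indels under 10 bp and 99% under 100 bp) while keeping both components
interpretable. Substitutions hitting the planted IR are mirrored to the
paired site to emulate plastid copy correction; indels are *not* mirrored,
so simulated IRs decay under long, indel-rich histories - a known
simplification that makes IR detection on deeply evolved tips conservative.
What the simulator does not model: codon-level selection, recombination,
base-composition heterogeneity along the genome, and alignment error (its
alignment is true by construction, so passing tests say nothing about
aligner artifacts on real data).

The guard bases at the four planted-IR junctions (fixed so the exact-match
detector cannot extend the IR by a chance flanking match) are part of the
root-genome construction, keeping "detected junctions equal planted
junctions" an exact statement.

## Problem sizes used in the test suite

The oracle-equivalence suites run the repeat finders against brute-force
enumerations on 100 random 2 kb sequences per finder, event extraction
against an independent column-scanning oracle on 200 random alignments of
up to 8 taxa and 400 columns, and parsimony placement against exhaustive
minimum-change enumeration on 500 random presence vectors over trees of up
to 6 tips. Rate recovery simulates the full study conditions (134 kb, 24
ingroup tips, 15.3 Myr crown) over 20 seeds and requires both mean lineage
rates within 3 Monte-Carlo standard errors. Enrichment calibration uses 200
replicate null datasets at 199 permutations each. These sizes were chosen so
each suite gives stable verdicts at desk scale; all fixtures are generated
in code under fixed seeds.

## Known limitations

* Outgroup-branch indels are systematically re-polarized onto the ingroup
  stem with swapped type; any outgroup method shares this, and crown-based
  lineage rates are immune.
* Deletions strictly interior to older insertions are invisible as
  deletions; their fragments are read as two insertions.
* Exact repeat matching means a single substitution splits a repeat copy;
  shared-repeat grouping across genomes tolerates this (it groups by
  position and span), but per-genome counts of old, decayed repeats will be
  lower than mismatch-tolerant tools would report.
* The GenBank reader handles single-record flat files with
  join/complement locations - the deposited-plastome case - not the full
  format grammar.
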