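---
title: "Methods: models, parameters and design choices in pirnakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in pirnakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnakit)
```

# Scope and coordinate conventions

`pirnakit` implements the analysis steps used to characterize piRNA master
clusters such as Drosophila *flamenco*: TE-copy annotation, weighted
small-RNA counting, cluster calling, ping-pong scoring, cross-genotype
insertion panels, horizontal-transfer calling, and assembly QC, together
with seeded synthetic-data generators that make all of it testable without
external downloads. Genome assembly, read mapping and repeat-library
construction are out of scope: assemblies, RepeatMasker annotations and
alignments are inputs.

Every genomic interval inside the package is **0-based half-open**; readers
convert at ingestion (RepeatMasker `.out` is 1-based inclusive, BED is
0-based) and writers convert back, so a single convention holds everywhere.
Consensus coordinates on TE family models remain 1-based inclusive,
matching RepeatMasker.

# TE-copy merging and classification

RepeatMasker reports fragments; biology cares about copies. Two adjacent
fragments belong to one copy when they lie on the same contig and strand,
resolve to the same family, are separated by at most `max_gap` genomic nt
(default 5000), and advance consistently along the family consensus —
non-decreasing consensus intervals for `+` copies, non-increasing for `-`,
with at most `max_overlap_cons` nt of overlap (default 30). The defaults
are deliberate plumbing, not biology: distance- and order-based joining is
how fragment mergers in this field behave, and both knobs are recorded in
the copy table so downstream users can see what produced it.

Libraries frequently annotate LTR retrotransposons as separate `FAMILY_LTR`
and `FAMILY_I` models. These are resolved to one family before merging;
internal-segment coordinates are shifted past the 5' LTR, and an
LTR-segment hit is assigned to the 3' LTR exactly when internal sequence of
the same element precedes it in element orientation (within `max_gap`,
uninterrupted by whole-model hits). This is a heuristic; it is correct for
the component orders RepeatMasker actually emits, and the generator
exercises both orientations.

**Completeness** is the covered fraction of the consensus (union of
fragment consensus intervals, computed with `IRanges`). Classification:

* non-LTR: full length iff completeness ≥ 0.70, the boundary inclusive
  (0.70 passes, 0.699 does not);
* LTR: additionally each LTR region and the interior must be ≥ 50% covered.
  The 50% presence rule is a lenient package choice — no tolerance is
  standard — and is configurable;
* an LTR-family copy covering only LTR sequence (zero interior coverage) is
  a **solo LTR**, the recombination product of two LTRs;
* everything else is a fragment.

Composition statistics define *antisense* relative to a caller-supplied
cluster strand (the transcription direction of the locus promoter), because
"antisense" at a uni-strand cluster only has meaning relative to the
precursor transcript. Window enrichment assigns an element to the tiling
window containing its start; start-assignment is the simplest reproducible
rule when elements straddle boundaries. The window defaults to 100 kb with
the size as a free parameter, since both 100-kb and per-megabase
conventions are in circulation for Ty3/mdg4 enrichment profiles.

The trap-model report computes two family sets over classified copies:
families with ≥ 2 full-length antisense copies, and families with ≥ 1
full-length copy plus ≥ 1 antisense fragment diverged strictly less than
10% from the consensus. The strict bound matters: an 8%-diverged fragment
counts, a 12%-diverged one does not.

# Weighted counting and ping-pong scores

A read mapping to *n* genomic places contributes 1/*n* at each placement
(weighted mode), so each read carries unit mass in total; unique mode drops
multimappers entirely. Both modes run through every counting surface
(feature counts, histograms, cluster calling, ping-pong stacks), with
weighted as the default since repeat-derived piRNAs are the object of
study.

Ping-pong amplification leaves +/− read pairs whose 5' ends overlap by
exactly 10 nt. For each `+` 5'-end stack at position *p* we take the
weighted `-` 5'-end counts at `p + o - 1` for offsets `o = 1..20`; offset
10 is the ping-pong configuration and the other 19 are its local
background. The score is the mid-rank of the offset-10 count among that
background,

$$\mathrm{score} = \frac{\#\{o \ne 10 : c_o < c_{10}\} + \tfrac12\,\#\{o \ne 10 : c_o = c_{10}\}}{19} \in [0,1],$$

so an isolated planted pair scores 1 and a flat background scores 0.5. The
score is a rank, hence invariant under uniform scaling of stack heights.
Design choices worth stating plainly:

* The cited class of tools reports a z-like score in [0, 1] that "takes
  into account" local coverage and the 10A bias without an explicit
  formula. We reimplement the idea as the auditable mid-rank above and
  report the partner-stack 10A fraction **separately** rather than folding
  it into the score; thresholds 0.8/0.9 keep their conventional role as
  reporting cuts.
* Pairs are anchored on `+` stacks only, so each 10-nt overlap is counted
  once. Strand-swapping on coordinate-reversed data maps the analysis onto
  itself with anchor and partner exchanged, which the suite checks.
* Sites are emitted only when both the anchor and the offset-10 partner
  stack are non-empty; a rank against an all-zero background is
  uninformative and c10 = 0 sites would be pure noise.

A known limitation follows directly from the rank construction: a chance
isolated +/− pair of single reads is indistinguishable from a tall planted
pair, because ranks ignore magnitude and any scale-invariant local score
must. Specificity therefore depends on background read density. The
calibration generator places background stacks at 0.2 per position in
total (split across strands, heights Poisson); at that density the
measured background rate of score ≥ 0.9 positions is ≈ 0.8%, against 100%
recall of planted height-15 stacks.

# Cluster calling

Sliding windows (1 kb window, 500 nt step) are scored by weighted 5'-end
count. Under a uniform-placement null the count is Poisson with mean
`lambda = N * window / L_total`. A window is significant when its
Bonferroni-adjusted upper tail clears the density p-value:
`n_tests * P(X >= k) <= 0.07`, with `n_tests` the number of sliding windows
evaluated genome-wide. The adjustment is the package's realization of a
"minimum read density with p-value 0.07" criterion: it calibrates the
density threshold against the whole scanned genome, holding the expected
number of falsely significant windows per scan below 0.07 regardless of
genome size (measured on simulated 1-Mb uniform backgrounds: ≈ 0.03 false
clusters/Mb). An uncorrected per-window test at p = 0.07 would mark ~5% of
null windows significant by construction and is not a usable cluster
caller.

Overlapping significant windows merge into candidate loci; each locus must
then pass four reported criteria — length ≥ 1 kb, weighted 1U-or-10A
fraction ≥ 0.33, top-1% distinct-sequence share ≤ 90%, main-strand
fraction ≥ 0.25 — with per-criterion flags in the output so a rejection is
always attributable. The top-1% rule operates on distinct read sequences
(`ceiling(0.01 * D)` of `D` distinct sequences, by weighted count), which
makes it scale-free in library depth. Clusters are called uni-strand at
main-strand fraction ≥ 0.75, else dual; the 0.75 cutoff is a package
convention (configurable), chosen so that clearly bidirectional loci
(~50/50) and clearly directional loci (> 90/10) fall on the intended sides.

Locus anchoring and delimitation mirror how *flamenco*-like clusters are
located in practice: find the conserved core promoter by exhaustive
mismatch scan (both orientations), then extend from the anchor window in
the transcription direction through windows with enough TE enrichment,
tolerating a bounded run of below-threshold windows, and report why
extension stopped (threshold or contig end) — the latter matters when a
locus runs into a contig break.

Assembly QC compares per-window coverage and soft-clip rates inside a
target region against the 99% quantiles of benchmark windows (conserved
single-copy genes, e.g. a BUSCO set; any such BED works). At least 20
benchmark windows are required for the quantile to be meaningful. With two
metrics and type-7 quantiles, up to one window per metric can exceed its
own q99 in small benchmark sets; the suite asserts the per-metric bound.

# Comparative panels and horizontal transfer

Insertion homology across genotypes is determined by synteny: TE
annotations (ordered tokens, not sequences) are aligned by global dynamic
programming with match +0.2, mismatch −0.1, gap −0.09, maximization, ties
broken match > mismatch > gap then leftmost. Tokens match when they share a
family group (a user-supplied equivalence table substitutes for manual
reconciliation of near-identical families like *mdg4-3*/*mdg4-5*) and, by
default, strand. The implementation is checked against an exhaustive
enumeration of all monotone pairings on lists up to length 8.

Panels are star-progressive around a reference genotype: matched tokens
join reference-seeded columns; unmatched tokens form insertion columns
keyed by flanking anchor, family group, strand and occurrence order, merged
across genotypes. Mismatch pairings are deliberately *not* treated as
homology — a forced pairing of different families says the DP found no
better option, not that the copies are orthologous. Star alignment cannot
distinguish two same-family private insertions falling between the same
reference anchors in different genotypes; with family-rich annotation this
is rare, and the panel generator uses a 30-family pool precisely so that
ground-truth homology is well-defined. Sharing spectra count columns by the
number of carriers; a copy full length in one genotype and fragmented in
others is shared, not private, but must be full length somewhere to enter
the full-length-only spectrum.

Percent identity is computed from a global Needleman–Wunsch alignment
(unit match/mismatch, flat unit gap cost, via `Biostrings`), as matching
columns over columns where both sequences have a base; gap columns are
excluded by default (configurable), and the pair is canonically ordered
before alignment so the function is exactly symmetric. Horizontal transfer
is called strictly above 98% identity — 0.98 exactly is vertical — against
a 93–97% vertical-descent baseline (the R1 element, which moves only
vertically); `ht_params()` warns when a user-supplied baseline overlaps the
threshold. Transfer direction is never inferred. The restriction-digest
utility matches IUPAC-degenerate motifs on the forward strand,
case-insensitively, and conserves total length by construction.

# Synthetic data: what it does and does not emulate

Generators are seeded (`sim_config(seed)`; each generator derives a fixed
offset stream) and deterministic: identical configurations give identical
outputs. Every emitted record traces to one truth entry via ids, and the
recovery tests close the loop module by module.

Defaults encode the study conditions the recovery tests assume: 200
insertions at 79% antisense; a seven-genotype panel of 200 columns with a
54%/46% private/fixed sharing mix; read lengths peaked at 26 nt with 1U and
10A probabilities of 0.8; multimapper counts equal to the planted family
copy number capped at 50; planted ping-pong stacks of height 15 at 20
positions over background stacks at 0.2 per position; a planted 5-kb
cluster carrying 5000 of 15000 reads on a 1-Mb contig. Problem sizes
(50-seed calibrations, 1-Mb contigs, 10 panel replicates in the acceptance
script) were chosen so each recovered proportion's Monte-Carlo error is
several times smaller than its tolerance while the full suite runs in
about a minute.

Deliberate simplifications, and what they mean for interpreting green
tests: background sequence is i.i.d. uniform ACGT — no heterochromatin
base composition, no nested insertions, no satellite arrays; truncation of
fragments is uniform over consensus windows; divergence is substitution-only
(no indels), so annotation coordinates are exact; insertions are spaced
more than `max_gap` apart so planted copies map one-to-one onto merged
copies — real tandem or nested copies of one family can legitimately merge
or split, and the tests do not probe that regime; there are no sequencing
errors or quality scores. Passing tests therefore demonstrate that the
algorithms implement their definitions and recover planted truth under
clean conditions, not that annotation of real heterochromatic assemblies
is this well-behaved.

# Numerical and degenerate-input choices

* Poisson tails use `ppois(k - 1, lambda, lower.tail = FALSE)` on the
  ceiling of weighted counts; weighted counts are real-valued, and the
  ceiling makes the test conservative.
* Mid-rank scores are clamped to [0, 1] against floating-point drift; ties
  in the length histogram resolve to the smallest length; the DP traceback
  preference (diagonal match, diagonal mismatch, gap in the second list,
  gap in the first) makes alignments deterministic.
* Empty inputs: empty record sets yield empty cluster calls; empty copy
  lists are an error for composition (percentages undefined); a region
  with no high-scoring ping-pong sites returns `NA` rather than 0, since
  "no signal" and "no signal inside" differ.
* All-sense copy sets report the antisense-LTR percentage as `NA`.
* `read_small_rna` skips unmapped SAM records with a logged count and
  refuses negative coordinates; hit counts fall back from the NH tag to
  read-id multiplicity to 1.

# Known limitations

Star-progressive panels understate sharing slightly when same-family
private insertions co-occur between the same anchors (measured ≈ 2 points
on the default panel); full multiple alignment of annotations would remove
the bias at substantial complexity and is out of scope. The ping-pong
score's rank construction cannot separate chance single-read pairs from
real stacks in very sparse data. The cluster caller's null assumes uniform
read placement; structured backgrounds (rDNA arrays, tRNA clusters) will
violate it and should be masked upstream. The promoter scan is ungapped by
design — indel-tolerant anchoring belongs to an aligner, not to this
package.
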