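---
title: "Coordinate translation through synteny-map graphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate translation through synteny-map graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntrans)
library(data.table)
```

## The problem

Comparative genomics constantly needs to move annotated features —
exons, transcripts, regulatory elements, arbitrary intervals — from one
genome's coordinate system into another's. Sequence similarity alone
cannot resolve which of several paralogous copies is the ortholog;
conserved synteny (the preserved local order and orientation of
genomic features) can. Whole-genome synteny maps, however, are
expensive to compute, and an all-to-all set over N genomes costs
O(N^2) alignments.

`syntrans` avoids the all-to-all requirement: genomes are nodes of an
undirected graph whose edges are the pairwise synteny maps that happen
to be available, and coordinates are translated *indirectly* along a
fixed shortest path through that graph, with sequence-level refinement
at the destination recovering the exactness that the hop-by-hop
interval arithmetic alone would lose. The cost of adding a new genome
is then a single synteny map against any already-connected genome.

## The pipeline

For each source interval, four stages:

1. **Candidate location.** On each hop of the fixed path, the interval's
   start and end are looked up among the hop's synteny anchors (binary
   search over the source-sorted anchor index). A position inside an
   anchor is interpolated proportionally; a position between anchors
   widens the candidate to the flanking anchors' target bounds. A
   candidate whose bounds land on one scaffold in consistent
   orientation within `break_span_nt` passes through; otherwise it is
   split into two `split_span_nt` windows, one anchored at each bound,
   so the boundary of the syntenic break can still be searched.
2. **Rapid alignment.** The source sequence is located inside the
   (possibly large) candidate by summed per-channel FFT
   cross-correlation of one-hot encoded sequence, blockwise over
   windows of `2^block_log2` nucleotides that overlap by
   `|source| + 2*flank_nt` (so no full-length placement straddles a
   block boundary). The best absolute peak defines a tight region of
   size `|source| + 2*flank_nt`.
3. **Local re-alignment.** A banded three-state (Gotoh) local alignment
   with gap-affine penalties against the tight region gives the exact
   coordinates. Sources longer than 100 nt are split into two 100 nt
   end chunks aligned independently. Alignments need not cover the
   whole source: if an alignment starts `k` nucleotides into the
   source, the reported target start is adjusted by `-k` (and
   symmetrically at the stop), which keeps boundaries exact when
   terminal mismatches are soft-clipped.
4. **Feature matching.** Translated transcripts are compared with
   annotations native to the target genome and each relationship is
   classified: full sense overlap (every source exon overlaps some
   target exon *and* vice versa, same strand), partial sense, intronic
   (sense/antisense), antisense (full/partial), or none.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `flank_nt` | 12 | nt | flank around the correlation peak; also anchors the alignment band |
| `block_log2` | 14 | — | FFT block size 2^14 nt |
| `break_span_nt` | 100000 | nt | maximum un-split candidate span |
| `split_span_nt` | 50000 | nt | size of each split side; also the widening cap past terminal anchors |
| `pvalue_threshold` | 1e-4 | — | acceptance threshold for refined alignments |
| match / mismatch / gap open / gap extend | +1 / −1 / −3 / −1 | score | conventional nucleotide scoring; penalties are config-exposed, a gap of length L costs `gap_open + L*gap_extend` |
| `band_halfwidth` | `flank_nt + 4` | nt | alignment band; must cover every placement the candidate region allows |

All of these are exposed through the configuration file and the
command-line wrapper (`inst/scripts/syntrans.R`).

## Design choices in detail

**Coordinates.** Internally everything is 0-based half-open; GTF and
anchor files are 1-based inclusive at the boundary only. A single
conversion point keeps interior arithmetic safe. Reverse-orientation
anchors are stored with ascending coordinates on both sides plus an
orientation flag, so one binary search serves both orientations.

**Anchor interpolation.** Anchors may differ in source/target length
(real synteny maps summarize gapped alignments), so a position inside
an anchor maps by proportional offset, computed as `(off * tlen) %/%
slen` — exact in double precision for genomic magnitudes, where the
algebraically equivalent `off * (tlen/slen)` is not.

**Widening.** Between anchors, the candidate bound comes from the
flanking anchors' inner target bounds — the tightest choice that still
brackets the ortholog under colinearity. Beyond the first or last
anchor of a scaffold the bound extends outward by `split_span_nt`,
clipped at the scaffold end; unbounded widening would swallow whole
scaffolds.

**Per-hop splitting.** The split test runs after *every* hop, not only
at the final genome. On multi-hop paths this keeps candidates from
growing without bound; a candidate that is already one side of a split
keeps only its own side if it splits again, capping the candidate
count at two per feature. This is a containment-preserving
strengthening of the final-stage split.

**Path choice.** Shortest path by hop count, or by accumulated genomic
distance when the configuration supplies per-map weights (the package
never estimates distances itself). Equal-cost ties resolve to fewer
hops, then the lexicographically smallest genome-name sequence, so
runs are reproducible. The path is fixed before translation begins and
never re-routed around a failed hop; per-hop failure reasons are
reported instead.

**Signal encoding.** One indicator channel per base, mean-centered per
channel per block; N contributes zero to all channels. Centering
removes genome-composition bias that otherwise produces spurious
correlation plateaus. Zero-padding to the next power of two removes
circular wrap-around, making the blockwise FFT correlation exactly
equal (to floating tolerance) to the naive sliding dot product — a
property the test suite asserts against a brute-force oracle.

**Significance.** The p-value of an alignment with `m` matches over
`L` columns is the binomial tail `P(X >= m)`, `X ~ Binomial(L, 0.25)`
— the chance a random same-length alignment matches at least as well.
For *acceptance* the trial count is `max(L, source length)`: with the
aligned length alone, a chance 8-mer exact run inside a long probe
would already reach p < 1e-4, so clipped source bases count as
non-match mass. Soft-clipping remains permitted (terminal mismatches
are not forced into the alignment); it simply cannot make a bad
placement look significant. The binomial model itself is a documented
choice behind the `alignment_pvalue()` surface and can be swapped.

**Reverse orientation.** When the composed anchor orientation is
reverse, the source is searched and aligned against the reverse
complement of the candidate region and coordinates are mirrored back;
the output GTF strand is flipped accordingly.

**Overlap classification.** "All exons overlap all exons" is read as
bidirectional coverage (every source exon hits some target exon and
vice versa); literal all-vs-all pairwise overlap is geometrically
impossible for more than one exon. Overlap means at least one shared
nucleotide — no minimum-fraction rule. A transcript overlapping exons
of one locus and introns of another reports both records; summaries
keep the best class under the precedence full > partial > intronic >
antisense.

## The simulator

The test substrate is a deterministic genome-evolution simulator: an
ancestral genome (uniform random sequence) evolves along a star, chain
or clade topology into 2–4 descendants. Per branch, mutation order is
fixed — inversions and tandem duplications first (segment level), then
small indels (geometric lengths), then substitutions — so the
coordinate bookkeeping is layered and auditable. Every edit updates an
exact piecewise-monotone coordinate map; the simulator therefore emits
genomes, *exact* synteny anchors, planted multi-exon gene models
(2–5 exons, 1–3 isoforms) carried through the map into every genome,
and a manifest of every exon's true coordinates (or its loss).
Duplicate copies are excluded from the canonical truth map and the
emitted anchors: upstream synteny aligners are assumed to have
resolved orthology among paralogs, which is exactly the assumption the
real tool makes. An optional jitter mode trims anchor ends by 0–20 nt
and drops 5% of anchors to mimic the raggedness of real maps and
exercise the widening and splitting logic.

Default study conditions: ~1 Mb per genome over two scaffolds, 5%
per-site substitutions, indel rate 2e-4 with mean length 3, two
inversions (5–50 kb) and one tandem duplication (1–10 kb) per branch,
60 planted genes. At this scale the full direct-versus-indirect
experiment (1,000 random 200 bp blocks, two routes) and the planted
gene translations run in well under five minutes on one CPU.

**What the simulator does not emulate** — and hence what passing tests
do not show about real data: realistic substitution processes
(transition bias, rate heterogeneity, GC content), transposable
elements and other repeats (the main source of cross-correlation
ambiguity in real genomes), assembly gaps and errors, whole-genome
duplication, and synteny-map noise beyond end-trimming jitter. The
acceptance thresholds met on simulated data are therefore upper bounds
on real-data behavior, not estimates of it.

## Numerical and degenerate-input choices

* Integer interpolation truncates toward the anchor start (`%/%`);
  monotonicity within an anchor is preserved in both orientations.
* A target interval shorter than `source + 2*flank` is correlated
  directly as one unpadded block; a source longer than a block is an
  error at the scan stage (end chunks are used upstream).
* Alignment tie-breaks are deterministic: at equal score the
  traceback prefers stop over diagonal over target-gap over
  source-gap, and the best cell is the first one reached in row-major
  order — clipped terminal ties are then restored by the `-k`
  boundary adjustment.
* Unparseable map rows abort by default; `skip_bad_rows` downgrades to
  a counted warning. Silent coordinate corruption is the worst failure
  mode of a liftover tool.
* Empty annotation sets, features with no anchor on their scaffold,
  and disconnected genome pairs are all explicit, named outcomes —
  the first two are per-feature results, the last is an error naming
  both genomes.

## Validation strategy

Every fast path has an independent slow oracle in the test suite:
binary-search anchor lookup against a linear scan; the FFT correlation
against the O(nm) sliding product; the banded Rcpp Gotoh against an
unbanded full-matrix Gotoh written separately in vectorized R; the
sorted-index overlap classifier against a quadratic brute force; graph
shortest paths against exhaustive path enumeration; binomial tails
against values frozen from an arbitrary-precision rational
computation. End-to-end properties (identity fixtures translate
exactly; round trips contain their origin; substitution-only
candidates always contain the truth; direct and indirect routes agree
on ground-truth segments; planted exon boundaries are exact) run on
the simulator at the scales stated above.

## Worked example

```{r example, eval = FALSE}
library(syntrans)

fx <- evolve(evolution_spec(seed = 1))      # A -> B -> C chain, ~1 Mb each
graph <- build_graph(names(fx$genomes), fx$maps)

rt <- run_translate(fx$genomes, graph, fx$genes, "A", "C",
                    target_annotation = fixture_annotation(fx, "C"))
rt$report$path          # "A->B->C"
run_evaluate(fx$manifest[genome == "C"], rt$results)
```

## Known limitations

* One path per genome pair; no multi-path voting and no re-routing
  around a failed hop.
* Anchors are trusted to be orthology-resolved; paralogous candidate
  regions are not re-ranked probabilistically.
* Exons are translated independently (GTF item granularity); there is
  no spliced alignment across introns.
* Whole-genome loading only — no indexed random access to FASTA.
* The binomial significance model ignores alignment score structure;
  it is deliberately simple, exact, and swappable.
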