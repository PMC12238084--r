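---
title: "Methods: tandem-repeat probe design and in-silico karyotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tandem-repeat probe design and in-silico karyotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatprobe)
```

## Scope and model

`repeatprobe` implements the computational backbone of repeat-based
oligo-FISH probe design for large plant genomes: tandem repeat (TR)
discovery, redundancy removal, probe design, electronic (in-silico)
localization, and karyotype comparison. Satellite tandem repeats — a
monomer of period 1 to ~2000 bp repeated tens to tens of thousands of
times — form megabase arrays that make ideal FISH targets because a short
labeled oligo hybridizes to hundreds of adjacent copies at one chromosomal
site. The pipeline turns an assembly into a small panel of named probes
and predicts, per chromosome, where each probe will light up.

## Wraparound alignment scoring

An array is scored by aligning its genomic segment against an unbounded
head-to-tail concatenation of a candidate monomer. The dynamic program
runs over monomer columns cyclically (after the last column the alignment
re-enters column 1 — "wraparound" DP), the whole segment must be
consumed, and the entry/exit columns are free. The score is

```
score = match * matches - mismatch_penalty * mismatches - indel_penalty * indels
```

with default weights 2 / 7 / 7 and a minimum reported score of 50
(inclusive), the parameterization under which the probe set was derived.
A perfect k-copy array therefore scores exactly `2 * length`, and the
smallest reportable perfect array is 25 bp. Wraparound columns are
propagated within each row by repeated left-to-right sweeps; with a
positive indel penalty the propagation converges after at most two
sweeps. `N` bases never match. The implementation is exact (C++ kernel);
the test suite checks it against an independent fitting-alignment oracle
on hundreds of random instances up to 100 bp. Memory is
`O(segment x period)` for the traceback, which is the practical limit for
very long arrays scored in one piece.

Copy number is reported as span / period, to one decimal, matching the
`.dat` convention of tandem-repeat scanners; percentages of matching and
indel columns are taken from one optimal traceback.

## The detector

The full statistical candidate model of Tandem Repeats Finder is not
re-implemented; the binding filter here is the score threshold, and
candidate discovery is deterministic and seed-based:

1. **Seeding.** Exact k-mers (default k = 13, shrunk to `floor(len/2)` on
   very short sequences so that short test arrays remain detectable) are
   paired with their nearest previous identical occurrence; each pair
   votes (position, distance), with distances capped at the maximum
   period (2000 bp).
2. **Clustering.** Per distance, seed positions closer than
   `max(4 x distance, 300)` bp are chained; chains need at least two
   seeds, which suppresses isolated chance k-mer repeats in random
   background.
3. **Period estimation.** Within a chain's span the fundamental period is
   chosen by divisor voting: among divisors `q` of the modal seed
   distance, the self-match fraction `mean(s[i] == s[i+q])` is computed
   and the smallest divisor within 90% of the best fraction (and at least
   0.6) wins. This keeps 50-copy arrays from being reported at a harmonic
   (2x) period, which would halve their copy number below the filter.
4. **Boundary refinement.** Bounds extend outward while the periodic
   phase keeps matching (tolerating two consecutive failures), then edge
   bases that break phase are trimmed, so perfect arrays keep exact
   boundaries.
5. **Consensus and re-scoring.** The consensus is the column-majority
   monomer over full frames (ties broken alphabetically), and the final
   coordinates, copy number, match/indel percentages and score come from
   the exact wraparound DP of the segment against that consensus.

Arrays with more than 20% `N` content are dropped. `Pm`/`Pi`
(probability-of-match/indel) are accepted in the configuration for parity
with the original parameterization but act only as documentation of the
intended tolerance; they do not gate candidates here.

Overlap elimination follows the filter question left open by the original
pipeline description: the default order is eliminate -> filter, the order
in which the steps are written there. De-overlap is greedy best-first —
descending score, ties by longer span, then smaller start, then input
order — so retained intervals are pairwise disjoint per chromosome and
every discarded array overlaps a retained array of at least its score.
Filtering retains arrays with period >= 10, copies >= 50 and percent
matches strictly > 70, exactly as printed; the published unit-length range
("1 to 1138 bp" among kept arrays) is inconsistent with the stated period
filter, and this toolkit simply applies the stated filter.

## Monomer clustering

Redundant monomers are collapsed with greedy incremental clustering in
CD-HIT's style: monomers sorted by descending length, first-fit assignment
to the first representative at >= 75% identity, otherwise a new cluster.
The identity metric is a global Needleman-Wunsch alignment with unit
weights that maximizes (score, matches) lexicographically; with unit
weights every such optimum has `columns = 2 * matches - score`, making
`identity = 100 * matches / columns` traceback-independent and symmetric —
a property the test suite asserts. Reverse-complement orientation is
always considered (satellites are recovered in either orientation);
rotation scanning is off by default because greedy incremental clustering
of linear sequences does not rotate, but tandem monomers are phase
ambiguous, so an opt-in flag maximizes identity over cyclic rotations of
the shorter sequence. The 75% threshold is used as the clustering cutoff
and probes are designed from representatives, which resolves the
ambiguity between "redundancy cutoff" and "design cutoff" in the original
description in the simplest way.

## Oligo design

Candidates are every window of each allowed length (default 40-45 nt;
the realized published set spanned 30-50 nt, available by overriding the
range) over the monomer in tandem context — the monomer concatenated with
itself so windows may span the junction. Every candidate is therefore a
substring of a real array of that monomer. Screens: GC within 30-70%,
no homopolymer longer than 6 nt, and no self reverse-complementary stem
of 8+ nt (a deliberately simple, testable hairpin proxy rather than full
secondary-structure folding). Survivors are ranked by closeness of their
nearest-neighbor melting temperature (unified NN table, 50 mM Na+,
200 nM oligo) to the candidate pool's median Tm — a central Tm makes
probes of one cocktail behave uniformly — and the top probe per cluster
is kept. Only the relative Tm ranking matters, so the exact thermodynamic
constants are not load-bearing.

Probe naming reconstructs the published convention, whose generation rule
was not stated: `C{chrom}-{i}` when one chromosome holds at least 30% of
the in-silico hits, `Co-{i}` for dispersed probes, `Tel-{i}` when the
monomer is a cyclic rotation (or tandem multiple) of the plant telomeric
motif TTTAGGG on either strand, `U-{i}` when unplaced. The 30% dispersal
cutoff is this package's choice; names are injective within a run.
Cocktails group probes by fluorophore channel (`Multiplex #1`,
`Multiplex #2`, ... in channel order); replaying the published assignment
yields the 7-probe TAMRA and 4-probe FAM cocktails.

## Electronic localization

BLAST is replaced by an ungapped sliding-identity scan: for a 30-50 nt
oligo at the >80% identity threshold, gapped alignment adds no practical
sensitivity, and the Hamming model is exactly testable against a naive
oracle. Every window of probe length on both strands with identity
strictly greater than 80% is a hit (so 9 substitutions in a 45-mer —
exactly 80.0% — are excluded and 8 are included); window matching runs
through `Biostrings::matchPattern` with the equivalent mismatch bound.
Plasmid-scale probes (e.g. a 45S rDNA clone) are fragmented into 500-bp
windows at 250-bp steps, each scanned as an oligo, and overlapping hits
merged per site.

"Chromosome positions" are interpreted as fixed, non-overlapping 1-Mb
bins anchored at coordinate 0 (the original granularity is unstated, so
bin size is configurable). A bin becomes a locus when its count is
strictly greater than 30 (oligo rule, per probe) or its density strictly
greater than 1 hit/Mb (plasmid rule, pro-rated for the short last bin);
adjacent called bins merge with summed counts. Counting is per probe by
default; summing over a named probe set reproduces the "any probe
combination" reading. Idiograms are emitted as self-contained SVG with a
TSV twin of the plotted marks so tests can query geometry (mark position
along the bar is proportional to the bin midpoint) without parsing SVG.

## Karyotype comparison and summary statistics

A signal site is `(chrom_label, arm, region, probe_id, intensity)`. Two
karyotypes are compared by matching reference sites on the
`(chrom_label, arm, region, probe_id)` key — `region` can be dropped for
coarse matching — with intensity compatibility: `strong` and `weak`
correspond (staining intensity varies between preparations), while
`absent` (a signal missing on one homolog) corresponds only to `absent`.
This keeps self-comparison at exactly 0% while an absent-vs-present pair
always mismatches. The mismatch percent is rounded half-up to one
decimal, matching the printed 41.0% (25/61) and 34.4% (21/61) values,
which the package reproduces from its site tables. The published catalog
itself is not distributed, so the package ships a synthetic catalog
builder with the published site count and probe panel; the comparison
arithmetic is independent of which concrete sites fill the table.

Group comparisons from published summary rows use the pooled-variance
two-sample t by default because the printed pollen-fertility statistic
(15.26) is reproduced exactly by the pooled formula at n = 10 per group;
Welch's statistic is available by flag. Several other printed t values in
the same table are not reproducible from their printed mean/SD/n under
either formula (likely computed from unrounded source data), so only the
pollen-fertility statistic and the moxa-length mean ratio (4.23/2.40 ->
1.8) serve as numeric anchors. Rounding of reported values is half away
from zero, as in the printed tables.

## Synthetic genomes and what passing tests show

The generator emulates the repeat landscape the pipeline assumes:
i.i.d. background at a configurable GC, plus planted arrays (monomer x
copies) with per-base substitutions and 1-bp indels (insertions copy a
random base; indels are applied after substitutions so truth intervals
stay exact). One seeded stream drives everything, so a seed fully
determines the FASTA bytes; the seed is recorded in the FASTA headers.
Random placement keeps a 500-bp margin between plants so neighbouring
arrays cannot fuse into one seed chain.

Recovery is scored at 50% reciprocal overlap with greedy one-to-one
matching; empty detection reports precision 1 with a vacuous flag. The
standard evaluation — thirty arrays (period 10-200 bp, 50-200 copies,
substitution divergence up to 10%) on a 2-Mb chromosome, five seeds —
runs detect -> resolve -> filter and requires recall and precision of at
least 0.9; in practice both sit at or near 1.0. These problem sizes keep
a full evaluation under a minute per seed on one CPU. What this does
*not* show: real satellite landscapes have higher-order repeat structure,
nested and truncated arrays, transposon interspersion and compositional
bias that i.i.d. background lacks, so recovery on synthetic genomes is an
upper bound on real-genome behaviour, and genome-scale counts from the
original multi-gigabase analysis are out of reach at desk scale.

## Pipeline determinism

`run_pipeline()` executes input -> detect -> resolve -> filter -> cluster
-> design -> map -> idiogram with one config and seed, records per-stage
item counts in `manifest.json`, and is byte-identical on reruns:
timestamps go to stderr only, manifests store file basenames, and every
random draw derives from the config seed. Probe names are assigned from
the in-silico localization during the map stage, since naming needs the
hit distribution. Any stage error aborts with the stage name while
completed outputs are preserved.

## Known limitations

- The detector targets satellite-scale arrays; microsatellite edge cases
  (period 1-5 at low copy number) ride on the same machinery but are not
  its design point, and interspersed repeats are out of scope.
- Wraparound scoring of very long arrays holds an `O(n x p)` traceback in
  memory.
- Indel-rich arrays (rates well above a few percent) blur the phase
  signal the boundary refiner uses; boundaries then come mostly from the
  seed chain.
- The hairpin screen is a stem-existence test, not a folding energy
  model.
- Clustering is all-pairs greedy (no k-mer prefilter) and is sized for
  the dozens-to-hundreds of monomers a filtered array set produces, not
  for millions of sequences.
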