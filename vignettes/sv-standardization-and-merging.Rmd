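---
title: "Standardizing, merging and benchmarking structural-variant callsets"
author: "svmeld"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing, merging and benchmarking structural-variant callsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svmeld)
```

## The problem

Structural variants (SVs) are genomic alterations larger than 50 bp:
deletions, insertions, inversions, duplications and translocations. No
single caller detects them all, so practice is to run several callers
and integrate. Two obstacles make that integration unreliable. First,
many callers — especially assembly- and split-read-based short-read
callers — report a large share of their calls as breakends (BND): VCF
records that state "position A is joined to position B in this
orientation" without committing to an SV type. Tools that merge on
SVTYPE silently drop or misclassify these. Second, merging itself is
usually limited to union/intersection, while real questions ("variants
seen by both assembly callers but neither read-signal caller",
"variants private to the tumour") need richer set algebra.

`svmeld` addresses both: a hierarchical breakend-to-canonical-type
corrector, and a merge engine with caller-set expressions, support
thresholds, hierarchical genotype resolution, benchmarking, and a
truth-free trio consistency statistic.

## Record model and coordinate conventions

Every VCF body line is normalized into one record per ALT allele with
1-based, fully closed coordinates, exactly as VCF prints them; interval
arithmetic converts to half-open form only inside overlap computations.
For DEL/DUP/INV, `|SVLEN| = END − POS` is enforced (END wins if the two
disagree); a missing SVLEN is derived from END − POS and a missing END
from POS + |SVLEN|; records with neither are rejected into a per-file
report rather than aborting the parse. Deletions carry negative SVLEN,
duplications and inversions positive, insertions their inserted length
with END = POS. Translocations and breakends carry a second breakpoint
(`chrom2`, `pos2`) and no length; translocation breakpoints are stored
with the lexicographically smaller contig first.

Caller dialects are normalized by a per-caller adapter table with a
generic fallback: DELLY's partner-breakpoint-in-`CHR2`+`END` and `CT`
orientation codes, LUMPY's `STRANDS=+-:6` evidence-count suffixes, and
the supporting-read INFO tags (`SUPPORT`, `RE`, `SU`, `DV`, `SR`, ...)
that stand in for a missing FORMAT `AD`. Adapters only *read* dialects;
output is always the normalized form, which makes normalization
idempotent — a property the test suite checks by re-reading written
files.

## Breakend classification

A breakend ALT takes one of four bracket forms. Writing `t` for the
sequence anchored at the record's own position and `p` for the partner
coordinate, the junction topology and the derived (own, mate) strand
pair are:

| pattern | meaning                                  | strands |
|---------|------------------------------------------|---------|
| `t[p[`  | forward join, partner continues rightward | `+-`    |
| `t]p]`  | partner's left side joins, inverted       | `++`    |
| `]p]t`  | partner's left side joins before `t`      | `-+`    |
| `[p[t`  | partner's right side joins, inverted      | `--`    |

Mate pairing tries `MATEID` cross-references first, then pairs the
remaining halves greedily on positional evidence: both cross-distances
(each half's stated mate position against the other half's own
position) must lie within the tolerance (default 3 bp). The greedy
order is worst cross-distance first, then summed distance, then input
order. The first key is deliberate: it makes the accepted pairing set
monotone in the tolerance (candidates that appear only at a larger
tolerance sort strictly after all candidates available at a smaller
one, so widening the tolerance can only add pairings). Ordering by
summed distance alone would not guarantee that.

Same-chromosome pairs classify by the decision table (L = leftmost
breakpoint, R = rightmost): `t[p[` at L with `]p]t` at R is a DEL —
the forward junction skips, hence deletes, the enclosed interval;
`]p]t` at L with `t[p[` at R means the sequence after R rejoins before
L, a tandem DUP; same-side brackets on both halves are an INV; anything
else, and any span under 50 bp (the SV size definition), is retained as
a BND pair with an audit reason. Cross-chromosome pairings each
collapse to one TRA record. Two pairings whose four coordinates agree
within tolerance are either duplicate evidence of one junction
(identical orientations → collapsed, subtype `merging`) or a reciprocal
exchange (complementary orientations → both kept, subtype `balanced`);
a lone pairing is `unbalanced`, and a half with no mate anywhere
becomes an unbalanced TRA flagged `no_mate`. Breakends are never
converted to INS: insertion calling needs sequence content that
breakpoint coordinates cannot supply.

Coordinate convention at junctions: a deletion planted as
`pos = s, end = e` is encoded as halves `s: N[chr:e[` and
`e: ]chr:s]N`, and the classifier reconstructs exactly
`pos = s, end = e, svlen = -(e - s)`. This self-consistent closed
convention avoids ±1 shifts inside the package; against external
callsets that use the strict "base-before-the-event" VCF convention, a
1 bp discrepancy is possible and is far below every matching threshold
used here.

When a collapsed pair's halves disagree on genotype fields, the half
with the higher variant-supporting read count donates them, falling
back to the first half in input order.

## Merging model

Records are bucketed by (SV type, chromosome) — (type, chromosome pair)
for TRA and BND — and matched pairwise. Non-TRA criteria: start and end
each within `max_distance` (default 50 bp, the strict end of the
commonly used 50–150 bp range; exposed as one knob), size ratio
(larger/smaller |SVLEN|) at most 1.3, and closed-interval Jaccard index
at least 0.7. Insertions are point-like, so the Jaccard criterion is
waived for them and position distance plus size ratio decide.
Translocations and breakends match when both breakpoints agree within
`tra_distance` (default 500 bp, mirroring the benchmark position
threshold) and strand orientations are consistent; records with
unknown strands are treated as consistent with anything.

Clusters are the connected components of the pairwise match graph
(single linkage). The merge literature is split between components and
stricter clique-like rules; components are used here because they match
prevailing merge-tool behaviour and admit a simple independent oracle —
the test suite compares the implementation against brute-force
transitive closure of the match matrix on randomized instances. A
consequence of single linkage is chaining: A~B and B~C merge A and C
even if they do not match directly.

Each component becomes one consensus record. The representative is the
member with the highest QUAL, ties broken by the higher variant AD, then
caller input order. Genotypes resolve hierarchically: a plurality of
called GT tokens wins (missing `./.` genotypes abstain unless every
member is missing); on a tie, the tied member with the highest variant
AD; on a remaining tie, the earliest caller in input order. Set
operations evaluate a boolean expression over each consensus record's
supporting-caller set; `NOT` between two terms is set difference, the
reading that matches the bracketed usage `[(A AND B) NOT (C OR D)]`,
and unary complement is also accepted. Union is `min_support(1)` and
intersection `min_support(n)`; `max_support(k)` and `min_support(k+1)`
partition the union — identities asserted wholesale in the tests.
Multi-sample merging (e.g. a trio) is the same machinery with each
input file as one support slot.

## Benchmarking and the trio statistic

Call/truth matching is one-to-one and greedy by ascending breakpoint
distance (the larger of the start and end discrepancies; ties broken by
truth input order), under a 500 bp position threshold, a minimum 0.7
size ratio, and type identity. Translocations use 5 kb on both
breakpoints and no size criterion (they have no length). Greedy
nearest-first was chosen over optimal assignment because the assignment
order is unspecified in common practice and greedy keeps TP counts
monotone in the position threshold, which the suite verifies. Precision,
recall and F1 are reported overall and per type, each type scored from
its own TP/FP/FN; with type matching required, cross-type matches
cannot occur.

The trio Mendelian violation rate merges child, father and mother as
three support slots and reports the proportion of child-supported
consensus variants with neither parent in the support set, after
excluding child variants with |SVLEN| < 30 bp (TRA and BND exempt, as
they carry no length). An optional BED exclusion mask and a
PASS-only FILTER screen are available but off by default, since mask
provenance is dataset-specific.

## The synthetic generator

The generator works at call level — coordinates on a contig model, no
reads and no reference sequence. `plantEvents()` places non-overlapping
(per type) events uniformly on the contigs, sizes uniform in
[50, 10000] bp by default, genotypes heterozygous with probability 0.7
(a 30:70 homozygous-to-heterozygous ratio, the composition used in
read-level SV simulation studies). `emitCallerVcf()` then emulates one
caller: each event survives a false-negative draw (default rate 0.1),
gets independent Gaussian jitter on both breakpoints (truncated to
contig bounds), and is emitted either canonically or as a breakend pair
according to `bnd_fraction` — real callers span the whole range, from
callers that emit every call as BND to long-read callers that rarely
do. False positives are placed uniformly at least 10 kb from any
same-type truth event. Inversions are emitted as a single breakend
junction pair rather than all four records of both junctions, so one
planted inversion corrects to exactly one INV record; emitting both
junctions would double-count every inversion downstream.

What passing tests on this generator do show: the classifier inverts
the breakend encoding exactly; the merge engine recovers multi-caller
consensus under realistic positional disagreement; the benchmark
arithmetic is correct. What they cannot show: robustness to read-level
artefacts (alignment noise, repeat-mediated breakpoint ambiguity,
coverage dropouts), caller-specific systematic biases, or performance
in complex regions where simple and nested variants overlap — all of
which require sequence-level data.

## Numerical and design choices

* Default problem sizes in the shipped checks: 500 events per type for
  the noiseless correction check, 750 events across five types for the
  three-caller end-to-end run, and ≤ 200-record instances for the
  clustering-oracle comparisons. These sizes give stable statistics
  (binomial standard error below 1% on the recovery rates) at
  desk-scale runtimes.
* Ties everywhere break deterministically (input order last), so a
  fixed seed gives byte-identical SVCF and JSON outputs; the VCF
  `##fileDate` header line is off by default for the same reason.
* Degenerate inputs: empty callsets write header-only files; an empty
  truth set scores recall 0 with a warning; an empty child callset in
  the trio statistic is an error; zero-length or missing sizes make the
  size-ratio criterion vacuous rather than a division error.
* QUAL of a collapsed breakend pair is the maximum over the halves;
  representatives carry their own QUAL.
* The SVCF intermediate format is a versioned, tab-separated, lossless
  serialization of the record model (one row per SV, support
  annotations included); its schema is this package's own definition.

## Known limitations

Breakend classification sees only coordinates and orientations; it
cannot distinguish, for example, an inverted duplication from a simple
inversion, and such cases fall into the retained-BND set by design.
Single-linkage merging can chain distinct nearby events at permissive
thresholds. The benchmark does no sequence comparison, so two
same-type, same-locus events with different inserted sequence count as
a match. Scaling targets are multi-caller single-genome studies, not
thousands-of-samples population merges.
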