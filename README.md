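# svmeld

Standardize, merge and benchmark structural-variant (SV) callsets in R.

Structural variants — deletions (DEL), insertions (INS), inversions (INV),
duplications (DUP) and translocations (TRA), all larger than 50 bp — are
reported very differently by different callers. Short-read callers in
particular emit many calls as ambiguous *breakends* (BND): VCF records that
describe one side of a novel adjacency with a bracketed ALT such as
`N[chr5:5000[` and leave the SV type unstated. Without special handling
these calls are discarded or mis-merged downstream. `svmeld` is aimed at
anyone integrating SV calls across callers, samples or sequencing
platforms: it reclassifies breakends into canonical SV types, merges
callsets under flexible set operations, and scores the result.

## What it does

**Breakend standardization.** Each BND ALT is parsed into one of the four
bracket orientations (`t[p[`, `t]p]`, `]p]t`, `[p[t`), mates are paired
(`MATEID` first, then positionally within a tolerance, default 3 bp), and
each junction is classified hierarchically:

* same chromosome, leftmost breakpoint `t[p[` joining forward to `]p]t`
  → **DEL** (the skipped interval is deleted);
* leftmost breakpoint `]p]t` joined back from downstream → tandem **DUP**;
* same-side brackets on both halves → **INV**;
* different chromosomes → **TRA**, annotated *balanced* (reciprocal
  pairings at mirrored coordinates with complementary orientations),
  *unbalanced* (a lone junction), or *merging* (duplicate representations
  of one junction, collapsed);
* anything ambiguous, conflicting, or spanning under 50 bp is retained as
  BND, and BNDs are never converted to INS. An audit table accounts for
  every input record.

**Merging.** Records are bucketed by type and chromosome (pair), matched
pairwise — start/end distance ≤ δ (default 50 bp), size ratio ≤ 1.3,
interval Jaccard ≥ 0.7, with translocations matched on both breakpoints at
a looser distance (500 bp) under strand consistency — and clustered as
connected components. Consensus genotypes are resolved by majority vote,
then highest variant-supporting read count (AD), then caller input order.
Selection goes beyond union/intersection: `min_support(k)`,
`max_support(k)`, single-caller extraction and boolean expressions such as
`(manta AND svaba) NOT (lumpy OR delly)`.

**Benchmarking.** Calls are matched one-to-one to a truth set (500 bp
position threshold, minimum 0.7 size ratio, type-aware; 5 kb for TRA) and
scored as precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = 2PR/(P+R),
overall and per type, with TP/FP/FN VCFs and JSON statistics. For trios a
truth-free check is provided: the Mendelian violation rate (MVR), the
proportion of a child's variants (|SVLEN| ≥ 30 bp; TRA/BND exempt) absent
from both parents.

**Synthetic fixtures.** A coordinate-level generator plants a ground-truth
event set (70% heterozygous by default) and emits caller-style VCFs with
configurable breakend fraction, positional jitter, false-negative rate and
false-positive count, so the whole pipeline is testable without external
data.

## Worked example

```r
library(svmeld)

vcf <- tempfile(fileext = ".vcf")
writeLines(c("##fileformat=VCFv4.2",
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
  "chr1\t1000\tb1\tN\tN[chr1:5000[\t60\tPASS\tSVTYPE=BND;MATEID=b2\tGT:AD\t0/1:12,20",
  "chr1\t5000\tb2\tN\t]chr1:1000]N\t60\tPASS\tSVTYPE=BND;MATEID=b1\tGT:AD\t0/1:10,18",
  "chr2\t100\tt1\tN\tN[chr3:9000[\t45\tPASS\tSVTYPE=BND\tGT:AD\t0/1:15,9"), vcf)

res <- correctBreakends(readSVVcf(vcf, caller = "manta"))
res
#> CorrectionResult: 3 input record(s); 3 converted, 0 retained BND, 0 pass-through
svRecords(res)[, c("record_id", "svtype", "pos", "end", "svlen", "chrom2", "pos2", "subtype")]
#>   record_id svtype  pos  end svlen chrom2 pos2    subtype
#> 1        b1    DEL 1000 5000 -4000   <NA>   NA       <NA>
#> 2        t1    TRA  100  100    NA   chr3 9000 unbalanced
svAudit(res)[, c("input_id", "disposition", "rule", "evidence", "output_id")]
#>   input_id disposition    rule evidence output_id
#> 1       b1   converted     del  mate_id        b1
#> 2       b2   converted     del  mate_id        b1
#> 3       t1   converted no_mate     <NA>        t1
```

The `b1`/`b2` mate pair encodes a forward junction from chr1:1000 to
chr1:5000, so it becomes a 4000 bp deletion (negative SVLEN by
convention); the lone cross-chromosome breakend `t1` becomes an unbalanced
translocation flagged `no_mate` in the audit. Downstream:

```r
merged <- mergeSVSets(list(callsetA, callsetB, callsetC))
consensus <- applySetOperation(merged, mode = "min_support", k = 2)
report <- benchmarkCalls(consensus, truth)
svMetrics(report)
```

A shell front-end with the same functionality ships in
`inst/scripts/svmeld` (subcommands `correct`, `merge`, `benchmark`,
`trio-mvr`, `svcf2vcf`, `synth`, `stat`; exit codes 0/1/2 for
success/validation error/I/O error).

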