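# svmosaic

Building a population-scale structural variant (SV) catalog from
short-read resequencing data is a pipeline problem, not a single-caller
problem: no individual caller is sensitive and precise across deletions,
insertions, inversions and tandem duplications from 50 bp to 1 Mb, and
thousands of per-sample call sets must be reconciled into a single map of
allelic events. `svmosaic` implements the computational core of such a
pipeline for plant resequencing panels (its defaults are tuned to a
rice-scale genome), for SV-pipeline developers and population genomicists
who need the merging, clustering, benchmarking and downstream annotation
statistics without re-running the callers themselves.

## What it computes

**Primitives.** Two calls `a`, `b` are compared by *reciprocal overlap*
`RO(a,b) = min(|a∩b|/|a|, |a∩b|/|b|)` and *breakpoint error*
`e(a,b) = |a.start − b.start| + |a.end − b.end|`. Benchmark size bins:
A 50–150 bp, B 151–500 bp, C 501 bp–5 kb, D 5–50 kb, E 50–250 kb,
F 0.25–1 Mb.

**Benchmarking** (`simulate_truth_set`, `emulate_caller`,
`evaluate_callset`). A prediction `p` matches a truth event `S` of the
same type when `RO(p,S) ≥ 0.9` and `e < min(10 bp, 0.1·(|p|+|S|))`; for
duplications the threshold relaxes to `RO ≥ 0.7` with no error constraint
(duplication breakpoints resolve poorly); insertions match within 10 bp of
site distance. TP/FP/FN, sensitivity and precision are reported per SV
type × size bin.

**Within-sample merging** (`merge_sample_calls`). Retains every anchor
caller (Pindel) call with FILTER `PASS`; all inversions from the keep-all
caller (Lumpy); and any other call supported by ≥ 2 callers at pairwise
`RO ≥ 0.7` when Lumpy is in the pair, else `RO ≥ 0.9`. Insertion sites
within 10 bp are chained and emitted once.

**Cross-sample clustering** (`cluster_all`). Per SV type: calls
overlapping by ≥ 1 bp are grouped; a similarity graph connects calls with
`RO ≥ 0.9`, or `RO ≥ 0.7` and `e ≤ 10 bp`; each connected component is
agglomerated by complete linkage under the distance
`d(a,b) = e(a,b) / (|a|+|b|)` and cut at height 0.1. Each resulting
cluster is one allelic event, with representative breakpoints (per-side
medians), carrier count, allele frequency and tightness (mean per-side
breakpoint deviation over the representative length). Insertions cluster
by single-linkage chaining of sites ≤ 10 bp apart.

**Annotation & regulatory statistics.** TE overlap classification (strict
at 80% reciprocal overlap with a single element, repeat-associated at
≥ 50% union coverage); genic feature assignment with CDS > 5′UTR > 3′UTR >
intron > promoter > intergenic precedence; TSS-relative coverage profiles
split at 40 bp; genes whose CDS is entirely deleted in a sample;
100-kb/50-kb sliding-window variant density with 2×-mean flagging;
per-position Fisher/chi-square independence tests between TFBS and SV
presence with the conditional `P(SV|TFBS) = P(TFBS∩SV)/P(TFBS)`;
linguistic sequence complexity `CL = Σ V_i / Σ min(K^i, N−i+1)`; and
hypergeometric gene set over-representation tests.

**Synthetic data** (`sim_config`, `simulate_panel`,
`simulate_annotations`). Seeded generators produce truth sets, jittered
caller emulations, multi-sample panels with planted allelic events and an
answer key, and gene/TE/TFBS annotation tracks with independent or
SV-avoiding TFBS placement — every analysis above can be validated against
a known ground truth.

## Worked example

```r
library(svmosaic)

cfg <- sim_config(seed = 11, panel_size = 20)
pan <- simulate_panel(cfg, n_events = 50)      # planted allelic events
cs  <- cluster_all(pan$calls, cluster_params(), panel = pan$panel)
cs
#> sv_cluster_set: 50 clusters from 497 calls across 20 samples
#>   by type: DEL=50
#>   mean tightness: 0.0133

pr <- planted_vs_recovered(pan, cs)
mclust::adjustedRandIndex(pr$planted_id, pr$cluster_id)
#> [1] 1
```

The 497 per-sample calls (each planted event carried by a Binomial draw of
the 20 samples, breakpoints jittered by 2% of event length) are grouped
back into exactly the 50 planted events (adjusted Rand index 1), and the
recovered clusters scatter their members' breakpoints by ~1.3% of the
event length on average (`tightness`).

A command-line wrapper for scripted pipelines is installed at
`inst/cli/svmosaic` (subcommands `simulate`, `merge`, `cluster`,
`benchmark`, `annotate`, `regstats`; every run writes a `manifest.json`
with input digests, parameters and the seed).

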