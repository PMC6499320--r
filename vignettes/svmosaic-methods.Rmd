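---
title: "Methods: SV merging, clustering and benchmarking in svmosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SV merging, clustering and benchmarking in svmosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svmosaic)
```

`svmosaic` implements the computational core of a population-scale
structural-variant (SV) discovery pipeline: per-sample integration of
multiple callers' output, cross-sample clustering of calls into allelic
events, a call-level benchmarking framework against simulated truth sets,
and the downstream annotation and regulatory statistics such a catalog
feeds. This vignette documents the models and procedures, the parameters
that matter and their defaults, the numerical choices, and what the
synthetic-data validation does and does not establish.

## Coordinate model and primitives

All intervals are 0-based half-open `[start, end)`; VCF and GFF3 readers
and writers convert from and to the 1-based inclusive conventions of
those formats. An insertion has no reference extent and is modeled as a
point (`start == end`) carrying its inserted length (and sequence, when
assembled). Two consequences follow consistently through the package:
reciprocal overlap is undefined for insertions — every insertion
comparison is a positional distance — and abutting intervals
(`[0,100)`, `[100,200)`) do not overlap. SVs are treated as unstranded.
The minimum event length is 10 bp by default (configurable), matching a
catalog whose events are longer than 9 nt.

Two primitives drive everything:

* **Reciprocal overlap**: `RO(a,b) = min(ov/|a|, ov/|b|)` with `ov` the
  intersection width. Thresholding this min-form at `t` is equivalent to
  requiring both fractions ≥ `t`.
* **Breakpoint error**: `e(a,b) = |Δstart| + |Δend|`, in bp.

Benchmark size bins are A 50–150, B 151–500, C 501–5000, D 5001–50000,
E 50001–250000, F 250001–1000000 bp. Published bin tables for such
designs often leave the B/C boundary ambiguous at 500 bp; we resolve it
as B-inclusive so the bins partition [50 bp, 1 Mb] exactly. Lengths
outside that range report the sentinel `"unbinned"`: they still cluster
and merge, they are only excluded from binned benchmarking.

## Benchmark matching criteria

A prediction `p` is a true positive for truth event `S` (same SV type)
when:

* **DEL/INV**: `RO ≥ 0.9` and `e < min(10, 0.1·(|p|+|S|))` bp. The
  published form of this rule — an absolute 10-bp cap *or* 10% of the
  combined length, "requiring less error" for small events — is
  internally inconsistent under a plain disjunction (an OR can only ever
  admit *more* error). We implement the parenthetical's intent: the 10%
  leg binds only when the combined size is below 100 bp, so small events
  face a tighter cap and large events never get a looser one. The plain
  OR variant remains available (`match_criteria(error_rule = "or")`).
  The absolute cap is strict (`< 10`), as stated for the benchmark;
  the clustering rule below uses `≤ 10`, also as stated — the two
  operators differ deliberately.
* **DUP**: `RO ≥ 0.7`, no error constraint — duplication breakpoints
  resolve too poorly for the strict rule to rank callers fairly.
* **INS**: site distance ≤ 10 bp, mirroring the insertion clustering
  radius; no published criterion exists for insertion matching.

Matching is a greedy one-to-one assignment over candidate pairs ranked by
descending RO, ascending `e`, then coordinate order (insertions by
ascending distance). Greedy was chosen over optimal assignment for
determinism and speed; a property test verifies that on instances small
enough to enumerate, greedy attains the maximum-cardinality matching.
True positives and false negatives are binned by the *truth* length,
false positives by the *predicted* length (the only length available for
a spurious call). Sensitivity and precision with empty denominators are
reported as missing, never coerced to 0.

## Within-sample merging

Per sample, calls from multiple callers are reduced to one list by three
retention rules: (a) every anchor-caller (default `pindel`) call with
FILTER `PASS` is kept unconditionally — the anchor is selected for
breakpoint precision; (b) every inversion from the designated keep-all
caller (default `lumpy`) is kept; (c) any other call supported by at
least two distinct callers is kept, where support between two calls of
the same type means `RO ≥ 0.7` if the relaxed caller (`lumpy`) is in the
pair and `RO ≥ 0.9` otherwise, counted per pairwise comparison against
the candidate (star topology, the simplest reading of "supported by at
least two callers"). Supported groups already represented by a kept
anchor call are dropped, and each surviving group is emitted once with
the breakpoints of its highest-priority caller. Keep-all inversions are
likewise deduplicated against kept anchor inversions — whether the
original pipelines did so is not documented; we apply it because the
output contract promises no same-type pair at `RO ≥ 0.9`.

Insertions merge separately: sites within 10 bp chain by single linkage;
each chain is emitted at its leftmost site with the longest assembled
sequence in the chain, and unchained insertions from either caller are
kept.

Merged calls carry a `supports` column listing every contributing
caller. This is what makes the merge idempotent — re-merging a merged
set returns it unchanged, because a representative's recorded support
still counts — and it is the provenance a downstream analyst needs.

## Cross-sample clustering

Clustering reconstructs allelic events: groups of per-sample calls
descending from one ancestral mutation. Per SV type:

1. **Grouping**: transitive closure of ≥ 1-bp overlap (computed by
   reducing sorted intervals).
2. **Similarity graph**: edge between `a` and `b` iff `RO ≥ 0.9`, or
   `RO ≥ 0.7` and `e ≤ 10` bp. The weak rule admits small events whose
   relative overlap is mediocre but whose absolute boundary difference is
   tiny.
3. **Connected components** of that graph.
4. **Complete-linkage agglomeration** within each component under
   `d(a,b) = e(a,b) / (|a|+|b|)`, cut at height 0.1 (inclusive: a cell
   survives while its merge height is ≤ 0.1). The denominator is the
   *sum* of the two lengths, consistent with the matching criterion's
   `|p|+|S|` normalization; a mean-length variant (differing only by a
   factor 2) is exposed as `cluster_params(length_norm = "mean")`.

Insertions skip steps 1–4 and chain by single linkage over sites ≤ 10 bp
apart, consistent with the within-sample insertion merge.

The agglomeration is implemented directly rather than through
`stats::hclust`: with integer breakpoints, tied merge heights occur, and
`hclust` resolves ties by input position, which would make the final
partition depend on input order. Our implementation breaks ties
lexicographically by each cell's (min start, min end, smallest sample
id), and `cluster_all` canonically sorts its input first, so the
partition is invariant under permutation of the input — a property the
test suite asserts, alongside agreement with an independent brute-force
implementation of steps 1–4 on random instances.

Each final cluster is summarized by representative breakpoints — the
per-side *low median* (the lower middle order statistic, always an
observed, integral coordinate) — member count, distinct carrier samples,
allele frequency (carriers over panel size), and **tightness**: the mean
over members of `(|Δstart| + |Δend|)/(2·L)` against the representative,
i.e. the average per-side breakpoint scatter as a fraction of event
length. Medians are used because they are robust to the occasional badly
jittered member. Tightness is the catalog-quality statistic: real
population catalogs built this way report average per-side scatter near
2% of event length.

## Synthetic data: what it emulates, and what it does not

The generators stand in for a multi-thousand-sample resequencing panel whose reads and callers
are far outside desk scale. All randomness derives from one integer seed
(each generator salts its own substream, so per-caller emulations err
independently), and every default is a study condition, not a dial:

* **Truth sets**: 1000 events per type for bins A–D and 200/100 for E/F,
  lengths uniform within bins (the within-bin distribution is not
  documented in published designs; uniform is the least-informative
  choice), placed non-overlapping per type on a rice-scale genome
  (twelve 31-Mb chromosomes). Each type is its own layer, as in
  read-level benchmark designs where each type's genome is simulated
  separately; packing all four types disjointly at these counts cannot
  fit the genome. The read-level design constants of the emulated
  experiment (83-bp reads, 500 ± 50 bp inserts, 2% error) are recorded
  in `sim_config()$read_design` for provenance but unused: benchmarking
  here is call-level, with caller behavior summarized by breakpoint
  jitter (`jitter_sd`), dropout (`fn_rate`) and bin-matched spurious
  calls (`fp_rate`).
* **Panels**: planted events with allele frequencies uniform on
  [0.1, 1], carriers drawn Bernoulli per sample (events drawn with zero
  carriers receive one forced carrier so the answer key always has
  exactly `n_events` cells), per-carrier breakpoint jitter with SD 2% of
  event length — chosen to mirror the breakpoint scatter observed in
  real multi-sample catalogs.
* **Annotations**: genes with a fixed 5′UTR/CDS/intron architecture on
  random strands; TFBS placed uniformly in each gene's
  [TSS−500, TSS+500] window at a Poisson mean of 36 sites per gene
  (≈ 30% per-position coverage probability — position-weight-matrix
  annotation from several hundred plant matrices is dense); deletions in
  the same windows at a Poisson mean of 4 per gene, half shorter than
  40 bp (≈ 40% per-position coverage, the regime of a population catalog
  where most promoters are hit in some sample). `avoidance = 0` places
  TFBS and SVs independently — the calibration null; `avoidance > 0`
  rejects TFBS-overlapping SV proposals with probability `1 − e^{−α}`,
  creating tunable mutual avoidance.

What passing these simulations does **not** show: robustness to the
caller-specific error structure of real data (systematic, not Gaussian,
breakpoint biases; FP clustering in repeats), to reference bias, or to
the sequence content of real promoters (our genome is i.i.d. random
nucleotides except for explicit SSR insets). The simulations validate
the *algorithms* — grouping, matching, linkage, counting, testing — not
the biology.

## Regulatory statistics: numerical choices

**TFBS–SV independence.** Per position around the TSS (strand-aware,
upstream negative), genes are cross-classified by TFBS and SV coverage
and tested for independence. The default is the two-sided Fisher exact
test — the counts are small and binary, and it is valid at every table
size. Exact conditional tests are, however, systematically
*conservative*: their rejection rate under the null sits below the
nominal level (we measure ≈ 0.042 at α = 0.05 under the simulator's
null), a textbook property of discrete tests and not an implementation
artifact. The asymptotic chi-square variant
(`tfbs_sv_independence(method = "chisq")`) is the calibrated choice at
these densities (measured ≈ 0.048–0.050), and it is the variant the
acceptance suite holds to the nominal level, while the Fisher default is
held to validity (never anticonservative). The conditional probability
`P(SV|TFBS) = P(TFBS∩SV)/P(TFBS)` is reported alongside and is exactly
consistent with the counts by construction; positions with no TFBS
carrier report a missing conditional and skip the test. Raw p-values are
the default (profiles of log p are the usual display); Benjamini–
Hochberg adjustment across the 1001 positions is optional.

**Linguistic complexity.** For window size `N = 10` and alphabet size
`K = 4`, `CL = Σᵢ Vᵢ / Σᵢ min(Kⁱ, N−i+1)` where `Vᵢ` counts distinct
substrings of length `i` in the window. `CL ∈ (0, 1]`; a homopolymer
10-mer scores 10/49 ≈ 0.204. Windows containing non-alphabet characters
(N, masks) are reported `NA` and excluded from averaged profiles.

**Enrichment.** One-sided over-representation p-values are the
hypergeometric upper tail `P(X ≥ list_hits)` — the Fisher exact
one-sided test — with the sample odds ratio of the 2×2 table; zero
margins give `p = 1` and an undefined odds ratio rather than an error.

## Annotation choices

* **TE classification** precedence: `strict_te` when a *single* TE
  record reaches 80% reciprocal overlap with the cluster;
  `repeat_associated` when the union of track records covers ≥ 50% of
  the cluster; else `none`. Strict implies the union criterion, so the
  classes nest. Insertions classify as `none`: an inserted sequence has
  no reference-interval geometry to overlap, and sequence-level TE
  matching is out of scope.
* **Feature assignment** precedence CDS > 5′UTR > 3′UTR > intron >
  promoter > intergenic mirrors severity for spanning variants; the
  promoter is the strand-aware 500 bp upstream of the TSS (matching the
  [TSS−500, TSS+500] regulatory window), configurable because long-SV
  density peaks a few hundred bp upstream.
* **Deleted genes** require the union of a sample's deletion clusters to
  cover *every* CDS base (strict full-coverage; 99% is not deleted).
  Genes without CDS are excluded with a warning. Per-variety-group
  summaries and a sharing table at carrier frequency ≥ 5 are produced
  when a group assignment is supplied.
* **Density windows**: 100-kb windows at 50-kb steps; a variant counts
  in every window containing its *start* (assignment by start avoids
  double counting within a window while keeping the sliding-window
  smoothing); windows with counts ≥ 2× the genome-wide mean are flagged;
  a second track yields the Pearson correlation of aligned window
  counts. Cluster counts (not raw call counts) are the intended input,
  but any table with `chrom`/`start` works.

## Problem sizes and determinism

The test and acceptance computations run at these scales, chosen as the
package's validation design: the full benchmark layout (17,200 truth
events over 4 types × 6 bins) for the noise-free self-benchmark; 100
seeds × 1000 events for the binomial dropout check; 200 random ≤ 30-call
instances against the brute-force clustering oracle; a 50-event,
20-sample planted panel for exact recovery (adjusted Rand index 1); 100
seeds × 500 genes × 1001 positions for the independence-test null; 1000
random 10-mers against the set-based complexity oracle. Every quantity
is reproducible from the seeds embedded in the tests, and
`scripts/acceptance.R --seed N` re-derives the headline numbers from any
seed.

## Known limitations

Translocations are out of scope (the discovery design cannot separate
them from events they contain), as are read-depth CNV genotyping,
running the external callers, TFBS prediction itself (sites arrive as a
BED track), and sequence-realistic TE insertion simulation. Caller
output dialects in the wild vary; only the normalized
SVTYPE/END/SVLEN-style VCF dialect is parsed, with caller-specific
quirks left to pre-conversion. Whether insertion clusters should also
compare inserted-sequence similarity is open; positions alone are used.
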