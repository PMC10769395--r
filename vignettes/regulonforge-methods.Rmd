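---
title: "Methods: repeat profiling, target calling and cohort screens in regulonforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat profiling, target calling and cohort screens in regulonforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonforge)
```

# Scope and model

`regulonforge` re-implements, as reusable and tested components, the
computational procedures used to characterize genes repressed by ETS-family
fusion oncoproteins (EWSR1::FLI1 / EWSR1::ERG) in Ewing sarcoma: GGAA
microsatellite composition of binding-site peaks, promoter/distal peak
classification, repressive-histone-mark assignment, direct-target calling,
tumor-cohort screens, and cell-motility metrics. Upstream steps that require
sequencing-scale data — read alignment, peak calling, differential-expression
model fitting, motif enrichment, image segmentation — are out of scope; their
outputs (narrowPeak/broadPeak files, DE tables, expression matrices,
detection tables) are this package's inputs.

All genomic coordinates are 0-based half-open throughout. A narrowPeak
summit offset of −1 means "no summit called"; such peaks fall back to the
interval midpoint `floor((start + end)/2)` wherever a summit is needed.

# Consecutive GGAA/TTCC run profiling

The unit of analysis is the *maximal run*: `(GGAA)_n` counts as one run with
multiplicity `n`, not as `n` nested singletons. Runs are gapless by
definition — one interrupting base splits a run in two. GGAA and TTCC have
no nontrivial self-overlap, so a greedy left-to-right scan is equivalent to
leftmost-longest regular-expression matching; the test suite holds the
implementation to exact agreement with an independent `(GGAA)+` regex oracle
on thousands of random sequences.

Parameters:

* `width` (bp, default 500) — the total window centered on the summit
  ("a range of 500 bp around the summit" is read as total window size, i.e.
  summit ± 250; the alternative ± 500 reading is available by setting
  `width = 1000`).
* pooling — a plus-strand GGAA microsatellite and its reverse complement
  (a TTCC run on the forward sequence) are the same biological element, so
  the default profile pools both motifs while scanning only the forward
  strand; `separate = TRUE` reports them apart. Pooling makes the profile
  invariant under reverse-complementing every window, which is tested
  exactly.
* A gapless alternation such as `GGAATTCC` is counted as two independent
  singleton runs (one per motif).

Per run-length bin {1, 2, 3, 4, >4} the profile reports the percentage of
peaks with at least one such run and the mean number of runs per peak.

# Promoter/distal classification and mark categories

The promoter of a gene is the strand-aware interval of positions whose
signed distance `d` to the TSS satisfies −3000 ≤ `d` < +1000 (`d = p − t` on
+, `d = t − p` on −; `t = start` on +, `t = end − 1` on −). A peak is
*promoter* iff its summit lies in any promoter (summit-centric by default,
matching summit-centered heatmap classification; any-overlap via
`by_summit = FALSE`). Classification is verified against exhaustive
per-position evaluation of the signed-distance definition and is invariant
under coordinate reflection with strand flipping.

Peak-to-gene assignment extends each gene span by a flank (default 5 kb) on
both sides and intersects half-open intervals. The source analyses say only
"in the proximity of the gene body"; 5 kb is a declared default, recorded in
output headers, not an inferred value.

Repressive-mark categories use the bp-gap convention: the distance between a
gene span and a mark peak is 0 when they overlap *or* are adjacent, else the
gap in bp. A mark is present iff its distance is ≤ `window` (default 10 kb —
again a declared quantification of a qualitative "in their proximity").
Categories are {H3K9me3_only, H3K27me3_only, both, none}; `closest_mark` is
the present mark with the smaller gap, with exact ties reported as
`both_tied` rather than broken arbitrarily. The worked 23/9/7/21 partition
of 60 loci summarizes to 38/15/12/35 percent (nearest integer).

# Direct-target calling

DEG filtering takes fold-change thresholds on the linear scale and compares
on log2 internally: up iff `2^log2fc ≥ fc` and `fdr < fdr_cut`; down
symmetrically with `2^log2fc ≤ 1/fc`. The fold-change boundary is inclusive
and the FDR boundary strict, following the usual "±1.5-fold change;
FDR < 0.05" phrasing. Intersection across experiments keeps genes
deregulated in the same direction in all experiments and excludes genes
with conflicting signs. Direct targets are `bound ∩ up` (positive) and
`bound ∩ down` (negative), where "bound" comes from the flank-extended
assignment above; set operations are identifier-space only, so DE genes
without coordinates still participate.

# Cohort statistics

* **Welch range screen** — one-directional: a gene passes when the tumor
  mean exceeds the cell-line mean and the one-sided Welch p (tumors
  greater) is below `p_cut` (default 0.01). Values are log2(x+1)-transformed
  by default: RPKM-like values are strongly right-skewed and the t-test only
  holds its nominal level on the log scale (at the default cohort shape the
  raw-scale screen ran at ~1.6–2% for a nominal 1%). `log_transform = FALSE`
  restores raw-scale testing.
* **Correlation screen** — Pearson on log2(x+1) values by default (the
  product-moment choice mirrors the R-value reporting of tumor-expression
  platforms); Spearman available and, being rank-based, invariant to
  monotone transforms. FDR control is Benjamini–Hochberg step-up, a declared
  choice where the source reports "FDR" without naming a procedure.
  Zero-variance candidates are flagged `degenerate` and never pass.
* **Quartile concordance** — the top quartile is the `ceil(N/4)` samples
  with the highest regulator expression (ties broken by sample order),
  reproducing "the 20 tumors" at N = 79; "median or higher" is inclusive
  (≥ cohort-wide median of the target). `k` is invariant to strictly
  increasing transforms of the target values.
* **Survival** — Kaplan–Meier product-limit curves per group and the
  two-group log-rank chi-square (1 df), split at the median expression by
  default (cutoff *scanning* is deliberately excluded: optimizing the split
  without correction inflates significance). Curves and the test come from
  the `survival` package; degenerate cases are pinned by convention (no
  events → curves ≡ 1, chi2 = 0, p = 1).
* **ΔΔCt** — `2^−[(Ct_tgt − Ct_ref)_treated − (Ct_tgt − Ct_ref)_control]`,
  with a housekeeping reference such as NACA.

# Synthetic data: what it emulates, and what a green test establishes

Each generator emits the exact file formats the pipeline reads plus a
ground-truth sidecar, and is byte-deterministic given the configuration
(per-stage seed substreams mean adding a stage never changes another
stage's draws). Defaults state the emulated conditions rather than tuned
values: 79 tumors vs 42 cell lines; an 85-sample survival cohort with a
planted hazard ratio of 3 at the median split; tracks imaged every 2 h over
96 h (49 frames); 200 peaks with planted run-length bins.

* *Genome/peaks* — uniform background over {A,C,G,T}; accidental runs of
  ≥ 2 motif copies are broken by base substitution; each planted run gets
  flanking breaker bases so it cannot extend. The truth table is produced by
  an independent post-generation regex scan of every profiling window, so
  accidental singletons (which a uniform background produces at a known
  rate, and which the profiler *must* count) are part of the recorded truth.
* *DE tables* — planted effects are exact (`±de_effect_log2`) with FDR
  drawn below 0.05 and nulls above it, so threshold recovery is exact by
  construction. This validates the filtering logic, not DE model fitting,
  which is out of scope.
* *Cohorts* — log-normal expression (exponentiated Gaussians, mimicking
  RPKM-like skew); shifted genes add `shift_delta` on the Gaussian scale for
  tumors; the regulator–target pairs are bivariate-normal with the planted
  correlation before exponentiation. Chosen realism constants (log-scale
  mean 1, SD 1) are fixed once here.
* *Survival* — exponential times with the hazard ratio applied to the
  above-median-expression half, uniform censoring on (0, 60) at baseline
  hazard 0.05: roughly 80–90% events, the simplest regime in which log-rank
  power at the stated effect is testable.
* *Tracks* — alternating directed (constant speed, so the truth length is
  exact arithmetic) and confined (Gaussian jitter) tracks on a collision-free
  grid; quality ~ N(150, 10) so the quality filter has both sides of its
  boundary populated.

None of these generators emulate read-level noise, chromatin-domain
structure, batch effects, or segmentation errors. A green suite therefore
establishes that the *procedures* are implemented to specification — not
that the biological conclusions of any particular study reproduce from raw
data, which would require the deposited sequencing cohorts.

# Numerical and design notes

* BH adjusted values are clamped with `q = max(q, p)`; the textbook
  `p·m/j` at `j = m` can dip a few ulp below `p` in floating point.
* `welch_t` is implemented directly (rather than wrapping `t.test`) so the
  zero-variance/equal-means case can return t = 0, p = 1 by convention; it
  is tested against `t.test` on non-degenerate inputs.
* Track linking is greedy nearest-neighbour with an ascending-distance
  matching order and track termination on a missed frame — sufficient for
  the collision-free synthetic regime, and clearly plumbing, not a
  re-implementation of LAP tracking.
* "Movement range" is the trajectory diameter (maximum pairwise
  displacement); net first-to-last displacement is available via
  `range_type = "net"`. Diameter ≤ total distance always holds.
* The pipeline configuration is JSON (no YAML parser among the package's
  dependency set); structure and semantics are unchanged from a YAML-style
  declarative config.
* Percentages are reported both exactly and rounded to the nearest integer
  (R's `round`, i.e. banker's rounding at .5 — irrelevant for the worked
  partitions).

# Known limitations

Interval logic assumes in-memory scale (thousands of peaks/genes, not
millions); the linker is not gap- or collision-aware; the mark-category
window and the gene-binding flank quantify qualitative proximity notions and
results should be read with their sensitivity in mind (both are recorded in
output headers); survival analysis supports right censoring only.
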