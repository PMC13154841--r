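---
title: "Benchmarking circular DNA/RNA detection with circleBench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking circular DNA/RNA detection with circleBench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circleBench)
```

## The problem

Extrachromosomal circular DNA (eccDNA) and circular RNA (circRNA) are
detected from short-read sequencing by finding reads that are inconsistent
with a linear template: split reads whose alignment is interrupted at the
circular junction (CJ) and discordant pairs whose orientation implies a
circle. Detection tools disagree substantially on real data, and on
biological samples there is no ground truth to arbitrate. circleBench
provides the infrastructure for both situations: a read simulator with
known truth for controlled evaluation, filtering and multi-tool consensus
strategies, and a junction read-imbalance statistic (deltaCJ) that flags
dubious circles without any truth set.

## The read simulator

A circular molecule of length $L$ is sampled by choosing a chromosome with
probability proportional to its length, a start uniformly among the
positions where the circle fits, and $L$ from either a uniform
distribution or a three-parameter lognormal
$L = \mathrm{loc} + \mathrm{scale}\cdot e^{s Z}$, $Z \sim N(0,1)$,
truncated by rejection to $[\min, \max]$. Rejection rather than clipping
preserves the distribution's shape; clipping would pile probability mass
onto the bounds. The defaults ($s = 1$, $\mathrm{loc} = 0$,
$\mathrm{scale} = 1000$, bounds 175–10,000 bp) describe a typical
small-eccDNA size spectrum with median near 1 kb.

Reads are paired-end with read length 150 bp and insert 500 bp by default.
The number of pairs per circle inverts the coverage definition

$$ \mathrm{coverage} = \frac{n_\mathrm{pairs} \cdot \ell_\mathrm{read}
   \cdot 2}{L} \quad\Rightarrow\quad n_\mathrm{pairs} =
   \left\lceil \frac{\mathrm{coverage} \cdot L}{2\,\ell_\mathrm{read}}
   \right\rceil, $$

so realized coverage is never below the request and every circle yields at
least one pair. Fragments start uniformly on the circularized template and
wrap across the junction; a pair is `split` when either read itself
crosses the junction, `discordant` when only the fragment spans it, else
`concordant`. The classification is per pair, with split taking
precedence. An optional enrichment fraction forces fragment starts into
the one-insert-length window upstream of the junction, raising the
split/discordant share.

Biological divergence is applied once per molecule as a Kimura
two-parameter substitution process (per-base rate 0.01 by default;
transitions $\kappa/(\kappa+2)$, each transversion $1/(\kappa+2)$, with
$\kappa = 2$). Sequencing errors are uniform substitutions per read base
(rate 0.001). Base qualities are constant Q40: quality profiles carry no
information for any downstream computation here, so modelling them would
only add parameters. Truth class and circle identity are encoded in the
read name (`circleID|pairIndex|class`), making evaluation self-contained.

What the generator does *not* emulate: formation bias from chromatin
state, transcription or repeats (circles land uniformly), indels,
amplification chemistry (rolling-circle or PCR bias), or long reads. Tests
that pass on simulated data therefore certify algorithmic correctness, not
robustness to those real-data effects.

## Matching, clustering and combination

Two circle calls are the same call when they lie on the same chromosome
and **both** junction coordinates differ by at most 20 bp. Both-endpoint
matching is the strictest reading consistent with comparing CJ coordinate
pairs, and 20 bp is the conventional tolerance for junction wobble across
tools.

Clustering across tools is representative-anchored: circles are processed
in coordinate order and each joins the first cluster whose current
representative (highest split-read support, ties broken by length, then
coordinates) it matches, else seeds a new cluster. Transitive chaining is
deliberately avoided — a chain of calls 15 bp apart could otherwise merge
circles arbitrarily far apart. With $n$ tools and cluster support $s$
(distinct tools), the combination strategies select: *Union* $s \ge 1$,
*Unique* $s = 1$, *Intersect* $s = n$, *Double* $2 \le s < n$, and
*Rosette* $s \ge 2$ (requiring $n \ge 3$). By construction Union is the
disjoint union of Unique, Double and Intersect, and
Intersect $\subseteq$ Rosette $\subseteq$ Union.

Filtering precedes combination: `filterSplit()` keeps calls with $\ge 2$
split reads (calls without split information pass unchanged — the filter
is inapplicable, not failed); `filterDuplicates()` greedily resolves
base-sharing overlaps in favour of split support, then length; the
combined filter applies them in that order. Greedy resolution by priority
is a deterministic extension of the pairwise rule to overlap chains, which
the pairwise rule alone leaves undefined.

## Benchmarking against truth

Predictions are assigned to truth circles one-to-one, greedily by start
offset, so duplicated predictions cannot inflate precision. Precision,
recall and F-score follow the standard definitions; degenerate cases
(no predictions, or precision + recall = 0) report 0. The junction
precision ratio is the fraction of matched truth circles recovered with
both endpoints within 1 bp among matches at the full 20-bp threshold —
the denominator interprets "maximum detections" as detections at the
default threshold. Length-spectrum agreement uses the two-sample
Kolmogorov–Smirnov test on lengths restricted to a range (full or
short-circle). A Yates-corrected chi-square (correction clamped at zero)
serves the 2×2 cross-cohort sharing comparisons.

## The deltaCJ junction screen

For a circle with junction coordinates $(s, e)$, reads are collected in
windows extending 20 nt on each side of both coordinates. Each unique
read contributes its MAPQ weight $w_i = 1 - 10^{-\mathrm{MAPQ}_i/10}$;
each side's weighted sum is ceilinged to an integer ($k_L$, $k_R$;
a positive sum never rounds to 0), $N = k_L + k_R$, and

$$ \Delta \mathrm{CJ} = \frac{|k_L - k_R|}{N}. $$

Balanced support gives 0; fully one-sided support gives 1 and suggests
the call's junction is wrong (e.g. a partial duplication of a real
circle). Significance under the null of side-symmetric support uses the
doubled binomial tail $p = 2 \cdot 0.5^N \sum_{i=0}^{k}\binom{N}{i}$ with
$k = \min(k_L, k_R)$. Doubling double-counts the midpoint term when $N$
is even (for $k=3, N=6$ the raw sum is 1.3125), so an even-$N$ balanced
split is reported as exactly 1 — midpoints are irrelevant for flagging
outliers. Setting the doubled tail below $\alpha$ at the most nearly
extreme split ($k=1$) requires $2(N+1)\,0.5^N < \alpha$, giving
$N > 8.58$ for $\alpha = 0.05$ (so 9 reads minimum) and $N > 11.26$ for
$\alpha = 0.01$ (12 reads).

Unequal local alignability shifts the expected split: with mean
mappabilities $M_L, M_R$ over the 30-nt regions just inside each
junction boundary, the expected left probability is
$p_L = M_L/(M_L+M_R)$ and the test becomes a doubled binomial tail under
$p_L$. The tail is evaluated on the *deficit* side — the side observed
below its expectation — then doubled and capped at 1; with $p_L = 0.5$
this reduces exactly to the symmetric case (verified against exhaustive
enumeration of all $2^N$ assignments up to $N = 12$). Probabilities are
Benjamini–Hochberg adjusted within one invocation (one family per circle
set), and circles with $p_\mathrm{adj} < 0.05$ are flagged as skewed.

Numerical and boundary choices worth knowing:

* A read overlapping both windows is assigned to the side with the larger
  window overlap; exact ties are side-uninformative and dropped. This
  resolves the tension between defining $N$ as the union of window reads
  and as $k_L + k_R$ of per-window sums, which double-counts shared reads.
* Missing mappability (no track, or no data at the junction) falls back
  to $p_L = 0.5$ and is flagged in the output.
* Windows are clipped at chromosome boundaries; circles shorter than
  60 bp use the whole circle for both mappability regions.
* $p_L \in \{0, 1\}$ with reads on the impossible side yields $p = 0$.
* Cohort summaries report the proportion of circles with $N \ge 9$, mean
  and median deltaCJ over those circles, and the proportion significant;
  `deltaDeltaCJ()` compares cohort means (e.g. a Rosette consensus versus
  a single tool).

Alignment access and mappability are abstract contracts
(`junctionReads()`, `trackMean()`) with BAM/bigWig adapters
(Rsamtools/rtracklayer) and deterministic in-memory implementations
(`FixtureAlignments`, `MappabilityFixture`), so the full statistic is
testable without binary files.

## Annotation

Junction coordinates are classified against RepeatMasker intervals
(classes LINE, SINE, DNA, satellite, other; non-overlapping coordinates
are non-repetitive) with priority LINE > SINE > DNA > satellite > other on
the rare multi-overlaps, and against gene models with the cascade
UTR/codon features, then exon, then intron (derived as gene minus exon
spans when not explicit), then intergenic. A circle's class is its start
coordinate's class, with the end coordinate's class in a secondary
column. `stratifiedBenchmark()` computes per-class detection metrics over
the truth annotation.

## Problem sizes and verification

The test suite works at desk scale, chosen to keep full runs in a couple
of minutes while leaving no algorithmic branch untested: clustering and
combination laws on up to 5 tools × 200 random circles; simulator
contracts on 10,000-pair runs (realized coverage within 5% of request;
truncated-lognormal lengths checked against an independent Monte-Carlo
draw by KS test); binomial tails verified against exhaustive enumeration
to $N = 12$; and an end-to-end run of 200 circles at ×30 on a 2-Mb
synthetic genome, where feeding the truth back as predictions must give
precision = recall = F = 1 and the junction screen on the simulated
alignments (circle reads plus linear background over the junction flanks,
the non-circular fraction a real library always contains) must give a
median deltaCJ below 0.1. Without that background the windows hold only
junction-proximal circle reads, $N$ is small and the median imbalance of
even perfect circles sits near 0.2 — worth remembering when interpreting
deltaCJ on unusually clean, background-free data.

## Limitations

The simulator's uniform placement makes repeat-class stratification on
simulated data sparse in rare classes; deltaCJ has no power below 9
junction reads and treats the two windows as independent evidence, which
overlapping circles can violate; and the consensus strategies count tool
support only — no weighting by tool reliability or read-level evidence
merging is attempted.
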