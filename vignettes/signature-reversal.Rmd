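---
title: "Signature reversal: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature reversal: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigrev)
```

## The problem

A disease state — the motivating case is the interferon-activated
monocyte compartment of people living with HIV on long-term
suppressive therapy — leaves a transcriptional signature: a set of
genes shifted up (and down) relative to controls, measured as
differential-expression tables in one or more biological contexts
(here: sorted CD14+ monocytes and whole PBMCs). Drug-perturbation
databases catalogue, for thousands of compounds, the transcriptional
response to treatment as ordered up- and down-regulated gene sets.
`sigrev` ranks those compounds by how strongly their response
*opposes* the disease signature, clusters them by reversal profile
across contexts, extracts the genes that the best cluster recurrently
pushes down, and re-checks candidates in a treated-versus-vehicle
expression experiment.

## Reversal scoring

### Pre-ranked enrichment

Each disease context yields a ranked list: genes sorted by a signed
per-gene score, descending. The default ranking metric is the DE test
statistic (it folds in dispersion, the usual choice for pre-ranked
GSEA); signed log2 fold-change is available via `metric = "log2fc"`
because with tabular inputs either is defensible and the upstream DE
model is not part of this package. Ties are broken by gene id, so a
ranking is a pure function of the table's contents.

For a gene set $S$ and ranked scores $s_1 \ge \dots \ge s_N$, the
running sum increases by $|s_i|^w / \sum_{j \in S} |s_j|^w$ at members
of $S$ and decreases by $1/(N - |S|)$ elsewhere; the enrichment score
ES is the signed deviation of maximum magnitude. $w = 1$ is the
default (standard GSEA weighting); $w = 0$ gives the classical
Kolmogorov–Smirnov statistic. Genes of $S$ missing from the ranking
are dropped with a message — they carry no rank information — rather
than being treated as misses.

### Permutation NES and p-value

Only ranked lists exist at this stage, so the null is gene-set
permutation: `n_perm` (default 1000) uniform random sets of the same
size. Normalization is sign-stratified, $\mathrm{NES} = \mathrm{ES} /
|\mathrm{mean}(\text{same-sign null ES})|$, the de-facto standard; the
p-value is $(1 + \#\{\text{same-sign nulls at least as extreme}\}) /
(1 + \#\{\text{same-sign nulls}\})$, never exactly zero. If no null
shares the observed sign the NES is reported as undefined (a classed
error), not silently zeroed.

The null distribution depends only on the ranking, the set size and
the weight — not on the particular gene set — so the library scan
computes one null per (context, set size) and shares it across drugs.
Its seed is derived deterministically from the stage seed and the
context label, which makes results independent of the order in which
drugs are scored, and, because a drug's up- and down-set of equal size
share the same null, makes the up/down-swap antisymmetry of ΔNES an
exact identity rather than a statistical one.

### ΔNES, clustering, selection, targets

Per drug and context, $\Delta\mathrm{NES} = \mathrm{NES(down)} -
\mathrm{NES(up)}$; large positive values mean the drug's response
opposes the disease. The drugs × contexts matrix is k-means clustered
on the raw values (NES values from one permutation scheme already
share a scale, so rows are not standardized): k-means++ seeding, Lloyd
iterations, `n_init = 10` restarts keeping the lowest total
within-cluster sum of squares. The function default is `k = 50`,
matching the figure-level choice in the motivating study, whose
methods text says `k = 40` — the discrepancy in the source is
surfaced, not resolved: `k` is always an explicit argument, and the
packaged default configuration for the 200-drug synthetic study uses
`k = 10`, scaled to that library size. An agglomerative alternative
(`method = "ward"`) exists because the same study's figure caption
calls the procedure hierarchical; k-means is the primary reading.

"Highest ΔNES in both contexts" is operationalized as the argmax over
clusters of the *minimum* across contexts of the per-context mean ΔNES
— robust to a cluster that dominates one context only; an overall-mean
rule is selectable. Ties break by larger overall mean, then larger
cluster, then lower index.

Recurring targets are counted from the leading edges (set members at
or before the running-sum extremum for positive ES) of the selected
drugs' *down* signatures, in one context — configurable, defaulting to
the first in lexicographic order, since nothing in the source material
fixes which context was used. The table is cut at `top_n = 35` rows,
mirroring the size of the recurring-target signature in the motivating
study.

## Validation readout

The verification experiment compares per-sample enrichment of fixed
gene signatures between treated and DMSO samples. The per-sample score
is an ssGSEA-style statistic: genes ranked by within-sample expression
(ties by gene id), rank weights $(N - \mathrm{pos} + 1)^{0.25}$, and
the score is the mean of the running sum — a normalized area in
$[-1, 1]$ that depends on the expression vector only through its
ranks, hence is invariant to any monotone per-sample transform. This
deliberately replaces a kernel-CDF GSVA-style score: at the scale of
this comparison the conclusion rests on rank separation between
groups, and the simpler statistic has clean extremal and monotonicity
properties that the test suite verifies directly. The exponent is
exposed (`weight = 0.25`).

Group comparison is a two-sided Wilcoxon rank-sum test (exact when the
combined sample size is ≤ 20 and untied; normal approximation with
continuity correction otherwise; all-constant groups are defined to
p = 1), with the median difference as effect size — negative means the
treatment reduced the signature. Donors are not paired (rank-sum, not
signed-rank), matching the named test in the source figure.
Significance labels are `**` p < 0.01, `*` p < 0.05, strict
inequalities, per-comparison; a Benjamini–Hochberg option exists but
is off by default to mirror per-comparison asterisks.

## The synthetic study

The generators exist so that every downstream stage has a planted
truth. The disease model is a normal location shift: module genes'
scores are $\mathcal N(\mu, \sigma)$, background $\mathcal N(0,
\sigma)$ — downstream stages consume only ranks of a per-gene score,
so negative-binomial count realism would add machinery without
changing what is being tested. Adjusted p-values are the
Benjamini–Hochberg transform of the two-sided normal tail of the
score, a deterministic monotone function of $|score|$ that makes
"top-N significant genes" well defined. The reference conditions
(`sim_config()` defaults) are a 2000-gene universe, a 137-gene module
(the size of a printed signature set in the motivating study) shifted
by 3 score units against unit noise, two contexts, and 200 drugs: 10%
reversers, 10% mimickers, 50-gene sets, coherence 0.8. Class counts
round down, reversers first, then mimickers, remainder neutral.

A reverser's down-set takes $\lceil \text{coherence} \cdot
\text{set\_size} \rceil$ genes from the module and the rest uniformly
from the remaining universe; at coherence 0 it is exactly a uniform
draw (the hypergeometric overlap a neutral drug has), at coherence 1
it sits inside the module. Its up-set is a uniform draw from the
universe excluding the down-set — the only neutral choice, since the
disease model has no down-module to mirror. Mimickers are the
symmetric construction. The planted classes are written only to a
JSON sidecar marked test-only; the files the pipeline consumes carry
no trace of them.

The validation generator gives every donor one sample per treatment
plus DMSO; module genes are elevated by the module effect on the log2
scale at baseline, a reverser subtracts coherence × elevation from
them, a mimicker adds it, neutrals add nothing; multiplicative
log-normal noise (default sd 0.5 on log2) is applied per gene and
sample. There is no donor random effect and no gene–gene correlation
beyond the planted module — so passing tests demonstrate recovery of
planted rank structure under independent noise, not robustness to
batch effects, correlated pathways, or count-level noise of real
expression data.

## Numerical choices

* The running sum accumulates hit mass and miss counts separately and
  divides the integer miss count once, so a single top-ranked (or
  bottom-ranked) gene attains ES exactly +1 (−1).
* The ES extremum uses an explicit tie rule: deviations within 1e-10
  of the maximum magnitude are tied and the earliest rank wins. On
  small discrete rankings a running sum can touch $+m$ and $-m$
  exactly, where bit-level accumulation noise would otherwise decide
  the sign of ES (and thereby which null stratum a permutation falls
  in). The O(set size) scorer used for permutations replays the same
  accumulation order, so the fast and full paths agree bit for bit.
* Degenerate inputs are classed errors, not silent values: empty
  overlap with the ranking, a set covering the whole universe, zero
  total hit weight, NES with an empty same-sign null stratum.
* k-means++ seeding falls back to uniform choice when all remaining
  distances are zero; duplicate seeds are dropped before Lloyd
  iterations so identical-row inputs degrade gracefully.

## Problem sizes in the test suite

Module tests run on small universes (hundreds of genes, tens of
drugs). The acceptance-style checks use: exhaustive subset enumeration
for all universes of 5–8 genes with set sizes 1–3 against 10,000
permutations; 200 random drugs for the ΔNES identity; the full
reference simulation (2000 genes, 200 drugs, 1000 permutations) for
planted-truth recovery; 20 independent replicates of the verification
experiment (5 donors, one reverser, one neutral per replicate); and
two complete pipeline runs compared byte for byte. These sizes were
chosen so the whole suite exercises every stage at full fidelity in
well under an hour on a single core.

## Known limitations

* **The ΔNES noise floor.** The NES of a *random* gene set has unit
  spread by construction (sign-stratified NES concentrates near ±1),
  and a reverser's up-set is random, so each reverser's ΔNES
  coordinate carries roughly one NES unit of irreducible noise per
  context even when its down-set signal is essentially constant. A
  planted reverser population therefore spans ~2.5 NES units per
  context, and a hard partition at moderate k splits it; the selected
  cluster is reliably *pure* (high precision) but captures only the
  strongest fraction of the planted reversers (modest recall). This is
  a property of the ΔNES statistic itself, not of the implementation;
  applications that need high recall should treat the selected cluster
  as the head of a ranked list, not as an exhaustive candidate set.
* Gene identifiers are opaque case-sensitive strings; no cross-database
  symbol mapping is attempted.
* The ssGSEA-style readout is not numerically comparable to kernel-CDF
  GSVA scores from other software, only rank-logically comparable.
* The package does not fit DE models, process single-cell data, or
  query perturbation databases; it consumes their tabular exports.
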