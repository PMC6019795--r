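---
title: "Scoring bidirectionally perturbed pathways across tissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring bidirectionally perturbed pathways across tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heteropath)
```

## The problem

Mean-based gene set enrichment asks whether a pathway's genes move up or
down *together* in one condition. Many biologically regulated pathways do
something different: in a given cell type some members are induced while
others are repressed, so the pathway's average expression barely moves. A
parametric average-fold-change score or a rank-based enrichment score sees
nothing, even though half the pathway is strongly perturbed in each
direction. This package scores exactly that kind of *bidirectional*
perturbation, for designs where the same cell type has been profiled in
several tissues (e.g. endothelial cells isolated from brain, lung and
heart), and carries the result through to promoter motif enrichment and a
tissue-specific transcription-factor network.

## The heterogeneity model

All expression values are log2-scale normalized intensities (RMA-style), so
a fold change of $c$ is a difference of $\log_2 c$.

**Virtual median cell.** For gene $i$, $M_2(i)$ is the median of its values
over *all* samples of all tissues — a synthetic reference profile of the
cell type. Each tissue $T$ is compared against it through

$$t_i(T) = \frac{M_1(i,T) - M_2(i)}{s(i,T)},$$

where $M_1(i,T)$ is the median over $T$'s replicates and $s(i,T)$ is the
pooled standard deviation of the two groups via the usual two-sample
formula $\sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}$. The reference
group defaults to all samples (`reference = "all"`); a variant using only
the other tissues' samples is available (`reference = "rest"`). A phrase
like "the standard deviation of the median" is not well defined, and the
all-samples group is the only reading under which a pooled standard
deviation exists; we expose both group choices because the alternative is
equally defensible.

**Filter and score.** A gene passes the fold-change filter in tissue $T$
when $|M_1 - M_2| \ge \log_2 c$, with $c = 2$ by default. The heterogeneity
score of gene set $S$ is

$$HS(S, T) = \sum_{i \in S,\ \mathrm{pass}} |t_i(T)|,$$

so up- and downregulated members contribute alike — a mean-zero
bidirectional perturbation produces a large $HS$ while its pathway Z-score
(below) stays near 0. Genes absent from the expression matrix are simply
not summed; a set with no measured or no passing members scores 0.

**Permutation inference.** Sample-to-tissue labels are permuted and steps
above recomputed per permutation. Two label assignments that differ only by
shuffling samples *within* a tissue induce the same grouping, so the
distinct arrangements number $N!/\prod_t n_t!$. When that count is at most
`exhaustive_cap` (default 10,000) all arrangements are enumerated and

$$p = \frac{\#\{HS_{perm} \ge HS_{obs}\}}{N_{arr}};$$

otherwise Monte Carlo sampling is used with the add-one estimator
$p = (1 + \#\{HS_{perm} \ge HS_{obs}\})/(1 + n_{perm})$. Ties count in both
cases, so $p > 0$ and the test is valid (never anti-conservative). The
observed arrangement is itself one of the enumerated ones, which is the
exhaustive analogue of the add-one correction.

**FDR and specificity.** Benjamini–Hochberg is applied jointly across all
(set, tissue) tests — the conservative family choice. A set's
"heterogeneous elements" are its measured members passing the filter
somewhere; the set is called specific to tissue $T$ when at least 60% of
those elements pass in $T$ and only in $T$. With any threshold above one
half at most one tissue can qualify.

**Pathway Z-score (display statistic).** Per tissue, the per-gene fold
change is $M_1 - M_2$; with $\mu, \sigma$ the mean and standard deviation
of all genes' fold changes, $x_p$ the set mean and $p$ the set size,
$Z = (x_p - \mu)\sqrt{p}/\sigma$. This is the heatmap statistic; it is
mean-based by construction, which is precisely why it stays near zero on
balanced bidirectional sets.

### Discreteness of the permutation null

With $k$ tissues of $n$ replicates, the null distribution of $HS(S,T)$ has
at most $\binom{kn}{n}$ atoms, because the score depends only on which
samples form $T$'s group. Three tissues of three replicates give 84 atoms:
no per-test p-value can fall below $1/84 \approx 0.012$, and after a joint
BH correction over, say, 63 tests a single truly perturbed set cannot reach
$q < 0.05$ no matter how strong its signal. This is a property of small
balanced designs, not of the implementation; q-values below 0.05 on such
designs arise only when a large fraction of the tested sets share the floor
(as happens on real organ panels with hundreds of pathways), or with more
replicates or tissues. We deliberately did not adopt the strictly-greater
tie convention, which would push the floor to $1/N_{arr}$: under the
fold-change filter many null sets have $HS = 0$ in *every* arrangement, and
a strict inequality would assign them $p = 1/N_{arr}$ instead of 1,
destroying calibration and the FDR. The tests assert the conservative
behaviour and treat the floor as part of the design.

## Comparator scores

Two minimal, self-contained comparators are included, labeled
`"pgsea-like"` and `"gsea-like"` in their output; parity with the published
packages is a non-goal — they exist to reproduce the qualitative contrasts
and to feed the evaluation protocol.

* **Average fold change (parametric).** Per sample, gene fold change =
  value − gene's all-sample median; the set score is the one-sample
  t-statistic of the members' fold changes against zero
  ($p$ two-sided on $n_{set}-1$ df, floored at $10^{-15}$; the standard
  deviation is floored at $10^{-8}$ so constant fold changes yield a large
  finite score). Per-tissue score = mean of per-sample scores; the
  aggregation is unstated in the comparator literature we mirror, and the
  mean is the obvious choice.
* **Weighted KS (rank-based).** Per tissue, genes are ranked by the
  pooled-variance two-sample t of that tissue against the rest (the
  t-statistic ranking); the enrichment score is the signed maximum of the
  weighted running sum with weight exponent 1. Significance is by phenotype
  permutation under the same arrangement scheme as the heterogeneity test,
  two-sided via $|ES|$.

## The simulation harness

Data follow a linear additive model $y_{ij} = \alpha_i + \beta_{ij} +
\varepsilon_{ij}$ with gene effect $\alpha_i \sim N(0,1)$, noise
$\varepsilon \sim N(0,1)$, and a sample effect $\beta \sim N(0,1)$ except
for the truly shifted genes in group 1, which get $\beta \sim
N(\mu_1, 0.5)$ with $\mu_1 = 0.5$ ("weak") or $1$ ("strong"). The shifted
genes are a configured fraction (rounded half-up) of a differentially
expressed set of 50 or 150 genes out of $m = 5000$; a disjoint same-size
set serves as the matched null. $\beta$ is drawn independently per (gene,
sample) cell: the construction already requires the sample effect to differ
between shifted and unshifted genes within the same sample, so a purely
per-sample shared effect is not implementable as stated. Null cells
therefore have variance 2 around the gene effect — the moment the generator
tests assert.

Samples split into three near-equal groups (group sizes
$\lceil\cdot\rceil$ first when $n$ is not divisible by 3, matching the
$n = 10, 20, 40$ designs). Each scoring method is turned into a
genes-to-samples score matrix and a classical one-way fixed-effects ANOVA
tests for a group mean difference at $\alpha = 0.05$; power and type-I
error are rejection rates over replicate datasets, reported with Wilson
intervals. The continuous-integration runs use 200 replicates per cell (the
full 500 is a flag away) and $n \in \{10, 20, 40\}$.

**Per-sample heterogeneity analogue.** $HS$ is defined per tissue, but the
ANOVA harness needs per-sample scores. The analogue used replaces the
tissue median with the sample value and the pooled standard deviation with
the gene's all-sample standard deviation:
$\sum_{i \in S,\ \mathrm{pass}} |x_{ij} - M_2(i)|/s_2(i)$. This is an
interpretation (the tissue-level score admits no unique per-sample
decomposition) and it has a consequence worth stating plainly: the score is
an absolute deviation, so it responds to the *variance* of the perturbed
cells as much as to their mean. The simulated strong effect tightens
group-1 variance ($\sigma_1 = 0.5$ versus 1) while shifting the mean by 1;
the two influences partially cancel, and in our runs the analogue's power
under the strong effect is *lower* than under the weak effect, while the
tissue-level algorithm itself has no such inversion. The power study
reports what it measures; the monotonicity-in-effect property holds for the
two mean-based comparators and fails for this analogue under these exact
generator settings. Type-I error is controlled for all three methods.

## The evaluation protocol

Ground truth for ROC analysis is built from the two comparators' q-values:
positive below 0.01 and negative above 0.2, in *both* methods by default
(`rule = "either"` is available; the agreement reading is the conservative
resolution of an ambiguous protocol sentence). The heterogeneity score is
swept at fold-change thresholds 1.5, 2 and 3 (per set, the maximum over
tissues, pooled across tissues); AUC is computed as the Mann–Whitney
statistic with half credit for ties — identical to the trapezoidal
integral of the tie-aware ROC curve — and its significance by permuting
the positive/negative labels, exhaustively when
$\binom{n}{n_{pos}} \le 10{,}000$. On synthetic fixtures, where truth is
known by construction, the same machinery runs without the comparators.

## Promoter scanning and the regulatory network

The scanner implements the MATCH-style similarity scores. With column
frequencies $f(i,b)$ (pseudocount 0.01 per cell before normalization) the
information weight is $I(i) = \sum_b f(i,b)\ln(4 f(i,b))$, a window scores
$\mathrm{Current} = \sum_i I(i) f(i, b_i)$, and
$\mathrm{MSS} = (\mathrm{Current} - \mathrm{Min})/(\mathrm{Max} -
\mathrm{Min})$ with Min/Max the per-position extreme weighted frequencies.
The core similarity score applies the same formula to the 5 consecutive
positions of largest total information (leftmost on ties; the whole motif
when shorter than 5). A hit requires both scores at or above the cutoff
(0.7 by default); both strands are scanned (minus strand via the
reverse-complemented matrix), windows containing N never match, and a
uniform matrix — where Max equals Min — scores 0 by convention and never
matches. Scores are clipped to $[0,1]$ against floating-point residue.

Motif over-representation compares the number of target promoters with at
least one hit against the same statistic on random same-size draws from a
user-supplied background, with the add-one empirical p-value. The minSum
cutoff selection samples positives from the matrix's own column
distributions, measures false negatives on them and false positives on
background windows (both on the MSS; the core score only gates hit
calling), and takes the cutoff minimizing FN% + FP% on a 0.50–1.00 grid,
preferring the larger cutoff on ties. Network edges are drawn, per
significant heterogeneous set and tissue, from transcription factors whose
motif is enriched ($p < 0.05$) *and* whose own expression is upregulated in
that tissue ($t > 0$ and passing the filter) to the set's filter-passing
members that carry a hit; curated factor–motif pairs are tagged
`annotated`, scan-only pairs `putative`.

## What the synthetic generators emulate — and what they do not

The expression fixture draws per-gene baselines $N(0, 1)$ with replicate
noise $N(0, 0.25)$ in log2 units — replicate variability typical of
RMA-processed arrays — and plants pathway perturbations as clean ±effect
shifts confined to one tissue, with decoy sets drawn from the whole gene
universe (so decoys can share genes with planted sets, as real pathways
overlap). It does not emulate correlated co-expression within pathways,
probe-level artifacts, heavy-tailed noise, or the broad continuum of
effect sizes in real organ panels; tests passing on it demonstrate the
algorithmic contracts (ranking, calibration, contrasts), not field
performance. The calibration fixtures use replicate noise of 1 log2 unit
so that the fold-change filter is genuinely exercised under the null. The
promoter fixture uses uniform-random 500 bp sequences with a 12 bp,
0.95-concentration consensus motif: long and sharp enough that a random
500 bp sequence matches at the 0.7 cutoff only ~20% of the time — a 10 bp
motif at the same cutoff matches most random sequences and cannot support
an enrichment test — while instances sampled from the matrix itself are
essentially always recovered. Real promoters are GC-biased and repetitive;
a GC-matched background mode is the obvious extension and the background
is always a user input.

## Numerical and design choices

* Zero-variance guard: $10^{-8}$ added to every pooled standard deviation;
  genes with both variance and numerator below the guard get $t = 0$.
* The fold-change filter is recomputed inside every permutation.
* Duplicate probes collapse to the per-sample maximum by default
  (`mean` and `first` available); the collapse rule in the source studies
  is unknown, and the maximum is the common conservative choice for
  presence signals. Missing values are rejected, not imputed.
* A fixed Mersenne-Twister stream seeded from the user seed makes every
  generator and Monte Carlo routine bit-reproducible; simulation replicates
  derive their stream from (seed, replicate index).
* Reported problem sizes in the test-suite: 2,000-gene fixtures with 21
  sets for the ranking contrast (50 seeds), 510 (set, tissue) tests for
  null calibration, 200-replicate simulation cells, 100-instance AUC
  oracle sweeps, 100-run motif-enrichment panels.

## Known limitations

* Small balanced designs carry the permutation-floor limit described
  above; with 3×3 designs, per-test p-values below 1/84 are impossible.
* The per-sample heterogeneity analogue is variance-sensitive (see the
  simulation section); conclusions about the tissue-level algorithm's
  power should rest on the tissue-level statistic.
* The comparator implementations are deliberately minimal; they are not
  drop-in replacements for the published packages.
* The scanner's core-region tie-break (leftmost) can differ from other
  MATCH implementations on exactly tied cores; ties have measure zero for
  matrices estimated from counts.
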