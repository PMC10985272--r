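---
title: "Detecting differential transcript usage in heterogeneous cohorts"
author: "heteroDTU authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential transcript usage in heterogeneous cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heteroDTU)
```

## The problem

Differential transcript usage (DTU) is a change, between groups of
samples, in the relative proportions of a gene's isoforms, independent of
the gene's overall expression level. Standard DTU tools assume both groups
are internally homogeneous: all cases share the event, all controls lack
it. In complex diseases that assumption routinely fails — a cohort
diagnosed with one label may contain several genetically distinct
subgroups, each carrying its own set of splicing abnormalities. An event
present in a quarter of the cases is diluted into insignificance when the
whole case group is compared against the controls.

heteroDTU detects such subgroup-restricted events. Per transcript it asks
whether the case group's isoform-fraction distribution is *bimodal*, and
if so, compares each side of the partition against the matched side of the
control group. Detected events are assembled into a binary gene-by-sample
event matrix from which case subgroups ("spliceotypes" — subgroups sharing
the same DTU events) are recovered by clustering.

## The statistic, step by step

**Isoform fractions.** Transcript counts $t_{i,j}$ (sample $i$, transcript
$j$) become isoform fractions
$\mathrm{IF}_{i,j} = t_{i,j} / \sum_{k \in G_j} t_{i,k}$, where $G_j$ is
the set of transcripts of $j$'s gene. Where the gene total is zero the
fraction is undefined and carried as `NA` — a 0/0 ratio carries no usage
information, so such samples are excluded from density fits and rank tests
rather than treated as zeros. Fractions are rounded to three decimals
(sub-millesimal differences are quantification noise) and jittered by
$\mathrm{U}(-5\times10^{-4}, 5\times10^{-4})$ to break the ties rounding
creates.

**Partitioning.** A Gaussian KDE with bandwidth $h$ is fitted to the case
group's fractions on a fixed 512-point grid covering $[0,1]$ extended by
$3h$ on each side. The split point $m$ is the lowest interior local
minimum bracketed by two local maxima; a unimodal fit yields no split.
Local extrema are read off discrete first differences of the grid values,
which makes the decision reproducible and resolution-independent at the
three-decimal fraction precision; maxima carrying less than $10^{-6}$ of
the peak density are disregarded as floating-point artifacts of the FFT
evaluation. Oversmoothing is deliberate: large $h$ suppresses spurious
multimodality from overdispersed data, at the cost of overlooking fine
substructure, and $h = 1$ disables subgroup search entirely (useful for
tissue-to-tissue comparisons).

**Tails and tests.** Given $m$, the left tails are the samples with
$\mathrm{IF} \le m$ in each group and the right tails those above. Left is
compared with left and right with right by two-sided Mann-Whitney U tests,
and the transcript's p-value is the smaller of the two. Without a split
the whole groups are compared. Exact U p-values are used when both groups
have fewer than 8 members and the data are tie-free; otherwise a normal
approximation with tie and continuity correction. Two guards temper
outlier effects: a control tail smaller than `nSmall` is expanded across
the split with the nearest-fraction control samples (a small control tail
is a sampling accident, not biology), whereas a case tail smaller than
`nSmall` invalidates the partition itself and forces whole-group mode —
case tails are the biological object of interest and must be large enough
to interpret.

**The empirical null.** Instead of modelling per-transcript dispersion,
the pipeline estimates a single null distribution of *minimal* U-statistic
p-values from the control group, in the spirit of min-P/max-T procedures.
Each of $S$ iterations randomly halves the controls, draws one shared
random split point $o_s \sim \mathrm{U}(0,1)$, runs the tail tests for
every transcript, takes each transcript's minimal tail p-value, and stores
the minimum across transcripts — with the proviso that a transcript may
contribute the stored minimum only once across all iterations, so a single
wildly overdispersed transcript cannot dominate the null. The calling
threshold is the $\max(1, \lfloor\kappa S\rfloor)$-th smallest stored
minimum; transcripts with observed $p \le$ threshold are candidates. We
use a non-strict comparison at the threshold. $\kappa$ trades sensitivity
for specificity: the candidate set is monotone in $\kappa$ by
construction.

With fewer than 16 controls each half drops below 8 samples and the rank
tests collapse onto a few discrete p-values. In that regime the halves are
padded to the true case/control sizes with fractions resampled from the
transcript's own pooled control values (preserving its marginal while
adding rank noise — the padding distribution is our choice; only "random
values" is prescribed), the shared split point is skipped, and the stored
p-value is a uniform draw from the lowest 1% of the iteration's p-values
rather than the minimum, restoring p-value variability. The
one-contribution-per-transcript rule is applied in both modes.

**Event vectors and the DTU matrix.** Each called transcript gets a binary
vector $v_j$ over all samples: controls are always 0; in split mode the
case tail whose test drove the call (the smaller p-value) is marked; in
whole-group mode every case sample is marked. The definition of $v_j$ in
terms of which samples carry the event is only loosely constrained by the
method's outputs, and "mark the driving tail" is our concrete rule. Gene
calls are the union over transcripts, and each called gene's row in the
event matrix $M$ is taken from its smallest-p transcript.

**Likelihood flags.** For each candidate, the control-group KDE is
evaluated at the case fractions; the score $L_j$ is the mean log density
(mean, not sum, so $L$ is invariant to subgroup size — the aggregator is
unspecified in the procedure's description and is our choice). In split
mode each tail is scored and the smaller value assigned. Scores across
candidates are screened by the modified z-score
$0.6745\,(L - \mathrm{med})/\mathrm{MAD}$ with the conventional 3.5
cutoff, flagging only the low side: case fractions sitting where controls
have no density are suspicious, an unusually concentrated case group is
not. Genes with at least one outlier transcript are flagged as the most
compelling candidates.

## Pre-filtering

Six stringent steps, each individually switchable, run in a fixed order on
the progressively surviving set: (1) transcript CPM $\ge 1$ in $\ge$
`nSmall` samples; (2) positive counts in $\ge p_r$ of case samples *and*
of control samples (we read "in both groups" as holding per group); (3)
gene count $\ge g_c$ in $\ge g_n$ samples; (4) IF $> f$ in $\ge$ `nSmall`
samples; (5) $\ge 2$ surviving transcripts per gene; (6) one isoform
dominant in $\ge p_d$ of controls. Defaults: `nSmall` 12 (the smallest
cohort scale at which the statistics behave), $p_r = 0.2$, $g_c = 10$,
$g_n = 1$, $f = 0.1$, $p_d = 0.75$. Because steps recompute gene totals
and fractions on the surviving set, re-filtering filtered output is a
no-op in ordinary data (only a gene hovering exactly at the $g_c$
boundary after losing a transcript could fall on a second pass).

Two auxiliary gates address very low expression. The *filtered-CPM mask*
recomputes gene-level CPM over the surviving genes only (library size =
per-sample total of surviving genes) and masks samples below CPM 10 out of
that gene's rank tests: at a gene count of 10, fractions of 0.2 vs 0.6
are four reads apart and carry no usage signal. The *sample QC* counts per
sample the genes under the gate and drops samples whose modified z-score
exceeds 3.5 on the high side only.

## The simulator

`simulateCohort()` emulates a bulk RNA-seq control population: log-normal
gene means (median 200 counts, $\sigma_{\log} = 1$), negative-binomial
per-sample gene totals (size 5, i.e. clearly super-Poisson), per-gene
isoform-fraction profiles with one dominant isoform (base fraction drawn
from $[0.55, 0.9]$) jittered per sample by a Dirichlet draw
(concentration 100), and stochastic rounding that preserves expected
totals. These values were fixed once as a plausible bulk cohort profile —
strong but imperfect dominance, dispersion visibly above Poisson — and
the dominance step retains over 80% of multi-transcript genes at the
default concentration, so the injector has a realistic gene pool.

`injectDTU()` reproduces the evaluation recipe: among genes with a
consistently dominant isoform in controls, select a superset $D$ (100 by
default), split the case samples into disjoint equal-size subgroups (the
subgroup sizes of the original design are unstated; disjoint equal splits
are our choice), draw 30 genes per subgroup from $D$ *with replacement* —
so events are shared between some subgroups and exclusive to others — and
swap the dominance of the most and least dominant isoforms
($\mathrm{IF}_\alpha \leftarrow v \pm \epsilon$,
$\mathrm{IF}_\beta \leftarrow u \pm \epsilon$, $\epsilon = 0.05$,
per-sample uniform noise truncated into $(0,1)$). Counts are rebuilt from
the sample's gene total and fractions renormalize on recomputation.
Genes drawn into no subgroup receive no perturbation, so evaluation truth
is the union of the subgroup gene sets, not $D$ itself. What the
simulator does *not* model: correlated gene expression, GC/length biases,
annotation errors, and real quantification uncertainty — passing tests
demonstrate the statistics behave as designed, not that real tissue data
are this clean. Pseudo inferential replicates are Poisson resamples
around the point estimates; real bootstrap or Gibbs replicate matrices
can be supplied instead, and calls then require a strict majority across
replicate runs (ties suppress the call). The null distribution is built
once from the point-estimate controls and reused across replicates.

## Confounder control

A candidate's event vector $v_j$ partitions all samples into high- and
low-IF sides. If a recorded covariate partitions them equally well, the
call cannot be distinguished from confounding. Per candidate we regress
$\mathrm{IF}_j$ on $[v_j, x_1, \dots, x_k]$ with 100 depth-one regression
trees (bootstrap of full sample size, split minimizing L1 loss around
leaf means, root split only with $\ge$ `nSmall` samples) and compute
permutation importances: $\gamma = R^2 - R^2_{\mathrm{shuffled}}$ over 50
shuffles per column, with $R^2 = 1 - u/v$ computed from leaf assignments
on the evaluated data and averaged over trees (tree-level averaging is
our choice of ensemble aggregation). The candidate is kept only if the
first quartile of $\gamma_{v_j}$ exceeds the largest third quartile among
the covariates. Categorical covariates are one-hot encoded; a covariate
scores as the per-permutation maximum over its dummies, which is
conservative toward dropping. Each tree scans columns in random order, so
two columns inducing the same partition (tied loss) share the splits
across the ensemble instead of the first column absorbing all of them —
without this, a covariate that mirrors $v_j$ exactly would appear
unimportant and the veto would never fire. With no covariates the
maximum over the empty set is $-\infty$ and every candidate is kept.

## Hyperparameter fitting

`fitHyperparameters()` estimates $(h^*, \kappa^*)$ from the user's own
controls: each of $n_e$ experiments halves the control group into
simulated case/control sets, pre-filters (skipping the dominance step,
which would bias the gene pool toward the genes about to be injected),
and injects subgroup DTU. Leave-one-out cross-validation over the grids
$h \in \{0.02, \dots, 0.20\}$, $\kappa \in \{0.1, \dots, 1\}$ selects per
step the pair maximizing mean F over the held-in experiments ("estimated
F-scores" we read as the mean over the $n_e - 1$ experiments), evaluates
it on the held-out one, and reports the modal pair plus the mean
held-out F as $\bar F$. The F-score is $2tp/(2tp + fp + fn)$. Ties break
toward the smaller $\kappa$, then the larger $h$ — the conservative
direction. Because the null build uses random split points rather than
the KDE, it is independent of $h$; each experiment therefore needs one
null build plus one test pass per bandwidth, and per-experiment derived
seeds make the result invariant to evaluation order. Without fitting,
the defaults are $(h, \kappa) = (0.09, 0.6)$. Fitting requires at least
16 controls and is reliable from about 32.

## Clustering

Case samples are compared by the proportion of DTU events unique to
either sample relative to their *pairwise* union of events (Jaccard
distance; the denominator — pairwise union versus global event count —
is ambiguous in the method's description, and the pairwise union keeps
the metric scale-free per pair). Two event-free samples are at distance
0. Agglomerative clustering uses average linkage by default (unspecified
upstream; ward/complete are selectable), and flat labels come from a
user-supplied $k$ or the largest gap in merge heights. All-one rows from
whole-group calls are shared by every case sample and therefore neutral
to the partition.

## Numerical choices and degenerate inputs

* Density evaluation for likelihood scores interpolates the 512-point
  grid linearly; values below $10^{-12}$ are floored before the log, and
  a case group sitting entirely on zero control density scores
  $-\infty$ and is flagged directly.
* Quartiles use the default type-7 (linear interpolation) definition.
* An odd control count sends the extra sample to the first half of the
  null split.
* `MAD = 0` in sample QC or flagging disables the respective screen with
  a warning rather than dividing by zero.
* Empty pre-filter survivor sets warn and return empty objects; empty
  groups in detection are errors.
* All randomness (jitter, splits, bootstraps, permutations) draws from
  the session RNG: `set.seed()` makes every pipeline output
  bit-reproducible.

## Problem sizes used in the test suite

The packaged checks run the full pipeline at the simulation design of the
evaluation study scaled to a desk machine: 1,000 genes, 60 case and 60
control samples, 100 injected events over 5 spliceotypes, 100 null
iterations, with 10 seeded replicates for the FDR and null-behaviour
properties; unit fixtures are far smaller. These sizes were chosen so
the whole suite exercises every claim in minutes while keeping the
per-spliceotype subgroup (12 samples) at the method's stated minimum
reliable scale.

## Known limitations

* Multi-way (more than two) subgroup splits per transcript are
  deliberately out of scope: oversmoothing folds them into a whole-group
  comparison.
* $\kappa$ is not a FWER target; it indexes an order statistic of the
  empirical null. Small $\kappa$ empirically controls family-wise error
  but offers no analytic guarantee.
* Confounding control vetoes calls; it does not adjust fractions for
  covariates, and confounders concentrated in the control group can
  still depress sensitivity through the null.
* Strong group-size imbalance degrades the tail tests; groups of at
  least 12, and 24 for comfortable normal approximation in the null,
  are recommended.
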