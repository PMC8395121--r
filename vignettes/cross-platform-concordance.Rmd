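---
title: "Cross-platform differential-expression concordance and transient dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform differential-expression concordance and transient dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degconcord)
```

## The problem

Transcriptome experiments are endpoint measurements: each study captures
one time point on one measurement platform. Building a time course of a
cellular response — for instance, the reaction of immune cells to altered
gravitational load over seconds to minutes — therefore means combining
differential-expression (DE) result tables produced by different
technologies, typically oligonucleotide microarrays and RNA-Seq. The two
platforms differ in sensitivity, dynamic range and normalization
artifacts, so any meta-analysis first has to establish *how far the
platforms agree*, and only then ask biological questions such as *does
the initial transcriptional response persist, drift, or revert?*

`degconcord` implements that comparison framework as composable
operations over per-gene DE tables (`deg_table`): regulation calls,
direction-aware overlap accounting, set-inclusion sweeps, rank
concordance, consensus DEG sets, biotype and chromosome-level
aggregation, three-time-point trajectory classification, and pre-ranked
gene set enrichment. A seeded synthetic generator produces paired-platform
tables with planted ground truth so every stage can be validated end to
end without any external download.

## Regulation calls

All downstream accounting rests on a four-way per-gene call at
significance level $\alpha$ (default 0.05, Benjamini–Hochberg adjusted
p-values throughout):

* `UP`: adjusted $p < \alpha$ and $\log_2\mathrm{FC} > 0$;
* `DOWN`: adjusted $p < \alpha$ and $\log_2\mathrm{FC} < 0$;
* `UNOBSERVED`: adjusted p-value missing (the gene is unobservable on
  that platform — filtered out before testing, or absent from the
  table);
* `NS`: everything else.

Two boundary choices are deliberate and conservative: equality
$p = \alpha$ is `NS` (the strict inequality leaves ties unassigned), and
a significant gene with $\log_2\mathrm{FC} = 0$ is `NS` because a call
requires a strict sign. Genes present in one table but absent from the
other are treated as `UNOBSERVED` in the absent table for every pairwise
operation; this mirrors the convention that only genes with a
non-missing adjusted p-value count towards any denominator.

## Directional overlap and the inclusion sweep

`directional_overlap()` cross-tabulates two call sets into eight
categories over the union of genes called `UP` or `DOWN` on at least one
platform — concordant (both up, both down), contradictory (opposite
directions), and platform-exclusive per direction — plus a `neither`
count for shared genes carrying no call at all. The eight called
categories partition the union exactly, which is asserted as a test
invariant. Two detection fractions are reported per direction because
"detected in the other data set" is genuinely ambiguous: *any-direction*
detection (significant in the other table regardless of sign) and
*direction-matched* detection. Both are exposed rather than choosing one.

A hard cutoff at 0.05 can make two platforms look more discordant than
they are. `inclusion_sweep()` keeps one platform's cutoff fixed at
$\alpha$ and halves the other's per iteration
($0.05, 0.025, 0.0125, 0.00625, 0.003125$ with the default four
halvings — the last value prints as 0.0031 at four decimals), reporting
the overlap count as a frequency of the swept platform's significant
genes. A stricter core that remains contained in the other platform's
calls indicates that disagreement lives in the marginally significant
tail, not in the strong signal.

## Consensus sets and cross-platform dynamics

`consensus_degs()` intersects two tables on genes significant in *both*
with the *same* fold-change sign; the average fold change is the
arithmetic mean of the two $\log_2$ values (log-scale averaging is
symmetric between up- and downregulation, which linear-scale averaging
is not). `rank_by_average_fc()` produces the top-$n$ table per
direction (default 21), ordered by $|\overline{\log_2\mathrm{FC}}|$
with lexicographic gene-id tie-breaks so output is reproducible.

For time courses, `classify_trajectories()` labels each gene with its
ordered call triple over three time points and reports hierarchical
counts: 3 groups by the first time point, split into 9 by the second,
into 27 by the third, plus a Sankey-ready edge list. Genes `UNOBSERVED`
at *any* time point are excluded from all levels (and counted), rather
than imputed: a flow is only meaningful for genes measurable everywhere.
The third time point can be a consensus call set (`consensus_calls()`)
when the last measurement is cross-validated by two platforms.

Adaptation is defined as *no longer carrying the initial call*: a gene
significantly regulated at the first time point has adapted at a later
one if it reverted to `NS` **or** reversed direction. This definition is
needed to reconcile two facts about transient responses: a response can
be called fully adapted even while some genes are counter-regulated
(not yet back at baseline) at the late time point. Pure reversion to
`NS` is exposed separately as `reverted_pct`. The percentage is
truncated (not rounded) to one decimal, matching the convention of
reporting such fractions alongside their raw counts (116/1058 prints as
10.9%). `persistence_fraction()` gives the reciprocal view: the share
of initially up- (down-) regulated genes still carrying that call later.

## Aggregated-level characterization

`biotype_composition()` reports per-direction biotype counts and
fractions after removing biotypes with fewer than `min_biotype_count`
(default 20) occurrences *in the entire table* — rare annotation classes
produce unstable percentages. Missing annotations are grouped as
`unannotated` rather than dropped.

`chromosome_enrichment_tests()` runs two independent Fisher exact test
families per chromosome:

1. **Total load** — is the chromosome's DEG count out of line with its
   share of observable genes?
   $[[n_{deg}, n_{obs}-n_{deg}], [N_{deg}-n_{deg},
   (N_{obs}-n_{obs})-(N_{deg}-n_{deg})]]$;
2. **Direction balance** — does its up:down ratio deviate from the rest
   of the genome? $[[n_{up}, n_{down}],
   [N_{up}-n_{up}, N_{down}-n_{down}]]$.

Each family is BH-adjusted **across chromosomes separately** (the two
families answer different questions and are corrected as separate test
families), and stars are assigned from adjusted values (`*` < 0.05,
`**` < 0.01). Expected counts under random placement are
$E[n_{deg}(c)] = N_{deg}\cdot n_{obs}(c)/N_{obs}$ and
$E[n_{up}(c)] = n_{deg}(c)\cdot N_{up}/(N_{up}+N_{down})$; the expected
totals sum to the observed DEG total by construction. The second test's
comparison group is the complement of the chromosome (not the global
totals including it), keeping the two margins independent. Chromosomes
are reported in natural order 1–22, X, Y, MT; non-canonical contigs are
grouped as `"other"` and excluded from testing unless requested.

## Statistical primitives

The pipeline's primitives are self-contained and oracle-tested:

* `bh_adjust()` is the textbook step-up estimator
  ($\mathrm{adj}_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)$), with
  missing values passed through and excluded from $m$. Adjustment is
  always applied per declared test family, never pooled.
* `fisher_exact_2x2()` computes the two-sided p by point-probability
  summation over the hypergeometric support, with a $1{+}10^{-7}$
  relative tolerance when comparing point probabilities so
  exactly-tied tables are never excluded by floating-point error. A
  zero margin is degenerate and returns 1.
* `quantile_normalize()` maps every sample to the per-rank mean
  distribution; within-column ties receive the mean of the target
  values over the tied ranks, making the operation idempotent.
* `median_polish()` is Tukey's sweep (rows first, default 10 sweeps,
  tolerance $10^{-6}$ on the absolute change in the residual $L_1$
  norm); the decomposition
  $x_{ij} = \mu + r_i + c_j + \varepsilon_{ij}$ is exact by
  construction.

`rma_summarize()` chains the last two as a simplified account of
array-style probe summarization. It deliberately omits the
convolution-model background correction of full RMA — it is a
two-step stand-in used to demonstrate *why* such processing narrows and
shifts fold-change distributions: forcing all samples onto a common
distribution compresses one-sided effect tails, which is exactly the
regime (a heavy tail of downregulated genes) in which the raw and
summarized per-gene effect distributions visibly differ. The test suite
asserts the narrowing as a strict IQR inequality on a tailed synthetic
probe matrix.

## Pre-ranked GSEA

`preranked_es()` is the weighted running-sum statistic: hits advance the
sum by $|s|^w / \sum_{hits}|s|^w$ (default $w = 1$), misses retreat by
$1/(N - N_{hits})$; the enrichment score is the signed maximal
deviation. `gsea_permutation()` builds the null by gene-label
permutation — random same-size sets from the ranking — because a
pre-ranked analysis only has per-gene statistics, not sample labels.
Permutations are shared across sets of equal size for speed. The
nominal p is sign-stratified,
$(1 + \#\{|ES_{perm}| \ge |ES|,\ \mathrm{same\ sign}\}) /
(1 + \#\{\mathrm{same\ sign}\})$, and NES divides the ES by the mean
$|ES_{perm}|$ of same-sign permutations, so the NES sign always matches
the ES sign. Results are BH-adjusted across sets. Set-size bounds
default to 3–5000 and the permutation count to 1000; note that the
attainable minimum of the nominal p is about $2/n_{perm}$ after sign
stratification, so detecting a planted set at FDR 0.05 among $k$ sets
needs $n_{perm} \gtrsim 40k$. `cross_platform_gsea()` intersects two
result lists on sets significant in both and classifies them by NES
sign pair into concordant-positive, concordant-negative and
contradictory.

## The synthetic generator

`simulate_paired_study()` draws, per gene: a regulation state
($U/D/N$) per time point from a three-state Markov chain; a latent
$\log_2$ effect for regulated states from a *sign-truncated* normal
(truncation guarantees the effect's sign matches the state); and two
platform readouts. RNA-Seq observes $\delta + \varepsilon$,
$\varepsilon \sim N(0, se_{rna}^2)$; the microarray observes
$a\,\delta + b + \varepsilon'$ with attenuation $a \in (0,1]$, additive
shift $b$, its own (larger) standard error, and dropout: each truly
upregulated gene's adjusted p-value is set missing with probability
`dropout_up_micro` *before* BH adjustment, so the dropped genes leave
the test family entirely. z-statistics ($\log FC/se$) provide two-sided
normal p-values and the per-gene GSEA ranking statistic.

The default configuration encodes the study conditions the analysis is
meant for: 20,000 observable genes; initial state probabilities
$(U, D, N) = (0.049, 0.004, 0.947)$ (a response of roughly a thousand
altered transcripts, overwhelmingly upregulated); first-transition
persistence of 0.89 for both directions with a large delayed-response
pool entering at the second time point; and a fully transient third
transition in which initially upregulated genes go to $NS$ (0.67) or
counter-regulate downward (0.33) but never stay up. Effects are
$\delta_U \sim TN(1.0, 0.5)$, $\delta_D \sim TN(-1.5, 0.5)$ — the
larger down-magnitude produces the downregulation-skewed tail —
with $se_{rna} = 0.25$, $se_{micro} = 0.30$, $a = 0.6$, $b = 0.1$, and
upregulated-gene dropout 0.5 (the array detecting roughly half the
upregulation the sequencing assay does). Chromosome placement is
proportional to per-chromosome observable gene counts (rough human gene
densities), with an optional planted enrichment multiplying one
chromosome's odds for truly regulated genes; biotypes are drawn from a
categorical distribution dominated by protein-coding genes.

Two generation modes separate concerns: `"calls-direct"` emits the
Markov states as noise-free calls for exact combinatorial checks of the
trajectory machinery, while `"full"` exercises the entire
effects → fold changes → p-values → BH → calls path. A `share_noise`
flag lets both platforms read one shared noise draw scaled by their own
standard errors; with attenuation 1, shift 0, equal standard errors and
no dropout this makes the two platforms' tables identical — the
degenerate configuration used to validate the readout layer.

What the generator does *not* emulate: count-level mean–variance
structure (negative binomial dispersion), probe-sequence effects, batch
structure, and correlated genes. Calibration and power results on this
generator therefore validate the *accounting and inference machinery*,
not the behavior of any specific DE model on real data.

## Numerical and design choices

* **Seeds.** Every stochastic operation takes or derives an integer
  seed and restores the caller's RNG state; identical seeds give
  byte-identical outputs, which the pipeline determinism test asserts
  via file hashes.
* **Attenuation recovery.** The generator/analysis pair is checked by
  recovering $a = 0.6$ from simulated data. A naive OLS slope of
  microarray on RNA-Seq fold changes is biased toward zero by
  errors-in-variables (the latent-effect variance over true DEGs is
  comparable to $se_{rna}^2$), so the check uses the moment-corrected
  slope $\widehat{a} = \mathrm{cov}(y, x)/(\mathrm{var}(x) -
  se_{rna}^2)$ with the generator's known RNA-Seq standard error.
* **Small-count trajectory cells.** The 27-category frequencies are
  compared to the product-chain law with a three-standard-error band
  where the expected count is at least 5, and with an exact binomial
  consistency test below that, where the normal approximation is
  meaningless.
* **Problem sizes.** The validation suite runs at 20,000 genes × 200
  replicates for chromosome-star null calibration, 1,000 genes × 200
  sets for GSEA null calibration, 5,000 genes for attenuation recovery,
  50 replicates for planted-set power, and 10,000 genes for the
  trajectory law — sizes at which the binomial error bands are tight
  enough to be informative while the whole suite completes in a few
  minutes on one core.

## A worked example

```{r example, eval = FALSE}
library(degconcord)

cfg <- synthetic_config(n_genes = 2000, n_gene_sets = 20,
                        set_size_range = c(10, 30), n_planted_sets = 2,
                        seed = 7)
res <- run_pipeline(cfg, output_dir = "replay_demo", gsea_n_perm = 200)
res$summary$overlap
res$summary$adaptation_pct_t1_t3
```

The report bundle contains per-stage TSVs (calls, sweep, consensus,
top fold-change tables, biotype composition, chromosome enrichment,
trajectory categories and edges, GSEA results) plus `summary.json` with
a provenance record (package version, seed, configuration hash).

## Limitations

* The consensus and overlap machinery joins strictly on gene
  identifier; probe-to-gene collapsing and symbol aliasing are upstream
  concerns and out of scope. Tables are assumed to have one row per
  gene.
* `rma_summarize()` is a didactic two-step operation, not a replacement
  for a full array preprocessing pipeline.
* The GSEA implementation uses plain gene-label permutations; it does
  not implement the adaptive multilevel ES approximation of modern
  implementations, so very small p-values are floored at
  $\sim 2/n_{perm}$.
* No statistical test is attached to trajectory flow counts: the flows
  are descriptive, and none is defined for them here.
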