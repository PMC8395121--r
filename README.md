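# degconcord

Cross-platform differential-expression concordance and transient
time-course dynamics for transcriptomics meta-analysis.

## What problem this solves

Transcriptome experiments are endpoint measurements, and in fields where
data are scarce and expensive — gravitational cell biology being the
motivating example — a time course must be assembled from separate
studies run on different platforms (oligonucleotide microarrays,
RNA-Seq). Before such a meta-analysis can say anything biological, it has
to quantify how far the platforms agree, where they disagree, and whether
disagreement lives in the strong signal or the marginal tail.
`degconcord` is for analysts doing exactly that: it consumes per-gene
differential-expression (DE) result tables (one per platform/time point)
and provides the comparison, aggregation and time-course machinery as
tested, composable R functions.

## What it computes

Per-gene regulation calls at FDR level α (default 0.05) split genes into
`UP` (adj. p < α, log2FC > 0), `DOWN` (adj. p < α, log2FC < 0),
`UNOBSERVED` (missing adj. p) and `NS`. On top of the calls:

- **Directional overlap** — concordant / contradictory /
  platform-exclusive intersection counts between two call sets, the
  accounting behind a direction-aware upset analysis;
- **Set-inclusion sweep** — one platform's cutoff fixed at α, the
  other's halved per iteration (0.05 → 0.003125), overlap reported as a
  frequency of the swept set;
- **Spearman concordance** of log2 fold changes, all genes or
  significant-in-both;
- **Consensus DEG sets** (significant in both platforms, same sign) with
  top-n tables ranked by |mean log2FC|;
- **Biotype composition** per direction with a low-occurrence filter
  (default: biotypes with < 20 genes in the table are dropped);
- **Chromosomal enrichment** — per chromosome, two Fisher exact test
  families (total DEG load vs observable share; up/down balance vs the
  rest of the genome), each BH-adjusted across chromosomes, starred at
  0.05/0.01, with expected counts under random placement;
- **Trajectory classification** over three time points into 3 → 9 → 27
  hierarchical categories, with adaptation fractions (a gene "adapts"
  when it no longer carries its initial call) and persistence fractions;
- **Pre-ranked GSEA** — weighted running-sum enrichment score,
  gene-permutation null, sign-stratified nominal p, NES, BH FDR, and a
  cross-platform comparison of significant sets by NES sign;
- **Self-contained primitives** — Benjamini–Hochberg step-up adjustment,
  two-sided Fisher exact test (point-probability summation), quantile
  normalization, Tukey median polish, and an RMA-style probe
  summarization built from the last two;
- **A synthetic study generator** — paired-platform, multi-time-point DE
  tables with planted ground truth: Markov regulation states, truncated
  normal effects with a downregulation-skewed tail, microarray
  attenuation/shift/dropout, planted chromosome enrichment and planted
  gene sets. Everything is deterministic given a seed.

I/O is plain text: TSV for DE tables, calls and all tabular outputs, GMT
for gene sets, JSON for summaries.

## A worked example

```r
library(degconcord)

cfg <- synthetic_config(n_genes = 2000, n_gene_sets = 20,
                        set_size_range = c(10, 30), n_planted_sets = 2,
                        seed = 7)
res <- run_pipeline(cfg, output_dir = "replay_demo", gsea_n_perm = 200)

str(res$summary$overlap)
#> List of 9
#>  $ both_up               : int 1
#>  $ both_down             : int 86
#>  $ contradictory_AupBdown: int 0
#>  $ contradictory_AdownBup: int 0
#>  $ A_only_up             : int 10
#>  $ A_only_down           : int 2
#>  $ B_only_up             : int 3
#>  $ B_only_down           : int 120
#>  $ neither               : int 1778
res$summary$spearman_rho_all
#> [1] 0.2593678
res$summary$adaptation_pct_t1_t3
#> [1] 100
```

Reading the numbers: at the final time point the microarray-style table
(A) and the RNA-Seq-style table (B) agree on 87 genes (1 up, 86 down)
with **zero** contradictory calls; the sequencing platform finds 123
additional DEGs the array misses (its better sensitivity), while the
array contributes 12 exclusive calls. The modest genome-wide rank
correlation (0.26) reflects that most genes are null noise — concordance
concentrates in the significant set. All initially altered genes have
adapted by the third time point (`adaptation_pct_t1_t3 = 100`), the
transient-response signature the default generator configuration
encodes. The output directory holds per-stage TSVs and a `summary.json`
whose provenance block records package version, seed and a configuration
hash; reruns with the same seed are byte-identical.

## Package layout

- `R/` — data model and I/O, statistical primitives, concordance,
  enrichment/aggregation, dynamics, GSEA, the synthetic generator, and
  the `run_pipeline()` replay workflow.
- `tests/testthat/` — unit, property and oracle tests per module plus an
  end-to-end acceptance suite.
- `vignettes/cross-platform-concordance.Rmd` — the methods vignette:
  model definitions, parameter meanings and defaults, design decisions,
  what the generator does and does not emulate, and known limitations.
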