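# Seeded generator of paired-platform, multi-time-point differential
# expression tables with planted ground truth. The generator emulates the
# statistical structure the downstream analysis assumes: a shared latent
# per-gene effect read out by two platforms, microarray fold-change
# attenuation plus an additive shift, dropout of truly upregulated genes on
# the array, a downregulation-skewed effect distribution, Markov transitions
# of regulation state across three time points, chromosome placement with an
# optional planted enrichment, biotype labels, and planted gene-set signal.

#' Configuration for the paired-platform study generator
#'
#' Defaults describe a genome-scale three-time-point hypergravity-style
#' study: roughly 20,000 observable genes of which ~5% start upregulated
#' and ~0.4% downregulated; strong persistence (0.89) of the initial call
#' into the second time point with a large delayed-response pool; and a
#' fully transient third time point at which initially altered genes
#' revert to baseline or counter-regulate. The microarray channel reads
#' the shared latent effect with fold-change attenuation (0.6), a small
#' additive shift, and dropout of half the truly upregulated genes.
#'
#' @param n_genes Number of genes (default 20000).
#' @param timepoints Number of time points, 1 to 3 (default 3).
#' @param initial_state_probs Probabilities over states `U`, `D`, `N` at
#'   the first time point.
#' @param transition_t1_t2,transition_t2_t3 Row-stochastic 3x3 matrices
#'   over `U`, `D`, `N` (rows = from, columns = to).
#' @param effect_mean_up,effect_mean_down,effect_sd Log2-scale effect
#'   distribution: truncated-normal means for up/down states and common
#'   sd. The default down mean is larger in magnitude than the up mean,
#'   giving the fold-change distribution a downregulated tail.
#' @param se_rnaseq,se_micro Per-platform standard errors of the observed
#'   log2 fold change.
#' @param attenuation_micro Multiplicative compression of the latent
#'   effect on the microarray, in (0, 1\].
#' @param dropout_up_micro Probability that a truly upregulated gene is
#'   unobservable (missing adjusted p) on the microarray at that time
#'   point.
#' @param shift_micro Additive log2 fold-change shift on the microarray.
#' @param chromosomes Named integer vector of observable gene counts per
#'   chromosome label; placement probability is proportional to these.
#' @param enriched_chromosome Chromosome label whose odds of receiving a
#'   truly regulated (time point 1) gene are multiplied by
#'   `enrichment_multiplier`; multiplier 1 plants nothing.
#' @param enrichment_multiplier Odds multiplier (default 1).
#' @param biotype_probs Named probability vector over biotype labels.
#' @param n_gene_sets,set_size_range,n_planted_sets Gene-set plan used by
#'   [make_gene_sets()].
#' @param share_noise When `TRUE`, both platforms read the same standard
#'   normal noise draws (scaled by their own standard errors). Useful for
#'   degenerate-configuration checks; default `FALSE` (independent
#'   platform noise).
#' @param seed Integer seed; all outputs are deterministic given it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_genes = 20000L,
    timepoints = 3L,
    initial_state_probs = c(U = 0.049, D = 0.004, N = 0.947),
    transition_t1_t2 = rbind(U = c(U = 0.89, D = 0.01, N = 0.10),
                             D = c(U = 0.01, D = 0.89, N = 0.10),
                             N = c(U = 0.185, D = 0.183, N = 0.632)),
    transition_t2_t3 = rbind(U = c(U = 0.000, D = 0.330, N = 0.670),
                             D = c(U = 0.002, D = 0.000, N = 0.998),
                             N = c(U = 0.001, D = 0.050, N = 0.949)),
    effect_mean_up = 1.0,
    effect_mean_down = -1.5,
    effect_sd = 0.5,
    se_rnaseq = 0.25,
    se_micro = 0.30,
    attenuation_micro = 0.6,
    dropout_up_micro = 0.5,
    shift_micro = 0.1,
    chromosomes = NULL,
    enriched_chromosome = "17",
    enrichment_multiplier = 1,
    biotype_probs = c(protein_coding = 0.78, lncRNA = 0.14,
                      processed_pseudogene = 0.04, snRNA = 0.02,
                      miRNA = 0.02),
    n_gene_sets = 100L,
    set_size_range = c(15L, 100L),
    n_planted_sets = 5L,
    share_noise = FALSE,
    seed = 1L) {
  if (is.null(chromosomes)) {
    # observable gene counts roughly proportional to annotated human
    # gene density per chromosome
    chromosomes <- c(`1` = 2000, `2` = 1300, `3` = 1100, `4` = 800,
                     `5` = 900, `6` = 1000, `7` = 950, `8` = 700,
                     `9` = 800, `10` = 750, `11` = 1300, `12` = 1050,
                     `13` = 350, `14` = 650, `15` = 650, `16` = 900,
                     `17` = 1200, `18` = 300, `19` = 1450, `20` = 550,
                     `21` = 250, `22` = 500, X = 850, Y = 60, MT = 13)
  }
  cfg <- list(n_genes = as.integer(n_genes), timepoints = as.integer(timepoints),
              initial_state_probs = initial_state_probs,
              transition_t1_t2 = transition_t1_t2,
              transition_t2_t3 = transition_t2_t3,
              effect_mean_up = effect_mean_up,
              effect_mean_down = effect_mean_down, effect_sd = effect_sd,
              se_rnaseq = se_rnaseq, se_micro = se_micro,
              attenuation_micro = attenuation_micro,
              dropout_up_micro = dropout_up_micro,
              shift_micro = shift_micro, chromosomes = chromosomes,
              enriched_chromosome = enriched_chromosome,
              enrichment_multiplier = enrichment_multiplier,
              biotype_probs = biotype_probs,
              n_gene_sets = as.integer(n_gene_sets),
              set_size_range = as.integer(set_size_range),
              n_planted_sets = as.integer(n_planted_sets),
              share_noise = isTRUE(share_noise),
              seed = as.integer(seed))
  problems <- character()
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(cfg$n_genes >= 1L, "n_genes must be >= 1")
  chk(cfg$timepoints %in% 1:3, "timepoints must be 1, 2, or 3")
  chk(abs(sum(cfg$initial_state_probs) - 1) < 1e-8 &&
        all(cfg$initial_state_probs >= 0),
      "initial_state_probs must be a probability vector")
  chk(setequal(names(cfg$initial_state_probs), c("U", "D", "N")),
      "initial_state_probs must be named U, D, N")
  for (nm in c("transition_t1_t2", "transition_t2_t3")) {
    m <- cfg[[nm]]
    chk(is.matrix(m) && all(dim(m) == c(3L, 3L)) && all(m >= 0) &&
          all(abs(rowSums(m) - 1) < 1e-8),
        paste(nm, "must be a 3x3 row-stochastic matrix"))
  }
  chk(cfg$effect_sd > 0, "effect_sd must be > 0")
  chk(cfg$se_rnaseq > 0 && cfg$se_micro > 0, "platform SEs must be > 0")
  chk(cfg$attenuation_micro > 0 && cfg$attenuation_micro <= 1,
      "attenuation_micro must lie in (0, 1]")
  chk(cfg$dropout_up_micro >= 0 && cfg$dropout_up_micro <= 1,
      "dropout_up_micro must lie in [0, 1]")
  chk(!is.null(names(cfg$chromosomes)) && all(cfg$chromosomes > 0),
      "chromosomes must be a named vector of positive counts")
  chk(is.null(cfg$enriched_chromosome) ||
        cfg$enriched_chromosome %in% names(cfg$chromosomes),
      "enriched_chromosome must be one of the chromosome labels")
  chk(cfg$enrichment_multiplier > 0, "enrichment_multiplier must be > 0")
  chk(abs(sum(cfg$biotype_probs) - 1) < 1e-8 && all(cfg$biotype_probs >= 0),
      "biotype_probs must be a probability vector")
  chk(length(cfg$set_size_range) == 2L &&
        cfg$set_size_range[1L] <= cfg$set_size_range[2L] &&
        cfg$set_size_range[1L] >= 1L,
      "set_size_range must be (min, max) with 1 <= min <= max")
  chk(cfg$n_planted_sets <= cfg$n_gene_sets,
      "n_planted_sets cannot exceed n_gene_sets")
  if (length(problems) > 0L) {
    stop("invalid synthetic_config:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# sample from a normal truncated to the positive (sign = 1) or negative
# (sign = -1) half-line, by inverse-CDF
rtruncnorm_signed <- function(n, mean, sd, sign) {
  if (n == 0L) return(numeric(0L))
  if (sign > 0) {
    lo <- stats::pnorm(0, mean, sd)
    stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
  } else {
    hi <- stats::pnorm(0, mean, sd)
    stats::qnorm(stats::runif(n) * hi, mean, sd)
  }
}

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

#' Simulate a paired-platform, multi-time-point DE study
#'
#' Draws a regulation state per gene and time point from the configured
#' Markov chain, a latent log2-scale effect per regulated gene-time
#' (truncated normal, so the effect's sign always matches the state), and
#' two platform readouts of that effect: RNA-Seq observes it directly
#' with noise; the microarray observes it attenuated, shifted, noisier,
#' and with dropout of truly upregulated genes. Per-gene z statistics and
#' two-sided normal p-values are BH-adjusted within each table.
#'
#' @param cfg A [synthetic_config()].
#' @param mode `"full"` (effects -> fold changes -> p-values -> calls) or
#'   `"calls-direct"` (emit the Markov-chain states as noise-free calls;
#'   no tables are generated).
#' @return A list with `tables` (per platform, a list of [deg_table()]
#'   per time point; `NULL` in calls-direct mode), `calls` (per platform
#'   per time point in full mode; one noise-free set per time point in
#'   calls-direct mode), and `truth` (states, effects, dropout mask,
#'   chromosome, biotype, and the config).
#' @export
simulate_paired_study <- function(cfg, mode = c("full", "calls-direct")) {
  stopifnot(inherits(cfg, "synthetic_config"))
  mode <- match.arg(mode)
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    tp <- cfg$timepoints
    gene_id <- sprintf("gene%05d", seq_len(n))
    states <- matrix(NA_character_, n, tp)
    lv <- c("U", "D", "N")
    states[, 1L] <- sample(lv, n, replace = TRUE,
                           prob = cfg$initial_state_probs[lv])
    transitions <- list(cfg$transition_t1_t2, cfg$transition_t2_t3)
    for (t in seq_len(tp - 1L)) {
      tr <- transitions[[t]]
      for (s in lv) {
        idx <- which(states[, t] == s)
        if (length(idx) > 0L) {
          states[idx, t + 1L] <- sample(lv, length(idx), replace = TRUE,
                                        prob = tr[s, lv])
        }
      }
    }
    # chromosome placement: proportional to observable counts, with the
    # enriched chromosome's odds multiplied for genes regulated at t1
    probs <- cfg$chromosomes / sum(cfg$chromosomes)
    chrom <- character(n)
    is_deg1 <- states[, 1L] != "N"
    chrom[!is_deg1] <- sample(names(probs), sum(!is_deg1), replace = TRUE,
                              prob = probs)
    probs_deg <- probs
    if (!is.null(cfg$enriched_chromosome)) {
      probs_deg[cfg$enriched_chromosome] <-
        probs_deg[cfg$enriched_chromosome] * cfg$enrichment_multiplier
      probs_deg <- probs_deg / sum(probs_deg)
    }
    chrom[is_deg1] <- sample(names(probs_deg), sum(is_deg1), replace = TRUE,
                             prob = probs_deg)
    biotype <- sample(names(cfg$biotype_probs), n, replace = TRUE,
                      prob = cfg$biotype_probs)
    effects <- matrix(0, n, tp)
    for (t in seq_len(tp)) {
      iu <- which(states[, t] == "U")
      id <- which(states[, t] == "D")
      effects[iu, t] <- rtruncnorm_signed(length(iu), cfg$effect_mean_up,
                                          cfg$effect_sd, 1)
      effects[id, t] <- rtruncnorm_signed(length(id), cfg$effect_mean_down,
                                          cfg$effect_sd, -1)
    }
    truth <- list(gene_id = gene_id, states = states, effects = effects,
                  chromosome = chrom, biotype = biotype, config = cfg)
    if (mode == "calls-direct") {
      map <- c(U = "UP", D = "DOWN", N = "NS")
      calls <- lapply(seq_len(tp), function(t) {
        regulation_calls(gene_id, map[states[, t]])
      })
      truth$dropout <- matrix(FALSE, n, tp)
      return(list(tables = NULL, calls = calls, truth = truth))
    }
    dropout <- matrix(FALSE, n, tp)
    # pre-drawn noise and dropout streams keep the RNG sequence fixed
    # regardless of configuration flags
    eps_rna <- matrix(stats::rnorm(n * tp), n, tp)
    eps_mic <- if (cfg$share_noise) eps_rna else
      matrix(stats::rnorm(n * tp), n, tp)
    dropout_u <- matrix(stats::runif(n * tp), n, tp)
    make_table <- function(platform, t) {
      delta <- effects[, t]
      if (platform == "rnaseq") {
        se <- cfg$se_rnaseq
        logfc <- delta + se * eps_rna[, t]
      } else {
        se <- cfg$se_micro
        logfc <- cfg$attenuation_micro * delta + cfg$shift_micro +
          se * eps_mic[, t]
      }
      z <- logfc / se
      p <- 2 * stats::pnorm(-abs(z))
      if (platform == "micro" && cfg$dropout_up_micro > 0) {
        drop <- states[, t] == "U" & dropout_u[, t] < cfg$dropout_up_micro
        p[drop] <- NA_real_
        dropout[drop, t] <<- TRUE
      }
      deg_table(data.frame(gene_id = gene_id, log2fc = logfc, pvalue = p,
                           adj_pvalue = bh_adjust(p), chromosome = chrom,
                           biotype = biotype, rank_stat = z,
                           stringsAsFactors = FALSE))
    }
    tables <- list(
      rnaseq = lapply(seq_len(tp), function(t) make_table("rnaseq", t)),
      micro = lapply(seq_len(tp), function(t) make_table("micro", t)))
    calls <- lapply(tables, function(pl) lapply(pl, classify_regulation))
    truth$dropout <- dropout
    list(tables = tables, calls = calls, truth = truth)
  })
}

#' Simulate a probe-level expression matrix with known gene effects
#'
#' Probe intensity is `baseline(gene) + condition_effect(gene, group) +
#' probe_affinity + sample_shift + noise` on the log2 scale. Samples are
#' split into two equal groups; a configurable fraction of genes carries a
#' one-sided (downregulated-in-group-2) tail of condition effects, the
#' regime in which quantile normalization plus median polish visibly
#' narrows the per-gene effect distribution relative to raw probe means.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples (>= 2; split into two groups).
#' @param n_probes_per_gene Probes per gene.
#' @param baseline_sd Sd of per-gene baseline expression around 8.
#' @param affinity_sd Sd of per-probe affinities.
#' @param shift_sd Sd of per-sample additive shifts.
#' @param noise_sd Sd of i.i.d. measurement noise.
#' @param tail_frac Fraction of genes in the one-sided effect tail.
#' @param tail_effect_mean Mean magnitude of the (negative) tail effects.
#' @param seed Integer seed.
#' @return A list with `matrix` (probes x samples), `probe_gene`,
#'   `group` (sample group labels), and `truth` (per-gene condition
#'   effects, per-probe affinities, per-sample shifts).
#' @export
simulate_probe_matrix <- function(n_genes = 200L, n_samples = 6L,
                                  n_probes_per_gene = 4L, baseline_sd = 1,
                                  affinity_sd = 0.5, shift_sd = 0.3,
                                  noise_sd = 0.1, tail_frac = 0.2,
                                  tail_effect_mean = 2, seed = 1L) {
  stopifnot(n_samples >= 2L, n_genes >= 1L, n_probes_per_gene >= 1L)
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    group <- rep(c("ctrl", "cond"), length.out = n_samples)
    group <- sort(group, decreasing = TRUE)  # ctrl first
    baseline <- stats::rnorm(n_genes, 8, baseline_sd)
    effect <- numeric(n_genes)
    tail_genes <- seq_len(round(tail_frac * n_genes))
    effect[tail_genes] <- -abs(stats::rnorm(length(tail_genes),
                                            tail_effect_mean, 0.5))
    probe_gene <- rep(genes, each = n_probes_per_gene)
    affinity <- stats::rnorm(length(probe_gene), 0, affinity_sd)
    shift <- stats::rnorm(n_samples, 0, shift_sd)
    m <- matrix(0, length(probe_gene), n_samples,
                dimnames = list(NULL, paste0(group, seq_len(n_samples))))
    for (s in seq_len(n_samples)) {
      signal <- baseline + if (group[s] == "cond") effect else 0
      m[, s] <- signal[match(probe_gene, genes)] + affinity + shift[s] +
        stats::rnorm(length(probe_gene), 0, noise_sd)
    }
    list(matrix = m, probe_gene = probe_gene, group = group,
         truth = list(gene_effects = stats::setNames(effect, genes),
                      baseline = stats::setNames(baseline, genes),
                      affinity = affinity, shift = shift))
  })
}

#' Build gene sets over a simulated study, with planted signal
#'
#' Draws `n_gene_sets` sets with sizes uniform in `set_size_range`. The
#' first `n_planted_sets` are drawn from the genes truly upregulated at
#' the first time point (so a pre-ranked GSEA on a first-time-point
#' ranking should flag them with positive NES); the remainder are drawn
#' uniformly from the whole gene universe.
#'
#' @param truth The `truth` component of [simulate_paired_study()].
#' @param cfg The [synthetic_config()] used (supplies the gene-set plan).
#' @param seed Integer seed (defaults to `cfg$seed + 1`).
#' @return A [gene_set_collection()] with attribute `planted` naming the
#'   planted sets.
#' @export
make_gene_sets <- function(truth, cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(seed, {
    universe <- truth$gene_id
    true_up <- universe[truth$states[, 1L] == "U"]
    size_choices <- cfg$set_size_range[1L]:cfg$set_size_range[2L]
    sizes <- if (length(size_choices) == 1L)
      rep(size_choices, cfg$n_gene_sets)
    else sample(size_choices, cfg$n_gene_sets, replace = TRUE)
    sets <- vector("list", cfg$n_gene_sets)
    names(sets) <- sprintf("SET_%03d", seq_len(cfg$n_gene_sets))
    for (i in seq_len(cfg$n_gene_sets)) {
      if (i <= cfg$n_planted_sets) {
        if (length(true_up) < sizes[i]) {
          stop("not enough truly upregulated genes (", length(true_up),
               ") to fill a planted set of size ", sizes[i], call. = FALSE)
        }
        sets[[i]] <- sample(true_up, sizes[i])
      } else {
        sets[[i]] <- sample(universe, sizes[i])
      }
    }
    out <- gene_set_collection(sets)
    attr(out, "planted") <- if (cfg$n_planted_sets > 0L)
      names(sets)[seq_len(cfg$n_planted_sets)] else character(0L)
    out
  })
}
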