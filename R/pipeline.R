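# End-to-end "replay" workflow: simulate a paired-platform study, then run
# classification, overlap, sweep, consensus, biotype, chromosome
# enrichment, trajectory dynamics and GSEA, writing a TSV + JSON report
# bundle with a provenance record. Every number in the JSON summary is
# produced by the corresponding module operation, never by report-side
# arithmetic.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(cfg), control = "all"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full simulate-then-analyze pipeline
#'
#' Chains the whole analysis on one synthetic study: simulate paired
#' tables, classify regulation per platform and time point, compute the
#' cross-platform directional overlap and set-inclusion sweep at the final
#' time point, build the consensus DEG set and its top fold-change tables,
#' characterize biotype composition and chromosomal enrichment, classify
#' three-time-point trajectories (skipped with a notice when fewer than
#' three time points are configured), and run pre-ranked GSEA on both
#' platforms with a cross-platform comparison. All tabular outputs are
#' TSV; a single JSON summary carries the headline numbers plus a
#' provenance record (package version, seed, configuration hash). Output
#' is byte-identical across reruns with the same configuration and seed.
#'
#' @param config A [synthetic_config()]; its `seed` is overridden by
#'   `seed` when that is supplied.
#' @param output_dir Directory for the report bundle (created if absent).
#' @param seed Optional integer overriding `config$seed`.
#' @param alpha Significance cutoff used throughout (default 0.05).
#' @param n_halvings Set-inclusion sweep halvings (default 4).
#' @param min_biotype_count Biotype low-count filter (default 20).
#' @param top_n Genes per direction in the top fold-change tables
#'   (default 21).
#' @param gsea_n_perm Permutations for GSEA (default 1000).
#' @return Invisibly, a list with the in-memory stage results and
#'   `summary` (what was written to `summary.json`).
#' @export
run_pipeline <- function(config = synthetic_config(), output_dir,
                         seed = NULL, alpha = 0.05, n_halvings = 4L,
                         min_biotype_count = 20L, top_n = 21L,
                         gsea_n_perm = 1000L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  sim <- stage("simulate", simulate_paired_study(config))
  tp <- config$timepoints
  rna <- sim$tables$rnaseq[[tp]]
  mic <- sim$tables$micro[[tp]]
  for (pl in names(sim$tables)) {
    for (t in seq_len(tp)) {
      write_tsv(sim$calls[[pl]][[t]],
                file.path(output_dir, sprintf("calls_%s_t%d.tsv", pl, t)))
    }
  }
  ov <- stage("overlap", directional_overlap(sim$calls$micro[[tp]],
                                             sim$calls$rnaseq[[tp]]))
  sweep_res <- stage("sweep", inclusion_sweep(mic, rna, alpha_fixed = alpha,
                                              n_halvings = n_halvings))
  write_tsv(sweep_res, file.path(output_dir, "inclusion_sweep.tsv"))
  cons <- stage("consensus", consensus_degs(mic, rna, alpha = alpha))
  write_tsv(cons, file.path(output_dir, "consensus_degs.tsv"))
  top_up <- rank_by_average_fc(cons, "UP", n = top_n)
  top_down <- rank_by_average_fc(cons, "DOWN", n = top_n)
  write_tsv(top_up, file.path(output_dir, "top_up_by_avg_fc.tsv"))
  write_tsv(top_down, file.path(output_dir, "top_down_by_avg_fc.tsv"))
  bt <- stage("biotype", biotype_composition(
    mic, sim$calls$micro[[tp]], min_biotype_count = min_biotype_count))
  write_tsv(bt$composition, file.path(output_dir, "biotype_composition.tsv"))
  ce <- stage("chrom-enrich", chromosome_enrichment_tests(
    mic, sim$calls$micro[[tp]]))
  write_tsv(ce, file.path(output_dir, "chromosome_enrichment.tsv"))
  rho <- stage("spearman", spearman_concordance(mic, rna))
  dyn <- NULL
  adapt <- NULL
  if (tp >= 3L) {
    cons_calls <- consensus_calls(mic, rna, alpha = alpha)
    dyn <- stage("dynamics", classify_trajectories(
      sim$calls$micro[[1L]], sim$calls$micro[[2L]], cons_calls))
    write_tsv(data.frame(label = names(dyn$level3),
                         count = as.integer(dyn$level3)),
              file.path(output_dir, "trajectory_27_categories.tsv"))
    write_tsv(dyn$edges, file.path(output_dir, "trajectory_edges.tsv"))
    adapt <- list(
      t1_t2 = adaptation_fraction(sim$calls$micro[[1L]],
                                  sim$calls$micro[[2L]]),
      t1_t3 = adaptation_fraction(sim$calls$micro[[1L]], cons_calls))
  } else {
    message("dynamics stage skipped: fewer than three time points")
  }
  sets <- stage("gene-sets", make_gene_sets(sim$truth, config))
  write_gmt(sets, file.path(output_dir, "gene_sets.gmt"))
  ranking <- function(t) stats::setNames(t$rank_stat, t$gene_id)
  gsea_rna <- stage("gsea", gsea_permutation(
    ranking(rna), sets, n_perm = gsea_n_perm, seed = config$seed,
    alpha = alpha))
  gsea_mic <- stage("gsea", gsea_permutation(
    ranking(mic)[!is.na(mic$adj_pvalue)], sets, n_perm = gsea_n_perm,
    seed = config$seed, alpha = alpha))
  write_tsv(gsea_rna, file.path(output_dir, "gsea_rnaseq.tsv"))
  write_tsv(gsea_mic, file.path(output_dir, "gsea_micro.tsv"))
  xg <- stage("gsea-compare", cross_platform_gsea(gsea_mic, gsea_rna,
                                                  alpha = alpha))
  write_tsv(xg$shared_significant,
            file.path(output_dir, "gsea_cross_platform.tsv"))
  summary <- list(
    provenance = list(
      package = "degconcord",
      version = as.character(utils::packageVersion("degconcord")),
      seed = config$seed,
      config_md5 = config_hash(config)),
    n_genes = config$n_genes,
    timepoints = tp,
    overlap = ov[c("both_up", "both_down", "contradictory_AupBdown",
                   "contradictory_AdownBup", "A_only_up", "A_only_down",
                   "B_only_up", "B_only_down", "neither")],
    spearman_rho_all = rho,
    n_consensus = nrow(cons),
    n_consensus_up = sum(cons$direction == "UP"),
    n_consensus_down = sum(cons$direction == "DOWN"),
    sweep_final_cutoff = sweep_res$cutoff_swept[nrow(sweep_res)],
    n_starred_chromosomes_total = sum(ce$stars_total != ""),
    adaptation_pct_t1_t3 = if (is.null(adapt)) NULL else
      adapt$t1_t3$fraction_pct,
    gsea = list(n_significant_rnaseq = sum(gsea_rna$significant),
                n_significant_micro = sum(gsea_mic$significant),
                n_concordant_positive = xg$n_concordant_positive,
                n_concordant_negative = xg$n_concordant_negative,
                n_contradictory = xg$n_contradictory))
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, overlap = ov, sweep = sweep_res,
                 consensus = cons, biotype = bt, chromosome = ce,
                 dynamics = dyn, adaptation = adapt, gsea_rnaseq = gsea_rna,
                 gsea_micro = gsea_mic, cross_gsea = xg, summary = summary))
}
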