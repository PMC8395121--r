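# Aggregated-level characterization of a DEG set: biotype composition with
# low-count filtering, per-chromosome expected counts, and the two Fisher
# exact test families (total DEG load; up/down ratio) with per-family BH
# correction and significance stars.

CANONICAL_CHROMOSOMES <- c(as.character(1:22), "X", "Y", "MT")

#' Biotype composition of up- and downregulated genes
#'
#' Counts and fractions of gene biotypes among the `UP` and `DOWN` calls.
#' Biotypes occurring fewer than `min_biotype_count` times across the
#' entire table (all genes, regardless of call) are filtered out before
#' per-direction counting; genes without a biotype annotation are grouped
#' as `"unannotated"`.
#'
#' @param t A [deg_table()].
#' @param calls Matching [regulation_calls()] (defaults to
#'   [classify_regulation()] of `t`).
#' @param min_biotype_count Occurrence threshold for retaining a biotype
#'   (default 20).
#' @return A list of class `biotype_composition`: `composition` (a
#'   data.frame with `direction`, `biotype`, `count`, `fraction`) and
#'   `filtered_out` (the dropped biotype labels). Fractions within a
#'   direction sum to 1 over retained biotypes.
#' @export
biotype_composition <- function(t, calls = classify_regulation(t),
                                min_biotype_count = 20L) {
  stopifnot(inherits(t, "deg_table"), inherits(calls, "regulation_calls"))
  biotype <- ifelse(is.na(t$biotype), "unannotated", t$biotype)
  tab <- table(biotype)
  keep <- names(tab)[tab >= min_biotype_count]
  filtered_out <- setdiff(names(tab), keep)
  call <- calls$call[match(t$gene_id, calls$gene_id)]
  rows <- list()
  for (dir in c("UP", "DOWN")) {
    bt <- biotype[call == dir & biotype %in% keep]
    if (length(bt) == 0L) next
    cnt <- table(bt)
    rows[[dir]] <- data.frame(direction = dir, biotype = names(cnt),
                              count = as.integer(cnt),
                              fraction = as.numeric(cnt) / sum(cnt),
                              stringsAsFactors = FALSE)
  }
  composition <- if (length(rows)) do.call(rbind, rows) else
    data.frame(direction = character(), biotype = character(),
               count = integer(), fraction = numeric())
  rownames(composition) <- NULL
  structure(list(composition = composition, filtered_out = filtered_out),
            class = "biotype_composition")
}

# Per-chromosome bookkeeping shared by the expected-count and test
# operations. Canonical chromosomes in natural order; anything else is
# grouped as "other".
chromosome_counts <- function(t, calls, include_other = FALSE) {
  stopifnot(inherits(t, "deg_table"), inherits(calls, "regulation_calls"))
  observable <- !is.na(t$adj_pvalue)
  chrom <- t$chromosome
  canonical <- chrom %in% CANONICAL_CHROMOSOMES
  chrom[!canonical & !is.na(chrom)] <- "other"
  keep <- observable & !is.na(chrom)
  if (!include_other) keep <- keep & chrom != "other"
  chrom <- factor(chrom[keep],
                  levels = c(CANONICAL_CHROMOSOMES,
                             if (include_other) "other"))
  call <- calls$call[match(t$gene_id[keep], calls$gene_id)]
  df <- data.frame(
    chromosome = levels(chrom),
    n_observable = as.integer(table(chrom)),
    n_deg = as.integer(table(chrom[call %in% c("UP", "DOWN")])),
    n_up = as.integer(table(chrom[call == "UP"])),
    n_down = as.integer(table(chrom[call == "DOWN"])),
    stringsAsFactors = FALSE)
  empty <- df$n_observable == 0L
  present_all <- unique(chrom_all <- {
    ca <- t$chromosome
    ca[!(ca %in% CANONICAL_CHROMOSOMES) & !is.na(ca)] <- "other"
    ca
  })
  unobservable_only <- empty & df$chromosome %in% present_all
  if (any(unobservable_only)) {
    warning("chromosome(s) with no observable genes excluded: ",
            paste(df$chromosome[unobservable_only], collapse = ", "),
            call. = FALSE)
  }
  df <- df[!empty, ]
  rownames(df) <- NULL
  df
}

#' Expected DEG counts per chromosome under random placement
#'
#' The expected total DEG count on a chromosome is the genome-wide DEG
#' total multiplied by that chromosome's share of observable genes
#' (adjusted p-value not missing). The expected upregulated count is the
#' chromosome's observed DEG count multiplied by the global ratio of up-
#' to up-plus-downregulated genes.
#'
#' @param t A [deg_table()].
#' @param calls Matching [regulation_calls()].
#' @param include_other Include non-canonical contigs (grouped as
#'   `"other"`); default `FALSE`.
#' @return A data.frame with one row per chromosome: `chromosome`,
#'   `n_observable`, `n_deg`, `n_up`, `n_down`, `expected_total`,
#'   `expected_up` (`NA` when there are no `UP`/`DOWN` genes globally).
#' @export
chromosome_expected_counts <- function(t, calls = classify_regulation(t),
                                       include_other = FALSE) {
  df <- chromosome_counts(t, calls, include_other)
  if (sum(df$n_observable) == 0L) {
    stop("no observable genes on any chromosome", call. = FALSE)
  }
  n_deg_total <- sum(df$n_deg)
  n_up_total <- sum(df$n_up)
  n_down_total <- sum(df$n_down)
  df$expected_total <- n_deg_total * df$n_observable / sum(df$n_observable)
  df$expected_up <- if (n_up_total + n_down_total == 0L) NA_real_ else
    df$n_deg * n_up_total / (n_up_total + n_down_total)
  df
}

#' Dual Fisher exact test families for chromosomal enrichment
#'
#' Two independent Fisher exact tests per chromosome. The first asks
#' whether the chromosome carries more (or fewer) DEGs than its share of
#' observable genes predicts: `[[n_deg, n_obs - n_deg], [N_deg - n_deg,
#' (N_obs - n_obs) - (N_deg - n_deg)]]`. The second asks whether its
#' up/down ratio deviates from the rest of the genome: `[[n_up, n_down],
#' [N_up - n_up, N_down - n_down]]`. Each family's p-values are BH-adjusted
#' across chromosomes separately, and stars assigned from the adjusted
#' values (`*` below `alpha_star`, `**` below `alpha_doublestar`).
#'
#' @param t A [deg_table()].
#' @param calls Matching [regulation_calls()].
#' @param alpha_star,alpha_doublestar Adjusted-p thresholds for `*` and
#'   `**` (defaults 0.05 and 0.01).
#' @param include_other Include non-canonical contigs as `"other"`.
#' @return A data.frame of class `chromosome_enrichment`, one row per
#'   chromosome, with observed and expected counts, `p_total`, `p_updown`,
#'   `adj_p_total`, `adj_p_updown`, `direction_of_deviation`
#'   (`"above"`/`"below"` expectation), `stars_total`, `stars_updown`.
#' @export
chromosome_enrichment_tests <- function(t, calls = classify_regulation(t),
                                        alpha_star = 0.05,
                                        alpha_doublestar = 0.01,
                                        include_other = FALSE) {
  df <- chromosome_expected_counts(t, calls, include_other)
  if (nrow(df) < 2L) stop("need at least 2 chromosomes", call. = FALSE)
  n_obs_total <- sum(df$n_observable)
  n_deg_total <- sum(df$n_deg)
  n_up_total <- sum(df$n_up)
  n_down_total <- sum(df$n_down)
  df$p_total <- vapply(seq_len(nrow(df)), function(i) {
    fisher_exact_2x2(
      df$n_deg[i], df$n_observable[i] - df$n_deg[i],
      n_deg_total - df$n_deg[i],
      (n_obs_total - df$n_observable[i]) - (n_deg_total - df$n_deg[i]))
  }, numeric(1L))
  df$p_updown <- vapply(seq_len(nrow(df)), function(i) {
    fisher_exact_2x2(df$n_up[i], df$n_down[i],
                     n_up_total - df$n_up[i], n_down_total - df$n_down[i])
  }, numeric(1L))
  df$adj_p_total <- bh_adjust(df$p_total)
  df$adj_p_updown <- bh_adjust(df$p_updown)
  df$direction_of_deviation <-
    ifelse(df$n_deg >= df$expected_total, "above", "below")
  stars <- function(p) ifelse(p < alpha_doublestar, "**",
                              ifelse(p < alpha_star, "*", ""))
  df$stars_total <- stars(df$adj_p_total)
  df$stars_updown <- stars(df$adj_p_updown)
  class(df) <- c("chromosome_enrichment", "data.frame")
  df
}
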