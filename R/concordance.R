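# Pairwise cross-platform comparison: regulation calls, directional overlap
# accounting, set-inclusion sweep, Spearman concordance, consensus DEG sets,
# top-N average-fold-change tables, and DEU gene-list overlap.

CALL_LEVELS <- c("UP", "DOWN", "NS", "UNOBSERVED")

#' Construct a set of per-gene regulation calls
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param call Character vector of calls in `UP`, `DOWN`, `NS`,
#'   `UNOBSERVED`.
#' @param alpha The significance cutoff the calls were made at.
#' @return A data.frame of class `regulation_calls` with attribute `alpha`.
#' @export
regulation_calls <- function(gene_id, call, alpha = 0.05) {
  gene_id <- trimws(as.character(gene_id))
  call <- as.character(call)
  stopifnot(length(gene_id) == length(call))
  if (anyDuplicated(gene_id)) stop("duplicate gene_id", call. = FALSE)
  if (!all(call %in% CALL_LEVELS)) {
    stop("calls must be one of ", paste(CALL_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(gene_id = gene_id, call = call,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("regulation_calls", "data.frame")
  out
}

#' Classify genes as up-/downregulated, non-significant, or unobserved
#'
#' A gene is `UP` when its adjusted p-value is strictly below `alpha` and
#' its log2 fold change is strictly positive, `DOWN` for strictly negative
#' fold change, `UNOBSERVED` when the adjusted p-value is missing, and `NS`
#' otherwise. Equality with `alpha` and a fold change of exactly zero are
#' both `NS` (the call requires a strict sign).
#'
#' @param t A [deg_table()].
#' @param alpha Significance cutoff in (0, 1); default 0.05.
#' @return A [regulation_calls()] object over the genes of `t`.
#' @export
classify_regulation <- function(t, alpha = 0.05) {
  stopifnot(inherits(t, "deg_table"), alpha > 0, alpha < 1)
  call <- rep("NS", nrow(t))
  sig <- !is.na(t$adj_pvalue) & t$adj_pvalue < alpha
  call[sig & !is.na(t$log2fc) & t$log2fc > 0] <- "UP"
  call[sig & !is.na(t$log2fc) & t$log2fc < 0] <- "DOWN"
  call[is.na(t$adj_pvalue)] <- "UNOBSERVED"
  regulation_calls(t$gene_id, call, alpha = alpha)
}

# Align two (or more) call sets onto the union of their gene spaces;
# genes absent from a set are UNOBSERVED there.
align_calls <- function(...) {
  sets <- list(...)
  universe <- unique(unlist(lapply(sets, function(s) s$gene_id)))
  mats <- lapply(sets, function(s) {
    v <- rep("UNOBSERVED", length(universe))
    v[match(s$gene_id, universe)] <- s$call
    v
  })
  c(list(gene_id = universe), stats::setNames(mats, paste0("call", seq_along(mats))))
}

#' Directional overlap between two call sets
#'
#' Cross-tabulates two sets of regulation calls over the union of their
#' gene spaces, separating concordant, contradictory and platform-exclusive
#' intersections — the accounting behind a direction-aware upset analysis,
#' which can expose contradictions a Venn diagram hides.
#'
#' @param callsA,callsB [regulation_calls()] objects. Genes absent from one
#'   side are `UNOBSERVED` there.
#' @return A list of class `directional_overlap` with counts `both_up`,
#'   `both_down`, `contradictory_AupBdown`, `contradictory_AdownBup`,
#'   `A_only_up`, `A_only_down`, `B_only_up`, `B_only_down` (these eight
#'   partition the genes called `UP` or `DOWN` in at least one set) and
#'   `neither` (shared genes with no call on either side); plus, per
#'   direction, `fraction_of_A_detected_in_B` (significant in B in any
#'   direction) and `fraction_of_A_same_direction_in_B`.
#' @export
directional_overlap <- function(callsA, callsB) {
  al <- align_calls(callsA, callsB)
  a <- al$call1; b <- al$call2
  a_sig <- a %in% c("UP", "DOWN")
  b_sig <- b %in% c("UP", "DOWN")
  counts <- list(
    both_up = sum(a == "UP" & b == "UP"),
    both_down = sum(a == "DOWN" & b == "DOWN"),
    contradictory_AupBdown = sum(a == "UP" & b == "DOWN"),
    contradictory_AdownBup = sum(a == "DOWN" & b == "UP"),
    A_only_up = sum(a == "UP" & !b_sig),
    A_only_down = sum(a == "DOWN" & !b_sig),
    B_only_up = sum(b == "UP" & !a_sig),
    B_only_down = sum(b == "DOWN" & !a_sig),
    neither = sum(!a_sig & !b_sig)
  )
  frac <- function(dir) {
    n <- sum(a == dir)
    if (n == 0L) {
      c(detected = NA_real_, same_direction = NA_real_)
    } else {
      c(detected = sum(a == dir & b_sig) / n,
        same_direction = sum(a == dir & b == dir) / n)
    }
  }
  up <- frac("UP"); down <- frac("DOWN")
  counts$fraction_of_A_detected_in_B <-
    c(UP = unname(up["detected"]), DOWN = unname(down["detected"]))
  counts$fraction_of_A_same_direction_in_B <-
    c(UP = unname(up["same_direction"]), DOWN = unname(down["same_direction"]))
  structure(counts, class = "directional_overlap")
}

#' Set-inclusion sweep over halved significance cutoffs
#'
#' One table's cutoff stays fixed at `alpha_fixed` while the other's is
#' halved at each iteration (0.05, 0.025, 0.0125, 0.00625, 0.003125 with
#' the defaults). At each step the overlap of genes significant in any
#' direction under both cutoffs is counted and expressed as a frequency of
#' the swept table's significant genes, tracing how strongly the stricter
#' core of one platform is contained in the other.
#'
#' @param tableA,tableB [deg_table()] objects.
#' @param alpha_fixed Fixed cutoff for the non-swept table (default 0.05).
#' @param n_halvings Number of halvings beyond the first iteration
#'   (default 4).
#' @param swept Which table's cutoff is lowered: `"B"` (default) or `"A"`.
#' @return A data.frame of class `inclusion_curve` with one row per
#'   iteration: `cutoff_swept`, `n_fixed`, `n_swept`, `n_overlap`,
#'   `frequency` (`n_overlap / n_swept`, `NA` when `n_swept` is 0).
#' @export
inclusion_sweep <- function(tableA, tableB, alpha_fixed = 0.05,
                            n_halvings = 4L, swept = c("B", "A")) {
  stopifnot(inherits(tableA, "deg_table"), inherits(tableB, "deg_table"),
            n_halvings >= 0L)
  swept <- match.arg(swept)
  fixed_t <- if (swept == "B") tableA else tableB
  swept_t <- if (swept == "B") tableB else tableA
  sig_ids <- function(t, cutoff) {
    t$gene_id[!is.na(t$adj_pvalue) & t$adj_pvalue < cutoff &
                !is.na(t$log2fc) & t$log2fc != 0]
  }
  fixed_ids <- sig_ids(fixed_t, alpha_fixed)
  rows <- lapply(0:n_halvings, function(k) {
    cutoff <- alpha_fixed / 2^k
    ids <- sig_ids(swept_t, cutoff)
    n_overlap <- length(intersect(fixed_ids, ids))
    data.frame(cutoff_swept = cutoff, n_fixed = length(fixed_ids),
               n_swept = length(ids), n_overlap = n_overlap,
               frequency = if (length(ids) == 0L) NA_real_ else
                 n_overlap / length(ids))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("inclusion_curve", "data.frame")
  out
}

#' Spearman concordance of log2 fold changes between two tables
#'
#' @param tableA,tableB [deg_table()] objects.
#' @param restrict `"all"` (all shared genes with a fold change on both
#'   sides) or `"significant_in_both"` (adjusted p below `alpha` on both
#'   sides).
#' @param alpha Cutoff used by the `significant_in_both` restriction.
#' @return Spearman's rho in \[-1, 1\] (average ranks for ties).
#' @export
spearman_concordance <- function(tableA, tableB,
                                 restrict = c("all", "significant_in_both"),
                                 alpha = 0.05) {
  stopifnot(inherits(tableA, "deg_table"), inherits(tableB, "deg_table"))
  restrict <- match.arg(restrict)
  m <- merge(tableA[, c("gene_id", "log2fc", "adj_pvalue")],
             tableB[, c("gene_id", "log2fc", "adj_pvalue")],
             by = "gene_id", suffixes = c("_A", "_B"))
  m <- m[!is.na(m$log2fc_A) & !is.na(m$log2fc_B), ]
  if (restrict == "significant_in_both") {
    m <- m[!is.na(m$adj_pvalue_A) & m$adj_pvalue_A < alpha &
             !is.na(m$adj_pvalue_B) & m$adj_pvalue_B < alpha, ]
  }
  if (nrow(m) < 3L) {
    stop("fewer than 3 shared genes after restriction", call. = FALSE)
  }
  stats::cor(m$log2fc_A, m$log2fc_B, method = "spearman")
}

#' Consensus DEG set across two platforms
#'
#' The genes significant (adjusted p < `alpha`) in both tables with the
#' same strict sign of log2 fold change — the cross-validated core whose
#' members both technologies agree on, in direction and significance.
#'
#' @param tableA,tableB [deg_table()] objects.
#' @param alpha Significance cutoff (default 0.05).
#' @return A data.frame of class `consensus_set` with `gene_id`,
#'   `direction` (`UP`/`DOWN`), `log2fc_A`, `log2fc_B`, and `avg_log2fc`
#'   (arithmetic mean of the two log2 fold changes).
#' @export
consensus_degs <- function(tableA, tableB, alpha = 0.05) {
  stopifnot(inherits(tableA, "deg_table"), inherits(tableB, "deg_table"))
  m <- merge(tableA[, c("gene_id", "log2fc", "adj_pvalue")],
             tableB[, c("gene_id", "log2fc", "adj_pvalue")],
             by = "gene_id", suffixes = c("_A", "_B"))
  keep <- !is.na(m$adj_pvalue_A) & m$adj_pvalue_A < alpha &
    !is.na(m$adj_pvalue_B) & m$adj_pvalue_B < alpha &
    !is.na(m$log2fc_A) & !is.na(m$log2fc_B) &
    sign(m$log2fc_A) == sign(m$log2fc_B) & m$log2fc_A != 0
  m <- m[keep, ]
  out <- data.frame(gene_id = m$gene_id,
                    direction = ifelse(m$log2fc_A > 0, "UP", "DOWN"),
                    log2fc_A = m$log2fc_A, log2fc_B = m$log2fc_B,
                    avg_log2fc = (m$log2fc_A + m$log2fc_B) / 2,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("consensus_set", "data.frame")
  out
}

#' Top consensus genes by average fold change
#'
#' @param consensus A [consensus_degs()] result.
#' @param direction `"UP"` or `"DOWN"`.
#' @param n Number of genes to return (default 21; fewer if the set is
#'   smaller).
#' @return The consensus records of that direction sorted by
#'   `abs(avg_log2fc)` descending, ties broken by `gene_id` ascending,
#'   truncated to `n`.
#' @export
rank_by_average_fc <- function(consensus, direction = c("UP", "DOWN"),
                               n = 21L) {
  stopifnot(inherits(consensus, "consensus_set"), n >= 1L)
  direction <- match.arg(direction)
  sub <- consensus[consensus$direction == direction, ]
  sub <- sub[order(-abs(sub$avg_log2fc), sub$gene_id), ]
  sub <- utils::head(sub, n)
  rownames(sub) <- NULL
  sub
}

#' Regulation calls from the cross-platform consensus
#'
#' Turns a consensus DEG set back into per-gene calls over the shared
#' gene space: consensus members are `UP`/`DOWN`, genes observable in both
#' tables but not in the consensus are `NS`, genes unobservable in either
#' table are `UNOBSERVED`. Useful as the third time point of a trajectory
#' analysis in which the last measurement is cross-validated by two
#' platforms.
#'
#' @param tableA,tableB [deg_table()] objects.
#' @param alpha Significance cutoff (default 0.05).
#' @return A [regulation_calls()] object over the shared gene space.
#' @export
consensus_calls <- function(tableA, tableB, alpha = 0.05) {
  cons <- consensus_degs(tableA, tableB, alpha = alpha)
  shared <- intersect(tableA$gene_id, tableB$gene_id)
  obs <- shared[!is.na(tableA$adj_pvalue[match(shared, tableA$gene_id)]) &
                  !is.na(tableB$adj_pvalue[match(shared, tableB$gene_id)])]
  universe <- union(tableA$gene_id, tableB$gene_id)
  call <- rep("UNOBSERVED", length(universe))
  call[universe %in% obs] <- "NS"
  call[match(cons$gene_id, universe)] <- cons$direction
  regulation_calls(universe, call, alpha = alpha)
}

#' Overlap of two differential-exon-usage gene lists
#'
#' @param listA,listB [deu_list()] objects (gene-level adjusted DEU
#'   p-values).
#' @param cutoffA,cutoffB Significance cutoffs (default 0.05 each).
#' @return A list with `n_A`, `n_B`, `n_overlap`, and `fraction_of_B_in_A`
#'   (`NA` when `n_B` is 0).
#' @export
deu_overlap <- function(listA, listB, cutoffA = 0.05, cutoffB = 0.05) {
  sig <- function(l, cutoff) names(l)[!is.na(l) & l < cutoff]
  a <- sig(listA, cutoffA)
  b <- sig(listB, cutoffB)
  n_overlap <- length(intersect(a, b))
  list(n_A = length(a), n_B = length(b), n_overlap = n_overlap,
       fraction_of_B_in_A = if (length(b) == 0L) NA_real_ else
         n_overlap / length(b))
}
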