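# Three-time-point trajectory classification (3 -> 9 -> 27 categories),
# flow counts, and adaptation/persistence fractions.

#' Classify per-gene regulation trajectories across three time points
#'
#' Each gene observed at all three time points receives an ordered triple
#' label over `U`, `D`, `N` (its call at each time). Counts are reported
#' hierarchically: 3 groups by the first time point, 9 by the first two,
#' 27 by all three. Genes `UNOBSERVED` at any time point are excluded from
#' every level and reported in `n_excluded`.
#'
#' @param calls_t1,calls_t2,calls_t3 [regulation_calls()] objects over a
#'   shared gene space (genes absent from one set are `UNOBSERVED` there).
#' @return A list of class `trajectory_flow` with `labels` (a data.frame
#'   of `gene_id`, `t1`, `t2`, `t3`, `label`), `level1`, `level2`,
#'   `level3` (named count tables), `edges` (a Sankey-ready data.frame of
#'   `parent_label`, `child_label`, `count`), and `n_excluded`.
#' @export
classify_trajectories <- function(calls_t1, calls_t2, calls_t3) {
  al <- align_calls(calls_t1, calls_t2, calls_t3)
  short <- c(UP = "U", DOWN = "D", NS = "N", UNOBSERVED = "X")
  c1 <- short[al$call1]; c2 <- short[al$call2]; c3 <- short[al$call3]
  observed <- c1 != "X" & c2 != "X" & c3 != "X"
  n_excluded <- sum(!observed)
  g <- al$gene_id[observed]
  c1 <- c1[observed]; c2 <- c2[observed]; c3 <- c3[observed]
  labels <- data.frame(gene_id = g, t1 = c1, t2 = c2, t3 = c3,
                       label = paste(c1, c2, c3, sep = ","),
                       stringsAsFactors = FALSE)
  lv <- c("U", "D", "N")
  level1 <- table(factor(c1, levels = lv))
  l2 <- paste(c1, c2, sep = ",")
  lv2 <- as.vector(outer(lv, lv, function(a, b) paste(a, b, sep = ",")))
  lv2 <- sort(lv2)
  level2 <- table(factor(l2, levels = lv2))
  lv3 <- sort(as.vector(outer(lv2, lv, function(a, b) paste(a, b, sep = ","))))
  level3 <- table(factor(labels$label, levels = lv3))
  e12 <- stats::aggregate(list(count = rep(1L, nrow(labels))),
                          by = list(parent_label = labels$t1,
                                    child_label = l2), FUN = sum)
  e23 <- stats::aggregate(list(count = rep(1L, nrow(labels))),
                          by = list(parent_label = l2,
                                    child_label = labels$label), FUN = sum)
  edges <- rbind(e12, e23)
  edges <- edges[order(edges$parent_label, edges$child_label), ]
  rownames(edges) <- NULL
  structure(list(labels = labels, level1 = level1, level2 = level2,
                 level3 = level3, edges = edges, n_excluded = n_excluded),
            class = "trajectory_flow")
}

#' Adaptation fraction between two time points
#'
#' A gene is "initially altered" when its call at the initial time point
#' is `UP` or `DOWN`, and has "adapted" at the later time point when it no
#' longer carries its initial call — reverted to `NS` or counter-regulated
#' in the opposite direction. Pure reversion to `NS` is reported
#' separately as `reverted`.
#'
#' @param calls_initial,calls_later [regulation_calls()] over a shared
#'   gene space.
#' @return A list with `n_initially_altered`, `n_adapted`, `n_reverted`,
#'   `fraction_pct` (percent adapted, truncated to one decimal place —
#'   the convention used when such fractions are reported alongside raw
#'   counts; `NA` when nothing was initially altered) and `reverted_pct`.
#' @export
adaptation_fraction <- function(calls_initial, calls_later) {
  al <- align_calls(calls_initial, calls_later)
  init <- al$call1; later <- al$call2
  altered <- init %in% c("UP", "DOWN")
  n_alt <- sum(altered)
  if (n_alt == 0L) {
    return(list(n_initially_altered = 0L, n_adapted = NA_integer_,
                n_reverted = NA_integer_, fraction_pct = NA_real_,
                reverted_pct = NA_real_))
  }
  adapted <- altered & later != init
  reverted <- altered & later == "NS"
  trunc1 <- function(x) floor(x * 10 + 1e-9) / 10
  list(n_initially_altered = n_alt,
       n_adapted = sum(adapted),
       n_reverted = sum(reverted),
       fraction_pct = trunc1(100 * sum(adapted) / n_alt),
       reverted_pct = trunc1(100 * sum(reverted) / n_alt))
}

#' Persistence fraction per direction between two time points
#'
#' For each direction, the fraction of genes carrying that call at the
#' initial time point that still carry it at the later time point.
#'
#' @param calls_initial,calls_later [regulation_calls()] over a shared
#'   gene space.
#' @return Named numeric vector with elements `UP` and `DOWN` (`NA` when
#'   the initial direction is empty).
#' @export
persistence_fraction <- function(calls_initial, calls_later) {
  al <- align_calls(calls_initial, calls_later)
  init <- al$call1; later <- al$call2
  vapply(c(UP = "UP", DOWN = "DOWN"), function(d) {
    n <- sum(init == d)
    if (n == 0L) NA_real_ else sum(init == d & later == d) / n
  }, numeric(1L))
}
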