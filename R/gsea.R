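# Pre-ranked gene set enrichment: weighted running-sum enrichment score,
# gene-permutation null with sign-stratified normalization (NES), BH-FDR
# across sets, and cross-platform comparison of significant sets.

#' Pre-ranked enrichment score for one gene set
#'
#' Walks the ranking from the top: at a gene in the set the running sum
#' increases by `|stat|^weight_exponent / sum(|stat|^weight_exponent over
#' set members)`, at a gene outside the set it decreases by
#' `1 / (N - N_hits)`. The enrichment score is the running-sum value of
#' maximal absolute deviation from zero (signed). With `weight_exponent =
#' 0` the walk is the classical Kolmogorov-Smirnov-like statistic and ends
#' exactly at zero.
#'
#' @param ranking_stats Named numeric vector of per-gene ranking statistics
#'   (e.g. a moderated t or Wald statistic); sorted internally by
#'   decreasing value.
#' @param gene_set Character vector of gene identifiers.
#' @param weight_exponent Weighting exponent on `|stat|` at hits
#'   (default 1, the "weighted" scheme).
#' @return The enrichment score in \[-1, 1\].
#' @export
preranked_es <- function(ranking_stats, gene_set, weight_exponent = 1) {
  stopifnot(is.numeric(ranking_stats), !is.null(names(ranking_stats)))
  ord <- order(ranking_stats, decreasing = TRUE)
  stats_sorted <- ranking_stats[ord]
  hit <- names(stats_sorted) %in% gene_set
  n_hits <- sum(hit)
  n <- length(stats_sorted)
  if (n_hits == 0L) stop("set not represented in the ranking", call. = FALSE)
  if (n_hits == n) stop("degenerate set: covers the whole ranking",
                        call. = FALSE)
  w <- abs(stats_sorted)^weight_exponent
  inc <- numeric(n)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (n - n_hits)
  running <- cumsum(inc)
  running[which.max(abs(running))]
}

# Enrichment score from sorted hit positions, given precomputed
# |stat|^weight for the full (already sorted) ranking. Evaluates the
# running sum only at the candidate extremes: the value at each hit and
# the value just before each hit. Used for permutation nulls.
es_from_positions <- function(pos, absw, n) {
  k <- length(pos)
  w <- absw[pos]
  cw <- cumsum(w) / sum(w)
  step <- 1 / (n - k)
  miss_before <- (pos - seq_len(k)) * step
  at_hit <- cw - miss_before
  before_hit <- c(0, cw[-k]) - miss_before
  cand <- c(at_hit, before_hit)
  cand[which.max(abs(cand))]
}

#' Gene-permutation GSEA over a collection of sets
#'
#' Computes the weighted enrichment score for every set, builds a null by
#' permuting gene labels (random sets of identical size drawn from the
#' ranking), and reports sign-stratified nominal p-values, normalized
#' enrichment scores, and BH-adjusted p-values across sets. Permutations
#' are shared across sets of equal size. Deterministic given `seed`.
#'
#' The nominal p-value is `(1 + #same-sign permutations with |ES| >=
#' |ES_obs|) / (1 + #same-sign permutations)`; NES is `ES / mean(|ES|
#' among same-sign permutations)`, so `sign(NES) = sign(ES)`.
#'
#' @param ranking_stats Named numeric vector of per-gene ranking
#'   statistics.
#' @param sets A [gene_set_collection()].
#' @param n_perm Number of gene-label permutations (>= 100; default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param alpha Significance level annotated on the result (default 0.05).
#' @param weight_exponent Hit weighting exponent (default 1).
#' @param min_size,max_size Set-size bounds after intersecting with the
#'   ranking (defaults 3 and 5000); sets outside are skipped with a
#'   warning.
#' @return A data.frame of class `gsea_result`: `set`, `size`, `es`,
#'   `nes`, `nominal_p`, `adj_p`, `significant`.
#' @export
gsea_permutation <- function(ranking_stats, sets, n_perm = 1000L, seed = 1L,
                             alpha = 0.05, weight_exponent = 1,
                             min_size = 3L, max_size = 5000L) {
  stopifnot(inherits(sets, "gene_set_collection"), n_perm >= 100L)
  ord <- order(ranking_stats, decreasing = TRUE)
  stats_sorted <- ranking_stats[ord]
  n <- length(stats_sorted)
  absw <- abs(stats_sorted)^weight_exponent
  pos_list <- lapply(sets, function(g) {
    sort(which(names(stats_sorted) %in% g))
  })
  sizes <- lengths(pos_list)
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  if (any(!keep)) {
    warning(sum(!keep), " set(s) outside size bounds skipped: ",
            paste(utils::head(names(sets)[!keep], 5L), collapse = ", "),
            call. = FALSE)
  }
  pos_list <- pos_list[keep]
  sizes <- sizes[keep]
  if (length(pos_list) == 0L) {
    out <- data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), nominal_p = numeric(),
                      adj_p = numeric(), significant = logical())
    class(out) <- c("gsea_result", "data.frame")
    return(out)
  }
  es_obs <- vapply(pos_list, es_from_positions, numeric(1L),
                   absw = absw, n = n)
  # one permutation null per distinct set size, shared across sets
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  null_by_size <- lapply(sort(unique(sizes)), function(k) {
    vapply(seq_len(n_perm), function(i) {
      es_from_positions(sort(sample.int(n, k)), absw, n)
    }, numeric(1L))
  })
  names(null_by_size) <- as.character(sort(unique(sizes)))
  res <- lapply(seq_along(pos_list), function(i) {
    es <- es_obs[i]
    null_es <- null_by_size[[as.character(sizes[i])]]
    same_sign <- null_es[sign(null_es) == sign(es)]
    n_same <- length(same_sign)
    nominal_p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + n_same)
    nes <- if (n_same == 0L) NA_real_ else es / mean(abs(same_sign))
    data.frame(set = names(pos_list)[i], size = sizes[i], es = es,
               nes = nes, nominal_p = nominal_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- bh_adjust(out$nominal_p)
  out$significant <- !is.na(out$adj_p) & out$adj_p < alpha
  out <- out[order(-out$nes), ]
  rownames(out) <- NULL
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Cross-platform comparison of significant gene sets
#'
#' Intersects two GSEA result lists on set name, keeps the sets
#' significant (adjusted p < `alpha`) in both, and classifies each shared
#' set by the sign pair of its normalized enrichment scores:
#' concordant-positive, concordant-negative, or contradictory.
#'
#' @param resA,resB [gsea_permutation()] results keyed by shared set
#'   names.
#' @param alpha Significance cutoff on the adjusted p-value (default
#'   0.05).
#' @return A list of class `cross_platform_gsea` with `shared_significant`
#'   (data.frame of `set`, `nes_A`, `nes_B`, `class`) and the counts
#'   `n_concordant_positive`, `n_concordant_negative`,
#'   `n_contradictory`.
#' @export
cross_platform_gsea <- function(resA, resB, alpha = 0.05) {
  stopifnot(inherits(resA, "gsea_result"), inherits(resB, "gsea_result"))
  m <- merge(resA[, c("set", "nes", "adj_p")],
             resB[, c("set", "nes", "adj_p")],
             by = "set", suffixes = c("_A", "_B"))
  m <- m[!is.na(m$adj_p_A) & m$adj_p_A < alpha &
           !is.na(m$adj_p_B) & m$adj_p_B < alpha, ]
  cls <- ifelse(m$nes_A > 0 & m$nes_B > 0, "concordant_positive",
                ifelse(m$nes_A < 0 & m$nes_B < 0, "concordant_negative",
                       "contradictory"))
  shared <- data.frame(set = m$set, nes_A = m$nes_A, nes_B = m$nes_B,
                       class = cls, stringsAsFactors = FALSE)
  shared <- shared[order(shared$set), ]
  rownames(shared) <- NULL
  structure(list(shared_significant = shared,
                 n_concordant_positive = sum(cls == "concordant_positive"),
                 n_concordant_negative = sum(cls == "concordant_negative"),
                 n_contradictory = sum(cls == "contradictory")),
            class = "cross_platform_gsea")
}
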