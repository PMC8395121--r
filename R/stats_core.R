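# Self-contained statistical primitives used throughout the pipeline:
# Benjamini-Hochberg step-up adjustment, the two-sided Fisher exact test,
# quantile normalization, and Tukey median polish (the RMA-style
# summarization pair used to explain cross-platform fold-change narrowing).

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment controlling the false discovery rate. Implemented
#' directly from the step-up definition: for p-values sorted ascending,
#' `adj_(i) = min_{j >= i} min(1, p_(j) * m / j)` with `m` the number of
#' non-missing p-values. Missing entries are passed through unchanged and
#' do not count towards `m`.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\]; `NA` allowed.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvals) {
  pvals <- as.numeric(pvals)
  bad <- !is.na(pvals) & (pvals < 0 | pvals > 1)
  if (any(bad)) stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(pvals))
  idx <- which(!is.na(pvals))
  m <- length(idx)
  if (m == 0L) return(out)
  p <- pvals[idx]
  o <- order(p, decreasing = TRUE)
  adj_sorted <- pmin(1, cummin(p[o] * m / (m:1)))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  out[idx] <- adj
  out
}

#' Construct and validate a 2x2 contingency table
#'
#' @param a,b,c,d Non-negative integer cell counts; rows are in-group /
#'   out-group, columns condition-1 / condition-2.
#' @return A list of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("contingency table cells must be non-negative integers",
         call. = FALSE)
  }
  if (sum(cells) == 0) stop("contingency table is all zero", call. = FALSE)
  structure(as.list(cells), class = "contingency_2x2")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by point-probability summation: the sum of
#' hypergeometric probabilities of all tables sharing the observed margins
#' whose point probability does not exceed that of the observed table
#' (within relative tolerance `1e-7`, so exactly-tied tables are never
#' excluded by floating-point error). A zero row or column margin is
#' degenerate: no association is testable and the p-value is 1.
#'
#' @param t A `contingency_2x2`, or the count `a` when `b`, `c`, `d` are
#'   given.
#' @param b,c,d Optional cell counts (used when `t` is a single count).
#' @return The two-sided p-value in (0, 1\].
#' @export
fisher_exact_2x2 <- function(t, b = NULL, c = NULL, d = NULL) {
  if (!inherits(t, "contingency_2x2")) t <- contingency_2x2(t, b, c, d)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1.0)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Quantile normalization of an expression matrix
#'
#' Forces every column (sample) of a genes-by-samples matrix of log2
#' intensities to the identical distribution: the per-rank mean of the
#' input columns. Within-column rank order is preserved; ties within a
#' column receive the mean of the target values over the tied ranks.
#'
#' @param m Numeric matrix (genes as rows, >= 2 columns, no missing
#'   entries).
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (anyNA(m)) stop("missing entries not allowed", call. = FALSE)
  sorted <- apply(m, 2L, sort)
  target <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    vals <- m[o, j]
    grp <- cumsum(c(TRUE, vals[-1L] != vals[-length(vals)]))
    out[o, j] <- stats::ave(target, grp, FUN = mean)
  }
  out
}

#' Tukey median polish of an expression matrix
#'
#' Iteratively sweeps row and column medians out of a matrix, decomposing
#' it into `overall + row_effects + col_effects + residuals` (the identity
#' holds exactly by construction). Used as the RMA-style probe
#' summarization step. Sweeps start with rows; iteration stops when the
#' absolute change in `sum(abs(residuals))` drops below `tol` or after
#' `max_iter` full sweeps.
#'
#' @param m Numeric matrix with at least one cell.
#' @param max_iter Maximum number of full row+column sweeps (>= 1).
#' @param tol Convergence tolerance on the residual L1 norm (> 0).
#' @return A list with `overall`, `row_effects`, `col_effects`,
#'   `residuals`, and the number of sweeps performed (`iterations`).
#' @export
median_polish <- function(m, max_iter = 10L, tol = 1e-6) {
  m <- as.matrix(m)
  if (length(m) == 0L) stop("empty matrix", call. = FALSE)
  stopifnot(max_iter >= 1L, tol > 0)
  res <- m
  overall <- 0
  row_eff <- numeric(nrow(m))
  col_eff <- numeric(ncol(m))
  last_l1 <- Inf
  iter <- 0L
  for (i in seq_len(max_iter)) {
    iter <- i
    rmed <- apply(res, 1L, stats::median)
    row_eff <- row_eff + rmed
    res <- res - rmed
    cmed_of_col <- stats::median(col_eff)
    col_eff <- col_eff - cmed_of_col
    overall <- overall + cmed_of_col
    cmed <- apply(res, 2L, stats::median)
    col_eff <- col_eff + cmed
    res <- sweep(res, 2L, cmed)
    rmed_of_row <- stats::median(row_eff)
    row_eff <- row_eff - rmed_of_row
    overall <- overall + rmed_of_row
    l1 <- sum(abs(res))
    if (abs(last_l1 - l1) < tol) break
    last_l1 <- l1
  }
  list(overall = overall, row_effects = row_eff, col_effects = col_eff,
       residuals = res, iterations = iter)
}

#' RMA-style probe summarization
#'
#' Quantile-normalizes a probes-by-samples matrix, then summarizes each
#' gene's probes into one expression value per sample by median polish
#' (per-gene `overall + col_effect`). This two-step operation is a
#' simplified account of why array processing compresses ("narrows")
#' fold-change distributions relative to per-probe means: forcing all
#' samples onto a common distribution and summarizing by medians both pull
#' in one-sided tails.
#'
#' @param m Probes-by-samples numeric matrix.
#' @param probe_gene Character vector, one gene identifier per probe row.
#' @param normalize Apply quantile normalization first (default `TRUE`).
#' @return Genes-by-samples matrix of summarized expression values.
#' @export
rma_summarize <- function(m, probe_gene, normalize = TRUE) {
  m <- as.matrix(m)
  stopifnot(length(probe_gene) == nrow(m))
  if (normalize) m <- quantile_normalize(m)
  genes <- unique(probe_gene)
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(m),
                dimnames = list(genes, colnames(m)))
  for (g in genes) {
    sub <- m[probe_gene == g, , drop = FALSE]
    mp <- median_polish(sub)
    out[g, ] <- mp$overall + mp$col_effects
  }
  out
}
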