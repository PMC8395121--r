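# Fixture builders and independent oracles. The oracles are deliberately
# naive (loops, enumeration, closed forms) and share no code with the
# package implementations they check.

make_deg <- function(gene_id, log2fc, adj_pvalue = NA_real_,
                     pvalue = NA_real_, chromosome = NA_character_,
                     biotype = NA_character_, rank_stat = NA_real_) {
  deg_table(data.frame(gene_id = gene_id, log2fc = log2fc,
                       pvalue = pvalue, adj_pvalue = adj_pvalue,
                       chromosome = chromosome, biotype = biotype,
                       rank_stat = rank_stat, stringsAsFactors = FALSE))
}

random_deg <- function(n, seed, with_chrom = FALSE) {
  set.seed(seed)
  adj <- runif(n)
  adj[runif(n) < 0.1] <- NA
  make_deg(sprintf("g%04d", seq_len(n)),
           log2fc = rnorm(n),
           adj_pvalue = adj,
           chromosome = if (with_chrom)
             sample(c(as.character(1:22), "X", "Y"), n, replace = TRUE)
           else NA_character_)
}

# O(m^2) step-up BH: adj_i = min over j with p_(j) >= p_i of
# min(1, p_(j) * m / rank_j)
oracle_bh <- function(p) {
  ok <- !is.na(p)
  m <- sum(ok)
  out <- rep(NA_real_, length(p))
  ranks <- rank(p[ok], ties.method = "max")
  pv <- p[ok]
  for (i in seq_len(m)) {
    cand <- vapply(seq_len(m), function(j) {
      if (pv[j] >= pv[i]) min(1, pv[j] * m / ranks[j]) else Inf
    }, numeric(1))
    out[which(ok)[i]] <- min(cand)
  }
  out
}

# full enumeration two-sided Fisher: probabilities of every table with the
# observed margins via choose(), point-probability rule
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1.0)
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(support, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }, numeric(1))
  p_obs <- prob[support == a]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# literal running-sum walk for the pre-ranked enrichment score
oracle_es_walk <- function(stats_named, gene_set, weight = 1) {
  o <- order(stats_named, decreasing = TRUE)
  s <- stats_named[o]
  hit <- names(s) %in% gene_set
  nh <- sum(hit)
  denom_hit <- sum(abs(s[hit])^weight)
  running <- 0
  best <- 0
  for (i in seq_along(s)) {
    if (hit[i]) {
      running <- running + abs(s[i])^weight / denom_hit
    } else {
      running <- running - 1 / (length(s) - nh)
    }
    if (abs(running) > abs(best)) best <- running
  }
  unname(best)
}

# naive per-gene loop version of directional_overlap counts
oracle_overlap <- function(callsA, callsB) {
  universe <- union(callsA$gene_id, callsB$gene_id)
  getc <- function(calls, g) {
    i <- match(g, calls$gene_id)
    if (is.na(i)) "UNOBSERVED" else calls$call[i]
  }
  counts <- c(both_up = 0, both_down = 0, contradictory_AupBdown = 0,
              contradictory_AdownBup = 0, A_only_up = 0, A_only_down = 0,
              B_only_up = 0, B_only_down = 0, neither = 0)
  for (g in universe) {
    a <- getc(callsA, g); b <- getc(callsB, g)
    asig <- a %in% c("UP", "DOWN"); bsig <- b %in% c("UP", "DOWN")
    key <- if (a == "UP" && b == "UP") "both_up"
    else if (a == "DOWN" && b == "DOWN") "both_down"
    else if (a == "UP" && b == "DOWN") "contradictory_AupBdown"
    else if (a == "DOWN" && b == "UP") "contradictory_AdownBup"
    else if (a == "UP") "A_only_up"
    else if (a == "DOWN") "A_only_down"
    else if (b == "UP") "B_only_up"
    else if (b == "DOWN") "B_only_down"
    else "neither"
    counts[key] <- counts[key] + 1
  }
  counts
}

# naive consensus membership by per-gene loop
oracle_consensus_ids <- function(tableA, tableB, alpha = 0.05) {
  shared <- intersect(tableA$gene_id, tableB$gene_id)
  keep <- character(0)
  for (g in shared) {
    ia <- match(g, tableA$gene_id); ib <- match(g, tableB$gene_id)
    pa <- tableA$adj_pvalue[ia]; pb <- tableB$adj_pvalue[ib]
    fa <- tableA$log2fc[ia]; fb <- tableB$log2fc[ib]
    if (!is.na(pa) && pa < alpha && !is.na(pb) && pb < alpha &&
        !is.na(fa) && !is.na(fb) && fa * fb > 0) {
      keep <- c(keep, g)
    }
  }
  sort(keep)
}
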