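# Domain containers: per-gene DE result tables, regulation calls, DEU lists,
# and GMT gene set collections, with strict validation on construction.

DEG_COLUMNS <- c("gene_id", "log2fc", "pvalue", "adj_pvalue",
                 "chromosome", "biotype", "rank_stat")

#' Construct a differential-expression result table
#'
#' A `deg_table` holds one platform/time-point worth of per-gene differential
#' expression results: log2 fold change, raw and FDR-adjusted p-values, and
#' optional chromosome, biotype and ranking-statistic annotations. A gene with
#' a missing adjusted p-value is "unobservable": it is excluded from all
#' downstream significance counting but retained in the table.
#'
#' @param df A data.frame with at least columns `gene_id` and `log2fc`;
#'   optional columns `pvalue`, `adj_pvalue`, `chromosome`, `biotype`,
#'   `rank_stat`. Missing optional columns are filled with `NA`.
#' @return A validated `deg_table` (a data.frame).
#' @details `gene_id` values are whitespace-trimmed and must be unique;
#'   comparisons across tables are case-sensitive and by identifier only.
#'   P-values outside \[0, 1\] are an error, never silently clipped.
#' @export
deg_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(c("gene_id", "log2fc"), names(df))
  if (length(missing_cols) > 0L) {
    stop("deg_table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(gene_id = trimws(as.character(df$gene_id)),
                    log2fc = as.numeric(df$log2fc),
                    stringsAsFactors = FALSE)
  for (col in c("pvalue", "adj_pvalue", "rank_stat")) {
    out[[col]] <- if (col %in% names(df)) as.numeric(df[[col]]) else NA_real_
  }
  for (col in c("chromosome", "biotype")) {
    out[[col]] <- if (col %in% names(df)) {
      v <- trimws(as.character(df[[col]]))
      v[v == ""] <- NA_character_
      v
    } else NA_character_
  }
  out <- out[DEG_COLUMNS]
  dup <- duplicated(out$gene_id)
  if (any(dup)) {
    stop("duplicate gene_id in deg_table: ", out$gene_id[which(dup)[1L]],
         call. = FALSE)
  }
  for (col in c("pvalue", "adj_pvalue")) {
    bad <- !is.na(out[[col]]) & (out[[col]] < 0 | out[[col]] > 1)
    if (any(bad)) {
      stop(col, " outside [0, 1] for gene ", out$gene_id[which(bad)[1L]],
           call. = FALSE)
    }
  }
  class(out) <- c("deg_table", "data.frame")
  out
}

#' @export
print.deg_table <- function(x, ...) {
  cat("deg_table with", nrow(x), "genes (",
      sum(!is.na(x$adj_pvalue)), "observable )\n")
  NextMethod()
}

#' Read a differential-expression table from TSV
#'
#' Reads a tab-separated file with a header row into a [deg_table()].
#' The tokens `NA`, `NaN` and the empty string are treated as missing on
#' input; [write_deg_table()] always writes `NA`.
#'
#' @param path Path to a TSV file.
#' @param column_map Optional named character vector mapping logical column
#'   names (`gene_id`, `log2fc`, `pvalue`, `adj_pvalue`, `chromosome`,
#'   `biotype`, `rank_stat`) to the physical column names in the file, e.g.
#'   `c(gene_id = "ensembl_id", log2fc = "logFC")`.
#' @return A `deg_table`.
#' @export
read_deg_table <- function(path, column_map = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", "NaN", ""),
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    stopifnot(!is.null(names(column_map)))
    missing_phys <- setdiff(unname(column_map), names(df))
    if (length(missing_phys) > 0L) {
      stop("column_map refers to absent column(s): ",
           paste(missing_phys, collapse = ", "), call. = FALSE)
    }
    for (logical_name in names(column_map)) {
      names(df)[names(df) == column_map[[logical_name]]] <- logical_name
    }
  }
  deg_table(df)
}

#' Write a differential-expression table to TSV
#'
#' @param t A `deg_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(t, path) {
  stopifnot(inherits(t, "deg_table"))
  utils::write.table(t, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Construct a gene set collection
#'
#' @param sets A named list of character vectors of gene identifiers.
#' @return A `gene_set_collection` (named list; duplicate genes within a set
#'   are removed).
#' @export
gene_set_collection <- function(sets) {
  stopifnot(is.list(sets))
  if (length(sets) > 0L && (is.null(names(sets)) || any(names(sets) == ""))) {
    stop("all gene sets must be named", call. = FALSE)
  }
  dup <- duplicated(names(sets))
  if (any(dup)) {
    stop("duplicate gene set name: ", names(sets)[which(dup)[1L]],
         call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  structure(sets, class = "gene_set_collection")
}

#' Read gene sets in GMT format
#'
#' Each line holds a set name, a description (discarded), and one or more
#' gene identifiers, all tab-separated — the MSigDB interchange layout.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop("GMT line ", short[1L], " has fewer than 3 fields", call. = FALSE)
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  gene_set_collection(sets)
}

#' Write gene sets in GMT format
#'
#' @param sets A `gene_set_collection`.
#' @param path Output file path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a differential-exon-usage gene list
#'
#' @param gene_id Character vector of gene identifiers (unique).
#' @param adj_pvalue Numeric vector of gene-level FDR-adjusted DEU p-values
#'   in \[0, 1\].
#' @return A named numeric vector of class `deu_list`.
#' @export
deu_list <- function(gene_id, adj_pvalue) {
  gene_id <- trimws(as.character(gene_id))
  adj_pvalue <- as.numeric(adj_pvalue)
  stopifnot(length(gene_id) == length(adj_pvalue))
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id in deu_list: ",
         gene_id[which(duplicated(gene_id))[1L]], call. = FALSE)
  }
  bad <- !is.na(adj_pvalue) & (adj_pvalue < 0 | adj_pvalue > 1)
  if (any(bad)) stop("DEU adj_pvalue outside [0, 1]", call. = FALSE)
  structure(stats::setNames(adj_pvalue, gene_id), class = "deu_list")
}
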