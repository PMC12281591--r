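# Compound-recognition by bidirectional connectivity scoring: each
# perturbation signature's extreme up and down gene sets are scored against
# a query ranking by preranked GSEA, and perturbations are ranked by the
# summarized NES (up-set NES minus down-set NES). A large positive score
# marks a perturbation transcriptionally similar to the query; a large
# negative one, a potential reverser.

#' Summarized connectivity score
#'
#' The connectivity statistic: the NES of a perturbation's up gene set
#' against the query ranking, minus the NES of its down gene set. A
#' perturbation that mimics the query drives its up set into the top of the
#' ranking (positive NES) and its down set into the bottom (negative NES),
#' so the difference rewards both. Vectorized.
#'
#' @param nes_up NES of the top-n up-regulated gene set.
#' @param nes_down NES of the bottom-n down-regulated gene set.
#' @return `nes_up - nes_down`.
#' @export
summarized_nes <- function(nes_up, nes_down) {
  if (any(!is.finite(nes_up)) || any(!is.finite(nes_down))) {
    stop_fmt("summarized_nes: inputs must be finite")
  }
  nes_up - nes_down
}

# Score one signature against a prepared query ranking. `null_cache` is an
# environment keyed by effective set size; nulls are reproducible functions
# of (params$seed, size), so sharing the cache across signatures changes
# nothing. Returns NULL when either extreme set is empty after intersection
# with the query universe (caller skips and logs).
score_one <- function(ranked, sig, n, params, null_cache) {
  sets <- extreme_sets(sig, n)
  universe <- ranked$genes
  up <- intersect(sets$up, universe)
  down <- intersect(sets$down, universe)
  if (!length(up) || !length(down)) return(NULL)
  dir_score <- function(members) {
    sc <- enrichment_score(ranked, members, params$exponent)
    key <- as.character(sc$size)
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- permutation_null(ranked, sc$size, params)
    }
    nz <- normalize_es(sc$es, null_cache[[key]])
    c(nes = nz$nes, p = nz$pvalue)
  }
  u <- dir_score(up)
  d <- dir_score(down)
  data.frame(batch = sig$batch, compound = sig$compound, dose = sig$dose,
             treat_time = sig$treat_time, cell = sig$cell,
             nes_up = u[["nes"]], p_up = u[["p"]],
             nes_down = d[["nes"]], p_down = d[["p"]],
             stringsAsFactors = FALSE)
}

#' Score a single perturbation signature against a query ranking
#'
#' Computes the signature's extreme up/down sets, scores both against the
#' query ranking by preranked GSEA, and returns the per-direction NES and
#' permutation p-values together with the summarized NES. Adjusted p-values
#' and ranks are assigned only by [connectivity_screen], whose BH family is
#' the whole screened library.
#'
#' @param query A [ranked_signature].
#' @param sig A [perturbation_signature].
#' @param n Extreme-set size.
#' @param params An [enrichment_params].
#' @return A one-row data.frame (`batch`, `compound`, `dose`, `treat_time`,
#'   `cell`, `nes_up`, `p_up`, `nes_down`, `p_down`, `total_nes`), or
#'   `NULL` if either extreme set shares no gene with the query universe
#'   (logged).
#' @export
score_signature <- function(query, sig, n = 500,
                            params = enrichment_params()) {
  stopifnot(inherits(query, "ranked_signature"),
            inherits(sig, "perturbation_signature"))
  row <- score_one(query, sig, n, params,
                   new.env(parent = emptyenv()))
  if (is.null(row)) {
    msg("score_signature: '", sig$compound,
        "' shares no up or down gene with the query universe; skipped")
    return(NULL)
  }
  row$total_nes <- summarized_nes(row$nes_up, row$nes_down)
  row
}

#' Connectivity screen of a perturbation library
#'
#' The screen: ranks the query DE table by log2 fold change (descending),
#' scores every library signature's extreme up/down gene sets against that
#' ranking, BH-adjusts the up-set and down-set p-value families separately
#' across all scored signatures, and orders signatures by summarized NES
#' descending (ties by `p_up + p_down` ascending, then compound name).
#' Permutation nulls are shared across signatures per effective set size
#' and seeded from `params$seed` and the size alone, so results do not
#' depend on library order.
#'
#' @param query_records A [de_table] for the query contrast.
#' @param library A `perturbation_library`, a list of
#'   [perturbation_signature] objects, or a numeric z-score matrix
#'   (genes x signatures) whose columns become signatures.
#' @param n Extreme-set size; default 500 as in LINCS-scale screens.
#'   Clamped to `floor(genes / 2)` with a warning when the library universe
#'   is smaller.
#' @param params An [enrichment_params].
#' @param degs_only If TRUE, restrict the query ranking to significant DEGs
#'   (`padj < alpha`) before ranking; default FALSE (all genes ranked).
#' @param alpha DEG threshold used when `degs_only = TRUE`.
#' @return An object of class `connectivity_screen`: a data.frame with
#'   columns `rank`, `batch`, `compound`, `dose`, `treat_time`, `cell`,
#'   `nes_up`, `p_up`, `padj_up`, `nes_down`, `p_down`, `padj_down`,
#'   `total_nes`, plus attributes `n`, `params` and `family_size`.
#' @export
connectivity_screen <- function(query_records, library, n = 500,
                                params = enrichment_params(),
                                degs_only = FALSE, alpha = 0.05) {
  stopifnot(inherits(query_records, "de_table"))
  if (is.matrix(library)) {
    library <- lapply(colnames(library), function(id) {
      perturbation_signature(id, library[, id])
    })
  }
  if (!length(library)) stop_fmt("library is empty")
  if (degs_only) {
    degs <- select_degs(query_records, alpha)
    keep <- query_records$gene %in% c(degs$up, degs$down)
    query_records <- query_records[keep, ]
    class(query_records) <- c("de_table", "data.frame")
    if (!nrow(query_records)) stop_fmt("no DEG at alpha = ", alpha)
  }
  ranked <- rank_genes(query_records, "log2fc")
  min_genes <- min(vapply(library, function(s) length(s$zscores), 0L))
  if (2 * n > min_genes) {
    n_new <- floor(min_genes / 2)
    warn("connectivity_screen: n = ", n, " too large for a ", min_genes,
         "-gene library universe; clamped to ", n_new)
    n <- n_new
  }
  null_cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(library))
  skipped <- character()
  for (i in seq_along(library)) {
    row <- score_one(ranked, library[[i]], n, params, null_cache)
    if (is.null(row)) {
      skipped <- c(skipped, library[[i]]$compound)
    } else {
      rows[[i]] <- row
    }
  }
  if (length(skipped)) {
    msg("connectivity_screen: skipped ", length(skipped),
        " signature(s) with no query overlap: ",
        paste(skipped, collapse = ", "))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop_fmt("all signatures were skipped")
  out <- do.call(rbind, rows)
  out$padj_up <- bh_adjust(out$p_up)
  out$padj_down <- bh_adjust(out$p_down)
  out$total_nes <- summarized_nes(out$nes_up, out$nes_down)
  o <- order(-out$total_nes, out$p_up + out$p_down, out$compound,
             method = "radix")
  out <- out[o, ]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("rank", "batch", "compound", "dose", "treat_time", "cell",
                 "nes_up", "p_up", "padj_up", "nes_down", "p_down",
                 "padj_down", "total_nes")]
  rownames(out) <- NULL
  structure(out, class = c("connectivity_screen", "data.frame"),
            n = n, params = params, family_size = nrow(out))
}

#' @export
print.connectivity_screen <- function(x, ...) {
  cat("Connectivity screen:", nrow(x), "signatures (extreme-set size n =",
      attr(x, "n"), ")\n")
  top <- utils::head(as.data.frame(x), 5L)
  top$nes_up <- round(top$nes_up, 3)
  top$nes_down <- round(top$nes_down, 3)
  top$total_nes <- round(top$total_nes, 3)
  print(top[, c("rank", "compound", "dose", "nes_up", "nes_down",
                "total_nes")])
  if (nrow(x) > 5L) cat("  ...", nrow(x) - 5L, "more\n")
  invisible(x)
}

#' @export
summary.connectivity_screen <- function(object, ...) {
  p <- attr(object, "params")
  cat("Connectivity screen summary\n")
  cat("  signatures scored :", nrow(object), "\n")
  cat("  extreme-set size n:", attr(object, "n"), "\n")
  cat("  permutations      :", p$n_perm, " exponent:", p$exponent,
      " seed:", p$seed, "\n")
  cat("  total NES range   : [", round(min(object$total_nes), 3), ",",
      round(max(object$total_nes), 3), "]\n")
  cat("  top signature     :", object$compound[1L], "(total NES",
      round(object$total_nes[1L], 3), ")\n")
  invisible(object)
}

#' @export
plot.connectivity_screen <- function(x, k = min(20L, nrow(x)), ...) {
  top <- utils::head(x, k)
  op <- graphics::par(mar = c(4, 8, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(top$total_nes),
                    names.arg = rev(paste0(top$compound, " #", top$rank)),
                    horiz = TRUE, las = 1, col = "steelblue",
                    xlab = "total NES (up - down)",
                    main = "Connectivity screen", ...)
  invisible(x)
}

#' Top rows of a connectivity screen
#'
#' Returns the `k` best-ranked signatures and summarizes compound-level
#' redundancy: the number of distinct compound names among them and each
#' compound's occurrence count (a compound may contribute several
#' dose/time/batch signatures).
#'
#' @param results A `connectivity_screen` (or a data.frame with at least
#'   `compound` and `total_nes` columns, e.g. from [read_connectivity]).
#' @param k Number of rows (default 10). If `k` exceeds the result count,
#'   all rows are returned with a warning.
#' @return A data.frame of class `connectivity_top` with attributes
#'   `n_compounds` (distinct compound count) and `compound_counts` (named
#'   integer vector).
#' @export
top_table <- function(results, k = 10) {
  if (!is_count(k) || k < 1) stop_fmt("k must be a positive integer")
  df <- as.data.frame(results)
  if (!all(c("compound", "total_nes") %in% names(df))) {
    stop_fmt("results must have 'compound' and 'total_nes' columns")
  }
  if (!"rank" %in% names(df)) {
    df <- df[order(-df$total_nes), ]
    df$rank <- seq_len(nrow(df))
  }
  df <- df[order(df$rank), ]
  if (k > nrow(df)) {
    warn("top_table: k = ", k, " exceeds the ", nrow(df),
         " available rows; returning all")
    k <- nrow(df)
  }
  top <- df[seq_len(k), ]
  rownames(top) <- NULL
  counts <- sort(table(top$compound), decreasing = TRUE)
  structure(top, class = c("connectivity_top", "data.frame"),
            n_compounds = length(counts),
            compound_counts = stats::setNames(as.integer(counts),
                                              names(counts)))
}

#' @export
print.connectivity_top <- function(x, ...) {
  cat("Top", nrow(x), "connectivity signatures —",
      attr(x, "n_compounds"), "distinct compound(s)\n")
  cc <- attr(x, "compound_counts")
  cat("  occurrences:",
      paste(sprintf("%s x%d", names(cc), cc), collapse = ", "), "\n")
  print(as.data.frame(x))
  invisible(x)
}

#' Write a connectivity table as TSV
#'
#' Mirrors the screen's ranked layout; NES columns at 6-decimal fixed
#' point, p-values at 6 significant digits. Header comment lines record the
#' extreme-set size, permutation count, exponent, seed and BH family size.
#'
#' @param x A `connectivity_screen` or `connectivity_top`.
#' @param path Output path.
#' @export
write_connectivity <- function(x, path) {
  df <- as.data.frame(x)
  p <- attr(x, "params")
  header <- c(
    sprintf("# n=%s", attr(x, "n") %||% "NA"),
    if (!is.null(p)) sprintf("# n_perm=%d exponent=%g seed=%d",
                             p$n_perm, p$exponent, p$seed),
    sprintf("# bh_family_size=%s", attr(x, "family_size") %||% nrow(df)))
  for (col in c("nes_up", "nes_down", "total_nes")) {
    df[[col]] <- fmt_score(df[[col]])
  }
  for (col in intersect(c("p_up", "padj_up", "p_down", "padj_down"),
                        names(df))) {
    df[[col]] <- fmt_p(df[[col]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a connectivity table from TSV
#'
#' Reads tables written by [write_connectivity] as well as externally
#' prepared ranked tables with the same column layout (comment lines
#' starting with `#` are ignored).
#'
#' @param path Path to a TSV file.
#' @return A data.frame; `rank` ordering is preserved as read.
#' @export
read_connectivity <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("compound", "nes_up", "nes_down", "total_nes")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop_fmt("connectivity table lacks column(s): ",
             paste(miss, collapse = ", "))
  }
  df
}
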