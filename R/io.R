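# Domain containers and file I/O: differential-expression tables (TSV),
# perturbation z-score matrices (GCT 1.2), gene-set collections (GMT).
# Gene identifiers are matched case-sensitively and exactly throughout;
# no symbol/accession mapping layer is provided.

#' Construct a differential-expression table
#'
#' A `de_table` is a data.frame with one row per gene and columns
#' `gene`, `log2fc`, `pvalue`, `padj` and optionally `stat` (the test
#' statistic, e.g. the Wald statistic of a DESeq2 fit). It is the query side
#' of every downstream analysis: DEG selection, ranking, enrichment and the
#' connectivity screen.
#'
#' @param gene Character vector of unique, non-empty gene identifiers.
#' @param log2fc Signed log2 fold changes.
#' @param pvalue Raw p-values in (0, 1].
#' @param padj Adjusted p-values in (0, 1]. Taken as given from the input;
#'   `padj >= pvalue` is not enforced.
#' @param stat Optional signed test statistics.
#' @return A data.frame of class `de_table`.
#' @export
de_table <- function(gene, log2fc, pvalue, padj, stat = NULL) {
  gene <- as.character(gene)
  if (any(!nzchar(gene))) stop_fmt("gene identifiers must be non-empty")
  dup <- anyDuplicated(gene)
  if (dup) stop_fmt("duplicate gene identifier: '", gene[dup], "'")
  n <- length(gene)
  if (length(log2fc) != n || length(pvalue) != n || length(padj) != n) {
    stop_fmt("column lengths differ")
  }
  if (any(!is.finite(log2fc))) stop_fmt("log2fc must be finite")
  assert_prob(pvalue, "pvalue")
  assert_prob(padj, "padj")
  out <- data.frame(gene = gene, log2fc = as.numeric(log2fc),
                    pvalue = as.numeric(pvalue), padj = as.numeric(padj),
                    stringsAsFactors = FALSE)
  if (!is.null(stat)) {
    if (length(stat) != n) stop_fmt("column lengths differ")
    out$stat <- as.numeric(stat)
  }
  class(out) <- c("de_table", "data.frame")
  out
}

#' Read a differential-expression table from TSV
#'
#' Reads a tab-separated table with a header row (e.g. a written-out DESeq2
#' results table). Rows with missing `log2fc`, `pvalue` or `padj` are dropped
#' and the drop count logged, mirroring the NA rows DESeq2 emits for
#' independent-filtering casualties.
#'
#' @param path Path to a TSV file.
#' @param column_map Named character vector mapping roles
#'   (`gene`, `log2fc`, `pvalue`, `padj`, `stat`) to column names in the
#'   file. `stat` is optional: it is used only if the mapped column exists.
#' @return A [de_table].
#' @export
read_de_table <- function(path,
                          column_map = c(gene = "gene",
                                         log2fc = "log2FoldChange",
                                         pvalue = "pvalue",
                                         padj = "padj",
                                         stat = "stat")) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("gene", "log2fc", "pvalue", "padj")
  for (role in required) {
    col <- column_map[[role]]
    if (is.null(col) || !col %in% names(raw)) {
      stop_fmt("required column '", col %||% role, "' (role ", role,
               ") not found in ", path)
    }
  }
  has_stat <- !is.null(column_map[["stat"]]) &&
    column_map[["stat"]] %in% names(raw)
  gene <- as.character(raw[[column_map[["gene"]]]])
  log2fc <- suppressWarnings(as.numeric(raw[[column_map[["log2fc"]]]]))
  pvalue <- suppressWarnings(as.numeric(raw[[column_map[["pvalue"]]]]))
  padj <- suppressWarnings(as.numeric(raw[[column_map[["padj"]]]]))
  stat <- if (has_stat) {
    suppressWarnings(as.numeric(raw[[column_map[["stat"]]]]))
  }
  keep <- is.finite(log2fc) & is.finite(padj) & is.finite(pvalue)
  n_drop <- sum(!keep)
  if (n_drop > 0) msg("read_de_table: dropped ", n_drop, " row(s) with NA ",
                      "log2fc/pvalue/padj")
  de_table(gene[keep], log2fc[keep], pvalue[keep], padj[keep],
           stat = if (has_stat) stat[keep])
}

#' Write a differential-expression table as TSV
#'
#' Columns are emitted in the fixed order gene, log2fc, pvalue, padj
#' (, stat); fold changes and statistics at 6-decimal fixed point, p-values
#' at 6 significant digits.
#'
#' @param x A [de_table].
#' @param path Output path.
#' @export
write_de_table <- function(x, path) {
  stopifnot(inherits(x, "de_table"))
  out <- data.frame(gene = x$gene,
                    log2fc = fmt_score(x$log2fc),
                    pvalue = fmt_p(x$pvalue),
                    padj = fmt_p(x$padj),
                    stringsAsFactors = FALSE)
  if (!is.null(x$stat)) out$stat <- fmt_score(x$stat)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GCT 1.2 z-score matrix
#'
#' GCT 1.2 is the text dialect used for LINCS L1000 level 5 exports: a
#' `#1.2` version line, a dimensions line, then a header and one row per
#' gene (`Name`, `Description`, one column per signature).
#'
#' @param path Path to a GCT file.
#' @return A list with elements `z` (numeric matrix, genes x signatures,
#'   dimnames set) and `description` (named character, per gene).
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop_fmt("GCT file too short: ", path)
  if (trimws(lines[1L]) != "#1.2") {
    stop_fmt("unsupported GCT version line '", trimws(lines[1L]),
             "'; only #1.2 is supported")
  }
  dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]]))
  if (length(dims) < 2L || any(is.na(dims[1:2]))) {
    stop_fmt("malformed GCT dimensions line")
  }
  n_row <- dims[1L]; n_col <- dims[2L]
  header <- strsplit(lines[3L], "\t")[[1L]]
  if (length(header) != n_col + 2L) {
    stop_fmt("GCT header has ", length(header) - 2L,
             " signature columns, declared ", n_col)
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != n_row) {
    stop_fmt("GCT declares ", n_row, " rows but body has ", length(body))
  }
  fields <- strsplit(body, "\t")
  bad <- which(lengths(fields) != n_col + 2L)
  if (length(bad)) stop_fmt("GCT data row ", bad[1L], " has wrong field count")
  genes <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(genes)) {
    stop_fmt("duplicate gene identifier in GCT: '",
             genes[anyDuplicated(genes)], "'")
  }
  desc <- vapply(fields, `[[`, "", 2L)
  z <- matrix(as.numeric(unlist(lapply(fields, `[`, -(1:2)))),
              nrow = n_row, ncol = n_col, byrow = TRUE,
              dimnames = list(genes, header[-(1:2)]))
  if (any(!is.finite(z))) stop_fmt("non-finite value in GCT body")
  list(z = z, description = stats::setNames(desc, genes))
}

#' Write a z-score matrix as GCT 1.2
#'
#' @param z Numeric matrix (genes x signatures) with dimnames.
#' @param path Output path.
#' @param description Optional per-gene description column (defaults to the
#'   gene identifier).
#' @export
write_gct <- function(z, path, description = NULL) {
  stopifnot(is.matrix(z), !is.null(rownames(z)), !is.null(colnames(z)))
  desc <- description %||% rownames(z)
  body <- vapply(seq_len(nrow(z)), function(i) {
    paste(c(rownames(z)[i], desc[i], fmt_score(z[i, ])), collapse = "\t")
  }, "")
  writeLines(c("#1.2",
               paste(nrow(z), ncol(z), sep = "\t"),
               paste(c("Name", "Description", colnames(z)), collapse = "\t"),
               body),
             path)
  invisible(path)
}

#' Read a gene-set collection from GMT
#'
#' One set per line: set id, description, then one or more member genes,
#' tab-separated. Duplicate members within a line are deduplicated with a
#' warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (members per set), with a
#'   `description` attribute (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t")[[1L]]
    if (length(f) < 3L) {
      stop_fmt("GMT line ", i, " has ", length(f),
               " field(s); need set id, description and >= 1 member")
    }
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warn("GMT set '", f[1L], "' (line ", i, ") has duplicate members; ",
           "deduplicated")
      members <- unique(members)
    }
    ids[i] <- f[1L]; desc[i] <- f[2L]; sets[[i]] <- members
  }
  if (anyDuplicated(ids)) stop_fmt("duplicate set id: '",
                                   ids[anyDuplicated(ids)], "'")
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(desc, ids)
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional named character vector of descriptions
#'   (defaults to the set id).
#' @export
write_gmt <- function(sets, path, description = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- description %||% attr(sets, "description") %||%
    stats::setNames(names(sets), names(sets))
  writeLines(vapply(names(sets), function(id) {
    paste(c(id, desc[[id]] %||% id, sets[[id]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Filter a count table to expressed protein-coding genes
#'
#' Retains genes whose mean count across samples is strictly greater than
#' `min_avg`, and, when an allow-list is given (typically protein-coding
#' identifiers), only genes on that list.
#'
#' @param counts Numeric matrix of non-negative counts, genes x samples,
#'   with rownames.
#' @param min_avg Mean-count threshold (strict `>`); default 5.
#' @param keep_ids Optional character allow-list.
#' @return The filtered count matrix.
#' @export
filter_genes <- function(counts, min_avg = 5, keep_ids = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (!is.numeric(min_avg) || length(min_avg) != 1L || min_avg < 0) {
    stop_fmt("min_avg must be a single non-negative number")
  }
  if (any(counts < 0)) stop_fmt("counts must be non-negative")
  keep <- rowMeans(counts) > min_avg
  if (!is.null(keep_ids)) keep <- keep & rownames(counts) %in% keep_ids
  if (!any(keep)) warn("filter_genes: no genes pass the filter")
  counts[keep, , drop = FALSE]
}

#' Select differentially expressed genes
#'
#' A gene is an up-regulated DEG when `padj < alpha` and `log2fc > 0`, and a
#' down-regulated DEG when `padj < alpha` and `log2fc < 0` (both thresholds
#' strict). Genes with `log2fc == 0` belong to neither set.
#'
#' @param records A [de_table].
#' @param alpha Adjusted-p threshold in (0, 1); default 0.05.
#' @return A list with character vectors `up` and `down`.
#' @export
select_degs <- function(records, alpha = 0.05) {
  stopifnot(inherits(records, "de_table"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_fmt("alpha must be in (0, 1)")
  }
  sig <- records$padj < alpha
  list(up = records$gene[sig & records$log2fc > 0],
       down = records$gene[sig & records$log2fc < 0])
}

#' Construct a ranked signature
#'
#' An ordered gene list with its ranking metric, the common currency of all
#' enrichment scoring. Metric values must be non-increasing.
#'
#' @param genes Character vector of unique gene identifiers.
#' @param metric Numeric vector of the same length, non-increasing.
#' @param metric_name Label of the ranking metric.
#' @return An object of class `ranked_signature` with elements `genes`,
#'   `metric`, `metric_name`.
#' @export
ranked_signature <- function(genes, metric, metric_name = "metric") {
  genes <- as.character(genes)
  if (length(genes) < 1L) stop_fmt("ranked signature must be non-empty")
  if (length(metric) != length(genes)) stop_fmt("lengths differ")
  dup <- anyDuplicated(genes)
  if (dup) stop_fmt("duplicate gene identifier: '", genes[dup], "'")
  if (any(!is.finite(metric))) stop_fmt("metric must be finite")
  if (is.unsorted(rev(metric))) stop_fmt("metric must be non-increasing")
  structure(list(genes = genes, metric = as.numeric(metric),
                 metric_name = metric_name),
            class = "ranked_signature")
}

#' @export
print.ranked_signature <- function(x, ...) {
  cat("Ranked signature:", length(x$genes), "genes by", x$metric_name,
      "(descending)\n")
  k <- min(5L, length(x$genes))
  cat("  head:", paste(sprintf("%s=%.3g", x$genes[1:k], x$metric[1:k]),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Rank genes of a DE table by a metric, descending
#'
#' Sorts by the chosen metric in descending order; ties are broken by gene
#' identifier ascending so the ranking is deterministic.
#'
#' @param records A [de_table].
#' @param metric `"log2fc"` (default) or `"stat"`.
#' @return A [ranked_signature].
#' @export
rank_genes <- function(records, metric = c("log2fc", "stat")) {
  stopifnot(inherits(records, "de_table"))
  metric <- match.arg(metric)
  if (is.null(records[[metric]])) {
    stop_fmt("metric column '", metric, "' not present")
  }
  m <- records[[metric]]
  if (any(!is.finite(m))) stop_fmt("metric '", metric, "' has missing values")
  o <- order(-m, records$gene, method = "radix")
  ranked_signature(records$gene[o], m[o], metric_name = metric)
}

#' Construct a perturbation signature
#'
#' One compound/dose/time/cell-line column of a LINCS-style level 5 matrix:
#' a named vector of per-gene z-scores plus its metadata.
#'
#' @param compound Compound (perturbagen) name.
#' @param zscores Named numeric vector of finite z-scores, names unique.
#' @param dose,treat_time,cell,batch Metadata strings, kept as given.
#' @return An object of class `perturbation_signature`.
#' @export
perturbation_signature <- function(compound, zscores, dose = "", treat_time = "",
                                   cell = "", batch = "") {
  if (!length(zscores)) stop_fmt("zscores must be non-empty")
  if (is.null(names(zscores)) || any(!nzchar(names(zscores)))) {
    stop_fmt("zscores must be named by gene")
  }
  dup <- anyDuplicated(names(zscores))
  if (dup) stop_fmt("duplicate gene identifier: '", names(zscores)[dup], "'")
  if (any(!is.finite(zscores))) stop_fmt("zscores must be finite")
  structure(list(compound = as.character(compound), dose = as.character(dose),
                 treat_time = as.character(treat_time),
                 cell = as.character(cell), batch = as.character(batch),
                 zscores = zscores),
            class = "perturbation_signature")
}

#' @export
print.perturbation_signature <- function(x, ...) {
  cat(sprintf("Perturbation signature: %s [%s, %s, %s, batch %s], %d genes\n",
              x$compound, x$dose, x$treat_time, x$cell, x$batch,
              length(x$zscores)))
  invisible(x)
}

#' Extreme up/down gene sets of a perturbation signature
#'
#' Selects the `n` genes with the largest z-scores (the up set) and the `n`
#' with the smallest (the down set), the predefined gene sets of the
#' connectivity screen. Selection is by z-score value regardless of sign;
#' `require_sign = TRUE` additionally demands `z > 0` (up) / `z < 0` (down),
#' clamping the set with a warning where not enough genes qualify. Ties at
#' the cutoff are broken by gene identifier ascending.
#'
#' @param sig A [perturbation_signature] or a named numeric z-score vector.
#' @param n Set size (the screen default is 500).
#' @param require_sign Restrict sets to strictly signed z-scores
#'   (default FALSE).
#' @return A list with character vectors `up` and `down`.
#' @export
extreme_sets <- function(sig, n, require_sign = FALSE) {
  z <- if (inherits(sig, "perturbation_signature")) sig$zscores else sig
  stopifnot(is.numeric(z), !is.null(names(z)))
  if (!is_count(n) || n < 1) stop_fmt("n must be a positive integer")
  if (2 * n > length(z)) {
    stop_fmt("2n = ", 2 * n, " exceeds the ", length(z),
             " genes in the signature")
  }
  g <- names(z)
  up <- g[order(-z, g, method = "radix")][seq_len(n)]
  down <- g[order(z, g, method = "radix")][seq_len(n)]
  if (require_sign) {
    up_ok <- up[z[up] > 0]
    down_ok <- down[z[down] < 0]
    if (length(up_ok) < n || length(down_ok) < n) {
      warn("extreme_sets: sign requirement clamped up set to ",
           length(up_ok), " and down set to ", length(down_ok), " genes")
    }
    up <- up_ok; down <- down_ok
  }
  list(up = up, down = down)
}
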