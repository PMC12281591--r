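# Preranked GSEA from first principles: weighted Kolmogorov-Smirnov running
# sum, gene-set permutation null, sign-stratified NES, and the
# over-representation / rank-aggregation statistics used alongside it.

#' Enrichment parameters
#'
#' @param exponent Weighting power applied to |metric| in the hit increment;
#'   1 is the classic weighted statistic, 0 the unweighted KS form.
#' @param n_perm Number of gene-set permutations for the null.
#' @param min_size,max_size Gene-set size bounds (after intersection with
#'   the ranked universe) outside which sets are skipped. The defaults
#'   (3, 5000) never skip a 500-gene connectivity set.
#' @param seed Integer seed; permutation nulls derive their streams from it.
#' @return A list of class `enrichment_params`.
#' @export
enrichment_params <- function(exponent = 1, n_perm = 1000, min_size = 3,
                              max_size = 5000, seed = 0) {
  if (!is.numeric(exponent) || length(exponent) != 1L || exponent < 0) {
    stop_fmt("exponent must be a single non-negative number")
  }
  if (!is_count(n_perm) || n_perm < 1) stop_fmt("n_perm must be >= 1")
  if (!is_count(min_size) || min_size < 1 || !is_count(max_size) ||
      max_size < min_size) {
    stop_fmt("need 1 <= min_size <= max_size")
  }
  structure(list(exponent = exponent, n_perm = as.integer(n_perm),
                 min_size = as.integer(min_size),
                 max_size = as.integer(max_size), seed = as.integer(seed)),
            class = "enrichment_params")
}

# Core running-sum evaluation on a precomputed weight vector. `hit` is a
# logical over ranked positions. Returns es only (fast path for permutation
# nulls); degenerate all-zero-weight draws score 0.
es_kernel <- function(w, hit, N) {
  n_h <- sum(hit)
  n_r <- sum(w[hit])
  if (n_r == 0) return(0)
  incr <- numeric(N)
  incr[hit] <- w[hit] / n_r
  incr[!hit] <- -1 / (N - n_h)
  pick_extremum(cumsum(incr))$es
}

# Signed extremum of a running sum. When the positive and negative peaks
# tie in magnitude (within 1e-9, absorbing accumulation-order noise), the
# positive peak wins by convention.
pick_extremum <- function(rs) {
  p <- max(rs)
  n <- min(rs)
  if (p + n >= -1e-9) {
    list(es = p, index = which.max(rs))
  } else {
    list(es = n, index = which.min(rs))
  }
}

#' Enrichment score of a gene set on a ranked list
#'
#' Walks the ranked list accumulating `|metric_i|^exponent / N_R` at each
#' member of the set (N_R normalizes the hit increments to total 1) and
#' `-1 / (N - N_H)` at each non-member. The enrichment score is the value
#' of the running sum at its point of maximal absolute deviation from zero
#' (signed); when the positive and negative peaks tie in magnitude (within
#' 1e-9) the positive peak is taken, a fixed convention for an otherwise
#' ambiguous extremum. The running sum returns to 0 at the end of the
#' list. The leading edge is the set members at or before the extremum for
#' a positive score, and at or after it for a negative score.
#'
#' @param ranked A [ranked_signature].
#' @param gene_set Character vector of member genes (members absent from
#'   the ranked universe are intersected away).
#' @param exponent Weighting power (default 1).
#' @return A list with `es`, `running_sum` (numeric, one value per ranked
#'   position), `leading_edge` (character) and `size` (effective set size).
#' @export
enrichment_score <- function(ranked, gene_set, exponent = 1) {
  stopifnot(inherits(ranked, "ranked_signature"))
  N <- length(ranked$genes)
  hit <- ranked$genes %in% gene_set
  n_h <- sum(hit)
  if (n_h == 0L) {
    stop_fmt("empty effective set: no gene-set member in the ranked universe")
  }
  if (n_h == N) {
    stop_fmt("gene set covers the whole ranked universe; ",
             "miss increment undefined")
  }
  w <- abs(ranked$metric)^exponent
  n_r <- sum(w[hit])
  if (n_r == 0 && exponent > 0) {
    stop_fmt("degenerate score: all hit metrics are zero with exponent > 0")
  }
  incr <- numeric(N)
  incr[hit] <- w[hit] / n_r
  incr[!hit] <- -1 / (N - n_h)
  rs <- cumsum(incr)
  ext <- pick_extremum(rs)
  es <- ext$es
  i_ext <- ext$index
  le <- if (es > 0) {
    ranked$genes[hit & seq_len(N) <= i_ext]
  } else if (es < 0) {
    ranked$genes[hit & seq_len(N) >= i_ext]
  } else {
    character()
  }
  list(es = es, running_sum = rs, leading_edge = le, size = n_h)
}

#' Permutation null distribution of the enrichment score
#'
#' Scores `n_perm` uniformly drawn gene subsets of the given size against
#' the ranked list — the gene-set (label) permutation null, the only scheme
#' available to a preranked analysis. The random stream is derived from
#' `params$seed` and `set_size` alone, so the null for a given size can be
#' shared across signatures and is identical regardless of evaluation
#' order.
#'
#' @param ranked A [ranked_signature].
#' @param set_size Size of the permuted sets (< universe size).
#' @param params An [enrichment_params].
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
permutation_null <- function(ranked, set_size, params = enrichment_params()) {
  stopifnot(inherits(ranked, "ranked_signature"),
            inherits(params, "enrichment_params"))
  N <- length(ranked$genes)
  if (!is_count(set_size) || set_size < 1 || set_size >= N) {
    stop_fmt("set_size must be in [1, universe size)")
  }
  w <- abs(ranked$metric)^params$exponent
  withr::with_seed(derive_seed(params$seed, paste0("null_size_", set_size)), {
    vapply(seq_len(params$n_perm), function(b) {
      hit <- logical(N)
      hit[sample.int(N, set_size)] <- TRUE
      es_kernel(w, hit, N)
    }, numeric(1L))
  })
}

#' Normalize an enrichment score against its permutation null
#'
#' Sign-stratified normalization: with `S` the null scores sharing the sign
#' of `es` (zeros excluded), `nes = es / mean(|S|)` and
#' `p = (#\{|s| >= |es|\} + 1) / (|S| + 1)`. If no null score shares the
#' sign, the mean over the whole null is used and the p-value floored at
#' `1 / (n_null + 1)`, with a warning. `es = 0` yields `nes = 0`, `p = 1`.
#'
#' @param es Enrichment score.
#' @param null Numeric vector of null enrichment scores.
#' @return A list with `nes` and `pvalue`.
#' @export
normalize_es <- function(es, null) {
  if (!length(null)) stop_fmt("null distribution is empty")
  if (!is.finite(es)) stop_fmt("es must be finite")
  if (es == 0) {
    warn("normalize_es: es = 0; nes = 0, p = 1")
    return(list(nes = 0, pvalue = 1))
  }
  S <- null[sign(null) == sign(es)]
  if (!length(S)) {
    warn("normalize_es: no same-sign null value; using |null| mean")
    return(list(nes = es / mean(abs(null)), pvalue = 1 / (length(null) + 1)))
  }
  list(nes = es / mean(abs(S)),
       pvalue = (sum(abs(S) >= abs(es)) + 1) / (length(S) + 1))
}

#' Preranked gene set enrichment analysis
#'
#' Scores every gene set of a collection against a ranked list, normalizes
#' against a shared per-size permutation null, and adjusts p-values by
#' Benjamini-Hochberg across all tested sets. Sets whose effective size
#' (after intersection with the ranked universe) falls outside
#' `[min_size, max_size]` are skipped with a log entry.
#'
#' @param ranked A [ranked_signature].
#' @param collection Named list of character vectors (e.g. from
#'   [read_gmt]).
#' @param params An [enrichment_params].
#' @return A data.frame of class `gsea_result` with columns `set_id`,
#'   `size`, `es`, `nes`, `pvalue`, `padj`, `leading_edge` (comma-joined),
#'   sorted by `nes` descending.
#' @export
gsea_preranked <- function(ranked, collection, params = enrichment_params()) {
  stopifnot(inherits(ranked, "ranked_signature"))
  if (!length(collection)) stop_fmt("gene-set collection is empty")
  if (is.null(names(collection))) stop_fmt("collection must be named")
  sizes <- vapply(collection, function(s) sum(ranked$genes %in% s), 0L)
  testable <- sizes >= params$min_size & sizes <= params$max_size
  if (any(!testable)) {
    msg("gsea_preranked: skipping ", sum(!testable), " set(s) outside size [",
        params$min_size, ", ", params$max_size, "]: ",
        paste(names(collection)[!testable], collapse = ", "))
  }
  if (!any(testable)) {
    warn("gsea_preranked: no testable gene set")
    out <- data.frame(set_id = character(), size = integer(), es = numeric(),
                      nes = numeric(), pvalue = numeric(), padj = numeric(),
                      leading_edge = character(), stringsAsFactors = FALSE)
    class(out) <- c("gsea_result", "data.frame")
    return(out)
  }
  ids <- names(collection)[testable]
  null_cache <- new.env(parent = emptyenv())
  rows <- lapply(ids, function(id) {
    sc <- enrichment_score(ranked, collection[[id]], params$exponent)
    key <- as.character(sc$size)
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- permutation_null(ranked, sc$size, params)
    }
    nz <- normalize_es(sc$es, null_cache[[key]])
    data.frame(set_id = id, size = sc$size, es = sc$es, nes = nz$nes,
               pvalue = nz$pvalue,
               leading_edge = paste(sc$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$pvalue)
  out <- out[order(-out$nes, out$set_id),
             c("set_id", "size", "es", "nes", "pvalue", "padj",
               "leading_edge")]
  rownames(out) <- NULL
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sorted ascending,
#' `padj_(i) = min_(j>=i)(p_(j) * m / j)` capped at 1, returned in input
#' order. Inputs outside (0, 1] are rejected.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  assert_prob(pvalues, "pvalue")
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis by the hypergeometric test
#'
#' For each gene set, tests whether the interest list overlaps the set
#' (intersected with the background) more than expected under uniform
#' draws from the background: one-sided upper-tail hypergeometric
#' `P(X >= overlap)` with the background as population. BH adjustment
#' across sets.
#'
#' @param interest Character vector of genes of interest (must be a subset
#'   of `background`).
#' @param background Character vector of all detected genes (>= 2).
#' @param collection Named list of character vectors.
#' @return A data.frame of class `ora_result` with columns `set_id`,
#'   `overlap`, `set_size`, `interest_size`, `background_size`,
#'   `gene_ratio`, `pvalue`, `padj`, sorted by `pvalue`.
#' @export
ora_fisher <- function(interest, background, collection) {
  interest <- unique(as.character(interest))
  background <- unique(as.character(background))
  if (length(background) < 2L) stop_fmt("background must have >= 2 genes")
  missing <- setdiff(interest, background)
  if (length(missing)) {
    stop_fmt("interest gene(s) absent from background: ",
             paste(utils::head(missing, 5L), collapse = ", "))
  }
  if (!length(collection) || is.null(names(collection))) {
    stop_fmt("collection must be a non-empty named list")
  }
  N <- length(background)
  k <- length(interest)
  rows <- lapply(names(collection), function(id) {
    set_bg <- intersect(unique(collection[[id]]), background)
    m <- length(set_bg)
    x <- length(intersect(set_bg, interest))
    p <- stats::phyper(x - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(set_id = id, overlap = x, set_size = m, interest_size = k,
               background_size = N,
               gene_ratio = if (k > 0) x / k else 0,
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$pvalue)
  out <- out[order(out$pvalue, out$set_id), ]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}

#' Aggregate rankings by mean rank
#'
#' Averages an item's 1-based ranks across several rankings (e.g. a
#' transcription factor's ranks across enrichment libraries, from which the
#' top candidates are selected). Items missing from a ranking receive that
#' ranking's length + 1 as a penalty rank (logged). Ties in the mean are
#' broken by item identifier ascending.
#'
#' @param rankings Named list; each element is either a character vector in
#'   rank order or a named numeric vector of 1-based ranks.
#' @return A data.frame with columns `item` and `mean_rank`, sorted by
#'   `mean_rank` ascending.
#' @export
mean_rank_aggregate <- function(rankings) {
  if (!length(rankings)) stop_fmt("rankings must be non-empty")
  rankings <- lapply(rankings, function(r) {
    if (is.character(r)) r <- stats::setNames(seq_along(r), r)
    if (is.null(names(r))) stop_fmt("each ranking must be named by item")
    r
  })
  items <- sort(unique(unlist(lapply(rankings, names))))
  n_penalty <- 0L
  ranks <- vapply(rankings, function(r) {
    v <- r[items]
    miss <- is.na(v)
    n_penalty <<- n_penalty + sum(miss)
    v[miss] <- length(r) + 1
    as.numeric(v)
  }, numeric(length(items)))
  if (n_penalty > 0) {
    msg("mean_rank_aggregate: ", n_penalty,
        " missing item-ranking pair(s) given penalty rank (length + 1)")
  }
  ranks <- matrix(ranks, nrow = length(items))
  mean_rank <- rowMeans(ranks)
  o <- order(mean_rank, items, method = "radix")
  data.frame(item = items[o], mean_rank = mean_rank[o],
             stringsAsFactors = FALSE, row.names = NULL)
}
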