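# Downstream comparative statistics: Jaccard similarity of DEG sets,
# footprint-based pathway activity scores, and reporter-metabolite
# aggregation of gene-level significance over a metabolic network.

#' Jaccard similarity of two gene sets
#'
#' `|a intersect b| / |a union b|`; duplicates are ignored. Both sets empty
#' is undefined and an error.
#'
#' @param a,b Character vectors of gene identifiers.
#' @return Similarity in [0, 1].
#' @export
jaccard <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (!length(a) && !length(b)) {
    stop_fmt("jaccard undefined for two empty sets")
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Pairwise Jaccard similarity matrix
#'
#' Compares DEG (or any gene) sets across conditions. Symmetric with unit
#' diagonal.
#'
#' @param named_sets Named list (>= 2 elements) of non-empty character
#'   vectors.
#' @return A symmetric numeric matrix with the set names as dimnames.
#' @export
jaccard_matrix <- function(named_sets) {
  if (!is.list(named_sets) || length(named_sets) < 2L ||
      is.null(names(named_sets))) {
    stop_fmt("named_sets must be a named list of >= 2 sets")
  }
  empty <- names(named_sets)[lengths(named_sets) == 0L]
  if (length(empty)) stop_fmt("empty set: '", empty[1L], "'")
  n <- length(named_sets)
  m <- diag(1, n)
  dimnames(m) <- list(names(named_sets), names(named_sets))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      m[i, j] <- m[j, i] <- jaccard(named_sets[[i]], named_sets[[j]])
    }
  }
  m
}

#' Select top-k footprint genes per pathway from a full weight table
#'
#' Keeps, for each pathway, the `k` genes with the largest absolute model
#' weight — the pathway's footprint signature.
#'
#' @param weights Numeric matrix (genes x pathways, dimnames set) or a
#'   data.frame with columns `gene`, `pathway`, `weight`.
#' @param k Footprint size per pathway (default 100).
#' @return A named list of pathway models (named numeric weight vectors).
#' @export
top_k_weights <- function(weights, k = 100) {
  if (!is_count(k) || k < 1) stop_fmt("k must be a positive integer")
  if (is.matrix(weights)) {
    stopifnot(!is.null(rownames(weights)), !is.null(colnames(weights)))
    models <- lapply(colnames(weights), function(p) {
      w <- weights[, p]
      w <- w[w != 0]
      w[order(-abs(w), names(w), method = "radix")][seq_len(min(k, length(w)))]
    })
    names(models) <- colnames(weights)
  } else {
    stopifnot(all(c("gene", "pathway", "weight") %in% names(weights)))
    models <- lapply(split(weights, weights$pathway), function(d) {
      w <- stats::setNames(d$weight, d$gene)
      w <- w[w != 0]
      w[order(-abs(w), names(w), method = "radix")][seq_len(min(k, length(w)))]
    })
  }
  models[lengths(models) > 0L]
}

#' Footprint-based pathway activity scores
#'
#' Scores each pathway model as the weighted sum of the per-gene test
#' statistics of its footprint genes, and normalizes against a
#' gene-permutation null: the statistic values are permuted over gene
#' labels `n_perm` times, and the activity z-score is
#' `(raw - mean(null)) / sd(null)` with a two-sided, +1-corrected
#' permutation p-value. Null draws depend only on the seed, the pathway
#' name and the statistic vector — not the weights — so rescaling weights
#' rescales `raw_score` but leaves the z-score unchanged.
#'
#' @param gene_stats Named numeric vector, gene -> test statistic (e.g. the
#'   Wald statistic of a DE fit).
#' @param models Named list of pathway models (named numeric weights), e.g.
#'   from [top_k_weights].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A data.frame of class `pathway_activity` with columns `pathway`,
#'   `n_genes`, `raw_score`, `zscore`, `pvalue`, sorted by `zscore`
#'   descending.
#' @export
progeny_scores <- function(gene_stats, models, n_perm = 1000, seed = 0) {
  if (!length(gene_stats) || is.null(names(gene_stats))) {
    stop_fmt("gene_stats must be a non-empty named vector")
  }
  if (!length(models) || is.null(names(models))) {
    stop_fmt("models must be a non-empty named list")
  }
  if (!is_count(n_perm) || n_perm < 1) stop_fmt("n_perm must be >= 1")
  n_genes <- length(gene_stats)
  rows <- lapply(names(models), function(p) {
    w <- models[[p]]
    if (any(!is.finite(w))) stop_fmt("non-finite weight in pathway '", p, "'")
    present <- names(w)[names(w) %in% names(gene_stats)]
    if (!length(present)) {
      msg("progeny_scores: pathway '", p,
          "' shares no gene with gene_stats; skipped")
      return(NULL)
    }
    w <- w[present]
    raw <- sum(w * gene_stats[present])
    m <- length(present)
    null <- withr::with_seed(derive_seed(seed, paste0("progeny_", p)), {
      vapply(seq_len(n_perm), function(b) {
        sum(w * gene_stats[sample.int(n_genes, m)])
      }, numeric(1L))
    })
    mu <- mean(null)
    s <- stats::sd(null)
    if (!is.finite(s) || s == 0) {
      warn("progeny_scores: null sd = 0 for pathway '", p, "'; zscore = 0")
      z <- 0
      pv <- 1
    } else {
      z <- (raw - mu) / s
      pv <- (sum(abs(null - mu) >= abs(raw - mu)) + 1) / (n_perm + 1)
    }
    data.frame(pathway = p, n_genes = m, raw_score = raw, zscore = z,
               pvalue = pv, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop_fmt("no pathway model overlaps gene_stats")
  out <- do.call(rbind, rows)
  out <- out[order(-out$zscore, out$pathway), ]
  rownames(out) <- NULL
  class(out) <- c("pathway_activity", "data.frame")
  out
}

#' Reporter-metabolite scores
#'
#' Identifies metabolites surrounded by significant transcriptional change.
#' Each gene's p-value is converted to a normal score
#' `Z = qnorm(1 - p)` (p clamped to [1e-15, 1 - 1e-15]); a metabolite with
#' `k` neighboring genes aggregates them as `Z_agg = sum(Z) / sqrt(k)`. The
#' aggregate is background-corrected against `n_samples` random size-k gene
#' draws from the full gene list (one null per distinct k):
#' `z_corrected = (Z_agg - mu_k) / sigma_k`, with upper-tail normal p-value
#' `1 - pnorm(z_corrected)`.
#'
#' Directional variants (e.g. reporter metabolites of down-regulation) are
#' obtained by restricting `gene_pvalues` to one DE direction before the
#' call; the aggregation itself is unsigned.
#'
#' @param gene_pvalues Named numeric vector of per-gene p-values in (0, 1).
#' @param network Named list, metabolite -> character vector of neighboring
#'   genes; every gene must appear in `gene_pvalues`.
#' @param n_samples Background draws per distinct neighborhood size
#'   (default 10000).
#' @param seed Integer seed.
#' @return A data.frame of class `reporter_scores` with columns
#'   `metabolite`, `k`, `z_agg`, `z_corrected`, `pvalue`, sorted by
#'   `z_corrected` descending.
#' @export
reporter_metabolites <- function(gene_pvalues, network, n_samples = 10000,
                                 seed = 0) {
  if (!length(network)) stop_fmt("network is empty")
  if (is.null(names(network))) stop_fmt("network must be named by metabolite")
  if (!length(gene_pvalues) || is.null(names(gene_pvalues))) {
    stop_fmt("gene_pvalues must be a non-empty named vector")
  }
  if (any(!is.finite(gene_pvalues) | gene_pvalues <= 0 |
          gene_pvalues >= 1)) {
    stop_fmt("gene p-values must lie in (0, 1)")
  }
  all_genes <- unique(unlist(network))
  missing <- setdiff(all_genes, names(gene_pvalues))
  if (length(missing)) {
    stop_fmt("network gene(s) absent from gene_pvalues: ",
             paste(utils::head(missing, 5L), collapse = ", "))
  }
  p <- pmin(pmax(gene_pvalues, 1e-15), 1 - 1e-15)
  Z <- stats::qnorm(1 - p)
  nG <- length(Z)
  ks <- vapply(network, function(g) length(unique(g)), 0L)
  if (any(ks < 1L)) stop_fmt("every metabolite needs >= 1 neighboring gene")
  null_stats <- new.env(parent = emptyenv())
  for (k in unique(ks)) {
    draws <- withr::with_seed(derive_seed(seed, paste0("reporter_k", k)), {
      vapply(seq_len(n_samples), function(b) {
        sum(Z[sample.int(nG, k)])
      }, numeric(1L)) / sqrt(k)
    })
    null_stats[[as.character(k)]] <- c(mu = mean(draws),
                                       sigma = stats::sd(draws))
  }
  z_agg <- vapply(network, function(g) sum(Z[unique(g)]), 0) / sqrt(ks)
  z_corr <- vapply(seq_along(ks), function(i) {
    ns <- null_stats[[as.character(ks[i])]]
    if (!is.finite(ns[["sigma"]]) || ns[["sigma"]] == 0) {
      warn("reporter_metabolites: background sd = 0 for k = ", ks[i],
           "; z_corrected = 0")
      0
    } else {
      (z_agg[i] - ns[["mu"]]) / ns[["sigma"]]
    }
  }, numeric(1L))
  out <- data.frame(metabolite = names(network), k = as.integer(ks),
                    z_agg = as.numeric(z_agg), z_corrected = z_corr,
                    pvalue = pmax(1 - stats::pnorm(z_corr), 1e-300),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$z_corrected, out$metabolite), ]
  rownames(out) <- NULL
  class(out) <- c("reporter_scores", "data.frame")
  out
}
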