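# Independent oracles and small fixture builders used across the suite.

# Brute-force running-sum enrichment score: explicit position-by-position
# loop, kept deliberately separate from the package's vectorized kernel.
# Shares the documented extremum tie rule: a positive/negative peak tie
# within 1e-9 resolves to the positive peak.
brute_es <- function(metric, hit, exponent = 1) {
  N <- length(metric)
  n_h <- sum(hit)
  n_r <- sum(abs(metric[hit])^exponent)
  run <- 0
  peak_pos <- 0
  peak_neg <- 0
  for (i in seq_len(N)) {
    run <- if (hit[i]) run + abs(metric[i])^exponent / n_r
           else run - 1 / (N - n_h)
    if (run > peak_pos) peak_pos <- run
    if (run < peak_neg) peak_neg <- run
  }
  if (peak_pos + peak_neg >= -1e-9) peak_pos else peak_neg
}

# Naive O(m^2) Benjamini-Hochberg: for each sorted index take the direct
# minimum over larger indices.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) ps[j] * m / j, numeric(1))
    adj[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# A ranked signature over n genes with metric values given (descending).
make_ranked <- function(metric, genes = sprintf("g%02d", seq_along(metric))) {
  ranked_signature(genes, metric)
}

# A tiny DE table with explicit fields.
make_de <- function(gene, log2fc, padj, pvalue = padj, stat = NULL) {
  de_table(gene, log2fc, pvalue, padj, stat = stat)
}

fixture_top10 <- function() {
  read_connectivity(system.file("extdata", "l1000_screen_top10.tsv",
                                package = "sigscreen"))
}
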