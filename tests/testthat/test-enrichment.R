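test_that("enrichment_score handles extreme-position and oracle cases", {
  r <- make_ranked(c(3, 2, 1, 0.5))
  # set = rank-1 gene: running sum peaks at 1 immediately
  sc <- enrichment_score(r, r$genes[1], exponent = 1)
  expect_equal(sc$es, 1.0)
  expect_equal(sc$leading_edge, r$genes[1])
  # set = rank-4 gene: maximal deviation is -1 just before the hit
  sc <- enrichment_score(r, r$genes[4], exponent = 1)
  expect_equal(sc$es, -1.0)
  expect_equal(sc$leading_edge, r$genes[4])

  # brute-force oracle on a 10-gene signed ranking
  metric <- c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5)
  r <- make_ranked(metric)
  hit <- seq_along(metric) %in% c(3, 7)
  sc <- enrichment_score(r, r$genes[hit], exponent = 1)
  expect_equal(sc$es, brute_es(metric, hit), tolerance = 1e-12)

  # running sum returns to zero
  expect_lt(abs(sc$running_sum[length(metric)]), 1e-9)
})

test_that("enrichment_score rejects degenerate configurations", {
  r <- make_ranked(c(3, 2, 1, 0))
  expect_error(enrichment_score(r, "absent"), "empty effective set")
  expect_error(enrichment_score(r, r$genes), "whole ranked universe")
  expect_error(enrichment_score(r, r$genes[4], exponent = 1), "degenerate")
  # exponent 0 tolerates zero metrics
  expect_equal(abs(enrichment_score(r, r$genes[4], exponent = 0)$es), 1)
})

test_that("enrichment_score matches oracles over many random cases", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(8:30, 1)
    metric <- sort(rnorm(n), decreasing = TRUE)
    r <- make_ranked(metric)
    k <- sample(seq_len(n - 1), 1)
    hit <- seq_len(n) %in% sample(n, k)
    expo <- sample(c(0, 0.5, 1, 2), 1)
    sc <- enrichment_score(r, r$genes[hit], exponent = expo)
    expect_equal(sc$es, brute_es(metric, hit, expo), tolerance = 1e-12)
    expect_lte(abs(sc$es), 1)
    expect_lt(abs(sc$running_sum[n]), 1e-9)
  }
})

test_that("enrichment_score agrees with fgsea's statistic", {
  set.seed(9)
  metric <- sort(rnorm(200), decreasing = TRUE)
  r <- make_ranked(metric)
  for (k in c(5, 20, 60)) {
    idx <- sort(sample(200, k))
    ours <- enrichment_score(r, r$genes[idx], exponent = 1)$es
    ref <- fgsea::calcGseaStat(stats::setNames(metric, r$genes), idx,
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("antisymmetry: reversing the list and negating metrics flips es", {
  set.seed(13)
  for (i in 1:20) {
    n <- 20
    metric <- sort(rnorm(n), decreasing = TRUE)
    hit <- seq_len(n) %in% sample(n, 4)
    rs_f <- cumsum(ifelse(hit, abs(metric)^1 / sum(abs(metric[hit])),
                          -1 / (n - 4)))
    # only claim antisymmetry when the extremum is unique
    if (sum(abs(abs(rs_f) - max(abs(rs_f))) < 1e-12) != 1L) next
    r_fwd <- make_ranked(metric)
    r_rev <- make_ranked(rev(-metric), genes = rev(r_fwd$genes))
    es_fwd <- enrichment_score(r_fwd, r_fwd$genes[hit])$es
    es_rev <- enrichment_score(r_rev, r_fwd$genes[hit])$es
    expect_equal(es_rev, -es_fwd, tolerance = 1e-10)
  }
})

test_that("permutation_null is reproducible, size-keyed and centred", {
  r <- make_ranked(sort(rnorm(100), decreasing = TRUE))
  p1 <- enrichment_params(n_perm = 1, seed = 5)
  expect_length(permutation_null(r, 10, p1), 1L)
  expect_identical(permutation_null(r, 10, p1), permutation_null(r, 10, p1))
  # largest admissible set size still defined
  expect_length(permutation_null(r, 99, p1), 1L)
  expect_error(permutation_null(r, 100, p1), "set_size")

  # Monte-Carlo sanity: on a symmetric uniform metric grid the null ES
  # distribution is symmetric, so its mean lies within 3 SE of 0
  r <- make_ranked(seq(1, -1, length.out = 100))
  null <- permutation_null(r, 10, enrichment_params(n_perm = 1000, seed = 8))
  se <- sd(null) / sqrt(length(null))
  expect_lt(abs(mean(null)), 3 * se)
})

test_that("normalize_es applies sign-stratified NES and tail p-value", {
  # nes forced by the formula
  null <- c(0.25, 0.25, 0.25, -0.4)
  expect_equal(normalize_es(0.5, null)$nes, 2.0)
  expect_equal(normalize_es(-0.5, c(-0.25, -0.25, 0.3))$nes, -2.0)

  # 99 same-sign nulls all smaller in magnitude -> p = 1/100
  null <- seq(0.001, 0.099, length.out = 99)
  expect_equal(normalize_es(0.9, null)$pvalue, 1 / 100)

  # counting with the +1 correction
  null <- c(0.95, seq(0.001, 0.05, length.out = 98))
  expect_equal(normalize_es(0.9, null)$pvalue, 2 / 100)

  # degenerate cases warn
  expect_warning(out <- normalize_es(0, c(0.1, -0.1)), "es = 0")
  expect_equal(out, list(nes = 0, pvalue = 1))
  expect_warning(out <- normalize_es(0.5, c(-0.25, -0.25)), "same-sign")
  expect_equal(out$pvalue, 1 / 3)
  expect_equal(out$nes, 2.0)
})

test_that("null permutation p-values are approximately uniform", {
  sim <- simulate_de_table(sim_config(n_genes = 500, frac_de = 0, seed = 17))
  ranked <- rank_genes(sim$records)
  params <- enrichment_params(n_perm = 200, seed = 17)
  sets <- simulate_gene_sets(100, c(15, 15), ranked$genes, seed = 17)
  res <- gsea_preranked(ranked, sets, params)
  ks <- suppressWarnings(ks.test(res$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("gsea_preranked filters by size, adjusts and sorts", {
  ranked <- make_ranked(sort(rnorm(50), decreasing = TRUE))
  params <- enrichment_params(n_perm = 100, min_size = 3, seed = 1)

  expect_warning(
    expect_message(out <- gsea_preranked(ranked, list(tiny = ranked$genes[1]),
                                         params), "skipping"),
    "no testable")
  expect_equal(nrow(out), 0L)

  # a set planted in the top decile of a simulated ranking wins, seeds 1..5
  for (seed in 1:5) {
    sim <- simulate_de_table(sim_config(n_genes = 300, frac_de = 0.3,
                                        seed = seed))
    ranked <- rank_genes(sim$records)
    top_decile <- ranked$genes[1:30]
    sets <- simulate_gene_sets(6, c(15, 15), ranked$genes,
                               frac_enriched = 0.9, target_genes = top_decile,
                               seed = seed)
    res <- gsea_preranked(ranked, sets,
                          enrichment_params(n_perm = 200, seed = seed))
    expect_equal(res$set_id[1], "enriched_01")
    expect_lte(res$pvalue[res$set_id == "enriched_01"], 0.05)
  }

  # duplicated sets give identical rows
  s <- list(a = ranked$genes[c(2, 5, 9, 12)], b = ranked$genes[c(2, 5, 9, 12)])
  res <- gsea_preranked(ranked, s, enrichment_params(n_perm = 100, seed = 2))
  expect_equal(res$es[1], res$es[2])
  expect_equal(res$nes[1], res$nes[2])
  expect_equal(res$padj[1], res$padj[2])
})

test_that("bh_adjust matches the naive step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.05, 0.05, 0.05)), c(0.05, 0.05, 0.05))
  expect_error(bh_adjust(c(0.1, 0)), "pvalue")
  expect_error(bh_adjust(c(0.1, 1.2)), "pvalue")

  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, naive_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
  }
})

test_that("ora_fisher computes exact hypergeometric tails", {
  background <- sprintf("g%02d", 1:20)
  set <- background[1:5]
  interest <- c(background[1:4], background[10])   # overlap 4
  res <- ora_fisher(interest, background, list(S = set))
  expect_equal(res$pvalue, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$overlap, 4L)
  expect_equal(res$gene_ratio, 4 / 5)

  # zero overlap: P(X >= 0) = 1
  res <- ora_fisher(background[10:12], background, list(S = background[1:2]))
  expect_equal(res$pvalue, 1)

  expect_error(ora_fisher(c("gX", background[1]), background, list(S = set)),
               "gX")
})

test_that("mean_rank_aggregate averages with penalty and tie rules", {
  # symmetric tie resolved by item id
  out <- mean_rank_aggregate(list(L1 = c(A = 1, B = 2), L2 = c(A = 2, B = 1)))
  expect_equal(out$item, c("A", "B"))
  expect_equal(out$mean_rank, c(1.5, 1.5))

  out <- mean_rank_aggregate(list(L1 = c(A = 1, B = 3, C = 2)))
  expect_equal(out$item, c("A", "C", "B"))

  # item missing from one length-3 ranking gets penalty rank 4
  expect_message(
    out <- mean_rank_aggregate(list(L1 = c(A = 1, B = 2, C = 3),
                                    L2 = c(B = 1, C = 2, D = 3))),
    "penalty")
  expect_equal(out$mean_rank[out$item == "A"], (1 + 4) / 2)

  expect_error(mean_rank_aggregate(list()), "non-empty")
})
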