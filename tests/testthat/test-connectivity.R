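test_that("summarized_nes subtracts and rejects non-finite input", {
  expect_equal(summarized_nes(0, 0), 0)
  expect_equal(summarized_nes(2.5, -3.5), 6)
  expect_equal(summarized_nes(c(1, 2), c(-1, -2)), c(2, 4))
  expect_error(summarized_nes(Inf, 0), "finite")
  expect_error(summarized_nes(1, NA_real_), "finite")
})

test_that("score_signature recovers the noise-free sign structure", {
  sim <- simulate_de_table(sim_config(n_genes = 50, frac_de = 0.5, seed = 0,
                                      noise_sd = 0))
  ranked_universe <- sim$records$gene
  # z proportional to the query metric
  z <- stats::setNames(sim$records$log2fc, ranked_universe)
  sig <- perturbation_signature("self", z)
  params <- enrichment_params(n_perm = 200, seed = 0)
  res <- score_signature(rank_genes(sim$records), sig, n = 5, params)
  expect_gt(res$nes_up, 0)
  expect_lt(res$nes_down, 0)
  expect_gt(res$total_nes, 0)

  # negating every z flips the summarized score's sign (same seed)
  neg <- perturbation_signature("antiself", -z)
  res_neg <- score_signature(rank_genes(sim$records), neg, n = 5, params)
  expect_lt(res_neg$total_nes, 0)

  # disjoint signature is skipped with a log entry
  foreign <- perturbation_signature("foreign",
                                    stats::setNames(rnorm(20),
                                                    paste0("x", 1:20)))
  expect_message(out <- score_signature(rank_genes(sim$records), foreign,
                                        n = 5, params), "skipped")
  expect_null(out)
})

test_that("connectivity_screen ranks the planted mimic first, inverter last", {
  cfg <- sim_config(seed = 7)  # n_genes 2000, frac_de 0.2, weight 2, sd 0.5
  sim <- simulate_de_table(cfg)
  lib <- simulate_library(sim$truth, cfg)
  scr <- connectivity_screen(sim$records, lib, n = 100,
                             params = enrichment_params(n_perm = 500,
                                                        seed = 7))
  expect_equal(scr$compound[1], "mimic_01")
  expect_equal(scr$compound[22], "inverter_01")
  expect_equal(scr$rank, 1:22)
  # row-wise identity of the summarized score
  expect_equal(scr$total_nes, scr$nes_up - scr$nes_down)
})

test_that("a single-signature screen is its own BH family", {
  sim <- simulate_de_table(sim_config(n_genes = 200, frac_de = 0.3, seed = 2))
  z <- stats::setNames(sim$records$log2fc, sim$records$gene)
  lib <- list(perturbation_signature("solo", z))
  scr <- connectivity_screen(sim$records, lib, n = 20,
                             params = enrichment_params(n_perm = 100,
                                                        seed = 2))
  expect_equal(nrow(scr), 1L)
  expect_equal(scr$rank, 1L)
  expect_equal(scr$padj_up, scr$p_up)
  expect_equal(scr$padj_down, scr$p_down)
})

test_that("byte-identical signatures tie and adjacent ranks follow names", {
  sim <- simulate_de_table(sim_config(n_genes = 200, frac_de = 0.3, seed = 4))
  z <- stats::setNames(sim$records$log2fc, sim$records$gene)
  lib <- list(perturbation_signature("twin_b", z),
              perturbation_signature("twin_a", z))
  scr <- connectivity_screen(sim$records, lib, n = 20,
                             params = enrichment_params(n_perm = 100,
                                                        seed = 4))
  expect_equal(scr$total_nes[1], scr$total_nes[2])
  expect_equal(scr$compound, c("twin_a", "twin_b"))
})

test_that("screen output is invariant to library order", {
  cfg <- sim_config(n_genes = 400, frac_de = 0.25, seed = 9, n_decoys = 6)
  sim <- simulate_de_table(cfg)
  lib <- simulate_library(sim$truth, cfg)
  params <- enrichment_params(n_perm = 200, seed = 9)
  scr1 <- connectivity_screen(sim$records, lib, n = 50, params = params)
  scr2 <- connectivity_screen(sim$records, rev(lib), n = 50, params = params)
  expect_equal(as.data.frame(scr1), as.data.frame(scr2))
})

test_that("shared per-size nulls equal per-signature recomputation", {
  cfg <- sim_config(n_genes = 300, frac_de = 0.3, seed = 11, n_decoys = 4)
  sim <- simulate_de_table(cfg)
  lib <- simulate_library(sim$truth, cfg)
  params <- enrichment_params(n_perm = 150, seed = 11)
  scr <- connectivity_screen(sim$records, lib, n = 40, params = params)
  ranked <- rank_genes(sim$records)
  for (i in seq_along(lib)) {
    solo <- score_signature(ranked, lib[[i]], n = 40, params = params)
    j <- which(scr$compound == solo$compound)
    expect_equal(scr$nes_up[j], solo$nes_up)
    expect_equal(scr$p_down[j], solo$p_down)
    expect_equal(scr$total_nes[j], solo$total_nes)
  }
})

test_that("screen clamps oversized n and rejects empty inputs", {
  sim <- simulate_de_table(sim_config(n_genes = 60, frac_de = 0.3, seed = 3))
  z <- stats::setNames(sim$records$log2fc, sim$records$gene)
  lib <- list(perturbation_signature("s", z))
  expect_warning(scr <- connectivity_screen(sim$records, lib, n = 500,
                   params = enrichment_params(n_perm = 50, seed = 3)),
                 "clamped")
  expect_equal(attr(scr, "n"), 30)
  expect_error(connectivity_screen(sim$records, list()), "empty")

  foreign <- list(perturbation_signature("f",
                    stats::setNames(rnorm(10), paste0("x", 1:10))))
  expect_error(suppressMessages(
    connectivity_screen(sim$records, foreign, n = 5,
                        params = enrichment_params(n_perm = 50, seed = 3))),
    "skipped")
})

test_that("top_table summarizes compound redundancy of a ranked table", {
  top <- top_table(fixture_top10(), 10)
  expect_equal(attr(top, "n_compounds"), 6L)
  expect_equal(attr(top, "compound_counts")[["nutlin-3"]], 3L)
  expect_equal(nrow(top), 10L)

  one <- top_table(fixture_top10(), 1)
  expect_equal(one$compound, "AMG-232")
  expect_equal(one$total_nes, max(fixture_top10()$total_nes))

  expect_warning(all_rows <- top_table(fixture_top10(), 99), "exceeds")
  expect_equal(nrow(all_rows), 10L)
})

test_that("connectivity tables round-trip through write/read", {
  sim <- simulate_de_table(sim_config(n_genes = 200, frac_de = 0.3, seed = 6))
  z <- stats::setNames(sim$records$log2fc, sim$records$gene)
  lib <- list(perturbation_signature("a", z),
              perturbation_signature("b", -z))
  scr <- connectivity_screen(sim$records, lib, n = 20,
                             params = enrichment_params(n_perm = 100,
                                                        seed = 6))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_connectivity(scr, f)
  back <- read_connectivity(f)
  expect_equal(back$compound, scr$compound)
  expect_equal(back$total_nes, round(scr$total_nes, 6))
  expect_equal(back$p_up, signif(scr$p_up, 6))
})
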