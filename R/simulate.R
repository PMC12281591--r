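# Synthetic-data generators. These emulate the statistical structure the
# pipeline consumes — a signed DE signature and z-score perturbation
# signatures correlated (mimics), anti-correlated (inverters) or independent
# (decoys) of it — not the upstream count-level assay.

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic DE table and perturbation
#' library. Defaults are the package's standard validation conditions: a
#' 2000-gene transcriptome with 20% true DE genes, unit-SD effect sizes,
#' moderate observation noise, and a 22-signature library of one mimic, one
#' inverter and twenty decoys at correlation weight 2 and signature noise
#' SD 0.5.
#'
#' @param n_genes Number of genes (>= 10).
#' @param frac_de Fraction of genes with a true effect, in [0, 1].
#' @param effect_sd SD of true log2 fold changes for DE genes.
#' @param null_noise_sd SD of observed log2FC around the truth (> 0 whenever
#'   a DE table is simulated: the per-gene test statistic divides by it).
#' @param seed Integer random seed.
#' @param n_mimics,n_inverters,n_decoys Library composition.
#' @param mimic_weight Correlation-strength coefficient a >= 0: mimic
#'   z-scores are `a * standardize(query log2FC) + noise`.
#' @param noise_sd SD of signature noise.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, frac_de = 0.2, effect_sd = 1,
                       null_noise_sd = 0.25, seed = 0,
                       n_mimics = 1, n_inverters = 1, n_decoys = 20,
                       mimic_weight = 2, noise_sd = 0.5) {
  if (!is_count(n_genes) || n_genes < 10) stop_fmt("n_genes must be >= 10")
  if (!is.numeric(frac_de) || length(frac_de) != 1L ||
      frac_de < 0 || frac_de > 1) {
    stop_fmt("frac_de must be in [0, 1]")
  }
  for (nm in c("effect_sd", "null_noise_sd", "mimic_weight", "noise_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop_fmt(nm, " must be a single non-negative number")
    }
  }
  for (nm in c("n_mimics", "n_inverters", "n_decoys")) {
    if (!is_count(get(nm))) stop_fmt(nm, " must be a non-negative integer")
  }
  structure(list(n_genes = as.integer(n_genes), frac_de = frac_de,
                 effect_sd = effect_sd, null_noise_sd = null_noise_sd,
                 seed = as.integer(seed),
                 n_mimics = as.integer(n_mimics),
                 n_inverters = as.integer(n_inverters),
                 n_decoys = as.integer(n_decoys),
                 mimic_weight = mimic_weight, noise_sd = noise_sd),
            class = "sim_config")
}

#' Simulate a differential-expression table with known truth
#'
#' `round(n_genes * frac_de)` genes receive a true log2FC drawn
#' `|N(0, effect_sd^2)|` with signs assigned half positive, half negative;
#' the rest are null (truth 0). Observed log2FC adds `N(0, null_noise_sd^2)`
#' noise to the truth; the per-gene statistic is observed / null_noise_sd,
#' p-values are two-sided normal tails and padj is Benjamini-Hochberg over
#' all genes. Under `frac_de = 0` the p-values are exactly uniform.
#'
#' @param config A [sim_config].
#' @return A list with `records` (a [de_table] including `stat`) and
#'   `truth` (named numeric vector of true log2FC).
#' @export
simulate_de_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$null_noise_sd <= 0) {
    stop_fmt("null_noise_sd must be > 0 to simulate test statistics")
  }
  n <- config$n_genes
  withr::with_seed(derive_seed(config$seed, "de_table"), {
    genes <- sprintf("g%05d", seq_len(n))
    truth <- stats::setNames(numeric(n), genes)
    n_de <- round(n * config$frac_de)
    if (n_de > 0) {
      de_idx <- sample.int(n, n_de)
      signs <- rep(c(1, -1), length.out = n_de)
      truth[de_idx] <- signs * abs(stats::rnorm(n_de, 0, config$effect_sd))
    }
    observed <- truth + stats::rnorm(n, 0, config$null_noise_sd)
    stat <- observed / config$null_noise_sd
    pvalue <- pmax(2 * stats::pnorm(-abs(stat)), 1e-300)
    records <- de_table(genes, observed, pvalue, bh_adjust(pvalue),
                        stat = stat)
    list(records = records, truth = truth)
  })
}

#' Simulate a perturbation-signature library with planted structure
#'
#' Builds mimics (`z = a * standardize(query) + noise`), inverters (same
#' with the sign flipped) and decoys (`z ~ N(0, 1)` i.i.d.), where
#' `standardize(x) = (x - mean(x)) / sd(x)` over genes so `mimic_weight` is
#' a z-scale slope. Each signature's compound name carries its role
#' (`mimic_01`, `inverter_01`, `decoy_07`, ...).
#'
#' @param query_truth Named numeric vector of the query's (true) log2 fold
#'   changes; its gene universe becomes the library universe.
#' @param config A [sim_config] supplying the library block and seed.
#' @return A list of [perturbation_signature] objects, class
#'   `perturbation_library`.
#' @export
simulate_library <- function(query_truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(query_truth)) stop_fmt("query_truth must be non-empty")
  if (is.null(names(query_truth))) stop_fmt("query_truth must be named")
  s <- stats::sd(query_truth)
  if (!is.finite(s) || s == 0) {
    stop_fmt("query_truth is constant; cannot standardize")
  }
  z_std <- (query_truth - mean(query_truth)) / s
  n <- length(z_std)
  roles <- c(rep("mimic", config$n_mimics),
             rep("inverter", config$n_inverters),
             rep("decoy", config$n_decoys))
  idx <- c(seq_len(config$n_mimics), seq_len(config$n_inverters),
           seq_len(config$n_decoys))
  withr::with_seed(derive_seed(config$seed, "library"), {
    lib <- mapply(function(role, i) {
      z <- switch(role,
        mimic = config$mimic_weight * z_std +
          stats::rnorm(n, 0, config$noise_sd),
        inverter = -config$mimic_weight * z_std +
          stats::rnorm(n, 0, config$noise_sd),
        decoy = stats::rnorm(n))
      names(z) <- names(z_std)
      perturbation_signature(sprintf("%s_%02d", role, i), z,
                             dose = "10 uM", treat_time = "24 h",
                             cell = "SYN", batch = "b01")
    }, roles, idx, SIMPLIFY = FALSE, USE.NAMES = FALSE)
    structure(lib, class = "perturbation_library")
  })
}

#' @export
print.perturbation_library <- function(x, ...) {
  cat("Perturbation library:", length(x), "signatures,",
      length(x[[1L]]$zscores), "genes\n")
  invisible(x)
}

#' Simulate a gene-set collection, optionally with enriched sets
#'
#' Draws `n_sets` sets of sizes uniform in `size_range` from `universe`.
#' The first `n_enriched` sets are enriched: a fraction `frac_enriched` of
#' their members (rounded) is drawn from `target_genes`, the remainder
#' uniformly from the universe; all other sets are uniform draws.
#'
#' @param n_sets Number of sets.
#' @param size_range Integer pair (min, max) of set sizes.
#' @param universe Character vector of gene identifiers.
#' @param frac_enriched Fraction of an enriched set's members drawn from
#'   `target_genes`, in [0, 1]; default 0 (no enrichment).
#' @param target_genes Genes the enriched sets concentrate on.
#' @param seed Integer random seed.
#' @param n_enriched Number of enriched sets (default 1 when
#'   `frac_enriched > 0`, else 0).
#' @return A named list of character vectors; enriched sets are named
#'   `enriched_<i>`, the rest `set_<i>`.
#' @export
simulate_gene_sets <- function(n_sets, size_range, universe,
                               frac_enriched = 0, target_genes = character(),
                               seed = 0,
                               n_enriched = if (frac_enriched > 0) 1L else 0L) {
  if (!is_count(n_sets)) stop_fmt("n_sets must be a non-negative integer")
  if (length(size_range) != 2L || any(size_range < 1) ||
      size_range[1L] > size_range[2L] || size_range[2L] > length(universe)) {
    stop_fmt("size_range must be 1 <= min <= max <= |universe|")
  }
  if (frac_enriched < 0 || frac_enriched > 1) {
    stop_fmt("frac_enriched must be in [0, 1]")
  }
  if (n_enriched > 0 && frac_enriched > 0 && !length(target_genes)) {
    stop_fmt("target_genes required when frac_enriched > 0")
  }
  withr::with_seed(derive_seed(seed, "gene_sets"), {
    sets <- lapply(seq_len(n_sets), function(i) {
      size <- sample_range(size_range)
      if (i <= n_enriched && frac_enriched > 0) {
        n_target <- min(round(size * frac_enriched), length(target_genes))
        hits <- sample(target_genes, n_target)
        rest <- sample(setdiff(universe, hits), size - n_target)
        c(hits, rest)
      } else {
        sample(universe, size)
      }
    })
    names(sets) <- ifelse(seq_len(n_sets) <= n_enriched,
                          sprintf("enriched_%02d", seq_len(n_sets)),
                          sprintf("set_%02d", seq_len(n_sets)))
    sets
  })
}

#' Simulate a bipartite gene-metabolite network
#'
#' A stand-in for the gene neighborhoods of metabolites in a genome-scale
#' metabolic model: each metabolite is assigned `k` genes uniformly without
#' replacement, `k` uniform in `degree_range`.
#'
#' @param n_metabolites Number of metabolites.
#' @param degree_range Integer pair (min, max) of neighborhood sizes.
#' @param universe Character vector of gene identifiers.
#' @param seed Integer random seed.
#' @return A named list mapping metabolite id to a character vector of
#'   neighboring genes.
#' @export
simulate_metabolite_network <- function(n_metabolites, degree_range, universe,
                                        seed = 0) {
  if (!is_count(n_metabolites)) {
    stop_fmt("n_metabolites must be a non-negative integer")
  }
  if (length(degree_range) != 2L || any(degree_range < 1) ||
      degree_range[1L] > degree_range[2L] ||
      degree_range[2L] > length(universe)) {
    stop_fmt("degree_range must be 1 <= min <= max <= |universe|")
  }
  withr::with_seed(derive_seed(seed, "metabolite_network"), {
    net <- lapply(seq_len(n_metabolites), function(i) {
      sample(universe, sample_range(degree_range))
    })
    names(net) <- sprintf("m%04d", seq_len(n_metabolites))
    net
  })
}

#' Simulate a small count table
#'
#' A minimal Poisson count generator provided to exercise
#' [filter_genes]; the analysis pipeline itself consumes DE tables, not
#' counts.
#'
#' @param n_genes,n_samples Table dimensions.
#' @param mean_range Range the per-gene Poisson mean is drawn from.
#' @param seed Integer random seed.
#' @return A non-negative integer matrix with gene rownames.
#' @export
simulate_count_table <- function(n_genes, n_samples, mean_range = c(0, 50),
                                 seed = 0) {
  stopifnot(is_count(n_genes), is_count(n_samples))
  withr::with_seed(derive_seed(seed, "count_table"), {
    lambda <- stats::runif(n_genes, mean_range[1L], mean_range[2L])
    matrix(stats::rpois(n_genes * n_samples, rep(lambda, n_samples)),
           nrow = n_genes,
           dimnames = list(sprintf("g%05d", seq_len(n_genes)),
                           sprintf("s%02d", seq_len(n_samples))))
  })
}
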