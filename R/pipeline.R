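# Pipeline orchestration: a validated YAML configuration drives the stages
# simulate -> degs -> gsea/ora -> screen -> jaccard/progeny/reporter, each
# writing a deterministic TSV, plus a JSON run manifest. Identical
# configurations reproduce byte-identical outputs.

pipeline_defaults <- function() {
  list(
    out_dir = "sigscreen_out",
    seed = 0L,
    stages = c("simulate", "degs", "screen"),
    inputs = list(de_table = NULL, de_tables = NULL, library = NULL,
                  gene_sets = NULL, pathway_models = NULL,
                  metabolite_network = NULL),
    params = list(alpha = 0.05, n_extreme = 500L, exponent = 1, n_perm = 1000L,
                  min_size = 3L, max_size = 5000L, degs_only = FALSE),
    simulate = list(n_genes = 2000L, frac_de = 0.2, effect_sd = 1,
                    null_noise_sd = 0.25, n_mimics = 1L, n_inverters = 1L,
                    n_decoys = 20L, mimic_weight = 2, noise_sd = 0.5)
  )
}

known_stages <- c("simulate", "degs", "gsea", "ora", "screen", "jaccard",
                  "progeny", "reporter")

#' Read a pipeline configuration file
#'
#' @param path Path to a YAML configuration document.
#' @return The raw configuration list (validate with [validate_config]).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_fmt("config file not found: ", path)
  yaml::read_yaml(path)
}

merge_block <- function(defaults, given, block) {
  if (is.null(given)) return(defaults)
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown)) {
    stop_fmt("unknown key(s) in '", block, "': ",
             paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, given)
}

#' Validate a pipeline configuration
#'
#' Checks every key against the known schema (unknown keys are an error
#' listing them), fills defaults, validates parameter ranges and stage
#' names, and verifies that every referenced input file exists. The
#' resolved configuration is echoed to the log.
#'
#' @param config A configuration list, e.g. from [read_pipeline_config].
#' @return The validated configuration, class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) stop_fmt("config must be a list")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop_fmt("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config[setdiff(names(config),
                                                    c("inputs", "params",
                                                      "simulate"))])
  cfg$inputs <- merge_block(defaults$inputs, config$inputs, "inputs")
  cfg$params <- merge_block(defaults$params, config$params, "params")
  cfg$simulate <- merge_block(defaults$simulate, config$simulate, "simulate")

  bad_stage <- setdiff(cfg$stages, known_stages)
  if (length(bad_stage)) {
    stop_fmt("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  }
  p <- cfg$params
  if (p$alpha <= 0 || p$alpha >= 1) stop_fmt("params$alpha must be in (0, 1)")
  enrichment_params(p$exponent, p$n_perm, p$min_size, p$max_size, cfg$seed)
  if (!is_count(p$n_extreme) || p$n_extreme < 1) stop_fmt("params$n_extreme must be a positive integer")
  do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
  for (key in c("de_table", "library", "gene_sets", "pathway_models",
                "metabolite_network")) {
    path <- cfg$inputs[[key]]
    if (!is.null(path) && !file.exists(path)) {
      stop_fmt("inputs$", key, ": file not found: ", path)
    }
  }
  if (!is.null(cfg$inputs$de_tables)) {
    miss <- !vapply(cfg$inputs$de_tables, file.exists, TRUE)
    if (any(miss)) {
      stop_fmt("inputs$de_tables: file(s) not found: ",
               paste(unlist(cfg$inputs$de_tables)[miss], collapse = ", "))
    }
  }
  msg("config validated; stages: ", paste(cfg$stages, collapse = ", "),
      "; seed ", cfg$seed, "; alpha ", p$alpha, "; n ", p$n_extreme,
      "; n_perm ", p$n_perm, "; exponent ", p$exponent)
  structure(cfg, class = "pipeline_config")
}

# Read a DE table whatever of the two supported column dialects it uses.
read_de_auto <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
  map <- c(gene = "gene",
           log2fc = if ("log2fc" %in% header) "log2fc" else "log2FoldChange",
           pvalue = "pvalue", padj = "padj", stat = "stat")
  read_de_table(path, map)
}

gct_as_library <- function(gct) {
  structure(lapply(colnames(gct$z), function(id) {
    perturbation_signature(id, gct$z[, id])
  }), class = "perturbation_library")
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in their canonical order
#' (simulate, degs, gsea, ora, screen, jaccard, progeny, reporter),
#' writing one TSV per stage into `out_dir` plus a `manifest.json`
#' recording the package version, the resolved configuration, the seed and
#' per-stage row counts. Stage dependencies are checked before anything
#' runs: a stage that needs a DE table accepts either `inputs$de_table` or
#' the `simulate` stage; `screen` likewise accepts a simulated library.
#'
#' @param config A `pipeline_config` (or a raw list, validated on entry).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  stages <- intersect(known_stages, config$stages)
  has_sim <- "simulate" %in% stages
  have_de <- has_sim || !is.null(config$inputs$de_table)
  have_lib <- has_sim || !is.null(config$inputs$library)
  need_de <- intersect(stages, c("degs", "gsea", "ora", "screen", "jaccard",
                                 "progeny", "reporter"))
  if (length(need_de) && !have_de) {
    stop_fmt("stage(s) ", paste(need_de, collapse = ", "),
             " need a DE table: provide inputs$de_table or enable the ",
             "simulate stage")
  }
  if ("screen" %in% stages && !have_lib) {
    stop_fmt("stage 'screen' needs a signature library: provide ",
             "inputs$library or enable the simulate stage")
  }
  for (st in intersect(stages, c("gsea", "ora"))) {
    if (is.null(config$inputs$gene_sets)) {
      stop_fmt("stage '", st, "' needs inputs$gene_sets (GMT)")
    }
  }
  if ("progeny" %in% stages && is.null(config$inputs$pathway_models)) {
    stop_fmt("stage 'progeny' needs inputs$pathway_models (TSV)")
  }
  if ("reporter" %in% stages && is.null(config$inputs$metabolite_network)) {
    stop_fmt("stage 'reporter' needs inputs$metabolite_network (TSV)")
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  eparams <- enrichment_params(config$params$exponent, config$params$n_perm,
                               config$params$min_size, config$params$max_size,
                               config$seed)
  counts <- list()
  de <- NULL
  lib <- NULL

  if (has_sim) {
    scfg <- do.call(sim_config, c(config$simulate, list(seed = config$seed)))
    sim <- simulate_de_table(scfg)
    de <- sim$records
    write_de_table(de, out("de_table.tsv"))
    truth_df <- data.frame(gene = names(sim$truth),
                           true_log2fc = fmt_score(sim$truth))
    utils::write.table(truth_df, out("truth.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    lib <- simulate_library(sim$truth, scfg)
    z <- vapply(lib, function(s) s$zscores, numeric(scfg$n_genes))
    colnames(z) <- vapply(lib, function(s) s$compound, "")
    write_gct(z, out("library.gct"))
    counts$simulate <- nrow(de)
    msg("stage simulate: ", nrow(de), " genes, ", length(lib), " signatures")
  }
  if (is.null(de) && !is.null(config$inputs$de_table)) {
    de <- read_de_auto(config$inputs$de_table)
  }
  if (is.null(lib) && !is.null(config$inputs$library)) {
    lib <- gct_as_library(read_gct(config$inputs$library))
  }

  degs <- NULL
  if (any(c("degs", "ora", "jaccard") %in% stages)) {
    degs <- select_degs(de, config$params$alpha)
  }
  if ("degs" %in% stages) {
    deg_df <- data.frame(
      gene = c(degs$up, degs$down),
      direction = rep(c("up", "down"), c(length(degs$up), length(degs$down))))
    utils::write.table(deg_df, out("degs.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    counts$degs <- nrow(deg_df)
    msg("stage degs: ", length(degs$up), " up, ", length(degs$down), " down")
  }
  if ("gsea" %in% stages) {
    sets <- read_gmt(config$inputs$gene_sets)
    res <- gsea_preranked(rank_genes(de, "log2fc"), sets, eparams)
    gd <- as.data.frame(res)
    for (col in c("es", "nes")) gd[[col]] <- fmt_score(gd[[col]])
    for (col in c("pvalue", "padj")) gd[[col]] <- fmt_p(gd[[col]])
    utils::write.table(gd, out("gsea.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    counts$gsea <- nrow(res)
  }
  if ("ora" %in% stages) {
    sets <- read_gmt(config$inputs$gene_sets)
    res <- ora_fisher(c(degs$up, degs$down), de$gene, sets)
    od <- as.data.frame(res)
    od$gene_ratio <- fmt_score(od$gene_ratio)
    for (col in c("pvalue", "padj")) od[[col]] <- fmt_p(od[[col]])
    utils::write.table(od, out("ora.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    counts$ora <- nrow(res)
  }
  if ("screen" %in% stages) {
    res <- connectivity_screen(de, lib, n = config$params$n_extreme, params = eparams,
                               degs_only = isTRUE(config$params$degs_only),
                               alpha = config$params$alpha)
    write_connectivity(res, out("screen.tsv"))
    counts$screen <- nrow(res)
    msg("stage screen: top signature ", res$compound[1L],
        " (total NES ", fmt_score(res$total_nes[1L]), ")")
  }
  if ("jaccard" %in% stages) {
    sets <- list(query_up = degs$up, query_down = degs$down)
    if (!is.null(config$inputs$de_tables)) {
      for (nm in names(config$inputs$de_tables)) {
        d <- select_degs(read_de_auto(config$inputs$de_tables[[nm]]),
                         config$params$alpha)
        sets[[paste0(nm, "_up")]] <- d$up
        sets[[paste0(nm, "_down")]] <- d$down
      }
    }
    sets <- sets[lengths(sets) > 0L]
    if (length(sets) < 2L) stop_fmt("stage 'jaccard' needs >= 2 non-empty ",
                                    "DEG sets")
    m <- jaccard_matrix(sets)
    md <- data.frame(set = rownames(m),
                     apply(m, 2, fmt_score), check.names = FALSE)
    utils::write.table(md, out("jaccard.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    counts$jaccard <- nrow(m)
  }
  if ("progeny" %in% stages) {
    wt <- utils::read.delim(config$inputs$pathway_models,
                            stringsAsFactors = FALSE)
    models <- top_k_weights(wt, k = 100)
    if (is.null(de$stat)) stop_fmt("stage 'progeny' needs a 'stat' column")
    res <- progeny_scores(stats::setNames(de$stat, de$gene), models,
                          n_perm = config$params$n_perm, seed = config$seed)
    pd <- as.data.frame(res)
    for (col in c("raw_score", "zscore")) pd[[col]] <- fmt_score(pd[[col]])
    pd$pvalue <- fmt_p(pd$pvalue)
    utils::write.table(pd, out("progeny.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    counts$progeny <- nrow(res)
  }
  if ("reporter" %in% stages) {
    edges <- utils::read.delim(config$inputs$metabolite_network,
                               stringsAsFactors = FALSE)
    if (ncol(edges) < 2L) stop_fmt("metabolite network must be a ",
                                   "two-column TSV (metabolite, gene)")
    net <- split(edges[[2L]], edges[[1L]])
    res <- reporter_metabolites(stats::setNames(de$pvalue, de$gene), net,
                                seed = config$seed)
    rd <- as.data.frame(res)
    for (col in c("z_agg", "z_corrected")) rd[[col]] <- fmt_score(rd[[col]])
    rd$pvalue <- fmt_p(rd$pvalue)
    utils::write.table(rd, out("reporter.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    counts$reporter <- nrow(res)
  }

  manifest <- list(
    package = "sigscreen",
    version = as.character(utils::packageVersion("sigscreen")),
    seed = config$seed,
    stages = stages,
    params = config$params,
    simulate = if (has_sim) config$simulate,
    row_counts = counts)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  msg("pipeline complete: ", length(stages), " stage(s) in ", config$out_dir)
  invisible(manifest)
}
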