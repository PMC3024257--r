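#' @name pipeline
#' @title End-to-end pipeline orchestration and command line
#' @description
#' `run_pipeline()` chains the stages on a synthetic study (or on files
#' supplied through the config): simulate/ingest, preprocess (filter,
#' merge, batch-correct), ISA module discovery in compendium-only (M1)
#' and compendium-plus-cases (M2) modes, dysregulation testing with
#' permutation validation, module hierarchy, enrichment, frequent-gene
#' counting and network analysis. Every stage's parameters and seed come
#' from the config; outputs and a manifest are written under a run
#' directory, and identical configs reproduce identical outputs.
NULL

#' Default pipeline configuration
#'
#' @param out_dir run directory.
#' @param rng_seed master seed; stage seeds are derived from it.
#' @return Nested config list; override entries before passing to
#'   [run_pipeline()].
#' @export
default_pipeline_config <- function(out_dir = tempfile("coexmod_run_"),
                                    rng_seed = 1L) {
  list(
    out_dir = out_dir,
    rng_seed = as.integer(rng_seed),
    simulate = list(enabled = TRUE, config = simulation_config(rng_seed = rng_seed)),
    input = list(compendium_paths = NULL, wbs_path = NULL,
                 annotation_gmt = NULL, network_tsv = NULL),
    preprocess = list(min_present_compendium = 10L, min_present_wbs = 6L),
    isa = list(gene_thresholds = seq(2, 4, by = 0.5),
               sample_thresholds = seq(1, 2, by = 0.5),
               n_seeds = 40L, seed_size = 10L, corr_limit = 0.9),
    dysreg = list(min_genes = 10L, fdr_level = 0.05, n_perm = 100L),
    network = list(min_evidence = 0.3, min_frequency = 2L,
                   n_subnetwork_draws = 1000L, n_random_hrg = 20L,
                   hrg_steps = 2000L, max_hrg_vertices = 120L)
  )
}

stage_log <- function(log, ...) {
  msg <- sprintf(...)
  message(msg)
  c(log, msg)
}

#' Run the full modular-analysis pipeline
#'
#' @param config list as from [default_pipeline_config()].
#' @return Invisibly, the run directory. A `manifest.json` records the
#'   stages, parameters, seed and output files; `log.txt` the filter
#'   counts of every stage.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  for (p in c(cfg$input$compendium_paths, cfg$input$wbs_path,
              cfg$input$annotation_gmt, cfg$input$network_tsv)) {
    if (!is.null(p) && !file.exists(p)) {
      stop_coexmod("config references missing path: ", p)
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  manifest <- list(package = "coexmod", rng_seed = cfg$rng_seed,
                   stages = list())
  log <- character(0)

  # --- data -----------------------------------------------------------
  if (isTRUE(cfg$simulate$enabled)) {
    study <- generate_study(cfg$simulate$config)
    compendium <- study$compendium
    wbs <- study$wbs_matrix
    truth <- study$truth
    jsonlite::write_json(truth, out("truth.json"), auto_unbox = TRUE,
                         digits = NA)
    ann <- generate_annotation(truth, universe = rownames(wbs$values),
                               rng_seed = cfg$rng_seed)
    net <- generate_network(truth, n_background_genes = 100L,
                            rng_seed = cfg$rng_seed)
    log <- stage_log(log, "simulate: %d datasets, %d genes, wbs %d samples",
                     length(compendium), nrow(wbs$values), ncol(wbs$values))
  } else {
    compendium <- lapply(cfg$input$compendium_paths, read_expression_tsv)
    wbs <- read_expression_tsv(cfg$input$wbs_path)
    ann <- if (!is.null(cfg$input$annotation_gmt))
      read_gmt(cfg$input$annotation_gmt) else NULL
    net <- if (!is.null(cfg$input$network_tsv))
      read_network_tsv(cfg$input$network_tsv) else NULL
    truth <- NULL
    log <- stage_log(log, "ingest: %d datasets, wbs %d samples",
                     length(compendium), ncol(wbs$values))
  }
  manifest$stages$data <- list(simulated = isTRUE(cfg$simulate$enabled))

  # --- preprocess -------------------------------------------------------
  filtered <- lapply(compendium, filter_features,
                     min_present = cfg$preprocess$min_present_compendium)
  merged <- merge_datasets(filtered)
  log <- stage_log(log, "preprocess: %d common features after merge",
                   nrow(merged$values))
  corrected <- combat_correct(merged, batch = merged$sample_meta$dataset_id,
                              covariates = merged$sample_meta$disease_status)
  wbs_f <- filter_features(wbs, min_present = cfg$preprocess$min_present_wbs)
  log <- stage_log(log, "preprocess: wbs %d features retained",
                   nrow(wbs_f$values))
  manifest$stages$preprocess <- cfg$preprocess

  # --- differential expression -----------------------------------------
  dge <- fold_change_filter(moderated_t_test(wbs_f))
  write_gene_stats(dge, out("gene_stats.tsv"))
  log <- stage_log(log, "dge: %d DEGs of %d genes", sum(dge$is_DEG), nrow(dge))

  # --- ISA (M1: compendium only; M2: compendium + case/control) --------
  isa_cfg <- cfg$isa
  m1 <- run_isa(corrected, isa_cfg$gene_thresholds, isa_cfg$sample_thresholds,
                n_seeds = isa_cfg$n_seeds, seed_size = isa_cfg$seed_size,
                corr_limit = isa_cfg$corr_limit,
                rng_seed = cfg$rng_seed, run_label = "M1")
  common <- intersect(rownames(corrected$values), rownames(wbs_f$values))
  if (length(common) >= 2) {
    m2_input <- merge_datasets(list(em_subset(corrected, features = common),
                                    em_subset(wbs_f, features = common)))
    # The case/control set enters as one extra batch. Disease status is
    # fully confounded with that batch in the synthetic study (only the
    # case/control set carries cases), so no covariate is protected here.
    m2_input <- combat_correct(
      m2_input,
      batch = ifelse(m2_input$sample_meta$dataset_id == "wbs", "wbs", "comp"),
      covariates = NULL)
    m2 <- run_isa(m2_input, isa_cfg$gene_thresholds,
                  isa_cfg$sample_thresholds, n_seeds = isa_cfg$n_seeds,
                  seed_size = isa_cfg$seed_size,
                  corr_limit = isa_cfg$corr_limit,
                  rng_seed = cfg$rng_seed + 1L, run_label = "M2")
  } else {
    m2 <- module_set(list(), run_label = "M2")
  }
  write_modules(m1, out("modules_m1.json"))
  write_modules(m2, out("modules_m2.json"))
  log <- stage_log(log, "isa: %d M1 modules, %d M2 modules",
                   length(m1$modules), length(m2$modules))
  manifest$stages$isa <- isa_cfg[c("n_seeds", "seed_size", "corr_limit")]

  # --- dysregulation + permutation -------------------------------------
  dys_results <- list()
  for (label in c("M1", "M2")) {
    ms <- if (label == "M1") m1 else m2
    if (length(ms$modules) == 0) next
    res <- tryCatch(
      dysregulation_test(ms, wbs_f, cfg$dysreg$min_genes,
                         cfg$dysreg$fdr_level),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(res) || nrow(res) == 0) next
    utils::write.table(res, out(sprintf("dysregulation_%s.tsv", label)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dys_results[[label]] <- res
    log <- stage_log(log, "dysreg %s: %d of %d tested modules significant",
                     label, sum(res$significant), nrow(res))
  }
  if (!is.null(dys_results$M2)) {
    perm <- permutation_validation(m2, wbs_f, cfg$dysreg$min_genes,
                                   cfg$dysreg$fdr_level,
                                   n_perm = cfg$dysreg$n_perm,
                                   rng_seed = cfg$rng_seed + 2L)
    jsonlite::write_json(
      perm[c("n_perm", "n_perm_with_any_significant", "mean_count",
             "median_count", "counts_per_permutation")],
      out("permutation_summary.json"), auto_unbox = TRUE, digits = NA)
    log <- stage_log(log, "permute: %d/%d permutations with any significant",
                     perm$n_perm_with_any_significant, perm$n_perm)
  }
  manifest$stages$dysreg <- cfg$dysreg

  # --- hierarchy, enrichment, frequency, network ------------------------
  dys_modules <- function(label, ms) {
    res <- dys_results[[label]]
    if (is.null(res)) return(list())
    ids <- res$module_id[res$significant]
    Filter(function(m) m$id %in% ids, ms$modules)
  }
  d1 <- dys_modules("M1", m1)
  d2 <- dys_modules("M2", m2)
  if (length(c(d1, d2)) >= 1) {
    dag <- build_hierarchy(c(d1, d2))
    write_hierarchy(dag, out("hierarchy_edges.tsv"), out("hierarchy.dot"))
    comp <- components(dag)
    log <- stage_log(log, "hierarchy: %d nodes, %d non-trivial components",
                     nrow(dag$nodes), nrow(comp))
  }
  if (!is.null(ann) && length(c(d1, d2)) >= 1) {
    enr <- enrich_modules(c(d1, d2), ann, universe = rownames(wbs_f$values))
    utils::write.table(enr, out("module_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log <- stage_log(log, "enrich: %d (module, category) tests, %d significant",
                     nrow(enr), sum(enr$adjusted_p <= 0.05))
  }
  freq <- gene_frequency(d1, d2)
  utils::write.table(freq, out("gene_frequency.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(net) && nrow(freq) > 0) {
    frequent <- freq$gene[freq$count_m1 + freq$count_m2 >=
                            cfg$network$min_frequency]
    sub <- extract_subnetwork(net, frequent,
                              min_evidence = 0)
    if (length(sub$vertices) >= 4 && nrow(sub$edges) >= 2) {
      obs <- total_evidence(sub)
      nullres <- random_subnetwork_null(net, length(sub$vertices),
                                        cfg$network$n_subnetwork_draws, obs,
                                        rng_seed = cfg$rng_seed + 3L)
      lc <- largest_component(sub)
      hier <- if (length(lc$vertices) >= 4 &&
                  length(lc$vertices) <= cfg$network$max_hrg_vertices) {
        hierarchy_significance(lc, cfg$network$n_random_hrg,
                               cfg$network$hrg_steps,
                               rng_seed = cfg$rng_seed + 4L)
      } else NULL
      jsonlite::write_json(
        list(n_frequent_genes = length(frequent),
             subnetwork_vertices = length(sub$vertices),
             subnetwork_edges = nrow(sub$edges),
             total_evidence = obs,
             evidence_empirical_p = nullres$empirical_p,
             hrg_observed_loglik = hier$observed_loglik,
             hrg_empirical_p = hier$empirical_p),
        out("network_analysis.json"), auto_unbox = TRUE, digits = NA)
      log <- stage_log(log,
                       "network: %d frequent genes, evidence p = %.4g",
                       length(frequent), nullres$empirical_p)
    }
  }

  writeLines(log, out("log.txt"))
  manifest$outputs <- list.files(cfg$out_dir)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(cfg$out_dir)
}

#' Command-line entry point
#'
#' Dispatches `coexmod <verb>` with `--config <json>`, `--seed <int>`
#' and `--out <dir>` flags. Verbs: `simulate` (write a synthetic study
#' to disk), `run-all` (full pipeline). An executable wrapper is
#' installed under `inst/cli/coexmod`.
#'
#' @param argv character vector of command-line arguments.
#' @return Exit status, invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: coexmod <simulate|run-all> [--config file.json] [--seed N] [--out DIR]"
  if (length(argv) < 1) { message(usage); return(invisible(1L)) }
  verb <- argv[1]
  opt <- function(flag, default = NULL) {
    i <- which(argv == flag)
    if (length(i) == 1 && i < length(argv)) argv[i + 1] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out_dir <- opt("--out", file.path(getwd(), "coexmod_run"))
  cfg <- default_pipeline_config(out_dir = out_dir, rng_seed = seed)
  cfg_path <- opt("--config")
  if (!is.null(cfg_path)) {
    user <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    cfg <- utils::modifyList(cfg, user)
    if (!is.null(user$simulate$config)) {
      cfg$simulate$config <- do.call(simulation_config, user$simulate$config)
    }
  }
  if (verb == "simulate") {
    study <- generate_study(cfg$simulate$config)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(study$compendium)) {
      write_expression_tsv(study$compendium[[i]],
                           file.path(out_dir, sprintf("dataset%d.tsv", i)))
    }
    write_expression_tsv(study$wbs_matrix, file.path(out_dir, "wbs.tsv"))
    jsonlite::write_json(study$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    message("wrote synthetic study to ", out_dir)
    return(invisible(0L))
  }
  if (verb == "run-all") {
    run_pipeline(cfg)
    return(invisible(0L))
  }
  message(usage)
  invisible(1L)
}
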