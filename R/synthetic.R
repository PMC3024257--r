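#' Configuration for the synthetic compendium generator
#'
#' Describes a multi-dataset fibroblast-style expression compendium with
#' planted co-expression modules, dataset batch effects, a separate
#' case/control matrix in which a subset of modules is dysregulated, and a
#' small "hemizygous" gene set with reduced dosage in cases. The defaults
#' are a scaled-down desk model: 2,000 genes, 4 datasets of 12 samples
#' each, 10 planted modules of 20-60 genes, and a case/control matrix of
#' 8 cases vs 9 controls.
#'
#' @param n_genes number of genes.
#' @param n_datasets number of compendium datasets (batches).
#' @param samples_per_dataset integer vector of per-dataset sample counts.
#' @param n_planted_modules number of planted co-expression modules.
#' @param module_gene_sizes integer vector (length `n_planted_modules`).
#' @param module_sample_fraction fraction of samples in which each module
#'   is active.
#' @param module_amplitude log2 shift of member genes in member samples.
#' @param module_sign_prob probability that a member gene gets a negative
#'   sign (anti-correlated module half).
#' @param batch_shift_sd sd of the gene-wise additive batch shift (log2).
#' @param batch_scale_sd sd of `log` multiplicative batch factors.
#' @param noise_sd sd of the i.i.d. Gaussian background noise (log2).
#' @param n_cases,n_controls sample counts of the case/control matrix.
#' @param case_effect_modules indices of modules dysregulated in cases.
#' @param case_effect_size log2 shift (along each member gene's sign)
#'   applied to case samples.
#' @param hemizygous_set_size size of the reduced-dosage gene set.
#' @param hemizygous_effect log2 shift of hemizygous genes in cases
#'   (negative; arrays compress the theoretical one-copy -1.0).
#' @param detection_dropout_rate probability a cell is flagged Absent.
#' @param rng_seed integer seed; all generator randomness flows from it.
#' @return A `simulation_config` list, validated.
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_datasets = 4L,
                              samples_per_dataset = rep(12L, 4L),
                              n_planted_modules = 10L,
                              module_gene_sizes = round(seq(20, 60, length.out = 10)),
                              module_sample_fraction = 0.25,
                              module_amplitude = 4,
                              module_sign_prob = 0.5,
                              batch_shift_sd = 0.3,
                              batch_scale_sd = 0.1,
                              noise_sd = 0.5,
                              n_cases = 8L,
                              n_controls = 9L,
                              case_effect_modules = 1:3,
                              case_effect_size = 1,
                              hemizygous_set_size = 13L,
                              hemizygous_effect = -0.5,
                              detection_dropout_rate = 0.1,
                              rng_seed = 1L) {
  assert_count(n_genes, "n_genes")
  assert_count(n_datasets, "n_datasets")
  if (length(samples_per_dataset) != n_datasets) {
    stop_coexmod("`samples_per_dataset` must have length `n_datasets`")
  }
  for (s in samples_per_dataset) assert_count(s, "samples_per_dataset")
  assert_count(n_planted_modules, "n_planted_modules", min = 0L)
  if (length(module_gene_sizes) > n_planted_modules) {
    stop_coexmod("`module_gene_sizes` longer than `n_planted_modules`")
  }
  if (n_planted_modules > 0 &&
      length(module_gene_sizes) != n_planted_modules) {
    stop_coexmod("`module_gene_sizes` must have length `n_planted_modules`")
  }
  if (any(module_gene_sizes > n_genes)) {
    stop_coexmod("module sizes cannot exceed `n_genes`")
  }
  if (sum(module_gene_sizes) + hemizygous_set_size > n_genes) {
    stop_coexmod("planted modules are gene-disjoint: sum(module_gene_sizes) ",
                 "+ hemizygous_set_size must be <= n_genes")
  }
  if (module_sample_fraction <= 0 || module_sample_fraction > 1) {
    stop_coexmod("`module_sample_fraction` must be in (0, 1]")
  }
  if (detection_dropout_rate < 0 || detection_dropout_rate > 1) {
    stop_coexmod("`detection_dropout_rate` must be in [0, 1]")
  }
  assert_count(n_cases, "n_cases")
  assert_count(n_controls, "n_controls")
  assert_count(hemizygous_set_size, "hemizygous_set_size", min = 0L)
  if (n_planted_modules == 0L) {
    case_effect_modules <- integer(0)
  } else if (!all(case_effect_modules %in% seq_len(n_planted_modules))) {
    stop_coexmod("`case_effect_modules` must index planted modules")
  }
  structure(
    list(
      n_genes = as.integer(n_genes), n_datasets = as.integer(n_datasets),
      samples_per_dataset = as.integer(samples_per_dataset),
      n_planted_modules = as.integer(n_planted_modules),
      module_gene_sizes = as.integer(module_gene_sizes),
      module_sample_fraction = module_sample_fraction,
      module_amplitude = module_amplitude,
      module_sign_prob = module_sign_prob,
      batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
      noise_sd = noise_sd,
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      case_effect_modules = as.integer(case_effect_modules),
      case_effect_size = case_effect_size,
      hemizygous_set_size = as.integer(hemizygous_set_size),
      hemizygous_effect = hemizygous_effect,
      detection_dropout_rate = detection_dropout_rate,
      rng_seed = as.integer(rng_seed)
    ),
    class = "simulation_config"
  )
}

#' Generate a synthetic compendium, case/control matrix and ground truth
#'
#' Background entries are i.i.d. Gaussian noise (mean 0, sd `noise_sd`) on
#' the log2 scale. Each planted module shifts its member genes by
#' `+/- module_amplitude` (sign drawn per gene) in its member compendium
#' samples. Dataset batch effects are gene-wise additive shifts
#' `N(0, batch_shift_sd)` plus multiplicative factors
#' `exp(N(0, batch_scale_sd))`, matching the location/scale model that
#' batch correction assumes. In the case/control matrix, genes of
#' `case_effect_modules` are shifted by `case_effect_size` along their
#' module sign in case samples, and hemizygous genes by
#' `hemizygous_effect` in cases. Detection flags are set Absent
#' independently at `detection_dropout_rate`.
#'
#' @param config a [simulation_config()].
#' @return A list with `compendium` (list of [expression_matrix()] per
#'   dataset), `wbs_matrix` (the case/control [expression_matrix()]), and
#'   `truth` (ground truth: module gene/sample index sets with signs,
#'   dysregulated module indices, hemizygous genes, batch assignments).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  with_rng(cfg$rng_seed, {
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    n_comp <- sum(cfg$samples_per_dataset)
    comp_samples <- sprintf("c%03d", seq_len(n_comp))
    batch <- rep(sprintf("dataset%d", seq_len(cfg$n_datasets)),
                 cfg$samples_per_dataset)

    modules <- vector("list", cfg$n_planted_modules)
    used <- integer(0)
    for (k in seq_len(cfg$n_planted_modules)) {
      size <- cfg$module_gene_sizes[k]
      pool <- setdiff(seq_len(cfg$n_genes), used)
      gidx <- sort(sample(pool, size))
      used <- c(used, gidx)   # planted modules gene-disjoint
      signs <- ifelse(stats::runif(size) < cfg$module_sign_prob, -1, 1)
      n_act <- max(2L, round(cfg$module_sample_fraction * n_comp))
      sidx <- sort(sample(n_comp, n_act))
      modules[[k]] <- list(genes = gidx, signs = signs, samples = sidx)
    }
    hemi <- if (cfg$hemizygous_set_size > 0) {
      pool <- setdiff(seq_len(cfg$n_genes), used)
      sort(sample(pool, min(cfg$hemizygous_set_size, length(pool))))
    } else integer(0)

    comp_vals <- matrix(stats::rnorm(cfg$n_genes * n_comp, 0, cfg$noise_sd),
                        cfg$n_genes, n_comp,
                        dimnames = list(genes, comp_samples))
    for (mod in modules) {
      comp_vals[mod$genes, mod$samples] <-
        comp_vals[mod$genes, mod$samples] + mod$signs * cfg$module_amplitude
    }
    # Batch effects: per-gene additive shift and multiplicative factor.
    for (b in unique(batch)) {
      cols <- which(batch == b)
      shift <- stats::rnorm(cfg$n_genes, 0, cfg$batch_shift_sd)
      scale <- exp(stats::rnorm(cfg$n_genes, 0, cfg$batch_scale_sd))
      comp_vals[, cols] <- comp_vals[, cols] * scale + shift
    }

    n_wbs <- cfg$n_cases + cfg$n_controls
    wbs_samples <- sprintf("w%03d", seq_len(n_wbs))
    wbs_group <- c(rep("case", cfg$n_cases), rep("control", cfg$n_controls))
    wbs_vals <- matrix(stats::rnorm(cfg$n_genes * n_wbs, 0, cfg$noise_sd),
                       cfg$n_genes, n_wbs,
                       dimnames = list(genes, wbs_samples))
    cases <- which(wbs_group == "case")
    for (k in cfg$case_effect_modules) {
      mod <- modules[[k]]
      wbs_vals[mod$genes, cases] <-
        wbs_vals[mod$genes, cases] + mod$signs * cfg$case_effect_size
    }
    if (length(hemi)) {
      wbs_vals[hemi, cases] <- wbs_vals[hemi, cases] + cfg$hemizygous_effect
    }

    comp_det <- matrix(stats::runif(length(comp_vals)) >=
                         cfg$detection_dropout_rate,
                       nrow(comp_vals), ncol(comp_vals),
                       dimnames = dimnames(comp_vals))
    wbs_det <- matrix(stats::runif(length(wbs_vals)) >=
                        cfg$detection_dropout_rate,
                      nrow(wbs_vals), ncol(wbs_vals),
                      dimnames = dimnames(wbs_vals))

    compendium <- lapply(unique(batch), function(b) {
      cols <- which(batch == b)
      meta <- data.frame(
        sample_id = comp_samples[cols], dataset_id = b,
        disease_status = "none", group = "other",
        stringsAsFactors = FALSE
      )
      expression_matrix(comp_vals[, cols, drop = FALSE],
                        comp_det[, cols, drop = FALSE], meta)
    })
    names(compendium) <- unique(batch)
    wbs_meta <- data.frame(
      sample_id = wbs_samples, dataset_id = "wbs",
      disease_status = ifelse(wbs_group == "case", "wbs", "none"),
      group = wbs_group, stringsAsFactors = FALSE
    )
    wbs_matrix <- expression_matrix(wbs_vals, wbs_det, wbs_meta)

    truth <- list(
      planted_module_members = lapply(modules, function(mod) {
        list(genes = genes[mod$genes], signs = mod$signs,
             samples = comp_samples[mod$samples])
      }),
      dysregulated_module_indices = cfg$case_effect_modules,
      hemizygous_genes = genes[hemi],
      batch_assignments = stats::setNames(batch, comp_samples)
    )
    list(compendium = compendium, wbs_matrix = wbs_matrix, truth = truth)
  })
}

#' Generate a synthetic gene-interaction network
#'
#' An undirected evidence-weighted graph over the truth's genes plus
#' `n_background_genes` extras: within each planted module's gene set
#' edges are drawn with `edge_prob_within`, all other pairs with
#' `edge_prob_between`; evidence scores are uniform in (0, 1].
#'
#' @param truth the `truth` element of [generate_study()].
#' @param n_background_genes extra genes outside any planted module.
#' @param edge_prob_within,edge_prob_between edge probabilities in [0,1].
#' @param rng_seed integer seed.
#' @return A [gene_network()].
#' @export
generate_network <- function(truth, n_background_genes = 0L,
                             edge_prob_within = 0.8,
                             edge_prob_between = 0.05,
                             rng_seed = 1L) {
  stopifnot(edge_prob_within >= 0, edge_prob_within <= 1,
            edge_prob_between >= 0, edge_prob_between <= 1)
  module_sets <- lapply(truth$planted_module_members, `[[`, "genes")
  genes <- unique(c(unlist(module_sets), truth$hemizygous_genes))
  if (n_background_genes > 0) {
    genes <- c(genes, sprintf("bg%04d", seq_len(n_background_genes)))
  }
  n <- length(genes)
  with_rng(rng_seed, {
    within <- matrix(FALSE, n, n)
    for (set in module_sets) {
      idx <- match(set, genes)
      within[idx, idx] <- TRUE
    }
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    p <- ifelse(within[pairs], edge_prob_within, edge_prob_between)
    keep <- stats::runif(nrow(pairs)) < p
    from <- genes[pairs[keep, 1L]]
    to <- genes[pairs[keep, 2L]]
    evidence <- 1 - stats::runif(sum(keep))  # uniform in (0, 1]
    gene_network(vertices = genes,
                 edges = data.frame(from = from, to = to,
                                    evidence = evidence,
                                    stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic annotation map
#'
#' One category per planted module (its exact member genes) plus
#' `n_random_categories` random gene sets drawn from the gene universe.
#'
#' @param truth the `truth` element of [generate_study()].
#' @param universe character vector of gene ids to draw random sets from;
#'   defaults to all genes mentioned in `truth`.
#' @param n_random_categories number of random categories.
#' @param category_size_range length-2 integer vector (min, max) size of
#'   random categories.
#' @param rng_seed integer seed.
#' @return An `annotation_map`: named list of `list(name, genes)`.
#' @export
generate_annotation <- function(truth, universe = NULL,
                                n_random_categories = 20L,
                                category_size_range = c(10L, 50L),
                                rng_seed = 1L) {
  module_sets <- lapply(truth$planted_module_members, `[[`, "genes")
  if (is.null(universe)) {
    universe <- unique(c(unlist(module_sets), truth$hemizygous_genes))
  }
  if (length(universe) == 0) stop_coexmod("empty gene universe")
  if (max(category_size_range) > length(universe)) {
    stop_coexmod("`category_size_range` exceeds universe size")
  }
  ann <- list()
  for (k in seq_along(module_sets)) {
    ann[[sprintf("PLANTED:%02d", k)]] <-
      list(name = sprintf("planted module %d", k), genes = module_sets[[k]])
  }
  with_rng(rng_seed, {
    lo <- category_size_range[1]
    hi <- category_size_range[2]
    for (k in seq_len(n_random_categories)) {
      size <- if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
      ann[[sprintf("RANDOM:%03d", k)]] <-
        list(name = sprintf("random category %d", k),
             genes = sample(universe, size))
    }
  })
  structure(ann, class = "annotation_map")
}
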