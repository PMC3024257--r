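#' @name module_stats
#' @title Module dysregulation statistics
#' @description
#' The central statistic of the workflow: every sample is scored by the
#' weighted average expression of a module's genes (weights = signed
#' gene scores), and a module is called dysregulated when its case and
#' control sample scores differ by a Welch (unequal-variance) t-test
#' after BH correction over the tested modules. A label-permutation run
#' validates the whole procedure; a replication test asks whether the
#' weighted mean log fold change of a module's genes differs from zero
#' in an independent cell type; frequent-gene counting identifies genes
#' recurring across dysregulated modules.
NULL

#' Weighted module sample scores
#'
#' `score(c) = sum_g w_g x_gc / sum_g |w_g|` over the module genes
#' present in `m`, computed for all samples of `m` (sample scores extend
#' to samples outside the module). With equal positive weights this is
#' the plain mean of module-gene expression; the normalizer makes scores
#' invariant to rescaling the gene scores.
#'
#' @param module a [transcription_module()].
#' @param m an [expression_matrix()] (typically standardized per gene).
#' @return Named numeric vector over the samples of `m`.
#' @export
module_sample_scores <- function(module, m) {
  w <- module$gene_scores[module$gene_scores != 0]
  present <- names(w) %in% rownames(m$values)
  if (!any(present)) stop_coexmod("no module genes present in matrix")
  if (!all(present)) {
    warning(sprintf("module %s: %d of %d genes absent from matrix, dropped",
                    module$id, sum(!present), length(w)))
    w <- w[present]
  }
  x <- m$values[names(w), , drop = FALSE]
  drop(crossprod(x, w)) / sum(abs(w))
}

# Welch two-sided t-test on a score vector split by group; returns
# c(t, p, df). Guards zero variance in both groups.
welch_t <- function(score, case_idx, ctrl_idx) {
  x <- score[case_idx]
  y <- score[ctrl_idx]
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  if (v1 + v2 == 0) return(c(t = 0, p = 1, df = NA_real_))
  tt <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  c(t = tt, p = 2 * stats::pt(abs(tt), df, lower.tail = FALSE), df = df)
}

# Internal core shared by dysregulation_test and permutation_validation:
# takes precomputed per-module score rows (modules x samples) and labels.
dysreg_core <- function(score_mat, case_idx, ctrl_idx, fdr_level) {
  res <- t(apply(score_mat, 1L, welch_t, case_idx = case_idx,
                 ctrl_idx = ctrl_idx))
  adj <- bh_adjust(res[, "p"])
  data.frame(
    module_id = rownames(score_mat),
    t_stat = res[, "t"], raw_p = res[, "p"], adjusted_p = adj,
    direction = ifelse(res[, "t"] >= 0, "up-in-case", "down-in-case"),
    significant = adj <= fdr_level,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Standardize wbs per gene and build the modules x samples score matrix
# for modules with >= min_genes usable genes. Returns NULL if none.
module_score_matrix <- function(modules, wbs, min_genes) {
  zs <- standardize(wbs, "per-gene")
  rows <- list()
  used <- integer(0)
  for (mod in modules) {
    w <- mod$gene_scores[mod$gene_scores != 0]
    n_used <- sum(names(w) %in% rownames(zs$values))
    if (n_used < min_genes) next
    rows[[mod$id]] <- suppressWarnings(module_sample_scores(mod, zs))
    used[mod$id] <- n_used
  }
  if (length(rows) == 0) return(NULL)
  list(scores = do.call(rbind, rows), n_genes_used = used)
}

#' Test modules for case/control dysregulation
#'
#' The case/control matrix is standardized per gene; each module with at
#' least `min_genes` genes present is scored with
#' [module_sample_scores()]; case vs control sample scores are compared
#' with a Welch two-sided t-test; BH correction runs across the tested
#' modules only (modules failing the size filter are excluded from the
#' BH family).
#'
#' @param ms a `module_set` or list of modules.
#' @param wbs an [expression_matrix()] with >= 2 cases and >= 2 controls.
#' @param min_genes minimum usable module genes (default 10).
#' @param fdr_level BH significance level (default 0.05).
#' @return data.frame: `module_id`, `n_genes_used`, `t_stat`, `raw_p`,
#'   `adjusted_p`, `direction`, `significant`.
#' @export
dysregulation_test <- function(ms, wbs, min_genes = 10L, fdr_level = 0.05) {
  modules <- if (inherits(ms, "module_set")) ms$modules else ms
  grp <- wbs$sample_meta$group
  case_idx <- which(grp == "case")
  ctrl_idx <- which(grp == "control")
  if (length(case_idx) < 2 || length(ctrl_idx) < 2) {
    stop_coexmod("need >= 2 cases and >= 2 controls")
  }
  sm <- module_score_matrix(modules, wbs, min_genes)
  if (is.null(sm)) {
    warning("no module with enough usable genes")
    return(data.frame(module_id = character(0), n_genes_used = integer(0),
                      t_stat = numeric(0), raw_p = numeric(0),
                      adjusted_p = numeric(0), direction = character(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  out <- dysreg_core(sm$scores, case_idx, ctrl_idx, fdr_level)
  cbind(out[, "module_id", drop = FALSE],
        n_genes_used = unname(sm$n_genes_used[out$module_id]),
        out[, -1, drop = FALSE])
}

#' Permutation validation of the dysregulation analysis
#'
#' Repeats [dysregulation_test()] under `n_perm` random case/control
#' relabelings (group sizes preserved) and records how many modules come
#' out significant in each permutation. On real signal, permuted labels
#' should yield (almost) no significant modules.
#'
#' @inheritParams dysregulation_test
#' @param n_perm number of label permutations.
#' @param rng_seed integer seed.
#' @return List of class `permutation_summary`: `n_perm`,
#'   `n_perm_with_any_significant`, `counts_per_permutation`,
#'   `mean_count` and `median_count` (over permutations with >= 1
#'   significant module; `NA` if none), and `permuted_labels` (matrix,
#'   one row per permutation).
#' @export
permutation_validation <- function(ms, wbs, min_genes = 10L,
                                   fdr_level = 0.05, n_perm = 1000L,
                                   rng_seed = 1L) {
  assert_count(n_perm, "n_perm")
  modules <- if (inherits(ms, "module_set")) ms$modules else ms
  grp <- wbs$sample_meta$group
  pos <- which(grp %in% c("case", "control"))
  labels <- grp[pos]
  sm <- module_score_matrix(modules, wbs, min_genes)
  if (is.null(sm)) stop_coexmod("no module with enough usable genes")
  perm_labels <- matrix("", n_perm, length(grp))
  counts <- with_rng(rng_seed, {
    vapply(seq_len(n_perm), function(i) {
      g <- grp
      g[pos] <- sample(labels)
      perm_labels[i, ] <<- g
      res <- dysreg_core(sm$scores, which(g == "case"),
                         which(g == "control"), fdr_level)
      sum(res$significant)
    }, 0L)
  })
  any_sig <- counts[counts > 0]
  structure(
    list(n_perm = n_perm,
         n_perm_with_any_significant = length(any_sig),
         counts_per_permutation = counts,
         mean_count = if (length(any_sig)) mean(any_sig) else NA_real_,
         median_count = if (length(any_sig)) stats::median(any_sig) else NA_real_,
         permuted_labels = perm_labels),
    class = "permutation_summary"
  )
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat(sprintf(
    "permutation_summary: %d/%d permutations with >= 1 significant module (mean %s, median %s)\n",
    x$n_perm_with_any_significant, x$n_perm,
    format(x$mean_count), format(x$median_count)))
  invisible(x)
}

#' Module replication on log-fold-change arrays
#'
#' For each module, the weighted mean log fold change of its genes is
#' computed per replication array (same weights and normalizer as
#' [module_sample_scores()]); a one-sample two-sided t-test asks whether
#' the mean across arrays differs from zero, BH-corrected across tested
#' modules. Log fold changes are already a case/control contrast, so no
#' per-gene standardization is applied (see the methods vignette).
#'
#' @param ms a `module_set` or list of modules.
#' @param logfc numeric matrix genes x replication arrays (>= 2 arrays).
#' @param min_genes minimum module genes present in `logfc`.
#' @param fdr_level BH significance level.
#' @return data.frame: `module_id`, `n_genes_used`, `mean_logfc`,
#'   `t_stat`, `raw_p`, `adjusted_p`, `direction`, `significant`.
#'   Modules whose scores have zero variance across arrays get `t = 0`,
#'   `p = 1`.
#' @export
replication_test <- function(ms, logfc, min_genes = 10L, fdr_level = 0.05) {
  modules <- if (inherits(ms, "module_set")) ms$modules else ms
  if (ncol(logfc) < 2) stop_coexmod("need >= 2 replication arrays")
  rows <- list()
  for (mod in modules) {
    w <- mod$gene_scores[mod$gene_scores != 0]
    w <- w[names(w) %in% rownames(logfc)]
    if (length(w) < min_genes) next
    score <- drop(crossprod(logfc[names(w), , drop = FALSE], w)) / sum(abs(w))
    sv <- stats::var(score)
    if (sv == 0) {
      tt <- 0; p <- 1
    } else {
      tt <- mean(score) / sqrt(sv / length(score))
      p <- 2 * stats::pt(abs(tt), length(score) - 1, lower.tail = FALSE)
    }
    rows[[mod$id]] <- data.frame(
      module_id = mod$id, n_genes_used = length(w),
      mean_logfc = mean(score), t_stat = tt, raw_p = p,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    warning("no module with enough usable genes")
    return(data.frame(module_id = character(0), n_genes_used = integer(0),
                      mean_logfc = numeric(0), t_stat = numeric(0),
                      raw_p = numeric(0), adjusted_p = numeric(0),
                      direction = character(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$adjusted_p <- bh_adjust(out$raw_p)
  out$direction <- ifelse(out$mean_logfc >= 0, "up-in-case", "down-in-case")
  out$significant <- out$adjusted_p <= fdr_level
  out
}

#' Count gene occurrences across two sets of dysregulated modules
#'
#' @param dys_m1,dys_m2 lists of `transcription_module`s (e.g. the
#'   dysregulated modules of two modular studies).
#' @return data.frame sorted by decreasing total count: `gene`,
#'   `count_m1`, `count_m2`, `intersection` (present in both sets).
#' @export
gene_frequency <- function(dys_m1, dys_m2) {
  count_in <- function(mods) {
    g <- unlist(lapply(mods, module_genes))
    if (length(g) == 0) return(integer(0))
    table(g)
  }
  t1 <- count_in(dys_m1)
  t2 <- count_in(dys_m2)
  genes <- union(names(t1), names(t2))
  if (length(genes) == 0) {
    return(data.frame(gene = character(0), count_m1 = integer(0),
                      count_m2 = integer(0), intersection = logical(0),
                      stringsAsFactors = FALSE))
  }
  c1 <- ifelse(genes %in% names(t1), as.integer(t1[genes]), 0L)
  c2 <- ifelse(genes %in% names(t2), as.integer(t2[genes]), 0L)
  out <- data.frame(gene = genes, count_m1 = c1, count_m2 = c2,
                    intersection = c1 >= 1L & c2 >= 1L,
                    stringsAsFactors = FALSE)
  out[order(-(out$count_m1 + out$count_m2), out$gene), , drop = FALSE]
}

#' Correlate gene frequency with a per-gene quantity
#'
#' Pearson correlation of module-frequency (total count) against any
#' per-gene quantity (differential-expression statistic, degree,
#' PageRank, ...), plus the least-squares slope with its two-sided p.
#'
#' @param freq output of [gene_frequency()].
#' @param quantity named numeric vector over genes.
#' @return List: `r`, `slope`, `slope_p`, `n`.
#' @export
correlate_frequency <- function(freq, quantity) {
  common <- intersect(freq$gene, names(quantity))
  if (length(common) < 3) stop_coexmod("need >= 3 genes in common")
  x <- (freq$count_m1 + freq$count_m2)[match(common, freq$gene)]
  y <- unname(quantity[common])
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_coexmod("constant input, correlation undefined")
  }
  fit <- stats::summary.lm(stats::lm(y ~ x))
  list(r = stats::cor(x, y),
       slope = fit$coefficients["x", "Estimate"],
       slope_p = fit$coefficients["x", "Pr(>|t|)"],
       n = length(common))
}
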