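#' @name isa
#' @title Iterative Signature Algorithm
#' @description
#' The ISA discovers potentially overlapping transcription modules
#' (biclusters): starting from many random gene seeds it alternates
#' between scoring samples by the weighted average expression of the
#' current genes and re-scoring genes on the selected samples, keeping at
#' each step only entries that deviate from the mean of the raw score
#' vector by more than a threshold in sd units (two-sided, so modules may
#' contain anti-correlated gene halves). Fixed points of this map are the
#' modules; a grid of (gene, sample) thresholds controls their
#' stringency.
NULL

#' Construct a transcription module
#'
#' @param id module identifier.
#' @param gene_scores named numeric over all genes; zero = non-member;
#'   rescaled so `max(abs(.)) == 1`.
#' @param sample_scores named numeric over all samples; zero =
#'   non-member. Member-sample values are the signed weighted averages of
#'   module-gene (standardized) expression, i.e. the raw ISA sample
#'   scores, so that [module_sample_scores()] reproduces them.
#' @param thresholds list with elements `gene` and `sample` (sd units).
#' @param seed_id integer tag of the originating random seed.
#' @param robustness internal strength score used for deduplication.
#' @return A `transcription_module`.
#' @export
transcription_module <- function(id, gene_scores, sample_scores,
                                 thresholds = list(gene = NA_real_, sample = NA_real_),
                                 seed_id = NA_integer_, robustness = NA_real_) {
  if (!any(gene_scores != 0) || !any(sample_scores != 0)) {
    stop_coexmod("module must have >= 1 nonzero gene and sample score")
  }
  if (is.null(names(gene_scores)) || is.null(names(sample_scores))) {
    stop_coexmod("scores must be named")
  }
  m <- max(abs(gene_scores))
  if (abs(m - 1) > 1e-8) gene_scores <- gene_scores / m
  structure(
    list(id = id, gene_scores = gene_scores, sample_scores = sample_scores,
         thresholds = thresholds, seed_id = seed_id, robustness = robustness),
    class = "transcription_module"
  )
}

#' Genes (nonzero-score features) of a module
#' @param mod a `transcription_module`.
#' @return Character vector of member gene ids.
#' @export
module_genes <- function(mod) names(mod$gene_scores)[mod$gene_scores != 0]

#' @export
print.transcription_module <- function(x, ...) {
  cat(sprintf("transcription_module %s: %d genes, %d samples (t_G=%s, t_C=%s)\n",
              x$id, sum(x$gene_scores != 0), sum(x$sample_scores != 0),
              format(x$thresholds$gene), format(x$thresholds$sample)))
  invisible(x)
}

module_set <- function(modules, source_matrix_id = NA_character_,
                       grid = list(), run_label = "other") {
  ids <- vapply(modules, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_coexmod("module ids must be unique")
  structure(list(modules = modules, source_matrix_id = source_matrix_id,
                 grid = grid, run_label = run_label),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set (%s): %d modules over %d threshold pairs\n",
              x$run_label, length(x$modules), length(x$grid)))
  invisible(x)
}

#' ISA double normalization
#'
#' @param E an [expression_matrix()] or plain numeric matrix
#'   (genes x samples) with no constant rows or columns.
#' @return List with `E_G` (rows standardized to mean 0, sd 1) and `E_C`
#'   (columns standardized), both genes x samples.
#' @export
isa_normalize <- function(E) {
  v <- if (inherits(E, "expression_matrix")) E$values else E
  list(E_G = standardize_matrix(v, 1L), E_C = standardize_matrix(v, 2L))
}

# Threshold a matrix of raw score columns: keep entries deviating from
# the column mean by more than thr column-sds (signed), zero the rest.
threshold_scores <- function(raw, thr) {
  n <- nrow(raw)
  mu <- colMeans(raw)
  sd <- sqrt(pmax(colSums(raw^2) - n * mu^2, 0) / (n - 1L))
  keep <- abs(sweep(raw, 2L, mu)) > rep(thr * sd, each = n)
  raw * keep
}

#' One ISA iteration
#'
#' Maps a gene-score vector to a (new gene-score, sample-score) pair:
#' sample scores are the weighted average expression of the current genes
#' (weights normalized by their absolute sum), thresholded at `t_C` sd
#' deviations from the mean; gene scores are recomputed from the
#' surviving samples and thresholded at `t_G`, then rescaled so
#' `max(abs(.)) == 1`.
#'
#' @param g gene-score vector (length `nrow(E_G)`, >= 1 nonzero entry).
#' @param E_G,E_C matrices from [isa_normalize()].
#' @param thr list with `gene` and `sample` thresholds (sd units, > 0).
#' @return List with `gene_scores` and `sample_scores`; both all-zero
#'   when the signature died (non-convergent seed).
#' @export
isa_step <- function(g, E_G, E_C, thr) {
  stopifnot(length(g) == nrow(E_G), any(g != 0),
            thr$gene > 0, thr$sample > 0)
  s_raw <- drop(crossprod(E_G, g)) / sum(abs(g))
  s <- drop(threshold_scores(cbind(s_raw), thr$sample))
  if (all(s == 0)) {
    return(list(gene_scores = numeric(length(g)),
                sample_scores = numeric(ncol(E_G))))
  }
  g_raw <- drop(E_C %*% s) / sum(abs(s))
  g_new <- drop(threshold_scores(cbind(g_raw), thr$gene))
  if (any(g_new != 0)) g_new <- g_new / max(abs(g_new))
  list(gene_scores = g_new, sample_scores = s)
}

# Iterate a batch of seed columns at one threshold pair until each
# converges, dies, or hits max_iter. Convergence requires the membership
# set to be identical over 2 consecutive iterations AND the gene-score
# vector to change by < 1e-8 in max norm (so reported modules are fixed
# points to numerical precision, not merely well-correlated with one).
# Returns converged gene score columns (max-normalized).
isa_iterate_batch <- function(seeds, E_G, E_C, t_G, t_C, max_iter = 100L) {
  G <- seeds
  k <- ncol(G)
  ng <- nrow(G)
  status <- rep("active", k)            # active / converged / dead
  stable <- rep(0L, k)                  # consecutive identical memberships
  out <- matrix(0, ng, k)
  active <- seq_len(k)
  for (it in seq_len(max_iter)) {
    Ga <- G[, active, drop = FALSE]
    denom <- colSums(abs(Ga))
    S_raw <- crossprod(E_G, Ga) / rep(denom, each = ncol(E_G))
    S <- threshold_scores(S_raw, t_C)
    alive_s <- colSums(abs(S)) > 0
    G_new <- matrix(0, ng, ncol(Ga))
    if (any(alive_s)) {
      Sa <- S[, alive_s, drop = FALSE]
      denomS <- colSums(abs(Sa))
      Gr <- (E_C %*% Sa) / rep(denomS, each = ng)
      Gt <- threshold_scores(Gr, t_G)
      mx <- apply(abs(Gt), 2L, max)
      ok <- mx > 0
      Gt[, ok] <- Gt[, ok, drop = FALSE] / rep(mx[ok], each = ng)
      G_new[, alive_s] <- Gt
    }
    for (j in seq_along(active)) {
      col <- active[j]
      gn <- G_new[, j]
      if (all(gn == 0)) { status[col] <- "dead"; next }
      same <- identical(gn != 0, G[, col] != 0)
      stable[col] <- if (same) stable[col] + 1L else 0L
      if (same && stable[col] >= 1L && max(abs(gn - G[, col])) < 1e-8) {
        status[col] <- "converged"
        out[, col] <- gn
      }
      G[, col] <- gn
    }
    active <- which(status == "active")
    if (length(active) == 0) break
  }
  out[, status == "converged", drop = FALSE]
}

# Build transcription_module objects from converged gene-score columns.
finalize_modules <- function(G, E_G, t_G, t_C, id_prefix, seed_ids) {
  genes <- rownames(E_G)
  samples <- colnames(E_G)
  mods <- list()
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    s_raw <- drop(crossprod(E_G, g)) / sum(abs(g))
    s <- drop(threshold_scores(cbind(s_raw), t_C))
    if (all(s == 0)) next
    # Canonical sign: majority of member sample scores positive.
    if (sum(s > 0) < sum(s < 0)) { g <- -g; s <- -s }
    # Robustness: bilinear strength per module cell, so that a pure
    # module outranks a diluted superset of itself during deduplication.
    rob <- abs(sum(g * (E_G %*% s))) /
      (sqrt(sum(g^2)) * sqrt(sum(s^2)) *
         sqrt(sum(g != 0) * sum(s != 0)))
    mods[[length(mods) + 1L]] <- transcription_module(
      id = sprintf("%s_%03d", id_prefix, j),
      gene_scores = stats::setNames(g, genes),
      sample_scores = stats::setNames(s, samples),
      thresholds = list(gene = t_G, sample = t_C),
      seed_id = seed_ids[j], robustness = rob
    )
  }
  mods
}

#' Deduplicate candidate modules
#'
#' Greedy deduplication: candidates are visited in order of decreasing
#' robustness (an internal strength score, the normalized bilinear form
#' of gene scores, standardized expression and sample scores); a
#' candidate is dropped when its full gene-score vector has absolute
#' Pearson correlation above `corr_limit` with an already-kept module.
#'
#' @param candidates list of `transcription_module`s.
#' @param corr_limit correlation limit in (0, 1].
#' @return Filtered list of modules.
#' @export
merge_modules <- function(candidates, corr_limit = 0.9) {
  stopifnot(corr_limit > 0, corr_limit <= 1)
  if (length(candidates) <= 1) return(candidates)
  rob <- vapply(candidates, function(m) m$robustness %||% NA_real_, 0)
  rob[is.na(rob)] <- -Inf
  ordidx <- order(-rob)
  kept <- list()
  kept_mat <- NULL
  for (i in ordidx) {
    g <- candidates[[i]]$gene_scores
    if (is.null(kept_mat)) {
      kept <- c(kept, candidates[i])
      kept_mat <- cbind(g)
      next
    }
    cors <- suppressWarnings(abs(stats::cor(kept_mat, g)))
    cors[is.na(cors)] <- 0
    if (all(cors <= corr_limit)) {
      kept <- c(kept, candidates[i])
      kept_mat <- cbind(kept_mat, g)
    }
  }
  kept
}

#' Run the ISA over a threshold grid
#'
#' For each (gene, sample) threshold pair, `n_seeds` random binary gene
#' seeds of `seed_size` genes are iterated to convergence; converged
#' signatures are deduplicated with [merge_modules()] within each pair
#' and then across the whole grid. Deterministic under `rng_seed`.
#'
#' @param E an [expression_matrix()] or numeric matrix (genes x samples).
#' @param gene_thresholds,sample_thresholds numeric vectors defining the
#'   grid (all pairs). Defaults: genes 2, 2.2, ..., 4; samples 1, 1.2,
#'   ..., 2.
#' @param n_seeds random seeds per threshold pair.
#' @param seed_size genes per random seed.
#' @param corr_limit deduplication limit, see [merge_modules()].
#' @param rng_seed integer seed.
#' @param run_label label stored on the result (e.g. `"M1"`, `"M2"`).
#' @return A `module_set`.
#' @export
run_isa <- function(E, gene_thresholds = seq(2, 4, by = 0.2),
                    sample_thresholds = seq(1, 2, by = 0.2),
                    n_seeds = 100L, seed_size = 10L, corr_limit = 0.9,
                    rng_seed = 1L, run_label = "other") {
  if (length(gene_thresholds) == 0 || length(sample_thresholds) == 0) {
    stop_coexmod("threshold grid must be non-empty")
  }
  v <- if (inherits(E, "expression_matrix")) E$values else E
  # Zero or constant matrices carry no structure: legal empty result.
  if (all(apply(v, 1L, stats::var) < 1e-24)) {
    return(module_set(list(), grid = list(), run_label = run_label))
  }
  nrm <- isa_normalize(v)
  grid <- expand.grid(gene = gene_thresholds, sample = sample_thresholds)
  candidates <- list()
  with_rng(rng_seed, {
    for (p in seq_len(nrow(grid))) {
      t_G <- grid$gene[p]
      t_C <- grid$sample[p]
      seeds <- matrix(0, nrow(v), n_seeds)
      for (j in seq_len(n_seeds)) {
        seeds[sample(nrow(v), min(seed_size, nrow(v))), j] <- 1
      }
      G <- isa_iterate_batch(seeds, nrm$E_G, nrm$E_C, t_G, t_C)
      if (ncol(G) == 0) next
      mods <- finalize_modules(G, nrm$E_G, t_G, t_C,
                               id_prefix = sprintf("p%02d", p),
                               seed_ids = seq_len(ncol(G)))
      candidates <- c(candidates, merge_modules(mods, corr_limit))
    }
  })
  kept <- merge_modules(candidates, corr_limit)
  # Re-id in a stable order.
  for (i in seq_along(kept)) kept[[i]]$id <- sprintf("mod%04d", i)
  module_set(kept, grid = split(grid, seq_len(nrow(grid))),
             run_label = run_label)
}
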