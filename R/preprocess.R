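#' @name preprocess
#' @title Filtering, probeset collapsing, merging and batch correction
#' @description
#' Preprocessing mirrors the standard microarray compendium workflow:
#' drop features that are rarely detected or unmapped to a gene, keep one
#' probeset per gene (the most variable), intersect and merge datasets,
#' and remove dataset batch effects with a parametric empirical-Bayes
#' location/scale adjustment that protects biological covariates.
NULL

# Normalize a feature->gene map to a named character vector.
as_feature_map <- function(map) {
  if (is.data.frame(map)) {
    if (ncol(map) < 2) stop_coexmod("feature map needs 2 columns")
    map <- stats::setNames(as.character(map[[2]]), as.character(map[[1]]))
  }
  if (is.null(names(map))) stop_coexmod("feature map must be named (feature -> gene)")
  if (anyDuplicated(names(map))) stop_coexmod("duplicate feature ids in map")
  map
}

#' Filter features by detection count and gene mapping
#'
#' Retains features detected (Present) in at least `min_present` samples
#' and present in the feature-to-gene map; input order preserved. The
#' detection cut is 6 samples for a 17-sample case/control set and 10 for
#' a large compendium in the workflow defaults; pass it explicitly.
#'
#' @param m an [expression_matrix()].
#' @param min_present minimum number of samples with a Present flag.
#' @param map feature -> gene map (named character vector or 2-column
#'   data.frame); `NULL` skips the mapping requirement.
#' @return Filtered `expression_matrix` (possibly zero rows, with a
#'   warning).
#' @export
filter_features <- function(m, min_present, map = NULL) {
  stopifnot(min_present >= 0)
  keep <- rowSums(m$detected) >= min_present
  if (!is.null(map)) {
    map <- as_feature_map(map)
    keep <- keep & feature_ids(m) %in% names(map)
  }
  if (!any(keep)) warning("filter_features: no features retained")
  em_subset(m, features = which(keep))
}

#' Collapse features to genes by maximum variance
#'
#' For genes represented by several features, keeps the single feature
#' with the highest sample variance (ties broken by lexicographically
#' smallest feature id) and relabels rows with gene ids.
#'
#' @param m an [expression_matrix()]; every feature must be mapped.
#' @param map feature -> gene map.
#' @return `expression_matrix` with one row per gene.
#' @export
collapse_to_genes <- function(m, map) {
  map <- as_feature_map(map)
  feats <- feature_ids(m)
  if (!all(feats %in% names(map))) {
    stop_coexmod("unmapped features: ",
                 paste(utils::head(setdiff(feats, names(map)), 5), collapse = ", "))
  }
  genes <- unname(map[feats])
  vars <- apply(m$values, 1L, stats::var)
  ord <- order(genes, -vars, feats)  # per gene: max variance, then id
  first <- ord[!duplicated(genes[ord])]
  first <- sort(first)  # keep input feature order
  out <- em_subset(m, features = first)
  rownames(out$values) <- genes[first]
  rownames(out$detected) <- genes[first]
  out
}

#' Merge datasets on their common features
#'
#' Features are intersected (order of the first input) and samples
#' concatenated; `sample_meta$dataset_id` distinguishes the sources.
#'
#' @param ms list of at least two [expression_matrix()] objects with
#'   disjoint sample ids.
#' @return A merged `expression_matrix`.
#' @export
merge_datasets <- function(ms) {
  if (length(ms) < 2) stop_coexmod("need at least 2 matrices to merge")
  common <- Reduce(intersect, lapply(ms, feature_ids))
  if (length(common) == 0) stop_coexmod("empty feature intersection")
  all_samples <- unlist(lapply(ms, sample_ids))
  if (anyDuplicated(all_samples)) stop_coexmod("sample ids must be disjoint")
  vals <- do.call(cbind, lapply(ms, function(m) m$values[common, , drop = FALSE]))
  det <- do.call(cbind, lapply(ms, function(m) m$detected[common, , drop = FALSE]))
  meta <- do.call(rbind, lapply(ms, `[[`, "sample_meta"))
  rownames(meta) <- NULL
  expression_matrix(vals, det, meta)
}

#' Empirical-Bayes batch correction (location/scale model)
#'
#' Fits, per gene, `value = alpha_g + X beta_g + gamma_gb + delta_gb eps`
#' where `b` indexes batches and `X` encodes protected covariates (e.g.
#' disease status). Batch location parameters `gamma` get a normal prior
#' and scale parameters `delta^2` an inverse-gamma prior, both with
#' hyperparameters estimated across genes by moments; posterior estimates
#' are found by the standard iterative conditional scheme and removed
#' from the data, while covariate effects are retained.
#'
#' Degenerate inputs are handled without shrinkage: if the batch location
#' estimates have (numerically) zero spread across genes, or within-batch
#' residual variance is zero, the raw per-batch estimates are removed
#' as-is, which makes correction exact for pure-shift batches.
#'
#' @param m an [expression_matrix()].
#' @param batch factor-like vector over samples (default
#'   `sample_meta$dataset_id`).
#' @param covariates optional factor-like vector over samples (default
#'   `sample_meta$disease_status`); pass `NULL` for no covariate.
#' @param tol,max_iter convergence control of the EB iteration.
#' @return Corrected `expression_matrix` of the same shape.
#' @export
combat_correct <- function(m, batch = NULL, covariates = NULL,
                           tol = 1e-4, max_iter = 100L) {
  v <- m$values
  n <- ncol(v)
  if (is.null(batch)) batch <- m$sample_meta$dataset_id
  batch <- factor(batch)
  if (nlevels(batch) < 2) stop_coexmod("need >= 2 batches")
  if (any(table(batch) < 2)) stop_coexmod("each batch needs >= 2 samples")

  X <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    covariates <- factor(covariates)
    if (nlevels(covariates) > 1) {
      # Confounding check: a covariate level entirely inside one batch
      # cannot be separated from that batch's effect.
      tab <- table(covariates, batch)
      solo <- rowSums(tab > 0) == 1
      if (any(solo)) {
        lvl <- rownames(tab)[which(solo)[1]]
        b <- colnames(tab)[which(tab[which(solo)[1], ] > 0)]
        stop_coexmod(sprintf(
          "covariate level '%s' is confounded with batch '%s'", lvl, b))
      }
      X <- cbind(X, stats::model.matrix(~covariates)[, -1, drop = FALSE])
    }
  }
  B <- stats::model.matrix(~0 + batch)
  n_b <- colSums(B)
  design <- cbind(B, X[, -1, drop = FALSE])  # batch means + covariates

  # Gene-wise least squares for the full model.
  fit <- t(solve(crossprod(design), crossprod(design, t(v))))
  batch_hat <- fit[, seq_len(nlevels(batch)), drop = FALSE]
  grand <- as.vector(batch_hat %*% (n_b / n))  # weighted overall intercept
  stand_mean <- outer(grand, rep(1, n)) +
    fit[, -seq_len(nlevels(batch)), drop = FALSE] %*%
      t(X[, -1, drop = FALSE])

  resid <- v - t(design %*% t(fit))
  pooled_var <- rowSums(resid^2) / n
  pooled_var[pooled_var == 0] <- 1  # constant genes: shift-only correction
  z <- (v - stand_mean) / sqrt(pooled_var)

  corrected <- z
  for (b in levels(batch)) {
    cols <- which(batch == b)
    nb <- length(cols)
    zb <- z[, cols, drop = FALSE]
    # Per-gene batch location (gamma_hat) after removing covariate part
    # already absorbed in stand_mean.
    gamma_hat <- rowMeans(zb)
    delta_hat <- apply(zb, 1L, stats::var)

    gbar <- mean(gamma_hat)
    t2 <- stats::var(gamma_hat)
    dbar <- mean(delta_hat)
    s2 <- stats::var(delta_hat)
    degenerate <- !is.finite(t2) || t2 < 1e-12 ||
      !is.finite(s2) || s2 < 1e-12 || dbar < 1e-12
    if (degenerate) {
      gamma_star <- gamma_hat
      delta_star <- delta_hat
    } else {
      # Inverse-gamma hyperparameters by moments.
      lambda <- (2 * s2 + dbar^2) / s2
      theta <- (dbar * s2 + dbar^3) / s2
      gamma_star <- gamma_hat
      delta_star <- delta_hat
      for (it in seq_len(max_iter)) {
        g_new <- (nb * t2 * gamma_hat + delta_star * gbar) /
          (nb * t2 + delta_star)
        ss <- rowSums((zb - g_new)^2)
        d_new <- (theta + 0.5 * ss) / (nb / 2 + lambda - 1)
        change <- max(abs(g_new - gamma_star), abs(d_new - delta_star))
        gamma_star <- g_new
        delta_star <- d_new
        if (change < tol) break
      }
    }
    scale <- sqrt(delta_star)
    scale[scale < 1e-12] <- 1
    corrected[, cols] <- (zb - gamma_star) / scale
  }
  out <- m
  out$values <- corrected * sqrt(pooled_var) + stand_mean
  out
}
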