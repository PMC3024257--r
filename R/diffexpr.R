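#' @name diffexpr
#' @title Single-gene differential expression
#' @description
#' Two-group differential expression with empirical-Bayes moderated
#' t-statistics: gene-wise pooled variances are shrunk toward a common
#' prior variance `s0^2` with prior degrees of freedom `d0`, estimated by
#' fitting a scaled F distribution to the sample variances (method of
#' moments on log variances). A fold-change filter and BH FDR control
#' define the differentially-expressed gene (DEG) set; Fisher's exact
#' test measures over-representation of gene classes among DEGs, and a
#' label-permutation test scores dysregulation of a prescribed gene set
#' (e.g. the hemizygous genes of a chromosomal deletion).
NULL

# Newton inversion of trigamma, as needed to solve for d0/2.
inv_trigamma <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Estimate variance-shrinkage hyperparameters
#'
#' Fits a scaled inverse-chi-square prior to gene-wise sample variances:
#' under the model, `s_g^2 ~ s0^2 * F(d, d0)`, so the mean and variance
#' of `log(s_g^2)` identify `(d0, s0^2)` through digamma/trigamma
#' moments. When the spread of log variances does not exceed the
#' theoretical within-gene component `trigamma(d/2)`, the prior is
#' degenerate and `d0 = Inf` (all variances shrunk to `s0^2`).
#'
#' @param sample_vars per-gene positive sample variances (>= 10 genes).
#' @param residual_df residual degrees of freedom `d` (>= 1).
#' @return List with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
estimate_shrinkage <- function(sample_vars, residual_df) {
  if (length(sample_vars) < 10) stop_coexmod("need >= 10 genes")
  if (any(sample_vars <= 0)) stop_coexmod("variances must be positive")
  if (residual_df < 1) stop_coexmod("residual_df must be >= 1")
  d <- residual_df
  z <- log(sample_vars)
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- stats::var(z)
  excess <- evar - trigamma(d / 2)
  if (excess <= 0) {
    # Degenerate prior: no excess spread beyond the chi-square noise, so
    # every gene shrinks fully to the plain mean of the variances.
    return(list(d0 = Inf, s0_sq = mean(sample_vars)))
  }
  d0 <- 2 * inv_trigamma(excess)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated two-group t-test
#'
#' Per gene: pooled variance `s^2` with `d = n1 + n2 - 2` df; posterior
#' variance `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)`; moderated
#' `t = (mean_case - mean_control) / (s~ sqrt(1/n1 + 1/n2))` with
#' `d0 + d` degrees of freedom, two-sided p, BH-adjusted across genes.
#'
#' @param m an [expression_matrix()].
#' @param groups optional case/control labels over samples (default
#'   `sample_meta$group`); levels `"case"` and `"control"`, >= 2 each.
#' @param params `NULL` to estimate shrinkage from the data
#'   ([estimate_shrinkage()]), or a list with `d0` and `s0_sq` (use
#'   `d0 = 0` for the ordinary t-test).
#' @return data.frame (one row per gene): `gene`, `mean_case`,
#'   `mean_control`, `log2_fold_change`, `ordinary_t`, `moderated_t`,
#'   `raw_p`, `adjusted_p`.
#' @export
moderated_t_test <- function(m, groups = NULL, params = NULL) {
  v <- m$values
  if (is.null(groups)) groups <- m$sample_meta$group
  case <- which(groups == "case")
  ctrl <- which(groups == "control")
  n1 <- length(case)
  n2 <- length(ctrl)
  if (n1 < 2 || n2 < 2) stop_coexmod("need >= 2 samples per group")
  d <- n1 + n2 - 2
  m1 <- rowMeans(v[, case, drop = FALSE])
  m2 <- rowMeans(v[, ctrl, drop = FALSE])
  ss1 <- rowSums((v[, case, drop = FALSE] - m1)^2)
  ss2 <- rowSums((v[, ctrl, drop = FALSE] - m2)^2)
  s2 <- (ss1 + ss2) / d
  se_fac <- sqrt(1 / n1 + 1 / n2)
  ord_t <- (m1 - m2) / (sqrt(s2) * se_fac)
  if (is.null(params)) params <- estimate_shrinkage(s2, d)
  d0 <- params$d0
  s0 <- params$s0_sq
  s_tilde <- if (is.infinite(d0)) rep(s0, length(s2)) else {
    (d0 * s0 + d * s2) / (d0 + d)
  }
  mod_t <- (m1 - m2) / (sqrt(s_tilde) * se_fac)
  # Total df d0 + d, capped at the pooled residual df of the whole
  # matrix (relevant only when d0 is infinite).
  df_total <- min(d0 + d, length(s2) * d)
  raw_p <- 2 * stats::pt(abs(mod_t), df = df_total, lower.tail = FALSE)
  data.frame(
    gene = rownames(v), mean_case = m1, mean_control = m2,
    log2_fold_change = m1 - m2, ordinary_t = ord_t, moderated_t = mod_t,
    raw_p = raw_p, adjusted_p = bh_adjust(raw_p),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Declare differentially expressed genes
#'
#' A gene is a DEG iff `adjusted_p <= fdr_level` and
#' `|log2 fold change| >= log2(min_ratio)` (a `min_ratio` of 1.5 is the
#' usual "minimum 50% change" rule).
#'
#' @param stats output of [moderated_t_test()].
#' @param min_ratio minimum fold change (>= 1) on the linear scale.
#' @param fdr_level BH-adjusted p-value cutoff.
#' @return `stats` with a logical `is_DEG` column added.
#' @export
fold_change_filter <- function(stats, min_ratio = 1.5, fdr_level = 0.05) {
  if (min_ratio < 1) stop_coexmod("`min_ratio` must be >= 1")
  stats$is_DEG <- stats$adjusted_p <= fdr_level &
    abs(stats$log2_fold_change) >= log2(min_ratio)
  stats
}

#' Fisher over-representation of a gene class in a selection
#'
#' One-sided (greater) hypergeometric test on the 2x2 table of class
#' membership vs selection; the odds ratio is the sample cross-product
#' ratio, with a Haldane 0.5 correction only when a cell is zero.
#'
#' @param overlap,class_size,selected,universe the table margins.
#' @return List with `odds_ratio` and `p`.
#' @export
fisher_overrep <- function(overlap, class_size, selected, universe) {
  if (overlap > min(class_size, selected) ||
      class_size > universe || selected > universe ||
      universe - class_size - selected + overlap < 0) {
    stop_coexmod("inconsistent 2x2 margins")
  }
  a <- overlap
  b <- class_size - overlap
  c <- selected - overlap
  d <- universe - class_size - selected + overlap
  if (any(c(a, b, c, d) == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  p <- stats::phyper(overlap - 1, class_size, universe - class_size,
                     selected, lower.tail = FALSE)
  list(odds_ratio = or, p = p)
}

#' Label-permutation test for a gene set
#'
#' The statistic is the mean moderated t of the set's genes; the null is
#' the same statistic under random case/control relabelings (group sizes
#' preserved), and `p = (1 + #{|null| >= |obs|}) / (n_perm + 1)`.
#'
#' @param m an [expression_matrix()].
#' @param gene_set character vector of gene ids (>= 1 present in `m`).
#' @param groups optional labels (default `sample_meta$group`).
#' @param n_perm number of permutations (>= 1).
#' @param rng_seed integer seed.
#' @return List with `observed` (mean moderated t), `p`, and the vector
#'   of `null` statistics.
#' @export
gene_set_label_permutation_test <- function(m, gene_set, groups = NULL,
                                            n_perm = 10000L, rng_seed = 1L) {
  assert_count(n_perm, "n_perm")
  if (is.null(groups)) groups <- m$sample_meta$group
  idx <- which(rownames(m$values) %in% gene_set)
  if (length(idx) == 0) stop_coexmod("gene_set disjoint from matrix")
  stat_for <- function(g) {
    mean(moderated_t_test(m, groups = g)$moderated_t[idx])
  }
  observed <- stat_for(groups)
  labels <- groups[groups %in% c("case", "control")]
  pos <- which(groups %in% c("case", "control"))
  null <- with_rng(rng_seed, {
    vapply(seq_len(n_perm), function(i) {
      g <- groups
      g[pos] <- sample(labels)
      stat_for(g)
    }, 0)
  })
  list(observed = observed,
       p = perm_pvalue(sum(abs(null) >= abs(observed)), n_perm),
       null = null)
}
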