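# Moderated t, shrinkage estimation, Fisher tests, label permutations.

test_that("estimate_shrinkage handles degenerate and simulated input", {
  expect_identical(estimate_shrinkage(rep(2, 50), 4),
                   list(d0 = Inf, s0_sq = 2))
  expect_error(estimate_shrinkage(c(1, 2), 4), ">= 10")
  expect_error(estimate_shrinkage(c(rep(1, 20), 0), 4), "positive")

  # recovery: variances ~ s0^2 chi^2_d / d with s0^2 = 2, d = 10
  set.seed(5)
  vars <- 2 * rchisq(5000, df = 10) / 10
  fit <- estimate_shrinkage(vars, 10)
  expect_gt(fit$s0_sq, 1.8)
  expect_lt(fit$s0_sq, 2.2)
  expect_gte(fit$d0, 50)
})

test_that("moderated_t_test limit cases and hand computation", {
  set.seed(2)
  v <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  grp <- rep(c("case", "control"), each = 3)
  m <- make_em(v, groups = grp)

  r0 <- moderated_t_test(m, params = list(d0 = 0, s0_sq = 1))
  expect_equal(r0$moderated_t, r0$ordinary_t, tolerance = 1e-12)

  rinf <- moderated_t_test(m, params = list(d0 = Inf, s0_sq = 0.7))
  se <- sqrt(0.7 * (1 / 3 + 1 / 3))
  expect_equal(rinf$moderated_t,
               (r0$mean_case - r0$mean_control) / se, tolerance = 1e-12)

  # 3-gene hand computation with d0 = 4, s0^2 = 1, n1 = n2 = 3
  v3 <- rbind(gA = c(1, 2, 3, 4, 5, 6),
              gB = c(0, 0, 1, 1, 1, 0),
              gC = c(2, 2, 2, 5, 5, 5.5))
  colnames(v3) <- sprintf("s%d", 1:6)
  m3 <- make_em(v3, groups = grp)
  r <- moderated_t_test(m3, params = list(d0 = 4, s0_sq = 1))
  for (i in 1:3) {
    x <- v3[i, 1:3]; y <- v3[i, 4:6]
    s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 4
    s_tilde <- (4 * 1 + 4 * s2) / 8
    t_hand <- (mean(x) - mean(y)) / sqrt(s_tilde * (2 / 3))
    expect_equal(r$moderated_t[i], t_hand, tolerance = 1e-10)
    expect_equal(r$raw_p[i], 2 * pt(abs(t_hand), 8, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  expect_error(moderated_t_test(make_em(v, groups = c("case", rep("control", 5)))),
               ">= 2 samples")
})

test_that("moderated_t_test agrees with the limma oracle", {
  set.seed(31)
  v <- matrix(rnorm(300 * 11), 300, 11,
              dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:11)))
  grp <- c(rep("case", 5), rep("control", 6))
  res <- moderated_t_test(make_em(v, groups = grp))
  fit <- limma::eBayes(limma::lmFit(v, cbind(1, grp == "case")))
  expect_equal(res$moderated_t, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(res$raw_p, unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("fold_change_filter combines FDR and fold-change rules", {
  st <- data.frame(gene = c("a", "b", "c"),
                   log2_fold_change = c(0.50, -1.0, 2.0),
                   adjusted_p = c(1e-6, 0.01, 0.2))
  out <- fold_change_filter(st, min_ratio = 1.5, fdr_level = 0.05)
  expect_identical(out$is_DEG, c(FALSE, TRUE, FALSE))  # 0.50 < log2(1.5)
  expect_false(any(fold_change_filter(st, 1.5, 0)$is_DEG))
  expect_error(fold_change_filter(st, min_ratio = 0.5), ">= 1")
})

test_that("fisher_overrep matches enumeration on small tables", {
  r <- fisher_overrep(2, 2, 2, 5)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_equal(fisher_overrep(0, 3, 4, 10)$p, 1, tolerance = 1e-12)
  expect_error(fisher_overrep(5, 4, 6, 10), "margins")

  set.seed(6)
  for (i in 1:50) {
    universe <- sample(4:10, 1)
    class_size <- sample(1:universe, 1)
    selected <- sample(1:universe, 1)
    lo <- max(0, class_size + selected - universe)
    hi <- min(class_size, selected)
    overlap <- if (lo == hi) lo else sample(lo:hi, 1)
    mine <- fisher_overrep(overlap, class_size, selected, universe)$p
    oracle <- hyper_tail_oracle(overlap, class_size, selected, universe)
    expect_equal(mine, oracle, tolerance = 1e-12)
  }
})

test_that("odds ratio uses Haldane correction only for zero cells", {
  expect_equal(fisher_overrep(2, 4, 4, 12)$odds_ratio,
               (2 * 6) / (2 * 2))
  expect_equal(fisher_overrep(3, 3, 3, 10)$odds_ratio,
               (3.5 * 7.5) / (0.5 * 0.5))
})

test_that("gene-set permutation test detects a shifted set exactly", {
  set.seed(9)
  v <- matrix(rnorm(100 * 10), 100, 10,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:10)))
  grp <- rep(c("case", "control"), each = 5)
  v[1:10, grp == "case"] <- v[1:10, grp == "case"] + 3
  m <- make_em(v, groups = grp)
  r <- gene_set_label_permutation_test(m, sprintf("g%03d", 1:10),
                                       n_perm = 99, rng_seed = 4)
  expect_equal(r$p, 1 / 100)
  expect_error(gene_set_label_permutation_test(m, "nope", n_perm = 10),
               "disjoint")
  expect_error(gene_set_label_permutation_test(m, "g001", n_perm = 0),
               "n_perm")
  # determinism
  r2 <- gene_set_label_permutation_test(m, sprintf("g%03d", 1:10),
                                        n_perm = 99, rng_seed = 4)
  expect_identical(r$null, r2$null)
})

test_that("gene-set permutation p-values are calibrated on null data", {
  set.seed(77)
  ps <- vapply(1:100, function(i) {
    v <- matrix(rnorm(60 * 12), 60, 12,
                dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:12)))
    m <- make_em(v, groups = rep(c("case", "control"), each = 6))
    gene_set_label_permutation_test(m, sprintf("g%02d", 1:10),
                                    n_perm = 200, rng_seed = i)$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("BH control keeps the realized FDR near nominal on null data", {
  set.seed(12)
  fdp <- vapply(1:100, function(i) {
    v <- matrix(rnorm(200 * 10), 200, 10,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:10)))
    m <- make_em(v, groups = rep(c("case", "control"), each = 5))
    st <- fold_change_filter(moderated_t_test(m), min_ratio = 1,
                             fdr_level = 0.05)
    n_disc <- sum(st$is_DEG)
    if (n_disc == 0) 0 else 1   # all discoveries are false on null data
  }, 0)
  expect_lte(mean(fdp), 0.08)
})

test_that("moderated t is monotone in the mean difference at fixed variance", {
  deltas <- seq(0, 2, by = 0.5)
  base <- c(-1, 0, 1)
  v <- t(vapply(deltas, function(d) c(base + d, base), numeric(6)))
  rownames(v) <- sprintf("g%d", seq_along(deltas))
  colnames(v) <- sprintf("s%d", 1:6)
  m <- make_em(v, groups = rep(c("case", "control"), each = 3))
  r <- moderated_t_test(m, params = list(d0 = 2, s0_sq = 1))
  expect_true(all(diff(r$moderated_t) > 0))
  # BH is monotone-preserving and never decreases a p-value
  expect_identical(order(r$adjusted_p, r$raw_p), order(r$raw_p))
  expect_true(all(r$adjusted_p >= r$raw_p))
})
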