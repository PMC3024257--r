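# Weighted sample scores, dysregulation testing, permutation validation,
# replication and frequent-gene counting.

mk_module <- function(id, weights, genes, samples) {
  g <- stats::setNames(numeric(length(genes)), genes)
  g[names(weights)] <- weights
  s <- stats::setNames(rep(1, length(samples)), samples)
  transcription_module(id, g, s)
}

test_that("module_sample_scores is the normalized weighted average", {
  v <- rbind(gA = c(2, 4), gB = c(0, 2), gC = c(9, 9))
  colnames(v) <- c("s1", "s2")
  m <- make_em(v)
  genes <- rownames(v)

  eq <- mk_module("eq", c(gA = 1, gB = 1), genes, colnames(v))
  expect_equal(unname(module_sample_scores(eq, m)), c(1, 3))
  opp <- mk_module("opp", c(gA = 1, gB = -1), genes, colnames(v))
  expect_equal(unname(module_sample_scores(opp, m)), c(1, 1))

  # non-member (zero-score) genes never contribute
  with_zero <- mk_module("z", c(gA = 1, gB = 1, gC = 0), genes, colnames(v))
  expect_equal(module_sample_scores(with_zero, m),
               module_sample_scores(eq, m))
  # rescaling weights leaves scores unchanged
  scaled <- mk_module("sc", c(gA = 0.25, gB = 0.25), genes, colnames(v))
  expect_equal(module_sample_scores(scaled, m), module_sample_scores(eq, m))

  # genes absent from the matrix are dropped with a warning
  extra <- mk_module("ex", c(gA = 1, gB = 1, gX = 1),
                     c(genes, "gX"), colnames(v))
  expect_warning(sc <- module_sample_scores(extra, m), "absent")
  expect_equal(unname(sc), c(1, 3))
  only_absent <- mk_module("ab", c(gX = 1), c(genes, "gX"), colnames(v))
  expect_error(suppressWarnings(module_sample_scores(only_absent, m)),
               "no module genes")
})

test_that("dysregulation_test flags the shifted module and honours the BH family", {
  cfg <- simulation_config(
    n_genes = 400L, n_datasets = 1L, samples_per_dataset = 6L,
    n_planted_modules = 5L, module_gene_sizes = rep(30L, 5L),
    case_effect_modules = 1L, case_effect_size = 1.5,
    hemizygous_set_size = 0L, rng_seed = 14L)
  st <- generate_study(cfg)
  wbs <- st$wbs_matrix
  mods <- truth_modules(st$truth, rownames(wbs$values), colnames(wbs$values))
  res <- dysregulation_test(mods, wbs, min_genes = 10L)
  expect_identical(nrow(res), 5L)
  expect_true(res$significant[res$module_id == "t01"])
  expect_identical(res$direction[res$module_id == "t01"], "up-in-case")
  expect_true(all(res$adjusted_p >= res$raw_p))
  expect_true(all(res$n_genes_used == 30L))

  # modules below min_genes leave the BH family and change adjusted p
  small <- mk_module("small", stats::setNames(rep(1, 3), rownames(wbs$values)[1:3]),
                     rownames(wbs$values), colnames(wbs$values))
  res2 <- dysregulation_test(c(mods, list(small)), wbs, min_genes = 10L)
  expect_false("small" %in% res2$module_id)
  res3 <- dysregulation_test(c(mods, list(small)), wbs, min_genes = 2L)
  expect_true("small" %in% res3$module_id)
  expect_false(isTRUE(all.equal(
    res3$adjusted_p[match(res$module_id, res3$module_id)], res$adjusted_p)))

  # a module absent from the matrix is excluded, not fatal
  foreign <- mk_module("f", stats::setNames(rep(1, 12), sprintf("zz%02d", 1:12)),
                       c(rownames(wbs$values), sprintf("zz%02d", 1:12)),
                       colnames(wbs$values))
  res4 <- dysregulation_test(c(mods, list(foreign)), wbs, min_genes = 10L)
  expect_false("f" %in% res4$module_id)
  expect_error(dysregulation_test(mods, st$compendium[[1]]), "cases")
})

test_that("permutation_validation is consistent and concentrated on near-true labels", {
  cfg <- simulation_config(
    n_genes = 600L, n_datasets = 1L, samples_per_dataset = 6L,
    n_planted_modules = 6L, module_gene_sizes = rep(30L, 6L),
    case_effect_modules = 1:2, case_effect_size = 1.2,
    hemizygous_set_size = 0L, rng_seed = 21L)
  st <- generate_study(cfg)
  wbs <- st$wbs_matrix
  mods <- truth_modules(st$truth, rownames(wbs$values), colnames(wbs$values))
  obs <- dysregulation_test(mods, wbs)
  n_obs <- sum(obs$significant)
  expect_gte(n_obs, 2L)

  pv <- permutation_validation(mods, wbs, n_perm = 150L, rng_seed = 3L)
  expect_identical(pv$n_perm, 150L)
  expect_lte(pv$n_perm_with_any_significant, 150L)
  truelab <- wbs$sample_meta$group
  # Permutations matching the observed count must be near-true labelings.
  # The two-sided test is symmetric under label exchange, so the
  # near-complement (agreement <= 3 with an 8/9 split, whose minimum
  # attainable agreement is 1) counts as near-true as well.
  big <- which(pv$counts_per_permutation >= n_obs)
  for (i in big) {
    agree <- sum(pv$permuted_labels[i, ] == truelab)
    expect_true(agree >= length(truelab) - 2 || agree <= 3)
  }
  # determinism
  pv2 <- permutation_validation(mods, wbs, n_perm = 150L, rng_seed = 3L)
  expect_identical(pv$counts_per_permutation, pv2$counts_per_permutation)
})

test_that("replication_test behaves on degenerate, null and strong input", {
  genes <- sprintf("g%02d", 1:40)
  mods <- list(mk_module("m1", stats::setNames(rep(1, 30), genes[1:30]),
                         genes, sprintf("x%d", 1:4)))
  zero <- matrix(0, 40, 6, dimnames = list(genes, sprintf("a%d", 1:6)))
  r0 <- replication_test(mods, zero)
  expect_equal(r0$t_stat, 0)
  expect_equal(r0$raw_p, 1)
  expect_false(r0$significant)

  set.seed(8)
  hits <- 0
  for (i in 1:100) {
    lf <- matrix(rnorm(40 * 6, 0, 0.5), 40, 6,
                 dimnames = list(genes, sprintf("a%d", 1:6)))
    lf[1:30, ] <- matrix(rep(rnorm(6, 0.8, 0.2), each = 30), 30, 6)
    r <- replication_test(mods, lf)
    hits <- hits + r$significant
    expect_identical(r$direction, ifelse(r$mean_logfc >= 0,
                                         "up-in-case", "down-in-case"))
  }
  expect_gte(hits, 95L)
  expect_error(replication_test(mods, zero[, 1, drop = FALSE]), ">= 2")
})

test_that("gene_frequency counts occurrences in both module sets", {
  genes <- sprintf("g%02d", 1:10)
  samples <- sprintf("s%d", 1:3)
  mk <- function(id, gs) mk_module(id, stats::setNames(rep(1, length(gs)), gs),
                                   genes, samples)
  m1 <- lapply(1:4, function(i) mk(paste0("a", i),
                                   if (i <= 3) c("g01", "g02") else "g02"))
  m2 <- lapply(1:3, function(i) mk(paste0("b", i),
                                   if (i <= 2) c("g01", "g03") else "g03"))
  tab <- gene_frequency(m1, m2)
  g01 <- tab[tab$gene == "g01", ]
  expect_identical(c(g01$count_m1, g01$count_m2), c(3L, 2L))
  expect_true(g01$intersection)
  g02 <- tab[tab$gene == "g02", ]
  expect_identical(c(g02$count_m1, g02$count_m2), c(4L, 0L))
  expect_false(g02$intersection)
  expect_identical(nrow(gene_frequency(list(), list())), 0L)
  # sorted by total count
  expect_true(all(diff(tab$count_m1 + tab$count_m2) <= 0))
})

test_that("correlate_frequency returns exact and calibrated results", {
  freq <- data.frame(gene = c("a", "b", "c", "d"),
                     count_m1 = c(1L, 2L, 3L, 4L),
                     count_m2 = c(0L, 1L, 2L, 3L))
  # total counts 1,3,5,7; quantity on the exact line y = 2x
  q <- stats::setNames(c(2, 6, 10, 14), c("a", "b", "c", "d"))
  r <- suppressWarnings(correlate_frequency(freq, q))
  expect_equal(r$r, 1)
  expect_equal(r$slope, 2)

  expect_error(correlate_frequency(freq[1:2, ], q), ">= 3")
  expect_error(correlate_frequency(freq, stats::setNames(rep(1, 4), freq$gene)),
               "constant")

  # independence: |r| < 0.1 in at least 95% of replicates at n = 1000
  set.seed(10)
  ok <- vapply(1:60, function(i) {
    genes <- sprintf("g%04d", 1:1000)
    f <- data.frame(gene = genes,
                    count_m1 = rpois(1000, 3), count_m2 = rpois(1000, 2))
    q <- stats::setNames(rnorm(1000), genes)
    abs(correlate_frequency(f, q)$r) < 0.1
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})
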