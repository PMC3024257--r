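# Network extraction, nulls, centrality, rewiring and HRG fitting.

toy_net <- function() {
  gene_network(
    c("a", "b", "c", "d", "e"),
    data.frame(from = c("a", "a", "b", "c", "d"),
               to = c("b", "c", "c", "d", "e"),
               evidence = c(0.9, 0.2, 0.5, 0.35, 0.8),
               stringsAsFactors = FALSE))
}

test_that("gene_network validates and canonicalizes edges", {
  expect_error(gene_network("a", data.frame(from = "a", to = "a", evidence = 1)),
               "self-loops")
  expect_error(gene_network(c("a", "b"),
                            data.frame(from = "a", to = "b", evidence = 1.2)),
               "evidence")
  net <- gene_network(c("b", "a"),
                      data.frame(from = c("b", "a"), to = c("a", "b"),
                                 evidence = c(0.5, 0.7)))
  expect_identical(nrow(net$edges), 1L)   # parallel edges collapsed
  expect_true(all(net$edges$from <= net$edges$to))
})

test_that("extract_subnetwork keeps selected genes and strong edges", {
  net <- toy_net()
  expect_identical(extract_subnetwork(net, net$vertices, 0)$edges, net$edges)
  expect_identical(nrow(extract_subnetwork(net, net$vertices, 1)$edges), 0L)
  sub <- extract_subnetwork(net, c("a", "b", "c"), 0.3)
  expect_identical(nrow(sub$edges), 2L)   # a-b (0.9), b-c (0.5); a-c 0.2 dropped
  expect_setequal(sub$edges$evidence, c(0.9, 0.5))
  expect_warning(extract_subnetwork(net, "zz"), "no selected")
})

test_that("total_evidence sums edge scores", {
  expect_identical(total_evidence(extract_subnetwork(toy_net(), "a")), 0)
  tri <- gene_network(c("x", "y", "z"),
                      data.frame(from = c("x", "x", "y"), to = c("y", "z", "z"),
                                 evidence = c(0.3, 0.4, 0.5)))
  expect_equal(total_evidence(tri), 1.2)
})

test_that("random_subnetwork_null has the right bounds and finds planted density", {
  net <- toy_net()
  full <- random_subnetwork_null(net, 5, 50, total_evidence(net), rng_seed = 1)
  expect_equal(full$empirical_p, 1)
  inf <- random_subnetwork_null(net, 3, 50, Inf, rng_seed = 1)
  expect_equal(inf$empirical_p, 1 / 51)
  expect_error(random_subnetwork_null(net, 9, 10, 1), "exceeds")

  st <- generate_study(simulation_config(
    n_genes = 100L, n_datasets = 1L, samples_per_dataset = 6L,
    n_planted_modules = 1L, module_gene_sizes = 12L,
    hemizygous_set_size = 0L, case_effect_modules = integer(0),
    rng_seed = 2L))
  nw <- generate_network(st$truth, n_background_genes = 60L,
                         edge_prob_within = 0.8, edge_prob_between = 0.05,
                         rng_seed = 3L)
  mod_genes <- st$truth$planted_module_members[[1]]$genes
  obs <- total_evidence(extract_subnetwork(nw, mod_genes))
  r <- random_subnetwork_null(nw, length(mod_genes), 1000, obs, rng_seed = 4)
  expect_lte(r$empirical_p, 0.01)
  # determinism
  r2 <- random_subnetwork_null(nw, length(mod_genes), 1000, obs, rng_seed = 4)
  expect_identical(r$null_values, r2$null_values)
})

test_that("pagerank matches closed forms and the linear-system oracle", {
  two <- gene_network(c("a", "b"),
                      data.frame(from = "a", to = "b", evidence = 1))
  expect_equal(unname(pagerank(two, 0.85)), c(0.5, 0.5), tolerance = 1e-10)

  star <- gene_network(c("hub", "l1", "l2", "l3"),
                       data.frame(from = rep("hub", 3),
                                  to = c("l1", "l2", "l3"), evidence = 1))
  pr <- pagerank(star, 0.85)
  # closed form: leaf = (1-d)/n + d*hub/3; hub = (1-d)/n + d*3*leaf
  leaf <- 0.15 / 4 / (1 - 0.85^2)  * (1 + 0.85 / 3 * 3)
  hub <- 0.15 / 4 * (1 + 3 * 0.85) / (1 - 0.85^2)
  expect_equal(unname(pr["hub"]), hub, tolerance = 1e-8)
  expect_equal(unname(pr["l1"]), (1 - hub) / 3, tolerance = 1e-8)
  expect_equal(sum(pr), 1, tolerance = 1e-10)

  # random graphs <= 10 vertices vs direct linear solve
  set.seed(5)
  for (i in 1:10) {
    n <- sample(3:10, 1)
    A <- matrix(0, n, n)
    ut <- upper.tri(A)
    A[ut] <- rbinom(sum(ut), 1, 0.4)
    A <- A + t(A)
    net <- adjacency_to_network(A)
    d <- 0.85
    deg <- colSums(A)
    M <- A
    M[, deg > 0] <- sweep(A[, deg > 0, drop = FALSE], 2, deg[deg > 0], "/")
    dang <- as.numeric(deg == 0)
    # x = (1-d)/n 1 + d (M + 1 dang^T / n) x  ->  solve linear system
    S <- diag(n) - d * (M + matrix(dang, n, n, byrow = TRUE) / n)
    x <- solve(S, rep((1 - d) / n, n))
    x <- x / sum(x)
    expect_equal(unname(pagerank(net, d)), as.vector(x), tolerance = 1e-8)
  }
})

test_that("degree_centrality_compare uses exact rank-sum p for small groups", {
  # 6 vertices: {a,b,c} (degree 3) strictly above {d,e,f} (degree 1)
  edges <- data.frame(
    from = c("a", "a", "b", "a", "b", "c"),
    to = c("b", "c", "c", "d", "e", "f"),
    evidence = 0.5)
  net <- gene_network(letters[1:6], edges)
  sub <- extract_subnetwork(net, c("a", "b", "c"))
  r <- degree_centrality_compare(sub, net, "degree")
  expect_equal(r$p, 0.1, tolerance = 1e-12)   # 2 / C(6,3)
  expect_error(degree_centrality_compare(net, net), "non-empty")
  r2 <- degree_centrality_compare(sub, net, "pagerank")
  expect_lt(r2$p, 0.2)
})

test_that("rewiring preserves the degree sequence exactly", {
  cyc <- gene_network(letters[1:4],
                      data.frame(from = c("a", "b", "c", "a"),
                                 to = c("b", "c", "d", "d"), evidence = 0.5))
  rw <- rewire_degree_preserving(cyc, 100, rng_seed = 2)
  expect_identical(unname(network_degree(rw)), rep(2L, 4))

  st_net <- make_er_graph(7, n = 15, m_target = 30)
  for (s in 1:5) {
    rw <- rewire_degree_preserving(st_net, rng_seed = s)
    expect_identical(sort(network_degree(rw)), sort(network_degree(st_net)))
    expect_identical(nrow(rw$edges), nrow(st_net$edges))
    expect_false(any(rw$edges$from == rw$edges$to))
    expect_identical(anyDuplicated(rw$edges[, c("from", "to")]), 0L)
    expect_setequal(rw$edges$evidence, st_net$edges$evidence)
  }

  # triangle + disjoint edge: every output is a simple graph on the same
  # degree sequence, and the chain explores more than one state
  tri_e <- gene_network(letters[1:5],
                        data.frame(from = c("a", "a", "b", "d"),
                                   to = c("b", "c", "c", "e"),
                                   evidence = 0.5))
  shapes <- unique(vapply(1:40, function(s) {
    rw <- rewire_degree_preserving(tri_e, 50, rng_seed = s)
    expect_identical(sort(network_degree(rw)), sort(network_degree(tri_e)))
    paste(sort(paste(rw$edges$from, rw$edges$to)), collapse = ";")
  }, ""))
  expect_gte(length(shapes), 2L)
})

test_that("hrg_loglik matches hand computations", {
  tri <- gene_network(c("a", "b", "c"),
                      data.frame(from = c("a", "a", "b"),
                                 to = c("b", "c", "c"), evidence = 1))
  d3 <- dendrogram_model(rbind(c(-2, -3), c(-1, 1)), tri)
  expect_equal(d3$loglik, 0)
  expect_equal(hrg_loglik(tri, d3), 0)

  path <- gene_network(c("a", "b", "c"),
                       data.frame(from = c("a", "b"), to = c("b", "c"),
                                  evidence = 1))
  dp <- dendrogram_model(rbind(c(-2, -3), c(-1, 1)), path)
  expect_equal(dp$loglik, -2 * log(2))
  expect_true(all(dendrogram_model(rbind(c(-1, -2), c(1, -3)), tri)$p %in% c(0, 1)))
  expect_error(dendrogram_model(rbind(c(-1, -1), c(1, -3)), tri), "overlap")
  bad <- gene_network(c("x", "y", "z"), data.frame(from = "x", to = "y",
                                                   evidence = 1))
  expect_error(hrg_loglik(bad, d3), "leaf set")
})

test_that("fit_hrg finds the enumerated optimum on 4-vertex graphs", {
  set.seed(9)
  for (trial in 1:8) {
    repeat {
      A <- matrix(0, 4, 4)
      A[upper.tri(A)] <- rbinom(6, 1, 0.5)
      A <- A + t(A)
      if (sum(A) > 0) break
    }
    net <- adjacency_to_network(A)
    tl <- enum_trees(as.list(net$vertices))
    expect_length(tl, 15L)
    lls <- vapply(tl, function(tr)
      dendrogram_model(tree_to_merge(tr, net$vertices), net)$loglik, 0)
    ft <- fit_hrg(net, n_steps = 400, rng_seed = trial)
    expect_equal(ft$best_loglik, max(lls), tolerance = 1e-12)
    expect_lte(ft$best_loglik, 0)
  }
})

test_that("fit_hrg prefers the clique split and improves with more steps", {
  # two 4-cliques joined by one edge
  v <- sprintf("v%02d", 1:8)
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1
  A[5:8, 5:8] <- 1
  diag(A) <- 0
  A[4, 5] <- A[5, 4] <- 1
  net <- adjacency_to_network(A)
  ft <- fit_hrg(net, n_steps = 4000, rng_seed = 1)
  set.seed(2)
  rand_lls <- vapply(1:100, function(i) {
    labs <- sample(net$vertices)
    merge <- cbind(c(-1, seq_len(6)), -(2:8))
    net2 <- gene_network(labs, net$edges)
    dendrogram_model(merge, net2)$loglik
  }, 0)
  expect_gte(ft$best_loglik, max(rand_lls))

  short <- fit_hrg(net, n_steps = 1, rng_seed = 5)$best_loglik
  long <- fit_hrg(net, n_steps = 10000, rng_seed = 5)$best_loglik
  expect_gte(long, short)
})

test_that("hierarchy_significance bounds and argument checks", {
  net <- make_hier_graph(1)
  r <- hierarchy_significance(net, n_random = 1, n_steps = 300, rng_seed = 1)
  expect_true(r$empirical_p %in% c(0.5, 1))
  tiny <- gene_network(c("a", "b", "c"),
                       data.frame(from = "a", to = "b", evidence = 1))
  expect_error(hierarchy_significance(tiny, 5), ">= 4")
})

test_that("largest_component extracts the biggest weak component", {
  net <- gene_network(letters[1:6],
                      data.frame(from = c("a", "b", "d"),
                                 to = c("b", "c", "e"), evidence = 0.5))
  lc <- largest_component(net)
  expect_setequal(lc$vertices, c("a", "b", "c"))
})
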