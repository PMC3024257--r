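#' @name network_analysis
#' @title Interaction-network analysis of frequent module genes
#' @description
#' Genes that recur across dysregulated modules are examined on an
#' evidence-weighted interaction network (STRING-style combined scores
#' rescaled to (0, 1]): the induced subnetwork's total edge evidence is
#' compared to uniform random vertex subsets; the degree and PageRank of
#' the frequent genes (computed in the full network) are compared to the
#' remaining vertices with Wilcoxon rank-sum tests; and the subnetwork's
#' hierarchical organization is tested by fitting hierarchical random
#' graphs to it and to degree-preserving rewired null networks.
NULL

#' Construct an undirected evidence-weighted gene network
#'
#' @param vertices character vertex names (gene symbols).
#' @param edges data.frame with columns `from`, `to`, `evidence`
#'   (scores in (0, 1]); self-loops forbidden, parallel edges collapse
#'   to the first occurrence; endpoints are stored sorted.
#' @return A `gene_network`.
#' @export
gene_network <- function(vertices, edges) {
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices)) stop_coexmod("duplicate vertices")
  stopifnot(all(c("from", "to", "evidence") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (!all(c(edges$from, edges$to) %in% vertices)) {
    stop_coexmod("edge endpoints must be listed vertices")
  }
  if (any(edges$from == edges$to)) stop_coexmod("self-loops not allowed")
  if (any(edges$evidence <= 0 | edges$evidence > 1)) {
    stop_coexmod("evidence scores must be in (0, 1]")
  }
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- edges[!duplicated(edges[, c("from", "to")]),
                 c("from", "to", "evidence"), drop = FALSE]
  rownames(edges) <- NULL
  structure(list(vertices = vertices, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d vertices, %d edges\n",
              length(x$vertices), nrow(x$edges)))
  invisible(x)
}

# Dense symmetric 0/1 adjacency matrix (vertex order preserved).
adjacency <- function(net) {
  n <- length(net$vertices)
  A <- matrix(0L, n, n, dimnames = list(net$vertices, net$vertices))
  i <- match(net$edges$from, net$vertices)
  j <- match(net$edges$to, net$vertices)
  A[cbind(i, j)] <- 1L
  A[cbind(j, i)] <- 1L
  A
}

#' Vertex degrees of a gene network
#' @param net a `gene_network`.
#' @return Named integer vector over all vertices.
#' @export
network_degree <- function(net) {
  d <- stats::setNames(integer(length(net$vertices)), net$vertices)
  tab <- table(c(net$edges$from, net$edges$to))
  d[names(tab)] <- as.integer(tab)
  d
}

#' Induced subnetwork of a gene set
#'
#' @param net a `gene_network`.
#' @param genes character gene set (intersected with the vertices; empty
#'   intersection gives an empty network with a warning).
#' @param min_evidence keep edges with evidence strictly above this
#'   (default 0 keeps all).
#' @return The induced `gene_network`.
#' @export
extract_subnetwork <- function(net, genes, min_evidence = 0) {
  stopifnot(min_evidence >= 0, min_evidence <= 1)
  keep_v <- intersect(net$vertices, genes)
  if (length(keep_v) == 0) warning("no selected genes in network")
  e <- net$edges
  e <- e[e$from %in% keep_v & e$to %in% keep_v & e$evidence > min_evidence, ,
         drop = FALSE]
  gene_network(keep_v, e)
}

#' Total edge evidence of a network
#' @param net a `gene_network`.
#' @return Sum of edge evidence scores (0 for an empty edge set).
#' @export
total_evidence <- function(net) sum(net$edges$evidence)

#' Random-subnetwork null for total evidence
#'
#' Draws `n_draws` uniform `k`-vertex subsets, induces their subgraphs
#' and records the total edge evidence;
#' `empirical_p = (1 + #\{null >= observed\}) / (n_draws + 1)`.
#'
#' @param net a `gene_network`.
#' @param k subset size (<= number of vertices).
#' @param n_draws number of random subsets.
#' @param observed the observed total evidence to compare against.
#' @param rng_seed integer seed.
#' @return List with `empirical_p` and `null_values`.
#' @export
random_subnetwork_null <- function(net, k, n_draws, observed, rng_seed = 1L) {
  assert_count(n_draws, "n_draws")
  if (k > length(net$vertices)) stop_coexmod("k exceeds vertex count")
  i <- match(net$edges$from, net$vertices)
  j <- match(net$edges$to, net$vertices)
  ev <- net$edges$evidence
  n <- length(net$vertices)
  null_values <- with_rng(rng_seed, {
    vapply(seq_len(n_draws), function(d) {
      inset <- logical(n)
      inset[sample(n, k)] <- TRUE
      sum(ev[inset[i] & inset[j]])
    }, 0)
  })
  list(empirical_p = perm_pvalue(sum(null_values >= observed), n_draws),
       null_values = null_values)
}

#' PageRank centrality
#'
#' Power iteration with uniform teleportation on the unweighted
#' adjacency; dangling (isolated) vertices spread their mass uniformly.
#' Scores sum to 1.
#'
#' @param net a `gene_network`.
#' @param damping damping factor in (0, 1).
#' @param tol L1 convergence tolerance.
#' @return Named numeric vector over vertices.
#' @export
pagerank <- function(net, damping = 0.85, tol = 1e-10) {
  stopifnot(damping > 0, damping < 1, length(net$vertices) > 0)
  A <- adjacency(net)
  n <- nrow(A)
  deg <- colSums(A)
  dangling <- deg == 0
  M <- A
  M[, !dangling] <- sweep(A[, !dangling, drop = FALSE], 2L,
                          deg[!dangling], "/")
  x <- rep(1 / n, n)
  for (it in 1:10000) {
    x_new <- (1 - damping) / n +
      damping * (drop(M %*% x) + sum(x[dangling]) / n)
    if (sum(abs(x_new - x)) < tol) { x <- x_new; break }
    x <- x_new
  }
  stats::setNames(x / sum(x), net$vertices)
}

#' Compare centrality of a vertex subset against the rest
#'
#' The measure (degree or PageRank) is computed for every vertex in the
#' full network; the subnetwork's vertices are compared to the remaining
#' vertices with a two-sided Wilcoxon rank-sum test (exact enumeration
#' for small tie-free samples, normal approximation with tie correction
#' otherwise).
#'
#' @param sub,full `gene_network`s; `sub`'s vertices must be a proper
#'   non-empty subset of `full`'s.
#' @param measure `"degree"` or `"pagerank"`.
#' @return List: `p`, `statistic` (rank-sum W), `in_values`,
#'   `out_values`.
#' @export
degree_centrality_compare <- function(sub, full,
                                      measure = c("degree", "pagerank")) {
  measure <- match.arg(measure)
  if (!all(sub$vertices %in% full$vertices)) {
    stop_coexmod("subnetwork vertices must be in the full network")
  }
  vals <- if (measure == "degree") network_degree(full) else pagerank(full)
  inside <- full$vertices %in% sub$vertices
  if (!any(inside) || all(inside)) stop_coexmod("both groups must be non-empty")
  x <- vals[inside]
  y <- vals[!inside]
  n <- length(x) + length(y)
  if (n <= 16) {
    # Exact enumeration over all C(n, m) group assignments; handles ties.
    ranks <- rank(c(x, y))
    obs <- sum(ranks[seq_along(x)])
    sums <- utils::combn(n, length(x), function(idx) sum(ranks[idx]))
    p_ge <- mean(sums >= obs)
    p_le <- mean(sums <= obs)
    p <- min(1, 2 * min(p_ge, p_le))
    w <- obs - length(x) * (length(x) + 1) / 2
    return(list(p = p, statistic = w, in_values = x, out_values = y))
  }
  exact <- n <= 50 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = exact, correct = FALSE))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       in_values = x, out_values = y)
}

#' Degree-preserving rewiring
#'
#' Randomizes a network with the double-edge-swap Markov chain: repeat
#' `n_swaps` attempts of picking two edges (a,b), (c,d) and replacing
#' them with (a,d), (c,b), rejecting swaps that would create self-loops
#' or parallel edges. The degree sequence is preserved exactly; the
#' multiset of evidence scores is carried by the edge slots, so
#' total-evidence statistics stay comparable.
#'
#' @param net a `gene_network` with >= 2 edges.
#' @param n_swaps number of attempted swaps (default 10x edge count).
#' @param rng_seed integer seed.
#' @return The rewired `gene_network`.
#' @export
rewire_degree_preserving <- function(net, n_swaps = NULL, rng_seed = 1L) {
  m <- nrow(net$edges)
  if (m < 2) stop_coexmod("need >= 2 edges")
  if (is.null(n_swaps)) n_swaps <- 10L * m
  from <- match(net$edges$from, net$vertices)
  to <- match(net$edges$to, net$vertices)
  n <- length(net$vertices)
  key <- function(a, b) ifelse(a < b, (a - 1) * n + b, (b - 1) * n + a)
  have <- new.env(hash = TRUE)
  for (e in seq_len(m)) assign(as.character(key(from[e], to[e])), TRUE, have)
  with_rng(rng_seed, {
    for (s in seq_len(n_swaps)) {
      e12 <- sample(m, 2L)
      a <- from[e12[1]]; b <- to[e12[1]]
      c_ <- from[e12[2]]; d <- to[e12[2]]
      # Random orientation so both rewirings of the 4 endpoints are
      # reachable (ergodicity of the swap chain).
      if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
      if (length(unique(c(a, b, c_, d))) < 4) next
      # swap to (a,d), (c,b)
      k1 <- as.character(key(a, d)); k2 <- as.character(key(c_, b))
      if (exists(k1, have, inherits = FALSE) ||
          exists(k2, have, inherits = FALSE)) next
      rm(list = c(as.character(key(a, b)), as.character(key(c_, d))),
         envir = have)
      assign(k1, TRUE, have); assign(k2, TRUE, have)
      to[e12[1]] <- d
      from[e12[2]] <- c_; to[e12[2]] <- b
    }
  })
  gene_network(net$vertices,
               data.frame(from = net$vertices[from], to = net$vertices[to],
                          evidence = net$edges$evidence,
                          stringsAsFactors = FALSE))
}

#' Largest connected component
#' @param net a `gene_network`.
#' @return The induced `gene_network` of the largest component.
#' @export
largest_component <- function(net) {
  n <- length(net$vertices)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  i <- match(net$edges$from, net$vertices)
  j <- match(net$edges$to, net$vertices)
  for (e in seq_along(i)) {
    a <- find(i[e]); b <- find(j[e])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n), find, 0L)
  big <- names(which.max(table(comp)))
  extract_subnetwork(net, net$vertices[comp == as.integer(big)])
}

#' Export a network as Graphviz DOT
#'
#' Edges are drawn with a grayscale intensity proportional to their
#' evidence score, mirroring the usual rendering of STRING subnetworks.
#'
#' @param net a `gene_network`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_network_dot <- function(net, path) {
  shade <- function(ev) {
    g <- as.integer(round((1 - ev) * 200))
    sprintf("#%02x%02x%02x", g, g, g)
  }
  lines <- c(
    "graph genes {",
    sprintf('  "%s";', net$vertices),
    sprintf('  "%s" -- "%s" [color="%s"];', net$edges$from, net$edges$to,
            shade(net$edges$evidence)),
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}
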