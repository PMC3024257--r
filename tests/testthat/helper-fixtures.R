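# Shared fixtures and independent oracles, all built in code.

# Quick expression_matrix from a plain matrix, with optional groups.
make_em <- function(v, groups = NULL, dataset = "d1") {
  if (is.null(rownames(v))) rownames(v) <- sprintf("g%03d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("s%03d", seq_len(ncol(v)))
  meta <- data.frame(
    sample_id = colnames(v),
    dataset_id = dataset,
    disease_status = if (is.null(groups)) "none" else groups,
    group = if (is.null(groups)) "other" else groups,
    stringsAsFactors = FALSE
  )
  expression_matrix(v, NULL, meta)
}

# Planted modules as transcription_module objects (weights = signs).
truth_modules <- function(truth, genes, samples) {
  lapply(seq_along(truth$planted_module_members), function(k) {
    mm <- truth$planted_module_members[[k]]
    g <- stats::setNames(numeric(length(genes)), genes)
    g[mm$genes] <- mm$signs
    s <- stats::setNames(rep(1, length(samples)), samples)
    transcription_module(sprintf("t%02d", k), g, s)
  })
}

best_jaccard <- function(ms, gene_set) {
  mods <- if (inherits(ms, "module_set")) ms$modules else ms
  if (length(mods) == 0) return(0)
  max(vapply(mods, function(m) {
    g <- module_genes(m)
    length(intersect(g, gene_set)) / length(union(g, gene_set))
  }, 0))
}

# --- dendrogram enumeration oracle (all rooted binary leaf-labeled
# trees; (2n-3)!! shapes) -------------------------------------------
enum_trees <- function(S) {
  if (length(S) == 1) return(list(S[[1]]))
  res <- list()
  n <- length(S)
  for (mask in 0:(2^(n - 1) - 2)) {
    bits <- as.logical(intToBits(mask))[seq_len(n - 1)]
    left <- S[c(TRUE, bits)]
    right <- S[c(FALSE, !bits)]
    for (lt in enum_trees(left)) {
      for (rt in enum_trees(right)) {
        res[[length(res) + 1]] <- list(lt, rt)
      }
    }
  }
  res
}

tree_to_merge <- function(tr, labels) {
  merge <- matrix(0L, length(labels) - 1, 2)
  cnt <- 0
  rec <- function(t) {
    if (!is.list(t)) return(-match(t, labels))
    a <- rec(t[[1]])
    b <- rec(t[[2]])
    cnt <<- cnt + 1
    merge[cnt, ] <<- c(a, b)
    cnt
  }
  rec(tr)
  merge
}

# --- random graphs ---------------------------------------------------
adjacency_to_network <- function(A, evidence = 0.5) {
  v <- sprintf("v%02d", seq_len(nrow(A)))
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  gene_network(v, data.frame(from = v[idx[, 1]], to = v[idx[, 2]],
                             evidence = rep(evidence, nrow(idx)),
                             stringsAsFactors = FALSE))
}

# Balanced 3-level hierarchical benchmark: 4 blocks of 6 in 2
# superblocks; dense within block, intermediate within superblock,
# sparse across.
make_hier_graph <- function(seed, n_blocks = 4, block_size = 6,
                            p_in = 0.9, p_mid = 0.3, p_out = 0.05) {
  set.seed(seed)
  n <- n_blocks * block_size
  blocks <- rep(seq_len(n_blocks), each = block_size)
  super <- ifelse(blocks <= n_blocks / 2, 1, 2)
  p <- outer(seq_len(n), seq_len(n), function(i, j)
    ifelse(blocks[i] == blocks[j], p_in,
           ifelse(super[i] == super[j], p_mid, p_out)))
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  A[ut] <- stats::rbinom(sum(ut), 1, p[ut])
  adjacency_to_network(A + t(A))
}

# Erdos-Renyi graph with approximately m_target edges on n vertices.
make_er_graph <- function(seed, n = 24, m_target = 120) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    ut <- upper.tri(A)
    A[ut] <- stats::rbinom(sum(ut), 1, m_target / choose(n, 2))
    A <- A + t(A)
    if (sum(A) / 2 >= 4) break
  }
  adjacency_to_network(A)
}

# Brute-force one-sided hypergeometric tail using only choose().
hyper_tail_oracle <- function(overlap, class_size, selected, universe) {
  ks <- overlap:min(class_size, selected)
  sum(vapply(ks, function(k) {
    choose(class_size, k) * choose(universe - class_size, selected - k)
  }, 0)) / choose(universe, selected)
}
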