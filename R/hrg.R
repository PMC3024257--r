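#' @name hrg
#' @title Hierarchical random graphs
#' @description
#' A hierarchical random graph (HRG) models a network by a binary
#' dendrogram over its vertices: each internal node `r` splits its
#' leaves into a left set (size `L_r`) and right set (size `R_r`), and
#' edges across the split appear independently with probability `p_r`.
#' At the maximum-likelihood `p_r = E_r / (L_r R_r)` (with `E_r` the
#' observed cross edges) the log-likelihood is
#' `sum_r E_r log p_r + (L_r R_r - E_r) log(1 - p_r)`, which is 0 for a
#' perfectly hierarchical graph and negative otherwise. The dendrogram
#' is fit by a Metropolis MCMC over subtree-exchange moves; comparing
#' the best likelihood against degree-preserving rewired networks tests
#' whether the network is more hierarchically organized than its degree
#' sequence alone explains.
NULL

# Per-split log-likelihood term with 0 log 0 = 0.
hrg_term <- function(E, LR) {
  if (LR == 0) return(0)
  p <- E / LR
  t <- 0
  if (E > 0) t <- t + E * log(p)
  if (LR - E > 0) t <- t + (LR - E) * log(1 - p)
  t
}

#' Construct a dendrogram model from an hclust-style merge matrix
#'
#' @param merge integer matrix (n-1 x 2), hclust convention: negative
#'   entries index leaves (vertices of `net`, in `net$vertices` order),
#'   positive entries index earlier merge rows.
#' @param net the `gene_network` the dendrogram spans.
#' @return A `dendrogram_model`: `merge`, `labels`, and per internal
#'   node `L`, `R`, `E`, `p`, plus `loglik`.
#' @export
dendrogram_model <- function(merge, net) {
  n <- length(net$vertices)
  if (!is.matrix(merge) || nrow(merge) != n - 1) {
    stop_coexmod("`merge` must be an (n-1) x 2 matrix")
  }
  ei <- match(net$edges$from, net$vertices)
  ej <- match(net$edges$to, net$vertices)
  leafsets <- vector("list", n - 1)
  L <- R <- E <- p <- numeric(n - 1)
  set_of <- function(x) {
    if (x < 0) {
      out <- logical(n); out[-x] <- TRUE; out
    } else leafsets[[x]]
  }
  for (r in seq_len(n - 1)) {
    ls <- set_of(merge[r, 1])
    rs <- set_of(merge[r, 2])
    if (any(ls & rs)) stop_coexmod("overlapping child leaf sets")
    leafsets[[r]] <- ls | rs
    L[r] <- sum(ls)
    R[r] <- sum(rs)
    E[r] <- sum((ls[ei] & rs[ej]) | (ls[ej] & rs[ei]))
    p[r] <- E[r] / (L[r] * R[r])
  }
  if (!all(leafsets[[n - 1]])) stop_coexmod("dendrogram must span all vertices")
  structure(
    list(merge = merge, labels = net$vertices, L = L, R = R, E = E, p = p,
         loglik = sum(mapply(hrg_term, E, L * R))),
    class = "dendrogram_model"
  )
}

#' @export
print.dendrogram_model <- function(x, ...) {
  cat(sprintf("dendrogram_model: %d leaves, loglik %.4f\n",
              length(x$labels), x$loglik))
  invisible(x)
}

#' Log-likelihood of a network under a dendrogram model
#'
#' @param net a `gene_network`.
#' @param d a `dendrogram_model` whose labels equal `net`'s vertex set.
#' @return The HRG log-likelihood (<= 0; 0 iff every `p_r` is 0 or 1).
#' @export
hrg_loglik <- function(net, d) {
  if (!setequal(d$labels, net$vertices) ||
      length(d$labels) != length(net$vertices)) {
    stop_coexmod("dendrogram leaf set must equal the network vertex set")
  }
  # Recompute against this network (labels may be ordered differently).
  net2 <- gene_network(d$labels, net$edges)
  dendrogram_model(d$merge, net2)$loglik
}

# --- MCMC fitting ----------------------------------------------------

# Internal state: arrays over nodes 1..(2n-1); 1..n leaves, rest
# internal; root = n+1 by construction of the random start? No: root
# tracked explicitly. leafset = logical matrix nodes x n.
hrg_random_state <- function(n) {
  child1 <- child2 <- parent <- integer(2 * n - 1)
  roots <- seq_len(n)
  nxt <- n + 1L
  while (length(roots) > 1) {
    pick <- sample(length(roots), 2L)
    a <- roots[pick[1]]; b <- roots[pick[2]]
    child1[nxt] <- a; child2[nxt] <- b
    parent[a] <- nxt; parent[b] <- nxt
    roots <- c(roots[-pick], nxt)
    nxt <- nxt + 1L
  }
  list(child1 = child1, child2 = child2, parent = parent,
       root = 2L * n - 1L)
}

fit_hrg_impl <- function(net, n_steps) {
  n <- length(net$vertices)
  ei <- match(net$edges$from, net$vertices)
  ej <- match(net$edges$to, net$vertices)
  cross_count <- function(ls, rs) {
    sum((ls[ei] & rs[ej]) | (ls[ej] & rs[ei]))
  }
  st <- hrg_random_state(n)
  nn <- 2L * n - 1L
  leafset <- matrix(FALSE, nn, n)
  leafset[cbind(seq_len(n), seq_len(n))] <- TRUE
  term <- numeric(nn)
  # Fill internal nodes bottom-up (children have smaller... not
  # guaranteed; do a post-order walk).
  order_nodes <- integer(0)
  walk <- function(v) {
    if (v <= n) return(invisible(NULL))
    walk(st$child1[v]); walk(st$child2[v])
    order_nodes <<- c(order_nodes, v)
    invisible(NULL)
  }
  walk(st$root)
  for (v in order_nodes) {
    ls <- leafset[st$child1[v], ]
    rs <- leafset[st$child2[v], ]
    leafset[v, ] <- ls | rs
    term[v] <- hrg_term(cross_count(ls, rs), sum(ls) * sum(rs))
  }
  ll <- sum(term)
  best_ll <- ll
  best <- st

  internal <- (n + 1L):nn
  movable <- internal[internal != st$root]
  for (step in seq_len(n_steps)) {
    r <- if (length(movable) == 1L) movable else sample(movable, 1L)
    p <- st$parent[r]
    s <- if (st$child1[p] == r) st$child2[p] else st$child1[p]
    a <- st$child1[r]; b <- st$child2[r]
    swap_a <- stats::runif(1) < 0.5
    keep <- if (swap_a) b else a       # stays under r
    out <- if (swap_a) a else b        # moves up under p
    new_r_set <- leafset[keep, ] | leafset[s, ]
    new_term_r <- hrg_term(cross_count(leafset[keep, ], leafset[s, ]),
                           sum(leafset[keep, ]) * sum(leafset[s, ]))
    new_term_p <- hrg_term(cross_count(new_r_set, leafset[out, ]),
                           sum(new_r_set) * sum(leafset[out, ]))
    delta <- (new_term_r + new_term_p) - (term[r] + term[p])
    if (delta >= 0 || stats::runif(1) < exp(delta)) {
      st$child1[r] <- keep; st$child2[r] <- s
      st$parent[s] <- r
      if (st$child1[p] == s) st$child1[p] <- out else st$child2[p] <- out
      st$parent[out] <- p
      # (r stays a child of p)
      leafset[r, ] <- new_r_set
      term[r] <- new_term_r
      term[p] <- new_term_p
      ll <- ll + delta
      if (ll > best_ll + 1e-12) {
        best_ll <- ll
        best <- st
      }
    }
  }
  list(state = best, loglik = best_ll)
}

# Convert an internal child-array state to an hclust-style merge matrix.
state_to_merge <- function(st, n) {
  merge <- matrix(0L, n - 1L, 2L)
  row_of <- integer(2L * n - 1L)
  nxt <- 0L
  assign_rows <- function(v) {
    if (v <= n) return(invisible(NULL))
    assign_rows(st$child1[v]); assign_rows(st$child2[v])
    nxt <<- nxt + 1L
    row_of[v] <<- nxt
    enc <- function(u) if (u <= n) -u else row_of[u]
    merge[nxt, ] <<- c(enc(st$child1[v]), enc(st$child2[v]))
    invisible(NULL)
  }
  assign_rows(st$root)
  merge
}

#' Fit a hierarchical random graph by MCMC
#'
#' Metropolis sampling over dendrograms: each step picks a random
#' non-root internal node and proposes one of its two subtree-exchange
#' neighbors (swapping the node's sibling with one of its children),
#' accepting with probability `min(1, exp(delta log L))`. Returns the
#' best model seen. Intended for desk-scale graphs (<= ~200 vertices).
#'
#' @param net a `gene_network` with >= 3 vertices (use
#'   [largest_component()] first if disconnected).
#' @param n_steps MCMC steps (default `50 * n^2`, at least 3000).
#' @param rng_seed integer seed.
#' @return List with `best` (a `dendrogram_model`) and `best_loglik`.
#' @export
fit_hrg <- function(net, n_steps = NULL, rng_seed = 1L) {
  n <- length(net$vertices)
  if (n < 3) stop_coexmod("need >= 3 vertices")
  if (is.null(n_steps)) n_steps <- max(3000L, 50L * n^2)
  assert_count(n_steps, "n_steps")
  fit <- with_rng(rng_seed, fit_hrg_impl(net, n_steps))
  best <- dendrogram_model(state_to_merge(fit$state, n), net)
  list(best = best, best_loglik = best$loglik)
}

#' Test for hierarchical organization against rewired nulls
#'
#' Fits an HRG to the network and to `n_random` degree-preserving
#' rewired versions;
#' `empirical_p = (1 + #\{null >= observed\}) / (n_random + 1)`. A small
#' p indicates more hierarchical structure than expected from the
#' degree sequence alone.
#'
#' @param net a connected `gene_network` with >= 4 vertices.
#' @param n_random number of rewired null networks.
#' @param n_steps MCMC steps per fit (see [fit_hrg()]).
#' @param rng_seed integer seed.
#' @return List: `observed_loglik`, `null_logliks`, `empirical_p`.
#' @export
hierarchy_significance <- function(net, n_random = 1000L, n_steps = NULL,
                                   rng_seed = 1L) {
  if (length(net$vertices) < 4) stop_coexmod("need >= 4 vertices")
  assert_count(n_random, "n_random")
  with_rng(rng_seed, {
    sub_seeds <- sample.int(.Machine$integer.max, 2L * n_random + 1L)
    obs <- fit_hrg(net, n_steps, rng_seed = sub_seeds[1])$best_loglik
    null <- vapply(seq_len(n_random), function(i) {
      rw <- rewire_degree_preserving(net, rng_seed = sub_seeds[2 * i])
      fit_hrg(rw, n_steps, rng_seed = sub_seeds[2 * i + 1])$best_loglik
    }, 0)
    list(observed_loglik = obs, null_logliks = null,
         empirical_p = perm_pvalue(sum(null >= obs), n_random))
  })
}
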