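#' @name module_graph
#' @title Subset hierarchy of modules
#' @description
#' Overlapping modules produced over a threshold grid are often nested:
#' raising the thresholds shrinks a module to its core. The hierarchy
#' connects two modules by a directed edge when all genes of the first
#' are included in the second; the stored edges are the transitive
#' reduction of that strict-subset relation, so edges point from smaller
#' to strictly larger gene sets ("direct" subset relations only).
NULL

#' Build the subset-relation DAG of a module list
#'
#' Modules with identical gene sets are collapsed into one node (their
#' ids joined with `+`); an edge A -> B means genes(A) is a strict
#' subset of genes(B) and no third node sits properly between them.
#'
#' @param modules list of `transcription_module`s (or a `module_set`).
#' @return A `hierarchy_dag`: list with `nodes` (data.frame `node_id`,
#'   `module_ids`, `n_genes`, `component`), `edges` (data.frame `from`,
#'   `to`), and `gene_sets` (named list).
#' @export
build_hierarchy <- function(modules) {
  if (inherits(modules, "module_set")) modules <- modules$modules
  sets <- lapply(modules, module_genes)
  ids <- vapply(modules, `[[`, "", "id")
  if (any(lengths(sets) == 0)) stop_coexmod("modules must have non-empty gene sets")

  # Collapse identical gene sets.
  keys <- vapply(sets, function(s) paste(sort(s), collapse = "\r"), "")
  uniq <- !duplicated(keys)
  node_sets <- sets[uniq]
  node_ids <- vapply(which(uniq), function(i) {
    paste(ids[keys == keys[i]], collapse = "+")
  }, "")
  names(node_sets) <- node_ids
  n <- length(node_sets)

  # Strict subset relation, then transitive reduction.
  sub <- matrix(FALSE, n, n, dimnames = list(node_ids, node_ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && length(node_sets[[i]]) < length(node_sets[[j]]) &&
          all(node_sets[[i]] %in% node_sets[[j]])) {
        sub[i, j] <- TRUE
      }
    }
  }
  red <- sub
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (sub[i, j]) {
        # Drop if a k exists with i < k < j.
        if (any(sub[i, ] & sub[, j])) red[i, j] <- FALSE
      }
    }
  }
  edges <- which(red, arr.ind = TRUE)
  edges_df <- data.frame(from = node_ids[edges[, 1L]],
                         to = node_ids[edges[, 2L]],
                         stringsAsFactors = FALSE)

  # Weakly connected components via union-find.
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in seq_len(nrow(edges_df))) {
    a <- find(match(edges_df$from[e], node_ids))
    b <- find(match(edges_df$to[e], node_ids))
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n), find, 0L)
  comp <- match(comp, unique(comp))

  nodes <- data.frame(
    node_id = node_ids,
    module_ids = node_ids,
    n_genes = lengths(node_sets),
    component = comp,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges_df, gene_sets = node_sets),
            class = "hierarchy_dag")
}

#' @export
print.hierarchy_dag <- function(x, ...) {
  cat(sprintf("hierarchy_dag: %d nodes, %d edges, %d components\n",
              nrow(x$nodes), nrow(x$edges), max(x$nodes$component, 0)))
  invisible(x)
}

#' Non-trivial components of a hierarchy DAG
#'
#' @param dag a `hierarchy_dag` from [build_hierarchy()].
#' @param min_size smallest component size reported (default 2, i.e.
#'   isolated modules are "trivial").
#' @return data.frame `component`, `n_modules`, sorted by decreasing
#'   size.
#' @export
components <- function(dag, min_size = 2L) {
  tab <- table(dag$nodes$component)
  keep <- tab[tab >= min_size]
  out <- data.frame(component = as.integer(names(keep)),
                    n_modules = as.integer(keep),
                    stringsAsFactors = FALSE)
  out[order(-out$n_modules, out$component), , drop = FALSE]
}

#' Export a hierarchy DAG
#'
#' Writes the edge list as TSV and optionally a Graphviz DOT file with
#' node annotations (gene-set size plus any logical flag columns given
#' in `annotations`, rendered as stars after the node label).
#'
#' @param dag a `hierarchy_dag`.
#' @param tsv_path,dot_path output paths (`NULL` to skip either).
#' @param annotations optional data.frame with a `node_id` column and
#'   logical flag columns.
#' @return Invisibly, the paths written.
#' @export
write_hierarchy <- function(dag, tsv_path = NULL, dot_path = NULL,
                            annotations = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(dag$edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(dot_path)) {
    flag_str <- rep("", nrow(dag$nodes))
    if (!is.null(annotations)) {
      idx <- match(dag$nodes$node_id, annotations$node_id)
      flags <- annotations[idx, setdiff(names(annotations), "node_id"),
                           drop = FALSE]
      flag_str <- apply(flags, 1L, function(r) {
        strrep("*", sum(r %in% TRUE))
      })
    }
    lines <- c(
      "digraph hierarchy {",
      "  rankdir=BT;",
      sprintf('  "%s" [label="%s (%d)%s"];', dag$nodes$node_id,
              dag$nodes$node_id, dag$nodes$n_genes, flag_str),
      sprintf('  "%s" -> "%s";', dag$edges$from, dag$edges$to),
      "}"
    )
    writeLines(lines, dot_path)
  }
  invisible(c(tsv = tsv_path, dot = dot_path))
}
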