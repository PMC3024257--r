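#' @name enrichment
#' @title Hypergeometric over-representation analysis
#' @description
#' Functional enrichment of gene lists and module gene sets against
#' annotation categories (GO/KEGG-style, supplied as GMT): one-sided
#' hypergeometric tests with Benjamini-Hochberg control. For module
#' enrichment the BH family pools all (module, category) tests, i.e. the
#' correction spans both the number of categories and the number of
#' modules. Categories are taken as given (no ontology-graph
#' propagation; supply a propagated GMT if desired).
NULL

#' Benjamini-Hochberg step-up adjustment
#'
#' `adjusted_(i) = min_{j >= i} min(1, p_(j) * m / j)` on the sorted
#' p-values, returned in input order.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop_coexmod("p-values must be in [0, 1]")
  }
  m <- length(pvals)
  ord <- order(pvals, decreasing = TRUE)
  adj <- pmin(1, cummin(pvals[ord] * m / (m:1)))
  adj[order(ord)]
}

#' Expected overlap count under the hypergeometric null
#'
#' @param category_size,selected,universe the margins
#'   (`category_size`, `selected` <= `universe`; `universe` > 0).
#' @return `category_size * selected / universe`.
#' @export
expected_count <- function(category_size, selected, universe) {
  if (universe <= 0) stop_coexmod("universe must be > 0")
  if (category_size > universe || selected > universe) {
    stop_coexmod("margins exceed universe")
  }
  category_size * selected / universe
}

#' Hypergeometric over-representation test of one category
#'
#' @param category,selected,universe character gene sets; `category` and
#'   `selected` must be subsets of `universe`.
#' @param gene_directions optional named sign vector (+1 up in cases, -1
#'   down) used to label the overlap direction: `"ind"` if all
#'   overlapping genes are up (induced), `"sup"` if all down
#'   (suppressed), else `"ind/sup"`; blank when not supplied.
#' @return One-row data.frame: `raw_p`, `odds_ratio`, `expected_count`,
#'   `count`, `category_size`, `direction`.
#' @export
hypergeom_test <- function(category, selected, universe,
                           gene_directions = NULL) {
  category <- unique(category)
  selected <- unique(selected)
  universe <- unique(universe)
  if (!all(category %in% universe)) stop_coexmod("category not within universe")
  if (!all(selected %in% universe)) stop_coexmod("selection not within universe")
  overlap <- intersect(category, selected)
  fr <- fisher_overrep(length(overlap), length(category), length(selected),
                       length(universe))
  direction <- ""
  if (!is.null(gene_directions) && length(overlap) > 0) {
    sgn <- sign(gene_directions[overlap])
    direction <- if (all(sgn > 0, na.rm = TRUE)) "ind"
    else if (all(sgn < 0, na.rm = TRUE)) "sup"
    else "ind/sup"
  }
  data.frame(
    raw_p = fr$p, odds_ratio = fr$odds_ratio,
    expected_count = expected_count(length(category), length(selected),
                                    length(universe)),
    count = length(overlap), category_size = length(category),
    direction = direction, stringsAsFactors = FALSE
  )
}

#' Enrichment of a gene list over an annotation map
#'
#' @param selected character gene list (e.g. DEGs).
#' @param ann an `annotation_map` (see [read_gmt()] /
#'   [generate_annotation()]).
#' @param universe character gene universe; categories are intersected
#'   with it.
#' @param gene_directions optional sign vector, see [hypergeom_test()].
#' @return data.frame with one row per category, BH-adjusted over the
#'   categories tested, sorted by `raw_p`.
#' @export
enrich_gene_list <- function(selected, ann, universe,
                             gene_directions = NULL) {
  if (length(universe) == 0) stop_coexmod("empty universe")
  selected <- intersect(selected, universe)
  rows <- lapply(names(ann), function(id) {
    cat_genes <- intersect(ann[[id]]$genes, universe)
    if (length(cat_genes) == 0) return(NULL)
    r <- hypergeom_test(cat_genes, selected, universe, gene_directions)
    cbind(data.frame(category = id, term = ann[[id]]$name,
                     stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(category = character(0), term = character(0),
                      raw_p = numeric(0), adjusted_p = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out$adjusted_p <- bh_adjust(out$raw_p)
  out[order(out$raw_p), , drop = FALSE]
}

#' Enrichment of module gene sets over an annotation map
#'
#' Every module's gene set is tested against every category;
#' Benjamini-Hochberg runs over the pooled family of
#' (modules x categories) tests.
#'
#' @param modules list of `transcription_module`s or a `module_set`.
#' @param ann an `annotation_map`.
#' @param universe character gene universe.
#' @param level_filter optional character vector of category ids to keep
#'   (e.g. pre-selected ontology level); applied before testing.
#' @return data.frame: `module_id`, `category`, `term`, `raw_p`,
#'   `adjusted_p`, `odds_ratio`, `expected_count`, `count`,
#'   `category_size`, sorted by `raw_p`.
#' @export
enrich_modules <- function(modules, ann, universe, level_filter = NULL) {
  if (inherits(modules, "module_set")) modules <- modules$modules
  if (length(universe) == 0) stop_coexmod("empty universe")
  if (!is.null(level_filter)) ann <- ann[names(ann) %in% level_filter]
  cat_sets <- lapply(ann, function(a) intersect(a$genes, universe))
  keep <- lengths(cat_sets) > 0
  ann <- ann[keep]
  cat_sets <- cat_sets[keep]
  rows <- list()
  for (mod in modules) {
    sel <- intersect(module_genes(mod), universe)
    if (length(sel) == 0) next
    for (id in names(ann)) {
      r <- hypergeom_test(cat_sets[[id]], sel, universe)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(module_id = mod$id, category = id,
                   term = ann[[id]]$name, stringsAsFactors = FALSE), r)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(module_id = character(0), category = character(0),
                      term = character(0), raw_p = numeric(0),
                      adjusted_p = numeric(0), stringsAsFactors = FALSE))
  }
  out$adjusted_p <- bh_adjust(out$raw_p)   # pooled family
  out[order(out$raw_p), , drop = FALSE]
}

#' Write enrichment results as TSV
#'
#' Column order follows the conventional over-representation table:
#' ID, adjusted p, direction, odds ratio, expected count, count,
#' category size, term (plus module_id first when present).
#'
#' @param rows output of [enrich_gene_list()] or [enrich_modules()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_enrichment_tsv <- function(rows, path) {
  cols <- c("category", "adjusted_p", "direction", "odds_ratio",
            "expected_count", "count", "category_size", "term")
  if ("module_id" %in% names(rows)) cols <- c("module_id", cols)
  cols <- intersect(cols, names(rows))
  utils::write.table(rows[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
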