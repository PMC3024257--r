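#' @name io
#' @title Readers and writers for the pipeline's plain-text formats
#' @description
#' Expression matrices travel as TSV (first column feature id, header =
#' sample ids) with a companion detection-flag TSV (P/A per cell) and a
#' sample-metadata TSV; annotations as GMT; networks as 3-column TSV
#' (STRING-style: combined scores above 1 are assumed on the 0-1000
#' scale and divided by 1000); module sets and ground truth as JSON.
#' Write-read round trips are lossless to full double precision.
NULL

read_tsv_checked <- function(path, what) {
  lines <- readLines(path)
  if (length(lines) < 1) stop_coexmod(sprintf("%s: empty file '%s'", what, path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1])) {
    bad <- which(nf != nf[1])[1]
    stop_coexmod(sprintf("%s: ragged row at line %d of '%s'", what, bad, path))
  }
  fields
}

#' Write / read an expression matrix as TSV
#'
#' `write_expression_tsv` writes the value matrix, a `P`/`A`
#' detection-flag matrix and the sample metadata next to each other;
#' `read_expression_tsv` reverses it. A missing flags file defaults to
#' all-detected (with a warning); a missing metadata file fills
#' defaults.
#'
#' @param m an [expression_matrix()].
#' @param path values TSV path; flags and metadata default to
#'   `<path>.flags.tsv` and `<path>.meta.tsv`.
#' @param flags_path,meta_path companion paths.
#' @return `read_expression_tsv` returns an `expression_matrix`;
#'   `write_expression_tsv` the main path, invisibly.
#' @export
write_expression_tsv <- function(m, path,
                                 flags_path = paste0(path, ".flags.tsv"),
                                 meta_path = paste0(path, ".meta.tsv")) {
  write_mat <- function(x, p, fmt) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(paste(c("feature_id", colnames(x)), collapse = "\t"), con)
    body <- apply(x, 1L, function(r) paste(fmt(r), collapse = "\t"))
    writeLines(paste(rownames(x), body, sep = "\t"), con)
  }
  write_mat(m$values, path, function(r) formatC(r, digits = 17, format = "g"))
  write_mat(m$detected, flags_path, function(r) ifelse(r, "P", "A"))
  utils::write.table(m$sample_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path,
                                flags_path = paste0(path, ".flags.tsv"),
                                meta_path = paste0(path, ".meta.tsv")) {
  fields <- read_tsv_checked(path, "expression TSV")
  header <- fields[[1]]
  samples <- header[-1]
  feats <- vapply(fields[-1], `[[`, "", 1L)
  if (anyDuplicated(feats)) {
    stop_coexmod(sprintf("duplicate feature id '%s' in '%s'",
                         feats[duplicated(feats)][1], path))
  }
  vals <- matrix(NA_real_, length(feats), length(samples),
                 dimnames = list(feats, samples))
  for (i in seq_along(feats)) {
    row <- suppressWarnings(as.numeric(fields[[i + 1L]][-1]))
    if (anyNA(row)) {
      stop_coexmod(sprintf("non-numeric cell at line %d of '%s'", i + 1L, path))
    }
    vals[i, ] <- row
  }
  detected <- NULL
  if (file.exists(flags_path)) {
    ff <- read_tsv_checked(flags_path, "flags TSV")
    detected <- do.call(rbind, lapply(ff[-1], function(r) r[-1] == "P"))
    dimnames(detected) <- list(vapply(ff[-1], `[[`, "", 1L), ff[[1]][-1])
    detected <- detected[feats, samples, drop = FALSE]
  } else {
    warning("no detection-flag file; assuming all detected")
  }
  meta <- NULL
  if (file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                              colClasses = "character")
  }
  expression_matrix(vals, detected, meta)
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one category per line, `name TAB description TAB gene1
#' TAB gene2 ...`.
#'
#' @param path file path.
#' @param ann an `annotation_map` (named list of `list(name, genes)`).
#' @return `read_gmt` returns an `annotation_map`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ann <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop_coexmod(sprintf("malformed GMT line %d of '%s'", i, path))
    }
    if (f[1] %in% names(ann)) {
      stop_coexmod(sprintf("duplicate category '%s' at line %d", f[1], i))
    }
    ann[[f[1]]] <- list(name = f[2], genes = f[-(1:2)])
  }
  structure(ann, class = "annotation_map")
}

#' @rdname read_gmt
#' @export
write_gmt <- function(ann, path) {
  lines <- vapply(names(ann), function(id) {
    paste(c(id, ann[[id]]$name, ann[[id]]$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an interaction network TSV
#'
#' Columns `gene_a`, `gene_b`, `evidence` (header optional on read).
#' Evidence scores greater than 1 are assumed to be STRING combined
#' scores on the 0-1000 scale and are divided by 1000.
#'
#' @param path file path.
#' @param net a `gene_network`.
#' @return `read_network_tsv` returns a `gene_network`.
#' @export
read_network_tsv <- function(path) {
  fields <- read_tsv_checked(path, "network TSV")
  if (identical(tolower(fields[[1]][1]), "gene_a")) fields <- fields[-1]
  if (any(lengths(fields) != 3)) stop_coexmod("network TSV needs 3 columns")
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  ev <- as.numeric(vapply(fields, `[[`, "", 3L))
  if (anyNA(ev)) stop_coexmod("non-numeric evidence score")
  if (any(ev > 1)) ev <- ev / 1000
  gene_network(unique(c(from, to)),
               data.frame(from = from, to = to, evidence = ev,
                          stringsAsFactors = FALSE))
}

#' @rdname read_network_tsv
#' @export
write_network_tsv <- function(net, path) {
  out <- net$edges
  names(out) <- c("gene_a", "gene_b", "evidence")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a module set as JSON
#'
#' Scores are stored sparsely (ids and values of the nonzero entries)
#' together with the full gene/sample universes, so round trips are
#' exact.
#'
#' @param ms a `module_set`.
#' @param path file path.
#' @return `read_modules` returns a `module_set`.
#' @export
write_modules <- function(ms, path) {
  mods <- lapply(ms$modules, function(m) {
    gi <- which(m$gene_scores != 0)
    si <- which(m$sample_scores != 0)
    list(id = m$id,
         thresholds = m$thresholds,
         seed_id = m$seed_id,
         robustness = m$robustness,
         genes = names(m$gene_scores)[gi],
         gene_scores = unname(m$gene_scores[gi]),
         samples = names(m$sample_scores)[si],
         sample_scores = unname(m$sample_scores[si]))
  })
  obj <- list(run_label = ms$run_label,
              source_matrix_id = ms$source_matrix_id,
              gene_universe = if (length(ms$modules))
                names(ms$modules[[1]]$gene_scores) else character(0),
              sample_universe = if (length(ms$modules))
                names(ms$modules[[1]]$sample_scores) else character(0),
              modules = mods)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_modules
#' @export
read_modules <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  genes <- obj$gene_universe
  samples <- obj$sample_universe
  mods <- lapply(obj$modules, function(m) {
    g <- stats::setNames(numeric(length(genes)), genes)
    g[m$genes] <- m$gene_scores
    s <- stats::setNames(numeric(length(samples)), samples)
    s[m$samples] <- m$sample_scores
    transcription_module(m$id, g, s,
                         thresholds = m$thresholds,
                         seed_id = m$seed_id %||% NA_integer_,
                         robustness = m$robustness %||% NA_real_)
  })
  module_set(mods, source_matrix_id = obj$source_matrix_id %||% NA_character_,
             run_label = obj$run_label %||% "other")
}

#' Write per-gene differential-expression statistics as TSV
#'
#' @param stats output of [moderated_t_test()] /
#'   [fold_change_filter()].
#' @param path file path.
#' @export
write_gene_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
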