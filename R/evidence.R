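# Evidence layers: arbitrary per-gene evidence tables attached to the
# project under a namespace, with explicit duplicate reduction.

PVAL_COLUMN_PATTERN <- "(pval|p_value|padj|fdr)"

default_reducer <- function(col, name) {
  if (is.numeric(col)) {
    if (grepl(PVAL_COLUMN_PATTERN, name, ignore.case = TRUE)) "min" else "max"
  } else if (is.logical(col)) {
    "any"
  } else {
    "concat_distinct"
  }
}

apply_reducer <- function(x, policy) {
  switch(policy,
    min = if (all(is.na(x))) x[NA_integer_] else min(x, na.rm = TRUE),
    max = if (all(is.na(x))) x[NA_integer_] else max(x, na.rm = TRUE),
    mean = if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE),
    any = any(x, na.rm = TRUE),
    concat_distinct = concat_distinct(x),
    lp_stop(paste0("unknown reducer policy: ", policy))
  )
}

#' Collapse multi-row evidence to one row per gene
#'
#' A gene can legitimately carry several evidence rows (multiple eQTL SNPs,
#' several coding variants); the gene sheet wants one row per gene. Each
#' column is collapsed by a policy — by default, numeric columns whose name
#' looks like a p-value (`pval`/`p_value`/`padj`/`fdr`) take the minimum
#' (the conservative aggregate), other numeric columns the maximum, logical
#' columns `any`, and text columns the sorted `;`-joined set of distinct
#' values. An `n_records` column records how many source rows each gene had.
#'
#' @param table Evidence data frame.
#' @param key Name of the column holding the resolved gene key.
#' @param reducers Optional named character vector, column -> policy
#'   (`min`, `max`, `mean`, `any`, `concat_distinct`), overriding defaults.
#' @return Tibble with one row per distinct key value plus `n_records`.
#' @export
reduce_duplicates <- function(table, key, reducers = NULL) {
  lp_assert(is.data.frame(table), "`table` must be a data frame")
  lp_assert(is_string(key) && key %in% names(table),
            paste0("key column not in table: ", key))
  tbl <- as_tibble(table)
  value_cols <- setdiff(names(tbl), key)

  policies <- vapply(value_cols, function(nm)
    default_reducer(tbl[[nm]], nm), character(1))
  if (!is.null(reducers)) {
    unknown <- setdiff(names(reducers), value_cols)
    if (length(unknown) > 0) {
      lp_stop(paste0("reducer given for absent column(s): ",
                     paste(unknown, collapse = ", ")))
    }
    policies[names(reducers)] <- unname(unlist(reducers))
  }
  for (nm in value_cols) {
    if (policies[[nm]] %in% c("min", "max", "mean") && !is.numeric(tbl[[nm]])) {
      lp_stop(paste0("reducer '", policies[[nm]], "' requires a numeric column, ",
                     "but `", nm, "` is ", class(tbl[[nm]])[[1]]))
    }
  }

  keys <- as.character(tbl[[key]])
  # stable, deterministic output order: first appearance order of keys
  groups <- split(seq_len(nrow(tbl)), factor(keys, levels = unique(keys)))
  rows <- lapply(groups, function(idx) {
    vals <- lapply(value_cols, function(nm) apply_reducer(tbl[[nm]][idx], policies[[nm]]))
    names(vals) <- value_cols
    vals$n_records <- length(idx)
    vals
  })
  out <- dplyr::bind_rows(lapply(rows, as_tibble))
  out <- dplyr::bind_cols(tibble(!!key := names(groups)), out)
  out
}

#' Map coordinate-linked evidence rows to genes
#'
#' Joins evidence rows carrying chr/start/end coordinates onto genes by
#' genomic overlap (any-overlap, 1-based closed). A row overlapping several
#' genes fans out to each of them (the packet is gene-centric); rows
#' overlapping no gene are dropped and counted in the report attribute.
#'
#' @param annotation An `lp_annotation`.
#' @param table Evidence data frame with a coordinate triple (auto-detected
#'   or named by `key`).
#' @param key Optional [link_key()] of kind `"coords"`.
#' @return Tibble: `gene_uid` plus all evidence columns, one row per
#'   (evidence row x overlapped gene); attribute `n_dropped` counts
#'   intergenic rows.
#' @export
coord_join <- function(annotation, table, key = NULL) {
  lp_assert(inherits(annotation, "lp_annotation"),
            "`annotation` must be an lp_annotation")
  lp_assert(is.data.frame(table), "`table` must be a data frame")
  key <- key %||% detect_link_key(table)
  lp_assert(key$kind == "coords", "coord_join needs a coords link key")
  cc <- key$columns

  chrom <- normalize_chrom(as.character(table[[cc[1]]]),
                           annotation_chrom_style(annotation))
  start <- suppressWarnings(as.numeric(table[[cc[2]]]))
  end <- suppressWarnings(as.numeric(table[[cc[3]]]))
  bad <- which(is.na(start) | is.na(end) | !is_whole(start) | !is_whole(end) |
                 start < 1 | end < start)
  if (length(bad) > 0) {
    lp_stop(paste0("malformed coordinates in evidence row(s): ",
                   paste(bad, collapse = ", ")))
  }
  if (nrow(table) == 0) {
    out <- dplyr::bind_cols(tibble(gene_uid = character()), as_tibble(table))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  gr_ev <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  gr_genes <- GenomicRanges::GRanges(
    annotation$chrom, IRanges::IRanges(annotation$start, annotation$end))
  hits <- GenomicRanges::findOverlaps(gr_ev, gr_genes)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  out <- dplyr::bind_cols(
    tibble(gene_uid = annotation$gene_uid[s]),
    as_tibble(table)[q, , drop = FALSE]
  )
  attr(out, "n_dropped") <- nrow(table) - length(unique(q))
  out
}

# Resolve an evidence table to a per-gene key column ("gene_uid") against
# the project's annotation + idmap. Returns list(table, n_dropped, kind).
resolve_evidence_keys <- function(annotation, idmap, table, key = NULL) {
  key <- key %||% detect_link_key(table)
  if (key$kind == "coords") {
    joined <- coord_join(annotation, table, key)
    return(list(table = joined, n_dropped = attr(joined, "n_dropped"),
                key = key))
  }
  tbl <- as_tibble(table)
  if (key$kind == "ensembl") {
    uid <- as.character(tbl[[key$columns]])
    uid[!uid %in% annotation$gene_uid] <- NA_character_
  } else {
    syms <- as.character(tbl[[key$columns]])
    # direct case-insensitive symbol match to the annotation first, then
    # alias resolution through the IdMap
    sym_to_uid <- setNames(annotation$gene_uid, tolower(annotation$gene_symbol))
    uid <- unname(sym_to_uid[tolower(syms)])
    if (!is.null(idmap) && any(is.na(uid))) {
      res <- resolve_symbols(syms[is.na(uid)], idmap)
      ens <- res$ensembl_id
      ens[!ens %in% annotation$gene_uid] <- NA_character_
      uid[is.na(uid)] <- ens
    }
  }
  keep <- !is.na(uid)
  out <- dplyr::bind_cols(tibble(gene_uid = uid[keep]),
                          tbl[keep, , drop = FALSE])
  list(table = out, n_dropped = sum(!keep), key = key)
}

#' Attach an evidence table to a project as a named layer
#'
#' The central extension point: any table with a linkable column (gene
#' symbol, Ensembl ID, or genomic coordinates) becomes a namespaced
#' evidence layer. The table is resolved to genes, reduced to one row per
#' gene ([reduce_duplicates()]), its columns prefixed `"<name>."`, and
#' left-joined onto the project gene sheet — the sheet keeps exactly its
#' rows and base columns, genes without evidence get missing values, and
#' provenance (source label, build, timestamp, reducer policies) is
#' recorded on the layer.
#'
#' @param project An `lp_project` from [init_project()].
#' @param table Evidence data frame.
#' @param name Layer namespace; must be unique within the project.
#' @param link_key Optional [link_key()] override.
#' @param reducers Optional reducer overrides (see [reduce_duplicates()]).
#' @param build Genome build of the evidence; must equal the project build
#'   for coordinate-linked tables (identifier-linked tables may omit it).
#' @param source Free-text provenance label (defaults to `name`).
#' @return The updated project.
#' @export
attach_layer <- function(project, table, name, link_key = NULL,
                         reducers = NULL, build = NULL, source = name) {
  lp_assert(inherits(project, "lp_project"), "`project` must be an lp_project")
  lp_assert(is_string(name) && nzchar(name), "`name` must be a non-empty string")
  lp_assert(grepl("^[A-Za-z][A-Za-z0-9_]*$", name),
            "layer name must be alphanumeric (it becomes a column prefix)")
  if (name %in% names(project$layers)) {
    lp_stop(paste0("a layer named '", name, "' is already attached"))
  }
  if (!is.null(build)) {
    check_same_build(project$build, build,
                     paste0("project and evidence layer '", name, "'"))
  }

  resolved <- resolve_evidence_keys(project$annotation, project$idmap,
                                    table, link_key)
  ev <- resolved$table
  drop_cols <- if (resolved$key$kind != "coords") resolved$key$columns else character()
  ev <- ev[, setdiff(names(ev), drop_cols), drop = FALSE]

  if (nrow(ev) > 0) {
    reduced <- reduce_duplicates(ev, "gene_uid", reducers)
  } else {
    reduced <- ev
    reduced$n_records <- integer()
  }
  names(reduced)[-1] <- paste0(name, ".", names(reduced)[-1])

  project$layers[[name]] <- list(
    name = name,
    link_key = resolved$key,
    reduced = reduced,
    n_source_rows = nrow(table),
    n_dropped = resolved$n_dropped,
    provenance = list(
      source = source,
      build = build_name(project$build),
      attached_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      reducers = as.list(reducers %||% list())
    )
  )
  project
}
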