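# Gene identifier harmonization: symbol <-> Ensembl <-> human ortholog,
# and auto-detection of how an arbitrary evidence table links to genes.

ENSEMBL_GENE_PATTERN <- "^ENS[A-Z]*G[0-9]{6,}"

#' Build an identifier map
#'
#' The IdMap drives all symbol resolution: each record pairs an Ensembl
#' gene ID with its primary symbol, any number of aliases, and (optionally)
#' a human ortholog symbol. Aliases may collide across records — ambiguity
#' is representable, and [resolve_symbols()] surfaces it explicitly rather
#' than guessing.
#'
#' @param df Data frame with columns `ensembl_id`, `primary_symbol`, and
#'   optionally `aliases` (pipe-delimited string or list column) and
#'   `human_ortholog`.
#' @return An `lp_idmap` tibble.
#' @export
id_map <- function(df) {
  lp_assert(is.data.frame(df), "`df` must be a data frame")
  m <- as_tibble(df)
  lp_assert(all(c("ensembl_id", "primary_symbol") %in% names(m)),
            "IdMap needs `ensembl_id` and `primary_symbol` columns")
  if (!"aliases" %in% names(m)) m$aliases <- list(character())
  if (!is.list(m$aliases)) {
    m$aliases <- lapply(as.character(m$aliases), function(a) {
      if (is.na(a) || !nzchar(a)) character() else trimws(strsplit(a, "\\|")[[1]])
    })
  }
  if (!"human_ortholog" %in% names(m)) m$human_ortholog <- NA_character_
  m$ensembl_id <- as.character(m$ensembl_id)
  m$primary_symbol <- as.character(m$primary_symbol)
  m$human_ortholog <- as.character(m$human_ortholog)
  if (anyDuplicated(m$ensembl_id)) lp_stop("IdMap ensembl_id values must be unique")
  if (anyDuplicated(m$primary_symbol)) lp_stop("IdMap primary_symbol values must be unique")
  class(m) <- unique(c("lp_idmap", class(m)))
  m
}

#' Read an identifier map from a delimited file
#'
#' Expects columns `ensembl_id`, `primary_symbol` (or `symbol`), optional
#' `aliases` (pipe-delimited within the cell) and `human_ortholog`.
#'
#' @param path CSV/TSV path (delimiter sniffed from the extension).
#' @return An `lp_idmap` tibble.
#' @export
read_idmap <- function(path) {
  if (!file.exists(path)) lp_stop_io(paste0("IdMap file not found: ", path))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"")
  if (!"primary_symbol" %in% names(df) && "symbol" %in% names(df)) {
    names(df)[names(df) == "symbol"] <- "primary_symbol"
  }
  id_map(df)
}

#' Define how a table links to genes
#'
#' @param kind One of `"symbol"`, `"ensembl"`, `"coords"`.
#' @param columns The column name carrying the key; for `kind = "coords"`,
#'   exactly three names (chrom, start, end).
#' @return An `lp_link_key`.
#' @export
link_key <- function(kind = c("symbol", "ensembl", "coords"), columns) {
  kind <- match.arg(kind)
  lp_assert(is.character(columns), "`columns` must be character")
  if (kind == "coords") {
    lp_assert(length(columns) == 3,
              "coords link key needs exactly three columns (chrom, start, end)")
  } else {
    lp_assert(length(columns) == 1,
              paste0(kind, " link key needs exactly one column"))
  }
  structure(list(kind = kind, columns = unname(columns)), class = "lp_link_key")
}

#' @export
print.lp_link_key <- function(x, ...) {
  cat("<link_key> ", x$kind, ": ", paste(x$columns, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Detect the linkable column(s) of an evidence table
#'
#' Any table can be attached as an evidence layer as long as it carries one
#' linkable key: a gene symbol column, an Ensembl ID column, or a genomic
#' coordinate triple. Detection precedence:
#'
#' 1. an explicit `override` always wins;
#' 2. a column whose non-missing values match the Ensembl gene ID pattern
#'    (`^ENS[A-Z]*G` + >= 6 digits) in at least 90% of rows;
#' 3. a case-insensitive `chr`/`start`/`end` column triple;
#' 4. a column named `gene_symbol`, `symbol`, or `gene`.
#'
#' Two Ensembl-like columns are ambiguous and raise an error requesting an
#' override; a table with no candidate raises an unlinkable-table error
#' listing its column names.
#'
#' @param table Evidence data frame (non-empty).
#' @param override Optional [link_key()] naming the key explicitly.
#' @return An `lp_link_key`.
#' @export
detect_link_key <- function(table, override = NULL) {
  lp_assert(is.data.frame(table), "`table` must be a data frame")
  if (!is.null(override)) {
    lp_assert(inherits(override, "lp_link_key"), "`override` must be a link_key()")
    missing_cols <- setdiff(override$columns, names(table))
    if (length(missing_cols) > 0) {
      lp_stop(paste0("override link key column(s) not in table: ",
                     paste(missing_cols, collapse = ", ")))
    }
    return(override)
  }

  ens_cols <- names(table)[vapply(table, function(col) {
    v <- as.character(col)
    v <- v[!is.na(v) & nzchar(v)]
    length(v) > 0 && mean(grepl(ENSEMBL_GENE_PATTERN, v)) >= 0.9
  }, logical(1))]
  if (length(ens_cols) == 1) return(link_key("ensembl", ens_cols))
  if (length(ens_cols) > 1) {
    lp_stop(paste0("ambiguous link key: columns ",
                   paste(ens_cols, collapse = ", "),
                   " all look like Ensembl IDs; pass an explicit link_key()"),
            class = "lp_ambiguous_link")
  }

  # an empty table carries no values to pattern-match; fall back to
  # conventional Ensembl column names so attaching it is still well defined
  if (nrow(table) == 0) {
    col_ens <- match_column(table, c("ensembl_id", "ensembl", "gene_id"))
    if (!is.na(col_ens)) return(link_key("ensembl", col_ens))
  }

  col_chr <- match_column(table, c("chr", "chrom", "chromosome", "seqnames"))
  col_start <- match_column(table, c("start", "start_bp", "bp_start", "pos"))
  col_end <- match_column(table, c("end", "end_bp", "bp_end", "stop"))
  if (!is.na(col_chr) && !is.na(col_start) && !is.na(col_end)) {
    return(link_key("coords", c(col_chr, col_start, col_end)))
  }

  col_sym <- match_column(table, c("gene_symbol", "symbol", "gene"))
  if (!is.na(col_sym)) return(link_key("symbol", col_sym))

  lp_stop(paste0("table is not linkable to genes: no Ensembl ID column, ",
                 "chr/start/end triple, or symbol column among: ",
                 paste(names(table), collapse = ", ")),
          class = "lp_unlinkable_table")
}

#' Resolve gene symbols against an IdMap
#'
#' Matching order per symbol: exact primary-symbol match (case-insensitive),
#' then a unique alias match. A symbol reachable through aliases of several
#' records is flagged `ambiguous` and never silently assigned; symbols
#' matching nothing are `unmapped` (a value, not an error).
#'
#' @param symbols Character vector of gene symbols.
#' @param idmap An [id_map()].
#' @return Tibble with `symbol`, `ensembl_id`, `status`
#'   (mapped/ambiguous/unmapped), plus a `report` attribute with the three
#'   counts (which always sum to `length(symbols)`).
#' @export
resolve_symbols <- function(symbols, idmap) {
  lp_assert(inherits(idmap, "lp_idmap"), "`idmap` must be an id_map()")
  symbols <- as.character(symbols)
  lower_primary <- tolower(idmap$primary_symbol)
  alias_tbl <- tibble(
    alias = tolower(unlist(idmap$aliases)),
    idx = rep(seq_len(nrow(idmap)), lengths(idmap$aliases))
  )

  resolve_one <- function(s) {
    if (is.na(s) || !nzchar(s)) return(c(NA_character_, "unmapped"))
    hit <- which(lower_primary == tolower(s))
    if (length(hit) == 1) return(c(idmap$ensembl_id[[hit]], "mapped"))
    if (length(hit) > 1) return(c(NA_character_, "ambiguous"))
    ali <- unique(alias_tbl$idx[alias_tbl$alias == tolower(s)])
    if (length(ali) == 1) return(c(idmap$ensembl_id[[ali]], "mapped"))
    if (length(ali) > 1) return(c(NA_character_, "ambiguous"))
    c(NA_character_, "unmapped")
  }

  res <- vapply(symbols, resolve_one, character(2), USE.NAMES = FALSE)
  out <- tibble(symbol = symbols, ensembl_id = res[1, ], status = res[2, ])
  attr(out, "report") <- c(
    mapped = sum(out$status == "mapped"),
    ambiguous = sum(out$status == "ambiguous"),
    unmapped = sum(out$status == "unmapped")
  )
  out
}

#' Fill annotation identifiers from an IdMap
#'
#' Fills in missing Ensembl IDs, symbols and human orthologs from the
#' IdMap. A gene never loses an identifier it already had: where the
#' annotation and IdMap disagree on an Ensembl ID the annotation's value is
#' kept and the conflict is listed in the report.
#'
#' @param annotation An `lp_annotation`.
#' @param idmap An [id_map()].
#' @return The updated annotation, with a `harmonize_report` attribute
#'   (counts of filled/unmapped/conflicts and the conflicting symbols).
#' @export
harmonize_annotation <- function(annotation, idmap) {
  lp_assert(inherits(annotation, "lp_annotation"),
            "`annotation` must be an lp_annotation")
  lp_assert(inherits(idmap, "lp_idmap"), "`idmap` must be an id_map()")
  ann <- annotation
  conflicts <- character()
  filled_ens <- 0L; filled_sym <- 0L; filled_orth <- 0L; unmapped <- 0L

  by_ens <- setNames(seq_len(nrow(idmap)), idmap$ensembl_id)
  res <- resolve_symbols(ann$gene_symbol, idmap)

  for (i in seq_len(nrow(ann))) {
    idx <- NA_integer_
    if (!is.na(ann$ensembl_id[[i]]) && ann$ensembl_id[[i]] %in% names(by_ens)) {
      idx <- by_ens[[ann$ensembl_id[[i]]]]
    } else if (res$status[[i]] == "mapped") {
      idx <- by_ens[[res$ensembl_id[[i]]]]
      if (!is.na(ann$ensembl_id[[i]]) &&
          ann$ensembl_id[[i]] != idmap$ensembl_id[[idx]]) {
        # annotation already carries a different Ensembl ID: keep it
        conflicts <- c(conflicts, ann$gene_symbol[[i]])
        idx <- NA_integer_
      }
    }
    if (is.na(idx)) {
      if (is.na(ann$ensembl_id[[i]]) || res$status[[i]] != "mapped") unmapped <- unmapped + 1L
      next
    }
    if (is.na(ann$ensembl_id[[i]])) {
      ann$ensembl_id[[i]] <- idmap$ensembl_id[[idx]]
      filled_ens <- filled_ens + 1L
    }
    if (is.na(ann$gene_symbol[[i]])) {
      ann$gene_symbol[[i]] <- idmap$primary_symbol[[idx]]
      filled_sym <- filled_sym + 1L
    }
    if (is.na(ann$human_ortholog[[i]]) && !is.na(idmap$human_ortholog[[idx]])) {
      ann$human_ortholog[[i]] <- idmap$human_ortholog[[idx]]
      filled_orth <- filled_orth + 1L
    }
  }
  # uids may change where Ensembl IDs were filled in
  ann$gene_uid <- ifelse(!is.na(ann$ensembl_id) & nzchar(ann$ensembl_id),
                         ann$ensembl_id, ann$gene_symbol)
  attr(ann, "harmonize_report") <- list(
    filled_ensembl = filled_ens, filled_symbol = filled_sym,
    filled_ortholog = filled_orth, unmapped = unmapped,
    conflicts = conflicts
  )
  ann
}
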