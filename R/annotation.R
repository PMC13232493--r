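# Gene annotation: one row per gene, dual identifiers, build-tagged.

ANNOTATION_COLS <- c("gene_uid", "gene_symbol", "ensembl_id", "chrom",
                     "start", "end", "strand", "biotype", "human_ortholog",
                     "expression_cpm")

#' Build a gene annotation table
#'
#' The annotation is the spine of every packet: one row per gene with both
#' identifiers (symbol and Ensembl ID — at least one required), 1-based
#' closed coordinates, strand, biotype, optional human ortholog symbol, and
#' optional expression level (cpm) in the study tissue or cell type. The
#' `gene_uid` column (Ensembl ID where present, else symbol) is the join
#' key used by evidence layers.
#'
#' @param genes Data frame with columns `gene_symbol`, `ensembl_id`,
#'   `chrom`, `start`, `end`, and optionally `strand` (`+`/`-`/`?`),
#'   `biotype`, `human_ortholog`, `expression_cpm`.
#' @param build A [genome_build()].
#' @return An `lp_annotation` tibble.
#' @export
gene_annotation <- function(genes, build) {
  lp_assert(is.data.frame(genes), "`genes` must be a data frame")
  if (!inherits(build, "genome_build")) build <- genome_build(build)
  g <- as_tibble(genes)

  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(g))
  if (length(missing_cols) > 0) {
    lp_stop(paste0("annotation lacks column(s): ",
                   paste(missing_cols, collapse = ", ")))
  }
  if (!"gene_symbol" %in% names(g)) g$gene_symbol <- NA_character_
  if (!"ensembl_id" %in% names(g)) g$ensembl_id <- NA_character_
  if (!"strand" %in% names(g)) g$strand <- "?"
  if (!"biotype" %in% names(g)) g$biotype <- NA_character_
  if (!"human_ortholog" %in% names(g)) g$human_ortholog <- NA_character_
  if (!"expression_cpm" %in% names(g)) g$expression_cpm <- NA_real_

  g$gene_symbol <- as.character(g$gene_symbol)
  g$ensembl_id <- as.character(g$ensembl_id)
  g$strand <- as.character(g$strand)
  g$strand[is.na(g$strand) | !(g$strand %in% c("+", "-"))] <- "?"
  g$start <- as.numeric(g$start)
  g$end <- as.numeric(g$end)
  g$expression_cpm <- as.numeric(g$expression_cpm)

  no_id <- (is.na(g$gene_symbol) | !nzchar(g$gene_symbol)) &
    (is.na(g$ensembl_id) | !nzchar(g$ensembl_id))
  if (any(no_id)) {
    lp_stop(paste0("annotation row(s) with neither gene_symbol nor ensembl_id: ",
                   paste(which(no_id), collapse = ", ")))
  }
  bad <- which(!is_whole(g$start) | !is_whole(g$end) | g$start < 1 | g$end < g$start)
  if (length(bad) > 0) {
    lp_stop(paste0("invalid gene coordinates in annotation row(s): ",
                   paste(bad, collapse = ", ")))
  }
  ens <- g$ensembl_id[!is.na(g$ensembl_id)]
  if (anyDuplicated(ens)) {
    lp_stop(paste0("duplicated ensembl_id in annotation: ",
                   paste(unique(ens[duplicated(ens)]), collapse = ", ")))
  }
  if (any(!is.na(g$expression_cpm) & g$expression_cpm < 0)) {
    lp_stop("expression_cpm must be non-negative")
  }

  g$gene_uid <- ifelse(!is.na(g$ensembl_id) & nzchar(g$ensembl_id),
                       g$ensembl_id, g$gene_symbol)
  if (anyDuplicated(g$gene_uid)) {
    lp_stop(paste0("duplicated gene identifier(s): ",
                   paste(unique(g$gene_uid[duplicated(g$gene_uid)]), collapse = ", ")))
  }
  g <- g[order(g$chrom, g$start, g$end), ANNOTATION_COLS]
  attr(g, "build") <- build
  class(g) <- unique(c("lp_annotation", class(g)))
  g
}

annotation_chrom_style <- function(annotation) {
  chrom_style(annotation$chrom)
}

#' Read a gene annotation from GTF or CSV
#'
#' GTF input keeps `gene` features only and maps the `gene_id`, `gene_name`
#' and `gene_biotype` attributes; CSV input expects the column names of
#' [gene_annotation()]. Coordinates in both are treated as 1-based closed
#' (the GTF convention). A BED-like table can be passed through
#' [gene_annotation()] manually after adding 1 to its starts.
#'
#' @param path Path to a `.gtf` or delimited text file.
#' @param build A [genome_build()] recorded on the result.
#' @param format `"auto"` (by extension), `"gtf"` or `"csv"`.
#' @return An `lp_annotation` tibble.
#' @export
read_annotation <- function(path, build, format = c("auto", "gtf", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) lp_stop_io(paste0("annotation file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "csv"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    df <- as.data.frame(gr)
    if ("type" %in% names(df)) df <- df[df$type == "gene", , drop = FALSE]
    genes <- tibble(
      gene_symbol = if ("gene_name" %in% names(df)) as.character(df$gene_name) else NA_character_,
      ensembl_id = if ("gene_id" %in% names(df)) as.character(df$gene_id) else NA_character_,
      chrom = as.character(df$seqnames),
      start = df$start,
      end = df$end,
      strand = as.character(df$strand),
      biotype = if ("gene_biotype" %in% names(df)) as.character(df$gene_biotype) else NA_character_
    )
  } else {
    genes <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  gene_annotation(genes, build)
}
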