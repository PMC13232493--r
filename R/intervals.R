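# Build-tagged genomic intervals, loci, and interval arithmetic.
#
# Coordinates are 1-based closed throughout the user-facing API (the
# convention of GWAS result tables and GTF annotation). BED-style
# half-open input is converted at read time, never stored.

#' Construct a genomic interval
#'
#' @param chrom Chromosome name (any style; see [parse_regions()] for style
#'   normalization).
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param build A [genome_build()].
#' @return A `genomic_interval` object.
#' @examples
#' genomic_interval("chr3", 131e6, 150e6, genome_build("mm39"))
#' @export
genomic_interval <- function(chrom, start, end, build) {
  lp_assert(is_string(chrom) && nzchar(chrom), "`chrom` must be a non-empty string")
  lp_assert(length(start) == 1 && is_whole(start),
            "`start` must be a single integer coordinate")
  lp_assert(length(end) == 1 && is_whole(end),
            "`end` must be a single integer coordinate")
  lp_assert(start >= 1, "`start` must be >= 1 (coordinates are 1-based)")
  lp_assert(end >= start, "`end` must be >= `start`")
  if (!inherits(build, "genome_build")) build <- genome_build(build)
  structure(
    list(chrom = chrom, start = as.numeric(start), end = as.numeric(end),
         build = build),
    class = "genomic_interval"
  )
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat("<genomic_interval> ", x$chrom, ":", format(x$start, scientific = FALSE),
      "-", format(x$end, scientific = FALSE), " [", x$build$name, "]\n", sep = "")
  invisible(x)
}

#' Interval width in megabases
#'
#' Width is reported as `(end - start) / 1e6` to one decimal, the convention
#' used when quoting GWAS locus spans (a 131-150 Mb locus "spans 19 Mb").
#' A point interval has width 0.
#'
#' @param interval A [genomic_interval()], or a loci table (in which case a
#'   width is returned per locus).
#' @return Numeric Mb width(s), rounded to one decimal.
#' @examples
#' b <- genome_build("mm39")
#' interval_width_mb(genomic_interval("chr3", 131000000, 150000000, b)) # 19
#' @export
interval_width_mb <- function(interval) {
  if (inherits(interval, "genomic_interval")) {
    return(round((interval$end - interval$start) / 1e6, 1))
  }
  if (is.data.frame(interval) && all(c("start", "end") %in% names(interval))) {
    return(round((interval$end - interval$start) / 1e6, 1))
  }
  lp_stop("`interval` must be a genomic_interval or a table with start/end")
}

# Chromosome style handling ---------------------------------------------------

# "chr"-prefixed ("chr3") vs plain ("3") naming. Mixed inputs are accepted
# and normalized to one style at parse time so overlap joins never miss.
chrom_style <- function(chroms) {
  chroms <- chroms[!is.na(chroms)]
  if (length(chroms) == 0) return("chr")
  if (mean(grepl("^chr", chroms, ignore.case = TRUE)) >= 0.5) "chr" else "plain"
}

normalize_chrom <- function(chroms, style = c("chr", "plain")) {
  style <- match.arg(style)
  bare <- sub("^[Cc][Hh][Rr]", "", chroms)
  if (style == "chr") paste0("chr", bare) else bare
}

# Internal: loci tibble constructor with class + build tag.
new_loci <- function(df, build) {
  df <- as_tibble(df)
  attr(df, "build") <- build
  class(df) <- unique(c("lp_loci", class(df)))
  df
}

#' Parse a region table into loci
#'
#' Reads a table of QTL intervals (one row per mapped peak interval, with
#' `chr`/`start`/`end` columns and an optional trait column) into a loci
#' table. Column matching is case-insensitive; both "chr3" and "3"
#' chromosome styles are accepted and normalized to `style`. Each locus gets
#' a slug identifier `locus_{chrom}_{startMb}_{endMb}` used for standardized
#' file naming, and rows are ordered deterministically by (chrom, start).
#'
#' @param table Data frame with chromosome/start/end columns (named `chr`,
#'   `chrom`, `chromosome` or `seqnames`; `start`; `end`, any case) and
#'   optionally `trait`/`traits`/`phenotype`.
#' @param build A [genome_build()] tagged onto the result.
#' @param style Target chromosome naming style: `"chr"` (chr-prefixed) or
#'   `"plain"`; pass the annotation's style so downstream joins line up.
#' @return An `lp_loci` tibble: `locus_id`, `chrom`, `start`, `end`,
#'   `traits` (list column), `peak_position`, `source_count`.
#' @examples
#' b <- genome_build("mm39")
#' parse_regions(data.frame(chr = "chr3", start = 131e6, end = 150e6), b)
#' @export
parse_regions <- function(table, build, style = c("chr", "plain")) {
  style <- match.arg(style)
  lp_assert(is.data.frame(table), "`table` must be a data frame")
  if (!inherits(build, "genome_build")) build <- genome_build(build)

  empty <- new_loci(
    tibble(locus_id = character(), chrom = character(), start = numeric(),
           end = numeric(), traits = list(), peak_position = numeric(),
           source_count = integer()),
    build
  )
  col_chr <- match_column(table, c("chr", "chrom", "chromosome", "seqnames"))
  col_start <- match_column(table, c("start", "start_bp", "bp_start"))
  col_end <- match_column(table, c("end", "end_bp", "bp_end", "stop"))
  if (is.na(col_chr)) lp_stop("region table lacks a chromosome column (chr/chrom/chromosome)")
  if (is.na(col_start)) lp_stop("region table lacks a `start` column")
  if (is.na(col_end)) lp_stop("region table lacks an `end` column")
  if (nrow(table) == 0) return(empty)

  col_trait <- match_column(table, c("trait", "traits", "phenotype"))
  col_peak <- match_column(table, c("peak", "peak_position", "peak_bp", "pos"))

  chrom <- normalize_chrom(as.character(table[[col_chr]]), style)
  start <- suppressWarnings(as.numeric(table[[col_start]]))
  end <- suppressWarnings(as.numeric(table[[col_end]]))

  bad <- which(is.na(start) | is.na(end) | !is_whole(start) | !is_whole(end))
  if (length(bad) > 0) {
    lp_stop(paste0("non-integer coordinates in region table row(s) ",
                   paste(bad, collapse = ", ")))
  }
  rev_rows <- which(start > end)
  if (length(rev_rows) > 0) {
    lp_stop(paste0("start > end in region table row(s) ",
                   paste(rev_rows, collapse = ", ")))
  }
  lp_assert(all(start >= 1), "coordinates must be >= 1 (1-based)")

  traits <- if (is.na(col_trait)) {
    rep(list(character()), nrow(table))
  } else {
    lapply(as.character(table[[col_trait]]), function(t) {
      if (is.na(t) || !nzchar(t)) character() else trimws(strsplit(t, "[;,|]")[[1]])
    })
  }
  peak <- if (is.na(col_peak)) rep(NA_real_, nrow(table)) else
    suppressWarnings(as.numeric(table[[col_peak]]))

  out <- tibble(
    chrom = chrom, start = start, end = end, traits = traits,
    peak_position = peak, source_count = 1L
  )
  out <- out[order(out$chrom, out$start, out$end), ]
  out$locus_id <- make_locus_ids(out$chrom, out$start, out$end)
  new_loci(out[, c("locus_id", "chrom", "start", "end", "traits",
                   "peak_position", "source_count")], build)
}

make_locus_ids <- function(chrom, start, end) {
  ids <- paste0("locus_", chrom, "_", fmt_mb(start), "_", fmt_mb(end))
  # slugs must be unique within a project; disambiguate deterministically
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  ids
}

loci_to_granges <- function(loci) {
  GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end)
  )
}

#' Merge overlapping loci
#'
#' GWAS scans of multiple related traits routinely call overlapping
#' intervals; for packet generation these are merged into distinct genomic
#' regions. Merging takes the bounding union of every maximal cluster of
#' transitively overlapping intervals (per chromosome), pools their traits,
#' and sums their `source_count`, so "49 significant loci" can become "20
#' distinct intervals". Two intervals separated by a positive gap merge only
#' if the gap (first bp after one interval to last bp before the next,
#' i.e. `start2 - end1`) is `<= max_gap`.
#'
#' The operation is idempotent and order-invariant.
#'
#' @param loci An `lp_loci` tibble from [parse_regions()].
#' @param max_gap Maximum inter-interval distance (bp) still merged;
#'   default 0 merges only genuinely overlapping intervals.
#' @return A merged `lp_loci` tibble, ordered by (chrom, start).
#' @export
merge_loci <- function(loci, max_gap = 0) {
  lp_assert(inherits(loci, "lp_loci"), "`loci` must come from parse_regions()")
  lp_assert(length(max_gap) == 1 && is_whole(max_gap) && max_gap >= 0,
            "`max_gap` must be a non-negative integer")
  build <- lp_build(loci)
  if (nrow(loci) <= 1) return(loci)

  gr <- loci_to_granges(loci)
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap

  merged <- tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = as.numeric(GenomicRanges::start(red)),
    end = as.numeric(GenomicRanges::end(red)),
    traits = lapply(revmap, function(idx)
      sort(unique(unlist(loci$traits[idx])))),
    peak_position = vapply(revmap, function(idx) {
      if (length(idx) == 1) loci$peak_position[[idx]] else NA_real_
    }, numeric(1)),
    source_count = vapply(revmap, function(idx)
      sum(loci$source_count[idx]), integer(1))
  )
  merged <- merged[order(merged$chrom, merged$start, merged$end), ]
  merged$locus_id <- make_locus_ids(merged$chrom, merged$start, merged$end)
  new_loci(merged[, c("locus_id", "chrom", "start", "end", "traits",
                      "peak_position", "source_count")], build)
}

#' Genes overlapping an interval
#'
#' Returns every gene in the annotation whose body shares at least 1 bp
#' with the query interval (any-overlap, strand-agnostic — the inclusive
#' default for candidate screens), sorted by start coordinate.
#'
#' @param annotation An `lp_annotation` table (see [gene_annotation()]).
#' @param interval A [genomic_interval()] on the same build.
#' @return The overlapping rows of `annotation`, sorted by `start`.
#' @export
genes_in_interval <- function(annotation, interval) {
  lp_assert(inherits(annotation, "lp_annotation"),
            "`annotation` must be an lp_annotation")
  lp_assert(inherits(interval, "genomic_interval"),
            "`interval` must be a genomic_interval")
  check_same_build(lp_build(annotation), interval$build,
                   "annotation and query interval")
  hit <- annotation$chrom == interval$chrom &
    annotation$start <= interval$end &
    annotation$end >= interval$start
  out <- annotation[hit, ]
  out[order(out$start), ]
}

#' Assign genes to loci
#'
#' Maps every gene in the annotation to the loci it overlaps (any-overlap).
#' A gene can legitimately sit in several loci when merged intervals on the
#' same chromosome remain disjoint but both cover it across traits; genes
#' overlapping no locus map to an empty character vector.
#'
#' @param annotation An `lp_annotation` table.
#' @param loci An `lp_loci` tibble on the same build.
#' @return Named list: `gene_uid` -> character vector of `locus_id`s.
#' @export
assign_loci <- function(annotation, loci) {
  lp_assert(inherits(annotation, "lp_annotation"),
            "`annotation` must be an lp_annotation")
  lp_assert(inherits(loci, "lp_loci"), "`loci` must be an lp_loci table")
  check_same_build(lp_build(annotation), lp_build(loci),
                   "annotation and loci")
  out <- setNames(rep(list(character()), nrow(annotation)),
                  annotation$gene_uid)
  if (nrow(loci) == 0 || nrow(annotation) == 0) return(out)
  gr_genes <- GenomicRanges::GRanges(annotation$chrom,
                                     IRanges::IRanges(annotation$start, annotation$end))
  gr_loci <- loci_to_granges(loci)
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_loci)
  for (k in seq_along(hits)) {
    g <- S4Vectors::queryHits(hits)[k]
    l <- S4Vectors::subjectHits(hits)[k]
    out[[g]] <- c(out[[g]], loci$locus_id[[l]])
  }
  out
}
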