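# Packet emission: per-locus merged gene sheets, summary statistics, and
# the multi-sheet workbook + figures bundle.

#' Generate the merged per-locus gene sheets
#'
#' Step 3 of the workflow. Builds the wide sheet (annotation columns, layer
#' columns in attachment order), evaluates the screening criteria, appends
#' one boolean column per criterion plus `evidence_count` and
#' `pass_required`, and writes one CSV per locus under
#' `outputs/sheets/`. Criteria referencing absent columns fail before any
#' file is written; re-running on identical inputs rewrites byte-identical
#' CSVs.
#'
#' @param project An `lp_project`.
#' @param criteria List of [criterion()] objects (may be empty).
#' @return List: `combined` (full sheet with result columns), `sheets`
#'   (named per-locus tibbles), `result` (the [evaluate_criteria()]
#'   result), `paths` (written CSVs).
#' @export
make_gene_sheet <- function(project, criteria = list()) {
  lp_assert(inherits(project, "lp_project"), "`project` must be an lp_project")
  sheet <- project_sheet(project)
  result <- evaluate_criteria(sheet, criteria)  # errors before any write

  collide <- intersect(names(result$table), names(sheet))
  if (length(collide) > 0) {
    lp_stop(paste0("criterion name(s) collide with sheet column(s): ",
                   paste(collide, collapse = ", ")))
  }
  combined <- dplyr::bind_cols(sheet, result$table)
  out_dir <- file.path(project$path, "outputs", "sheets")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (project$mode == "region") {
    ids <- project$loci$locus_id
    sheets <- setNames(lapply(ids, function(id) {
      combined[!is.na(combined$locus_id) & combined$locus_id == id, ,
               drop = FALSE]
    }), ids)
  } else {
    sheets <- list(genes = combined)
  }
  paths <- vapply(names(sheets), function(id) {
    p <- file.path(out_dir, paste0(id, "_complete.csv"))
    utils::write.csv(flatten_list_cols(sheets[[id]]), p, row.names = FALSE,
                     na = "")
    p
  }, character(1))
  list(combined = combined, sheets = sheets, result = result, paths = paths)
}

# List columns (e.g. pubmed id lists) render as ";"-joined cells in CSV
# and workbook sheets.
flatten_list_cols <- function(df) {
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(x) {
        if (length(x) == 0) NA_character_ else paste(x, collapse = ";")
      }, character(1))
    }
  }
  df
}

#' Summary statistics for a criteria screen
#'
#' Counts and integer percentages (round-half-away-from-zero, see
#' [percent_of()]) for a screen: how many genes passed the required
#' criteria, and how many satisfied each criterion. A screen of 2,149
#' genes with 950 passing reports 44%.
#'
#' @param result An [evaluate_criteria()] result.
#' @return An `lp_summary_stats` list: `n_total`, `n_pass_required`,
#'   `pct_pass_required`, and `per_criterion` (tibble of name, kind,
#'   n_true, pct).
#' @export
summarize_counts <- function(result) {
  lp_assert(inherits(result, "lp_criteria_result"),
            "`result` must come from evaluate_criteria()")
  tbl <- result$table
  n_total <- nrow(tbl)
  n_pass <- sum(tbl$pass_required)
  crit_names <- c(result$required, result$supportive)
  per_criterion <- tibble(
    name = crit_names,
    kind = c(rep("required", length(result$required)),
             rep("supportive", length(result$supportive))),
    n_true = vapply(crit_names, function(nm) sum(tbl[[nm]]), integer(1)),
    pct = percent_of(vapply(crit_names, function(nm) sum(tbl[[nm]]), integer(1)),
                     n_total)
  )
  structure(
    list(n_total = n_total, n_pass_required = n_pass,
         pct_pass_required = percent_of(n_pass, n_total),
         per_criterion = per_criterion),
    class = "lp_summary_stats"
  )
}

#' @export
print.lp_summary_stats <- function(x, ...) {
  cat("<summary> ", x$n_pass_required, " of ", x$n_total,
      " genes pass required criteria (",
      x$pct_pass_required %na% "NA", "%)\n", sep = "")
  if (nrow(x$per_criterion) > 0) print(x$per_criterion)
  invisible(x)
}

# Workbook sheet names are capped at 31 characters; collisions after
# truncation get a deterministic numeric suffix.
truncate_sheet_names <- function(names) {
  out <- substr(names, 1, 31)
  while (anyDuplicated(out)) {
    d <- which(duplicated(out))
    for (i in d) {
      k <- sum(out[seq_len(i)] == out[i])
      stem <- substr(names[i], 1, 31 - nchar(as.character(k)) - 1)
      out[i] <- paste0(stem, "_", k)
    }
  }
  out
}

#' Build the packet for one locus
#'
#' Emits the standardized per-locus review bundle under
#' `outputs/packets/<locus_id>/`: a multi-sheet workbook (sheets in fixed
#' order — Summary, Complete, any custom sheets, MouseMine, OpenTargets),
#' one CSV per sheet (the canonical output; the workbook renders the same
#' tables), and the figures (evidence-overlap UpSet; locus zoom when a
#' scan is attached). The Summary sheet records generation metadata,
#' criteria definitions, layer provenance and screen counts; the mined
#' sheets list each linked phenotype with PubMed IDs and the disease score.
#' Packets are identically structured across loci so they can be compared
#' side by side.
#'
#' @param project An `lp_project`.
#' @param locus_id Locus to emit (region mode), or `NULL` in gene mode.
#' @param sheet_data A [make_gene_sheet()] result for this project.
#' @param custom_sheets Optional named character vector of criteria
#'   expressions; each becomes a sheet subsetting Complete.
#' @param plots Render figures (default `TRUE`).
#' @return List with `dir`, `workbook` (path or `NA` if no workbook writer
#'   is available), `csvs`, `plots`, and `sheets` (the emitted tables).
#' @export
build_packet <- function(project, locus_id = NULL, sheet_data,
                         custom_sheets = NULL, plots = TRUE) {
  lp_assert(inherits(project, "lp_project"), "`project` must be an lp_project")
  if (project$mode == "region") {
    lp_assert(is_string(locus_id) && locus_id %in% project$loci$locus_id,
              "unknown locus_id for this project")
    complete <- sheet_data$sheets[[locus_id]]
    slug <- locus_id
    keep <- !is.na(sheet_data$combined$locus_id) &
      sheet_data$combined$locus_id == locus_id
  } else {
    complete <- sheet_data$sheets$genes
    slug <- "genes"
    keep <- rep(TRUE, nrow(sheet_data$combined))
  }
  result <- sheet_data$result

  # custom sheets: named criteria-expression subsets of Complete
  custom <- list()
  for (nm in names(custom_sheets)) {
    v <- evaluate_expression(custom_sheets[[nm]], complete)
    v[is.na(v)] <- FALSE
    custom[[nm]] <- complete[v, , drop = FALSE]
  }

  genes_here <- unique(complete$gene_uid)
  assoc <- project$mined$associations
  mousemine <- empty_associations()[, c("gene", "trait_label", "trait_id",
                                        "pubmed_ids")]
  opentargets <- empty_associations()[, c("gene", "trait_label", "trait_id",
                                          "disease_score", "pubmed_ids")]
  if (!is.null(assoc) && nrow(assoc) > 0) {
    here <- assoc[assoc$gene %in% genes_here, , drop = FALSE]
    mm <- here[here$source == "intermine", , drop = FALSE]
    ot <- here[here$source == "opentargets", , drop = FALSE]
    if (nrow(mm) > 0) mousemine <- mm[, c("gene", "trait_label", "trait_id",
                                          "pubmed_ids")]
    if (nrow(ot) > 0) opentargets <- ot[, c("gene", "trait_label", "trait_id",
                                            "disease_score", "pubmed_ids")]
  }

  stats <- summarize_counts(result)
  n_here <- nrow(complete)
  n_pass_here <- sum(complete$pass_required)
  crit_names <- vapply(result$criteria, function(c) c$name, character(1))
  crit_desc <- vapply(result$criteria, function(c)
    paste0("[", c$kind, "] ", c$expression), character(1))
  summary_sheet <- tibble(
    field = c("packet", "mode", "genome_build", "species", "tool_version",
              "generated_at", "genes_in_packet", "genes_passing_required",
              "pct_passing_required", "layers",
              if (length(crit_names)) paste0("criterion:", crit_names)),
    value = c(slug, project$mode, build_name(project$build),
              project$build$species,
              as.character(utils::packageVersion("locuspacket")),
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              as.character(n_here), as.character(n_pass_here),
              as.character(percent_of(n_pass_here, n_here) %na% "NA"),
              paste(names(project$layers), collapse = ";"),
              crit_desc)
  )

  sheets <- c(
    list(Summary = summary_sheet, Complete = complete),
    custom,
    list(MouseMine = mousemine, OpenTargets = opentargets)
  )
  names(sheets) <- truncate_sheet_names(names(sheets))

  pdir <- file.path(project$path, "outputs", "packets", slug)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  csvs <- vapply(names(sheets), function(nm) {
    p <- file.path(pdir, paste0(slug, "_", nm, ".csv"))
    utils::write.csv(flatten_list_cols(sheets[[nm]]), p, row.names = FALSE,
                     na = "")
    p
  }, character(1))

  wb_path <- file.path(pdir, paste0(slug, "_packet.xlsx"))
  wb <- write_workbook(lapply(sheets, flatten_list_cols), wb_path)

  plot_paths <- character()
  if (isTRUE(plots)) {
    oc <- overlap_counts(result_subset(result, keep))
    if (attr(oc, "n_genes") > 0 && length(result$supportive) > 0) {
      up <- file.path(pdir, paste0(slug, "_upset.png"))
      plot_upset(oc, out_path = up)
      plot_paths <- c(plot_paths, up)
    }
    if (!is.null(project$scan) && project$mode == "region") {
      loc <- project$loci[project$loci$locus_id == locus_id, ]
      window_scan <- project$scan[
        project$scan$chrom == loc$chrom &
          project$scan$position >= loc$start &
          project$scan$position <= loc$end, , drop = FALSE]
      if (nrow(window_scan) > 0) {
        lz <- file.path(pdir, paste0(slug, "_locuszoom.png"))
        plot_locus_zoom(
          scan = window_scan, threshold = project$scan_threshold,
          genes = complete,
          haplotype_effects = window_effects(project$haplotype_effects,
                                             loc$chrom, loc$start, loc$end),
          highlight = complete$gene_symbol[complete$pass_required],
          out_path = lz
        )
        plot_paths <- c(plot_paths, lz)
      }
    }
  }

  list(dir = pdir, workbook = wb, csvs = csvs, plots = plot_paths,
       sheets = sheets, stats = stats)
}

# Restrict a criteria result to a logical row subset (e.g. one locus).
result_subset <- function(result, keep) {
  structure(
    list(table = result$table[keep, , drop = FALSE],
         criteria = result$criteria, required = result$required,
         supportive = result$supportive),
    class = "lp_criteria_result"
  )
}

window_effects <- function(he, chrom, start, end) {
  if (is.null(he)) return(NULL)
  if (!inherits(he, "lp_haplotype_effects") && is.list(he)) {
    he <- he[[chrom]]
    if (is.null(he)) return(NULL)
  }
  keep <- he$positions >= start & he$positions <= end
  if (!any(keep)) return(NULL)
  haplotype_effects(he$positions[keep], he$effects[keep, , drop = FALSE],
                    he$founder_labels)
}

# --- Workbook rendering ------------------------------------------------------
#
# Sheets are serialized to typed JSON and rendered to .xlsx by a small
# openpyxl helper (shipped under inst/python). CSV stays the canonical
# output; if no `python` with openpyxl is on the PATH the workbook is
# skipped (returned as NA) and the CSVs stand alone.

workbook_available <- function() {
  python <- Sys.which("python")
  if (!nzchar(python)) return(FALSE)
  code <- suppressWarnings(system2(python, c("-c", shQuote("import openpyxl")),
                                   stdout = FALSE, stderr = FALSE))
  identical(code, 0L)
}

#' Write tables to a multi-sheet workbook
#'
#' Renders named data frames as the sheets of one `.xlsx` workbook, in
#' order. Cell types are preserved (numbers, booleans, text; `NA` becomes
#' an empty cell). Rendering is delegated to an openpyxl helper script run
#' through the `python` on the PATH.
#'
#' @param sheets Named list of data frames.
#' @param path Output `.xlsx` path.
#' @return The path, or `NA_character_` (with a warning) when no workbook
#'   renderer is available.
#' @export
write_workbook <- function(sheets, path) {
  lp_assert(is.list(sheets) && length(sheets) > 0 && !is.null(names(sheets)),
            "`sheets` must be a named list of data frames")
  bad <- names(sheets)[nchar(names(sheets)) > 31]
  if (length(bad) > 0) {
    lp_stop(paste0("sheet name(s) exceed 31 characters: ",
                   paste(bad, collapse = ", ")))
  }
  if (!workbook_available()) {
    warning("no workbook renderer available (python + openpyxl not found); ",
            "CSV sheets were still written")
    return(NA_character_)
  }
  payload <- list(sheets = lapply(names(sheets), function(nm) {
    df <- as.data.frame(sheets[[nm]])
    list(
      name = nm,
      columns = as.list(names(df)),
      types = as.list(unname(vapply(df, function(col) {
        if (is.logical(col)) "bool" else if (is.numeric(col)) "num" else "str"
      }, character(1)))),
      rows = lapply(seq_len(nrow(df)), function(i) {
        lapply(df[i, , drop = FALSE], function(v) {
          v <- v[[1]]
          if (is.na(v)) NULL else v
        })
      })
    )
  }))
  json_path <- tempfile(fileext = ".json")
  on.exit(unlink(json_path), add = TRUE)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                              digits = NA), json_path)
  script <- system.file("python", "write_xlsx.py", package = "locuspacket")
  code <- system2(Sys.which("python"), c(shQuote(script), shQuote(json_path),
                                         shQuote(path)),
                  stdout = FALSE, stderr = "")
  if (!identical(code, 0L) || !file.exists(path)) {
    lp_stop_io(paste0("workbook rendering failed for ", path))
  }
  path
}
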