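# Project lifecycle: the standardized directory, the gene-sheet spine,
# and project persistence.

PROJECT_DIRS <- c("inputs", "cache", "supplementary", "outputs")

#' Initialize an evidence-packet project
#'
#' Step 1 of the workflow. Validates the input table against the chosen
#' mode, creates the standardized project directory
#' (`inputs/`, `cache/`, `supplementary/`, `outputs/`), harmonizes gene
#' identifiers against the IdMap, resolves loci and per-locus gene
#' membership (region mode), and writes project metadata. Validation runs
#' before any directory is written, so a malformed input never leaves a
#' half-created project behind.
#'
#' @param path Project directory to create (refused if non-empty, unless
#'   `overwrite = TRUE`).
#' @param input Region mode: table with chr/start/end (+ optional trait)
#'   columns. Gene mode: table with a `gene_symbol` column.
#' @param mode `"region"` or `"gene"`.
#' @param build A [genome_build()]; every attached layer must match it.
#' @param annotation An `lp_annotation` on the same build.
#' @param idmap Optional [id_map()] used to harmonize identifiers.
#' @param max_gap Passed to [merge_loci()] (region mode).
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return An `lp_project`.
#' @export
init_project <- function(path, input, mode = c("region", "gene"), build,
                         annotation, idmap = NULL, max_gap = 0,
                         overwrite = FALSE) {
  mode <- match.arg(mode)
  lp_assert(is.data.frame(input), "`input` must be a data frame")
  if (!inherits(build, "genome_build")) build <- genome_build(build)
  lp_assert(inherits(annotation, "lp_annotation"),
            "`annotation` must be an lp_annotation")
  check_same_build(build, lp_build(annotation), "project and annotation")
  if (!is.null(idmap)) lp_assert(inherits(idmap, "lp_idmap"),
                                 "`idmap` must be an id_map()")

  # --- validate input shape and content before touching the filesystem ---
  if (!is.null(idmap)) annotation <- harmonize_annotation(annotation, idmap)
  if (mode == "region") {
    loci <- merge_loci(
      parse_regions(input, build, style = annotation_chrom_style(annotation)),
      max_gap = max_gap
    )
  } else {
    col_sym <- match_column(input, c("gene_symbol", "symbol", "gene"))
    if (is.na(col_sym)) {
      lp_stop("gene mode requires a `gene_symbol` column in the input table")
    }
    loci <- new_loci(parse_regions(data.frame(chr = character(),
                                              start = numeric(),
                                              end = numeric()), build), build)
  }

  if (dir.exists(path) && length(list.files(path, all.files = TRUE,
                                            no.. = TRUE)) > 0 && !overwrite) {
    lp_stop_io(paste0("project directory exists and is not empty: ", path,
                      " (pass overwrite = TRUE to reuse it)"))
  }
  for (d in PROJECT_DIRS) {
    dir.create(file.path(path, d), recursive = TRUE, showWarnings = FALSE)
  }

  # --- gene membership -------------------------------------------------
  if (mode == "region") {
    membership <- assign_loci(annotation, loci)
    spine <- dplyr::bind_rows(lapply(names(membership), function(uid) {
      ids <- membership[[uid]]
      if (length(ids) == 0) return(NULL)
      tibble(locus_id = ids, gene_uid = uid)
    }))
    if (is.null(spine) || nrow(spine) == 0) {
      spine <- tibble(locus_id = character(), gene_uid = character())
    }
  } else {
    syms <- as.character(input[[match_column(input, c("gene_symbol", "symbol", "gene"))]])
    uid_by_symbol <- setNames(annotation$gene_uid, tolower(annotation$gene_symbol))
    uid <- unname(uid_by_symbol[tolower(syms)])
    if (!is.null(idmap) && any(is.na(uid))) {
      res <- resolve_symbols(syms[is.na(uid)], idmap)
      ens <- res$ensembl_id
      ens[!ens %in% annotation$gene_uid] <- NA_character_
      uid[is.na(uid)] <- ens
    }
    spine <- tibble(locus_id = NA_character_, gene_uid = uid,
                    input_symbol = syms)
  }

  utils::write.csv(input, file.path(path, "inputs", "input_table.csv"),
                   row.names = FALSE)

  project <- structure(
    list(
      path = normalizePath(path),
      mode = mode,
      build = build,
      loci = loci,
      annotation = annotation,
      idmap = idmap,
      spine = spine,
      layers = list(),
      mined = list(associations = NULL, credible_sets = NULL),
      scan = NULL,
      haplotype_effects = NULL,
      metadata = list(
        created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        tool_version = as.character(utils::packageVersion("locuspacket")),
        mode = mode,
        build = build_name(build),
        species = build$species,
        n_input_rows = nrow(input),
        n_loci = nrow(loci),
        n_genes = length(unique(spine$gene_uid[!is.na(spine$gene_uid)]))
      )
    ),
    class = "lp_project"
  )
  write_project_metadata(project)
  project
}

write_project_metadata <- function(project) {
  meta <- project$metadata
  meta$harmonize_report <- attr(project$annotation, "harmonize_report")
  writeLines(
    jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE, null = "null"),
    file.path(project$path, "metadata.json")
  )
  invisible(project)
}

#' @export
print.lp_project <- function(x, ...) {
  cat("<lp_project> ", x$path, "\n",
      "  mode: ", x$mode, "   build: ", build_name(x$build), "\n",
      "  loci: ", nrow(x$loci), "   genes: ", x$metadata$n_genes, "\n",
      "  layers: ", if (length(x$layers) > 0)
        paste(names(x$layers), collapse = ", ") else "(none)", "\n",
      sep = "")
  invisible(x)
}

#' Attach GWAS scan and haplotype-effect tracks for plotting
#'
#' Stores the per-marker association scan (and optionally per-position
#' founder haplotype effects) on the project so [build_packet()] can render
#' locus-zoom figures. The significance threshold comes from the upstream
#' mapping (typically set by permutation) and is recorded, not computed.
#'
#' @param project An `lp_project`.
#' @param scan Scan table: `marker`, `chrom`, `position`, plus one numeric
#'   LOD column per condition.
#' @param threshold Genome-wide significance LOD threshold.
#' @param haplotype_effects Optional list per chromosome or single object
#'   from [haplotype_effects()].
#' @return The updated project.
#' @export
set_scan <- function(project, scan, threshold, haplotype_effects = NULL) {
  lp_assert(inherits(project, "lp_project"), "`project` must be an lp_project")
  validate_scan(scan)
  lp_assert(length(threshold) == 1 && is.numeric(threshold) && threshold >= 0,
            "`threshold` must be a non-negative number")
  project$scan <- as_tibble(scan)
  project$scan_threshold <- threshold
  project$haplotype_effects <- haplotype_effects
  project
}

validate_scan <- function(scan) {
  lp_assert(is.data.frame(scan), "`scan` must be a data frame")
  need <- c("marker", "chrom", "position")
  miss <- setdiff(need, names(scan))
  if (length(miss) > 0) {
    lp_stop(paste0("scan table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  lod_cols <- setdiff(names(scan), need)
  lp_assert(length(lod_cols) >= 1, "scan table needs at least one LOD column")
  for (nm in lod_cols) {
    lp_assert(is.numeric(scan[[nm]]) && all(scan[[nm]] >= 0, na.rm = TRUE),
              paste0("LOD column `", nm, "` must be non-negative numeric"))
  }
  invisible(TRUE)
}

#' Per-position founder haplotype effects
#'
#' Effect trajectories for the k founder haplotypes of a genetic reference
#' population (k = 8 for the Collaborative Cross): one effect estimate per
#' founder per genomic position, rendered as the middle track of a
#' locus-zoom figure.
#'
#' @param positions Ordered bp positions.
#' @param effects Numeric matrix, `length(positions)` rows x k columns.
#' @param founder_labels Character vector of k founder names.
#' @return An `lp_haplotype_effects`.
#' @export
haplotype_effects <- function(positions, effects, founder_labels) {
  effects <- as.matrix(effects)
  lp_assert(length(positions) == nrow(effects),
            "effects must have one row per position")
  lp_assert(ncol(effects) == length(founder_labels),
            "effects must have one column per founder label")
  lp_assert(all(is_whole(positions) & positions >= 1),
            "positions must be positive integers")
  lp_assert(!is.unsorted(positions), "positions must be ordered")
  structure(list(positions = as.numeric(positions), effects = effects,
                 founder_labels = as.character(founder_labels)),
            class = "lp_haplotype_effects")
}

#' Record mined associations and credible sets on a project
#'
#' @param project An `lp_project`.
#' @param associations Association tibble ([query_opentargets()] /
#'   [query_intermine()] output, possibly concatenated).
#' @param credible_sets Optional [query_qtl()] output.
#' @return The updated project.
#' @export
set_mined <- function(project, associations = NULL, credible_sets = NULL) {
  lp_assert(inherits(project, "lp_project"), "`project` must be an lp_project")
  if (!is.null(associations)) project$mined$associations <- associations
  if (!is.null(credible_sets)) project$mined$credible_sets <- credible_sets
  project
}

#' The merged per-gene sheet of a project
#'
#' Builds the wide gene sheet: one row per gene (x locus in region mode),
#' base annotation columns first, then every attached layer's prefixed
#' columns in attachment order. The join is a left join on the gene key:
#' attaching evidence never adds or removes sheet rows, and genes absent
#' from a layer carry missing values — screening logic needs absent
#' evidence to be visible as missingness.
#'
#' @param project An `lp_project`.
#' @param locus_id Optional locus filter.
#' @return The merged sheet tibble.
#' @export
project_sheet <- function(project, locus_id = NULL) {
  lp_assert(inherits(project, "lp_project"), "`project` must be an lp_project")
  ann <- as_tibble(project$annotation)
  base <- dplyr::left_join(project$spine, ann, by = "gene_uid")
  if (!is.null(locus_id)) {
    base <- base[!is.na(base$locus_id) & base$locus_id %in% locus_id, ,
                 drop = FALSE]
  }
  sheet <- base
  for (layer in project$layers) {
    sheet <- dplyr::left_join(sheet, layer$reduced, by = "gene_uid")
  }
  sheet
}

#' Save / load a project
#'
#' Projects persist as a single RDS under the project root so multi-step
#' (and command-line) workflows can resume; all human-readable outputs are
#' written separately as CSV/JSON.
#'
#' @param project An `lp_project`.
#' @return `save_project()` the project path, invisibly; `load_project()`
#'   the project.
#' @export
save_project <- function(project) {
  lp_assert(inherits(project, "lp_project"), "`project` must be an lp_project")
  saveRDS(project, file.path(project$path, "project.rds"))
  invisible(project$path)
}

#' @param path Project directory.
#' @rdname save_project
#' @export
load_project <- function(path) {
  f <- file.path(path, "project.rds")
  if (!file.exists(f)) {
    lp_stop(paste0("no project found at ", path,
                   " (expected ", f, "); run init first"))
  }
  readRDS(f)
}
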