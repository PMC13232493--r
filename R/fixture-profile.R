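# Canned fixture profiles: a complete, internally consistent set of
# pipeline inputs (annotation, regions, IdMap, evidence layers, scan,
# recorded API payloads, criteria) with a planted-truth manifest, plus a
# runner that drives the whole pipeline over a profile.

RELATED_TRAIT_PATTERNS <- c("cardi", "heart", "myocard")
EXPLICIT_TRAIT_PATTERNS <- c("cardiac hypertrophy")
CC_FOUNDERS <- c("AJ", "B6", "129S1", "NOD", "NZO", "CAST", "PWK", "WSB")

profile_criteria <- function() {
  list(
    criterion("protein_coding", 'biotype == "protein_coding"', "required"),
    criterion("has_human_ortholog", "!is_missing(human_ortholog)", "required"),
    criterion("expressed", "expression_cpm > 5", "required"),
    criterion("DE", "de.padj < 0.05", "supportive"),
    criterion("cis_eQTL", "!is_missing(eqtl.pval)", "supportive"),
    criterion("CC_variant", "!is_missing(variant.consequence)", "supportive"),
    criterion("trait_prior", "traits.n_hits > 0", "supportive")
  )
}

#' Generate a complete synthetic study profile
#'
#' Produces every input the pipeline consumes, mutually consistent and
#' fully deterministic under `seed`: a gene annotation (written as GTF),
#' a region table whose intervals overlap so locus merging is exercised,
#' an IdMap with aliases (including one deliberately ambiguous alias),
#' symbol-, Ensembl- and coordinate-linked evidence layers with planted
#' positives, a GWAS scan with planted peaks and founder haplotype
#' effects, a pre-seeded API payload cache, and the screening criteria.
#' The manifest records the planted truth — merged intervals, per-locus
#' gene membership, screened genes, per-criterion positives, and
#' evidence-overlap class counts — computed from the construction itself,
#' so a pipeline run over the profile can be checked exactly.
#'
#' The `"mini"` profile (2 chromosomes, 60 genes, 3 merged loci) is sized
#' for tests; `"cc_like"` mimics the shape of a Collaborative Cross
#' GWAS study (10 chromosomes, 20 merged loci, 8 founder haplotypes, two
#' conditions) for demonstrations — mined payloads there cover the first
#' locus only.
#'
#' @param dir Directory to write the profile files into.
#' @param profile `"mini"` or `"cc_like"`.
#' @param seed RNG seed; one seed fixes every file byte-for-byte.
#' @return List: file paths (`paths`), in-memory objects (`annotation`,
#'   `regions`, `idmap`, `layers`, `scan`, `haplotype_effects`,
#'   `criteria`), mining config (`mined_genes`, `cache_dir`, endpoints,
#'   `patterns`), and the planted-truth `manifest`.
#' @export
fixture_profile <- function(dir, profile = c("mini", "cc_like"), seed = 1) {
  profile <- match.arg(profile)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  cfg <- if (profile == "mini") {
    list(n_chrom = 2, gpc = 30,
         # per-chromosome gene index ranges covered by input regions;
         # the two chr1 regions overlap and merge into one locus
         regions = list(
           list(chrom = 1, j1 = 5, j2 = 14, trait = "EF"),
           list(chrom = 1, j1 = 10, j2 = 19, trait = "HW"),
           list(chrom = 2, j1 = 3, j2 = 12, trait = "EF"),
           list(chrom = 2, j1 = 20, j2 = 24, trait = "HR")
         ),
         merged = list(
           list(chrom = 1, j1 = 5, j2 = 19, source_count = 2L),
           list(chrom = 2, j1 = 3, j2 = 12, source_count = 1L),
           list(chrom = 2, j1 = 20, j2 = 24, source_count = 1L)
         ),
         plant_de = c(3L, 2L, 0L), plant_eqtl = c(2L, 1L, 1L),
         plant_var = c(2L, 2L, 0L), plant_trait = c(2L, 1L, 1L),
         mine_loci = 1:3, page_size = 2L)
  } else {
    regions <- list(); merged <- list()
    for (ci in 1:10) {
      regions[[length(regions) + 1]] <- list(chrom = ci, j1 = 5, j2 = 104,
                                             trait = "EF")
      regions[[length(regions) + 1]] <- list(chrom = ci, j1 = 110, j2 = 209,
                                             trait = "HW")
      merged[[length(merged) + 1]] <- list(chrom = ci, j1 = 5, j2 = 104,
                                           source_count = 1L)
      merged[[length(merged) + 1]] <- list(chrom = ci, j1 = 110, j2 = 209,
                                           source_count = 1L)
    }
    list(n_chrom = 10, gpc = 215, regions = regions, merged = merged,
         plant_de = rep(c(3L, 2L), 10), plant_eqtl = rep(c(2L, 1L), 10),
         plant_var = rep(c(3L, 2L), 10), plant_trait = rep(c(2L, 1L), 10),
         mine_loci = 1L, page_size = 25L)
  }

  ann_fix <- make_annotation(
    n_chrom = cfg$n_chrom, genes_per_chrom = cfg$gpc,
    fraction_protein_coding = 0.8, fraction_with_ortholog = 0.74,
    fraction_expressed = 0.6, seed = seed,
    gtf_path = file.path(dir, "annotation.gtf")
  )
  ann <- ann_fix$annotation
  flags <- ann_fix$manifest$genes
  screened_uid <- flags$gene_uid[flags$protein_coding & flags$has_ortholog &
                                   flags$expressed]

  # gene_uid vector for chromosome `ci`, per-chromosome indices j1..j2
  uid_range <- function(ci, j1, j2) {
    sprintf("ENSMUSG%011d", ((ci - 1) * cfg$gpc) + (j1:j2))
  }
  gene_row <- function(uid) match(uid, ann$gene_uid)
  region_bounds <- function(ci, j1, j2) {
    uids <- uid_range(ci, j1, j2)
    r <- gene_row(uids)
    c(max(1, ann$start[r[1]] - 500), ann$end[r[length(r)]] + 500)
  }

  regions_tbl <- dplyr::bind_rows(lapply(cfg$regions, function(rg) {
    b <- region_bounds(rg$chrom, rg$j1, rg$j2)
    tibble(chr = paste0("chr", rg$chrom), start = b[1], end = b[2],
           trait = rg$trait)
  }))

  loci_truth <- dplyr::bind_rows(lapply(cfg$merged, function(m) {
    b <- region_bounds(m$chrom, m$j1, m$j2)
    uids <- uid_range(m$chrom, m$j1, m$j2)
    tibble(chrom = paste0("chr", m$chrom), start = b[1], end = b[2],
           source_count = m$source_count,
           gene_uids = list(uids),
           screened = list(intersect(uids, screened_uid)))
  }))

  # plant layer positives among the screened genes of each locus, with
  # offsets so the evidence sets overlap partially (interesting UpSet)
  pick <- function(pool, k, offset) {
    if (length(pool) == 0 || k == 0) return(character())
    idx <- ((offset + seq_len(min(k, length(pool))) - 1) %% length(pool)) + 1
    unique(pool[idx])
  }
  plant <- list(de = character(), eqtl = character(), variant = character(),
                trait = character())
  for (i in seq_len(nrow(loci_truth))) {
    pool <- loci_truth$screened[[i]]
    plant$de <- c(plant$de, pick(pool, cfg$plant_de[i], 0))
    plant$eqtl <- c(plant$eqtl, pick(pool, cfg$plant_eqtl[i], 1))
    plant$variant <- c(plant$variant, pick(pool, cfg$plant_var[i], 2))
    plant$trait <- c(plant$trait, pick(pool, cfg$plant_trait[i], 3))
  }

  layers <- make_evidence_layers(
    ann, plant = list(de = plant$de, eqtl = plant$eqtl,
                      variant = plant$variant),
    seed = seed + 1
  )

  # IdMap: every gene, aliases for the first five, one deliberately
  # ambiguous alias shared by genes 2 and 3, orthologs as annotated
  aliases <- rep(list(character()), nrow(ann))
  ord <- order(ann$ensembl_id)
  for (k in 1:5) aliases[[ord[k]]] <- paste0(ann$gene_symbol[ord[k]], "-ali")
  aliases[[ord[2]]] <- c(aliases[[ord[2]]], "SharedAlias")
  aliases[[ord[3]]] <- c(aliases[[ord[3]]], "SharedAlias")
  idmap <- id_map(tibble(
    ensembl_id = ann$ensembl_id, primary_symbol = ann$gene_symbol,
    aliases = aliases, human_ortholog = ann$human_ortholog
  ))

  # scan + haplotype effects
  chrom_sizes <- vapply(split(ann$end, ann$chrom), max, numeric(1)) + 5e4
  scan_spec <- dplyr::bind_rows(lapply(seq_len(nrow(loci_truth)), function(i) {
    tibble(chrom = loci_truth$chrom[i], start = loci_truth$start[i],
           end = loci_truth$end[i],
           condition = "ISO", peak_lod = 8)
  }))
  scan <- make_scan(scan_spec, conditions = c("ISO", "Ctrl"),
                    chrom_sizes = chrom_sizes, markers_per_chrom = 120,
                    threshold = 6, seed = seed + 2)
  l1 <- loci_truth[1, ]
  l1_pos <- sort(scan$position[scan$chrom == l1$chrom &
                                 scan$position >= l1$start &
                                 scan$position <= l1$end])
  he <- with_seed(seed + 3, haplotype_effects(
    positions = l1_pos,
    effects = matrix(round(stats::rnorm(length(l1_pos) * 8, 0, 1), 3),
                     ncol = 8),
    founder_labels = CC_FOUNDERS
  ))

  # recorded API payloads for the genes of the mined loci
  mined_genes <- sort(unique(unlist(
    loci_truth$gene_uids[cfg$mine_loci])))
  api_plant <- list()
  for (uid in plant$trait) {
    api_plant[[uid]] <- list(n_diseases = 3L, n_cardiac = 2L,
                             n_phenotypes = 2L, phenotype_cardiac = TRUE,
                             l2g = c(0.9, 0.4, 0.6))
  }
  # a couple of genes with only non-cardiac annotation, and one paginated
  noise <- setdiff(mined_genes, plant$trait)
  if (length(noise) >= 2) {
    api_plant[[noise[1]]] <- list(n_diseases = 2L, n_cardiac = 0L,
                                  n_phenotypes = 1L)
    api_plant[[noise[2]]] <- list(n_diseases = 5L, n_cardiac = 0L,
                                  n_phenotypes = 0L)
  }
  cache_dir <- file.path(dir, "cache")
  api_manifest <- make_api_fixtures(
    mined_genes, plant = api_plant, cache_dir = cache_dir, seed = seed + 4,
    page_size = cfg$page_size
  )

  criteria <- profile_criteria()
  trait_uid <- intersect(plant$trait, mined_genes)

  # expected UpSet classes over screened gene x locus rows, from the
  # planted sets alone
  supportive_sets <- list(DE = plant$de, cis_eQTL = plant$eqtl,
                          CC_variant = plant$variant, trait_prior = trait_uid)
  keys <- character()
  for (i in seq_len(nrow(loci_truth))) {
    for (uid in loci_truth$screened[[i]]) {
      members <- names(supportive_sets)[vapply(supportive_sets,
                                               function(s) uid %in% s,
                                               logical(1))]
      keys <- c(keys, paste(members, collapse = "&"))
    }
  }
  upset_truth <- table(keys)

  # write file renditions for the command-line workflow
  paths <- list(
    annotation = file.path(dir, "annotation.gtf"),
    annotation_csv = file.path(dir, "annotation.csv"),
    regions = file.path(dir, "regions.csv"),
    idmap = file.path(dir, "idmap.csv"),
    de = file.path(dir, "de.csv"),
    eqtl = file.path(dir, "eqtl.csv"),
    variants = file.path(dir, "variants.csv"),
    scan = file.path(dir, "scan.csv"),
    criteria = file.path(dir, "criteria.yaml"),
    cache = cache_dir
  )
  utils::write.csv(regions_tbl, paths$regions, row.names = FALSE)
  # CSV rendition keeps expression_cpm, which GTF cannot carry
  utils::write.csv(as.data.frame(ann)[, setdiff(ANNOTATION_COLS, "gene_uid")],
                   paths$annotation_csv, row.names = FALSE)
  idmap_flat <- idmap
  idmap_flat$aliases <- vapply(idmap$aliases, paste, character(1),
                               collapse = "|")
  utils::write.csv(as.data.frame(idmap_flat)[, c("ensembl_id",
                                                 "primary_symbol", "aliases",
                                                 "human_ortholog")],
                   paths$idmap, row.names = FALSE)
  utils::write.csv(layers$de, paths$de, row.names = FALSE)
  utils::write.csv(layers$eqtl, paths$eqtl, row.names = FALSE)
  utils::write.csv(layers$variants, paths$variants, row.names = FALSE)
  utils::write.csv(scan, paths$scan, row.names = FALSE)
  yaml::write_yaml(lapply(criteria, function(cr)
    list(name = cr$name, kind = cr$kind, expression = cr$expression)),
    paths$criteria)

  list(
    profile = profile, seed = seed, dir = dir, paths = paths,
    build = genome_build("mm39", "Mus musculus"),
    annotation = ann, regions = regions_tbl, idmap = idmap,
    layers = layers[c("de", "eqtl", "variants")],
    scan = scan, scan_threshold = 6, haplotype_effects = he,
    criteria = criteria,
    mined_genes = mined_genes, cache_dir = cache_dir,
    endpoint = OT_DEFAULT_ENDPOINT,
    mine_url = "https://www.mousemine.org/mousemine/service",
    page_size = cfg$page_size,
    patterns = list(explicit = EXPLICIT_TRAIT_PATTERNS,
                    related = RELATED_TRAIT_PATTERNS),
    manifest = list(
      seed = seed,
      loci = loci_truth,
      n_gene_locus_rows = sum(lengths(loci_truth$gene_uids)),
      n_screened_rows = sum(lengths(loci_truth$screened)),
      planted = plant,
      trait_positive = trait_uid,
      layer_manifest = layers$manifest,
      api = api_manifest,
      upset = setNames(as.integer(upset_truth), names(upset_truth))
    )
  )
}

#' Run the full pipeline over a fixture profile
#'
#' Drives the three workflow steps end to end: initialize the project from
#' the profile's regions and annotation, attach the three evidence layers,
#' mine the recorded payload cache and attach the trait-link layer
#' (related-pass filter, per-gene hit counts), attach the scan, and
#' generate the gene sheets. Everything is offline and deterministic.
#'
#' @param profile A [fixture_profile()] result.
#' @param path Project directory to create.
#' @param overwrite Passed to [init_project()].
#' @return List: `project`, `sheet_data` (from [make_gene_sheet()]).
#' @export
run_fixture_pipeline <- function(profile, path, overwrite = FALSE) {
  project <- init_project(
    path, profile$regions, mode = "region", build = profile$build,
    annotation = profile$annotation, idmap = profile$idmap,
    overwrite = overwrite
  )
  project <- attach_layer(project, profile$layers$de, "de",
                          build = profile$build)
  project <- attach_layer(project, profile$layers$eqtl, "eqtl",
                          build = profile$build)
  project <- attach_layer(project, profile$layers$variants, "variant",
                          build = profile$build)

  assoc <- dplyr::bind_rows(
    query_opentargets(profile$mined_genes, sections = "diseases",
                      cache_dir = profile$cache_dir, offline = TRUE,
                      endpoint = profile$endpoint,
                      page_size = profile$page_size),
    query_intermine(profile$mined_genes, mine_url = profile$mine_url,
                    cache_dir = profile$cache_dir, offline = TRUE)
  )
  credible <- query_qtl(profile$mined_genes, min_l2g = 0.5,
                        cache_dir = profile$cache_dir, offline = TRUE,
                        endpoint = profile$endpoint)
  project <- set_mined(project, associations = assoc,
                       credible_sets = credible)

  related <- filter_traits(assoc, profile$patterns, pass = "related")
  hits <- table(factor(related$gene, levels = profile$mined_genes))
  traits_tbl <- tibble(gene_id = profile$mined_genes,
                       n_hits = as.integer(hits))
  project <- attach_layer(project, traits_tbl, "traits")

  project <- set_scan(project, profile$scan, profile$scan_threshold,
                      profile$haplotype_effects)
  sheet_data <- make_gene_sheet(project, profile$criteria)
  save_project(project)
  list(project = project, sheet_data = sheet_data)
}
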