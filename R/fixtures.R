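# Deterministic synthetic-data generator. Every input the pipeline
# consumes can be generated here with planted ground truth, recorded in a
# manifest, so end-to-end counts are exactly checkable. Fixtures plant
# outcomes; they do not simulate genetics (no LD, no genotypes).

CARDIAC_TRAIT_POOL <- c(
  "cardiac hypertrophy", "dilated cardiomyopathy", "heart failure",
  "abnormal myocardial fiber morphology", "increased heart weight"
)
OTHER_TRAIT_POOL <- c(
  "asthma", "type 2 diabetes", "short stature", "abnormal gait",
  "hearing loss", "cataract"
)

#' Generate a synthetic gene annotation
#'
#' Lays out non-overlapping genes along `n_chrom` chromosomes with a
#' controlled composition of biotypes, human-ortholog presence, and
#' expression above the 5 cpm screening threshold. Fraction-times-count
#' products are rounded to integers; the manifest records both the
#' requested fractions and the exact realized counts. The same seed
#' reproduces byte-identical output (including the GTF, if written).
#'
#' @param n_chrom Number of chromosomes.
#' @param genes_per_chrom Genes per chromosome.
#' @param fraction_protein_coding Fraction of protein-coding genes.
#' @param fraction_with_ortholog Fraction with a human ortholog.
#' @param fraction_expressed Fraction expressed above 5 cpm.
#' @param seed RNG seed.
#' @param build A [genome_build()] (default a synthetic mouse build).
#' @param gtf_path Optional path: write the annotation as a GTF file.
#' @return List: `annotation` (an `lp_annotation`), `manifest` (per-gene
#'   flags + realized counts), `gtf_path`.
#' @export
make_annotation <- function(n_chrom = 2, genes_per_chrom = 50,
                            fraction_protein_coding = 0.8,
                            fraction_with_ortholog = 0.74,
                            fraction_expressed = 0.6,
                            seed = 1,
                            build = genome_build("mm39", "Mus musculus"),
                            gtf_path = NULL) {
  lp_assert(all(c(fraction_protein_coding, fraction_with_ortholog,
                  fraction_expressed) >= 0 &
                  c(fraction_protein_coding, fraction_with_ortholog,
                    fraction_expressed) <= 1),
            "fractions must be in [0, 1]")
  n <- n_chrom * genes_per_chrom
  if (n == 0) {
    ann <- gene_annotation(
      tibble(gene_symbol = character(), ensembl_id = character(),
             chrom = character(), start = numeric(), end = numeric()),
      build)
    return(list(annotation = ann,
                manifest = list(n_genes = 0L,
                                genes = tibble(gene_uid = character())),
                gtf_path = NULL))
  }

  with_seed(seed, {
    genes <- dplyr::bind_rows(lapply(seq_len(n_chrom), function(ci) {
      len <- sample(5000:80000, genes_per_chrom, replace = TRUE)
      gap <- sample(2000:50000, genes_per_chrom, replace = TRUE)
      end <- cumsum(len + gap)
      start <- end - len + 1
      tibble(chrom = paste0("chr", ci), start = start, end = end,
             strand = sample(c("+", "-"), genes_per_chrom, replace = TRUE))
    }))
    idx <- seq_len(n)
    genes$gene_symbol <- sprintf("Smg%04d", idx)
    genes$ensembl_id <- sprintf("ENSMUSG%011d", idx)

    n_pc <- round(fraction_protein_coding * n)
    n_orth <- round(fraction_with_ortholog * n)
    n_expr <- round(fraction_expressed * n)
    pc <- sort(sample(idx, n_pc))
    orth <- sort(sample(idx, n_orth))
    expr <- sort(sample(idx, n_expr))

    genes$biotype <- ifelse(idx %in% pc, "protein_coding",
                            sample(c("lincRNA", "processed_pseudogene"),
                                   n, replace = TRUE))
    genes$human_ortholog <- ifelse(idx %in% orth,
                                   toupper(genes$gene_symbol), NA_character_)
    genes$expression_cpm <- round(ifelse(idx %in% expr,
                                         stats::runif(n, 5.5, 250),
                                         stats::runif(n, 0, 4.5)), 3)
    ann <- gene_annotation(genes, build)
    manifest <- list(
      seed = seed,
      n_genes = n,
      requested = list(protein_coding = fraction_protein_coding,
                       with_ortholog = fraction_with_ortholog,
                       expressed = fraction_expressed),
      n_protein_coding = n_pc,
      n_with_ortholog = n_orth,
      n_expressed = n_expr,
      genes = tibble(
        gene_uid = ann$gene_uid,
        protein_coding = ann$biotype == "protein_coding",
        has_ortholog = !is.na(ann$human_ortholog),
        expressed = ann$expression_cpm > 5
      )
    )
    if (!is.null(gtf_path)) write_gtf(ann, gtf_path)
    list(annotation = ann, manifest = manifest, gtf_path = gtf_path)
  })
}

#' Write an annotation as a GTF file
#'
#' Emits gene features with `gene_id`, `gene_name` and `gene_biotype`
#' attributes. The writer is deliberately free of run-dependent headers so
#' regeneration under one seed is byte-identical.
#'
#' @param annotation An `lp_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  lp_assert(inherits(annotation, "lp_annotation"),
            "`annotation` must be an lp_annotation")
  strand <- ifelse(annotation$strand %in% c("+", "-"), annotation$strand, ".")
  attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                   annotation$ensembl_id, annotation$gene_symbol,
                   annotation$biotype %na% "")
  lines <- sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   annotation$chrom, as.integer(annotation$start),
                   as.integer(annotation$end), strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic GWAS scan with planted peaks
#'
#' Produces a marker table with background LOD safely below the stated
#' significance threshold and, inside each specified interval, a smooth
#' peak for its designated condition rising to the requested LOD. The
#' threshold emulates a permutation-derived genome-wide cutoff; it is an
#' input here, never computed.
#'
#' @param loci_spec Data frame: `chrom`, `start`, `end`, `condition`,
#'   `peak_lod` (one planted peak per row; may be empty).
#' @param conditions All condition names (columns of the scan).
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param markers_per_chrom Markers per chromosome.
#' @param threshold Significance threshold the background stays below.
#' @param seed RNG seed.
#' @return Scan tibble: `marker`, `chrom`, `position`, one LOD column per
#'   condition.
#' @export
make_scan <- function(loci_spec, conditions, chrom_sizes,
                      markers_per_chrom = 200, threshold = 6, seed = 1) {
  lp_assert(is.data.frame(loci_spec), "`loci_spec` must be a data frame")
  if (nrow(loci_spec) > 0) {
    need <- c("chrom", "start", "end", "condition", "peak_lod")
    miss <- setdiff(need, names(loci_spec))
    lp_assert(length(miss) == 0,
              paste0("loci_spec lacks column(s): ", paste(miss, collapse = ", ")))
    for (i in seq_len(nrow(loci_spec))) {
      size <- chrom_sizes[[loci_spec$chrom[[i]]]]
      if (is.null(size) || is.na(size) || loci_spec$end[[i]] > size) {
        lp_stop(paste0("planted interval outside chromosome span in row ", i))
      }
    }
    lp_assert(all(loci_spec$condition %in% conditions),
              "every planted condition must appear in `conditions`")
  }
  with_seed(seed, {
    scan <- dplyr::bind_rows(lapply(names(chrom_sizes), function(ch) {
      pos <- sort(sample(seq_len(chrom_sizes[[ch]]), markers_per_chrom))
      tibble(marker = sprintf("%s_m%04d", ch, seq_len(markers_per_chrom)),
             chrom = ch, position = pos)
    }))
    for (cond in conditions) {
      lod <- stats::runif(nrow(scan), 0, 0.5 * threshold)
      if (nrow(loci_spec) > 0) {
        for (i in seq_len(nrow(loci_spec))) {
          if (loci_spec$condition[[i]] != cond) next
          inw <- scan$chrom == loci_spec$chrom[[i]] &
            scan$position >= loci_spec$start[[i]] &
            scan$position <= loci_spec$end[[i]]
          if (!any(inw)) next
          center <- (loci_spec$start[[i]] + loci_spec$end[[i]]) / 2
          width <- (loci_spec$end[[i]] - loci_spec$start[[i]]) / 4
          bump <- loci_spec$peak_lod[[i]] *
            exp(-((scan$position[inw] - center)^2) / (2 * width^2))
          # guarantee the peak reaches the planted LOD at the nearest marker
          nearest <- which.min(abs(scan$position[inw] - center))
          bump[nearest] <- loci_spec$peak_lod[[i]]
          lod[inw] <- pmax(lod[inw], bump)
        }
      }
      scan[[cond]] <- round(lod, 4)
    }
    scan
  })
}

#' Generate synthetic evidence layers with planted positives
#'
#' Builds the three canonical study-specific evidence tables, each linked
#' by a deliberately different key so link-key auto-detection is
#' exercised: a differential-expression table linked by gene symbol, an
#' eQTL table linked by Ensembl ID, and a coding-variant table linked by
#' genomic coordinates. Exactly the planted genes satisfy each layer's
#' headline criterion (`de.padj < 0.05`; an eQTL record present; at least
#' one protein-altering variant row); some planted genes carry multiple
#' rows to exercise duplicate reduction.
#'
#' @param annotation An `lp_annotation`.
#' @param plant List with `de`, `eqtl`, `variant`: character vectors of
#'   `gene_uid`s to plant (must exist in the annotation).
#' @param seed RNG seed.
#' @param n_background_de Non-significant DE rows added for realism.
#' @return List: `de`, `eqtl`, `variants` tables and `manifest` (planted
#'   sets plus per-gene expected `n_records`).
#' @export
make_evidence_layers <- function(annotation, plant, seed = 1,
                                 n_background_de = 20) {
  lp_assert(inherits(annotation, "lp_annotation"),
            "`annotation` must be an lp_annotation")
  plant <- list(de = plant$de %||% character(),
                eqtl = plant$eqtl %||% character(),
                variant = plant$variant %||% character())
  for (nm in names(plant)) {
    unknown <- setdiff(plant[[nm]], annotation$gene_uid)
    if (length(unknown) > 0) {
      lp_stop(paste0("planted ", nm, " gene(s) not in annotation: ",
                     paste(unknown, collapse = ", ")))
    }
  }
  uid_row <- match(plant$variant, annotation$gene_uid)

  with_seed(seed, {
    # DE: symbol-linked; planted genes significant, background rows not
    bg_pool <- setdiff(annotation$gene_uid, plant$de)
    bg <- sort(sample(bg_pool, min(n_background_de, length(bg_pool))))
    de_uids <- c(plant$de, bg)
    de_rows <- match(de_uids, annotation$gene_uid)
    de <- tibble(
      gene_symbol = annotation$gene_symbol[de_rows],
      logFC = round(stats::rnorm(length(de_uids), 0, 2), 3),
      pval = round(c(stats::runif(length(plant$de), 1e-6, 1e-3),
                     stats::runif(length(bg), 0.1, 0.9)), 6),
      padj = round(c(stats::runif(length(plant$de), 1e-4, 0.049),
                     stats::runif(length(bg), 0.06, 0.95)), 6)
    )

    # eQTL: Ensembl-linked; only planted genes present; later half of the
    # planted set gets a second SNP row (reduction keeps the min p)
    dup_eqtl <- plant$eqtl[seq_len(length(plant$eqtl)) > length(plant$eqtl) / 2]
    eq_uids <- c(plant$eqtl, dup_eqtl)
    eqtl <- tibble(
      gene_id = eq_uids,
      snp = sprintf("rs%06d", sample.int(999999, length(eq_uids))),
      pval = round(stats::runif(length(eq_uids), 1e-8, 1e-3), 10),
      beta = round(stats::rnorm(length(eq_uids), 0, 1), 3)
    )

    # variants: coordinate-linked; first planted gene gets 3 rows
    n_rows_per <- rep(1L, length(plant$variant))
    if (length(n_rows_per) > 0) n_rows_per[1] <- 3L
    var_rows <- rep(seq_along(plant$variant), n_rows_per)
    vr <- uid_row[var_rows]
    vpos <- vapply(vr, function(r)
      sample(seq(annotation$start[r], annotation$end[r]), 1), numeric(1))
    variants <- tibble(
      chr = annotation$chrom[vr],
      start = vpos,
      end = vpos,
      ref = sample(c("A", "C", "G", "T"), length(vr), replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), length(vr), replace = TRUE),
      consequence = sample(c("missense_variant", "start_lost"), length(vr),
                           replace = TRUE, prob = c(0.9, 0.1)),
      strain = sample(c("PWK/PhJ", "CAST/EiJ", "WSB/EiJ"), length(vr),
                      replace = TRUE)
    )

    manifest <- list(
      seed = seed,
      planted = plant,
      de_background = bg,
      eqtl_n_records = setNames(as.integer(table(eq_uids)[plant$eqtl]),
                                plant$eqtl),
      variant_n_records = setNames(n_rows_per, plant$variant)
    )
    list(de = de, eqtl = eqtl, variants = variants, manifest = manifest)
  })
}

#' Generate recorded API payload fixtures
#'
#' Pre-seeds a request cache with JSON payloads shaped like the mining
#' module's Open Targets-style and InterMine-style responses, under
#' exactly the cache keys the query functions will compute — so
#' [query_opentargets()], [query_intermine()] and [query_qtl()] run fully
#' offline against them. Disease counts above `page_size` span multiple
#' pages, exercising pagination.
#'
#' @param genes Gene IDs to cover (every gene gets payloads, even if
#'   empty).
#' @param plant Named list per gene: `n_diseases`, `n_cardiac` (how many
#'   of the diseases come from the cardiac trait pool), `n_phenotypes`,
#'   `l2g` (numeric vector of credible-set L2G scores). Genes absent from
#'   `plant` get empty payloads.
#' @param cache_dir Cache directory to seed.
#' @param seed RNG seed (pubmed IDs, study labels).
#' @param endpoint,mine_url Endpoints the queries will use.
#' @param page_size Page size the queries will use.
#' @return Manifest list: per-gene planted counts and expected cardiac
#'   matches.
#' @export
make_api_fixtures <- function(genes, plant = list(), cache_dir,
                              seed = 1, endpoint = OT_DEFAULT_ENDPOINT,
                              mine_url = "https://www.mousemine.org/mousemine/service",
                              page_size = 25) {
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  genes <- unique(as.character(genes))
  manifest <- list(seed = seed, genes = list(), page_size = page_size)

  with_seed(seed, {
    for (gene in genes) {
      p <- plant[[gene]] %||% list()
      n_dis <- p$n_diseases %||% 0L
      n_card <- min(p$n_cardiac %||% 0L, n_dis)
      n_phen <- p$n_phenotypes %||% 0L
      l2g <- p$l2g %||% numeric()

      labels <- c(
        CARDIAC_TRAIT_POOL[seq_len(min(n_card, length(CARDIAC_TRAIT_POOL)))],
        rep(CARDIAC_TRAIT_POOL, length.out = max(0, n_card - length(CARDIAC_TRAIT_POOL))),
        rep(OTHER_TRAIT_POOL, length.out = n_dis - n_card)
      )
      rows <- lapply(seq_len(n_dis), function(i) {
        list(disease = list(id = sprintf("EFO_%07d", i),
                            name = labels[[i]]),
             score = round(stats::runif(1, 0.05, 0.95), 3),
             pubmedIds = as.list(sprintf("%08d", sample.int(99999999, 2))))
      })
      n_pages <- max(1L, ceiling(n_dis / page_size))
      for (pg in seq_len(n_pages) - 1L) {
        page_rows <- rows[seq_len(n_dis) > pg * page_size &
                            seq_len(n_dis) <= (pg + 1) * page_size]
        payload <- jsonlite::toJSON(
          list(data = list(target = list(associatedDiseases = list(
            count = n_dis,
            rows = page_rows
          )))),
          auto_unbox = TRUE, null = "null", digits = NA)
        cache_store(cache_dir, endpoint,
                    ot_request_body(gene, "diseases", pg, page_size),
                    as.character(payload))
      }

      phen_rows <- lapply(seq_len(n_phen), function(i) {
        lbl <- if (i == 1 && (p$phenotype_cardiac %||% FALSE)) {
          CARDIAC_TRAIT_POOL[[4]]
        } else {
          OTHER_TRAIT_POOL[[((i - 1) %% length(OTHER_TRAIT_POOL)) + 1]]
        }
        list(phenotype = lbl,
             phenotype_id = sprintf("MP:%07d", i),
             pubmed_ids = as.list(sprintf("%08d", sample.int(99999999, 3))))
      })
      im_payload <- jsonlite::toJSON(list(results = phen_rows),
                                     auto_unbox = TRUE, null = "null",
                                     digits = NA)
      cache_store(cache_dir, mine_url,
                  im_request_body(gene, c("phenotype", "pubmed")),
                  as.character(im_payload))

      cs_rows <- lapply(seq_along(l2g), function(i) {
        list(studyId = sprintf("STUDY%03d", i),
             qtlType = c("eqtl", "pqtl", "sqtl")[((i - 1) %% 3) + 1],
             tissue = c("heart", "liver", "whole blood")[((i - 1) %% 3) + 1],
             leadVariant = sprintf("%d_%d_A_G", sample.int(19, 1),
                                   sample.int(1e8, 1)),
             l2g = l2g[[i]],
             colocH4 = round(stats::runif(1, 0, 1), 3))
      })
      qtl_payload <- jsonlite::toJSON(
        list(data = list(target = list(credibleSets = cs_rows))),
        auto_unbox = TRUE, null = "null", digits = NA)
      cache_store(cache_dir, endpoint, qtl_request_body(gene),
                  as.character(qtl_payload))

      manifest$genes[[gene]] <- list(
        n_diseases = n_dis, n_cardiac = n_card, n_phenotypes = n_phen,
        n_credible = length(l2g), l2g = l2g
      )
    }
  })
  manifest
}
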