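test_that("make_annotation realizes the requested composition exactly", {
  fix <- make_annotation(n_chrom = 2, genes_per_chrom = 50,
                         fraction_protein_coding = 0.8,
                         fraction_with_ortholog = 0.74, seed = 1)
  ann <- fix$annotation
  expect_equal(nrow(ann), 100)
  expect_equal(sum(ann$biotype == "protein_coding"), 80)
  expect_equal(sum(!is.na(ann$human_ortholog)), 74)
  expect_equal(fix$manifest$n_protein_coding, 80)
  expect_equal(fix$manifest$n_with_ortholog, 74)
  # genes are non-overlapping by construction
  for (ch in split(ann, ann$chrom)) {
    ch <- ch[order(ch$start), ]
    expect_true(all(ch$start[-1] > ch$end[-nrow(ch)]))
  }
})

test_that("one seed reproduces the GTF byte for byte", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.gtf"); f2 <- file.path(d, "b.gtf")
  make_annotation(seed = 5, gtf_path = f1)
  make_annotation(seed = 5, gtf_path = f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- file.path(d, "c.gtf")
  make_annotation(seed = 6, gtf_path = f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("a GTF written by the generator reads back equivalently", {
  d <- withr::local_tempdir()
  fix <- make_annotation(n_chrom = 1, genes_per_chrom = 10, seed = 2,
                         gtf_path = file.path(d, "x.gtf"))
  back <- read_annotation(file.path(d, "x.gtf"), BUILD)
  expect_equal(back$ensembl_id, fix$annotation$ensembl_id)
  expect_equal(back$start, fix$annotation$start)
  expect_equal(back$biotype, fix$annotation$biotype)
})

test_that("an empty annotation is representable", {
  fix <- make_annotation(n_chrom = 0, genes_per_chrom = 0, seed = 1)
  expect_equal(nrow(fix$annotation), 0)
})

test_that("planted scan peaks exceed the threshold only in their window", {
  sizes <- c(chr1 = 5e6, chr2 = 5e6)
  spec <- data.frame(chrom = "chr1", start = 1e6, end = 2e6,
                     condition = "ISO", peak_lod = 8)
  scan <- make_scan(spec, conditions = c("ISO", "Ctrl"), chrom_sizes = sizes,
                    markers_per_chrom = 300, threshold = 6, seed = 3)
  inw <- scan$chrom == "chr1" & scan$position >= 1e6 & scan$position <= 2e6
  expect_gte(max(scan$ISO[inw]), 6)
  expect_lt(max(scan$ISO[!inw]), 6)
  expect_lt(max(scan$Ctrl), 6)      # no peak planted for the other condition

  expect_identical(scan, make_scan(spec, conditions = c("ISO", "Ctrl"),
                                   chrom_sizes = sizes,
                                   markers_per_chrom = 300, threshold = 6,
                                   seed = 3))
  bg <- make_scan(spec[0, ], conditions = "ISO", chrom_sizes = sizes,
                  markers_per_chrom = 50, threshold = 6, seed = 3)
  expect_lt(max(bg$ISO), 6)
  expect_lp_error(
    make_scan(data.frame(chrom = "chr1", start = 1, end = 9e6,
                         condition = "ISO", peak_lod = 8),
              conditions = "ISO", chrom_sizes = sizes, seed = 1),
    pattern = "outside chromosome span")
})

test_that("evidence layers plant their positives exactly", {
  ann <- tiny_annotation(20)
  plant <- list(de = ann$gene_uid[1:4], eqtl = ann$gene_uid[3:6],
                variant = ann$gene_uid[c(2, 8)])
  layers <- make_evidence_layers(ann, plant, seed = 9)
  # exactly the planted DE genes are significant
  sig <- layers$de$gene_symbol[layers$de$padj < 0.05]
  expect_setequal(sig, ann$gene_symbol[match(plant$de, ann$gene_uid)])
  expect_gt(nrow(layers$de), length(plant$de))  # background rows exist
  # eqtl table covers exactly the planted genes; later half duplicated
  expect_setequal(unique(layers$eqtl$gene_id), plant$eqtl)
  expect_equal(unname(layers$manifest$eqtl_n_records), c(1L, 1L, 2L, 2L))
  # first variant gene carries 3 rows
  expect_equal(unname(layers$manifest$variant_n_records), c(3L, 1L))
  expect_equal(nrow(layers$variants), 4)
  # variant coordinates sit inside their gene bodies
  r <- match(plant$variant[1], ann$gene_uid)
  in_gene <- layers$variants$start >= ann$start[r] &
    layers$variants$end <= ann$end[r]
  expect_equal(sum(in_gene), 3)
})

test_that("planting a gene missing from the annotation is an error", {
  ann <- tiny_annotation(5)
  expect_lp_error(
    make_evidence_layers(ann, list(de = "ENSMUSG99999999999"), seed = 1),
    pattern = "not in annotation")
})

test_that("empty planting yields evidence that satisfies no criterion", {
  ann <- tiny_annotation(8)
  layers <- make_evidence_layers(ann, list(), seed = 2, n_background_de = 5)
  expect_true(all(layers$de$padj >= 0.05))
  expect_equal(nrow(layers$eqtl), 0)
  expect_equal(nrow(layers$variants), 0)
})

test_that("the fixture profile reproduces itself byte for byte per seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- fixture_profile(file.path(d1, "f"), "mini", seed = 8)
  p2 <- fixture_profile(file.path(d2, "f"), "mini", seed = 8)
  for (nm in c("regions", "idmap", "de", "eqtl", "variants", "scan",
               "criteria", "annotation", "annotation_csv")) {
    expect_identical(readLines(p1$paths[[nm]]), readLines(p2$paths[[nm]]),
                     info = nm)
  }
  # identical cache contents under identical keys
  f1 <- sort(basename(list.files(p1$cache_dir)))
  f2 <- sort(basename(list.files(p2$cache_dir)))
  expect_identical(f1, f2)
  expect_identical(p1$manifest$upset, p2$manifest$upset)
})
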