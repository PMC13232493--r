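test_that("reduce_duplicates applies the default per-column policies", {
  tbl <- tibble::tibble(
    gene = c("A", "A", "A", "B"),
    pval = c(0.3, 0.01, 0.2, 0.5),
    beta = c(1, 3, 2, -1),
    consequence = c("missense", "missense", "start_loss", "missense")
  )
  out <- reduce_duplicates(tbl, "gene")
  a <- out[out$gene == "A", ]
  expect_equal(a$pval, 0.01)                       # p-value pattern -> min
  expect_equal(a$beta, 3)                          # other numeric -> max
  expect_equal(a$consequence, "missense;start_loss")  # distinct, sorted
  expect_equal(a$n_records, 3L)
  expect_equal(out$n_records[out$gene == "B"], 1L)
  expect_equal(out[out$gene == "B", c("pval", "beta")],
               tibble::tibble(pval = 0.5, beta = -1))
})

test_that("reduce_duplicates is invariant to input row order", {
  set.seed(11)
  tbl <- tibble::tibble(gene = sample(LETTERS[1:5], 40, replace = TRUE),
                        padj = runif(40), note = sample(letters, 40, TRUE))
  a <- reduce_duplicates(tbl, "gene")
  b <- reduce_duplicates(tbl[sample.int(40), ], "gene")
  expect_identical(a[order(a$gene), ], b[order(b$gene), ])
})

test_that("reducer misconfiguration is caught by name", {
  tbl <- tibble::tibble(gene = "A", label = "x")
  expect_lp_error(reduce_duplicates(tbl, "gene", reducers = c(label = "mean")),
                  pattern = "label")
  expect_lp_error(reduce_duplicates(tbl, "gene", reducers = c(ghost = "min")),
                  pattern = "ghost")
})

test_that("coord_join maps rows to genes by any-overlap with fan-out", {
  ann <- gene_annotation(
    tibble::tibble(gene_symbol = c("A", "B"),
                   ensembl_id = c("ENSMUSG00000000001", "ENSMUSG00000000002"),
                   chrom = "chr1", start = c(100, 201), end = c(200, 300)),
    BUILD)
  ev <- data.frame(chr = c("chr1", "chr1", "chr1"),
                   start = c(150, 5000, 180), end = c(150, 5000, 250),
                   effect = c("a", "b", "c"))
  out <- coord_join(ann, ev)
  expect_equal(out$gene_uid[out$effect == "a"], "ENSMUSG00000000001")
  # intergenic row dropped and counted
  expect_false("b" %in% out$effect)
  expect_equal(attr(out, "n_dropped"), 1L)
  # a row spanning two adjacent genes fans out to both
  expect_setequal(out$gene_uid[out$effect == "c"],
                  c("ENSMUSG00000000001", "ENSMUSG00000000002"))
  expect_lp_error(
    coord_join(ann, data.frame(chr = "chr1", start = 10, end = 5)),
    pattern = "malformed")
})

fresh_project <- function(ann = tiny_annotation(10)) {
  loci <- data.frame(chr = "chr1", start = 1, end = max(ann$end) + 10)
  init_project(withr::local_tempdir(.local_envir = parent.frame()),
               loci, mode = "region", build = BUILD, annotation = ann)
}

test_that("attach_layer is a left join: spine rows and columns unchanged", {
  project <- fresh_project()
  base <- project_sheet(project)
  de <- tibble::tibble(gene_symbol = c("Tg01", "Tg03", "Tg05"),
                       padj = c(0.01, 0.2, 0.001))
  project <- attach_layer(project, de, "de")
  sheet <- project_sheet(project)
  expect_equal(nrow(sheet), nrow(base))
  expect_identical(sheet[names(base)], base)
  expect_equal(sum(!is.na(sheet$de.padj)), 3)
  expect_true(all(c("de.padj", "de.n_records") %in% names(sheet)))
})

test_that("attaching an empty evidence table only adds all-missing columns", {
  project <- fresh_project()
  empty <- tibble::tibble(gene_symbol = character(), padj = numeric())
  project <- attach_layer(project, empty, "de")
  sheet <- project_sheet(project)
  expect_equal(nrow(sheet), 10)
  expect_true(all(is.na(sheet$de.padj)))
})

test_that("namespacing keeps same-named columns from colliding", {
  project <- fresh_project()
  project <- attach_layer(
    project, tibble::tibble(gene_symbol = "Tg01", pval = 0.1), "de")
  project <- attach_layer(
    project, tibble::tibble(gene_id = "ENSMUSG00000000002", pval = 0.2),
    "eqtl")
  sheet <- project_sheet(project)
  expect_true(all(c("de.pval", "eqtl.pval") %in% names(sheet)))
  expect_lp_error(
    attach_layer(project, tibble::tibble(gene_symbol = "Tg01", x = 1), "de"),
    pattern = "already attached")
})

test_that("attach_layer enforces the shared genome build", {
  project <- fresh_project()
  expect_lp_error(
    attach_layer(project, tibble::tibble(gene_symbol = "Tg01", x = 1),
                 "old", build = genome_build("mm10")),
    class = "lp_build_mismatch", pattern = "liftOver")
})

test_that("attachment order never changes cell values", {
  project <- fresh_project()
  de <- tibble::tibble(gene_symbol = c("Tg01", "Tg04"), padj = c(0.01, 0.6))
  eq <- tibble::tibble(gene_id = c("ENSMUSG00000000004"), pval = 1e-5)
  p1 <- attach_layer(attach_layer(project, de, "de"), eq, "eqtl")
  p2 <- attach_layer(attach_layer(project, eq, "eqtl"), de, "de")
  s1 <- project_sheet(p1)
  s2 <- project_sheet(p2)
  expect_identical(s1[sort(names(s1))], s2[sort(names(s2))])
})
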