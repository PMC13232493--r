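test_that("integer percentages round half away from zero", {
  expect_equal(percent_of(950, 2149), 44L)
  expect_equal(percent_of(6, 21), 29L)
  expect_equal(percent_of(2, 5), 40L)
  expect_equal(percent_of(6, 10), 60L)
  expect_equal(percent_of(0, 10), 0L)
  expect_equal(percent_of(1, 200), 1L)   # 0.5 rounds up, away from zero
  expect_true(is.na(percent_of(3, 0)))
})

test_that("init_project resolves loci and membership in region mode", {
  ann <- tiny_annotation(12)  # genes every 900 bp from 1000, length 400
  regions <- data.frame(chr = "chr1",
                        start = c(1000, 2000, 6000),
                        end = c(1500, 2600, 7000))
  dir <- withr::local_tempdir()
  project <- init_project(file.path(dir, "p"), regions, mode = "region",
                          build = BUILD, annotation = ann)
  expect_true(all(dir.exists(file.path(project$path,
                                       c("inputs", "cache", "supplementary",
                                         "outputs")))))
  # brute-force membership check
  expected <- unlist(lapply(seq_len(nrow(project$loci)), function(i) {
    l <- project$loci[i, ]
    ann$gene_uid[ann$start <= l$end & ann$end >= l$start]
  }))
  expect_setequal(project$spine$gene_uid, expected)
  expect_true(file.exists(file.path(project$path, "metadata.json")))
})

test_that("gene mode takes a symbol list and builds no loci", {
  ann <- tiny_annotation(10)
  dir <- withr::local_tempdir()
  project <- init_project(
    file.path(dir, "p"),
    data.frame(gene_symbol = c("Tg01", "Tg02", "Tg03", "Tg04", "Tg05")),
    mode = "gene", build = BUILD, annotation = ann)
  expect_equal(nrow(project$loci), 0)
  expect_equal(nrow(project$spine), 5)
  expect_lp_error(
    init_project(file.path(dir, "q"), data.frame(x = 1), mode = "gene",
                 build = BUILD, annotation = ann),
    pattern = "gene_symbol")
})

test_that("validation failures leave no half-written project behind", {
  ann <- tiny_annotation(5)
  dir <- withr::local_tempdir()
  target <- file.path(dir, "never")
  expect_lp_error(
    init_project(target, data.frame(chr = "chr1", start = 10, end = 5),
                 mode = "region", build = BUILD, annotation = ann),
    pattern = "start > end")
  expect_false(dir.exists(target))

  occupied <- file.path(dir, "occupied")
  dir.create(occupied)
  writeLines("x", file.path(occupied, "keep.txt"))
  expect_error(
    init_project(occupied, data.frame(chr = "chr1", start = 1, end = 5),
                 mode = "region", build = BUILD, annotation = ann),
    class = "lp_io_error", regexp = "not empty")
})

test_that("gene sheets stack base, layer, and result columns in order", {
  prof <- fixture_profile(withr::local_tempdir(), "mini", seed = 1)
  res <- run_fixture_pipeline(prof, withr::local_tempdir())
  sheet <- res$sheet_data$combined
  base <- project_sheet(res$project)
  n_criteria <- length(prof$criteria)
  expect_equal(ncol(sheet), ncol(base) + n_criteria + 2)  # + count + pass
  expect_equal(names(sheet)[seq_len(ncol(base))], names(base))
  expect_equal(tail(names(sheet), 2), c("evidence_count", "pass_required"))
  # one CSV per locus, rows matching the locus membership
  expect_length(res$sheet_data$paths, nrow(res$project$loci))
  expect_true(all(file.exists(res$sheet_data$paths)))
})

test_that("criteria referencing absent columns fail before any write", {
  ann <- tiny_annotation(5)
  dir <- withr::local_tempdir()
  project <- init_project(
    file.path(dir, "p"),
    data.frame(chr = "chr1", start = 1, end = max(ann$end)),
    mode = "region", build = BUILD, annotation = ann)
  expect_lp_error(
    make_gene_sheet(project, list(criterion("x", "ghost.col > 1", "required"))),
    class = "lp_eval_error", pattern = "ghost.col")
  expect_false(dir.exists(file.path(project$path, "outputs", "sheets")))
})

test_that("sheets without criteria keep all rows and add no result columns", {
  ann <- tiny_annotation(5)
  project <- init_project(
    file.path(withr::local_tempdir(), "p"),
    data.frame(chr = "chr1", start = 1, end = max(ann$end)),
    mode = "region", build = BUILD, annotation = ann)
  out <- make_gene_sheet(project, list())
  expect_equal(nrow(out$combined), 5)
  expect_equal(ncol(out$combined), ncol(project_sheet(project)) + 2)
})

test_that("re-running the pipeline writes byte-identical gene sheets", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- fixture_profile(file.path(d1, "f"), "mini", seed = 4)
  p2 <- fixture_profile(file.path(d2, "f"), "mini", seed = 4)
  r1 <- run_fixture_pipeline(p1, file.path(d1, "proj"))
  r2 <- run_fixture_pipeline(p2, file.path(d2, "proj"))
  for (i in seq_along(r1$sheet_data$paths)) {
    expect_identical(readLines(r1$sheet_data$paths[[i]]),
                     readLines(r2$sheet_data$paths[[i]]))
  }
})

test_that("packets emit the five standard sheets in order", {
  prof <- fixture_profile(withr::local_tempdir(), "mini", seed = 1)
  res <- run_fixture_pipeline(prof, withr::local_tempdir())
  locus <- res$project$loci$locus_id[[1]]
  pk <- build_packet(res$project, locus, res$sheet_data,
                     custom_sheets = c(Screened = "pass_required"),
                     plots = FALSE)
  expect_equal(names(pk$sheets),
               c("Summary", "Complete", "Screened", "MouseMine", "OpenTargets"))
  expect_true(all(file.exists(pk$csvs)))
  # the custom sheet is the criteria-expression subset of Complete
  expect_equal(nrow(pk$sheets$Screened),
               sum(pk$sheets$Complete$pass_required))
  # complete sheet holds exactly the genes of the locus
  expect_equal(nrow(pk$sheets$Complete),
               sum(res$sheet_data$combined$locus_id == locus, na.rm = TRUE))
})

test_that("mined sheets are present with headers even when nothing was mined", {
  ann <- tiny_annotation(5)
  project <- init_project(
    file.path(withr::local_tempdir(), "p"),
    data.frame(chr = "chr1", start = 1, end = max(ann$end)),
    mode = "region", build = BUILD, annotation = ann)
  sd <- make_gene_sheet(project, list())
  pk <- build_packet(project, project$loci$locus_id[[1]], sd, plots = FALSE)
  expect_equal(nrow(pk$sheets$MouseMine), 0)
  expect_equal(names(pk$sheets$OpenTargets),
               c("gene", "trait_label", "trait_id", "disease_score",
                 "pubmed_ids"))
  mm_csv <- utils::read.csv(pk$csvs[["MouseMine"]])
  expect_equal(names(mm_csv), c("gene", "trait_label", "trait_id",
                                "pubmed_ids"))
})

test_that("workbook sheet names are truncated with collision suffixes", {
  long_a <- paste(rep("a", 40), collapse = "")
  nms <- locuspacket:::truncate_sheet_names(c(long_a, long_a, "ok"))
  expect_true(all(nchar(nms) <= 31))
  expect_equal(anyDuplicated(nms), 0)
  expect_equal(nms[[3]], "ok")
})

test_that("summarize_counts reports screen fractions as integer percents", {
  sheet <- tibble::tibble(cpm = c(rep(10, 6), rep(1, 15)))
  res <- evaluate_criteria(sheet, list(
    criterion("expr", "cpm > 5", "required")))
  st <- summarize_counts(res)
  expect_equal(st$n_total, 21)
  expect_equal(st$n_pass_required, 6)
  expect_equal(st$pct_pass_required, 29L)
  expect_equal(st$per_criterion$pct, 29L)
})
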