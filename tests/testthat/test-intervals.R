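test_that("parse_regions builds loci from chr/start/end tables", {
  loci <- parse_regions(
    data.frame(chr = "chr3", start = 131000000, end = 150000000,
               trait = "EF"),
    BUILD)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$chrom, "chr3")
  expect_equal(loci$start, 131e6)
  expect_equal(loci$end, 150e6)
  expect_equal(loci$traits[[1]], "EF")
  expect_equal(loci$locus_id, "locus_chr3_131_150")
  expect_equal(interval_width_mb(loci), 19.0)
})

test_that("parse_regions accepts case-insensitive columns and empty input", {
  loci <- parse_regions(
    data.frame(CHR = c("chr2", "chr1"), START = c(5, 1), END = c(9, 4)),
    BUILD)
  # deterministic (chrom, start) order
  expect_equal(loci$chrom, c("chr1", "chr2"))
  expect_equal(nrow(parse_regions(
    data.frame(chr = character(), start = numeric(), end = numeric()),
    BUILD)), 0)
})

test_that("parse_regions normalizes mixed chromosome naming styles", {
  tbl <- data.frame(chr = c("3", "chr3"), start = c(100, 900),
                    end = c(500, 1200))
  expect_equal(parse_regions(tbl, BUILD, style = "chr")$chrom,
               c("chr3", "chr3"))
  expect_equal(parse_regions(tbl, BUILD, style = "plain")$chrom,
               c("3", "3"))
})

test_that("parse_regions rejects malformed input with row context", {
  expect_lp_error(parse_regions(data.frame(start = 1, end = 2), BUILD),
                  pattern = "chromosome column")
  expect_lp_error(parse_regions(data.frame(chr = "chr1", end = 2), BUILD),
                  pattern = "`start`")
  expect_lp_error(
    parse_regions(data.frame(chr = "chr1", start = 10, end = 5), BUILD),
    pattern = "start > end.*1")
  expect_lp_error(
    parse_regions(data.frame(chr = "chr1", start = 1.5, end = 5), BUILD),
    pattern = "non-integer")
})

test_that("interval_width_mb reports one-decimal megabase spans", {
  expect_equal(interval_width_mb(
    genomic_interval("chr3", 131000000, 150000000, BUILD)), 19.0)
  expect_equal(interval_width_mb(genomic_interval("chr1", 500, 500, BUILD)),
               0.0)
  expect_equal(interval_width_mb(
    genomic_interval("chr1", 1, 12800001, BUILD)), 12.8)
})

test_that("merge_loci fuses transitively overlapping intervals", {
  loci <- parse_regions(
    data.frame(chr = c("chr1", "chr1", "chr2"),
               start = c(100, 150, 100), end = c(200, 300, 200),
               trait = c("a", "b", "a")),
    BUILD)
  merged <- merge_loci(loci)
  expect_equal(nrow(merged), 2)
  chr1 <- merged[merged$chrom == "chr1", ]
  expect_equal(c(chr1$start, chr1$end), c(100, 300))
  expect_equal(chr1$source_count, 2L)
  expect_equal(chr1$traits[[1]], c("a", "b"))
  expect_equal(merged$source_count[merged$chrom == "chr2"], 1L)

  single <- parse_regions(data.frame(chr = "chr1", start = 5, end = 9), BUILD)
  expect_equal(merge_loci(single), single)
})

test_that("merge_loci honors the max_gap boundary exactly", {
  loci <- parse_regions(
    data.frame(chr = "chr1", start = c(100, 201), end = c(200, 300)), BUILD)
  expect_equal(nrow(merge_loci(loci, max_gap = 0)), 2)
  g1 <- merge_loci(loci, max_gap = 1)
  expect_equal(nrow(g1), 1)
  expect_equal(c(g1$start, g1$end), c(100, 300))
})

test_that("merge_loci preserves the build tag; cross-build joins refuse", {
  a <- parse_regions(data.frame(chr = "chr1", start = 1, end = 5), BUILD)
  expect_identical(attr(merge_loci(a), "build", exact = TRUE)$name, "mm39")
  ann <- tiny_annotation(3)
  b <- parse_regions(data.frame(chr = "chr1", start = 3, end = 8),
                     genome_build("mm10"))
  expect_lp_error(assign_loci(ann, b), class = "lp_build_mismatch")
})

test_that("genes_in_interval uses any-overlap, strand-agnostic semantics", {
  ann <- gene_annotation(
    tibble::tibble(gene_symbol = c("A", "B"),
                   ensembl_id = c("ENSMUSG00000000001", "ENSMUSG00000000002"),
                   chrom = c("chr1", "chr2"), start = c(100, 100),
                   end = c(200, 200), strand = c("+", "-")),
    BUILD)
  # 1 bp shared at the query edge is an overlap
  hit <- genes_in_interval(ann, genomic_interval("chr1", 200, 300, BUILD))
  expect_equal(hit$gene_symbol, "A")
  # same coordinates on another chromosome are not
  expect_equal(nrow(genes_in_interval(
    ann, genomic_interval("chr2", 300, 400, BUILD))), 0)
  expect_lp_error(
    genes_in_interval(ann, genomic_interval("chr1", 1, 10,
                                            genome_build("mm10"))),
    class = "lp_build_mismatch")
})

test_that("genes_in_interval recovers a full chromosome and is monotone", {
  fix <- make_annotation(n_chrom = 2, genes_per_chrom = 50, seed = 7)
  ann <- fix$annotation
  chr1 <- genes_in_interval(
    ann, genomic_interval("chr1", 1, max(ann$end) + 1, BUILD))
  expect_setequal(chr1$gene_uid, ann$gene_uid[ann$chrom == "chr1"])
  expect_false(is.unsorted(chr1$start))

  mid <- floor(stats::median(ann$start[ann$chrom == "chr1"]))
  narrow <- genes_in_interval(ann, genomic_interval("chr1", mid, mid + 1e5, BUILD))
  wide <- genes_in_interval(ann, genomic_interval("chr1", mid - 1e5, mid + 2e5, BUILD))
  expect_true(all(narrow$gene_uid %in% wide$gene_uid))
})

test_that("assign_loci maps genes to every overlapping locus", {
  ann <- gene_annotation(
    tibble::tibble(gene_symbol = c("Wide", "Lonely"),
                   ensembl_id = c("ENSMUSG00000000010", "ENSMUSG00000000011"),
                   chrom = c("chr1", "chr9"), start = c(100, 100),
                   end = c(1000, 200)),
    BUILD)
  loci <- parse_regions(
    data.frame(chr = c("chr1", "chr1"), start = c(50, 600),
               end = c(150, 700)), BUILD)
  m <- assign_loci(ann, loci)
  expect_length(m[["ENSMUSG00000000010"]], 2)
  expect_equal(m[["ENSMUSG00000000011"]], character())
})

test_that("after merging, no gene maps to two loci that overlap", {
  set.seed(42)
  for (rep in 1:10) {
    df <- random_intervals(20, n_chrom = 2, span = 3000)
    loci <- merge_loci(parse_regions(df, BUILD))
    # merged loci are pairwise disjoint per chromosome
    by_chrom <- split(loci, loci$chrom)
    for (ch in by_chrom) {
      if (nrow(ch) < 2) next
      ch <- ch[order(ch$start), ]
      expect_true(all(ch$start[-1] > ch$end[-nrow(ch)]))
    }
  }
})
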