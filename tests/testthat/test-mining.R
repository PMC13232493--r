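# All mining tests run offline against payloads recorded with
# make_api_fixtures(), which seeds the cache under the exact keys the
# query functions compute.

seed_cache <- function(plant, genes = names(plant), page_size = 2) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  make_api_fixtures(genes, plant = plant, cache_dir = dir, seed = 99,
                    page_size = page_size)
  dir
}

test_that("the request cache is content-addressed and order-insensitive", {
  k1 <- cache_key("https://x", list(a = 1, b = list(c = 2, d = 3)))
  k2 <- cache_key("https://x", list(b = list(d = 3, c = 2), a = 1))
  expect_identical(k1, k2)
  expect_false(identical(k1, cache_key("https://y", list(a = 1))))

  dir <- withr::local_tempdir()
  cache_store(dir, "https://x", list(a = 1), '{"v": 1}')
  p1 <- cached_request("https://x", list(a = 1), dir, offline = TRUE)
  p2 <- cached_request("https://x", list(a = 1), dir, offline = TRUE)
  expect_identical(p1, p2)
  expect_identical(p1, '{"v": 1}')
})

test_that("offline cache misses are explicit errors, not silent fetches", {
  dir <- withr::local_tempdir()
  expect_lp_error(
    cached_request("https://x", list(q = "novel"), dir, offline = TRUE),
    class = "lp_offline_miss", pattern = "offline cache miss")
})

test_that("malformed cached payloads fail with the cache key named", {
  dir <- withr::local_tempdir()
  cache_store(dir, "https://mine", locuspacket:::im_request_body(
    "G1", c("phenotype", "pubmed")), "{not json")
  expect_lp_error(
    query_intermine("G1", "https://mine", cache_dir = dir),
    class = "lp_io_error", pattern = "malformed JSON")
})

test_that("disease associations come back verbatim, in stable order", {
  dir <- seed_cache(list(G1 = list(n_diseases = 3, n_cardiac = 2)),
                    genes = c("G1", "G2"), page_size = 25)
  out <- query_opentargets(c("G1", "G2"), cache_dir = dir, page_size = 25)
  expect_equal(nrow(out), 3)
  expect_equal(unique(out$gene), "G1")
  expect_equal(unique(out$source), "opentargets")
  expect_true(all(out$disease_score >= 0 & out$disease_score <= 1))
  expect_false(is.unsorted(out$trait_id))
  # deterministic: same cache, same result
  expect_identical(out, query_opentargets(c("G1", "G2"), cache_dir = dir,
                                          page_size = 25))
})

test_that("pagination drains all pages without duplicating rows", {
  dir <- seed_cache(list(G1 = list(n_diseases = 5, n_cardiac = 1)),
                    page_size = 2)
  out <- query_opentargets("G1", cache_dir = dir, page_size = 2)
  expect_equal(nrow(out), 5)
  expect_equal(anyDuplicated(out$trait_id), 0)
})

test_that("an empty gene list issues no request at all", {
  missing_dir <- file.path(tempdir(), "no-such-cache")
  out <- query_opentargets(character(), cache_dir = missing_dir)
  expect_equal(nrow(out), 0)
  expect_equal(nrow(query_qtl(character(), cache_dir = missing_dir)), 0)
})

test_that("phenotype associations carry their PubMed evidence", {
  dir <- seed_cache(list(G1 = list(n_phenotypes = 2)), genes = c("G1", "G2"))
  out <- query_intermine(c("G1", "G2"),
                         "https://www.mousemine.org/mousemine/service",
                         cache_dir = dir)
  expect_equal(nrow(out), 2)          # G2 has none, so it is absent
  expect_equal(unique(out$gene), "G1")
  expect_equal(unique(out$source), "intermine")
  expect_true(all(lengths(out$pubmed_ids) == 3))
})

test_that("credible sets are filtered by the L2G confidence threshold", {
  dir <- seed_cache(list(G1 = list(l2g = c(0.9, 0.4, 0.6))))
  kept <- query_qtl("G1", cache_dir = dir, min_l2g = 0.5)
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$l2g_score >= 0.5))
  all_rows <- query_qtl("G1", cache_dir = dir, min_l2g = 0)
  expect_equal(nrow(all_rows), 3)
  expect_true(all(!is.na(all_rows$coloc_h4)))

  eqtl_only <- query_qtl("G1", cache_dir = dir, min_l2g = 0,
                         qtl_types = "eqtl")
  expect_true(all(eqtl_only$qtl_type == "eqtl"))
  expect_lt(nrow(eqtl_only), nrow(all_rows))
  expect_lp_error(query_qtl("G1", cache_dir = dir, qtl_types = "gwasqtl"),
                  pattern = "unknown qtl_type")
})

test_that("trait filtering supports explicit and related passes", {
  assoc <- tibble::tibble(
    gene = "G1",
    trait_label = c("cardiac hypertrophy", "hypertension", "asthma"),
    source = "opentargets")
  expect_equal(filter_traits(assoc, "cardiac")$trait_label,
               "cardiac hypertrophy")
  expect_equal(nrow(filter_traits(assoc, character())), 0)
  related <- filter_traits(assoc, c("cardiac", "blood pressure|hypertension"))
  expect_equal(nrow(related), 2)

  pat <- list(explicit = "cardiac", related = c("cardiac", "hypertension"))
  expl <- filter_traits(assoc, pat, pass = "explicit")
  rel <- filter_traits(assoc, pat, pass = "related")
  expect_true(all(expl$trait_label %in% rel$trait_label))
  expect_lp_error(filter_traits(assoc, "(unclosed"), pattern = "invalid")
})
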