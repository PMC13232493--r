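# Offline-first annotation mining: Open Targets-style GraphQL payloads
# (diseases, drugs, interactions, molecular-QTL credible sets) and
# InterMine-style phenotype payloads, served through a content-addressed
# request cache. Every query is a pure function of cached payloads, so runs
# against recorded fixtures are fully deterministic and network-free.

QTL_TYPES <- c("eqtl", "pqtl", "sqtl", "sceqtl", "scpqtl")
OPENTARGETS_SECTIONS <- c("diseases", "known_drugs", "interactions")
OT_DEFAULT_ENDPOINT <- "https://api.platform.opentargets.org/api/v4/graphql"

# Canonicalize a request body: named lists sorted by name at every level,
# so parameter order never changes the cache key.
canonicalize_body <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x)))) {
      x <- x[order(names(x))]
    }
    lapply(x, canonicalize_body)
  } else {
    x
  }
}

#' Cache key for a mining request
#'
#' Content-addressed: the md5 of the canonicalized (endpoint, body) pair.
#' Request parameter order does not affect the key.
#'
#' @param endpoint Endpoint URL or label.
#' @param body Request body (named list).
#' @return Hex digest string.
#' @export
cache_key <- function(endpoint, body) {
  canon <- jsonlite::toJSON(
    list(body = canonicalize_body(body), endpoint = endpoint),
    auto_unbox = TRUE, null = "null", digits = NA
  )
  digest::digest(as.character(canon), algo = "md5", serialize = FALSE)
}

cache_path <- function(cache_dir, key) file.path(cache_dir, paste0(key, ".json"))

#' Store a payload in a request cache
#'
#' Used by live fetches and by the fixture generator to pre-seed caches.
#'
#' @param cache_dir Cache directory (created if needed).
#' @param endpoint,body The request the payload answers.
#' @param payload Raw payload text (JSON string).
#' @param url Source URL recorded in provenance.
#' @return The cache key, invisibly.
#' @export
cache_store <- function(cache_dir, endpoint, body, payload, url = endpoint) {
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  key <- cache_key(endpoint, body)
  entry <- list(
    endpoint = endpoint,
    url = url,
    retrieved_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    payload = payload
  )
  writeLines(
    jsonlite::toJSON(entry, auto_unbox = TRUE, null = "null"),
    cache_path(cache_dir, key)
  )
  invisible(key)
}

default_fetcher <- function(endpoint, body) {
  if (!requireNamespace("httr", quietly = TRUE)) {
    lp_stop_io("live requests need the 'httr' package; run offline against a cache")
  }
  resp <- httr::POST(endpoint, body = body, encode = "json",
                     httr::accept_json())
  status <- httr::status_code(resp)
  if (status >= 400) {
    lp_stop_io(paste0("HTTP ", status, " from ", endpoint),
               class = "lp_http_error")
  }
  httr::content(resp, as = "text", encoding = "UTF-8")
}

#' Fetch a payload through the request cache
#'
#' The first call for a request stores the raw response; every later
#' identical call (parameter order irrelevant) returns byte-identical
#' payload text without touching the network. In offline mode a cache miss
#' is an explicit error naming the request, and the network is never
#' touched. Live fetches retry up to 3 times with exponential backoff
#' before surfacing the endpoint and status.
#'
#' @param endpoint Endpoint URL or label.
#' @param body Request body (named list).
#' @param cache_dir Cache directory.
#' @param offline If `TRUE` (default), never touch the network.
#' @param fetcher Function `(endpoint, body) -> payload text`; defaults to
#'   an HTTP POST with JSON body.
#' @return Payload text (JSON string).
#' @export
cached_request <- function(endpoint, body, cache_dir, offline = TRUE,
                           fetcher = default_fetcher) {
  key <- cache_key(endpoint, body)
  path <- cache_path(cache_dir, key)
  if (file.exists(path)) {
    entry <- tryCatch(
      jsonlite::fromJSON(path, simplifyVector = FALSE),
      error = function(e) {
        lp_stop_io(paste0("malformed cache entry ", key, ": ",
                          conditionMessage(e)))
      }
    )
    return(entry$payload)
  }
  if (offline) {
    lp_stop_io(
      paste0("offline cache miss for request to ", endpoint,
             " (cache key ", key, "); re-run online or pre-seed the cache"),
      class = "lp_offline_miss"
    )
  }
  payload <- NULL
  for (attempt in 1:3) {
    payload <- tryCatch(fetcher(endpoint, body), error = function(e) e)
    if (!inherits(payload, "error")) break
    if (attempt < 3) Sys.sleep(0.5 * 2^(attempt - 1))
  }
  if (inherits(payload, "error")) {
    lp_stop_io(paste0("request to ", endpoint, " failed after 3 attempts: ",
                      conditionMessage(payload)))
  }
  cache_store(cache_dir, endpoint, body, payload)
  payload
}

parse_payload <- function(payload, key_hint) {
  tryCatch(
    jsonlite::fromJSON(payload, simplifyVector = FALSE),
    error = function(e) {
      lp_stop_io(paste0("malformed JSON payload for cache key ", key_hint,
                        ": ", conditionMessage(e)))
    }
  )
}

# Request builders shared with the fixture generator, so recorded payloads
# land under exactly the keys the queries will ask for.
ot_request_body <- function(gene, section, index, size) {
  list(
    query = "target_section_page",
    variables = list(ensemblId = gene, section = section,
                     index = index, size = size)
  )
}

im_request_body <- function(gene, views) {
  list(service = "query/results", gene = gene, views = views)
}

qtl_request_body <- function(gene) {
  list(query = "target_credible_sets", variables = list(ensemblId = gene))
}

empty_associations <- function() {
  tibble(gene = character(), section = character(), trait_label = character(),
         trait_id = character(), source = character(),
         disease_score = numeric(), pubmed_ids = list())
}

#' Query gene-disease/drug/interaction associations (Open Targets style)
#'
#' Drains all result pages for each gene and section from the cache (or the
#' live endpoint when `offline = FALSE`), returning one association row per
#' linked disease, known drug, or interaction partner, with the disease
#' score copied verbatim when the service supplies one. Rows are ordered
#' deterministically by (gene, section, trait_id).
#'
#' @param genes Ensembl gene IDs (empty input issues no request).
#' @param sections Subset of `diseases`, `known_drugs`, `interactions`.
#' @param cache_dir Request cache directory.
#' @param offline Never touch the network when `TRUE` (default).
#' @param endpoint GraphQL endpoint URL.
#' @param page_size Rows per page request.
#' @param fetcher Optional fetch function for live mode.
#' @return Association tibble: `gene`, `section`, `trait_label`,
#'   `trait_id`, `source` (`"opentargets"`), `disease_score`,
#'   `pubmed_ids` (list column).
#' @export
query_opentargets <- function(genes, sections = "diseases", cache_dir,
                              offline = TRUE, endpoint = OT_DEFAULT_ENDPOINT,
                              page_size = 50, fetcher = default_fetcher) {
  bad <- setdiff(sections, OPENTARGETS_SECTIONS)
  if (length(bad) > 0) {
    lp_stop(paste0("unknown section(s): ", paste(bad, collapse = ", "),
                   " (allowed: ", paste(OPENTARGETS_SECTIONS, collapse = ", "), ")"))
  }
  genes <- unique(as.character(genes))
  if (length(genes) == 0) return(empty_associations())

  rows <- list()
  for (gene in genes) {
    for (section in sections) {
      index <- 0L
      got <- 0L
      repeat {
        body <- ot_request_body(gene, section, index, page_size)
        payload <- cached_request(endpoint, body, cache_dir, offline, fetcher)
        parsed <- parse_payload(payload, cache_key(endpoint, body))
        block <- parsed$data$target[[ot_section_field(section)]]
        if (is.null(block)) break
        total <- block$count %||% length(block$rows)
        for (r in block$rows) {
          rows[[length(rows) + 1L]] <- ot_row_to_association(gene, section, r)
        }
        got <- got + length(block$rows)
        if (got >= total || length(block$rows) == 0) break
        index <- index + 1L
      }
    }
  }
  if (length(rows) == 0) return(empty_associations())
  out <- dplyr::bind_rows(rows)
  out <- dplyr::distinct(out, .data$gene, .data$section, .data$trait_id,
                         .data$trait_label, .keep_all = TRUE)
  out[order(out$gene, out$section, out$trait_id), ]
}

ot_section_field <- function(section) {
  switch(section,
    diseases = "associatedDiseases",
    known_drugs = "knownDrugs",
    interactions = "interactions")
}

ot_row_to_association <- function(gene, section, r) {
  if (section == "diseases") {
    tibble(gene = gene, section = section,
           trait_label = r$disease$name %||% NA_character_,
           trait_id = r$disease$id %||% NA_character_,
           source = "opentargets",
           disease_score = as.numeric(r$score %||% NA_real_),
           pubmed_ids = list(as.character(unlist(r$pubmedIds %||% list()))))
  } else if (section == "known_drugs") {
    tibble(gene = gene, section = section,
           trait_label = r$drug$name %||% NA_character_,
           trait_id = r$drug$id %||% NA_character_,
           source = "opentargets",
           disease_score = as.numeric(r$score %||% NA_real_),
           pubmed_ids = list(character()))
  } else {
    tibble(gene = gene, section = section,
           trait_label = r$partner$symbol %||% NA_character_,
           trait_id = r$partner$id %||% NA_character_,
           source = "opentargets",
           disease_score = as.numeric(r$score %||% NA_real_),
           pubmed_ids = list(character()))
  }
}

#' Query mouse phenotype associations (InterMine style)
#'
#' Maps phenotype rows for each gene to association records with
#' `source = "intermine"` and the supporting PubMed IDs attached. Genes
#' with no phenotype rows are absent from the output.
#'
#' @param genes Gene identifiers as known to the mine.
#' @param mine_url Mine endpoint URL (e.g. a MouseMine-compatible service).
#' @param views Field views requested from the mine.
#' @param cache_dir,offline,fetcher See [cached_request()].
#' @return Association tibble (same shape as [query_opentargets()], with
#'   `section = "phenotypes"`).
#' @export
query_intermine <- function(genes, mine_url, views = c("phenotype", "pubmed"),
                            cache_dir, offline = TRUE,
                            fetcher = default_fetcher) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) return(empty_associations())
  rows <- list()
  for (gene in genes) {
    body <- im_request_body(gene, views)
    payload <- cached_request(mine_url, body, cache_dir, offline, fetcher)
    parsed <- parse_payload(payload, cache_key(mine_url, body))
    for (r in parsed$results) {
      rows[[length(rows) + 1L]] <- tibble(
        gene = gene, section = "phenotypes",
        trait_label = r$phenotype %||% NA_character_,
        trait_id = r$phenotype_id %||% NA_character_,
        source = "intermine",
        disease_score = NA_real_,
        pubmed_ids = list(as.character(unlist(r$pubmed_ids %||% list())))
      )
    }
  }
  if (length(rows) == 0) return(empty_associations())
  out <- dplyr::bind_rows(rows)
  out[order(out$gene, out$trait_id, out$trait_label), ]
}

empty_credible_sets <- function() {
  tibble(study_id = character(), qtl_type = character(),
         tissue_or_cell = character(), target_gene = character(),
         lead_variant = character(), l2g_score = numeric(),
         coloc_h4 = numeric())
}

#' Query fine-mapped molecular-QTL credible sets
#'
#' Retrieves fine-mapped credible sets (eQTL, pQTL, sQTL and single-cell
#' variants) for each gene. Each record carries a locus-to-gene (L2G)
#' prediction score in \[0, 1\]; records below `min_l2g` are dropped so only
#' high-confidence variant-gene assignments remain (set `min_l2g = 0` to
#' keep everything). GWAS colocalization posteriors (`coloc_h4`) are passed
#' through when the service supplies them.
#'
#' @param genes Ensembl gene IDs.
#' @param qtl_types Subset of `eqtl`, `pqtl`, `sqtl`, `sceqtl`, `scpqtl`.
#' @param min_l2g Minimum L2G score retained (default 0.5).
#' @param cache_dir,offline,endpoint,fetcher See [query_opentargets()].
#' @return Credible-set tibble: `study_id`, `qtl_type`, `tissue_or_cell`,
#'   `target_gene`, `lead_variant`, `l2g_score`, `coloc_h4`.
#' @export
query_qtl <- function(genes, qtl_types = QTL_TYPES, min_l2g = 0.5,
                      cache_dir, offline = TRUE,
                      endpoint = OT_DEFAULT_ENDPOINT,
                      fetcher = default_fetcher) {
  bad <- setdiff(qtl_types, QTL_TYPES)
  if (length(bad) > 0) {
    lp_stop(paste0("unknown qtl_type(s): ", paste(bad, collapse = ", "),
                   " (allowed: ", paste(QTL_TYPES, collapse = ", "), ")"))
  }
  lp_assert(length(min_l2g) == 1 && is.numeric(min_l2g) &&
              min_l2g >= 0 && min_l2g <= 1,
            "`min_l2g` must be a number in [0, 1]")
  genes <- unique(as.character(genes))
  if (length(genes) == 0) return(empty_credible_sets())

  rows <- list()
  for (gene in genes) {
    body <- qtl_request_body(gene)
    payload <- cached_request(endpoint, body, cache_dir, offline, fetcher)
    parsed <- parse_payload(payload, cache_key(endpoint, body))
    for (r in parsed$data$target$credibleSets) {
      rows[[length(rows) + 1L]] <- tibble(
        study_id = r$studyId %||% NA_character_,
        qtl_type = r$qtlType %||% NA_character_,
        tissue_or_cell = r$tissue %||% NA_character_,
        target_gene = gene,
        lead_variant = r$leadVariant %||% NA_character_,
        l2g_score = as.numeric(r$l2g %||% NA_real_),
        coloc_h4 = as.numeric(r$colocH4 %||% NA_real_)
      )
    }
  }
  if (length(rows) == 0) return(empty_credible_sets())
  out <- dplyr::bind_rows(rows)
  if (any(!is.na(out$l2g_score) & (out$l2g_score < 0 | out$l2g_score > 1))) {
    lp_stop("service returned an L2G score outside [0, 1]")
  }
  out <- out[out$qtl_type %in% qtl_types, , drop = FALSE]
  out <- out[!is.na(out$l2g_score) & out$l2g_score >= min_l2g, , drop = FALSE]
  out[order(out$target_gene, out$study_id, out$lead_variant), ]
}

#' Filter trait associations by phenotype patterns
#'
#' Mined gene-trait associations are best read in two passes: an
#' `explicit` pass matching the study's primary phenotype (known genes that
#' may explain a locus), then a `related` pass with a broader pattern list
#' (e.g. blood pressure alongside cardiac hypertrophy) surfacing less
#' well-studied candidates. Patterns are case-insensitive regular
#' expressions (plain substrings work as-is); the unfiltered association
#' table is left untouched — only the filtered view changes.
#'
#' @param associations Association tibble (from the query functions).
#' @param patterns Character vector of patterns, or a named list with
#'   `explicit` and `related` entries selected by `pass`.
#' @param pass Which pass this is: `"explicit"` or `"related"`.
#' @return The matching association rows (empty for an empty pattern list).
#' @export
filter_traits <- function(associations, patterns,
                          pass = c("explicit", "related")) {
  pass <- match.arg(pass)
  if (is.list(patterns) && !is.null(names(patterns))) {
    lp_assert(pass %in% names(patterns),
              paste0("`patterns` has no '", pass, "' entry"))
    patterns <- patterns[[pass]]
  }
  patterns <- as.character(patterns)
  lp_assert(is.data.frame(associations) && "trait_label" %in% names(associations),
            "`associations` must carry a trait_label column")
  if (length(patterns) == 0) {
    return(associations[0, , drop = FALSE])
  }
  hit <- rep(FALSE, nrow(associations))
  for (p in patterns) {
    m <- tryCatch(
      suppressWarnings(grepl(p, associations$trait_label, ignore.case = TRUE)),
      error = function(e) {
        lp_stop(paste0("invalid trait pattern '", p, "': ", conditionMessage(e)))
      }
    )
    hit <- hit | (m %na% FALSE)
  }
  associations[hit, , drop = FALSE]
}
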