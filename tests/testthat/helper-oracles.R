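# Independent oracles used by the property-style suites. Each one takes
# the dumbest correct route (pairwise enumeration, per-row host-language
# evaluation, explicit subset enumeration) so it shares no code path with
# the implementation it checks.

BUILD <- genome_build("mm39", "Mus musculus")

# Brute-force transitive-closure merge: repeatedly fuse any two intervals
# on one chromosome whose gap (start2 - end1 for the later one) is
# <= max_gap, until a fixed point. Returns a sorted chrom/start/end tibble.
oracle_merge <- function(df, max_gap = 0) {
  rows <- split(df, seq_len(nrow(df)))
  repeat {
    fused <- FALSE
    for (i in seq_along(rows)) {
      if (is.null(rows[[i]])) next
      for (j in seq_along(rows)) {
        if (i == j || is.null(rows[[j]]) || is.null(rows[[i]])) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom != b$chrom) next
        gap <- max(a$start, b$start) - min(a$end, b$end)
        if (gap <= max_gap) {
          rows[[i]]$start <- min(a$start, b$start)
          rows[[i]]$end <- max(a$end, b$end)
          rows[j] <- list(NULL)
          fused <- TRUE
        }
      }
    }
    if (!fused) break
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[order(out$chrom, out$start, out$end), c("chrom", "start", "end")]
  rownames(out) <- NULL
  out
}

# Normalize any loci-like object to a bare chrom/start/end frame for
# comparison against oracle output.
interval_frame <- function(x) {
  data.frame(chrom = as.character(x$chrom), start = as.numeric(x$start),
             end = as.numeric(x$end))
}

random_intervals <- function(n, n_chrom = 3, span = 1000) {
  start <- sample.int(span, n, replace = TRUE)
  len <- sample.int(80, n, replace = TRUE)
  data.frame(chr = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
             start = start, end = start + len)
}

# Per-row evaluation through R's own evaluator: parse the expression text
# with base R, evaluate it in a one-row environment where is_missing /
# contains / abs are defined, then coerce a missing result to FALSE. This
# exercises R's native three-valued semantics, a route disjoint from the
# package's vectorized AST walker.
oracle_evaluate <- function(expression, sheet) {
  parsed <- parse(text = expression)[[1]]
  vapply(seq_len(nrow(sheet)), function(i) {
    env <- new.env(parent = baseenv())
    for (nm in names(sheet)) assign(nm, sheet[[nm]][[i]], envir = env)
    assign("true", TRUE, envir = env)
    assign("false", FALSE, envir = env)
    assign("is_missing", is.na, envir = env)
    assign("contains", function(x, s) {
      out <- grepl(s, as.character(x), fixed = TRUE)
      out[is.na(x)] <- NA
      out
    }, envir = env)
    assign("abs", base::abs, envir = env)
    v <- eval(parsed, env)
    isTRUE(v)
  }, logical(1))
}

# Explicit 2^k subset enumeration of UpSet classes over a boolean matrix
# (rows already restricted to the screened genes).
oracle_upset <- function(mat) {
  k <- ncol(mat)
  nms <- colnames(mat)
  counts <- integer()
  for (code in 0:(2^k - 1)) {
    members <- nms[bitwAnd(code, 2^(seq_len(k) - 1)) > 0]
    hit <- apply(mat, 1, function(row) identical(nms[row], members))
    n <- sum(hit)
    if (n > 0) counts[[paste(members, collapse = "&")]] <- n
  }
  counts
}

# Small deterministic annotation used across tests.
tiny_annotation <- function(n = 10, chrom = "chr1", start0 = 1000,
                            gap = 500, len = 400) {
  starts <- start0 + (seq_len(n) - 1) * (gap + len)
  gene_annotation(
    tibble::tibble(
      gene_symbol = sprintf("Tg%02d", seq_len(n)),
      ensembl_id = sprintf("ENSMUSG%011d", seq_len(n)),
      chrom = chrom, start = starts, end = starts + len - 1,
      strand = rep(c("+", "-"), length.out = n),
      biotype = "protein_coding",
      human_ortholog = sprintf("TG%02d", seq_len(n)),
      expression_cpm = 10
    ),
    BUILD
  )
}

expect_lp_error <- function(expr, class = "lp_validation_error",
                            pattern = NULL) {
  expect_error(expr, regexp = pattern, class = class)
}
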