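# The screening engine: a small, safe boolean expression language over
# gene-sheet columns, three-valued (Kleene) evaluation, required vs
# supportive criteria, and UpSet-style evidence-overlap counts.
#
# The grammar is closed by construction: identifiers name sheet columns,
# the only callables are is_missing/contains/abs, and nothing else is
# evaluable — so user criteria files can never execute arbitrary code.

# --- Tokenizer ---------------------------------------------------------------

CRITERIA_FUNCTIONS <- c("is_missing", "contains", "abs")

tokenize_expression <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    two <- substr(text, i, i + 1L)
    if (two %in% c("==", "!=", "<=", ">=")) { push("op", two, i); i <- i + 2L; next }
    if (ch %in% c("<", ">")) { push("op", ch, i); i <- i + 1L; next }
    if (ch == "&") { push("and", ch, i); i <- i + 1L; next }
    if (ch == "|") { push("or", ch, i); i <- i + 1L; next }
    if (ch == "!") { push("not", ch, i); i <- i + 1L; next }
    if (ch == "(") { push("lparen", ch, i); i <- i + 1L; next }
    if (ch == ")") { push("rparen", ch, i); i <- i + 1L; next }
    if (ch == ",") { push("comma", ch, i); i <- i + 1L; next }
    if (ch == "\"" || ch == "'") {
      rest <- substr(text, i + 1L, n)
      close_rel <- regexpr(ch, rest, fixed = TRUE)
      if (close_rel < 0) {
        lp_stop(paste0("parse error at position ", i, ": unterminated string"))
      }
      push("string", substr(rest, 1L, close_rel - 1L), i)
      i <- i + close_rel + 1L
      next
    }
    if (grepl("^[0-9.]$", ch)) {
      m <- regmatches(substr(text, i, n),
                      regexpr("^[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?", substr(text, i, n)))
      if (length(m) == 0 || !nzchar(m)) {
        lp_stop(paste0("parse error at position ", i, ": malformed number"))
      }
      push("number", as.numeric(m), i)
      i <- i + nchar(m)
      next
    }
    if (grepl("^[A-Za-z_]$", ch)) {
      m <- regmatches(substr(text, i, n),
                      regexpr("^[A-Za-z_][A-Za-z0-9_.]*", substr(text, i, n)))
      if (tolower(m) %in% c("true", "false")) {
        push("bool", tolower(m) == "true", i)
      } else {
        push("ident", m, i)
      }
      i <- i + nchar(m)
      next
    }
    lp_stop(paste0("parse error at position ", i, ": unexpected character '", ch, "'"),
            class = "lp_parse_error")
  }
  tokens
}

# --- Recursive-descent parser ------------------------------------------------
#
# or   := and ('|' and)*
# and  := cmp ('&' cmp)*
# cmp  := term (('=='|'!='|'<'|'<='|'>'|'>=') term)?
# term := '!' term | primary
# primary := number | string | true | false | column
#          | fn '(' args ')' | '(' or ')'

#' Parse a criteria expression
#'
#' Parses a boolean screening expression into a validated expression tree.
#' Identifiers are sheet column names (dots allowed, e.g. `de.padj`);
#' literals are numbers, quoted strings, and `true`/`false`; operators are
#' `== != < <= > >= & | !` with C-like precedence and parentheses; the
#' only functions are `is_missing(col)`, `contains(col, "substring")` and
#' `abs(x)`. Anything else is a parse error — the language cannot call
#' into R, so criteria files are safe to evaluate.
#'
#' @param expression Expression string, e.g.
#'   `'expression_cpm > 5 & biotype == "protein_coding"'`.
#' @return An `lp_expression` tree (also usable with [evaluate_expression()]).
#' @export
parse_expression <- function(expression) {
  lp_assert(is_string(expression) && nzchar(trimws(expression)),
            "`expression` must be a non-empty string")
  tokens <- tokenize_expression(expression)
  pos <- 1L

  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { tok <- tokens[[pos]]; pos <<- pos + 1L; tok }
  expect <- function(type, what) {
    tok <- peek()
    if (is.null(tok) || tok$type != type) {
      at <- if (is.null(tok)) paste0("end of expression") else
        paste0("position ", tok$pos)
      lp_stop(paste0("parse error at ", at, ": expected ", what),
              class = "lp_parse_error")
    }
    advance()
  }

  parse_or <- function() {
    node <- parse_and()
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      node <- list(type = "or", lhs = node, rhs = parse_and())
    }
    node
  }
  parse_and <- function() {
    node <- parse_cmp()
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      node <- list(type = "and", lhs = node, rhs = parse_cmp())
    }
    node
  }
  parse_cmp <- function() {
    node <- parse_term()
    tok <- peek()
    if (!is.null(tok) && tok$type == "op") {
      advance()
      node <- list(type = "cmp", op = tok$value, lhs = node, rhs = parse_term())
    }
    node
  }
  parse_term <- function() {
    tok <- peek()
    if (!is.null(tok) && tok$type == "not") {
      advance()
      return(list(type = "not", arg = parse_term()))
    }
    parse_primary()
  }
  parse_primary <- function() {
    tok <- peek()
    if (is.null(tok)) {
      lp_stop("parse error at end of expression: expected a value",
              class = "lp_parse_error")
    }
    if (tok$type == "number") { advance(); return(list(type = "num", value = tok$value)) }
    if (tok$type == "string") { advance(); return(list(type = "str", value = tok$value)) }
    if (tok$type == "bool") { advance(); return(list(type = "bool", value = tok$value)) }
    if (tok$type == "lparen") {
      advance()
      node <- parse_or()
      expect("rparen", "')'")
      return(node)
    }
    if (tok$type == "ident") {
      advance()
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "lparen") {
        if (!tok$value %in% CRITERIA_FUNCTIONS) {
          lp_stop(paste0("parse error at position ", tok$pos,
                         ": unknown function '", tok$value,
                         "' (allowed: ", paste(CRITERIA_FUNCTIONS, collapse = ", "), ")"),
                  class = "lp_parse_error")
        }
        advance()
        args <- list()
        if (!is.null(peek()) && peek()$type != "rparen") {
          args[[1]] <- parse_or()
          while (!is.null(peek()) && peek()$type == "comma") {
            advance()
            args[[length(args) + 1L]] <- parse_or()
          }
        }
        expect("rparen", "')' closing the call")
        n_expected <- if (tok$value == "contains") 2L else 1L
        if (length(args) != n_expected) {
          lp_stop(paste0(tok$value, "() takes ", n_expected, " argument(s)"),
                  class = "lp_parse_error")
        }
        return(list(type = "call", fn = tok$value, args = args))
      }
      return(list(type = "col", name = tok$value))
    }
    lp_stop(paste0("parse error at position ", tok$pos,
                   ": unexpected '", tok$value, "'"),
            class = "lp_parse_error")
  }

  tree <- parse_or()
  if (pos <= length(tokens)) {
    tok <- tokens[[pos]]
    lp_stop(paste0("parse error at position ", tok$pos,
                   ": unexpected trailing '", tok$value, "'"),
            class = "lp_parse_error")
  }
  structure(list(tree = tree, source = expression), class = "lp_expression")
}

#' @export
print.lp_expression <- function(x, ...) {
  cat("<criteria expression> ", x$source, "\n", sep = "")
  invisible(x)
}

# --- Evaluator ---------------------------------------------------------------
#
# Vectorized over sheet rows. Missingness follows Kleene three-valued
# logic: comparisons with NA are NA, & and | resolve when one side
# determines the outcome (R's native semantics), ! propagates NA, and
# is_missing() is the only construct that observes NA directly.

node_label <- function(node) {
  if (node$type == "col") node$name else "expression"
}

eval_node <- function(node, sheet, n) {
  switch(node$type,
    num = rep(node$value, n),
    str = rep(node$value, n),
    bool = rep(node$value, n),
    col = {
      if (!node$name %in% names(sheet)) {
        lp_stop(paste0("unknown column in criteria expression: `", node$name, "`"),
                class = "lp_eval_error")
      }
      sheet[[node$name]]
    },
    not = {
      v <- eval_node(node$arg, sheet, n)
      if (!is.logical(v)) {
        lp_stop("`!` applied to a non-boolean value", class = "lp_eval_error")
      }
      !v
    },
    call = eval_call(node, sheet, n),
    cmp = eval_cmp(node, sheet, n),
    and = {
      l <- as_logical_operand(eval_node(node$lhs, sheet, n), "&")
      r <- as_logical_operand(eval_node(node$rhs, sheet, n), "&")
      l & r
    },
    or = {
      l <- as_logical_operand(eval_node(node$lhs, sheet, n), "|")
      r <- as_logical_operand(eval_node(node$rhs, sheet, n), "|")
      l | r
    },
    lp_stop(paste0("internal: unknown node type ", node$type))
  )
}

as_logical_operand <- function(v, op) {
  if (!is.logical(v)) {
    lp_stop(paste0("operand of `", op, "` is not boolean"),
            class = "lp_eval_error")
  }
  v
}

eval_call <- function(node, sheet, n) {
  switch(node$fn,
    is_missing = {
      v <- eval_node(node$args[[1]], sheet, n)
      is.na(v)
    },
    contains = {
      v <- eval_node(node$args[[1]], sheet, n)
      pat <- node$args[[2]]
      if (pat$type != "str") {
        lp_stop("contains() needs a quoted string as its second argument",
                class = "lp_eval_error")
      }
      out <- grepl(pat$value, as.character(v), fixed = TRUE)
      out[is.na(v)] <- NA
      out
    },
    abs = {
      v <- eval_node(node$args[[1]], sheet, n)
      if (!is.numeric(v)) {
        lp_stop(paste0("abs() applied to non-numeric `",
                       node_label(node$args[[1]]), "`"),
                class = "lp_eval_error")
      }
      abs(v)
    }
  )
}

eval_cmp <- function(node, sheet, n) {
  l <- eval_node(node$lhs, sheet, n)
  r <- eval_node(node$rhs, sheet, n)
  op <- node$op
  if (op %in% c("<", "<=", ">", ">=")) {
    if (!is.numeric(l) || !is.numeric(r)) {
      offender <- if (!is.numeric(l)) node_label(node$lhs) else node_label(node$rhs)
      lp_stop(paste0("operator `", op, "` needs numeric operands but `",
                     offender, "` is not numeric"),
              class = "lp_eval_error")
    }
  } else {
    compatible <- (is.numeric(l) && is.numeric(r)) ||
      (is.character(l) && is.character(r)) ||
      (is.logical(l) && is.logical(r))
    if (!compatible) {
      lp_stop(paste0("operator `", op, "` compares incompatible types for `",
                     node_label(node$lhs), "` and `", node_label(node$rhs), "`"),
              class = "lp_eval_error")
    }
  }
  switch(op,
    "==" = l == r, "!=" = l != r,
    "<" = l < r, "<=" = l <= r, ">" = l > r, ">=" = l >= r)
}

#' Evaluate a parsed expression over a sheet
#'
#' Returns the raw three-valued result (`TRUE`/`FALSE`/`NA`) per row,
#' without the final missing-to-false coercion applied by
#' [evaluate_criteria()].
#'
#' @param expr An [parse_expression()] result (or expression string).
#' @param sheet Data frame of gene-sheet columns.
#' @return Logical vector of `nrow(sheet)` values (may contain `NA`).
#' @export
evaluate_expression <- function(expr, sheet) {
  if (is.character(expr)) expr <- parse_expression(expr)
  lp_assert(inherits(expr, "lp_expression"), "`expr` must be a parsed expression")
  v <- eval_node(expr$tree, sheet, nrow(sheet))
  if (!is.logical(v)) {
    lp_stop("criteria expression does not evaluate to TRUE/FALSE",
            class = "lp_eval_error")
  }
  as.logical(v)
}

# --- Criteria ----------------------------------------------------------------

#' Define a screening criterion
#'
#' Criteria come in two kinds. `required` criteria are hard screens: a gene
#' must satisfy every one of them to stay in the candidate pool (e.g.
#' protein-coding, human ortholog present, expressed above 5 cpm in the
#' validation cell type). `supportive` criteria accumulate evidence (e.g.
#' differential expression, a cis-eQTL, a coding variant, a prior trait
#' link): they never remove a gene, but their per-gene count and overlap
#' pattern drive prioritization.
#'
#' @param name Unique criterion name.
#' @param expression Expression string (see [parse_expression()]).
#' @param kind `"required"` or `"supportive"`.
#' @return An `lp_criterion`.
#' @examples
#' criterion("expressed", "expression_cpm > 5", "required")
#' @export
criterion <- function(name, expression, kind = c("required", "supportive")) {
  kind <- match.arg(kind)
  lp_assert(is_string(name) && nzchar(name), "`name` must be a non-empty string")
  parsed <- parse_expression(expression)
  structure(list(name = name, expression = expression, parsed = parsed,
                 kind = kind),
            class = "lp_criterion")
}

#' Read criteria from a YAML or JSON file
#'
#' The file holds a list of `{name, kind, expression}` entries.
#'
#' @param path Path to `.yaml`/`.yml` or `.json`.
#' @return List of [criterion()] objects.
#' @export
read_criteria <- function(path) {
  if (!file.exists(path)) lp_stop_io(paste0("criteria file not found: ", path))
  entries <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  lapply(entries, function(e) {
    lp_assert(all(c("name", "kind", "expression") %in% names(e)),
              "each criteria entry needs name, kind, expression")
    criterion(e$name, e$expression, e$kind)
  })
}

check_criteria <- function(criteria) {
  lp_assert(is.list(criteria), "`criteria` must be a list of criterion()")
  ok <- vapply(criteria, inherits, logical(1), what = "lp_criterion")
  lp_assert(all(ok), "`criteria` must be a list of criterion() objects")
  nms <- vapply(criteria, function(c) c$name, character(1))
  if (anyDuplicated(nms)) {
    lp_stop(paste0("duplicated criterion name(s): ",
                   paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  criteria
}

#' Evaluate required and supportive criteria over a gene sheet
#'
#' Each criterion is evaluated with three-valued logic and the final value
#' coerced missing-to-false: a gene with no evidence for a criterion does
#' not meet it (use `is_missing()` inside an expression to ask about
#' missingness itself). `pass_required` is the conjunction of all required
#' criteria (vacuously true when there are none); `evidence_count` is the
#' per-gene number of satisfied supportive criteria.
#'
#' @param sheet Gene sheet data frame.
#' @param criteria List of [criterion()] objects.
#' @return An `lp_criteria_result`: `$table` has one logical column per
#'   criterion plus `evidence_count` and `pass_required`, row-aligned with
#'   `sheet`; `$criteria` keeps the definitions.
#' @export
evaluate_criteria <- function(sheet, criteria) {
  lp_assert(is.data.frame(sheet), "`sheet` must be a data frame")
  criteria <- check_criteria(criteria)
  n <- nrow(sheet)

  cols <- lapply(criteria, function(cr) {
    v <- evaluate_expression(cr$parsed, sheet)
    v[is.na(v)] <- FALSE  # absent evidence is unmet evidence
    v
  })
  names(cols) <- vapply(criteria, function(c) c$name, character(1))
  kinds <- vapply(criteria, function(c) c$kind, character(1))

  tbl <- if (length(cols) > 0) as_tibble(cols) else tibble(.rows = n)
  required <- names(cols)[kinds == "required"]
  supportive <- names(cols)[kinds == "supportive"]

  pass_required <- rep(TRUE, n)
  for (nm in required) pass_required <- pass_required & tbl[[nm]]
  evidence_count <- if (length(supportive) > 0) {
    as.integer(rowSums(tbl[, supportive, drop = FALSE]))
  } else {
    rep(0L, n)
  }
  tbl$evidence_count <- evidence_count
  tbl$pass_required <- pass_required

  structure(
    list(table = tbl, criteria = criteria,
         required = required, supportive = supportive),
    class = "lp_criteria_result"
  )
}

#' @export
print.lp_criteria_result <- function(x, ...) {
  cat("<criteria result> ", nrow(x$table), " genes; ",
      sum(x$table$pass_required), " pass ", length(x$required),
      " required criteria; ", length(x$supportive),
      " supportive criteria\n", sep = "")
  invisible(x)
}

#' Screen a sheet to the genes passing all required criteria
#'
#' @param sheet The sheet the result was computed on.
#' @param result An [evaluate_criteria()] result row-aligned with `sheet`.
#' @return The passing rows, column and row order preserved.
#' @export
screen <- function(sheet, result) {
  lp_assert(inherits(result, "lp_criteria_result"),
            "`result` must come from evaluate_criteria()")
  lp_assert(nrow(sheet) == nrow(result$table),
            "`result` was not computed on this sheet (row counts differ)")
  sheet[result$table$pass_required, , drop = FALSE]
}

#' Evidence-overlap (UpSet) class counts
#'
#' Partitions the genes passing the required screen by their exact set of
#' satisfied supportive criteria (standard UpSet semantics: classes are
#' disjoint, and a gene with no satisfied criterion falls in the empty
#' class). Counts always sum to the number of passing genes.
#'
#' @param result An [evaluate_criteria()] result.
#' @param criteria_names Criteria to include (default: all supportive).
#' @return An `lp_overlap_counts` tibble: `members` (list of criterion
#'   names), `key` (`"A&B"`-style label, `""` for the empty class), and
#'   `count`, sorted by descending count.
#' @export
overlap_counts <- function(result, criteria_names = NULL) {
  lp_assert(inherits(result, "lp_criteria_result"),
            "`result` must come from evaluate_criteria()")
  criteria_names <- criteria_names %||% result$supportive
  known <- setdiff(names(result$table), c("evidence_count", "pass_required"))
  bad <- setdiff(criteria_names, known)
  if (length(bad) > 0) {
    lp_stop(paste0("unknown criterion name(s): ", paste(bad, collapse = ", ")))
  }

  tbl <- result$table[result$table$pass_required, , drop = FALSE]
  if (nrow(tbl) == 0) {
    out <- tibble(members = list(), key = character(), count = integer())
    attr(out, "criteria_names") <- criteria_names
    attr(out, "n_genes") <- 0L
    class(out) <- unique(c("lp_overlap_counts", class(out)))
    return(out)
  }
  keys <- vapply(seq_len(nrow(tbl)), function(i) {
    members <- criteria_names[vapply(criteria_names,
                                     function(nm) isTRUE(tbl[[nm]][[i]]),
                                     logical(1))]
    paste(members, collapse = "&")
  }, character(1))
  counts <- table(keys)
  out <- tibble(
    key = names(counts),
    members = lapply(names(counts), function(k)
      if (nzchar(k)) strsplit(k, "&", fixed = TRUE)[[1]] else character()),
    count = as.integer(counts)
  )
  out <- out[order(-out$count, out$key), c("members", "key", "count")]
  stopifnot(sum(out$count) == nrow(tbl))  # conservation, by construction
  attr(out, "criteria_names") <- criteria_names
  attr(out, "n_genes") <- nrow(tbl)
  class(out) <- unique(c("lp_overlap_counts", class(out)))
  out
}
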