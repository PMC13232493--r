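test_that("the expression grammar parses screening criteria", {
  e <- parse_expression('expression_cpm > 5 & biotype == "protein_coding"')
  expect_equal(e$tree$type, "and")
  expect_equal(e$tree$lhs$type, "cmp")
  expect_equal(e$tree$lhs$op, ">")
  expect_equal(e$tree$lhs$lhs$name, "expression_cpm")
  expect_equal(e$tree$rhs$op, "==")
  expect_equal(e$tree$rhs$rhs$value, "protein_coding")

  expect_s3_class(parse_expression("!is_missing(eqtl.pval)"), "lp_expression")
  expect_s3_class(parse_expression("abs(logFC) >= 1 | de.padj < 0.05"),
                  "lp_expression")
})

test_that("parse errors carry a position and reject unsafe constructs", {
  expect_lp_error(parse_expression("a > (b"), class = "lp_parse_error",
                  pattern = "expected ')'")
  expect_lp_error(parse_expression("system('ls')"), class = "lp_parse_error",
                  pattern = "unknown function")
  expect_lp_error(parse_expression("a > 1 extra"), class = "lp_parse_error",
                  pattern = "trailing")
  expect_lp_error(parse_expression("a @ b"), class = "lp_parse_error",
                  pattern = "position")
})

test_that("missing evidence means criterion unmet; is_missing escapes that", {
  sheet <- tibble::tibble(de.padj = c(NA, 0.01, 0.5))
  res <- evaluate_criteria(sheet, list(
    criterion("de", "de.padj < 0.05", "supportive"),
    criterion("no_de", "is_missing(de.padj)", "supportive")
  ))
  expect_equal(res$table$de, c(FALSE, TRUE, FALSE))
  expect_equal(res$table$no_de, c(TRUE, FALSE, FALSE))
  expect_equal(res$table$evidence_count, c(1L, 1L, 0L))
})

test_that("Kleene logic resolves when one operand decides the outcome", {
  sheet <- tibble::tibble(a = c(NA, 10), b = c(1, 1))
  # NA & FALSE is FALSE; NA | TRUE is TRUE
  res <- evaluate_criteria(sheet, list(
    criterion("and_false", "a > 5 & b > 5", "supportive"),
    criterion("or_true", "a > 5 | b > 0", "supportive"),
    criterion("and_na", "a > 5 & b > 0", "supportive")
  ))
  expect_equal(res$table$and_false, c(FALSE, FALSE))
  expect_equal(res$table$or_true, c(TRUE, TRUE))
  expect_equal(res$table$and_na, c(FALSE, TRUE))  # NA coerces to FALSE
})

test_that("evaluation errors name the offending column and operator", {
  sheet <- tibble::tibble(biotype = "protein_coding")
  expect_lp_error(
    evaluate_criteria(sheet, list(criterion("x", "nope > 1", "required"))),
    class = "lp_eval_error", pattern = "nope")
  expect_lp_error(
    evaluate_criteria(sheet, list(criterion("x", "biotype > 1", "required"))),
    class = "lp_eval_error", pattern = "biotype")
  expect_lp_error(
    evaluate_criteria(sheet, list(criterion("x", 'biotype == 5', "required"))),
    class = "lp_eval_error", pattern = "==")
})

test_that("contains() and abs() work over sheet columns", {
  sheet <- tibble::tibble(consequence = c("missense;start_loss", NA, "synonymous"),
                          logFC = c(-2, 0.1, NA))
  res <- evaluate_criteria(sheet, list(
    criterion("var", 'contains(consequence, "missense")', "supportive"),
    criterion("big", "abs(logFC) > 1", "supportive")
  ))
  expect_equal(res$table$var, c(TRUE, FALSE, FALSE))
  expect_equal(res$table$big, c(TRUE, FALSE, FALSE))
})

test_that("screen keeps exactly the genes passing all required criteria", {
  set.seed(5)
  n <- 100
  sheet <- tibble::tibble(
    gene = sprintf("g%03d", 1:n),
    cpm = c(runif(44, 6, 50), runif(n - 44, 0, 4.9))[sample.int(n)]
  )
  res <- evaluate_criteria(sheet, list(criterion("expr", "cpm > 5", "required")))
  kept <- screen(sheet, res)
  expect_equal(nrow(kept), 44)
  expect_equal(names(kept), names(sheet))
  expect_true(all(kept$cpm > 5))

  # no required criteria: everything passes
  res0 <- evaluate_criteria(sheet, list())
  expect_equal(nrow(screen(sheet, res0)), n)
  # contradictory criterion: nothing does
  resc <- evaluate_criteria(sheet, list(
    criterion("never", "cpm > 1 & cpm < 0", "required")))
  expect_equal(nrow(screen(sheet, resc)), 0)
})

test_that("screening is monotone in the required criteria set", {
  set.seed(6)
  sheet <- tibble::tibble(a = runif(50), b = runif(50))
  r1 <- evaluate_criteria(sheet, list(criterion("a", "a > 0.3", "required")))
  r2 <- evaluate_criteria(sheet, list(criterion("a", "a > 0.3", "required"),
                                      criterion("b", "b > 0.3", "required")))
  expect_lte(nrow(screen(sheet, r2)), nrow(screen(sheet, r1)))
})

test_that("overlap classes are exact true-sets and conserve the total", {
  tbl <- tibble::tibble(A = c(TRUE, TRUE, TRUE), B = c(FALSE, FALSE, TRUE))
  res <- evaluate_criteria(tbl, list(criterion("sa", "A", "supportive"),
                                     criterion("sb", "B", "supportive")))
  oc <- overlap_counts(res)
  expect_equal(oc$count[oc$key == "sa"], 2L)
  expect_equal(oc$count[oc$key == "sa&sb"], 1L)
  expect_equal(sum(oc$count), 3L)

  none <- evaluate_criteria(tibble::tibble(x = 1), list(
    criterion("s", "x > 5", "supportive")))
  oc0 <- overlap_counts(none)
  expect_equal(oc0$key, "")
  expect_equal(oc0$count, 1L)

  expect_lp_error(overlap_counts(res, criteria_names = "ghost"),
                  pattern = "ghost")
})
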