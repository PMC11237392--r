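test_that("parser handles allele-redundant rules, complexes and single leaves", {
  g <- parse_gpr("PGI1_Scer or PGI1_Seub")
  expect_equal(g$kind, "or")
  expect_equal(vapply(g$children, `[[`, "", "gene"), c("PGI1_Scer", "PGI1_Seub"))

  g <- parse_gpr("((PFK1_Scer or PFK1_Seub) and (PFK2_Scer or PFK2_Seub))")
  expect_equal(g$kind, "and")
  expect_true(all(vapply(g$children, `[[`, "", "kind") == "or"))

  g <- parse_gpr("FBA1_Seub")
  expect_equal(g$kind, "leaf")
  expect_equal(g$gene, "FBA1_Seub")

  expect_null(parse_gpr(""))
  expect_null(parse_gpr("   "))
})

test_that("and binds tighter than or; keywords are case-insensitive", {
  g <- parse_gpr("a or b and c")
  expect_equal(g$kind, "or")
  expect_equal(g$children[[2]]$kind, "and")
  g2 <- parse_gpr("a OR b AND c")
  expect_true(gpr_identical(g, g2))
  # gene ids stay case-sensitive
  expect_false(gpr_identical(parse_gpr("A"), parse_gpr("a")))
})

test_that("parse errors carry a position and name the defect", {
  expect_error(parse_gpr("a or (b and c"), "position.*unbalanced", ignore.case = TRUE)
  expect_error(parse_gpr("a or or b"), "empty operand")
  expect_error(parse_gpr("a b"), "unexpected token")
  expect_error(parse_gpr("(a))"), "unexpected")
})

test_that("format/parse round trip is structural identity on random trees", {
  set.seed(11)
  for (i in 1:60) {
    tree <- random_gpr(max_depth = 6)
    expect_true(gpr_identical(parse_gpr(format_gpr(tree)), tree))
  }
  # fixed spot checks of rendering
  expect_equal(format_gpr(gpr_or(gpr_leaf("a"), gpr_leaf("b"))), "a or b")
  expect_equal(format_gpr(gpr_and(gpr_or(gpr_leaf("a"), gpr_leaf("b")),
                                  gpr_leaf("c"))), "(a or b) and c")
  expect_equal(format_gpr(gpr_leaf("g")), "g")
})

test_that("boolean evaluation matches exhaustive truth tables", {
  # one redundant allele suffices; a lost complex subunit kills the rule
  expect_true(evaluate_gpr(parse_gpr("a or b"), absent = "a"))
  expect_false(evaluate_gpr(parse_gpr("a and b"), absent = "a"))
  expect_false(evaluate_gpr(parse_gpr("(a or b) and c"), absent = c("a", "c")))

  set.seed(7)
  for (i in 1:25) {
    tree <- random_gpr(max_depth = 4, genes = paste0("g", 1:8))
    rule <- format_gpr(tree)
    genes <- gpr_genes(tree)
    stopifnot(length(genes) <= 10)
    combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(genes)))
    for (r in seq_len(nrow(combos))) {
      present <- genes[unlist(combos[r, ])]
      expect_identical(evaluate_gpr(tree, absent = setdiff(genes, present)),
                       boolean_oracle(rule, present))
    }
  }
})

test_that("expression aggregation follows OR = sum, AND = min, recursively", {
  expect_identical(aggregate_gpr(parse_gpr("a or b"), c(a = 5, b = 7)), 12)
  expect_identical(aggregate_gpr(parse_gpr("a and b"), c(a = 5, b = 7)), 5)
  expect_identical(aggregate_gpr(parse_gpr("(a or b) and c"),
                                 c(a = 5, b = 7, c = 6)), 6)
  # missing gene counts as 0; negative levels rejected
  expect_identical(aggregate_gpr(parse_gpr("a or b"), c(a = 5)), 5)
  expect_error(aggregate_gpr(parse_gpr("a"), c(a = -1)), "non-negative")
})

test_that("aggregation matches the postfix-evaluation oracle on random trees", {
  set.seed(23)
  for (i in 1:200) {
    tree <- random_gpr(max_depth = 5)
    rule <- format_gpr(tree)
    genes <- gpr_genes(tree)
    expr <- stats::setNames(round(runif(length(genes), 0, 50), 3), genes)
    expect_equal(aggregate_gpr(tree, expr), aggregate_oracle(rule, expr),
                 tolerance = 1e-12)
  }
})

test_that("aggregation is monotone and bounded by its children", {
  set.seed(31)
  for (i in 1:30) {
    tree <- random_gpr(max_depth = 4)
    genes <- gpr_genes(tree)
    expr <- stats::setNames(runif(length(genes), 0, 30), genes)
    base <- aggregate_gpr(tree, expr)
    # raising any one leaf never lowers the aggregate
    g <- sample(genes, 1)
    expr2 <- expr; expr2[g] <- expr2[g] + 10
    expect_gte(aggregate_gpr(tree, expr2), base)
  }
  # equal alleles add under OR (no saturation); complexes stay at the level
  expect_identical(aggregate_gpr(parse_gpr("a or b"), c(a = 4, b = 4)), 8)
  expect_identical(aggregate_gpr(parse_gpr("a and b and c"),
                                 c(a = 4, b = 4, c = 4)), 4)
  # OR >= max child, AND <= min child
  tree <- parse_gpr("(a and b) or (c and d)")
  expr <- c(a = 3, b = 9, c = 2, d = 5)
  expect_gte(aggregate_gpr(tree, expr), 3)
  tree2 <- parse_gpr("(a or b) and (c or d)")
  expect_lte(aggregate_gpr(tree2, expr), min(3 + 9, 2 + 5))
})

test_that("gpr_genes returns the exact leaf set", {
  expect_setequal(gpr_genes(parse_gpr("(a or b) and c")), c("a", "b", "c"))
  expect_identical(gpr_genes(gpr_leaf("g")), "g")
  expect_identical(gpr_genes(NULL), character())
  set.seed(5)
  for (i in 1:10) {
    tree <- random_gpr(max_depth = 4)
    walk <- function(nd) {
      if (nd$kind == "leaf") return(nd$gene)
      unlist(lapply(nd$children, walk))
    }
    expect_setequal(gpr_genes(tree), unique(walk(tree)))
  }
})
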