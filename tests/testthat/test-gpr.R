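test_that("GPR grammar honours precedence, flattening and operator spellings", {
  e <- parse_gpr("(gA and gB) or gC")
  expect_identical(e$kind, "or")
  expect_identical(e$children[[1]]$kind, "and")
  expect_identical(gpr_genes(e), c("gA", "gB", "gC"))

  # bare gene is a leaf
  expect_identical(unclass(parse_gpr("gA")),
                   list(kind = "gene", gene = "gA"))

  # AND binds tighter than OR when no parentheses disambiguate
  e2 <- parse_gpr("gA or gB and gC")
  expect_identical(e2$kind, "or")
  expect_identical(e2$children[[2]]$kind, "and")

  # operator chains flatten to n-ary nodes
  e3 <- parse_gpr("gA or gB or gC or gD")
  expect_length(e3$children, 4L)

  # accepted spellings are interchangeable
  for (rule in c("gA && gB", "gA & gB", "gA AND gB", "gA And gB"))
    expect_identical(deparse_gpr(parse_gpr(rule)), "gA and gB")
  for (rule in c("gA || gB", "gA | gB", "gA OR gB"))
    expect_identical(deparse_gpr(parse_gpr(rule)), "gA or gB")
})

test_that("malformed GPR rules fail with a character offset", {
  expect_error(parse_gpr("gA and or gB"), "character 8")
  expect_error(parse_gpr("(gA and gB"), "unbalanced")
  expect_error(parse_gpr("gA and"), "dangling")
  expect_error(parse_gpr("gA gB"), "unexpected token")
  expect_error(parse_gpr(""), "non-empty")
})

test_that("AND is min, OR is sum, and nesting composes", {
  em <- c(gA = 5, gB = 3, gC = 2)
  expect_equal(evaluate_ras(parse_gpr("gA and gB"), em), 3)
  expect_equal(evaluate_ras(parse_gpr("gA or gB"), em), 8)
  # frozen from the recursive reference evaluator: min(5,3) + 2
  expect_equal(evaluate_ras(parse_gpr("(gA and gB) or gC"), em), 5)
  expect_equal(evaluate_ras(parse_gpr("gA"), em), 5)
})

test_that("missing-gene policy drops (skip) or zeroes (zero) absent genes", {
  e <- parse_gpr("gA and gB")
  em <- c(gA = 5)
  expect_equal(evaluate_ras(e, em, "skip"), 5)
  expect_equal(evaluate_ras(e, em, "zero"), 0)
  # fully unmeasured -> undefined under skip, 0 under zero
  expect_true(is.na(evaluate_ras(e, c(gX = 1), "skip")))
  expect_equal(evaluate_ras(e, c(gX = 1), "zero"), 0)
  expect_error(evaluate_ras(e, c(gA = -1)), "non-negative")
})

test_that("random GPR trees match the reference evaluator under both policies", {
  set.seed(42)
  for (i in 1:250) {
    tree <- random_gpr_tree()
    rule <- render_gpr_tree(tree)
    genes <- tree_genes(tree)
    measured <- genes[stats::runif(length(genes)) < 0.7]
    em <- stats::setNames(as.numeric(sample(0:1000, length(measured),
                                            replace = TRUE)), measured)
    parsed <- parse_gpr(rule)
    for (policy in c("skip", "zero")) {
      got <- evaluate_ras(parsed, em, policy)
      want <- reference_eval_gpr(tree, em, policy)
      expect_identical(is.na(got), is.na(want), info = rule)
      if (!is.na(want)) expect_identical(got, want, info = rule)
    }
  }
})

test_that("RAS is monotone in abundances and scale-equivariant", {
  set.seed(7)
  for (i in 1:50) {
    tree <- random_gpr_tree()
    rule <- render_gpr_tree(tree)
    genes <- tree_genes(tree)
    em <- stats::setNames(as.numeric(sample(0:100, length(genes),
                                            replace = TRUE)), genes)
    parsed <- parse_gpr(rule)
    base <- evaluate_ras(parsed, em)
    # raising one gene never lowers the score
    g <- sample(genes, 1L)
    em2 <- em
    em2[g] <- em2[g] + 50
    expect_gte(evaluate_ras(parsed, em2), base)
    # multiplying all abundances by k multiplies the score by k
    k <- 3.7
    expect_equal(evaluate_ras(parsed, em * k), base * k, tolerance = 1e-12)
  }
})
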