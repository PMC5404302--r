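# Expression engine: evaluation, complexity, random generation, variation.

test_that("evaluation computes arithmetic and protects against non-finite results", {
  expect_equal(evaluate_expression(parse_expression("(x1 + x2)"),
                                   c(x1 = 1, x2 = 2)), 3)
  expect_equal(evaluate_expression(parse_expression("x3"), c(x3 = 0.7)), 0.7)
  # protected division: near-zero denominator returns 1.0
  expect_equal(evaluate_expression(parse_expression("(x1 / x2)"),
                                   c(x1 = 5, x2 = 0)), 1.0)
  expect_equal(evaluate_expression(parse_expression("(x1 / x2)"),
                                   c(x1 = 5, x2 = 1e-12)), 1.0)
  # overflow clamps rather than going infinite
  big <- evaluate_expression(parse_expression("((x1 * x1) * (x1 * x1))"),
                             c(x1 = 1e200))
  expect_true(is.finite(big))
  # missing feature errors by name
  expect_error(evaluate_expression(parse_expression("(x1 + zz)"), c(x1 = 1)),
               "zz")
})

test_that("evaluation is vectorised over samples and deterministic", {
  tr <- parse_expression("((g1 * g2) - (g1 / 2))")
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("g1", "g2")))
  v1 <- evaluate_expression(tr, x)
  expect_length(v1, 10)
  expect_identical(v1, evaluate_expression(tr, x))
  expect_equal(v1, x[, "g1"] * x[, "g2"] - x[, "g1"] / 2)
})

test_that("building-block count equals total node count", {
  expect_identical(count_building_blocks(parse_expression("x1")), 1L)
  expect_identical(count_building_blocks(parse_expression("(x1 + x2)")), 3L)
  expect_identical(count_building_blocks(parse_expression("((x1 + x2) * 2.5)")), 5L)
})

test_that("random trees respect the depth bound and the seed", {
  bb <- tiny_blocks()
  set.seed(1)
  leaf <- random_tree(bb, max_depth = 1)
  expect_true(leaf$kind %in% c("feat", "const"))
  set.seed(42); t1 <- random_tree(bb, max_depth = 4)
  set.seed(42); t2 <- random_tree(bb, max_depth = 4)
  expect_identical(t1, t2)
  set.seed(7)
  for (i in 1:1000) {
    tr <- random_tree(bb, max_depth = 4)
    expect_lte(mces:::tree_depth(tr), 4L)
    expect_true(mces:::validate_tree(tr, bb))
  }
  expect_error(random_tree(bb, max_depth = 0), "max_depth")
})

test_that("mutation respects size contracts and leaves the input unchanged", {
  bb <- tiny_blocks()
  # swap preserves node count on 1000 random trees
  set.seed(3)
  for (i in 1:1000) {
    tr <- random_tree(bb, max_depth = 4)
    sw <- mces:::mutate_swap(tr, bb)
    expect_identical(count_building_blocks(sw), count_building_blocks(tr))
    expect_true(mces:::validate_tree(sw, bb))
  }
  # remove on a single leaf is a no-op (floor at one node)
  leaf <- parse_expression("g1")
  expect_identical(mces:::mutate_remove(leaf), leaf)
  # add strictly grows, remove strictly shrinks multi-node trees
  set.seed(4)
  for (i in 1:100) {
    tr <- random_tree(bb, max_depth = 4)
    n <- count_building_blocks(tr)
    expect_gt(count_building_blocks(mces:::mutate_add(tr, bb)), n)
    if (n > 1) expect_lt(count_building_blocks(mces:::mutate_remove(tr)), n)
  }
  # the dispatching mutator validates rates and does not modify its input
  tr <- parse_expression("(g1 + g2)")
  before <- tr
  set.seed(5)
  out <- mutate_tree(tr, bb)
  expect_identical(tr, before)
  expect_true(mces:::validate_tree(out, bb))
  expect_error(mutate_tree(tr, bb, rates = c(add = 0.9, remove = 0.9, swap = 0.9)),
               "rates")
})

test_that("recombination draws material from both parents", {
  bb <- tiny_blocks()
  # two leaves: offspring is one of them
  set.seed(11)
  for (i in 1:20) {
    off <- recombine_trees(parse_expression("g1"), parse_expression("g2"))
    expect_true(format_expression(off) %in% c("g1", "g2"))
  }
  # leaf provenance: every feature leaf of the child comes from a parent
  a <- parse_expression("(g1 + g2)")
  b <- parse_expression("(g3 * g4)")
  set.seed(12)
  for (i in 1:100) {
    off <- recombine_trees(a, b)
    expect_true(all(expression_features(off) %in% c("g1", "g2", "g3", "g4")))
    expect_true(mces:::validate_tree(off, bb))
  }
  # both-parent content for multi-node parents
  set.seed(13)
  saw_b <- FALSE
  for (i in 1:50) {
    off <- recombine_trees(a, b)
    feats <- expression_features(off)
    expect_true(any(feats %in% c("g1", "g2")) || off$kind == "op")
    if (any(feats %in% c("g3", "g4"))) saw_b <- TRUE
  }
  expect_true(saw_b)
  # determinism under a fixed seed
  set.seed(14); o1 <- recombine_trees(a, b)
  set.seed(14); o2 <- recombine_trees(a, b)
  expect_identical(o1, o2)
})

test_that("protected evaluation stays finite on extreme inputs", {
  bb <- tiny_blocks(4)
  set.seed(21)
  x <- matrix(runif(5 * 4, -1e6, 1e6), 5, 4,
              dimnames = list(NULL, bb$feature_names))
  for (i in 1:1000) {
    tr <- random_tree(bb, max_depth = 5)
    expect_true(all(is.finite(evaluate_expression(tr, x))))
  }
})

test_that("expression strings round-trip losslessly", {
  bb <- building_blocks(c("Gsg1", "Stip1", "weird-name", "x.1"))
  set.seed(31)
  for (i in 1:200) {
    tr <- random_tree(bb, max_depth = 5)
    s <- format_expression(tr)
    expect_identical(format_expression(parse_expression(s)), s)
    expect_identical(parse_expression(s), tr)
  }
  # the documented example format, including negative constants
  tr <- parse_expression("((Gsg1 + 2.5) * Stip1)")
  expect_identical(format_expression(tr), "((Gsg1 + 2.5) * Stip1)")
  expect_identical(parse_expression("(g - -2.5)")$right$value, -2.5)
  # non-syntactic names survive via backticks
  tr2 <- parse_expression("(`weird-name` / 3)")
  expect_identical(expression_features(tr2), "weird-name")
})
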