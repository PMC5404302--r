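# Pareto domination, front extraction, and the grid tournament.

fake_solution <- function(acc, cplx) {
  structure(list(expression = paste0("s", acc, "_", cplx),
                 accuracy = acc, complexity = cplx),
            class = "ces_classifier")
}

test_that("domination requires weak improvement in both with one strict", {
  expect_true(dominates(0.9, 5, 0.8, 10))
  expect_false(dominates(0.9, 5, 0.9, 5))
  expect_false(dominates(0.9, 10, 0.8, 5))
  expect_false(dominates(0.8, 5, 0.9, 10))
  expect_true(dominates(0.9, 5, 0.9, 6))
  expect_true(dominates(0.91, 5, 0.9, 5))
})

test_that("pareto_front returns exactly the non-dominated members in order", {
  sols <- list(fake_solution(0.9, 5), fake_solution(0.8, 3), fake_solution(0.7, 10))
  front <- pareto_front(sols)
  expect_equal(vapply(front, `[[`, numeric(1), "accuracy"), c(0.9, 0.8))
  expect_length(pareto_front(sols[1]), 1)
  expect_error(pareto_front(list()), "non-empty")
})

test_that("pareto_front matches the quadratic brute-force filter", {
  set.seed(10)
  for (i in 1:500) {
    m <- sample(1:30, 1)
    acc <- round(runif(m), 2)   # rounding forces coordinate ties
    cplx <- sample(1:12, m, replace = TRUE)
    mask <- mces:::pareto_mask(acc, cplx)
    expect_identical(mask, brute_pareto_mask(acc, cplx))
    # no dominated pair inside the front
    keep <- which(mask)
    for (a in keep) for (b in keep) {
      if (a != b) expect_false(dominates(acc[a], cplx[a], acc[b], cplx[b]))
    }
  }
})

test_that("every cell of a toroidal grid has exactly 8 distinct neighbors", {
  for (d in c(3L, 4L, 5L)) {
    for (r in seq_len(d)) for (c in seq_len(d)) {
      nb <- neighborhood(d, r, c)
      expect_equal(nrow(nb), 8)
      expect_equal(nrow(unique(nb)), 8)
      expect_false(any(nb[, 1] == r & nb[, 2] == c))
      expect_true(all(nb >= 1 & nb <= d))
    }
  }
  # corner wrap: (1,1) of a 5x5 grid touches the opposite corner
  nb <- neighborhood(5, 1, 1)
  expect_true(any(nb[, 1] == 5 & nb[, 2] == 5))
  expect_error(neighborhood(5, 0, 1), "outside")
  expect_error(neighborhood(5, 1, 6), "outside")
})

test_that("a cell dominating its neighborhood repopulates all 8 neighbors", {
  d <- 4L
  ds <- separable_dataset(n_classes = 2, per_class = 5, p = 4)
  bb <- building_blocks(colnames(ds$x))
  set.seed(20)
  cells <- replicate(d * d, mces:::make_classifier(parse_expression("(g2 + g3)"),
                                                   ds$x, ds$labels),
                     simplify = FALSE)
  # plant one strictly dominating solution: the separating feature, 1 block
  champ <- mces:::make_classifier(parse_expression("g1"), ds$x, ds$labels)
  expect_equal(champ$accuracy, 1.0)
  pos <- mces:::grid_index(d, 2L, 2L)
  cells[[pos]] <- champ
  set.seed(21)
  step <- mces:::tournament_step(cells, d, ds$x, ds$labels, bb,
                                 c(add = 0.25, remove = 0.25, swap = 0.5))
  nb <- neighborhood(d, 2L, 2L)
  nb_idx <- mces:::grid_index(d, nb[, 1], nb[, 2])
  for (i in nb_idx) {
    expect_false(identical(step$cells[[i]]$expression, "(g2 + g3)"))
  }
  # untouched cells and the champion persist
  rest <- setdiff(seq_len(d * d), nb_idx)
  for (i in rest) expect_identical(step$cells[[i]], cells[[i]])
  expect_length(step$created, 8)
})

test_that("a grid of identical fitnesses does not change", {
  d <- 4L
  ds <- separable_dataset(n_classes = 2, per_class = 5, p = 4)
  bb <- building_blocks(colnames(ds$x))
  cells <- replicate(d * d, mces:::make_classifier(parse_expression("g2"),
                                                   ds$x, ds$labels),
                     simplify = FALSE)
  step <- mces:::tournament_step(cells, d, ds$x, ds$labels, bb,
                                 c(add = 0.25, remove = 0.25, swap = 0.5))
  expect_identical(step$cells, cells)
  expect_length(step$created, 0)
})

test_that("tournament steps are bit-identical under a fixed seed", {
  ds <- separable_dataset(n_classes = 3, per_class = 5, p = 6)
  bb <- building_blocks(colnames(ds$x))
  d <- 4L
  set.seed(30)
  cells <- replicate(d * d,
                     mces:::make_classifier(random_tree(bb, 3), ds$x, ds$labels),
                     simplify = FALSE)
  set.seed(31)
  s1 <- mces:::tournament_step(cells, d, ds$x, ds$labels, bb,
                               c(add = 0.25, remove = 0.25, swap = 0.5))
  set.seed(31)
  s2 <- mces:::tournament_step(cells, d, ds$x, ds$labels, bb,
                               c(add = 0.25, remove = 0.25, swap = 0.5))
  expect_identical(s1, s2)
})
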