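# Evolution loop, elitist archive, multi-level runs, and the ces() interface.

test_that("evolution finds a perfectly discriminating feature", {
  ds <- separable_dataset(n_classes = 3, per_class = 8, p = 10)
  set.seed(50)
  res <- evolve(ds$x, ds$labels, ces_config(grid_dim = 10, generations = 200))
  acc <- vapply(res$archive, `[[`, numeric(1), "accuracy")
  cplx <- vapply(res$archive, `[[`, numeric(1), "complexity")
  expect_equal(max(acc), 1.0)
  # the front holds a complexity-1 perfect classifier
  expect_true(any(acc == 1.0 & cplx == 1))
})

test_that("archive best accuracy is non-decreasing over generations", {
  ds <- separable_dataset(n_classes = 3, per_class = 6, p = 8)
  set.seed(51)
  res <- evolve(ds$x, ds$labels, ces_config(grid_dim = 8, generations = 60))
  expect_false(is.unsorted(res$trace))
  # archive is itself a Pareto front: no internal domination
  acc <- vapply(res$archive, `[[`, numeric(1), "accuracy")
  cplx <- vapply(res$archive, `[[`, numeric(1), "complexity")
  for (a in seq_along(acc)) for (b in seq_along(acc)) {
    if (a != b) expect_false(dominates(acc[a], cplx[a], acc[b], cplx[b]))
  }
})

test_that("generations=1 performs exactly one tournament step", {
  ds <- separable_dataset(n_classes = 2, per_class = 5, p = 5)
  set.seed(52)
  res <- evolve(ds$x, ds$labels, ces_config(grid_dim = 5, generations = 1))
  expect_length(res$trace, 2)  # initial grid + one step
  expect_error(ces_config(generations = 0), "generations")
})

test_that("runs are bit-reproducible given (data, config, seed)", {
  ds <- separable_dataset(n_classes = 3, per_class = 5, p = 6)
  cfg <- ces_config(grid_dim = 6, generations = 25)
  f1 <- ces(ds$x, ds$labels, cfg, seed = 123)
  f2 <- ces(ds$x, ds$labels, cfg, seed = 123)
  expect_identical(f1$archive, f2$archive)
  expect_identical(f1$best, f2$best)
  f3 <- ces(ds$x, ds$labels, cfg, seed = 124)
  expect_false(identical(f3$archive, f1$archive))
})

test_that("multi-level runs seed the next grid and never lose the best", {
  ds <- separable_dataset(n_classes = 3, per_class = 6, p = 8)
  cfg1 <- ces_config(grid_dim = 6, generations = 15, pareto_levels = 1)
  cfg2 <- ces_config(grid_dim = 6, generations = 15, pareto_levels = 2)
  set.seed(60)
  lv <- run_levels(ds$x, ds$labels, cfg2)
  expect_length(lv, 2)
  best1 <- max(vapply(lv[[1]]$archive, `[[`, numeric(1), "accuracy"))
  best2 <- max(vapply(lv[[2]]$archive, `[[`, numeric(1), "accuracy"))
  expect_gte(best2, best1)
  # pareto_levels = 1 is a single evolve call
  set.seed(61)
  lv1 <- run_levels(ds$x, ds$labels, cfg1)
  set.seed(61)
  ev <- evolve(ds$x, ds$labels, cfg1)
  expect_identical(lv1[[1]], ev)
})

test_that("level seeding places every archive member when it fits the grid", {
  ds <- separable_dataset(n_classes = 3, per_class = 6, p = 8)
  cfg <- ces_config(grid_dim = 6, generations = 10)
  set.seed(62)
  bb <- building_blocks(colnames(ds$x))
  l1 <- mces:::evolve_run(ds$x, ds$labels, cfg, bb)
  # reproduce level-2 grid construction and inspect the initial cells
  d <- cfg$grid_dim
  cells <- vector("list", d * d)
  k <- min(length(l1$archive), d * d)
  cells[seq_len(k)] <- l1$archive[seq_len(k)]
  seeded_exprs <- vapply(cells[seq_len(k)], `[[`, character(1), "expression")
  archive_exprs <- vapply(l1$archive, `[[`, character(1), "expression")
  expect_identical(seeded_exprs, archive_exprs[seq_len(k)])
  if (length(l1$archive) <= d * d) {
    expect_true(all(archive_exprs %in% seeded_exprs))
  }
})

test_that("archive truncation preserves the accuracy extremes", {
  mk <- function(acc, cplx, id) {
    structure(list(expression = paste0("e", id), accuracy = acc,
                   complexity = cplx), class = "ces_classifier")
  }
  # a strictly decreasing-complexity front of 30 members, cap at 10
  front <- lapply(1:30, function(i) mk(i / 30, 31 - i, i))
  trunc <- mces:::archive_truncate(front, 10)
  expect_length(trunc, 10)
  acc <- vapply(trunc, `[[`, numeric(1), "accuracy")
  expect_equal(max(acc), 1.0)
  expect_equal(min(acc), 1 / 30)
})

test_that("degenerate datasets are rejected", {
  x <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(ces(x, rep("one", 5)), "at least 2 classes")
  expect_error(ces(x, c("a", "a", "a", "a", "b")), "fewer than 2 samples")
})

test_that("ces model methods work end to end", {
  ds <- separable_dataset(n_classes = 3, per_class = 6, p = 6)
  fit <- ces(ds$x, ds$labels, ces_config(grid_dim = 8, generations = 120),
             seed = 70)
  pred <- predict(fit, ds$x)
  expect_true(all(pred %in% levels(ds$labels)))
  expect_gte(multiclass_accuracy(pred, ds$labels), 0.9)
  expect_output(print(fit), "computational evolution")
  s <- summary(fit)
  expect_s3_class(s, "summary.ces")
  expect_true(all(diff(s$front$accuracy) <= 0))
  grDevices::pdf(NULL); on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})
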