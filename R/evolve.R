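## Grid-based Pareto domination tournament (spatially structured evolution).
##
## Classifiers live on a D x D toroidal lattice; every cell has exactly the
## 8 Moore neighbors. Each generation is a synchronous update of a frozen
## copy of the grid: a cell whose fitness Pareto-dominates all 8 neighbors
## repopulates those 8 positions with mutated copies of itself; each new
## expression is re-fit (medians, thresholds, flags) on the training data and
## re-scored. An external elitist archive keeps the Pareto front over every
## classifier ever evaluated.

#' Evolution configuration
#'
#' @param grid_dim side length D of the toroidal solution grid (default 36).
#' @param generations number of tournament generations per run (default 1000).
#' @param rates mutation-rate vector \code{c(add=, remove=, swap=)}, see
#'   \code{\link{mutate_tree}}.
#' @param max_depth maximum depth of initial random trees.
#' @param pareto_levels number of chained runs; each level seeds its initial
#'   grid with the previous level's archive (default 1).
#' @param operators,constant_range,expert_bias building-block options, see
#'   \code{\link{building_blocks}}.
#' @param archive_cap maximum archive size; beyond it the interior member
#'   with the smallest accuracy gap to its neighbour on the front is dropped,
#'   never the accuracy extremes.
#' @return A list of class \code{"ces_config"}.
#' @export
ces_config <- function(grid_dim = 36L, generations = 1000L,
                       rates = c(add = 0.25, remove = 0.25, swap = 0.5),
                       max_depth = 4L, pareto_levels = 1L,
                       operators = c("+", "-", "*", "/"),
                       constant_range = c(-10, 10),
                       expert_bias = 0.8, archive_cap = 500L) {
  if (grid_dim < 3L) stop("'grid_dim' must be >= 3")
  if (generations < 1L) stop("'generations' must be >= 1")
  if (pareto_levels < 1L) stop("'pareto_levels' must be >= 1")
  structure(list(grid_dim = as.integer(grid_dim),
                 generations = as.integer(generations),
                 rates = rates, max_depth = as.integer(max_depth),
                 pareto_levels = as.integer(pareto_levels),
                 operators = operators, constant_range = constant_range,
                 expert_bias = expert_bias,
                 archive_cap = as.integer(archive_cap)),
            class = "ces_config")
}

## Build an evaluated classifier: expression + fitted rule + fitness.
make_classifier <- function(tree, x, labels) {
  values <- evaluate_expression(tree, x)
  fit <- fit_rule(values, labels)
  structure(list(tree = tree,
                 expression = format_expression(tree),
                 rule = fit$rule,
                 accuracy = fit$accuracy,
                 complexity = count_building_blocks(tree),
                 features = expression_features(tree)),
            class = "ces_classifier")
}

#' @export
print.ces_classifier <- function(x, ...) {
  cat("CES classifier\n")
  cat("  expression:", x$expression, "\n")
  cat("  accuracy:  ", format(x$accuracy), " complexity: ", x$complexity, "\n")
  print(x$rule)
  invisible(x)
}

#' Predict class labels with a fitted classifier
#'
#' Evaluates the classifier's expression on new samples and applies its
#' frozen training-fitted threshold rule.
#'
#' @param object a \code{ces_classifier}.
#' @param newdata numeric matrix or data frame, samples in rows, named
#'   feature columns.
#' @param ... ignored.
#' @return Character vector of predicted class labels.
#' @export
predict.ces_classifier <- function(object, newdata, ...) {
  classify_sample(evaluate_expression(object$tree, newdata), object$rule)
}

#' Moore neighborhood on the toroidal grid
#'
#' The 8 immediate neighbors of a cell, with wrap-around at the borders so
#' every cell of a grid with D >= 3 has exactly 8 distinct neighbors.
#'
#' @param dim grid side length D >= 3.
#' @param row,col 1-based cell coordinates.
#' @return An 8 x 2 integer matrix of (row, col) coordinates.
#' @examples
#' neighborhood(5, 1, 1)  # wraps: includes (5, 5)
#' @export
neighborhood <- function(dim, row, col) {
  if (dim < 3L) stop("'dim' must be >= 3")
  if (row < 1L || row > dim || col < 1L || col > dim) {
    stop("cell (", row, ", ", col, ") outside a ", dim, " x ", dim, " grid")
  }
  off <- cbind(rep(-1:1, each = 3L), rep(-1:1, times = 3L))
  off <- off[!(off[, 1L] == 0L & off[, 2L] == 0L), , drop = FALSE]
  cbind(row = ((row - 1L + off[, 1L]) %% dim) + 1L,
        col = ((col - 1L + off[, 2L]) %% dim) + 1L)
}

## Toroidal shift of a matrix: element [r, c] of the result is M[r+dr, c+dc]
## with wrap-around.
torus_shift <- function(m, dr, dc) {
  d <- nrow(m)
  m[((seq_len(d) - 1L + dr) %% d) + 1L, ((seq_len(d) - 1L + dc) %% d) + 1L]
}

grid_index <- function(dim, row, col) (col - 1L) * dim + row  # column-major

## One synchronous tournament generation. Returns the successor grid and the
## list of newly created (mutated, re-fit) classifiers.
tournament_step <- function(cells, dim, x, labels, blocks, rates) {
  acc <- matrix(vapply(cells, function(s) s$accuracy, numeric(1)), dim, dim)
  cplx <- matrix(vapply(cells, function(s) s$complexity, numeric(1)), dim, dim)

  offsets <- cbind(rep(-1:1, each = 3L), rep(-1:1, times = 3L))
  offsets <- offsets[!(offsets[, 1L] == 0L & offsets[, 2L] == 0L), , drop = FALSE]
  dom <- matrix(TRUE, dim, dim)
  for (k in seq_len(nrow(offsets))) {
    as_ <- torus_shift(acc, offsets[k, 1L], offsets[k, 2L])
    cs_ <- torus_shift(cplx, offsets[k, 1L], offsets[k, 2L])
    dom <- dom & (acc >= as_) & (cplx <= cs_) & ((acc > as_) | (cplx < cs_))
  }

  winners <- integer(dim * dim)  # per target: index of winning dominator, 0 = none
  dom_idx <- which(dom)          # column-major order
  for (i in dom_idx) {
    r <- ((i - 1L) %% dim) + 1L
    c <- ((i - 1L) %/% dim) + 1L
    nb <- neighborhood(dim, r, c)
    for (t in grid_index(dim, nb[, 1L], nb[, 2L])) {
      w <- winners[t]
      if (w == 0L) {
        winners[t] <- i
      } else {
        ## conflict: higher accuracy, then lower complexity, then smaller
        ## (row, col) -- row-major order comparison
        better <- acc[i] > acc[w] ||
          (acc[i] == acc[w] && (cplx[i] < cplx[w] ||
            (cplx[i] == cplx[w] && rowmajor_rank(i, dim) < rowmajor_rank(w, dim))))
        if (better) winners[t] <- i
      }
    }
  }

  new_cells <- cells
  created <- vector("list", sum(winners > 0L))
  j <- 0L
  for (t in which(winners > 0L)) {  # deterministic target order
    parent <- cells[[winners[t]]]
    child_tree <- mutate_tree(parent$tree, blocks, rates)
    child <- make_classifier(child_tree, x, labels)
    new_cells[[t]] <- child
    j <- j + 1L
    created[[j]] <- child
  }
  list(cells = new_cells, created = created)
}

rowmajor_rank <- function(i, dim) {
  r <- ((i - 1L) %% dim)
  c <- ((i - 1L) %/% dim)
  r * dim + c
}

## --- elitist archive -------------------------------------------------------

## Merge new classifiers into the archive and reduce to the Pareto front,
## deduplicating identical expression strings; truncate to 'cap'.
archive_update <- function(archive, new, cap) {
  all <- c(archive, new)
  expr <- vapply(all, function(s) s$expression, character(1))
  all <- all[!duplicated(expr)]
  acc <- vapply(all, function(s) s$accuracy, numeric(1))
  cplx <- vapply(all, function(s) s$complexity, numeric(1))
  keep <- pareto_mask(acc, cplx)
  front <- all[keep]
  if (length(front) > cap) front <- archive_truncate(front, cap)
  front
}

## Drop interior members (never the accuracy extremes) with the smallest
## accuracy gap to the member below them on the accuracy axis; ties broken by
## higher complexity, then later insertion order.
archive_truncate <- function(front, cap) {
  while (length(front) > cap) {
    acc <- vapply(front, function(s) s$accuracy, numeric(1))
    cplx <- vapply(front, function(s) s$complexity, numeric(1))
    ord <- order(acc, -cplx, seq_along(acc))
    interior <- ord[-c(1L, length(ord))]
    gaps <- acc[interior] - acc[ord[-c(length(ord) - 1L, length(ord))]]
    victim <- interior[which.min(gaps)]
    front <- front[-victim]
  }
  front
}

## --- evolution loop --------------------------------------------------------

## Core loop shared by evolve() and run_levels(). 'init' optionally supplies
## classifiers for the first cells of the initial grid.
evolve_run <- function(x, labels, config, blocks, init = NULL) {
  d <- config$grid_dim
  ncell <- d * d
  cells <- vector("list", ncell)
  k <- if (is.null(init)) 0L else min(length(init), ncell)
  if (k > 0L) cells[seq_len(k)] <- init[seq_len(k)]
  if (k < ncell) {
    for (i in (k + 1L):ncell) {
      cells[[i]] <- make_classifier(random_tree(blocks, config$max_depth), x, labels)
    }
  }
  archive <- archive_update(list(), cells, config$archive_cap)
  trace <- numeric(config$generations + 1L)
  trace[1L] <- max(vapply(archive, function(s) s$accuracy, numeric(1)))
  for (gen in seq_len(config$generations)) {
    step <- tournament_step(cells, d, x, labels, blocks, config$rates)
    cells <- step$cells
    if (length(step$created)) {
      archive <- archive_update(archive, step$created, config$archive_cap)
    }
    trace[gen + 1L] <- max(vapply(archive, function(s) s$accuracy, numeric(1)))
  }
  list(cells = cells, archive = archive, trace = trace)
}

#' Run one evolution (a single Pareto level)
#'
#' Evolves a random initial grid of classifiers on the training data for
#' \code{config$generations} tournament generations, maintaining an external
#' archive equal to the Pareto front over all classifiers ever evaluated.
#' Uses R's global RNG; call \code{set.seed} (or use \code{\link{ces}}) for
#' reproducible runs.
#'
#' @param x numeric matrix, samples in rows, named feature columns.
#' @param labels class label per sample (>= 2 classes, each with >= 2
#'   samples).
#' @param config a \code{\link{ces_config}}.
#' @param blocks optional \code{\link{building_blocks}}; defaults to the
#'   columns of \code{x} with the config's operator set.
#' @return A list with \code{cells} (final grid, column-major),
#'   \code{archive} (Pareto-front classifiers), and \code{trace} (best
#'   archive accuracy after each generation).
#' @export
evolve <- function(x, labels, config = ces_config(), blocks = NULL) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  check_dataset(x, labels)
  if (is.null(blocks)) {
    blocks <- building_blocks(colnames(x), operators = config$operators,
                              constant_range = config$constant_range,
                              expert_bias = config$expert_bias)
  }
  evolve_run(x, labels, config, blocks)
}

#' Chained multi-level evolution
#'
#' Level 1 evolves from a random grid; every subsequent level seeds its
#' initial grid with the previous level's archive (one member per cell,
#' remainder random) and evolves again, so the best solutions of one run
#' become the starting points of the next.
#'
#' @inheritParams evolve
#' @return A list of per-level results as returned by \code{\link{evolve}}.
#' @export
run_levels <- function(x, labels, config = ces_config(), blocks = NULL) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  check_dataset(x, labels)
  if (is.null(blocks)) {
    blocks <- building_blocks(colnames(x), operators = config$operators,
                              constant_range = config$constant_range,
                              expert_bias = config$expert_bias)
  }
  levels <- vector("list", config$pareto_levels)
  seed_pool <- NULL
  for (l in seq_len(config$pareto_levels)) {
    levels[[l]] <- evolve_run(x, labels, config, blocks, init = seed_pool)
    seed_pool <- levels[[l]]$archive
  }
  levels
}

check_dataset <- function(x, labels) {
  if (is.null(colnames(x))) stop("'x' must have named feature columns")
  if (nrow(x) != length(labels)) stop("row count of 'x' must match 'labels'")
  counts <- table(labels)
  if (length(counts) < 2L) stop("need at least 2 classes")
  if (any(counts < 2L)) {
    stop("class '", names(counts)[counts < 2L][1L], "' has fewer than 2 samples")
  }
  if (any(!is.finite(x))) stop("'x' contains non-finite values")
  invisible(TRUE)
}
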