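## Pareto fitness: accuracy (maximize) vs building-block count (minimize).

#' Pareto domination between two fitness records
#'
#' \code{a} dominates \code{b} when \code{a} is at least as accurate and at
#' most as complex, with at least one of the two strict.
#'
#' @param acc_a,cplx_a accuracy and complexity of solution a.
#' @param acc_b,cplx_b accuracy and complexity of solution b.
#' @return \code{TRUE} iff a dominates b.
#' @examples
#' dominates(0.9, 5, 0.8, 10)  # TRUE
#' dominates(0.9, 10, 0.8, 5)  # FALSE (incomparable)
#' @export
dominates <- function(acc_a, cplx_a, acc_b, cplx_b) {
  (acc_a >= acc_b) && (cplx_a <= cplx_b) && (acc_a > acc_b || cplx_a < cplx_b)
}

#' Pareto front of a set of classifiers
#'
#' Returns exactly the members not dominated by any other member, in their
#' original order.
#'
#' @param solutions a non-empty list of classifiers (objects with
#'   \code{accuracy} and \code{complexity} fields), or any list accompanied
#'   by explicit \code{accuracy}/\code{complexity} vectors.
#' @param accuracy,complexity optional numeric vectors overriding the fields.
#' @return The non-dominated sublist.
#' @export
pareto_front <- function(solutions, accuracy = NULL, complexity = NULL) {
  if (!is.list(solutions) || length(solutions) == 0L) stop("need a non-empty list")
  if (is.null(accuracy)) {
    accuracy <- vapply(solutions, function(s) s$accuracy, numeric(1))
  }
  if (is.null(complexity)) {
    complexity <- vapply(solutions, function(s) s$complexity, numeric(1))
  }
  keep <- pareto_mask(accuracy, complexity)
  solutions[keep]
}

## Logical mask of non-dominated points, by descending-accuracy sweep.
## A point is non-dominated iff its complexity is minimal within its own
## accuracy group AND strictly smaller than the minimum complexity of every
## higher-accuracy group. Coordinate duplicates do not dominate each other,
## so whole groups of tied minima are kept.
pareto_mask <- function(accuracy, complexity) {
  keep <- logical(length(accuracy))
  best_prev <- Inf  # min complexity among strictly higher accuracies
  for (a in sort(unique(accuracy), decreasing = TRUE)) {
    g <- which(accuracy == a)
    gmin <- min(complexity[g])
    if (gmin < best_prev) keep[g[complexity[g] == gmin]] <- TRUE
    best_prev <- min(best_prev, gmin)
  }
  keep
}
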