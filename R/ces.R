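#' Fit a multi-class computational-evolution classifier
#'
#' Evolves symbolic discriminant expressions over the features of \code{x} by
#' genetic programming on a toroidal Pareto-domination grid, classifying
#' samples by the median/threshold rule with exhaustive search over the
#' 2^(n-1) inequality directions. The returned model holds the full elitist
#' archive (the accuracy-versus-complexity Pareto front over every classifier
#' evaluated) and the single best classifier used by \code{predict}.
#'
#' @param x numeric matrix or data frame, samples in rows, named feature
#'   columns (typically log-transformed expression values).
#' @param labels class label per sample; at least 2 classes with at least 2
#'   samples each.
#' @param config a \code{\link{ces_config}} controlling grid size,
#'   generations, mutation rates, and Pareto levels.
#' @param expert optional expert-knowledge features biasing the search:
#'   \code{NULL} (none), \code{TRUE} (rank features on \code{x} itself with
#'   \code{\link{expert_features}}, top 100 at p < 0.05), or a character
#'   vector of feature names.
#' @param seed optional integer seed; the whole run is reproducible given
#'   (data, config, seed).
#' @return An object of class \code{"ces"} with components \code{best} (a
#'   \code{ces_classifier}), \code{archive}, \code{levels} (per-level
#'   archives), \code{trace}, \code{config}, \code{classes}, \code{call}.
#' @examples
#' sim <- ces_simulate(n_classes = 2, samples_per_class = 10, n_features = 8,
#'                     n_informative = 1, delta = 6, seed = 1)
#' fit <- ces(sim$x, sim$labels,
#'            config = ces_config(grid_dim = 5, generations = 10), seed = 1)
#' print(fit)
#' @seealso \code{\link{ces_cv}} for the repeated k-fold evaluation protocol.
#' @export
ces <- function(x, labels, config = ces_config(), expert = NULL, seed = NULL) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  check_dataset(x, labels)
  if (!is.null(seed)) set.seed(seed)

  expert_set <- NULL
  if (isTRUE(expert)) {
    expert_set <- expert_features(x, labels)
  } else if (is.character(expert)) {
    expert_set <- expert
  }
  blocks <- building_blocks(colnames(x), operators = config$operators,
                            constant_range = config$constant_range,
                            expert_features = expert_set,
                            expert_bias = config$expert_bias)
  levels <- run_levels(x, labels, config, blocks)
  archive <- levels[[length(levels)]]$archive
  structure(list(best = select_best(archive),
                 archive = archive,
                 levels = lapply(levels, `[[`, "archive"),
                 trace = levels[[length(levels)]]$trace,
                 config = config,
                 classes = levels(labels),
                 expert = expert_set,
                 seed = seed,
                 call = match.call()),
            class = "ces")
}

#' Best classifier of an archive
#'
#' The archive member with the highest training accuracy; ties are broken
#' toward fewer building blocks, then the lexicographically smallest
#' expression string.
#'
#' @param archive non-empty list of evaluated classifiers.
#' @return A single \code{ces_classifier}.
#' @export
select_best <- function(archive) {
  if (!is.list(archive) || length(archive) == 0L) stop("empty archive")
  acc <- vapply(archive, function(s) s$accuracy, numeric(1))
  cplx <- vapply(archive, function(s) s$complexity, numeric(1))
  expr <- vapply(archive, function(s) s$expression, character(1))
  archive[[order(-acc, cplx, expr)[1L]]]
}

#' @export
print.ces <- function(x, ...) {
  cat("Multi-class computational evolution classifier\n")
  cat("  classes:   ", paste(x$classes, collapse = ", "), "\n")
  cat("  grid:      ", x$config$grid_dim, "x", x$config$grid_dim,
      ", generations: ", x$config$generations,
      ", levels: ", x$config$pareto_levels, "\n", sep = "")
  cat("  archive:   ", length(x$archive), " Pareto-front classifiers\n", sep = "")
  cat("  best:      ", x$best$expression, "\n", sep = "")
  cat("  training accuracy ", format(x$best$accuracy),
      ", complexity ", x$best$complexity, "\n", sep = "")
  invisible(x)
}

#' @export
summary.ces <- function(object, ...) {
  acc <- vapply(object$archive, function(s) s$accuracy, numeric(1))
  cplx <- vapply(object$archive, function(s) s$complexity, numeric(1))
  front <- data.frame(
    expression = vapply(object$archive, function(s) s$expression, character(1)),
    accuracy = acc, complexity = cplx, stringsAsFactors = FALSE)
  front <- front[order(-front$accuracy, front$complexity), , drop = FALSE]
  rownames(front) <- NULL
  out <- list(front = front, best = object$best, classes = object$classes,
              config = object$config,
              selected_features = object$best$features)
  class(out) <- "summary.ces"
  out
}

#' @export
print.summary.ces <- function(x, ...) {
  cat("CES archive Pareto front (", nrow(x$front), " classifiers):\n", sep = "")
  print(utils::head(x$front, 15L))
  if (nrow(x$front) > 15L) cat("  ...\n")
  cat("\nBest classifier:\n")
  print(x$best)
  cat("Selected features:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' Predict method for CES models
#'
#' Applies the model's best classifier (expression plus its frozen
#' training-fitted threshold rule) to new samples.
#'
#' @param object a fitted \code{\link{ces}} model.
#' @param newdata numeric matrix or data frame with the features the
#'   expression references.
#' @param ... ignored.
#' @return Character vector of predicted class labels.
#' @export
predict.ces <- function(object, newdata, ...) {
  predict(object$best, newdata)
}

#' Plot the archive Pareto front
#'
#' Accuracy against building-block count for every archive member, with the
#' best classifier highlighted.
#'
#' @param x a fitted \code{\link{ces}} model.
#' @param ... further arguments passed to \code{plot}.
#' @export
plot.ces <- function(x, ...) {
  acc <- vapply(x$archive, function(s) s$accuracy, numeric(1))
  cplx <- vapply(x$archive, function(s) s$complexity, numeric(1))
  graphics::plot(cplx, acc, xlab = "building blocks (complexity)",
                 ylab = "training accuracy", main = "CES Pareto front",
                 pch = 19, ...)
  graphics::points(x$best$complexity, x$best$accuracy, col = 2, pch = 1, cex = 2)
  invisible(x)
}
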