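## Repeated stratified k-fold cross-validation protocol.

#' Build a repeated stratified k-fold plan
#'
#' Within each repetition the test sets partition the samples; folds are
#' stratified so each test set preserves the class proportions (roughly 1/k
#' of every class). The plan is deterministic given the seed.
#'
#' @param labels class label per sample; every class needs at least \code{k}
#'   samples.
#' @param r number of repetitions (default 10).
#' @param k number of folds per repetition (default 5).
#' @param seed optional integer seed.
#' @return An object of class \code{"fold_plan"}: a list with \code{r},
#'   \code{k}, \code{n}, and \code{test_sets}, a list of r*k integer vectors
#'   of test-sample indices (rep-major order).
#' @examples
#' plan <- make_folds(rep(c("A", "B"), 50), r = 10, k = 5, seed = 1)
#' lengths(plan$test_sets)[1:5]  # each test set has 20 of the 100 samples
#' @export
make_folds <- function(labels, r = 10L, k = 5L, seed = NULL) {
  labels <- as.factor(labels)
  n <- length(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("class '", names(counts)[counts < k][1L], "' has fewer than k = ",
         k, " samples")
  }
  if (!is.null(seed)) set.seed(seed)
  test_sets <- vector("list", r * k)
  for (rep_i in seq_len(r)) {
    fold_of <- integer(n)
    for (cls in levels(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
    for (fold_i in seq_len(k)) {
      test_sets[[(rep_i - 1L) * k + fold_i]] <- which(fold_of == fold_i)
    }
  }
  structure(list(r = as.integer(r), k = as.integer(k), n = n,
                 test_sets = test_sets),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("Fold plan: ", x$r, " repetitions x ", x$k, "-fold = ",
      x$r * x$k, " evaluations on ", x$n, " samples\n", sep = "")
  invisible(x)
}

#' Cross-validated evaluation of the CES classifier
#'
#' Runs the full pipeline independently in every fold: expert-knowledge
#' features are ranked on the training split only, evolution is fit on the
#' training split, and the best classifier (expression plus its frozen
#' training-fitted rule) is applied once to the held-out split. No test
#' sample influences training in any fold.
#'
#' @param x numeric matrix, samples in rows, named feature columns
#'   (transformed expression values).
#' @param labels class label per sample.
#' @param config a \code{\link{ces_config}} (use reduced grid/generations
#'   for quick runs).
#' @param r,k repetitions and folds (defaults 10 and 5).
#' @param expert_k,expert_alpha expert-knowledge ranking parameters passed
#'   to \code{\link{expert_features}}; \code{expert_k = 0} disables expert
#'   knowledge.
#' @param seed integer seed; fold assignment and every per-fold evolution are
#'   reproducible given (data, config, seed).
#' @return An object of class \code{"ces_cv"}: per-fold results
#'   (\code{folds}, a data frame), per-fold feature sets and classifiers,
#'   and aggregate mean accuracy, mean pairwise Tanimoto stability, and mean
#'   selected-feature count.
#' @export
ces_cv <- function(x, labels, config = ces_config(), r = 10L, k = 5L,
                   expert_k = 100L, expert_alpha = 0.05, seed = NULL) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  check_dataset(x, labels)
  if (!is.null(seed)) set.seed(seed)
  plan <- make_folds(labels, r = r, k = k)
  n_eval <- length(plan$test_sets)
  fold_acc <- numeric(n_eval)
  fold_sets <- vector("list", n_eval)
  fold_classifiers <- vector("list", n_eval)
  for (i in seq_len(n_eval)) {
    test_idx <- plan$test_sets[[i]]
    train_idx <- setdiff(seq_len(nrow(x)), test_idx)
    x_train <- x[train_idx, , drop = FALSE]
    y_train <- droplevels(labels[train_idx])
    expert_set <- NULL
    if (expert_k > 0L) {
      expert_set <- expert_features(x_train, y_train, k = expert_k,
                                    alpha = expert_alpha)
      if (length(expert_set) == 0L) expert_set <- NULL
    }
    blocks <- building_blocks(colnames(x), operators = config$operators,
                              constant_range = config$constant_range,
                              expert_features = expert_set,
                              expert_bias = config$expert_bias)
    levels_out <- run_levels(x_train, y_train, config, blocks)
    best <- select_best(levels_out[[length(levels_out)]]$archive)
    pred <- predict(best, x[test_idx, , drop = FALSE])
    fold_acc[i] <- multiclass_accuracy(pred, labels[test_idx])
    fold_sets[[i]] <- best$features
    fold_classifiers[[i]] <- best
  }
  folds <- data.frame(
    rep = rep(seq_len(plan$r), each = plan$k),
    fold = rep(seq_len(plan$k), times = plan$r),
    accuracy = fold_acc,
    n_features = lengths(fold_sets),
    features = vapply(fold_sets, paste, character(1), collapse = ";"),
    expression = vapply(fold_classifiers, function(s) s$expression, character(1)),
    stringsAsFactors = FALSE)
  structure(list(folds = folds,
                 feature_sets = fold_sets,
                 classifiers = fold_classifiers,
                 plan = plan,
                 mean_accuracy = mean(fold_acc),
                 stability = if (n_eval >= 2L &&
                                 all(lengths(fold_sets) > 0L)) stability(fold_sets) else NA_real_,
                 mean_n_features = mean(lengths(fold_sets)),
                 config = config, seed = seed,
                 call = match.call()),
            class = "ces_cv")
}

#' @export
print.ces_cv <- function(x, ...) {
  cat("CES repeated cross-validation (", x$plan$r, " rep, ", x$plan$k,
      "-fold = ", length(x$plan$test_sets), " evaluations)\n", sep = "")
  cat("  mean test accuracy:    ", format(x$mean_accuracy), "\n")
  cat("  Tanimoto stability:    ", format(x$stability), "\n")
  cat("  mean selected features:", format(x$mean_n_features), "\n")
  invisible(x)
}

#' @export
summary.ces_cv <- function(object, ...) {
  cat("Per-fold results:\n")
  print(object$folds[, c("rep", "fold", "accuracy", "n_features", "expression")])
  cat("\n")
  print(object)
  freq <- feature_frequency(object$feature_sets)
  if (nrow(freq)) {
    cat("\nFeatures selected in >= 2 folds:\n")
    print(freq)
  }
  invisible(object)
}
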