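## Accuracy and feature-set stability metrics.

#' Balanced accuracy from binary confusion counts
#'
#' \deqn{A = (TP/(TP+FN) + TN/(TN+FP)) / 2}
#' the mean of sensitivity and specificity, used for binary classifiers.
#'
#' @param tp,fn,tn,fp non-negative confusion counts; both \code{tp + fn} and
#'   \code{tn + fp} must be positive.
#' @return Balanced accuracy in \[0, 1\].
#' @examples
#' balanced_accuracy(tp = 5, fn = 5, tn = 10, fp = 0)  # 0.75
#' @export
balanced_accuracy <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  if (tp + fn == 0) stop("no positive-class samples (TP + FN = 0)")
  if (tn + fp == 0) stop("no negative-class samples (TN + FP = 0)")
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

#' Multi-class classification accuracy
#'
#' The fraction of correct predictions,
#' \deqn{A = Correct / (Correct + Incorrect).}
#'
#' @param predicted,truth equal-length non-empty label vectors.
#' @return Accuracy in \[0, 1\].
#' @export
multiclass_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("'predicted' and 'truth' lengths differ")
  if (length(predicted) == 0L) stop("no predictions")
  mean(as.character(predicted) == as.character(truth))
}

#' Tanimoto similarity between two feature sets
#'
#' \deqn{S(s, s') = 1 - (|s| + |s'| - 2|s \cap s'|) / (|s| + |s'| - |s \cap s'|)}
#' which equals the Jaccard index \eqn{|s \cap s'| / |s \cup s'|}: 1 means
#' the sets share all features, 0 that they share none.
#'
#' @param s,s2 non-empty character vectors (duplicates ignored).
#' @return Similarity in \[0, 1\].
#' @examples
#' tanimoto(letters[1:6], letters[4:9])  # 1/3
#' @export
tanimoto <- function(s, s2) {
  s <- unique(as.character(s))
  s2 <- unique(as.character(s2))
  if (length(s) == 0L || length(s2) == 0L) stop("feature sets must be non-empty")
  i <- length(intersect(s, s2))
  a <- length(s)
  b <- length(s2)
  1 - (a + b - 2 * i) / (a + b - i)
}

#' Mean pairwise Tanimoto stability of a collection of feature sets
#'
#' Feature-selection stability across cross-validation folds or repeated
#' runs: the mean Tanimoto similarity over all unordered pairs of sets.
#'
#' @param sets a list of at least two non-empty character vectors.
#' @return Mean pairwise similarity in \[0, 1\].
#' @examples
#' stability(list(c("a", "b"), c("a", "b"), c("c", "d")))  # 1/3
#' @export
stability <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L) stop("need at least 2 feature sets")
  m <- length(sets)
  pairs <- utils::combn(m, 2L)
  mean(apply(pairs, 2L, function(p) tanimoto(sets[[p[1L]]], sets[[p[2L]]])))
}

#' Feature occurrence counts across repeated runs
#'
#' Tabulates how often each feature appears across the final classifiers of
#' repeated runs, dropping features that appear only once.
#'
#' @param runs list of character vectors (one selected feature set per run).
#' @return A data frame with columns \code{feature} and \code{count}
#'   (count >= 2), sorted by descending count then feature name.
#' @export
feature_frequency <- function(runs) {
  if (!is.list(runs) || length(runs) < 1L) stop("need at least 1 run")
  tab <- table(unlist(lapply(runs, function(s) unique(as.character(s)))))
  tab <- tab[tab >= 2L]
  if (length(tab) == 0L) {
    return(data.frame(feature = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(feature = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
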