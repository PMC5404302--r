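## Multi-class median/threshold classification rule.
##
## Training test values are split by class; each class's median is computed;
## classes are ordered by ascending median; the mean of each successive pair
## of ordered medians becomes a threshold. A sample's class is determined by
## where its test value falls among the thresholds. Each of the n-1
## inequalities may independently be strict or not, giving 2^(n-1) candidate
## rules; fitting searches all of them and keeps the most accurate.

#' Per-class medians of test values, ordered ascending
#'
#' Even-sized classes use the midpoint of the two central order statistics.
#' Classes with equal medians keep their first-appearance order (the order of
#' \code{levels} for factors, first occurrence otherwise).
#'
#' @param values numeric vector of test values.
#' @param labels class label per value (factor or character); every class
#'   must have at least one value.
#' @return A data frame with columns \code{class} and \code{median}, sorted
#'   by ascending median.
#' @examples
#' class_medians(c(1, 2, 3, 10, 20, 30), rep(c("A", "B"), each = 3))
#' @export
class_medians <- function(values, labels) {
  labels <- as.factor(labels)
  if (length(values) != length(labels)) stop("'values' and 'labels' lengths differ")
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  counts <- table(labels)
  if (any(counts == 0L)) {
    stop("class '", names(counts)[counts == 0L][1L], "' has no values")
  }
  med <- vapply(split(values, labels), stats::median, numeric(1))
  ord <- order(med, seq_along(med))  # stable: ties keep level order
  data.frame(class = levels(labels)[ord], median = unname(med[ord]),
             stringsAsFactors = FALSE)
}

#' Thresholds from ordered class medians
#'
#' Each threshold is the mean of a successive pair of ordered medians:
#' \code{t_i = (m_i + m_(i+1)) / 2}.
#'
#' @param ordered_medians non-decreasing numeric vector of length >= 2.
#' @return Numeric vector of length \code{n - 1}, non-decreasing.
#' @examples
#' compute_thresholds(c(1, 3, 7))  # 2, 5
#' @export
compute_thresholds <- function(ordered_medians) {
  n <- length(ordered_medians)
  if (n < 2L) stop("need at least 2 medians")
  if (is.unsorted(ordered_medians)) stop("'ordered_medians' must be non-decreasing")
  (ordered_medians[-n] + ordered_medians[-1L]) / 2
}

#' Construct a multi-class threshold rule
#'
#' @param classes ordered class labels (ascending class median), length n >= 2.
#' @param thresholds non-decreasing numeric vector of n-1 thresholds.
#' @param strict_flags logical vector of n-1 inequality directions. With flag
#'   i \code{FALSE}, a test value equal to threshold t_i belongs to the upper
#'   class (the comparison against t_i is \code{>=}); with flag i
#'   \code{TRUE} the comparison is strict (\code{>}) and the boundary value
#'   stays with the lower class.
#' @return An object of class \code{"mc_rule"}.
#' @export
mc_rule <- function(classes, thresholds, strict_flags = rep(FALSE, length(thresholds))) {
  classes <- as.character(classes)
  n <- length(classes)
  if (n < 2L) stop("need at least 2 classes")
  if (anyDuplicated(classes)) stop("'classes' must be distinct")
  if (length(thresholds) != n - 1L || length(strict_flags) != n - 1L) {
    stop("need n-1 thresholds and n-1 strict flags for n classes")
  }
  if (is.unsorted(thresholds)) stop("'thresholds' must be non-decreasing")
  structure(list(classes = classes, thresholds = as.numeric(thresholds),
                 strict_flags = as.logical(strict_flags)),
            class = "mc_rule")
}

#' @export
print.mc_rule <- function(x, ...) {
  n <- length(x$classes)
  cat("Multi-class threshold rule (", n, " classes)\n", sep = "")
  cmp <- ifelse(x$strict_flags, ">", ">=")
  cat("  ", x$classes[1L], "\n", sep = "")
  for (i in seq_len(n - 1L)) {
    cat("  ", cmp[i], " ", format(x$thresholds[i]), " -> ", x$classes[i + 1L],
        "\n", sep = "")
  }
  invisible(x)
}

#' Classify test values with a threshold rule
#'
#' The rule partitions the real line: a value below the first threshold maps
#' to the first (lowest-median) class, and each threshold crossed moves the
#' prediction one class up. Flag i decides which class owns a value exactly
#' equal to threshold t_i (see \code{\link{mc_rule}}).
#'
#' @param v numeric vector of finite test values.
#' @param rule an \code{\link{mc_rule}}.
#' @return Character vector of predicted class labels.
#' @examples
#' r <- mc_rule(c("c1", "c2", "c3"), c(2, 5))
#' classify_sample(c(-100, 2, 4, 5), r)
#' @export
classify_sample <- function(v, rule) {
  stopifnot(inherits(rule, "mc_rule"))
  if (any(!is.finite(v))) stop("test values must be finite")
  idx <- classify_index(v, rule$thresholds, rule$strict_flags)
  rule$classes[idx]
}

## Integer class index (1..n) for a vector of test values. Hot path of the
## 2^(n-1) search, so kept allocation-light.
classify_index <- function(v, thresholds, strict_flags) {
  idx <- rep.int(1L, length(v))
  for (i in seq_along(thresholds)) {
    idx <- idx + if (strict_flags[i]) (v > thresholds[i]) else (v >= thresholds[i])
  }
  idx
}

## All 2^m flag vectors in lexicographic order (all-FALSE first, element 1
## most significant).
flag_vectors <- function(m) {
  if (m == 0L) return(list(logical(0)))
  lapply(0:(2^m - 1L), function(f) {
    as.logical(bitwAnd(bitwShiftR(f, (m - 1L):0), 1L))
  })
}

#' Fit the multi-class rule to training test values
#'
#' Computes class medians and thresholds, then evaluates every one of the
#' 2^(n-1) inequality-direction combinations and keeps the one with the
#' highest training accuracy (simple multi-class accuracy). Accuracy ties are
#' broken toward the lexicographically smallest flag vector, all-\code{FALSE}
#' first.
#'
#' @param values numeric vector of training test values.
#' @param labels class label per value.
#' @return A list with components \code{rule} (an \code{\link{mc_rule}}) and
#'   \code{accuracy} (training accuracy of the returned rule).
#' @examples
#' fit_rule(c(1, 2, 8, 9), c("A", "A", "B", "B"))
#' @export
fit_rule <- function(values, labels) {
  labels <- as.factor(labels)
  med <- class_medians(values, labels)
  thresholds <- compute_thresholds(med$median)
  n <- nrow(med)
  truth_idx <- match(as.character(labels), med$class)
  best_acc <- -1
  best_flags <- NULL
  for (flags in flag_vectors(n - 1L)) {
    pred_idx <- classify_index(values, thresholds, flags)
    acc <- mean(pred_idx == truth_idx)
    if (acc > best_acc) {
      best_acc <- acc
      best_flags <- flags
    }
  }
  list(rule = mc_rule(med$class, thresholds, best_flags), accuracy = best_acc)
}
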