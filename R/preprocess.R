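## Expression-data preprocessing: low-count filter, log2(x+1) transform,
## and expert-knowledge feature pre-ranking by one-way F statistic.

#' Remove features with uniformly low raw counts
#'
#' A feature is kept only if at least one sample has a raw count of 5 or
#' more; features never reaching that count carry essentially no signal and
#' are removed before transformation.
#'
#' @param x non-negative integer matrix of raw counts, samples in rows,
#'   named feature columns.
#' @param min_count the count at least one sample must reach (default 5).
#' @return The matrix restricted to the kept feature columns.
#' @examples
#' m <- cbind(lo = c(0L, 4L, 4L), hi = c(0L, 0L, 5L))
#' colnames(filter_low_counts(m))  # "hi"
#' @export
filter_low_counts <- function(x, min_count = 5) {
  x <- as.matrix(x)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
    stop("raw counts must be non-negative integers")
  }
  keep <- apply(x, 2L, max) >= min_count
  x[, keep, drop = FALSE]
}

#' log2(x + 1) transform
#'
#' Entrywise \code{log2(x + 1)}: strictly monotone, maps zero to zero, and
#' stabilises the heavy right tail of expression counts / FPKM values.
#'
#' @param x non-negative numeric matrix.
#' @return Matrix of the same shape.
#' @export
log_transform <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x)) || any(x < 0)) stop("entries must be non-negative")
  log2(x + 1)
}

#' One-way F statistics per feature
#'
#' Vectorised one-way analysis of variance across the class labels, one F
#' statistic (and p-value from the F distribution with n-1 and N-n degrees of
#' freedom) per feature column.
#'
#' @param x numeric matrix, samples in rows, named feature columns.
#' @param labels class label per sample; every class needs >= 2 samples.
#' @return A data frame with columns \code{feature}, \code{F}, \code{p},
#'   in the column order of \code{x}. Features with zero within- and
#'   between-class variance get \code{F = NaN}.
#' @export
feature_f_stats <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nrow(x) != length(labels)) stop("row count of 'x' must match 'labels'")
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("class '", names(counts)[counts < 2L][1L], "' has fewer than 2 samples")
  }
  n_cls <- nlevels(labels)
  n_tot <- nrow(x)
  ind <- stats::model.matrix(~ labels - 1)           # samples x classes
  group_sum <- crossprod(ind, x)                     # classes x features
  group_n <- as.numeric(counts)
  group_mean <- group_sum / group_n
  grand_mean <- colMeans(x)
  ssb <- colSums(group_n * sweep(group_mean, 2L, grand_mean)^2)
  sst <- colSums(sweep(x, 2L, grand_mean)^2)
  ssw <- sst - ssb
  df1 <- n_cls - 1L
  df2 <- n_tot - n_cls
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  data.frame(feature = colnames(x), F = unname(f), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Expert-knowledge feature pre-ranking
#'
#' Ranks features by the one-way F statistic across the classes and returns
#' at most \code{k} features with the largest F among those with p-value
#' below \code{alpha}. The result is the "expert knowledge" set that biases
#' leaf sampling during evolution (see \code{\link{building_blocks}}).
#'
#' @param x numeric matrix, samples in rows, named feature columns.
#' @param labels class label per sample; every class needs >= 2 samples.
#' @param k maximum number of features returned (default 100).
#' @param alpha p-value cutoff (default 0.05).
#' @return Character vector of feature names, ordered by descending F
#'   statistic (ties by feature name).
#' @export
expert_features <- function(x, labels, k = 100L, alpha = 0.05) {
  fs <- feature_f_stats(x, labels)
  fs <- fs[!is.nan(fs$F) & !is.na(fs$p) & fs$p < alpha, , drop = FALSE]
  fs <- fs[order(-fs$F, fs$feature), , drop = FALSE]
  utils::head(fs$feature, k)
}
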