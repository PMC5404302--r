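## Synthetic multi-class expression-data generator.
##
## Emulates a transformed RNA-Seq feature matrix: a small number of
## class-informative features among many exchangeable noise features. With
## the default monotone profile the class means of each informative feature
## increase with class index in steps of delta noise standard deviations, so
## a single informative feature is median-separable exactly as the CES
## threshold rule assumes; the non-monotone mode permutes the class means,
## forcing composite expressions.

#' Generate a synthetic multi-class expression dataset
#'
#' @param n_classes number of classes (default 4).
#' @param samples_per_class samples per class (default 30).
#' @param n_features total number of features (default 500).
#' @param n_informative number of class-informative features (default 6).
#' @param delta between-class mean shift of informative features. For the
#'   Gaussian model, in units of the noise standard deviation; for the
#'   count model, the per-class-step shift of log2 mean expression.
#' @param model \code{"gaussian"} for values on the transformed scale, or
#'   \code{"nb"} for negative-binomial raw counts (suitable for
#'   \code{\link{filter_low_counts}} / \code{\link{log_transform}}).
#' @param dispersion negative-binomial dispersion for the count model
#'   (default 0.2, a typical bulk RNA-Seq overdispersion).
#' @param monotone if \code{TRUE} (default) informative class means increase
#'   with class index; if \code{FALSE} the class-mean profile of each
#'   informative feature is randomly permuted.
#' @param seed optional integer seed; the dataset is bit-reproducible.
#' @return A list with \code{x} (samples x features numeric matrix),
#'   \code{labels} (factor), and \code{informative} (character vector of the
#'   ground-truth informative feature names).
#' @examples
#' sim <- ces_simulate(n_classes = 3, samples_per_class = 5, n_features = 20,
#'                     n_informative = 2, delta = 3, seed = 1)
#' dim(sim$x)
#' sim$informative
#' @export
ces_simulate <- function(n_classes = 4L, samples_per_class = 30L,
                         n_features = 500L, n_informative = 6L,
                         delta = 2, model = c("gaussian", "nb"),
                         dispersion = 0.2, monotone = TRUE, seed = NULL) {
  model <- match.arg(model)
  if (n_classes < 2L) stop("'n_classes' must be >= 2")
  if (n_informative > n_features) stop("'n_informative' must be <= 'n_features'")
  if (delta < 0) stop("'delta' must be non-negative")
  if (!is.null(seed)) set.seed(seed)

  n <- n_classes * samples_per_class
  labels <- factor(rep(paste0("class", seq_len(n_classes)), each = samples_per_class))
  feature_names <- sprintf("g%04d", seq_len(n_features))
  informative <- if (n_informative > 0L) feature_names[seq_len(n_informative)] else character()

  ## class-mean offsets (in delta units) per informative feature
  class_idx <- as.integer(labels)
  offsets <- matrix(rep(seq_len(n_classes) - 1L, times = max(n_informative, 1L)),
                    nrow = n_classes)
  if (!monotone && n_informative > 0L) {
    for (j in seq_len(n_informative)) offsets[, j] <- sample(offsets[, j])
  }

  if (model == "gaussian") {
    x <- matrix(stats::rnorm(n * n_features), nrow = n,
                dimnames = list(sprintf("s%03d", seq_len(n)), feature_names))
    for (j in seq_len(n_informative)) {
      x[, j] <- x[, j] + delta * offsets[class_idx, j]
    }
  } else {
    ## baseline log2 mean per feature, class shift on the log2 scale
    base_log2 <- stats::runif(n_features, 3, 8)
    log2_mu <- matrix(rep(base_log2, each = n), nrow = n)
    for (j in seq_len(n_informative)) {
      log2_mu[, j] <- log2_mu[, j] + delta * offsets[class_idx, j]
    }
    x <- matrix(stats::rnbinom(n * n_features, mu = 2^log2_mu,
                               size = 1 / dispersion),
                nrow = n,
                dimnames = list(sprintf("s%03d", seq_len(n)), feature_names))
    storage.mode(x) <- "double"
  }
  list(x = x, labels = labels, informative = informative)
}
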