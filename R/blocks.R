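#' Building-block vocabulary for expression trees
#'
#' A building-block set defines the atoms from which symbolic discriminant
#' expressions are assembled: binary arithmetic operators, a closed range for
#' ephemeral real constants, and the feature (gene) identifiers that may
#' appear as leaves. Optionally an "expert knowledge" feature subset biases
#' leaf sampling: with probability \code{expert_bias} a feature leaf is drawn
#' from \code{expert_features} instead of the full vocabulary.
#'
#' @param feature_names character vector of unique feature identifiers.
#' @param operators binary operator symbols; any subset of
#'   \code{c("+", "-", "*", "/")}. Division is protected (see
#'   \code{\link{evaluate_expression}}).
#' @param constant_range length-2 numeric, closed interval from which leaf
#'   constants are drawn uniformly.
#' @param expert_features optional character vector (subset of
#'   \code{feature_names}) toward which feature-leaf sampling is biased.
#' @param expert_bias probability in \[0, 1\] of drawing a feature leaf from
#'   \code{expert_features} when that set is non-empty.
#'
#' @return An object of class \code{"building_blocks"}.
#' @examples
#' building_blocks(c("Gsg1", "Stip1", "Pex11a"))
#' @export
building_blocks <- function(feature_names,
                            operators = c("+", "-", "*", "/"),
                            constant_range = c(-10, 10),
                            expert_features = NULL,
                            expert_bias = 0.8) {
  feature_names <- as.character(feature_names)
  if (length(feature_names) == 0L) {
    stop("'feature_names' must be non-empty")
  }
  if (anyDuplicated(feature_names)) {
    stop("'feature_names' must be unique")
  }
  operators <- match.arg(operators, c("+", "-", "*", "/"), several.ok = TRUE)
  if (length(operators) == 0L) stop("'operators' must be non-empty")
  constant_range <- as.numeric(constant_range)
  if (length(constant_range) != 2L || any(!is.finite(constant_range)) ||
      constant_range[1L] > constant_range[2L]) {
    stop("'constant_range' must be a finite closed interval c(lower, upper)")
  }
  if (!is.null(expert_features)) {
    expert_features <- as.character(expert_features)
    missing <- setdiff(expert_features, feature_names)
    if (length(missing)) {
      stop("expert features not in 'feature_names': ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
  }
  if (!is.numeric(expert_bias) || length(expert_bias) != 1L ||
      expert_bias < 0 || expert_bias > 1) {
    stop("'expert_bias' must be a probability in [0, 1]")
  }
  structure(
    list(feature_names = feature_names,
         operators = operators,
         constant_range = constant_range,
         expert_features = expert_features,
         expert_bias = expert_bias),
    class = "building_blocks"
  )
}

#' @export
print.building_blocks <- function(x, ...) {
  cat("Building-block set:\n")
  cat("  operators:  ", paste(x$operators, collapse = " "), "\n")
  cat("  constants:  uniform on [", x$constant_range[1L], ", ",
      x$constant_range[2L], "]\n", sep = "")
  cat("  features:   ", length(x$feature_names), "\n")
  if (!is.null(x$expert_features)) {
    cat("  expert set: ", length(x$expert_features),
        " features, bias ", x$expert_bias, "\n", sep = "")
  }
  invisible(x)
}
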