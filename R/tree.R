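## Symbolic expression trees.
##
## A tree is a nested list; each node is one of
##   list(kind = "feat",  name  = <character>)
##   list(kind = "const", value = <double>)
##   list(kind = "op",    op    = <"+","-","*","/">, left = <node>, right = <node>)
## All operators are binary. Division is protected and every intermediate is
## clamped to a finite range so that evaluation can never produce NaN/Inf.

.FINITE_CLAMP <- 1e12
.DIV_EPS <- 1e-9

feat_node <- function(name) list(kind = "feat", name = name)
const_node <- function(value) list(kind = "const", value = as.numeric(value))
op_node <- function(op, left, right) list(kind = "op", op = op, left = left, right = right)

#' Evaluate a symbolic discriminant expression
#'
#' Computes the scalar "test value" of an expression tree for each sample.
#' Arithmetic is protected: a division whose denominator has absolute value
#' below 1e-9 returns 1.0, and any non-finite intermediate is clamped to
#' +/- 1e12, so the result is always finite.
#'
#' @param tree an expression tree, e.g. from \code{\link{random_tree}} or
#'   \code{\link{parse_expression}}.
#' @param data a named numeric vector (one sample), or a numeric matrix /
#'   data frame with samples in rows and named feature columns.
#' @return A numeric vector of test values, one per sample.
#' @examples
#' tr <- parse_expression("(x1 + x2)")
#' evaluate_expression(tr, c(x1 = 1, x2 = 2))
#' @export
evaluate_expression <- function(tree, data) {
  if (is.numeric(data) && is.null(dim(data))) {
    data <- matrix(data, nrow = 1L, dimnames = list(NULL, names(data)))
  }
  data <- as.matrix(data)
  if (is.null(colnames(data))) stop("'data' must have named feature columns")
  eval_node(tree, data)
}

eval_node <- function(node, x) {
  switch(node$kind,
    feat = {
      j <- match(node$name, colnames(x))
      if (is.na(j)) stop("feature '", node$name, "' not present in the data")
      v <- unname(x[, j])
      if (any(!is.finite(v))) stop("non-finite value for feature '", node$name, "'")
      v
    },
    const = rep.int(node$value, nrow(x)),
    op = {
      a <- eval_node(node$left, x)
      b <- eval_node(node$right, x)
      r <- switch(node$op,
        "+" = a + b,
        "-" = a - b,
        "*" = a * b,
        "/" = {
          out <- a / b
          out[abs(b) < .DIV_EPS] <- 1.0
          out
        },
        stop("unknown operator '", node$op, "'")
      )
      bad <- !is.finite(r)
      if (any(bad)) r[bad] <- sign(r[bad]) * .FINITE_CLAMP
      r[is.na(r)] <- 0  # NaN with no sign; cannot arise from finite clamped operands
      r
    },
    stop("invalid node kind")
  )
}

#' Count the building blocks of an expression
#'
#' Model complexity is the total number of building blocks in the expression:
#' every feature reference, constant, and operator counts as one.
#'
#' @param tree an expression tree.
#' @return A positive integer node count.
#' @examples
#' count_building_blocks(parse_expression("((x1 + x2) * 2.5)"))  # 5
#' @export
count_building_blocks <- function(tree) {
  if (tree$kind == "op") {
    1L + count_building_blocks(tree$left) + count_building_blocks(tree$right)
  } else {
    1L
  }
}

tree_depth <- function(tree) {
  if (tree$kind == "op") {
    1L + max(tree_depth(tree$left), tree_depth(tree$right))
  } else {
    1L
  }
}

#' Features referenced by an expression
#'
#' @param tree an expression tree.
#' @return Sorted character vector of distinct feature names appearing as
#'   leaves of the expression.
#' @export
expression_features <- function(tree) {
  collect <- function(node) {
    switch(node$kind,
      feat = node$name,
      const = character(),
      op = c(collect(node$left), collect(node$right))
    )
  }
  sort(unique(collect(tree)))
}

## Structural validator used by tests: checks node shapes and that every
## referenced feature exists in the vocabulary.
validate_tree <- function(tree, blocks = NULL) {
  ok <- switch(tree$kind,
    feat = is.character(tree$name) && length(tree$name) == 1L &&
      (is.null(blocks) || tree$name %in% blocks$feature_names),
    const = is.numeric(tree$value) && length(tree$value) == 1L && is.finite(tree$value),
    op = {
      (is.null(blocks) || tree$op %in% blocks$operators) &&
        !is.null(tree$left) && !is.null(tree$right) &&
        validate_tree(tree$left, blocks) && validate_tree(tree$right, blocks)
    },
    FALSE
  )
  isTRUE(ok)
}

random_leaf <- function(blocks, feat_prob = 0.75) {
  if (stats::runif(1) < feat_prob) {
    pool <- blocks$feature_names
    if (!is.null(blocks$expert_features) && length(blocks$expert_features) &&
        stats::runif(1) < blocks$expert_bias) {
      pool <- blocks$expert_features
    }
    feat_node(pool[sample.int(length(pool), 1L)])
  } else {
    const_node(stats::runif(1, blocks$constant_range[1L], blocks$constant_range[2L]))
  }
}

#' Draw a random expression tree
#'
#' Grow-style construction: the probability of placing a leaf rises linearly
#' with depth, and the depth bound forces leaves at \code{max_depth}, so the
#' initial population mixes single-leaf and bushier expressions.
#' Randomness comes from R's global RNG; call \code{set.seed} for
#' reproducibility.
#'
#' @param blocks a \code{\link{building_blocks}} vocabulary.
#' @param max_depth maximum tree depth (a single leaf has depth 1).
#' @return An expression tree.
#' @examples
#' set.seed(1)
#' bb <- building_blocks(paste0("g", 1:5))
#' format_expression(random_tree(bb, max_depth = 3))
#' @export
random_tree <- function(blocks, max_depth = 4L) {
  stopifnot(inherits(blocks, "building_blocks"))
  if (!is.numeric(max_depth) || max_depth < 1) stop("'max_depth' must be >= 1")
  grow <- function(depth) {
    leaf_prob <- depth / (max_depth + 1)
    if (depth >= max_depth || stats::runif(1) < leaf_prob) {
      random_leaf(blocks)
    } else {
      op <- blocks$operators[sample.int(length(blocks$operators), 1L)]
      op_node(op, grow(depth + 1L), grow(depth + 1L))
    }
  }
  grow(1L)
}

## --- preorder indexing helpers (used by mutation and recombination) -------

## Returns the subtree at preorder position i (root = 1).
subtree_at <- function(tree, i) {
  res <- NULL
  walk <- function(node) {
    count <<- count + 1L
    if (count == i) {
      res <<- node
      return(TRUE)
    }
    if (node$kind == "op") {
      if (walk(node$left)) return(TRUE)
      if (walk(node$right)) return(TRUE)
    }
    FALSE
  }
  count <- 0L
  walk(tree)
  res
}

## Returns a copy of tree with the subtree at preorder position i replaced.
replace_at <- function(tree, i, replacement) {
  count <- 0L
  rec <- function(node) {
    count <<- count + 1L
    if (count == i) return(replacement)
    if (node$kind == "op") {
      node$left <- rec(node$left)
      node$right <- rec(node$right)
    }
    node
  }
  rec(tree)
}

## --- serialization --------------------------------------------------------

#' Serialize an expression tree to an infix string
#'
#' The format is ordinary parenthesized infix arithmetic (valid R syntax,
#' with non-syntactic feature names backtick-quoted) and round-trips
#' losslessly through \code{\link{parse_expression}}: constants are printed
#' with 17 significant digits.
#'
#' @param tree an expression tree.
#' @return A single character string, e.g. \code{"((Gsg1 + 2.5) * Stip1)"}.
#' @seealso \code{\link{parse_expression}}
#' @export
format_expression <- function(tree) {
  switch(tree$kind,
    feat = deparse(as.name(tree$name), backtick = TRUE),
    const = sprintf("%.17g", tree$value),
    op = paste0("(", format_expression(tree$left), " ", tree$op, " ",
                format_expression(tree$right), ")")
  )
}

#' Parse an infix expression string into a tree
#'
#' Inverse of \code{\link{format_expression}}. Accepts any R-syntax
#' arithmetic expression over \code{+ - * /}, feature names (backtick-quoted
#' if non-syntactic), and numeric literals.
#'
#' @param text a single character string.
#' @return An expression tree.
#' @examples
#' tr <- parse_expression("((Gsg1 + 2.5) * Stip1)")
#' count_building_blocks(tr)  # 5
#' @export
parse_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  lang <- tryCatch(str2lang(text),
                   error = function(e) stop("cannot parse expression: ",
                                            conditionMessage(e)))
  lang_to_tree(lang)
}

lang_to_tree <- function(lang) {
  if (is.name(lang)) return(feat_node(as.character(lang)))
  if (is.numeric(lang)) return(const_node(as.numeric(lang)))
  if (is.call(lang)) {
    fn <- as.character(lang[[1L]])
    if (fn == "(") return(lang_to_tree(lang[[2L]]))
    if (fn == "-" && length(lang) == 2L) {
      arg <- lang_to_tree(lang[[2L]])
      if (arg$kind == "const") return(const_node(-arg$value))
      return(op_node("-", const_node(0), arg))
    }
    if (fn %in% c("+", "-", "*", "/") && length(lang) == 3L) {
      return(op_node(fn, lang_to_tree(lang[[2L]]), lang_to_tree(lang[[3L]])))
    }
  }
  stop("unsupported expression element: ", deparse(lang))
}
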