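## Variation operators for expression trees.

#' Mutate an expression tree
#'
#' One of three structural mutations is applied, chosen with the supplied
#' probabilities (which may sum to less than 1; the remainder leaves the tree
#' unchanged):
#' \describe{
#'   \item{add}{a uniformly chosen node is wrapped in a new operator node
#'     whose other argument is a fresh random leaf (node count grows by 2);}
#'   \item{remove}{a uniformly chosen operator node is replaced by one of its
#'     children ("hoist"; node count shrinks, never below 1 -- a single-leaf
#'     tree is returned unchanged);}
#'   \item{swap}{a uniformly chosen node is exchanged in place: a leaf for a
#'     fresh random leaf, an operator symbol for another operator (node count
#'     unchanged).}
#' }
#'
#' @param tree an expression tree.
#' @param blocks a \code{\link{building_blocks}} vocabulary.
#' @param rates named numeric vector of probabilities
#'   \code{c(add=, remove=, swap=)} with non-negative entries summing to at
#'   most 1.
#' @return A new expression tree; the input is not modified.
#' @examples
#' set.seed(7)
#' bb <- building_blocks(paste0("g", 1:4))
#' tr <- parse_expression("(g1 + g2)")
#' format_expression(mutate_tree(tr, bb))
#' @export
mutate_tree <- function(tree, blocks,
                        rates = c(add = 0.25, remove = 0.25, swap = 0.5)) {
  stopifnot(inherits(blocks, "building_blocks"))
  if (!is.numeric(rates) || length(rates) != 3L ||
      !all(c("add", "remove", "swap") %in% names(rates)) ||
      any(rates < 0) || sum(rates) > 1 + 1e-12) {
    stop("'rates' must be probabilities c(add=, remove=, swap=) summing to <= 1")
  }
  u <- stats::runif(1)
  kind <- if (u < rates[["add"]]) "add"
          else if (u < rates[["add"]] + rates[["remove"]]) "remove"
          else if (u < rates[["add"]] + rates[["remove"]] + rates[["swap"]]) "swap"
          else "none"
  switch(kind,
    add = mutate_add(tree, blocks),
    remove = mutate_remove(tree),
    swap = mutate_swap(tree, blocks),
    none = tree
  )
}

mutate_add <- function(tree, blocks) {
  n <- count_building_blocks(tree)
  i <- sample.int(n, 1L)
  old <- subtree_at(tree, i)
  op <- blocks$operators[sample.int(length(blocks$operators), 1L)]
  leaf <- random_leaf(blocks)
  wrapped <- if (stats::runif(1) < 0.5) op_node(op, old, leaf) else op_node(op, leaf, old)
  replace_at(tree, i, wrapped)
}

mutate_remove <- function(tree) {
  if (tree$kind != "op") return(tree)  # cannot shrink below one node
  n <- count_building_blocks(tree)
  idx <- which(vapply(seq_len(n), function(i) subtree_at(tree, i)$kind == "op", logical(1)))
  i <- idx[sample.int(length(idx), 1L)]
  node <- subtree_at(tree, i)
  child <- if (stats::runif(1) < 0.5) node$left else node$right
  replace_at(tree, i, child)
}

mutate_swap <- function(tree, blocks) {
  n <- count_building_blocks(tree)
  i <- sample.int(n, 1L)
  node <- subtree_at(tree, i)
  repl <- if (node$kind == "op") {
    node$op <- blocks$operators[sample.int(length(blocks$operators), 1L)]
    node
  } else {
    random_leaf(blocks)
  }
  replace_at(tree, i, repl)
}

#' Recombine two expression trees (subtree crossover)
#'
#' A copy of parent \code{a} receives a uniformly chosen subtree of parent
#' \code{b} at a uniformly chosen crossover point. When \code{a} has more
#' than one node the crossover point excludes the root, so the offspring
#' always retains material from both parents; two single-leaf parents yield
#' one of the two leaves.
#'
#' @param a,b expression trees (unmodified).
#' @return A new expression tree.
#' @export
recombine_trees <- function(a, b) {
  na <- count_building_blocks(a)
  nb <- count_building_blocks(b)
  donor <- subtree_at(b, sample.int(nb, 1L))
  if (na == 1L) {
    # replacing the root: offspring is the donor subtree (or parent a itself)
    return(if (stats::runif(1) < 0.5) donor else a)
  }
  i <- 1L + sample.int(na - 1L, 1L)  # never the root of a
  replace_at(a, i, donor)
}
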