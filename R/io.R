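## Readers and writers: expression matrices, label tables, classifier
## records, archive and cross-validation reports. Matrices are stored the
## way expression data are deposited -- features as rows, one column per
## sample, a feature-identifier first column -- and transposed internally to
## samples x features. Tab- and comma-delimited files are both accepted
## (delimiter sniffed from the header line).

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Load an expression matrix and sample labels
#'
#' @param matrix_path TSV/CSV file: feature identifiers in the first column,
#'   one further column per sample.
#' @param labels_path two-column TSV/CSV without header: sample identifier,
#'   class label.
#' @return A list with \code{x} (samples x features numeric matrix, sample
#'   order taken from the label file) and \code{labels} (factor).
#' @export
load_dataset <- function(matrix_path, labels_path) {
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(labels_path)) stop("label file not found: ", labels_path)
  m <- utils::read.table(matrix_path, header = TRUE, sep = sniff_sep(matrix_path),
                         check.names = FALSE, stringsAsFactors = FALSE,
                         comment.char = "", quote = "\"")
  if (ncol(m) < 2L) stop("matrix file needs a feature column plus sample columns: ",
                         matrix_path)
  features <- as.character(m[[1L]])
  dup <- features[duplicated(features)]
  if (length(dup)) stop("duplicate feature name in ", matrix_path, ": ", dup[1L])
  vals <- m[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1L]
      stop("non-numeric cell in ", matrix_path, " (feature row ",
           if (is.na(bad)) "?" else bad, ", sample column '",
           colnames(vals)[j], "')")
    }
  }
  x <- t(as.matrix(vals))
  colnames(x) <- features

  lab <- utils::read.table(labels_path, header = FALSE, sep = sniff_sep(labels_path),
                           stringsAsFactors = FALSE, comment.char = "",
                           col.names = c("sample", "class"))
  missing <- setdiff(lab$sample, rownames(x))
  if (length(missing)) {
    stop("sample '", missing[1L], "' in ", labels_path,
         " is absent from the matrix file")
  }
  x <- x[lab$sample, , drop = FALSE]
  list(x = x, labels = factor(lab$class))
}

#' Write an expression matrix and label table
#'
#' Inverse of \code{\link{load_dataset}}: features as rows in a TSV with a
#' \code{feature} identifier column, and a two-column (sample, class) label
#' TSV without header.
#'
#' @param x samples x features numeric matrix with row and column names.
#' @param labels class label per sample.
#' @param matrix_path,labels_path output file paths.
#' @export
write_dataset <- function(x, labels, matrix_path, labels_path) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("s%03d", seq_len(nrow(x)))
  out <- data.frame(feature = colnames(x), t(x), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(rownames(x), as.character(labels)),
                     labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

## --- classifier records ----------------------------------------------------

#' Serialize a classifier to a plain-text record
#'
#' One structured text record holding the expression string, ordered class
#' labels, thresholds (17 significant digits, so re-parsing is bit-exact),
#' inequality flags, and training accuracy. Round-trips losslessly through
#' \code{\link{parse_classifier}}.
#'
#' @param classifier a \code{ces_classifier}.
#' @param path optional file to write the record to.
#' @return The record as a character vector of lines (invisibly when
#'   \code{path} is given).
#' @export
serialize_classifier <- function(classifier, path = NULL) {
  num <- function(v) sprintf("%.17g", v)
  lines <- c(
    paste0("expression\t", classifier$expression),
    paste0("classes\t", paste(classifier$rule$classes, collapse = "\t")),
    paste0("thresholds\t", paste(num(classifier$rule$thresholds), collapse = "\t")),
    paste0("flags\t", paste(classifier$rule$strict_flags, collapse = "\t")),
    paste0("accuracy\t", num(classifier$accuracy))
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse a serialized classifier record
#'
#' @param text character vector of record lines, or a length-1 path to a
#'   record file.
#' @return A \code{ces_classifier} (tree, rule, fitness, feature set).
#' @seealso \code{\link{serialize_classifier}}
#' @export
parse_classifier <- function(text) {
  if (length(text) == 1L && file.exists(text)) text <- readLines(text)
  fields <- strsplit(text, "\t", fixed = TRUE)
  names(fields) <- vapply(fields, `[[`, character(1), 1L)
  fields <- lapply(fields, `[`, -1L)
  needed <- c("expression", "classes", "thresholds", "flags")
  missing <- setdiff(needed, names(fields))
  if (length(missing)) stop("classifier record is missing field '", missing[1L], "'")
  tree <- parse_expression(fields$expression)
  rule <- mc_rule(fields$classes, as.numeric(fields$thresholds),
                  as.logical(fields$flags))
  acc <- if ("accuracy" %in% names(fields)) as.numeric(fields$accuracy) else NA_real_
  structure(list(tree = tree,
                 expression = format_expression(tree),
                 rule = rule,
                 accuracy = acc,
                 complexity = count_building_blocks(tree),
                 features = expression_features(tree)),
            class = "ces_classifier")
}

## --- reports ---------------------------------------------------------------

#' Write an archive as a TSV report
#'
#' One row per archive classifier: expression string, training accuracy,
#' complexity (building-block count), and the semicolon-joined selected
#' feature list.
#'
#' @param archive list of \code{ces_classifier} objects.
#' @param path output TSV path.
#' @export
write_archive <- function(archive, path) {
  out <- data.frame(
    expression = vapply(archive, function(s) s$expression, character(1)),
    accuracy = vapply(archive, function(s) s$accuracy, numeric(1)),
    complexity = vapply(archive, function(s) s$complexity, numeric(1)),
    features = vapply(archive, function(s) paste(s$features, collapse = ";"),
                      character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write a cross-validation report
#'
#' Mirrors the evaluation tables of the protocol: one detail row per fold
#' (accuracy, number of selected genes, expression) followed by a summary
#' row with the aggregate mean accuracy, mean pairwise Tanimoto distance,
#' and mean number of selected genes.
#'
#' @param cv a \code{\link{ces_cv}} result.
#' @param path output TSV path.
#' @export
write_cv_report <- function(cv, path) {
  stopifnot(inherits(cv, "ces_cv"))
  detail <- data.frame(
    row = "fold",
    rep = cv$folds$rep, fold = cv$folds$fold,
    accuracy = cv$folds$accuracy,
    tanimoto = NA_real_,
    n_selected = cv$folds$n_features,
    expression = cv$folds$expression,
    stringsAsFactors = FALSE)
  summary_row <- data.frame(
    row = "summary", rep = NA_integer_, fold = NA_integer_,
    accuracy = cv$mean_accuracy,
    tanimoto = cv$stability,
    n_selected = cv$mean_n_features,
    expression = "",
    stringsAsFactors = FALSE)
  utils::write.table(rbind(detail, summary_row), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
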