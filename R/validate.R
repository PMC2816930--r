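# Input validation shared across the package. All user-facing validation
# failures signal a condition of class "dksig_error" so the CLI can map them
# to exit code 2.

dks_stop <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("dksig_error", "error")))
}

#' Validate a genes-by-samples expression matrix
#'
#' An expression matrix for this package is a plain numeric matrix with unique
#' gene identifiers as rownames and unique sample identifiers as colnames, all
#' values finite, at least one gene and two samples.
#'
#' @param X numeric matrix (genes in rows, samples in columns) with rownames
#'   and colnames set.
#' @param min_samples minimum number of columns required (2 for training;
#'   classification accepts any number).
#' @return the validated matrix, invisibly unchanged.
#' @export
validate_expression <- function(X, min_samples = 2L) {
  if (!is.matrix(X) || !is.numeric(X))
    dks_stop("expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(X)) || (ncol(X) > 0L && is.null(colnames(X))))
    dks_stop("expression matrix must carry gene ids (rownames) and sample ids (colnames)")
  if (nrow(X) < 1L || ncol(X) < min_samples)
    dks_stop("expression matrix needs at least 1 gene and ", min_samples,
             " sample(s); got ", nrow(X), " x ", ncol(X))
  dup_g <- unique(rownames(X)[duplicated(rownames(X))])
  if (length(dup_g))
    dks_stop("duplicated gene ids: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(X)[duplicated(colnames(X))])
  if (length(dup_s))
    dks_stop("duplicated sample ids: ", paste(dup_s, collapse = ", "))
  if (any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1L, ]
    dks_stop("non-finite expression value at gene '", rownames(X)[bad[1L]],
             "', sample '", colnames(X)[bad[2L]],
             "'; missing values are rejected, not imputed")
  }
  invisible(X)
}

#' Construct a class-label vector
#'
#' Bundles per-sample class labels with the ordered list of unique classes and
#' per-class sample counts. At least two classes are required and no class may
#' be empty or hold every sample (the out-of-class increment -N/(N - N_l) is
#' undefined otherwise).
#'
#' @param labels character vector of per-sample class labels, optionally named
#'   by sample id.
#' @param classes optional ordered character vector of the unique classes;
#'   defaults to order of first appearance.
#' @return an object of class \code{dks_labels}: a list with elements
#'   \code{labels}, \code{classes} and \code{counts}.
#' @examples
#' y <- dks_labels(c("C1", "C1", "C2", "C3", "C1", "C2", "C3", "C2"))
#' y$counts
#' @export
dks_labels <- function(labels, classes = NULL) {
  labels <- as.character(labels)
  if (anyNA(labels)) dks_stop("class labels contain NA")
  if (is.null(classes)) classes <- unique(labels)
  classes <- as.character(classes)
  unknown <- setdiff(labels, classes)
  if (length(unknown))
    dks_stop("labels not in the class list: ", paste(unique(unknown), collapse = ", "))
  N <- length(labels)
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1L))
  if (length(classes) < 2L)
    dks_stop("at least 2 classes are required; got ",
             length(classes), " (", paste(classes, collapse = ", "), ")")
  if (any(counts == 0L))
    dks_stop("empty class(es): ",
             paste(classes[counts == 0L], collapse = ", "))
  if (any(counts == N))
    dks_stop("class '", classes[counts == N][1L],
             "' holds all ", N, " samples; the KS increment is undefined")
  structure(list(labels = labels, classes = classes, counts = counts),
            class = "dks_labels")
}

#' @export
print.dks_labels <- function(x, ...) {
  cat("dks_labels:", length(x$labels), "samples,",
      length(x$classes), "classes\n")
  print(x$counts)
  invisible(x)
}

# Check sample alignment between a matrix and labels; returns dks_labels.
align_labels <- function(X, Y) {
  if (!inherits(Y, "dks_labels")) Y <- dks_labels(Y)
  if (length(Y$labels) != ncol(X))
    dks_stop("label count (", length(Y$labels),
             ") does not match sample count (", ncol(X), ")")
  Y
}

as_class <- function(Y, target_class) {
  target_class <- as.character(target_class)
  if (!target_class %in% Y$classes)
    dks_stop("unknown class '", target_class, "'; known classes: ",
             paste(Y$classes, collapse = ", "))
  target_class
}
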