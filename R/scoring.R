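# Tissue-set enrichment scoring: the inverted-GSEA KS running sum.
#
# For a fixed gene, samples are ordered by that gene's expression and the
# running sum increments by N/N_l at samples of the target class and by
# -N/(N - N_l) elsewhere. Its maximum over the decreasing-order list is the
# up-regulation score u_il; over the increasing-order list, the down score
# d_il. u_il/N equals the one-sided two-sample KS statistic D+ between the
# class and the rest.

# Deterministic sample order for one gene: expression (direction), ties broken
# by id ascending in C-locale byte order (radix) so results are platform-stable.
order_samples <- function(expr, ids, decreasing) {
  if (decreasing) order(-expr, ids, method = "radix")
  else            order(expr, ids, method = "radix")
}

#' KS running-sum increments along an ordered sample list
#'
#' @param order integer permutation of \code{1..N} giving the sample order
#'   (e.g. by decreasing expression of one gene).
#' @param labels a \code{\link{dks_labels}} object (or label vector).
#' @param target_class class whose membership drives the increments.
#' @return numeric vector of length N: \code{N/N_l} at positions where the
#'   ordered sample belongs to \code{target_class}, \code{-N/(N - N_l)}
#'   elsewhere. Sums to zero.
#' @examples
#' y <- dks_labels(c("C2", "C1", "C2", "C1", "C2", "C1", "C3", "C3"))
#' ks_increments(1:8, y, "C1")
#' @export
ks_increments <- function(order, labels, target_class) {
  if (!inherits(labels, "dks_labels")) labels <- dks_labels(labels)
  target_class <- as_class(labels, target_class)
  N <- length(labels$labels)
  if (length(order) != N || !setequal(order, seq_len(N)))
    dks_stop("'order' must be a permutation of 1..", N)
  Nl <- labels$counts[[target_class]]
  ifelse(labels$labels[order] == target_class, N / Nl, -N / (N - Nl))
}

# Shared kernel: max of the running sum of increments for labels in the given
# sample order. Returns the full partial-sum vector when partial = TRUE.
running_max <- function(ord_labels, target_class, N, Nl, partial = FALSE) {
  inc <- ifelse(ord_labels == target_class, N / Nl, -N / (N - Nl))
  ps <- cumsum(inc)
  if (partial) ps else max(ps)
}

#' Up-regulation score of one gene for one class
#'
#' Sorts samples by decreasing expression, accumulates the KS increments and
#' returns the maximum partial sum u_il.
#'
#' @param expr numeric expression vector for one gene, optionally named by
#'   sample id (names are the tie-break key; defaults to positional ids).
#' @inheritParams ks_increments
#' @return the score u_il in \[0, N\].
#' @examples
#' x <- c(1088.3, 841.9, 762.8, 681.2, 744.0, 878.7, 660.1, 1163.2)
#' y <- dks_labels(c("C1", "C1", "C2", "C3", "C1", "C2", "C3", "C2"))
#' score_gene_up(x, y, "C1")    # 16/5
#' @export
score_gene_up <- function(expr, labels, target_class) {
  score_gene_dir(expr, labels, target_class, decreasing = TRUE)
}

#' Down-regulation score of one gene for one class
#'
#' Sorts samples by increasing expression and returns the maximum partial sum
#' d_il. With distinct expression values this equals minus the minimum of the
#' decreasing-order running sum.
#'
#' @inheritParams score_gene_up
#' @return the score d_il in \[0, N\].
#' @export
score_gene_down <- function(expr, labels, target_class) {
  score_gene_dir(expr, labels, target_class, decreasing = FALSE)
}

score_gene_dir <- function(expr, labels, target_class, decreasing) {
  if (!inherits(labels, "dks_labels")) labels <- dks_labels(labels)
  target_class <- as_class(labels, target_class)
  N <- length(labels$labels)
  if (length(expr) != N)
    dks_stop("expression vector length (", length(expr),
             ") does not match sample count (", N, ")")
  if (any(!is.finite(expr))) dks_stop("non-finite expression values")
  ids <- names(expr)
  if (is.null(ids)) ids <- sprintf("s%06d", seq_len(N))
  ord <- order_samples(expr, ids, decreasing = decreasing)
  running_max(labels$labels[ord], target_class, N,
              labels$counts[[target_class]])
}

#' Score every gene against every class
#'
#' Computes the G x K matrices U (up scores), D (down scores) and the
#' difference matrices U^delta = U - D and D^delta = D - U. The differences
#' penalize genes whose class samples split between both extremes of the
#' ordered list (high u and high d simultaneously), the worst case for a
#' classifier.
#'
#' @param X genes-by-samples numeric matrix (see
#'   \code{\link{validate_expression}}).
#' @param Y a \code{\link{dks_labels}} object or label vector aligned with the
#'   columns of \code{X}.
#' @return an object of class \code{dks_scores}: list with G x K matrices
#'   \code{up}, \code{down}, \code{up_delta}, \code{down_delta} and the class
#'   vector \code{classes}.
#' @examples
#' sim <- dks_simulate(G = 30, n_per_class = 5, seed = 1)
#' sc <- dks_score(sim$X, sim$Y)
#' head(sc$up_delta)
#' @export
dks_score <- function(X, Y) {
  validate_expression(X)
  Y <- align_labels(X, Y)
  G <- nrow(X); N <- ncol(X)
  classes <- Y$classes; K <- length(classes)
  counts <- Y$counts
  sids <- colnames(X)
  up <- matrix(0, G, K, dimnames = list(rownames(X), classes))
  down <- up
  for (i in seq_len(G)) {
    xi <- X[i, ]
    lab_up <- Y$labels[order(-xi, sids, method = "radix")]
    lab_dn <- Y$labels[order(xi, sids, method = "radix")]
    for (k in seq_len(K)) {
      Nl <- counts[[k]]
      pos <- N / Nl; neg <- -N / (N - Nl)
      up[i, k] <- max(cumsum(ifelse(lab_up == classes[k], pos, neg)))
      down[i, k] <- max(cumsum(ifelse(lab_dn == classes[k], pos, neg)))
    }
  }
  structure(list(up = up, down = down,
                 up_delta = up - down, down_delta = down - up,
                 classes = classes),
            class = "dks_scores")
}

#' @export
print.dks_scores <- function(x, ...) {
  cat("dks_scores:", nrow(x$up), "genes x", length(x$classes), "classes (",
      paste(x$classes, collapse = ", "), ")\n")
  invisible(x)
}
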