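# Weighted scoring variant: favour genes that are not only class-biased but
# also among the highest (or lowest) expressed genes overall, since the
# classification step ranks the signature genes within each sample.

#' Rank of each gene's class-mean expression
#'
#' For each class, averages each gene's expression over that class's samples
#' and ranks the genes so that rank 1 is the largest mean. Ties in class means
#' are broken by gene id ascending, so each column is always a permutation of
#' \code{1..G}.
#'
#' @inheritParams dks_score
#' @return G x K integer matrix of ranks.
#' @examples
#' class_mean_ranks(dks_example_means(),
#'                  dks_labels(c("C1", "C2", "C3"), c("C1", "C2", "C3")))
#' @export
class_mean_ranks <- function(X, Y) {
  validate_expression(X)
  Y <- align_labels(X, Y)
  G <- nrow(X)
  gids <- rownames(X)
  ranks <- matrix(NA_integer_, G, length(Y$classes),
                  dimnames = list(gids, Y$classes))
  for (cl in Y$classes) {
    m <- rowMeans(X[, Y$labels == cl, drop = FALSE])
    ord <- order(-m, gids, method = "radix")
    ranks[ord, cl] <- seq_len(G)
  }
  ranks
}

#' Rank-based gene weights
#'
#' Converts class-mean ranks into weights \code{w_il = -log(rank/G)}: the top
#' ranked gene in a class gets weight \code{log(G)}, the bottom ranked gene
#' weight 0. The logarithm base only rescales the weights monotonically; it is
#' configurable because the down-weight \code{1 - w} is not base-invariant.
#'
#' @param ranks G x K integer matrix from \code{\link{class_mean_ranks}}.
#' @param G total number of genes.
#' @param log_base base of the logarithm; default natural log.
#' @return an object of class \code{dks_weights}: list with matrices
#'   \code{weights} (w_il) and \code{mean_ranks}.
#' @export
dks_weights <- function(ranks, G = nrow(ranks), log_base = exp(1)) {
  if (!is.matrix(ranks)) dks_stop("'ranks' must be a matrix")
  if (any(ranks < 1L | ranks > G))
    dks_stop("ranks must lie in 1..G (G = ", G, ")")
  structure(list(weights = -log(ranks / G, base = log_base),
                 mean_ranks = ranks),
            class = "dks_weights")
}

#' Weighted score matrices
#'
#' Applies the weights elementwise: the weighted up score is
#' \code{w * u} and the weighted down score \code{(1 - w) * d}. The formula is
#' applied exactly as defined, so \code{1 - w} can be negative for highly
#' expressed genes (\code{w > 1} when rank < G/base); such genes are thereby
#' penalized as down-signature candidates.
#'
#' @param scores a \code{\link{dks_score}} result.
#' @param W a \code{\link{dks_weights}} object (or bare weight matrix).
#' @return a \code{dks_scores} object holding the weighted matrices and their
#'   difference matrices.
#' @export
weighted_scores <- function(scores, W) {
  if (!inherits(scores, "dks_scores")) dks_stop("'scores' must be a dks_scores object")
  w <- if (inherits(W, "dks_weights")) W$weights else W
  if (!identical(dim(w), dim(scores$up)))
    dks_stop("weight matrix dimensions (", paste(dim(w), collapse = "x"),
             ") do not match score matrices (",
             paste(dim(scores$up), collapse = "x"), ")")
  up <- w * scores$up
  down <- (1 - w) * scores$down
  structure(list(up = up, down = down,
                 up_delta = up - down, down_delta = down - up,
                 classes = scores$classes),
            class = "dks_scores")
}
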