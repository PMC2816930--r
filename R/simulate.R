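# Synthetic labelled expression data with known class-specific signal, used
# throughout the tests and examples. The generator emulates log-scale
# microarray intensities: gene baselines drawn once, i.i.d. Gaussian noise,
# and for each class a block of "informative" genes shifted up (and another
# block shifted down) in that class's samples only.

#' Simulate a labelled expression matrix with class-specific signatures
#'
#' Gene baselines are drawn from N(\code{baseline_mean}, \code{baseline_sd}^2)
#' on the log2 scale and every value gets i.i.d. N(0, \code{noise_sd}^2)
#' noise. Distinct blocks of \code{informative} genes per class are shifted by
#' \code{+effect * noise_sd} (up-informative) or \code{-effect * noise_sd}
#' (down-informative) in that class's samples only, so the ground truth of
#' which genes mark which class is known exactly.
#'
#' @param G total number of genes; must satisfy
#'   \code{2 * informative * K <= G}.
#' @param K number of classes (labelled C1..CK).
#' @param n_per_class samples per class; scalar or length-K vector.
#' @param informative informative genes per class per direction.
#' @param effect shift of informative genes in units of \code{noise_sd}.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline
#'   log2 expression.
#' @param noise_sd within-gene noise standard deviation (log2 units).
#' @param scale \code{"log"} returns the log2-scale values; \code{"raw"}
#'   exponentiates them (lognormal intensities). The classifier is rank-based,
#'   so the two are equivalent downstream.
#' @param seed integer seed; the spec fully determines the output given the
#'   seed.
#' @return list with the expression matrix \code{X}, labels \code{Y}
#'   (a \code{\link{dks_labels}}), and \code{truth}: per class, the up- and
#'   down-informative gene ids.
#' @examples
#' sim <- dks_simulate(G = 50, n_per_class = 6, seed = 1)
#' sim$truth$C1$up
#' @export
dks_simulate <- function(G = 200L, K = 3L, n_per_class = 20L,
                         informative = 5L, effect = 5,
                         baseline_mean = 7, baseline_sd = 1.5, noise_sd = 1,
                         scale = c("log", "raw"), seed = NULL) {
  scale <- match.arg(scale)
  G <- as.integer(G); K <- as.integer(K)
  informative <- as.integer(informative)
  if (K < 2L) dks_stop("K must be >= 2")
  if (informative < 0L || effect < 0)
    dks_stop("'informative' and 'effect' must be non-negative")
  if (2L * informative * K > G)
    dks_stop("infeasible: 2 * informative * K = ", 2L * informative * K,
             " exceeds G = ", G)
  n_per_class <- rep_len(as.integer(n_per_class), K)
  if (any(n_per_class < 1L)) dks_stop("n_per_class must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))

  N <- sum(n_per_class)
  classes <- paste0("C", seq_len(K))
  labels <- rep(classes, n_per_class)
  gids <- sprintf("g%04d", seq_len(G))
  sids <- sprintf("s%03d", seq_len(N))

  base <- stats::rnorm(G, baseline_mean, baseline_sd)
  X <- matrix(base, G, N) + matrix(stats::rnorm(G * N, 0, noise_sd), G, N)
  dimnames(X) <- list(gids, sids)

  truth <- stats::setNames(vector("list", K), classes)
  nxt <- 1L
  for (k in seq_len(K)) {
    up <- gids[seq.int(nxt, length.out = informative)]; nxt <- nxt + informative
    dn <- gids[seq.int(nxt, length.out = informative)]; nxt <- nxt + informative
    in_class <- labels == classes[k]
    X[up, in_class] <- X[up, in_class] + effect * noise_sd
    X[dn, in_class] <- X[dn, in_class] - effect * noise_sd
    truth[[k]] <- list(up = up, down = dn)
  }
  if (scale == "raw") X <- 2^X
  list(X = X, Y = dks_labels(labels, classes = classes), truth = truth)
}

#' Built-in worked example: one gene, eight samples
#'
#' A single gene measured in eight samples of three classes, small enough to
#' trace the KS running sum by hand: sorting the values in decreasing order
#' and accumulating +8/3 at class-C1 samples and -8/5 elsewhere gives a
#' running sum peaking at u = 16/5; the increasing-order sum peaks at
#' d = 8/5.
#'
#' @return list with the 1 x 8 matrix \code{X} and labels \code{Y}.
#' @examples
#' ex <- dks_example_gene()
#' score_gene_up(ex$X[1, ], ex$Y, "C1")
#' @export
dks_example_gene <- function() {
  X <- matrix(c(1088.3, 841.9, 762.8, 681.2, 744.0, 878.7, 660.1, 1163.2),
              nrow = 1,
              dimnames = list("g1", paste0("s", 1:8)))
  list(X = X, Y = dks_labels(c("C1", "C1", "C2", "C3", "C1", "C2", "C3", "C2"),
                             classes = c("C1", "C2", "C3")))
}

#' Built-in worked example: 3 x 3 class-mean matrix
#'
#' Three genes' average expression in three classes, used to trace the
#' rank-based weighting: in class C1 the value 823.64 ranks second of the
#' three means, so gene g1 gets weight -log(2/3).
#'
#' @return a 3 x 3 numeric matrix (genes x classes).
#' @export
dks_example_means <- function() {
  matrix(c(823.64, 987.77, 678.98,
           777.64, 486.87, 123.68,
           652.38, 878.98, 268.98),
         nrow = 3,
         dimnames = list(c("g1", "g2", "g3"), c("C1", "C2", "C3")))
}
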