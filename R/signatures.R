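# Signature selection: equal-size per-class up/down gene lists taken from the
# difference score matrices, plus the rescaled variant's per-class
# normalization factors.

# Full per-class selection order (all G genes, best first) from a score table.
# Boundary ties broken by gene id ascending. The t-gene signature is always a
# prefix of this order, which sweep exploits.
signature_order <- function(scores) {
  gids <- rownames(scores$up_delta)
  pick <- function(M) lapply(stats::setNames(scores$classes, scores$classes),
                             function(cl) gids[order(-M[, cl], gids, method = "radix")])
  list(up = pick(scores$up_delta), down = pick(scores$down_delta))
}

#' Select per-class gene signatures from a score table
#'
#' For each class takes the \code{t} genes with the largest up-difference
#' score (u - d) as the up signature and the \code{t} genes with the largest
#' down-difference score (d - u) as the down signature. Equal signature sizes
#' across classes guarantee each class equal weight at classification.
#' Signatures of different classes may share genes.
#'
#' @param scores a \code{\link{dks_score}} (or \code{\link{weighted_scores}})
#'   result.
#' @param t number of genes per class per direction; \code{1 <= t <= G}.
#' @param mode which signatures the classifier will use: \code{"both"} (sum of
#'   up and down enrichment), \code{"up"} or \code{"down"}.
#' @param variant scoring variant label stored in the model (\code{"default"},
#'   \code{"weighted"} or \code{"rescaled"}).
#' @param log_base logarithm base recorded for the weighted variant.
#' @return an object of class \code{dks_model} with per-class \code{up} and
#'   \code{down} gene lists (ordered by decreasing selection score),
#'   \code{t}, \code{mode}, \code{variant} and (once fitted) \code{rescale}.
#' @export
select_signatures <- function(scores, t, mode = c("both", "up", "down"),
                              variant = c("default", "weighted", "rescaled"),
                              log_base = exp(1)) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  if (!inherits(scores, "dks_scores")) dks_stop("'scores' must be a dks_scores object")
  G <- nrow(scores$up)
  t <- as.integer(t)
  if (length(t) != 1L || is.na(t) || t < 1L || t > G)
    dks_stop("'t' must be a single integer in 1..G (G = ", G, "); got ", t)
  ord <- signature_order(scores)
  structure(list(variant = variant, mode = mode, t = t,
                 classes = scores$classes,
                 up = lapply(ord$up, utils::head, t),
                 down = lapply(ord$down, utils::head, t),
                 rescale = NULL, log_base = log_base),
            class = "dks_model")
}

#' Per-class rescaling factors from training samples
#'
#' The rescaled variant divides each class's enrichment score by the maximum
#' score that class's signature attains among the training samples, so scores
#' are constrained to fall between 0 and 1 and arbitrary expression-level
#' differences between signatures cancel.
#'
#' @param model a \code{\link{select_signatures}} model.
#' @param X_train the training expression matrix the signatures were drawn
#'   from.
#' @return named numeric vector of factors r_l > 0.
#' @export
rescale_factors <- function(model, X_train) {
  stopifnot(inherits(model, "dks_model"))
  raw <- model
  raw$rescale <- NULL
  E <- dks_classify(X_train, raw)
  r <- vapply(model$classes,
              function(cl) max(E[[paste0("E_", cl)]]), numeric(1L))
  names(r) <- model$classes
  if (any(r <= 0))
    dks_stop("non-positive rescaling factor for class(es) ",
             paste(model$classes[r <= 0], collapse = ", "),
             "; rescaling is undefined here - use the default variant instead")
  r
}

#' Train a Dual-KS signature classifier
#'
#' Scores every gene against every class with the KS running-sum statistic,
#' selects the top \code{t} up- and down-regulated genes per class, and (for
#' the chosen variant) applies rank weighting before selection or fits
#' rescaling factors after it.
#'
#' @inheritParams dks_score
#' @param t genes per class per direction.
#' @param variant \code{"default"} (raw difference scores), \code{"weighted"}
#'   (rank-weighted scores) or \code{"rescaled"} (raw scores with per-class
#'   score normalization fitted on the training samples).
#' @param mode \code{"both"}, \code{"up"} or \code{"down"}.
#' @param log_base logarithm base for the weighted variant's weights.
#' @return a \code{dks_model}; see \code{\link{select_signatures}}.
#' @examples
#' sim <- dks_simulate(G = 60, n_per_class = 8, seed = 7)
#' model <- dks_train(sim$X, sim$Y, t = 5, variant = "rescaled")
#' model
#' @export
dks_train <- function(X, Y, t, variant = c("default", "weighted", "rescaled"),
                      mode = c("both", "up", "down"), log_base = exp(1)) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  validate_expression(X)
  Y <- align_labels(X, Y)
  scores <- dks_score(X, Y)
  if (variant == "weighted") {
    W <- dks_weights(class_mean_ranks(X, Y), nrow(X), log_base = log_base)
    scores <- weighted_scores(scores, W)
  }
  model <- select_signatures(scores, t, mode = mode, variant = variant,
                             log_base = log_base)
  if (variant == "rescaled") model$rescale <- rescale_factors(model, X)
  model
}

#' @export
print.dks_model <- function(x, ...) {
  cat("dks_model (variant =", x$variant, ", mode =", x$mode,
      ", t =", x$t, ")\n")
  for (cl in x$classes) {
    cat("  ", cl, " up:   ", paste(utils::head(x$up[[cl]], 5L), collapse = " "),
        if (x$t > 5L) "..." else "", "\n", sep = "")
    cat("  ", cl, " down: ", paste(utils::head(x$down[[cl]], 5L), collapse = " "),
        if (x$t > 5L) "..." else "", "\n", sep = "")
  }
  if (!is.null(x$rescale)) {
    cat("  rescale:", paste(sprintf("%s=%.4g", names(x$rescale), x$rescale),
                            collapse = " "), "\n")
  }
  invisible(x)
}
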