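# Classification of new samples: for each class, a GSEA-style KS enrichment of
# that class's signature genes within the sample's expression-ordered pooled
# signature list, argmax over classes.
#
# The pooled up (or down) list holds one entry per (class, signature gene), so
# its length is n = t*K and each class contributes n_l = t entries even when
# classes share genes; the increment test is "entry contributed by class l",
# which keeps every running sum terminating at exactly zero.

pooled_entries <- function(sig_lists) {
  list(genes = unlist(sig_lists, use.names = FALSE),
       src = rep(names(sig_lists), lengths(sig_lists)))
}

enrich_direction <- function(x, sig_lists, decreasing) {
  p <- pooled_entries(sig_lists)
  n <- length(p$genes)
  missing <- setdiff(unique(p$genes), names(x))
  if (length(missing))
    dks_stop("signature gene(s) absent from the sample: ",
             paste(missing, collapse = ", "),
             "; supply them or classify with allow_missing = TRUE")
  expr <- unname(x[p$genes])
  ord <- if (decreasing) order(-expr, p$genes, method = "radix")
         else            order(expr, p$genes, method = "radix")
  src_ord <- p$src[ord]
  vapply(names(sig_lists), function(cl) {
    nl <- length(sig_lists[[cl]])
    max(cumsum(ifelse(src_ord == cl, n / nl, -n / (n - nl))))
  }, numeric(1L))
}

#' Per-class enrichment scores of one sample
#'
#' Sorts the pooled up-signature genes by decreasing expression in the sample
#' and the pooled down-signature genes by increasing expression, and computes
#' each class's maximum KS running sum (u'_l and d'_l). Only the gene ranks
#' matter, so any strictly monotone transform of the expression values leaves
#' the scores unchanged.
#'
#' @param x named numeric vector of the sample's expression values; must cover
#'   every signature gene.
#' @param model a \code{\link{dks_train}} model.
#' @return list with named numeric vectors \code{up} (u'_l) and \code{down}
#'   (d'_l); the element not used by the model's mode is all-NA.
#' @export
dks_enrichment <- function(x, model) {
  stopifnot(inherits(model, "dks_model"))
  if (is.null(names(x))) dks_stop("the expression vector must be named by gene id")
  na <- stats::setNames(rep(NA_real_, length(model$classes)), model$classes)
  up <- if (model$mode %in% c("both", "up"))
    enrich_direction(x, model$up, decreasing = TRUE) else na
  down <- if (model$mode %in% c("both", "down"))
    enrich_direction(x, model$down, decreasing = FALSE) else na
  list(up = up, down = down)
}

#' Classify one sample
#'
#' Combines the enrichment scores according to the model's mode
#' (\code{E_l = u'_l + d'_l}, or the single term for up/down-only models),
#' divides by the class rescaling factor when the model carries one, and
#' assigns the class with the maximum score. Ties are broken by class order in
#' the model and flagged.
#'
#' @inheritParams dks_enrichment
#' @param sample_id identifier stored in the result.
#' @return a one-row data.frame: \code{sample_id}, one \code{E_<class>} column
#'   per class, \code{call}, \code{margin} (top minus runner-up score) and
#'   \code{tie}.
#' @export
dks_classify_sample <- function(x, model, sample_id = "sample") {
  e <- dks_enrichment(x, model)
  E <- switch(model$mode,
              both = e$up + e$down,
              up = e$up,
              down = e$down)
  if (!is.null(model$rescale)) E <- E / model$rescale[model$classes]
  top <- which.max(E)  # first maximum = model class order
  sorted <- sort(E, decreasing = TRUE)
  margin <- if (length(E) > 1L) sorted[1L] - sorted[2L] else 0
  out <- data.frame(sample_id = sample_id, t(E), call = model$classes[top],
                    margin = unname(margin),
                    tie = sum(E == E[top]) > 1L,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[seq_along(E) + 1L] <- paste0("E_", model$classes)
  rownames(out) <- NULL
  out
}

#' Classify every column of an expression matrix
#'
#' @param X_new genes-by-samples matrix containing every signature gene (extra
#'   genes are ignored).
#' @param model a \code{\link{dks_train}} model.
#' @param allow_missing if TRUE, genes absent from \code{X_new} are dropped
#'   from every class's signatures symmetrically (both directions) and the
#'   pooled sizes n, n_l recomputed; the default is a hard error, since
#'   dropping a gene from one class only would bias the scores.
#' @return data.frame with one row per sample (see
#'   \code{\link{dks_classify_sample}}); zero-row for a zero-column matrix.
#' @examples
#' sim <- dks_simulate(G = 60, n_per_class = 8, seed = 7)
#' model <- dks_train(sim$X, sim$Y, t = 5)
#' head(dks_classify(sim$X, model))
#' @export
dks_classify <- function(X_new, model, allow_missing = FALSE) {
  stopifnot(inherits(model, "dks_model"))
  validate_expression(X_new, min_samples = 0L)
  if (allow_missing) model <- drop_missing_genes(model, rownames(X_new))
  res <- lapply(seq_len(ncol(X_new)), function(j)
    dks_classify_sample(stats::setNames(X_new[, j], rownames(X_new)),
                        model, sample_id = colnames(X_new)[j]))
  if (!length(res)) {
    out <- data.frame(sample_id = character(0L))
    for (cl in model$classes) out[[paste0("E_", cl)]] <- numeric(0L)
    out$call <- character(0L); out$margin <- numeric(0L); out$tie <- logical(0L)
    return(out)
  }
  do.call(rbind, res)
}

# Symmetric removal of unmeasured genes from every signature list; refuses to
# continue if any class's list empties or fills the whole pooled list.
drop_missing_genes <- function(model, available) {
  all_genes <- unique(c(unlist(model$up), unlist(model$down)))
  missing <- setdiff(all_genes, available)
  if (!length(missing)) return(model)
  strip <- function(lists) lapply(lists, function(g) setdiff(g, missing))
  model$up <- strip(model$up)
  model$down <- strip(model$down)
  check <- function(lists, dir) {
    nl <- lengths(lists); n <- sum(nl)
    if (any(nl == 0L))
      dks_stop("after dropping unmeasured genes the ", dir,
               " signature of class(es) ",
               paste(names(lists)[nl == 0L], collapse = ", "), " is empty")
    if (any(nl == n))
      dks_stop("after dropping unmeasured genes class '",
               names(lists)[nl == n][1L], "' holds the entire pooled ", dir,
               " list; classification is undefined")
  }
  if (model$mode %in% c("both", "up")) check(model$up, "up")
  if (model$mode %in% c("both", "down")) check(model$down, "down")
  model
}
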