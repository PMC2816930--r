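# Minimal base-graphics summaries; deliberately plain.

#' Plot per-class enrichment scores across samples
#'
#' Draws each class's enrichment score for every classified sample, sorted by
#' the score of one class, with the class calls along the axis.
#'
#' @param results data.frame from \code{\link{dks_classify}}.
#' @param sort_by class whose score defines the sample order; defaults to the
#'   first score column.
#' @param ... passed to \code{matplot}.
#' @export
dks_plot_scores <- function(results, sort_by = NULL, ...) {
  score_cols <- grep("^E_", names(results), value = TRUE)
  if (!length(score_cols)) dks_stop("no E_<class> score columns in 'results'")
  if (is.null(sort_by)) sort_by <- sub("^E_", "", score_cols[1L])
  key <- paste0("E_", sort_by)
  if (!key %in% score_cols) dks_stop("unknown class '", sort_by, "'")
  ord <- order(results[[key]], decreasing = TRUE)
  M <- as.matrix(results[ord, score_cols, drop = FALSE])
  graphics::matplot(M, type = "b", pch = seq_along(score_cols), lty = 1,
                    xlab = paste0("samples (sorted by ", sort_by, " score)"),
                    ylab = "enrichment score", xaxt = "n", ...)
  graphics::axis(1, at = seq_len(nrow(M)), labels = results$call[ord],
                 las = 2, cex.axis = 0.7)
  graphics::legend("topright", legend = sub("^E_", "", score_cols),
                   pch = seq_along(score_cols), lty = 1,
                   col = seq_along(score_cols), bty = "n")
  invisible(NULL)
}

#' @export
plot.dks_sweep <- function(x, ...) {
  tab <- x$table
  vs <- unique(tab$variant)
  graphics::plot(range(tab$t), range(tab$err632plus), type = "n",
                 xlab = "genes per class (t)", ylab = "err632+", ...)
  for (i in seq_along(vs)) {
    d <- tab[tab$variant == vs[i], ]
    graphics::lines(d$t, d$err632plus, type = "b", col = i, pch = i)
  }
  graphics::legend("topright", legend = vs, col = seq_along(vs),
                   pch = seq_along(vs), lty = 1, bty = "n")
  invisible(x)
}
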