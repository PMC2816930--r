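# Building models from externally supplied signatures (e.g. GMT files from
# other discovery methods): the KS classification step works with any equal-
# size per-class gene lists.

#' Build a signature model from explicit gene lists
#'
#' Lets signatures identified by other methodologies (or loaded from a GMT
#' file via \code{\link{read_gmt}}) be used with the KS classification step.
#' All classes must contribute the same number of genes per direction and each
#' list must be duplicate-free.
#'
#' @param up named list (class -> character vector of gene ids), ordered best
#'   first.
#' @param down named list with the same classes and sizes; defaults to
#'   \code{up} for up-only models.
#' @param mode \code{"both"}, \code{"up"} or \code{"down"}.
#' @param rescale optional named numeric vector of positive per-class
#'   rescaling factors.
#' @return a \code{dks_model} usable with \code{\link{dks_classify}}.
#' @examples
#' m <- dks_model(up = list(A = c("g1", "g2"), B = c("g3", "g4")),
#'                mode = "up")
#' dks_classify_sample(c(g1 = 4, g2 = 3, g3 = 2, g4 = 1), m)
#' @export
dks_model <- function(up, down = up, mode = c("both", "up", "down"),
                      rescale = NULL) {
  mode <- match.arg(mode)
  check_lists <- function(lists, what) {
    if (!is.list(lists) || is.null(names(lists)) || any(!nzchar(names(lists))))
      dks_stop(what, " signatures must be a named list (class -> gene ids)")
    if (length(unique(lengths(lists))) != 1L)
      dks_stop(what, " signatures must have equal sizes across classes; got ",
               paste(lengths(lists), collapse = ", "))
    dup <- vapply(lists, anyDuplicated, integer(1L)) > 0L
    if (any(dup))
      dks_stop("duplicated genes within the ", what, " signature of class(es) ",
               paste(names(lists)[dup], collapse = ", "))
    lapply(lists, as.character)
  }
  up <- check_lists(up, "up")
  down <- check_lists(down, "down")
  if (!identical(names(up), names(down)))
    dks_stop("up and down signatures name different classes")
  if (length(up) < 2L) dks_stop("at least 2 classes are required")
  if (!is.null(rescale)) {
    if (!identical(sort(names(rescale)), sort(names(up))) || any(rescale <= 0))
      dks_stop("rescale must be positive and named by class")
    rescale <- rescale[names(up)]
  }
  structure(list(variant = if (is.null(rescale)) "default" else "rescaled",
                 mode = mode, t = length(up[[1L]]), classes = names(up),
                 up = up, down = down, rescale = rescale, log_base = exp(1)),
            class = "dks_model")
}
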