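# Text interchange: expression matrices (TSV/CSV, genes as rows), label
# tables, GMT gene sets, JSON models and tab-separated result tables. All
# output is UTF-8 with LF line endings and carries the run configuration and
# package version in '#' comment lines; no timestamps, so identical runs are
# byte-identical.

MODEL_FORMAT_VERSION <- 1L

pkg_version <- function() as.character(utils::packageVersion("dksig"))

#' Read a genes-by-samples expression matrix from TSV or CSV
#'
#' The first column holds gene ids and the header row sample ids. All body
#' cells must be numeric and finite.
#'
#' @param path file path.
#' @param format \code{"tsv"} (default) or \code{"csv"}.
#' @param transpose set TRUE for files with samples as rows.
#' @return a validated numeric matrix.
#' @export
read_expression <- function(path, format = c("tsv", "csv"), transpose = FALSE) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2L) dks_stop("expression file needs gene ids plus >= 1 sample column")
  gids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (is.logical(v) && all(is.na(v))) {  # column of literal NA cells
      body[[j]] <- as.numeric(v)
    } else if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1L]
      dks_stop("non-numeric expression value '", v[bad], "' at row ", bad,
               " (gene '", gids[bad], "'), column '", names(body)[j], "'")
    }
  }
  X <- as.matrix(body)
  rownames(X) <- gids
  if (transpose) X <- t(X)
  validate_expression(X, min_samples = 1L)
  X
}

#' Write an expression matrix as TSV or CSV
#'
#' Values are printed with 15 significant digits so a write/read round trip is
#' lossless at that precision.
#'
#' @param X expression matrix.
#' @inheritParams read_expression
#' @param gene_col header of the gene id column.
#' @export
write_expression <- function(X, path, format = c("tsv", "csv"),
                             gene_col = "gene_id") {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c(gene_col, colnames(X)), collapse = sep), con)
  body <- apply(format(X, digits = 15, scientific = FALSE, trim = TRUE), 1L,
                paste, collapse = sep)
  writeLines(paste(rownames(X), body, sep = sep), con)
  invisible(path)
}

#' Read per-sample class labels
#'
#' Two tab-separated columns: sample id, class. A header line
#' \code{sample_id<TAB>class} is accepted and skipped. Rows are matched to the
#' expression sample order by id, so file row order is irrelevant.
#'
#' @param path file path.
#' @param sample_ids sample ids (usually \code{colnames} of the expression
#'   matrix) defining the output order.
#' @return a \code{\link{dks_labels}} aligned to \code{sample_ids}.
#' @export
read_labels <- function(path, sample_ids) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("sample_id", "class"),
                          colClasses = "character")
  if (nrow(df) && identical(tolower(df[1L, 1L]), "sample_id"))
    df <- df[-1L, , drop = FALSE]
  if (anyDuplicated(df$sample_id))
    dks_stop("duplicated sample ids in label file: ",
             paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  missing <- setdiff(sample_ids, df$sample_id)
  if (length(missing))
    dks_stop("samples present in the matrix but not the label file: ",
             paste(missing, collapse = ", "))
  extra <- setdiff(df$sample_id, sample_ids)
  if (length(extra))
    dks_stop("samples present in the label file but not the matrix: ",
             paste(extra, collapse = ", "))
  dks_labels(df$class[match(sample_ids, df$sample_id)])
}

#' Write a label table
#' @param Y a \code{\link{dks_labels}}.
#' @param sample_ids sample ids, aligned with \code{Y$labels}.
#' @param path file path.
#' @export
write_labels <- function(Y, sample_ids, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("sample_id\tclass",
               paste(sample_ids, Y$labels, sep = "\t")), con)
  invisible(path)
}

#' Export model signatures as a GMT gene-set file
#'
#' One line per class and direction, named \code{CLASS_up} / \code{CLASS_down}
#' with a description recording the variant and signature size.
#'
#' @param model a \code{\link{dks_train}} model.
#' @param path file path.
#' @export
write_gmt <- function(model, path) {
  stopifnot(inherits(model, "dks_model"))
  desc <- paste0("variant=", model$variant, ";t=", model$t)
  lines <- character(0L)
  for (cl in model$classes) {
    lines <- c(lines,
               paste(c(paste0(cl, "_up"), desc, model$up[[cl]]), collapse = "\t"),
               paste(c(paste0(cl, "_down"), desc, model$down[[cl]]), collapse = "\t"))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a GMT gene-set file
#' @param path file path.
#' @return named list of character gene-id vectors, with the description lines
#'   in attribute \code{"descriptions"}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    dks_stop("GMT line(s) with fewer than 3 fields: line ",
             paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1L), 2L), names(sets))
  sets
}

#' Serialize a model to JSON
#'
#' The document carries a format-version field, the package version and every
#' model component (variant, mode, t, log base, classes, signatures, rescale
#' factors), so a model can be stored and reloaded losslessly.
#'
#' @param model a \code{\link{dks_train}} model.
#' @param path file path.
#' @export
write_dks_model <- function(model, path) {
  stopifnot(inherits(model, "dks_model"))
  doc <- list(format_version = MODEL_FORMAT_VERSION,
              package = "dksig", package_version = pkg_version(),
              variant = model$variant, mode = model$mode, t = model$t,
              log_base = model$log_base, classes = model$classes,
              up = model$up, down = model$down,
              rescale = as.list(model$rescale))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model from JSON
#' @param path file path.
#' @return a \code{dks_model}.
#' @export
read_dks_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format_version) ||
      doc$format_version > MODEL_FORMAT_VERSION)
    dks_stop("unsupported model format version: ",
             if (is.null(doc$format_version)) "missing" else doc$format_version)
  rescale <- if (length(doc$rescale)) unlist(doc$rescale) else NULL
  structure(list(variant = doc$variant, mode = doc$mode, t = as.integer(doc$t),
                 classes = doc$classes,
                 up = lapply(doc$up, as.character)[doc$classes],
                 down = lapply(doc$down, as.character)[doc$classes],
                 rescale = rescale, log_base = doc$log_base),
            class = "dks_model")
}

# '#'-prefixed provenance header written atop result tables.
config_header <- function(config) {
  cfg <- paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1L)),
    sep = "=", collapse = " ")
  c(paste0("# dksig ", pkg_version()), paste0("# config: ", cfg))
}

#' Write classification results as tab-separated text
#' @param results data.frame from \code{\link{dks_classify}}.
#' @param path file path.
#' @param config named list recorded in the header for provenance.
#' @export
write_classification <- function(results, path, config = list()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(config_header(config), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a sweep result table plus its JSON summary
#' @param sweep a \code{\link{dks_sweep}} result.
#' @param path path of the TSV table; the JSON summary (optimum and settings)
#'   goes to \code{paste0(path, ".json")}.
#' @param config named list recorded in the header.
#' @export
write_sweep <- function(sweep, path, config = list()) {
  stopifnot(inherits(sweep, "dks_sweep"))
  con <- file(path, open = "wb")
  writeLines(config_header(config), con)
  utils::write.table(sweep$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  jsonlite::write_json(
    list(package_version = pkg_version(),
         optimum_t = sweep$optimum_t, optimum_variant = sweep$optimum_variant,
         grid = sweep$grid, variants = sweep$variants, mode = sweep$mode,
         B = sweep$B, seed = sweep$seed, config = config),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
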