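#' Read a wide-matrix spectra CSV
#'
#' Expected layout: header `sample_id,label,<wn_1>,...,<wn_N>` where the
#' intensity column names are the wavenumbers of the shared grid; one row per
#' spectrum. The `label` column may be empty for unlabelled spectra.
#'
#' @param path Path to a CSV file.
#' @return A [spectra_set()].
#' @export
read_spectra <- function(path) {
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged file: line %d has %d fields, header has %d",
                 bad, nf[bad], nf[1]), call. = FALSE)
  }
  need <- c("sample_id", "label")
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  miss <- setdiff(need, header)
  if (length(miss)) {
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  dt <- data.table::fread(path, header = TRUE, sep = ",", colClasses = list(
    character = need), data.table = FALSE, fill = FALSE)
  wn_cols <- setdiff(names(dt), need)
  if (length(wn_cols) < 2) stop("fewer than 2 intensity columns", call. = FALSE)
  grid <- suppressWarnings(as.numeric(wn_cols))
  if (anyNA(grid)) {
    stop(sprintf("non-numeric wavenumber column name: %s",
                 sQuote(wn_cols[which(is.na(grid))[1]])), call. = FALSE)
  }
  mat <- as.matrix(dt[, wn_cols, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(dt[wn_cols], is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric intensities in column %s", sQuote(wn_cols[bad])),
         call. = FALSE)
  }
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("missing/non-numeric intensity at row %d (sample %s), wavenumber %s",
                 bad[1], sQuote(dt$sample_id[bad[1]]), wn_cols[bad[2]]), call. = FALSE)
  }
  labels <- dt$label
  if (all(is.na(labels)) || all(labels == "")) {
    labels <- NULL
  } else {
    labels[is.na(labels)] <- ""
    if (any(labels == "")) {
      stop(sprintf("row %d has an empty label while others are labelled",
                   which(labels == "")[1]), call. = FALSE)
    }
  }
  spectra_set(grid, mat, labels = labels, ids = dt$sample_id)
}

#' Write a spectra set as a wide-matrix CSV
#'
#' Inverse of [read_spectra()]: intensities are written with full double
#' precision so that a read/write round trip reproduces the set exactly.
#'
#' @param set A [spectra_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  lab <- if (is.null(set$labels)) rep("", nrow(set$spectra)) else as.character(set$labels)
  df <- data.frame(sample_id = set$ids, label = lab, check.names = FALSE,
                   stringsAsFactors = FALSE)
  # doubles serialized at 17 significant digits so the round trip is exact
  mat <- as.data.frame(matrix(sprintf("%.17g", set$spectra), nrow(set$spectra)))
  names(mat) <- sprintf("%.17g", set$grid)
  data.table::fwrite(cbind(df, mat), path, quote = FALSE)
  invisible(path)
}

#' Write an analysis result as versioned JSON
#'
#' All derived artifacts (band counts, CV metrics, ROC points) circulate as
#' JSON documents carrying a `schema` tag.
#'
#' @param x A named list (or object coercible to one).
#' @param path Output path.
#' @param schema Schema tag string embedded in the document.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path, schema) {
  stopifnot(is.character(schema), length(schema) == 1)
  doc <- c(list(schema = schema), as.list(x))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_result_json
#' @export
read_result_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
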