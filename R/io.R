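#' Read a feature table from TSV or BIOM
#'
#' TSV tables follow the QIIME convention: lines starting with '#' are
#' comments, except a header line whose first cell is "#OTU ID", which marks a
#' features-as-rows table. Tables without the sentinel are read as
#' samples-as-rows with sample identifiers in the first column. BIOM 1.0
#' (JSON) and BIOM 2.1 (HDF5) are read through the biomformat package when it
#' is installed.
#'
#' @param path Path to an existing file.
#' @param format One of "auto", "tsv", "biom". "auto" decides by file
#'   extension (.biom -> biom) and falls back to tsv.
#' @return A validated \code{\link{feature_table}} (samples x features).
#' @export
read_feature_table <- function(path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # features x samples
    return(feature_table(t(m)))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty file: ", path)
  # locate header: first line that is not a pure comment, or the sentinel line
  is_sentinel <- startsWith(lines, "#OTU ID")
  header_idx <- if (any(is_sentinel)) which(is_sentinel)[1] else {
    w <- which(!startsWith(lines, "#"))
    if (length(w) == 0) stop("no header line found in ", path)
    w[1]
  }
  features_as_rows <- any(is_sentinel)
  body <- lines[seq(header_idx, length(lines))]
  body <- body[!(startsWith(body, "#") & !startsWith(body, "#OTU ID"))]
  con <- textConnection(body)
  on.exit(close(con))
  df <- utils::read.table(con, sep = "\t", header = TRUE, check.names = FALSE,
                          comment.char = "", quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed table (need id column plus counts): ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(df)[-1][!vapply(df[-1], is.numeric, logical(1))][1]
    stop(sprintf("non-numeric counts in column '%s' of %s", bad, path))
  }
  rownames(m) <- ids
  if (features_as_rows) m <- t(m)
  feature_table(m)
}

#' Write a feature table to TSV
#'
#' Emits the QIIME-style features-as-rows layout with the "#OTU ID" header
#' sentinel, in deterministic (table) order, so that
#' \code{read_feature_table(write_feature_table(x))} round-trips counts,
#' identifiers and order losslessly.
#'
#' @param table A \code{feature_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  m <- t(unclass(table))  # features x samples
  header <- paste(c("#OTU ID", colnames(m)), collapse = "\t")
  rows <- paste(rownames(m),
                apply(m, 1, function(r) paste(format(r, scientific = FALSE, trim = TRUE),
                                              collapse = "\t")),
                sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read sample metadata (QIIME2 dialect)
#'
#' The first column ("sample-id", "#SampleID" or "sampleid" variants) holds
#' sample identifiers; an optional "#q2:types" row is dropped. Missing
#' optional columns are permitted — operations that need a column check for it
#' themselves.
#'
#' @param path Path to a tab-separated metadata file.
#' @return A data.frame with a \code{sample_id} column first.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          comment.char = "", quote = "", stringsAsFactors = FALSE)
  first <- tolower(gsub("[^a-z]", "", tolower(names(df)[1])))
  if (!first %in% c("sampleid", "id", "featureid")) {
    warning("first metadata column '", names(df)[1],
            "' does not look like a sample identifier column; using it anyway")
  }
  names(df)[1] <- "sample_id"
  # drop QIIME2 type-annotation row if present
  if (nrow(df) > 0 && startsWith(as.character(df$sample_id[1]), "#q2:")) {
    df <- df[-1, , drop = FALSE]
    df[] <- lapply(df, utils::type.convert, as.is = TRUE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample identifiers in metadata")
  rownames(df) <- NULL
  df
}

#' Read a feature taxonomy map
#'
#' Expects TSV with feature identifiers in the first column and a lineage
#' string (e.g. "k__Bacteria; p__...; g__Bacillus") in the second; a third
#' confidence column is ignored.
#'
#' @param path Path to the taxonomy TSV.
#' @return Named character vector: lineage strings keyed by feature id.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          comment.char = "", quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("taxonomy file needs at least id and lineage columns")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate feature identifiers in taxonomy")
  lin <- as.character(df[[2]])
  if (any(!nzchar(lin))) stop("empty lineage string in taxonomy")
  stats::setNames(lin, ids)
}

#' Read and validate a labeled square distance matrix
#'
#' @param path TSV with row and column labels; values must be symmetric within
#'   1e-9 with an exactly-zero diagonal.
#' @return Numeric matrix with matching dimnames; diagonal forced to exact 0
#'   and the matrix symmetrised within the stated tolerance.
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          comment.char = "", quote = "", row.names = 1,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  validate_distance_matrix(m)
}

#' @rdname read_distance_matrix
#' @param m A square numeric matrix with labels.
#' @export
validate_distance_matrix <- function(m) {
  if (nrow(m) != ncol(m)) stop("distance matrix is not square")
  if (is.null(rownames(m)) || is.null(colnames(m))) stop("distance matrix must be labeled")
  if (!identical(rownames(m), colnames(m))) stop("row/column labels disagree")
  if (anyDuplicated(rownames(m))) stop("duplicate labels in distance matrix")
  if (any(m < 0)) stop("negative distances")
  if (max(abs(m - t(m))) > 1e-9) stop("distance matrix asymmetric beyond 1e-9")
  if (any(abs(diag(m)) > 1e-9)) stop("distance matrix diagonal not zero")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Write a labeled distance matrix to TSV
#' @param m Labeled square matrix.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  header <- paste(c("", colnames(m)), collapse = "\t")
  rows <- paste(rownames(m),
                apply(m, 1, function(r) paste(format(r, digits = 17, scientific = FALSE,
                                                     trim = TRUE), collapse = "\t")),
                sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}
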