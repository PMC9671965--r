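#' Construct a validated feature table
#'
#' A feature table holds non-negative integer read counts for a set of samples
#' (rows) by a set of features (columns, typically amplicon sequence variants,
#' ASVs). It is the universal input of the toolkit: the post-denoising count
#' table every downstream step consumes.
#'
#' @param counts Numeric matrix, samples in rows and features in columns, with
#'   unique non-empty dimnames. Values must be non-negative and integral
#'   (floats within 1e-6 of an integer are coerced; anything else is rejected,
#'   since denoised count tables are integral by construction).
#' @return An object of class \code{feature_table}: the validated count matrix
#'   (storage mode double, integral values) with class attribute set.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("f1", "f2")))
#' ft <- feature_table(m)
#' sample_totals(ft)
#' @export
feature_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix (samples x features)")
  }
  dn <- dimnames(counts)
  if (is.null(dn)) dn <- list(NULL, NULL)
  # zero-extent margins legitimately carry no names (e.g. every sample dropped)
  if (is.null(dn[[1]])) {
    if (nrow(counts) > 0) stop("counts must have sample (row) names")
    dn[1] <- list(character(0))
  }
  if (is.null(dn[[2]])) {
    if (ncol(counts) > 0) stop("counts must have feature (column) names")
    dn[2] <- list(character(0))
  }
  dimnames(counts) <- dn
  if (anyDuplicated(dn[[1]])) stop("duplicate sample identifiers: ",
                                   paste(unique(dn[[1]][duplicated(dn[[1]])]), collapse = ", "))
  if (anyDuplicated(dn[[2]])) stop("duplicate feature identifiers: ",
                                   paste(unique(dn[[2]][duplicated(dn[[2]])]), collapse = ", "))
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', feature '%s'",
                 dn[[1]][bad[1]], dn[[2]][bad[2]]))
  }
  off <- abs(counts - round(counts))
  if (any(off > 1e-6)) {
    bad <- which(off > 1e-6, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count %.6g at sample '%s', feature '%s'",
                 counts[bad[1], bad[2]], dn[[1]][bad[1]], dn[[2]][bad[2]]))
  }
  counts <- round(counts)
  storage.mode(counts) <- "double"
  class(counts) <- c("feature_table", class(counts))
  counts
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features, %s total reads\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Sample identifiers and feature identifiers of a feature table
#' @param table A \code{feature_table}.
#' @return Character vector of identifiers, in table order.
#' @export
ft_samples <- function(table) rownames(table)

#' @rdname ft_samples
#' @export
ft_features <- function(table) colnames(table)

# keep the class when subsetting with drop = FALSE
#' @export
`[.feature_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("feature_table", class(out))
  out
}

#' Per-sample total read counts
#'
#' @param table A \code{feature_table}.
#' @return Named numeric vector of exact integer row sums, one per sample.
#' @export
sample_totals <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  rowSums(unclass(table))
}
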