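#' Read a source-proportion table
#'
#' Samples-by-sources TSV as emitted by microbial source-tracking tools
#' (columns such as sea_water, sediment, beach_sand, unknown). Proportions
#' must be non-negative and sum to 1 per sample within 1e-6.
#'
#' @param path Path to the TSV (first column sample identifiers).
#' @return Data.frame with sample_id first and one numeric column per source.
#' @export
read_source_proportions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          comment.char = "", quote = "", stringsAsFactors = FALSE)
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  validate_source_proportions(df)
}

validate_source_proportions <- function(df) {
  num <- df[, -1, drop = FALSE]
  if (!all(vapply(num, is.numeric, logical(1)))) stop("non-numeric source proportions")
  if (any(as.matrix(num) < 0)) stop("negative source proportions")
  sums <- rowSums(num)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("per-sample source proportions do not sum to 1 (max deviation ",
         format(max(abs(sums - 1))), ")")
  }
  df
}

#' Sea-water to sediment source ratio
#'
#' Per-sample contrast of the proportion of microbes attributed to sea water
#' versus marine sediment: \deqn{log2((p_{SW} + c) / (p_{SED} + c))} with a
#' symmetric pseudocount c (default 1e-4) guarding zero attributions. The
#' log scale makes the ratio antisymmetric — swapping sources flips the
#' sign — and accommodates samples dominated by either source. Sensitivity to
#' the pseudocount is reported alongside (ratio recomputed at c/10 and
#' c*10).
#'
#' @param props Source-proportion data.frame
#'   (\code{\link{read_source_proportions}}).
#' @param sw,sed Column names of the sea-water and sediment sources.
#' @param pseudo Pseudocount (default 1e-4).
#' @return Data.frame: sample_id, sw_sed_ratio, ratio_pseudo_down,
#'   ratio_pseudo_up.
#' @export
sw_sed_ratio <- function(props, sw = "sea_water", sed = "sediment", pseudo = 1e-4) {
  for (col in c(sw, sed)) {
    if (!col %in% names(props)) stop("missing source column '", col, "'")
  }
  ratio_at <- function(c) log2((props[[sw]] + c) / (props[[sed]] + c))
  data.frame(sample_id = props$sample_id,
             sw_sed_ratio = ratio_at(pseudo),
             ratio_pseudo_down = ratio_at(pseudo / 10),
             ratio_pseudo_up = ratio_at(pseudo * 10),
             stringsAsFactors = FALSE)
}

#' Group summary of SW:SED ratios
#'
#' Per-group median and interquartile range of the per-sample ratios, with an
#' omnibus Kruskal-Wallis test across groups when more than one group is
#' present.
#'
#' @param ratios Numeric vector of per-sample ratios.
#' @param grouping Grouping vector, same length; NA-group samples are
#'   excluded with a warning.
#' @return List with \code{summary} (data.frame: group, n, median, q25, q75)
#'   and \code{test} (Kruskal-Wallis H/p, or NULL for a single group).
#' @export
ratio_group_summary <- function(ratios, grouping) {
  stopifnot(length(ratios) == length(grouping))
  keep <- !is.na(grouping) & !is.na(ratios)
  if (any(!keep)) warning(sum(!keep), " samples with missing ratio/group excluded")
  ratios <- ratios[keep]; grouping <- as.character(grouping[keep])
  if (length(ratios) == 0) stop("no complete observations")
  sp <- split(ratios, grouping)
  summ <- data.frame(group = names(sp),
                     n = vapply(sp, length, integer(1)),
                     median = vapply(sp, stats::median, numeric(1)),
                     q25 = vapply(sp, function(v) unname(stats::quantile(v, 0.25)), numeric(1)),
                     q75 = vapply(sp, function(v) unname(stats::quantile(v, 0.75)), numeric(1)),
                     stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  test <- if (length(sp) >= 2 && length(unique(ratios)) >= 2) {
    kruskal_wallis(ratios, grouping)
  } else NULL
  list(summary = summ, test = test)
}
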