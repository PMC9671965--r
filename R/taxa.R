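# Lineage matching is case-insensitive fixed-substring search over the whole
# lineage string; features with no taxonomy entry never match.
lineage_matches <- function(feature_ids, taxonomy, patterns) {
  if (length(patterns) == 0) stop("patterns must be non-empty")
  lin <- taxonomy[feature_ids]
  lin[is.na(lin)] <- ""
  lin_lc <- tolower(lin)
  hit <- rep(FALSE, length(lin))
  for (p in patterns) {
    hit <- hit | grepl(tolower(p), lin_lc, fixed = TRUE)
  }
  hit
}

#' Filter features by taxonomic lineage
#'
#' Removes (or with \code{keep = TRUE}, retains) features whose lineage string
#' contains any of the given patterns, case-insensitively, at any rank.
#' The default pattern removes chloroplast reads, the dominant non-microbial
#' contaminant of aquatic host-associated 16S libraries. Features without a
#' taxonomy entry are treated as non-matching. Counts of surviving features
#' and the sample set are unchanged.
#'
#' @param table A \code{\link{feature_table}}.
#' @param taxonomy Named character vector of lineages (see
#'   \code{\link{read_taxonomy}}).
#' @param patterns Character vector of substrings to match (non-empty).
#' @param keep If \code{FALSE} (default) matching features are dropped; if
#'   \code{TRUE} only matching features are retained.
#' @return A \code{feature_table} with the surviving features, sample order
#'   unchanged.
#' @export
filter_features_by_taxon <- function(table, taxonomy, patterns = "chloroplast",
                                     keep = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  hit <- lineage_matches(ft_features(table), taxonomy, patterns)
  sel <- if (keep) hit else !hit
  table[, sel, drop = FALSE]
}

#' Prevalence and relative abundance of a taxon by group
#'
#' For each level of a metadata grouping column, reports the fraction of
#' samples containing at least one read of a feature matching \code{pattern},
#' and summary statistics of the per-sample relative abundance of matching
#' reads (matching reads / total reads). Used e.g. to tabulate how often
#' probiotic genera such as Bacillus occur across host species and body sites.
#'
#' @inheritParams filter_features_by_taxon
#' @param pattern Single lineage substring (e.g. "g__Bacillus").
#' @param metadata Data.frame with \code{sample_id} plus the grouping column.
#' @param group_by Name of the grouping column in \code{metadata}.
#' @return Data.frame with columns group, n_samples, prevalence (in [0, 1]),
#'   mean_rel_abundance, median_rel_abundance. Groups with zero samples in the
#'   table are dropped with a warning.
#' @export
taxon_prevalence <- function(table, taxonomy, pattern, metadata, group_by) {
  stopifnot(inherits(table, "feature_table"), length(pattern) == 1)
  if (!group_by %in% names(metadata)) stop("metadata lacks column '", group_by, "'")
  hit <- lineage_matches(ft_features(table), taxonomy, pattern)
  totals <- sample_totals(table)
  match_reads <- rowSums(unclass(table)[, hit, drop = FALSE])
  rel <- ifelse(totals > 0, match_reads / totals, 0)
  groups <- metadata[[group_by]][match(ft_samples(table), metadata$sample_id)]
  levels_all <- unique(metadata[[group_by]])
  missing_groups <- setdiff(levels_all, groups)
  if (length(missing_groups) > 0) {
    warning("groups with no samples in table excluded: ",
            paste(missing_groups, collapse = ", "))
  }
  keep <- !is.na(groups)
  res <- lapply(split(seq_len(nrow(table))[keep], groups[keep]), function(idx) {
    data.frame(n_samples = length(idx),
               prevalence = mean(match_reads[idx] > 0),
               mean_rel_abundance = mean(rel[idx]),
               median_rel_abundance = stats::median(rel[idx]))
  })
  out <- do.call(rbind, res)
  out <- cbind(group = names(res), out)
  rownames(out) <- NULL
  out
}
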