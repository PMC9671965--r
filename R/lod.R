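#' On-target read fractions for positive extraction controls
#'
#' For each positive control, computes the fraction of its reads assigned to
#' features whose lineage matches any of the control's expected taxa. This is
#' the y-axis of the limit-of-detection curve: well-sequenced controls are
#' dominated by their known input organisms, while controls near extinction
#' dilution are dominated by the contamination floor.
#'
#' @param table A \code{\link{feature_table}} containing the control samples.
#' @param taxonomy Named lineage vector (\code{\link{read_taxonomy}}).
#' @param controls Data.frame with columns \code{sample_id},
#'   \code{expected_taxa} (semicolon-separated lineage substrings), and
#'   optionally \code{known_cells} (cells input to DNA extraction).
#' @return Data.frame of class \code{control_series}: sample_id, total_reads,
#'   on_target_fraction (0 when total_reads is 0), known_cells (NA if absent).
#' @export
control_target_fraction <- function(table, taxonomy, controls) {
  stopifnot(inherits(table, "feature_table"))
  if (!all(c("sample_id", "expected_taxa") %in% names(controls))) {
    stop("controls needs sample_id and expected_taxa columns")
  }
  missing <- setdiff(controls$sample_id, ft_samples(table))
  if (length(missing) > 0) {
    stop("controls absent from table: ", paste(missing, collapse = ", "))
  }
  if (any(!nzchar(trimws(controls$expected_taxa)))) {
    stop("every control needs non-empty expected_taxa")
  }
  totals <- sample_totals(table)
  frac <- vapply(seq_len(nrow(controls)), function(i) {
    sid <- controls$sample_id[i]
    pats <- trimws(strsplit(controls$expected_taxa[i], ";", fixed = TRUE)[[1]])
    pats <- pats[nzchar(pats)]
    hit <- lineage_matches(ft_features(table), taxonomy, pats)
    tot <- totals[[sid]]
    if (tot == 0) 0 else sum(unclass(table)[sid, hit]) / tot
  }, numeric(1))
  out <- data.frame(sample_id = controls$sample_id,
                    total_reads = unname(totals[controls$sample_id]),
                    on_target_fraction = frac,
                    known_cells = if ("known_cells" %in% names(controls))
                      controls$known_cells else NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("control_series", class(out))
  out
}

hill_curve <- function(x, K, h, p_max) p_max * x^h / (K^h + x^h)

#' Fit the allosteric-sigmoid (Hill) limit-of-detection curve
#'
#' Least-squares fit of \deqn{p(x) = p_{max} x^h / (K^h + x^h)} to
#' (x, on-target fraction) pairs from a positive-control dilution series,
#' where x is either the total read count or the known cell count. K is the
#' point of half-maximal on-target fraction, h the Hill exponent and p_max the
#' asymptote (bounded at 1, optionally pinned to 1). The fit is deterministic:
#' a fixed log-spaced grid of starting values (K in \{1e2, 1e3, 1e4\} scaled
#' into the data range, h in \{0.5, 1, 2, 4\}) is tried and the converged fit
#' with smallest residual sum of squares wins; ties break to the smallest K,
#' then smallest h.
#'
#' @param series A \code{control_series} data.frame
#'   (\code{\link{control_target_fraction}}), or any data.frame with
#'   \code{on_target_fraction} and the column named by \code{x}.
#' @param x Name of the predictor column: "total_reads" (default) or
#'   "known_cells".
#' @param fix_pmax If TRUE, pin the asymptote at exactly 1 instead of
#'   estimating it.
#' @return Object of class \code{sigmoid_fit} with elements K, h, p_max, rss,
#'   n, and fitted().
#' @export
fit_allosteric_sigmoid <- function(series, x = "total_reads", fix_pmax = FALSE) {
  if (!all(c(x, "on_target_fraction") %in% names(series))) {
    stop("series needs columns '", x, "' and 'on_target_fraction'")
  }
  xs <- as.numeric(series[[x]])
  ys <- as.numeric(series$on_target_fraction)
  ok <- !is.na(xs) & !is.na(ys)
  xs <- xs[ok]; ys <- ys[ok]
  if (length(xs) < 4) stop("need at least 4 points to fit the sigmoid")
  if (length(unique(xs)) < 2) stop("predictor values span fewer than 2 distinct values")
  if (any(ys < 0 | ys > 1)) stop("on_target_fraction outside [0, 1]")
  if (length(unique(ys)) == 1) {
    stop("degenerate fit: all on-target fractions identical (", ys[1], ")")
  }
  # positive x required by the power law; zero-read controls carry no signal
  pos <- xs > 0
  xs <- xs[pos]; ys <- ys[pos]
  if (length(xs) < 4) stop("need at least 4 points with positive predictor")

  K_grid <- c(1e2, 1e3, 1e4)
  h_grid <- c(0.5, 1, 2, 4)
  p0 <- min(max(max(ys), 0.1), 1)

  best <- NULL
  tried <- character(0)
  for (K0 in K_grid) for (h0 in h_grid) {
    tried <- c(tried, sprintf("K0=%.4g h0=%.2g", K0, h0))
    fit <- tryCatch({
      if (fix_pmax) {
        minpack.lm::nlsLM(ys ~ x^h / (K^h + x^h),
                          data = list(ys = ys, x = xs),
                          start = list(K = K0, h = h0),
                          lower = c(K = 1e-12, h = 1e-6),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(ys ~ p_max * x^h / (K^h + x^h),
                          data = list(ys = ys, x = xs),
                          start = list(K = K0, h = h0, p_max = p0),
                          lower = c(K = 1e-12, h = 1e-6, p_max = 1e-6),
                          upper = c(K = Inf, h = Inf, p_max = 1),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    cf <- stats::coef(fit)
    cand <- list(K = unname(cf["K"]), h = unname(cf["h"]),
                 p_max = if (fix_pmax) 1 else unname(cf["p_max"]), rss = rss)
    if (is.null(best) ||
        rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 &&
         (cand$K < best$K - 1e-12 ||
          (abs(cand$K - best$K) <= 1e-12 && cand$h < best$h)))) {
      best <- cand
    }
  }
  if (is.null(best)) {
    stop("sigmoid fit failed to converge; initializations tried: ",
         paste(tried, collapse = "; "))
  }
  structure(list(K = best$K, h = best$h, p_max = best$p_max, rss = best$rss,
                 n = length(xs), predictor = x),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("Hill sigmoid fit on %s (n = %d): K = %.4g, h = %.4g, p_max = %.4g, RSS = %.4g\n",
              x$predictor, x$n, x$K, x$h, x$p_max, x$rss))
  invisible(x)
}

#' Evaluate a fitted sigmoid
#' @param object A \code{sigmoid_fit}.
#' @param newdata Numeric vector of predictor values.
#' @param ... Unused.
#' @return Predicted on-target fractions.
#' @export
predict.sigmoid_fit <- function(object, newdata, ...) {
  hill_curve(newdata, object$K, object$h, object$p_max)
}

#' Closed-form limit of detection from a sigmoid fit
#'
#' Inverts the fitted Hill curve analytically at the target on-target fraction
#' t: \deqn{x^* = K (t / (p_{max} - t))^{1/h}.} The read-count limit of
#' detection is reported as the integer ceiling of x* (read totals are
#' integers; the first attainable total at or above the threshold).
#'
#' @param fit A \code{sigmoid_fit} on the read axis.
#' @param threshold Target fraction in (0, p_max); default 0.9, the
#'   conventional KatharoSeq setting.
#' @return Integer-valued limit of detection in reads.
#' @export
solve_lod <- function(fit, threshold = 0.9) {
  x <- invert_sigmoid(fit, threshold)
  # snap away sub-nano floating fuzz so an analytically integral crossing
  # point is not pushed to the next integer
  ceiling(round(x, 9))
}

# analytic inversion shared by the read- and cell-axis limits
invert_sigmoid <- function(fit, threshold) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (threshold <= 0) stop("threshold must be positive")
  if (threshold >= fit$p_max) {
    stop(sprintf("threshold %.4g >= fitted asymptote p_max %.4g: curve never attains it",
                 threshold, fit$p_max))
  }
  fit$K * (threshold / (fit$p_max - threshold))^(1 / fit$h)
}

#' Cell-count limit of detection
#'
#' Fits the same allosteric sigmoid with known input cell counts as predictor
#' and inverts it at the threshold, yielding the smallest number of cells into
#' DNA extraction at which the assay reads predominantly on-target. Reported
#' on the continuous cell scale (not rounded): positive controls are counted
#' by plating, so fractional interpolated values are meaningful.
#'
#' @param series A \code{control_series} with \code{known_cells} for >= 4
#'   points.
#' @inheritParams fit_allosteric_sigmoid
#' @param threshold Target fraction, default 0.9.
#' @return List with elements lod_cells, threshold, and fit (the
#'   \code{sigmoid_fit} on the cell axis).
#' @export
solve_lod_cells <- function(series, threshold = 0.9, fix_pmax = FALSE) {
  if (!"known_cells" %in% names(series) || sum(!is.na(series$known_cells)) < 4) {
    stop("known_cells required for at least 4 controls")
  }
  fit <- fit_allosteric_sigmoid(series, x = "known_cells", fix_pmax = fix_pmax)
  list(lod_cells = invert_sigmoid(fit, threshold), threshold = threshold, fit = fit)
}

#' Exclude samples below the read-count limit of detection
#'
#' Retention is inclusive at exactly the limit: samples with total reads
#' strictly below \code{lod_reads} are excluded. Exclusion is decided on the
#' table as given — in the standard workflow that is the table before
#' chloroplast removal, matching the processing order of the assay
#' (exclude at the LoD first, filter contaminant lineages second).
#'
#' @param table A \code{\link{feature_table}}.
#' @param lod_reads Read-count limit of detection (>= 1).
#' @return List with \code{table} (retained samples, feature set unchanged)
#'   and \code{excluded}, a data.frame of sample_id and total_reads for the
#'   dropped samples.
#' @export
filter_by_lod <- function(table, lod_reads) {
  stopifnot(inherits(table, "feature_table"), lod_reads >= 1)
  totals <- sample_totals(table)
  drop <- totals < lod_reads
  list(table = table[!drop, , drop = FALSE],
       excluded = data.frame(sample_id = names(totals)[drop],
                             total_reads = unname(totals[drop]),
                             stringsAsFactors = FALSE))
}
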