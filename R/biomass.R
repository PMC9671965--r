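#' Fit the log-log read-to-cell calibration regression
#'
#' Ordinary least squares of log10(known cells) on log10(total reads) over
#' positive controls that passed the limit of detection. The fitted line plays
#' the role of a qPCR standard curve: log10 read count stands in for log10
#' Ct, and the model predicts absolute cell input from sequencing depth.
#' Cells are the response and reads the predictor; the inverse convention is
#' deliberately not offered, to avoid silently mixing the two.
#'
#' @param reads Total read counts of the calibration controls (>= 1).
#' @param cells Known cell counts input to extraction (> 0), same length.
#' @return Object of class \code{calibration_model} with intercept (log10
#'   cells), slope (log10 cells per log10 reads), r_squared, p_value
#'   (two-sided slope t-test, n - 2 df), n, and the training read domain.
#' @export
fit_calibration <- function(reads, cells) {
  ok <- !is.na(reads) & !is.na(cells)
  reads <- as.numeric(reads[ok]); cells <- as.numeric(cells[ok])
  if (length(reads) < 3) stop("need at least 3 calibration points")
  if (any(reads < 1)) stop("calibration reads must be >= 1")
  if (any(cells <= 0)) stop("calibration cell counts must be > 0")
  lx <- log10(reads); ly <- log10(cells)
  if (stats::var(lx) == 0) stop("zero variance in reads: cannot fit calibration")
  fit <- stats::lm(ly ~ lx)
  sm <- suppressWarnings(summary(fit))  # zero-residual fits are legitimate
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(reads),
                 read_domain = range(reads)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(paste0("read-to-cell calibration (n = %d): log10(cells) = %.4g + %.4g * ",
                     "log10(reads)\n  R^2 = %.4f, slope p = %.3g, read domain [%g, %g]\n"),
              x$n, x$intercept, x$slope, x$r_squared, x$p_value,
              x$read_domain[1], x$read_domain[2]))
  invisible(x)
}

#' Predict cell counts in the PCR input from read totals
#'
#' @param model A \code{\link{fit_calibration}} model.
#' @param total_reads Read totals (>= 1); zero reads carry no signal and are
#'   rejected.
#' @return Data.frame with total_reads, est_cells_in_pcr = 10^(a + b *
#'   log10(reads)), and extrapolated (TRUE when reads fall outside the
#'   training domain; predictions are returned unclipped but flagged).
#' @export
predict_cells <- function(model, total_reads) {
  stopifnot(inherits(model, "calibration_model"))
  total_reads <- as.numeric(total_reads)
  if (any(is.na(total_reads)) || any(total_reads < 1)) {
    stop("total_reads must be >= 1 (estimate undefined at zero reads)")
  }
  est <- 10^(model$intercept + model$slope * log10(total_reads))
  data.frame(total_reads = total_reads,
             est_cells_in_pcr = est,
             extrapolated = total_reads < model$read_domain[1] |
                            total_reads > model$read_domain[2])
}

#' Normalize an in-PCR cell estimate to cells per gram of tissue
#'
#' Scales the cell estimate from the PCR input up to the whole DNA eluate
#' (elution_volume / pcr_input_volume; with the assay defaults 60 ul eluted
#' and 5 ul into PCR the factor is 12), then divides by the wet mass of
#' tissue that went into extraction. Under the single-16S-copy-per-genome
#' assumption the result is microbial cells per gram; strictly it is 16S
#' copies per gram, and \code{copies_per_genome} rescales all estimates
#' linearly if a community-wide copy number is known.
#'
#' @param est_cells_in_pcr Estimated cells in the PCR input volume.
#' @param elution_volume DNA extraction elution volume, ul (default 60).
#' @param pcr_input_volume Volume of eluate amplified, ul (default 5).
#' @param tissue_mass Tissue mass into extraction, grams; NA yields a flagged
#'   NA estimate, never a silent zero.
#' @param copies_per_genome Assumed 16S copies per genome (default 1).
#' @return Data.frame with est_cells_total, cells_per_gram,
#'   log10_cells_per_gram and missing_mass flag.
#' @export
cells_per_gram <- function(est_cells_in_pcr, elution_volume = 60,
                           pcr_input_volume = 5, tissue_mass,
                           copies_per_genome = 1) {
  if (any(elution_volume <= 0, na.rm = TRUE) || any(pcr_input_volume <= 0, na.rm = TRUE)) {
    stop("volumes must be positive")
  }
  if (any(!is.na(tissue_mass) & tissue_mass <= 0)) stop("tissue_mass must be positive")
  if (copies_per_genome <= 0) stop("copies_per_genome must be positive")
  total <- est_cells_in_pcr * (elution_volume / pcr_input_volume) / copies_per_genome
  cpg <- total / tissue_mass
  data.frame(est_cells_total = total,
             cells_per_gram = cpg,
             log10_cells_per_gram = log10(cpg),
             missing_mass = is.na(tissue_mass))
}

#' Per-sample biomass report
#'
#' Applies the calibration model to every sample in the table, normalizes by
#' per-sample volumes and tissue mass from the metadata (falling back to the
#' assay defaults of 60 ul elution / 5 ul PCR input when columns are absent),
#' and returns one row per sample in table order.
#'
#' @param table A \code{\link{feature_table}} of retained samples.
#' @param metadata Data.frame with \code{sample_id} and optionally
#'   \code{tissue_mass}, \code{elution_volume}, \code{pcr_input_volume}.
#' @param model A \code{calibration_model}.
#' @param copies_per_genome Assumed 16S copies per genome (default 1).
#' @return Data.frame: sample_id, total_reads, est_cells_in_pcr,
#'   est_cells_total, cells_per_gram, log10_cells_per_gram, extrapolated,
#'   missing_mass.
#' @export
biomass_report <- function(table, metadata, model, copies_per_genome = 1) {
  stopifnot(inherits(table, "feature_table"))
  totals <- sample_totals(table)
  sids <- ft_samples(table)
  if (length(sids) == 0) {
    return(data.frame(sample_id = character(0), total_reads = numeric(0),
                      est_cells_in_pcr = numeric(0), est_cells_total = numeric(0),
                      cells_per_gram = numeric(0), log10_cells_per_gram = numeric(0),
                      extrapolated = logical(0), missing_mass = logical(0)))
  }
  idx <- match(sids, metadata$sample_id)
  getcol <- function(col, default) {
    if (col %in% names(metadata)) {
      v <- metadata[[col]][idx]
      v[is.na(v) & col != "tissue_mass"] <- default
      v
    } else rep(default, length(sids))
  }
  mass <- getcol("tissue_mass", NA_real_)
  elu <- getcol("elution_volume", 60)
  pcr <- getcol("pcr_input_volume", 5)
  pred <- predict_cells(model, pmax(totals, 1))
  norm <- cells_per_gram(pred$est_cells_in_pcr, elu, pcr, mass, copies_per_genome)
  out <- data.frame(sample_id = sids, total_reads = unname(totals),
                    est_cells_in_pcr = pred$est_cells_in_pcr,
                    est_cells_total = norm$est_cells_total,
                    cells_per_gram = norm$cells_per_gram,
                    log10_cells_per_gram = norm$log10_cells_per_gram,
                    extrapolated = pred$extrapolated,
                    missing_mass = norm$missing_mass,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
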