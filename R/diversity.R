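# run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards; every stochastic routine in the package routes
# through this so no call touches global RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Rarefy a feature table to even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to exactly \code{depth}; samples with fewer total reads
#' than the depth are dropped. Deterministic for a fixed seed.
#'
#' @param table A \code{\link{feature_table}}.
#' @param depth Target depth (>= 1); 5000 reads is the conventional depth for
#'   cross-study gamma-diversity comparisons.
#' @param seed Integer seed (mandatory; no global RNG state is consumed).
#' @return A \code{feature_table} whose row sums all equal \code{depth}.
#' @export
rarefy_counts <- function(table, depth, seed) {
  stopifnot(inherits(table, "feature_table"), depth >= 1)
  totals <- sample_totals(table)
  keep <- totals >= depth
  sub <- unclass(table)[keep, , drop = FALSE]
  with_seed(seed, {
    for (i in seq_len(nrow(sub))) {
      cc <- sub[i, ]
      tot <- sum(cc)
      if (tot == depth) next
      pos <- sample.int(tot, depth)
      cum <- cumsum(cc)
      feat <- findInterval(pos - 1L, cum) + 1L
      sub[i, ] <- tabulate(feat, nbins = length(cc))
    }
  })
  feature_table(sub)
}

#' Chao1 richness estimate
#'
#' Bias-corrected by default: \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))},
#' where F1 and F2 are the singleton and doubleton counts, which degrades
#' gracefully when no doubletons are present. \code{bias_corrected = FALSE}
#' gives the classic \eqn{S_{obs} + F_1^2 / (2 F_2)} form (infinite when F2 is
#' zero and F1 is not).
#'
#' @param counts Non-negative integer vector of per-feature counts for one
#'   sample.
#' @param bias_corrected Use the (F2 + 1) denominator (default TRUE).
#' @return Estimated richness; 0 for an empty (all-zero or length-zero)
#'   vector.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (length(counts) == 0) return(0)
  if (any(counts < 0)) stop("negative counts")
  counts <- counts[counts > 0]
  if (length(counts) == 0) return(0)
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 == 0) {
      if (f1 == 0) s_obs else Inf
    } else s_obs + f1^2 / (2 * f2)
  }
}

#' Shannon diversity
#'
#' \eqn{-\sum p_i \log p_i} over nonzero relative abundances, natural log by
#' default.
#'
#' @param counts Non-negative vector with positive total.
#' @param base Logarithm base (default e).
#' @return Shannon entropy.
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("negative counts")
  tot <- sum(counts)
  if (tot <= 0) stop("Shannon undefined for an all-zero sample")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the subtree spanning the root and the present
#' features (union of root-to-tip paths). Present features that are not tips
#' of the tree are ignored with a warning.
#'
#' @param present Character vector of present feature identifiers.
#' @param tree Rooted \code{ape::phylo} tree with branch lengths whose tips
#'   are feature identifiers.
#' @return Total branch length (same units as the tree).
#' @export
faith_pd <- function(present, tree) {
  stopifnot(inherits(tree, "phylo"))
  present <- unique(present)
  absent <- setdiff(present, tree$tip.label)
  if (length(absent) > 0) {
    warning(length(absent), " present features not in tree, ignored")
    present <- setdiff(present, absent)
  }
  if (length(present) == 0) stop("no present feature is a tip of the tree")
  comm <- matrix(as.integer(tree$tip.label %in% present), nrow = 1,
                 dimnames = list("s", tree$tip.label))
  picante::pd(comm, tree, include.root = TRUE)$PD
}

#' Partition gamma diversity into shared and group-exclusive features
#'
#' For feature sets pooled by group (e.g. all ASVs observed in each
#' vertebrate class), reports per group the total feature count, the number
#' exclusive to that group (absent from every other group's union), and the
#' exclusive percentage (exclusive / total * 100, reported to one decimal).
#'
#' @param sets Named list of character vectors, one per group.
#' @return Data.frame: group, total, exclusive, pct_exclusive (NA with a
#'   flag for empty groups).
#' @export
gamma_partition <- function(sets) {
  if (length(sets) < 1 || is.null(names(sets))) stop("sets must be a non-empty named list")
  sets <- lapply(sets, unique)
  out <- data.frame(group = names(sets),
                    total = vapply(sets, length, integer(1)),
                    exclusive = NA_integer_, pct_exclusive = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(sets)) {
    others <- unique(unlist(sets[-i], use.names = FALSE))
    excl <- sum(!(sets[[i]] %in% others))
    out$exclusive[i] <- excl
    out$pct_exclusive[i] <- if (out$total[i] > 0) {
      round(100 * excl / out$total[i], 1)
    } else NA_real_
  }
  rownames(out) <- NULL
  out
}

#' Cumulative feature accumulation curve
#'
#' k-th value is the size of the union of the first k units' feature sets.
#' With \code{order = "as_given"} the provided unit order is used (e.g. host
#' species arranged by class, then order and family); with
#' \code{order = "random"} the curve is averaged over seeded random
#' permutations with a 2.5/97.5 percentile band, since extrapolation from a
#' single ordering is fragile.
#'
#' @param sets Named list of character vectors, one per unit, in curve order.
#' @param order "as_given" or "random".
#' @param n_perm Number of permutations when \code{order = "random"}.
#' @param seed Seed for the permutations.
#' @return Data.frame of class \code{accumulation_curve}: k, unit (as_given
#'   only), cumulative (or mean/lo/hi across permutations).
#' @export
accumulation_curve <- function(sets, order = c("as_given", "random"),
                               n_perm = 999, seed = NULL) {
  order <- match.arg(order)
  if (length(sets) < 1) stop("need at least one unit")
  sets <- lapply(sets, unique)
  cum_curve <- function(idx) {
    seen <- character(0)
    vapply(idx, function(i) {
      seen <<- unique(c(seen, sets[[i]]))
      length(seen)
    }, numeric(1))
  }
  k <- seq_along(sets)
  if (order == "as_given") {
    out <- data.frame(k = k, unit = names(sets), cumulative = cum_curve(k),
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(seed)) stop("seed required for order = 'random'")
    curves <- with_seed(seed, {
      vapply(seq_len(n_perm), function(p) cum_curve(sample(k)), numeric(length(k)))
    })
    curves <- matrix(curves, nrow = length(k))
    out <- data.frame(k = k,
                      mean = rowMeans(curves),
                      lo = apply(curves, 1, stats::quantile, 0.025),
                      hi = apply(curves, 1, stats::quantile, 0.975))
  }
  attr(out, "ordering") <- order
  class(out) <- c("accumulation_curve", class(out))
  out
}

#' Michaelis-Menten saturation fit of an accumulation curve
#'
#' Nonlinear least squares of \eqn{G(s) = V_{max} s / (K_m + s)} to
#' (units, cumulative richness) points. Vmax estimates the asymptotic total
#' unique-feature richness as sampling effort grows; Km is the number of
#' units at which half of it has been observed. Initialization is
#' deterministic (Vmax0 = 2 * max G, Km0 = median s). The fit is not
#' constrained to dominate the observed maximum; an undershooting asymptote
#' is flagged rather than hidden.
#'
#' @param s Numeric vector of sampling-unit counts (e.g. number of host
#'   species), or an \code{accumulation_curve} (then \code{g} is taken from
#'   it).
#' @param g Cumulative richness at each s.
#' @return Object of class \code{saturation_fit}: Vmax, Km, r_squared
#'   (1 - RSS/TSS against the mean model), n, undershoot flag.
#' @export
fit_saturation <- function(s, g = NULL) {
  if (inherits(s, "accumulation_curve")) {
    g <- if ("cumulative" %in% names(s)) s$cumulative else s$mean
    s <- s$k
  }
  s <- as.numeric(s); g <- as.numeric(g)
  if (length(s) != length(g) || length(s) < 3) stop("need >= 3 (s, g) points")
  if (any(s <= 0)) stop("sampling-unit counts must be positive")
  start <- list(Vmax = 2 * max(g), Km = stats::median(s))
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ Vmax * s / (Km + s), data = list(g = g, s = s),
                      start = start, lower = c(Vmax = 1e-12, Km = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("saturation fit failed to converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((g - mean(g))^2)
  structure(list(Vmax = unname(cf["Vmax"]), Km = unname(cf["Km"]),
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 n = length(s), undershoot = unname(cf["Vmax"]) < max(g)),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten saturation fit (n = %d): Vmax = %.6g, Km = %.6g, R^2 = %.4f%s\n",
              x$n, x$Vmax, x$Km, x$r_squared,
              if (isTRUE(x$undershoot)) " [asymptote below observed maximum]" else ""))
  invisible(x)
}

#' Feature sets observed per grouping unit
#'
#' Convenience bridge from a feature table to the set-based gamma operations:
#' pools samples by a metadata column and returns, per group, the identifiers
#' of features with at least one read.
#'
#' @param table A \code{\link{feature_table}}.
#' @param metadata Data.frame with \code{sample_id} and the grouping column.
#' @param group_by Name of the grouping column.
#' @return Named list of character vectors.
#' @export
feature_sets_by_group <- function(table, metadata, group_by) {
  stopifnot(inherits(table, "feature_table"))
  if (!group_by %in% names(metadata)) stop("metadata lacks column '", group_by, "'")
  groups <- metadata[[group_by]][match(ft_samples(table), metadata$sample_id)]
  keep <- !is.na(groups)
  m <- unclass(table)
  lapply(split(seq_len(nrow(m))[keep], groups[keep]), function(idx) {
    colnames(m)[colSums(m[idx, , drop = FALSE]) > 0]
  })
}
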