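#' Configuration for the synthetic generators
#'
#' Bundles every knob of the seeded generators with defaults emulating the
#' control design of a KatharoSeq-style plate: an 8-step, 10-fold serial
#' dilution of positive controls run in 4 replicates (32 positives), a
#' Poisson contamination floor, and a log-log read-to-cell relationship with
#' the slope magnitude observed in marine-fish mucosal calibrations.
#'
#' @param seed Integer seed; every generator is a pure function of its
#'   config, seed included.
#' @param start_cells Cells in the most concentrated control (default 1e7).
#' @param fold Dilution factor between steps (default 10).
#' @param n_steps Number of dilution steps (default 8).
#' @param replicates Replicates per step (default 4).
#' @param floor_reads Mean contaminant reads per control (Poisson; default
#'   115, which places the on-target fraction at 0.9 near 1150 total reads).
#' @param a,b True calibration intercept/slope: log10(cells) = a + b *
#'   log10(reads). Defaults a = -9.5, b = 3.497 put the 0.9-fraction
#'   limit of detection near 16 cells.
#' @param sigma Dispersion of the realized cell input around its nominal
#'   value, on the log10-cell scale (pipetting/plating error; default 0.2).
#'   On the log10-read axis this is sigma / b.
#' @param n_contaminants Number of contaminant features carrying the floor.
#' @param n_species,n_body_sites Community generator dimensions.
#' @param features_per_site Size of the per-site evolving feature pool.
#' @param core_fraction Fraction of the pool present in every species at a
#'   site (site-specific core).
#' @param lambda Phylosymbiosis mixing weight in [0, 1]: probability that a
#'   species' state for a feature is inherited from the phylogenetic
#'   gain/loss process rather than drawn independently.
#' @param gain_loss_rate Per-unit-branch-length flip rate of the symmetric
#'   presence/absence process (default 0.5 on a unit-height tree).
#' @param root_prob Presence probability at the root and for independent
#'   draws (default 0.5).
#' @param n_tips,birth Host-tree generator: number of tips and pure-birth
#'   speciation rate.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 7,
                       start_cells = 1e7, fold = 10, n_steps = 8, replicates = 4,
                       floor_reads = 115, a = -9.5, b = 3.497, sigma = 0.2,
                       n_contaminants = 5,
                       n_species = 24, n_body_sites = 1, features_per_site = 300,
                       core_fraction = 0.1, lambda = 0.6,
                       gain_loss_rate = 0.5, root_prob = 0.5,
                       n_tips = 24, birth = 1) {
  cfg <- list(seed = seed, start_cells = start_cells, fold = fold,
              n_steps = n_steps, replicates = replicates,
              floor_reads = floor_reads, a = a, b = b, sigma = sigma,
              n_contaminants = n_contaminants, n_species = n_species,
              n_body_sites = n_body_sites, features_per_site = features_per_site,
              core_fraction = core_fraction, lambda = lambda,
              gain_loss_rate = gain_loss_rate, root_prob = root_prob,
              n_tips = n_tips, birth = birth)
  stopifnot(cfg$n_steps >= 1, cfg$replicates >= 1, cfg$fold > 1,
            cfg$lambda >= 0, cfg$lambda <= 1, cfg$sigma >= 0,
            cfg$floor_reads >= 0, cfg$b != 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a positive-control dilution series
#'
#' Emulates the dilution-to-extinction design used to calibrate absolute
#' abundance: \code{n_steps} serial dilutions of a two-organism mock
#' community, \code{replicates} each. The realized cell input of each control
#' wobbles around its nominal value by Normal(0, sigma) on the log10-cell
#' scale; target reads follow the inverse calibration
#' \code{round(10^((log10 cells - a)/b + eps))} with eps = Normal(0,
#' sigma / b) on the read axis. Contaminant reads are drawn from a fixed
#' Poisson floor, so the on-target fraction rises sigmoidally with total
#' reads. With sigma = 0 and floor_reads = 0 the series is exact: all
#' fractions are 1 and the calibration is recovered to optimizer precision
#' whenever nominal reads are integral.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{table} (a \code{\link{feature_table}}, controls x
#'   features), \code{metadata} (sample_id, role, known_cells,
#'   expected_taxa), \code{taxonomy}, and \code{truth} (a, b, sigma,
#'   floor_reads, and lod_reads_true, the total read count at on-target
#'   fraction 0.9 implied by the floor).
#' @export
simulate_dilution_series <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_steps * config$replicates
  cells_nominal <- rep(config$start_cells / config$fold^(seq_len(config$n_steps) - 1),
                       each = config$replicates)
  sample_ids <- sprintf("ctrl_d%02d_r%d",
                        rep(seq_len(config$n_steps), each = config$replicates),
                        rep(seq_len(config$replicates), times = config$n_steps))
  target_features <- c("asv_bacillus", "asv_paracoccus")
  contam_features <- sprintf("asv_contam%02d", seq_len(config$n_contaminants))
  taxonomy <- c(
    stats::setNames(c("k__Bacteria; p__Firmicutes; g__Bacillus; s__subtilis",
                      "k__Bacteria; p__Proteobacteria; g__Paracoccus; s__sp"),
                    target_features),
    stats::setNames(sprintf("k__Bacteria; p__Unknown; g__Contaminant%02d",
                            seq_len(config$n_contaminants)),
                    contam_features))
  with_seed(config$seed, {
    eps <- if (config$sigma > 0) {
      stats::rnorm(n, 0, config$sigma / abs(config$b))
    } else numeric(n)
    target_reads <- round(10^((log10(cells_nominal) - config$a) / config$b + eps))
    contam_reads <- if (config$floor_reads > 0) {
      stats::rpois(n, config$floor_reads)
    } else integer(n)
    counts <- matrix(0, n, length(target_features) + length(contam_features),
                     dimnames = list(sample_ids, c(target_features, contam_features)))
    for (i in seq_len(n)) {
      # split target reads between the two mock organisms, contaminant reads
      # uniformly across the floor features
      t1 <- if (target_reads[i] > 0) stats::rbinom(1, target_reads[i], 0.5) else 0
      counts[i, 1:2] <- c(t1, target_reads[i] - t1)
      if (contam_reads[i] > 0) {
        spl <- stats::rmultinom(1, contam_reads[i],
                                rep(1, config$n_contaminants))[, 1]
        counts[i, contam_features] <- spl
      }
    }
  })
  metadata <- data.frame(sample_id = sample_ids, role = "positive_control",
                         known_cells = cells_nominal,
                         expected_taxa = "g__Bacillus; g__Paracoccus",
                         stringsAsFactors = FALSE)
  truth <- list(a = config$a, b = config$b, sigma = config$sigma,
                floor_reads = config$floor_reads,
                lod_reads_true = if (config$floor_reads > 0) {
                  10 * config$floor_reads  # solves 1 - floor/r = 0.9
                } else 1,
                seed = config$seed)
  list(table = feature_table(counts), metadata = metadata,
       taxonomy = taxonomy, truth = truth)
}

#' Simulate an ultrametric host tree
#'
#' Pure-birth tree rescaled to unit height, with species-like tip labels.
#'
#' @param config A \code{\link{sim_config}} (uses n_tips, birth, seed).
#' @return An ultrametric \code{ape::phylo} with tips sp01, sp02, ...
#' @export
simulate_host_tree <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"), config$n_tips >= 3)
  tree <- with_seed(config$seed, ape::rphylo(config$n_tips, config$birth, 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%02d", seq_len(config$n_tips))
  tree
}

# evolve presence/absence of n_feat binary traits along a tree: root states
# Bernoulli(root_prob), each edge of length t flips a state with probability
# (1 - exp(-2 * rate * t)) / 2 (symmetric two-state Markov chain). Consumes
# the current RNG stream. Returns tips x features 0/1 matrix.
evolve_presence <- function(tree, n_feat, rate, root_prob) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  states <- matrix(NA_integer_, n_node, n_feat)
  root <- n_tip + 1
  states[root, ] <- stats::rbinom(n_feat, 1, root_prob)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    p_flip <- (1 - exp(-2 * rate * ord$edge.length[e])) / 2
    flips <- stats::rbinom(n_feat, 1, p_flip)
    states[child, ] <- ifelse(flips == 1, 1L - states[parent, ], states[parent, ])
  }
  out <- states[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate per-species, per-body-site communities with planted phylosymbiosis
#'
#' Each body site has its own feature pool whose presence/absence evolves
#' along the host tree as a symmetric gain/loss process (so closely related
#' species share more features), a site-specific core present in every
#' species, and independent noise: for each species-by-feature cell the
#' phylogenetically inherited state is used with probability \code{lambda}
#' and an independent Bernoulli draw otherwise. With lambda = 1 and no core
#' the microbiota distances are a monotone function of tree distance; with
#' lambda = 0 there is no phylogenetic signal. Present features receive
#' log-normal read counts so both presence/absence and abundance-weighted
#' distances respond to lambda.
#'
#' @param config A \code{\link{sim_config}}.
#' @param tree Host tree whose tips are the species (default: simulated from
#'   the same config).
#' @return List with one element per body site, each containing \code{table}
#'   (species x features \code{feature_table}), \code{sets} (per-species
#'   present-feature lists), plus \code{tree} and \code{truth} (lambda,
#'   rate).
#' @export
simulate_fish_tables <- function(config = sim_config(),
                                 tree = simulate_host_tree(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(tree, "phylo"))
  species <- tree$tip.label
  n_sp <- length(species)
  n_feat <- config$features_per_site
  n_core <- round(config$core_fraction * n_feat)
  sites <- with_seed(config$seed + 1L, {
    lapply(seq_len(config$n_body_sites), function(s) {
      pool <- sprintf("site%d_asv%04d", s, seq_len(n_feat + n_core))
      evolving <- pool[seq_len(n_feat)]
      core <- pool[seq_len(n_core) + n_feat]
      phylo_state <- evolve_presence(tree, n_feat, config$gain_loss_rate,
                                     config$root_prob)
      use_phylo <- matrix(stats::rbinom(n_sp * n_feat, 1, config$lambda),
                          n_sp, n_feat)
      noise <- matrix(stats::rbinom(n_sp * n_feat, 1, config$root_prob),
                      n_sp, n_feat)
      presence <- ifelse(use_phylo == 1, phylo_state, noise)
      presence <- cbind(presence,
                        matrix(1L, n_sp, n_core))  # site core: everywhere
      dimnames(presence) <- list(species, pool)
      counts <- presence
      npres <- sum(presence > 0)
      counts[presence > 0] <- pmax(1, round(stats::rlnorm(npres, meanlog = 3,
                                                          sdlog = 1)))
      list(table = feature_table(counts),
           sets = apply(presence > 0, 1, function(r) pool[r], simplify = FALSE))
    })
  })
  names(sites) <- sprintf("site%d", seq_len(config$n_body_sites))
  list(sites = sites, tree = tree,
       truth = list(lambda = config$lambda, rate = config$gain_loss_rate,
                    seed = config$seed))
}

#' Jaccard distance matrix from presence sets
#'
#' \eqn{d(A, B) = 1 - |A \cap B| / |A \cup B|}; the presence/absence
#' dissimilarity used to score planted phylosymbiosis against tree distance.
#'
#' @param sets Named list of character vectors (features present per unit).
#' @return Labeled symmetric distance matrix.
#' @export
jaccard_matrix <- function(sets) {
  n <- length(sets)
  if (n < 2 || is.null(names(sets))) stop("need >= 2 named sets")
  m <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    uni <- length(union(sets[[i]], sets[[j]]))
    d <- if (uni == 0) 0 else 1 - inter / uni
    m[i, j] <- m[j, i] <- d
  }
  m
}
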