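# small in-code fixtures shared across the suite

toy_table <- function() {
  feature_table(matrix(c(1, 2, 0,
                         3, 4, 5), nrow = 2, byrow = TRUE,
                       dimnames = list(c("s1", "s2"), c("f1", "f2", "f3"))))
}

toy_taxonomy <- function() {
  c(f1 = "k__Bacteria; p__Firmicutes; g__Bacillus",
    f2 = "k__Bacteria; p__Cyanobacteria; c__Chloroplast",
    f3 = "k__Bacteria; p__Proteobacteria; g__Vibrio")
}

# exact Hill-curve control series (K = 500, h = 2, p_max = 1)
exact_hill_series <- function() {
  x <- c(50, 100, 200, 500, 1000, 2000, 5000, 10000)
  data.frame(total_reads = x, on_target_fraction = x^2 / (500^2 + x^2))
}

labeled_dist <- function(x, prefix = "s") {
  m <- as.matrix(dist(x))
  dimnames(m) <- list(paste0(prefix, seq_len(nrow(m))),
                      paste0(prefix, seq_len(nrow(m))))
  m
}

# dilution-series config whose nominal reads are exact powers of 10, so the
# zero-noise calibration is recoverable to optimizer precision
exact_dilution_config <- function(seed = 1) {
  sim_config(seed = seed, a = 0, b = 2, start_cells = 1e14, fold = 100,
             n_steps = 8, replicates = 2, sigma = 0, floor_reads = 0)
}
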