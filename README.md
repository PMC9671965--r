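# microload

Absolute microbial biomass from 16S amplicon read counts, plus the
quantitative diversity toolkit that surrounds such estimates in
host-associated microbiome surveys (fish gill/skin/gut mucosa being the
motivating system).

Amplicon sequencing is compositional: read counts say nothing about total
microbial load unless the experiment is calibrated. `microload` implements
the KatharoSeq-style calibration workflow for plates that carry serial
dilutions of positive extraction controls with known cell inputs:

1. **Limit of detection.** For each positive control, the fraction of reads
   assigned to its known input organisms is modeled against total reads with
   an allosteric-sigmoid (Hill) curve, p(r) = p_max · r^h / (K^h + r^h).
   The read-count limit of detection at threshold t (conventionally 0.9) is
   the closed-form inversion r\* = K · (t / (p_max − t))^(1/h); samples below
   it are excluded. The same fit on the known-cell axis gives the
   cell-count detection limit.
2. **Calibration.** Controls passing the LoD fit an OLS regression of
   log10(cells) on log10(reads) — the analogue of a qPCR standard curve.
3. **Biomass.** Sample read totals are converted to cells in the PCR input,
   scaled by elution/PCR volumes (default 60 µl / 5 µl, factor 12) and
   divided by tissue mass to give microbial cells per gram (strictly, 16S
   copies per gram under a one-copy-per-genome assumption).

Around the core: seeded rarefaction, Chao1 / Shannon / Faith's PD,
gamma-diversity partitioning into shared and group-exclusive features,
accumulation curves with Michaelis–Menten saturation extrapolation
(G(s) = Vmax·s/(Km+s)), Mantel tests of phylosymbiosis against host
divergence time, distance-matrix PERMANOVA, Kruskal–Wallis/Spearman with
BH-FDR, and log2 sea-water:sediment source-ratio summaries. A seeded
synthetic-data generator produces dilution series, ultrametric host trees
and per-species feature tables with planted ground truth, so every stage is
testable without external downloads.

## Worked example

Simulate a calibration plate (8-step, 10-fold dilution of a two-organism
mock community, 4 replicates, Poisson contamination floor), derive the LoD,
fit the calibration, and estimate biomass:

```r
library(microload)

cfg <- sim_config(seed = 7)
sim <- simulate_dilution_series(cfg)
series <- control_target_fraction(sim$table, sim$taxonomy, sim$metadata)

fit <- fit_allosteric_sigmoid(series)
fit
#> Hill sigmoid fit on total_reads (n = 32): K = 205, h = 1.259, p_max = 0.9965, RSS = 0.0004709

lod <- solve_lod(fit, threshold = 0.9)
lod
#> [1] 1208

kept <- filter_by_lod(sim$table, lod)
nrow(kept$excluded)       # low-input controls below the detection limit
#> [1] 6

passing <- series[series$total_reads >= lod, ]
model <- fit_calibration(passing$total_reads, passing$known_cells)
model
#> read-to-cell calibration (n = 26): log10(cells) = -9.988 + 3.586 * log10(reads)
#>   R^2 = 0.9853, slope p = 1.63e-23, read domain [1233, 70771]

meta <- sim$metadata
meta$tissue_mass <- 0.2   # grams of tissue into each extraction
report <- biomass_report(kept$table, meta, model)
head(report[, c("sample_id", "total_reads", "est_cells_in_pcr", "cells_per_gram")], 3)
#>     sample_id total_reads est_cells_in_pcr cells_per_gram
#> 1 ctrl_d01_r1       70771         25432823     1525969395
#> 2 ctrl_d01_r2       44770          4922420      295345214
#> 3 ctrl_d01_r3       47821          6235369      374122148
```

The generator planted slope b = 3.497 with a 115-read contamination floor
(true 0.9-threshold LoD 1150 reads); the pipeline recovers an LoD of 1208
reads and a slope of 3.586 from this noisy plate. `cells_per_gram` is
est_cells_in_pcr × 12 / 0.2 for each sample.

A command-line front end covering the same operations (lod, biomass,
rarefy, alpha, gamma, accumulate, mmfit, mantel, permanova, ratio,
simulate) is installed under the package's `exec/` directory; run it with
`Rscript $(Rscript -e 'cat(system.file("exec","microload",package="microload"))') --help`.
Every run writes a JSON manifest sidecar with parameters, input digests and
seeds.

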