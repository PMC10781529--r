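#!/usr/bin/env Rscript
# Validates the pipeline end to end on synthetic band matrices with known
# structure: cluster recovery under scoring noise and detection of planted
# genotype-specific bands. Writes results/synthetic/.

suppressPackageStartupMessages(library(bandiv))
dir.create("results/synthetic", recursive = TRUE, showWarnings = FALSE)

recovery_rate <- function(delta, n_rep = 200, n_bands = 40, seed0 = 3000) {
  hits <- 0
  for (r in seq_len(n_rep)) {
    spec <- synth_spec(10, c(A = n_bands), freq = c(0.2, 0.8),
                       clusters = list(blocks = list(1:5, 6:10),
                                       delta = delta),
                       seed = seed0 + r)
    got <- lapply(cut_clusters(upgma(jaccard_similarity(
      generate_bands(spec))), 2), sort)
    got <- got[order(vapply(got, min, character(1)))]
    if (identical(got, planted_truth(spec)$partition)) hits <- hits + 1
  }
  hits / n_rep
}

deltas <- c(0, 0.05, 0.1, 0.2, 0.3)
rates <- vapply(deltas, recovery_rate, numeric(1))
tab <- data.frame(delta = deltas, recovery = rates)
print(tab, row.names = FALSE)
write.csv(tab, "results/synthetic/cluster_recovery.csv", row.names = FALSE)
cat(sprintf("\nk=2 recovery at delta = 0.05: %.1f%% of 200 replicates\n",
            100 * rates[deltas == 0.05]))

found_all <- TRUE
for (seed in 1:50) {
  spec <- synth_spec(10, c(A = 30), freq = c(0.3, 0.7),
                     n_unique_pos = 2, n_unique_neg = 2, seed = seed)
  truth <- planted_truth(spec)
  found <- genotype_specific_markers(generate_bands(spec))
  ok <- all(paste(truth$markers$genotype, truth$markers$polarity) %in%
              paste(found$genotype, found$polarity))
  found_all <- found_all && ok
}
cat(sprintf("planted unique markers recovered in all 50 noiseless runs: %s\n",
            found_all))
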