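#!/usr/bin/env Rscript
# Protein (SDS-PAGE) profile of the ten bottle gourd cultivars: per-band
# statistics, negative biochemical markers, Jaccard similarity and UPGMA
# tree. Writes results/protein/.

suppressPackageStartupMessages(library(bandiv))

prot <- bg_protein()
res <- run_analysis(list(protein = prot), "results/protein")

ls <- res$protein$locus_stats
cat(sprintf("protein bands: %d (%d monomorphic, %d polymorphic; %.2f%%)\n",
            n_loci(prot), sum(ls$klass == "monomorphic"),
            sum(ls$klass != "monomorphic"), polymorphism_percent(prot)))
cat("per-cultivar band counts:\n")
print(colSums(prot$presence))

mk <- res$protein$markers
cat("\nnegative biochemical markers (band absent in exactly one cultivar):\n")
print(mk[, c("genotype", "polarity", "size")], row.names = FALSE)

rep <- res$protein$extremes
cat(sprintf("\nJaccard similarity range: %.3f (%s-%s) to %.3f\n",
            rep$min, rep$min_pairs$g1[1], rep$min_pairs$g2[1], rep$max))
cat("UPGMA tree:", to_newick(res$protein$tree), "\n")
cat("k=2 cut:\n"); print(res$protein$cuts[[1]])
cat("\ntables written under results/protein/\n")
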