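#!/usr/bin/env Rscript
# Stage 1: generate the study-like synthetic dataset.
#
# One structured species (three populations: a Southeast-Asian-like source,
# an Arabian/South-Asian-like daughter and an Australian-like daughter
# founded through a Late Pleistocene bottleneck), one star-like recently
# expanded species, and a deep outgroup; 456 bp, mid-Aegean COI mutation
# rate. The truth record (every generating parameter) is written next to
# the FASTA so later stages can be checked against it.

library(barcodemog)

seed <- 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

dataset <- generate_study_like(seed = seed)
write_study_like(dataset, "results/data/study_like")

aln <- dataset$alignment
cat(sprintf("dataset: %d sequences x %d sites\n",
            n_sequences(aln), n_sites(aln)))
print(table(aln$meta$species, aln$meta$population))
cat("\ntruth: Pop3 colonised", dataset$truth$scenario$t2, "generations ago;",
    "star expansion", dataset$truth$star_expansion$t_change,
    "generations ago\n")
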