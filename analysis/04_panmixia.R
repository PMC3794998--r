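#!/usr/bin/env Rscript
# Stage 4: pairwise panmixia screens (Hudson-Boos-Kaplan K_ST permutation
# tests) for each marker independently, and the panmictic groupings they
# imply (connected components of the non-rejected pairs).

suppressMessages(library(sealmix))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
alpha_mt <- study_mtdna_alpha()

show <- function(scr, marker) {
  cat(sprintf("%s: %d pairs tested, %d panmictic groups:\n", marker,
              nrow(scr$table), length(scr$groups)))
  for (grp in scr$groups) cat("  {", paste(grp, collapse = ", "), "}\n")
  if (length(scr$skipped)) {
    cat("  skipped (n < 2):", paste(scr$skipped, collapse = ", "), "\n")
  }
}

ds <- read_genepop("results/data/genotypes.gen")
dm <- pairwise_genotype_distances(ds, "genotype_smouse_peakall")
scr <- panmixia_screen(dm, ds$sites, n_perm = 5000,
                       seed = sub_seed(seed, "scr", "usat"))
show(scr, "microsatellites")
write_panmixia_csv(scr, "results/panmixia_microsat.csv")

for (region in c("coi", "cr")) {
  aln <- read_fasta_alignment(sprintf("results/data/%s.fasta", region))
  dm <- pairwise_sequence_distances(aln, alpha_mt[[region]])
  scr <- panmixia_screen(dm, aln$sites, n_perm = 5000,
                         seed = sub_seed(seed, "scr", region))
  show(scr, toupper(region))
  write_panmixia_csv(scr, sprintf("results/panmixia_%s.csv", region))
}
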