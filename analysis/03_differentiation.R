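#!/usr/bin/env Rscript
# Stage 3: between-site structure.
#
# Pairwise Weir-Cockerham F_ST with permutation significance, one-level
# AMOVA for all three markers (microsatellites on allele-count-difference
# distances; COI and CR on TN93+gamma distances), repeated without the
# isolate, and average pairwise differences.

suppressMessages(library(sealmix))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
ds <- read_genepop("results/data/genotypes.gen")
alpha_mt <- study_mtdna_alpha()

sites <- unique(ds$sites)
prs <- combn(sites, 2)
fst <- do.call(rbind, lapply(seq_len(ncol(prs)), function(ci) {
  pr <- prs[, ci]
  t <- fst_permutation_test(ds, pr, n_perm = 499,
                            seed = sub_seed(seed, "fst", pr[1], pr[2]))
  data.frame(site_a = pr[1], site_b = pr[2], theta = t$statistic, p = t$p)
}))
write.csv(fst, "results/pairwise_fst.csv", row.names = FALSE)
cat(sprintf("pairwise F_ST: %d pairs, %.0f%% significantly > 0 at 0.05\n",
            nrow(fst), 100 * mean(fst$p <= 0.05)))
sai <- fst[fst$site_a == "Saimaa" | fst$site_b == "Saimaa", ]
cat(sprintf("  isolate pairs: theta %.3f-%.3f (pronounced differentiation)\n",
            min(sai$theta), max(sai$theta)))

dm_usat <- pairwise_genotype_distances(ds, "allele_count_diff")
apd <- avg_pairwise_differences(dm_usat, ds$sites)
write.csv(round(apd$between, 3), "results/avg_pairwise_between.csv")
write.csv(data.frame(site = names(apd$within), within = apd$within),
          "results/avg_pairwise_within.csv", row.names = FALSE)

amova_rows <- list()
run_amova <- function(dm, labels, marker, scope) {
  am <- amova(dm, labels, n_perm = 16000,
              seed = sub_seed(seed, "amova", marker, scope))
  cat(sprintf("AMOVA %-13s %-12s among %6.2f%%  within %6.2f%%  p = %.4g\n",
              marker, scope, am$table$percent[1], am$table$percent[2], am$p))
  cbind(marker = marker, scope = scope, am$table,
        phi_st = am$phi_st, p = am$p)
}
amova_rows$usat <- run_amova(dm_usat, ds$sites, "microsatellite", "all_sites")
keep <- ds$sites != "Saimaa"
amova_rows$usat2 <- run_amova(
  dist_matrix(dm_usat$values[keep, keep], dm_usat$ids[keep], dm_usat$metric),
  ds$sites[keep], "microsatellite", "excl_isolate")

for (region in c("coi", "cr")) {
  aln <- read_fasta_alignment(sprintf("results/data/%s.fasta", region))
  dm <- pairwise_sequence_distances(aln, alpha_mt[[region]])
  amova_rows[[paste0(region, "1")]] <-
    suppressWarnings(run_amova(dm, aln$sites, region, "all_sites"))
  keep <- aln$sites != "Saimaa"
  amova_rows[[paste0(region, "2")]] <- suppressWarnings(run_amova(
    dist_matrix(dm$values[keep, keep], dm$ids[keep], dm$metric),
    aln$sites[keep], region, "excl_isolate"))
}
write.csv(do.call(rbind, amova_rows), "results/amova.csv", row.names = FALSE)
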