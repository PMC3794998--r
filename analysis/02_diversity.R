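#!/usr/bin/env Rscript
# Stage 2: within-site diversity from the GenePop file written by stage 1.
#
# Duplicate-genotype screen, per site x locus heterozygosity with
# Monte-Carlo Hardy-Weinberg tests, pairwise linkage tests, Bonferroni
# thresholds, and rarefied allelic richness curves.

suppressMessages(library(sealmix))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
ds <- read_genepop("results/data/genotypes.gen")

flags <- find_duplicate_genotypes(ds)
cat("one-mismatch duplicate screen:", nrow(flags), "flagged pairs\n")
write.csv(flags, "results/duplicates.csv", row.names = FALSE)

het <- heterozygosity(ds)
hwe <- do.call(rbind, lapply(which(het$polymorphic & het$n >= 3), function(r) {
  t <- hwe_test(ds, het$site[r], het$locus[r], n_perm = 499,
                seed = sub_seed(seed, "hwe"))
  data.frame(site = het$site[r], locus = het$locus[r], p = t$p,
             p_homozygote_excess = t$p_homozygote_excess)
}))
het <- merge(het, hwe, all.x = TRUE, sort = FALSE)
adj_hwe <- bonferroni_alpha(0.05, nrow(hwe), 1)
cat(sprintf("HWE: %d tests, Bonferroni-adjusted alpha = %g; %d below it\n",
            nrow(hwe), adj_hwe,
            sum(hwe$p <= attr(adj_hwe, "unrounded"), na.rm = TRUE)))
cat(sprintf("homozygote excess (p <= %g, one-sided): %.1f%% of tests\n",
            attr(adj_hwe, "unrounded"),
            100 * mean(hwe$p_homozygote_excess <=
                         attr(adj_hwe, "unrounded"), na.rm = TRUE)))
write.csv(het, "results/diversity_site_locus.csv", row.names = FALSE)
write.csv(heterozygosity_site_means(het), "results/diversity_site_means.csv",
          row.names = FALSE)

pairs <- combn(ds$loci, 2)
ld <- do.call(rbind, lapply(unique(ds$sites), function(s) {
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(ci) {
    t <- ld_test(ds, s, pairs[, ci], n_perm = 199, seed = sub_seed(seed, "ld"))
    data.frame(site = s, locus_a = pairs[1, ci], locus_b = pairs[2, ci],
               G = t$statistic, p = t$p)
  }))
}))
adj_ld <- bonferroni_alpha(0.05, sum(!is.na(ld$p)), 1)
cat(sprintf("linkage: %d tests, adjusted alpha = %g; %.1f%% significant\n",
            sum(!is.na(ld$p)), adj_ld,
            100 * mean(ld$p <= attr(adj_ld, "unrounded"), na.rm = TRUE)))
write.csv(ld, "results/ld_tests.csv", row.names = FALSE)

rar <- rarefied_allelic_richness(ds, c(5, 10, 20), n_reps = 1000,
                                 seed = sub_seed(seed, "rar"))
a20 <- rar[rar$N == 20, ]
cat("standardized allelic richness (N = 20):\n")
for (r in order(a20$mean_richness)) {
  cat(sprintf("  %-12s %5.2f +/- %.2f\n", a20$unit[r], a20$mean_richness[r],
              a20$sd_richness[r]))
}
write.csv(as.data.frame(rar), "results/rarefaction.csv", row.names = FALSE)

low <- a20$unit[which.min(a20$mean_richness)]
high <- a20$unit[which.max(a20$mean_richness)]
rd <- richness_difference_test(ds, c(high, low), N = 20, n_reps = 100,
                               n_perm = 199, seed = sub_seed(seed, "rdt"))
cat(sprintf("richness difference %s vs %s at N = 20: %.2f (p = %.4g)\n",
            high, low, rd$statistic, rd$p))
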