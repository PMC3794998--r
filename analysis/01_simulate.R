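#!/usr/bin/env Rscript
# Stage 1: generate the emulated study's raw inputs.
#
# Writes the standard-format files every later stage reads back: a GenePop
# genotype file (11 breeding sites, 354 seals, 9 microsatellite loci), two
# aligned mtDNA FASTA files (COI and control region, 475 bp), a telemetry
# CSV for a tagged cohort, and an hourly haulout CSV.

suppressMessages(library(sealmix))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

st <- study_sites()
cat("study design:", nrow(st), "sites,", sum(st$n_microsat), "genotyped seals\n")
write.csv(st, "results/data/study_design.csv", row.names = FALSE)

ds <- study_genotypes(seed = seed)
write_genepop(ds, "results/data/genotypes.gen",
              title = sprintf("emulated ringed-seal microsatellites (seed %d)", seed))
cat("wrote genotypes.gen:", n_individuals(ds), "individuals x",
    length(ds$loci), "loci\n")

for (region in c("coi", "cr")) {
  aln <- study_mtdna_alignment(region, seed = seed)
  write_fasta_alignment(aln, sprintf("results/data/%s.fasta", region))
  cat(sprintf("wrote %s.fasta: %d sequences x %d bp from %d sites\n",
              region, length(aln$ids), aln$length, length(unique(aln$sites))))
}

# tagged cohort: eight seals with individual seasonal regimes; one tag
# transmits implausible fixes to exercise the speed filter
cohort <- lapply(1:8, function(k) {
  spec <- movement_regime_spec(
    capture_site = c(70.5 + k / 10, -156.8 + k / 2),
    winter_sd_km = c(5, 10, 20, 30, 8, 15, 25, 12)[k],
    summer_mean_km = c(800, 400, 60, 1200, 250, 30, 600, 150)[k],
    summer_sd_km = 0.25 * c(800, 400, 60, 1200, 250, 30, 600, 150)[k],
    obs_per_month = c(10, 8, 6, 12, 9, 7, 10, 8)[k],
    seed = sub_seed(seed, "cohort", k))
  simulate_track(spec, animal_id = sprintf("seal%02d", k),
                 inject_outliers = if (k == 4) 2L else 0L)
})
write_telemetry_csv(cohort, "results/data/telemetry.csv")
cat("wrote telemetry.csv:", sum(vapply(cohort, function(t) nrow(t$records),
                                       numeric(1))), "fixes for 8 seals\n")

haul <- simulate_haulout(45, dry_window = 4:18, base_dry = 0.08,
                         peak_dry = 0.6, seed = sub_seed(seed, "haul"))
haul$timestamp <- format(haul$timestamp, "%Y-%m-%dT%H:%M:%S")
write.csv(haul, "results/data/haulout.csv", row.names = FALSE)
cat("wrote haulout.csv:", nrow(haul) / 24, "days of hourly dry time\n")
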